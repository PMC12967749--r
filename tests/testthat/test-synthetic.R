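test_that("mean surfaces follow the limitation rules", {
  s <- scenario("single_limitation", "N", effects = c(N = 2), mu_c = 1,
                sigma_log = 0)
  expect_equal(mean_surface(s, "N+P"), 2)
  expect_equal(mean_surface(s, "P"), 1)
  s <- scenario("independent_colimitation", c("N", "Fe"),
                effects = c(N = 1.8, Fe = 1.6), mu_c = 1, sigma_log = 0)
  expect_equal(mean_surface(s, "N+Fe"), 2.88)
  expect_equal(mean_surface(s, "N"), 1.8)
  s <- scenario("simultaneous_colimitation", c("N", "Fe"), f_joint = 2,
                mu_c = 1, sigma_log = 0)
  expect_equal(mean_surface(s, "N"), 1)
  expect_equal(mean_surface(s, "N+Fe"), 2)
  expect_equal(mean_surface(s, "N+Fe+Zn"), 2)
  s <- scenario("serial_limitation", c("N", "Fe"), effects = c(N = 2, Fe = 1.5),
                mu_c = 1, sigma_log = 0)
  expect_equal(mean_surface(s, "Fe"), 1)      # secondary alone: no response
  expect_equal(mean_surface(s, "N"), 2)
  expect_equal(mean_surface(s, "N+Fe"), 3)
  # the 2021 Zn+Co cup carries the Zn signal
  s <- scenario("single_limitation", "Zn", effects = c(Zn = 1.7), mu_c = 1,
                sigma_log = 0)
  expect_equal(mean_surface(s, "Zn+Co"), 1.7)
})

test_that("noise-free replicates equal the mean surface and seeds reproduce", {
  d <- design_for_year(2022)
  scn <- scenario("single_limitation", "N", sigma_log = 0)
  bio <- generate_biomass(list(S1 = scn), d, seed = 10, response_vars = "chl_a")
  sub <- bio[bio$treatment == "N+P", ]
  expect_equal(sub$biomass, rep(mean_surface(scn, "N+P"), 5))
  scn2 <- scenario("single_limitation", "N", sigma_log = 0.3)
  b1 <- generate_biomass(list(S1 = scn2), d, seed = 10)
  b2 <- generate_biomass(list(S1 = scn2), d, seed = 10)
  expect_identical(b1$biomass, b2$biomass)
  b3 <- generate_biomass(list(S1 = scn2), d, seed = 11)
  expect_false(identical(b1$biomass, b3$biomass))
})

test_that("extending a cohort never perturbs existing streams", {
  d <- design_for_year(2022)
  scns <- stats::setNames(lapply(1:3, function(i)
    scenario("single_limitation", "P")), c("A", "B", "C"))
  small <- generate_biomass(scns, d, seed = 5, response_vars = "chl_a")
  scns$D <- scenario("no_response")
  big <- generate_biomass(scns, d, seed = 5, response_vars = "chl_a")
  expect_identical(small$biomass,
                   big$biomass[big$stream_id %in% c("A", "B", "C")])
})

test_that("lognormal noise has the stated log-scale moments", {
  d <- design_for_year(2022)
  scn <- scenario("single_limitation", "N", sigma_log = 0.2, n_rep = 4000L)
  bio <- generate_biomass(list(S1 = scn), d, seed = 6, response_vars = "chl_a")
  ctrl <- bio$biomass[bio$treatment == "CTRL"]
  expect_equal(mean(log(ctrl)), log(mean_surface(scn, "CTRL")),
               tolerance = 0.02)
  expect_equal(stats::sd(log(ctrl)), 0.2, tolerance = 0.02)
})

test_that("covariate generation injects MCAR blanks at the configured rate", {
  ids <- sprintf("S%03d", 1:41)  # 41 x 100 = 4100 cells
  gen <- generate_covariates(ids, missing_rate = 0.015,
                             missing_groups = c("water_quality", "landscape",
                                                "soil_metal_decile"),
                             seed = 12)
  n_missing <- sum(is.na(gen$covariates$value))
  expect_gt(n_missing, 30)   # binomial(4100, 0.015): ~62 expected
  expect_lt(n_missing, 100)
  gen2 <- generate_covariates(ids, missing_rate = 0.015,
                              missing_groups = c("water_quality", "landscape",
                                                 "soil_metal_decile"),
                              seed = 12)
  expect_identical(gen2$covariates$value, gen$covariates$value)
})

test_that("planted covariate rules reproduce labels exactly when noiseless", {
  ids <- sprintf("S%03d", 1:60)
  gen <- generate_covariates(ids, rule = fe_rule(), label_noise = 0,
                             missing_rate = 0, seed = 13)
  wide <- covariates_wide(gen$covariates)[ids, ]
  expect_identical(unname(gen$labels),
                   unname(wide$DRP > 5.6 & wide$N_DEP < 3.6))
  # nuisance variables carry no label signal by construction
  expect_lt(abs(stats::cor(wide$WQ05, gen$labels)), 0.35)
  # conditioning on external labels is honoured
  forced <- stats::setNames(rep(c(TRUE, FALSE), 30), ids)
  gen2 <- generate_covariates(ids, rule = fe_rule(), labels = forced,
                              missing_rate = 0, seed = 14)
  expect_identical(gen2$labels, forced)
  bad <- threshold_rule(list(list(var = "NOPE", dir = ">", cut = 1)))
  expect_error(generate_covariates(ids, rule = bad, seed = 1),
               "absent from the generator")
})

test_that("noise-free classification recovers every planted scenario", {
  for (year in c(2021L, 2022L)) {
    d <- design_for_year(year)
    for (tpl in scenario_pool(year)) {
      scn <- scenario(tpl$category, tpl$elements, sigma_log = 0)
      bio <- generate_biomass(list(S1 = scn), d, seed = 1,
                              response_vars = "chl_a")
      cl <- first_classification(bio)
      expect_true(evaluate_recovery(cl, scn),
                  label = paste(year, tpl$category,
                                treatment_label(tpl$elements)))
    }
  }
})

test_that("exact recovery degrades monotonically with replicate noise", {
  rates <- vapply(c(0, 0.15, 0.45), function(s) {
    recovery_rate(n = 120, year = 2022L, sigma_log = s, seed = 17)$rate
  }, numeric(1))
  expect_equal(rates[1], 1)
  expect_true(all(diff(rates) <= 0))
})

test_that("super-additive scenarios exceed the interaction threshold noise-free", {
  d <- design_for_year(2022)
  for (g in c(exp(0.385), exp(0.6), exp(1))) {
    scn <- scenario("independent_colimitation", c("N", "P"), g = g,
                    sigma_log = 0)
    rr <- compute_all_ratios(
      generate_biomass(list(S1 = scn), d, seed = 1, response_vars = "chl_a"))
    irr <- rr$value[rr$label == "NxP"]
    expect_gt(irr, default_thresholds()$theta_interaction)
  }
})
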