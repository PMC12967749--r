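test_that("single contrasts land in the expected taxonomy branches", {
  # strongly N-responsive, no extra combined response: single N limitation
  r <- classify_combination(0.9, 0.1, 1.0, 0.05)
  expect_identical(r$category, "single_limitation")
  expect_identical(r$responding, 1L)
  expect_identical(r$interaction_class, "additive")
  # response only to the combination: simultaneous, super-additive
  r <- classify_combination(0.05, 0.02, 0.8, 0.8)
  expect_identical(r$category, "simultaneous_colimitation")
  expect_identical(r$interaction_class, "super_additive")
  # second element adds onto a met first limitation: serial
  r <- classify_combination(0.5, 0.1, 0.95, NA)
  expect_identical(r$category, "serial_limitation")
  expect_identical(r$primary, 1L)
  expect_identical(r$secondary, 2L)
  expect_identical(r$interaction_class, "not_applicable")
  # both respond singly: independent co-limitation
  expect_identical(classify_combination(0.5, 0.4, 1.0, 0)$category,
                   "independent_colimitation")
  # collapse on one axis counts as a negative response
  expect_identical(classify_combination(-Inf, 0.1, 0.2, NA)$category,
                   "negative_response")
  # exactly at a threshold is not a response (strict inequality)
  expect_identical(classify_combination(0.326, 0.0, 0.3, NA)$category,
                   "no_response")
})

test_that("classification agrees with the decision-table oracle on a dense grid", {
  vals <- c(-Inf, -1, -0.4, -0.327, -0.326, -0.3, 0, 0.3, 0.326, 0.327, 0.9)
  grid <- expand.grid(a = vals, b = vals, ab = vals,
                      irr = c(NA, -0.386, -0.385, 0, 0.385, 0.386))
  got <- mapply(function(a, b, ab, irr) {
    r <- classify_combination(a, b, ab, irr)
    paste(r$category, r$interaction_class)
  }, grid$a, grid$b, grid$ab, grid$irr)
  want <- oracle_classify(grid$a, grid$b, grid$ab, grid$irr)
  expect_identical(unname(got), paste(want$category, want$interaction_class))
})

test_that("raising the stimulation threshold shrinks single-supply evidence", {
  # Monotonicity holds for evidence carried by single-supply stimulation
  # (single, serial, independent labels). The full roll-up is deliberately
  # non-monotone: once single responses drop below a high threshold, a
  # responsive combined treatment reroutes to the simultaneous branch and
  # re-adds its elements -- the taxonomy's reading of combined-only response.
  d <- design_for_year(2022)
  set.seed(31)
  for (i in 1:15) {
    mu <- stats::setNames(exp(stats::rnorm(12, 1, 0.6)), d$treatments)
    rr <- compute_all_ratios(biomass_from_means(mu, d))
    n_limited <- vapply(c(0.1, 0.326, 0.6, 1.2), function(ts) {
      cl <- classify_cohort(rr, default_thresholds(theta_single = ts))[[1]]
      labs <- cl$labels[cl$labels$category != "simultaneous_colimitation", ]
      singles <- cl$ratios[cl$ratios$contrast_type == "single", ]
      one_el <- lengths(lapply(singles$label, parse_treatment)) == 1L
      length(union(
        unlist(lapply(labs$rollup, parse_treatment)),
        singles$label[one_el & singles$status == "ok" & singles$value > ts]))
    }, integer(1))
    expect_true(all(diff(n_limited) <= 0))
  }
  # the simultaneous reroute, concretely:
  r_low <- classify_combination(0.5, 0.4, 0.95,
                                thresholds = default_thresholds(theta_single = 0.326))
  r_high <- classify_combination(0.5, 0.4, 0.95,
                                 thresholds = default_thresholds(theta_single = 0.6))
  expect_identical(r_low$category, "independent_colimitation")
  expect_identical(r_high$category, "simultaneous_colimitation")
})

test_that("serial secondaries are never counted as (co-)limited", {
  d <- design_for_year(2022)
  for (pair in list(c("N", "P"), c("N", "Fe"), c("P", "Fe"),
                    c("Fe", "N"), c("Fe", "P"))) {
    scn <- scenario("serial_limitation", pair, sigma_log = 0)
    bio <- generate_biomass(list(S1 = scn), d, seed = 1, response_vars = "chl_a")
    cl <- first_classification(bio)
    expect_identical(unname(cl$element_status[pair[2]]), "serial_secondary_only")
    expect_identical(unname(cl$element_status[pair[1]]), "limited_or_colimited")
    # appears in serial labels only
    labs <- cl$labels
    in_colim <- vapply(seq_len(nrow(labs)), function(j) {
      labs$category[j] %in% c("independent_colimitation",
                              "simultaneous_colimitation") &&
        pair[2] %in% parse_treatment(labs$rollup[j])
    }, logical(1))
    expect_false(any(in_colim))
  }
})

test_that("simultaneous pair co-limitation marks both elements limited", {
  d <- design_for_year(2022)
  scn <- scenario("simultaneous_colimitation", c("N", "P"), sigma_log = 0)
  cl <- first_classification(
    generate_biomass(list(S1 = scn), d, seed = 2, response_vars = "chl_a"))
  expect_identical(unname(cl$element_status[c("N", "P")]),
                   rep("limited_or_colimited", 2))
  expect_identical(unname(cl$element_status[c("Fe", "Zn")]), rep("none", 2))
})

test_that("element status is a pure roll-up of labels and single ratios", {
  d <- design_for_year(2022)
  set.seed(32)
  for (i in 1:10) {
    mu <- stats::setNames(exp(stats::rnorm(12, 1, 0.7)), d$treatments)
    rr <- compute_all_ratios(biomass_from_means(mu, d))
    cl <- classify_cohort(rr)[[1]]
    # independent recomputation from the exported labels
    ts <- cl$thresholds$theta_single
    singles <- cl$ratios[cl$ratios$contrast_type == "single", ]
    one_el <- lengths(lapply(singles$label, parse_treatment)) == 1L
    limited <- union(
      unlist(lapply(cl$labels$rollup, parse_treatment)),
      singles$label[one_el & singles$status == "ok" & singles$value > ts])
    sec <- cl$labels$secondary[cl$labels$category == "serial_limitation"]
    sec <- sec[sec %in% elements()]
    neg <- singles$label[one_el &
                           ((singles$status == "ok" & singles$value < -ts) |
                              singles$status == "collapse")]
    neg <- union(neg, cl$labels$primary[cl$labels$kind == "added" &
                                          cl$labels$category == "negative_response"])
    for (el in elements()) {
      want <- if (el %in% limited) "limited_or_colimited"
      else if (el %in% sec) "serial_secondary_only"
      else if (el %in% neg) "negative"
      else "none"
      expect_identical(unname(cl$element_status[el]), want)
    }
  }
})

test_that("cohort summaries compute the published arithmetic", {
  d <- design_for_year(2022)
  # 40 streams: 30 N-limited singles, 10 non-responsive
  scns <- c(
    stats::setNames(lapply(1:30, function(i)
      scenario("single_limitation", "N", sigma_log = 0)),
      sprintf("L%02d", 1:30)),
    stats::setNames(lapply(1:10, function(i)
      scenario("no_response", sigma_log = 0)), sprintf("U%02d", 1:10)))
  bio <- generate_biomass(scns, d, seed = 3, response_vars = "chl_a")
  cls <- classify_cohort(compute_all_ratios(bio))
  sm <- summarize_cohort(cls)
  n_row <- sm$elements[sm$elements$element == "N", ]
  expect_equal(n_row$n_limited, 30L)
  expect_equal(n_row$pct_limited, 75)
  expect_equal(n_row$n_single_stimulated, 30L)
  expect_equal(n_row$median_rr, 0.89, tolerance = 1e-9)
  expect_equal(sm$pct_any_response, 75)
  expect_error(summarize_cohort(list()), "empty")
})

test_that("interaction-class distribution reflects the co-limited labels", {
  d <- design_for_year(2022)
  scns <- stats::setNames(lapply(1:6, function(i)
    scenario("independent_colimitation", c("N", "P"), g = exp(0.5),
             sigma_log = 0)), sprintf("S%02d", 1:6))
  bio <- generate_biomass(scns, d, seed = 4, response_vars = "chl_a")
  sm <- summarize_cohort(classify_cohort(compute_all_ratios(bio)))
  ic <- sm$interaction_classes
  expect_identical(ic$interaction_class[which.max(ic$n)], "super_additive")
  expect_equal(ic$pct[ic$interaction_class == "super_additive"], 100)
  expect_true("N+P" %in% sm$combinations$combination)
})

test_that("median response ratios convert to the printed percent scale", {
  expect_equal(round(rr_to_percent(0.326), 1), 38.5)
  expect_equal(round(rr_to_percent(0.89)), 144)
  expect_equal(rr_to_percent(0), 0)
  set.seed(33)
  vals <- stats::rnorm(20, 0.5, 0.4)
  expect_equal(rr_to_percent(vals), 100 * expm1(vals))
})
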