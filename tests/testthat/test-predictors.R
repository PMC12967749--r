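# small grid keeps unit tests quick; the full default grid runs in the
# planted-threshold acceptance check
small_grid <- function(p) {
  expand.grid(mtry = max(1L, floor(p / 3)), maxnodes = NA_integer_,
              ntree = 300L)
}

test_that("PMM leaves complete tables untouched and never fabricates values", {
  ids <- sprintf("S%03d", 1:30)
  gen <- generate_covariates(ids, missing_rate = 0, seed = 21)
  done <- impute_pmm(gen$covariates, seed = 1)
  expect_equal(done$value, gen$covariates$value)

  gen2 <- generate_covariates(ids, missing_rate = 0.05, seed = 21)
  done2 <- impute_pmm(gen2$covariates, seed = 1)
  expect_false(anyNA(done2$value))
  for (v in unique(gen2$covariates$variable_name)) {
    obs <- gen2$covariates$value[gen2$covariates$variable_name == v]
    imp <- done2$value[done2$variable_name == v]
    expect_true(all(imp %in% obs[!is.na(obs)]),
                label = paste("imputed values of", v, "are observed donors"))
  }
  # deterministic under a fixed seed
  done3 <- impute_pmm(gen2$covariates, seed = 1)
  expect_identical(done3$value, done2$value)
})

test_that("k=1 PMM matches a hand-computed regression + nearest-donor oracle", {
  # x-spacing chosen so the two candidate donors are not equidistant in
  # prediction space (an exact tie would make the donor choice fragile)
  x <- c(1, 2, 3, 4, 5.2, 6)
  y <- c(2.1, 3.9, 6.2, 8.1, NA, 12.2)
  wide <- data.frame(X = x, Y = y)
  done <- suppressWarnings(impute_pmm(wide, k = 1, seed = 1))
  # oracle: OLS of Y on X over observed rows, nearest predicted donor
  obs <- which(!is.na(y))
  fit <- coef(stats::lm(y[obs] ~ x[obs]))
  pred <- fit[1] + fit[2] * x
  donor <- obs[which.min(abs(pred[obs] - pred[5]))]
  expect_equal(done$Y[5], y[donor])
  expect_equal(done$Y[obs], y[obs])
})

test_that("sparse variables fall back to the observed median with a warning", {
  wide <- data.frame(X = 1:6, Y = c(1, 2, NA, NA, NA, NA))
  expect_warning(done <- impute_pmm(wide, k = 5, seed = 1), "fewer than k\\+1")
  expect_equal(done$Y[3:6], rep(1.5, 4))
})

test_that("a separable planted rule yields a well-performing model", {
  ids <- sprintf("S%03d", 1:150)
  gen <- generate_covariates(ids, rule = fe_rule(), label_noise = 0,
                             missing_rate = 0, seed = 22)
  wide <- covariates_wide(gen$covariates)[ids, ]
  rep <- fit_presence_model(wide, gen$labels[ids], element = "Fe",
                            grid = small_grid(ncol(wide)), seed = 22)
  expect_true(rep$well_performing)
  expect_gt(rep$test_accuracy, rep$no_information_rate)
  expect_lt(rep$train_misclassification, 0.30)
  # gate recomputes from the stored rates
  expect_identical(rep$well_performing,
                   rep$train_misclassification < 0.30 &&
                     rep$test_accuracy > rep$no_information_rate)
  # the planted drivers dominate the importance ranking
  expect_true(all(c("DRP", "N_DEP") %in% utils::head(rep$importance$variable, 4)))
  # identical inputs + seed give identical reports
  rep2 <- fit_presence_model(wide, gen$labels[ids], element = "Fe",
                             grid = small_grid(ncol(wide)), seed = 22)
  expect_equal(rep2$test_accuracy, rep$test_accuracy)
  expect_identical(rep2$importance, rep$importance)
})

test_that("the no-information rate is the holdout majority proportion", {
  ids <- sprintf("S%03d", 1:40)
  gen <- generate_covariates(ids, missing_rate = 0, seed = 23)
  wide <- covariates_wide(gen$covariates)[ids, ]
  labels <- c(rep(TRUE, 30), rep(FALSE, 10))  # 30 of 40 limited
  rep <- fit_presence_model(wide, labels, grid = small_grid(ncol(wide)),
                            seed = 23)
  # stratified 80/20 split: 6 positive + 2 negative held out
  expect_equal(rep$no_information_rate, 0.75)
  expect_length(rep$test_idx, 8L)
})

test_that("shuffled labels fail the performance gate", {
  ids <- sprintf("S%03d", 1:60)
  gen <- generate_covariates(ids, rule = fe_rule(), missing_rate = 0,
                             seed = 24)
  wide <- covariates_wide(gen$covariates)[ids, ]
  set.seed(99)
  shuffled <- sample(gen$labels)
  rep <- fit_presence_model(wide, shuffled, grid = small_grid(ncol(wide)),
                            seed = 24)
  expect_false(rep$well_performing)
  err <- tryCatch(fit_presence_model(wide, rep(TRUE, 60)),
                  condition = identity)
  expect_s3_class(err, "colimstat_degenerate_labels")
})

test_that("partial dependence stays in [0,1] and ignores irrelevant features", {
  ids <- sprintf("S%03d", 1:150)
  gen <- generate_covariates(ids, rule = fe_rule(), missing_rate = 0,
                             seed = 25)
  wide <- covariates_wide(gen$covariates)[ids, ]
  rep <- fit_presence_model(wide, gen$labels[ids],
                            grid = small_grid(ncol(wide)), seed = 25)
  pd_drp <- partial_dependence(rep, "DRP")
  expect_true(all(pd_drp$prob >= 0 & pd_drp$prob <= 1))
  expect_equal(nrow(pd_drp), 50L)
  pd_noise <- partial_dependence(rep, "SOIL07")
  expect_lt(diff(range(pd_noise$prob)), diff(range(pd_drp$prob)) / 2)
  expect_error(partial_dependence(rep, "NOPE"), "unknown feature")
})

test_that("threshold detection finds the largest jump and its direction", {
  step_up <- data.frame(value = 1:10, prob = c(rep(0.1, 5), rep(0.9, 5)))
  thr <- detect_threshold(step_up)
  expect_true(thr$detected)
  expect_equal(thr$threshold, 5.5)
  expect_identical(thr$direction, "increase")
  step_down <- data.frame(value = 1:10, prob = c(rep(0.8, 3), rep(0.2, 7)))
  thr <- detect_threshold(step_down)
  expect_equal(thr$threshold, 3.5)
  expect_identical(thr$direction, "decrease")
  flat <- data.frame(value = 1:10, prob = rep(0.4, 10))
  expect_false(detect_threshold(flat)$detected)
  expect_error(detect_threshold(flat[1:2, ]), "at least 3")
})

test_that("threshold screening counts rule-satisfying streams", {
  wide <- data.frame(DRP = c(8, 2, 9, 6, 1), N_DEP = c(2, 2, 5, 3, 1),
                     row.names = sprintf("S%d", 1:5))
  res <- screen_by_thresholds(wide, fe_rule())
  expect_equal(res$n, 2L)
  expect_setequal(res$stream_ids, c("S1", "S4"))
  all_res <- screen_by_thresholds(wide, threshold_rule(list()))
  expect_equal(all_res$n, 5L)
  labs <- stats::setNames(c(TRUE, FALSE, TRUE, TRUE, FALSE), rownames(wide))
  res2 <- screen_by_thresholds(wide, fe_rule(), labels = labs)
  expect_equal(unname(res2$crosstab["TRUE", "TRUE"]), 2L)
  bad <- threshold_rule(list(list(var = "NOPE", dir = ">", cut = 0)))
  expect_error(screen_by_thresholds(wide, bad), "unknown variable")
})
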