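#' Impute missing covariates by predictive mean matching
#'
#' Type-1 PMM: for each variable with missing cells, a linear regression on
#' a basis of fully observed covariates (screened to the columns most
#' correlated with the target when the basis is wider than the data support)
#' predicts both observed and missing cells; each missing cell receives the
#' observed value of one of the \code{k} donors whose predictions lie
#' nearest its own. Imputed values are therefore always values actually
#' observed for that variable. Deterministic under a fixed seed. A variable
#' with fewer than \code{k + 1} observed values falls back to the observed
#' median, with a warning; a variable missing more than 10\% of its cells
#' is imputed normally but flagged with a warning.
#'
#' @param x A \code{covariate_table} or wide data.frame (rows = streams).
#' @param k Donor count (default 5).
#' @param seed Integer seed for donor draws.
#' @return Completed object of the same shape as \code{x}.
#' @export
impute_pmm <- function(x, k = 5L, seed = 1L) {
  if (k < 1L) stop("donor count k must be >= 1", call. = FALSE)
  if (inherits(x, "covariate_table")) {
    wide <- covariates_wide(x)
    done <- impute_pmm_wide(wide, k, seed)
    out <- as.data.frame(x)
    idx <- cbind(match(out$stream_id, rownames(done)),
                 match(out$variable_name, colnames(done)))
    out$value <- as.matrix(done)[idx]
    return(covariate_table(out))
  }
  impute_pmm_wide(as.data.frame(x), k, seed)
}

impute_pmm_wide <- function(wide, k, seed) {
  set.seed(stream_seed(seed, 2L))
  complete_vars <- names(wide)[colSums(is.na(wide)) == 0L]
  targets <- names(wide)[colSums(is.na(wide)) > 0L]
  for (v in targets) {
    y <- wide[[v]]
    obs <- which(!is.na(y)); mis <- which(is.na(y))
    if (length(obs) < k + 1L) {
      warning("variable '", v, "' has fewer than k+1 observed values; ",
              "falling back to observed median")
      wide[[v]][mis] <- stats::median(y[obs])
      next
    }
    if (mean(is.na(y)) > 0.10) {
      warning("variable '", v, "' is missing ",
              sprintf("%.0f%%", 100 * mean(is.na(y))),
              " of its values; donor matching may be unreliable")
    }
    basis <- pmm_basis(wide, complete_vars, y, obs)
    fit <- stats::lm.fit(x = cbind(1, as.matrix(basis[obs, , drop = FALSE])),
                         y = y[obs])
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pred <- drop(cbind(1, as.matrix(basis)) %*% beta)
    for (m in mis) {
      d <- abs(pred[obs] - pred[m])
      donors <- obs[order(d)][seq_len(k)]
      pick <- if (k == 1L) donors else donors[sample.int(k, 1L)]
      wide[[v]][m] <- y[pick]
    }
  }
  wide
}

# at most n_obs/2 (and 15) basis columns, screened by |cor| with the target
pmm_basis <- function(wide, complete_vars, y, obs) {
  basis <- wide[, complete_vars, drop = FALSE]
  basis <- basis[, vapply(basis, function(col) stats::sd(col) > 0, logical(1)),
                 drop = FALSE]
  p_max <- max(1L, min(15L, floor(length(obs) / 2)))
  if (ncol(basis) > p_max) {
    cors <- abs(vapply(basis, function(col) {
      suppressWarnings(stats::cor(col[obs], y[obs]))
    }, numeric(1)))
    cors[is.na(cors)] <- 0
    basis <- basis[, order(-cors)[seq_len(p_max)], drop = FALSE]
  }
  basis
}

#' Default random-forest tuning grid
#'
#' Three tuned parameters: candidate variables per split
#' (sqrt(p), p/3, p/10), maximum terminal nodes (4, 8, 16, unlimited) and
#' tree count (250, 500, 1000).
#'
#' @param p Number of predictor columns.
#' @return data.frame of candidate combinations (NA maxnodes = unlimited).
#' @export
default_tuning_grid <- function(p) {
  expand.grid(
    mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3), floor(p / 10)))),
    maxnodes = c(4L, 8L, 16L, NA_integer_),
    ntree = c(250L, 500L, 1000L)
  )
}

#' Fit a tuned presence/absence limitation model
#'
#' Random-forest classifier for presence/absence of (co-)limitation of one
#' element. Streams are split 80/20 into training and holdout sets
#' (stratified by label); the tuning grid is searched by out-of-bag error on
#' the training set; the selected model is scored on the holdout. The model
#' is well-performing when its training (out-of-bag) misclassification rate
#' is below 30\% and its holdout accuracy exceeds the no-information rate
#' (the holdout's majority-class proportion).
#'
#' @param features data.frame of numeric predictors, one row per stream
#'   (complete; impute first).
#' @param labels Logical (or 0/1) presence of limitation per stream.
#' @param element Element name carried into the report.
#' @param grid Tuning grid (see \code{\link{default_tuning_grid}}).
#' @param split_fraction Training fraction (default 0.8).
#' @param seed Integer seed controlling the split and each fit.
#' @param importance_type "impurity" (mean decrease in Gini, default) or
#'   "permutation".
#' @return Object of class \code{predictor_report}: element, selected tuning
#'   values, train_misclassification, test_accuracy, no_information_rate,
#'   well_performing, importance (ranked data.frame), the fitted model and
#'   the split indices.
#' @export
fit_presence_model <- function(features, labels, element = "Fe",
                               grid = default_tuning_grid(ncol(features)),
                               split_fraction = 0.8, seed = 1L,
                               importance_type = c("impurity", "permutation")) {
  importance_type <- match.arg(importance_type)
  if (nrow(features) < 10L) {
    stop("need at least 10 streams to fit a presence/absence model",
         call. = FALSE)
  }
  if (anyNA(features)) stop("features contain missing values; impute first",
                            call. = FALSE)
  y <- factor(ifelse(as.logical(labels), "present", "absent"),
              levels = c("absent", "present"))
  if (length(unique(y)) < 2L) {
    cond <- structure(class = c("colimstat_degenerate_labels", "error",
                                "condition"),
                      list(message = "labels contain a single class",
                           call = sys.call()))
    stop(cond)
  }
  set.seed(stream_seed(seed, 3L))
  train_idx <- sort(unlist(lapply(levels(y), function(lv) {
    i <- which(y == lv)
    sample(i, max(1L, round(split_fraction * length(i))))
  })))
  test_idx <- setdiff(seq_len(nrow(features)), train_idx)
  x_tr <- features[train_idx, , drop = FALSE]; y_tr <- y[train_idx]
  oob <- numeric(nrow(grid))
  for (j in seq_len(nrow(grid))) {
    set.seed(stream_seed(seed, 100L + j))
    args <- list(x = x_tr, y = y_tr, mtry = grid$mtry[j],
                 ntree = grid$ntree[j])
    if (!is.na(grid$maxnodes[j])) args$maxnodes <- grid$maxnodes[j]
    fit <- do.call(randomForest::randomForest, args)
    oob[j] <- fit$err.rate[grid$ntree[j], "OOB"]
  }
  best <- which.min(oob)
  set.seed(stream_seed(seed, 100L + best))
  args <- list(x = x_tr, y = y_tr, mtry = grid$mtry[best],
               ntree = grid$ntree[best],
               importance = importance_type == "permutation")
  if (!is.na(grid$maxnodes[best])) args$maxnodes <- grid$maxnodes[best]
  model <- do.call(randomForest::randomForest, args)
  train_misclass <- unname(model$err.rate[grid$ntree[best], "OOB"])
  pred <- stats::predict(model, features[test_idx, , drop = FALSE])
  test_accuracy <- mean(pred == y[test_idx])
  nir <- max(table(y[test_idx])) / length(test_idx)
  imp <- randomForest::importance(
    model, type = if (importance_type == "permutation") 1 else 2)
  importance <- data.frame(variable = rownames(imp),
                           importance = imp[, 1], row.names = NULL,
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$importance), ]
  structure(
    list(element = element,
         tuning = grid[best, , drop = FALSE],
         train_misclassification = train_misclass,
         test_accuracy = test_accuracy,
         no_information_rate = unname(nir),
         well_performing = train_misclass < 0.30 && test_accuracy > nir,
         importance = importance,
         model = model, features = features, labels = y,
         train_idx = train_idx, test_idx = test_idx),
    class = "predictor_report")
}

#' @export
print.predictor_report <- function(x, ...) {
  cat("Random-forest limitation model:", x$element, "\n")
  cat(sprintf("  tuning: mtry=%d, maxnodes=%s, ntree=%d\n", x$tuning$mtry,
              ifelse(is.na(x$tuning$maxnodes), "unlimited",
                     x$tuning$maxnodes), x$tuning$ntree))
  cat(sprintf("  training misclassification (OOB): %.1f%%\n",
              100 * x$train_misclassification))
  cat(sprintf("  holdout accuracy: %.1f%% (no-information rate %.1f%%)\n",
              100 * x$test_accuracy, 100 * x$no_information_rate))
  cat("  well-performing:", x$well_performing, "\n")
  cat("  top predictors:",
      paste(utils::head(x$importance$variable, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Partial-dependence curve of a fitted model
#'
#' Average predicted probability of limitation presence as one feature is
#' swept over a grid (50 evenly spaced points between the feature's 2.5th
#' and 97.5th percentiles, avoiding tail artefacts) with all other features
#' held at their observed values.
#'
#' @param report A \code{predictor_report} (or list with \code{model} and
#'   \code{features}).
#' @param feature Feature name.
#' @param grid_points Number of grid points (default 50).
#' @return data.frame of class \code{pd_curve} with columns \code{value},
#'   \code{prob}.
#' @export
partial_dependence <- function(report, feature, grid_points = 50L) {
  features <- report$features
  if (!feature %in% names(features)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  v <- features[[feature]]
  lo <- stats::quantile(v, 0.025); hi <- stats::quantile(v, 0.975)
  if (hi <= lo) {
    warning("feature '", feature, "' is (near-)constant; flat curve")
    grid <- rep(lo, max(3L, grid_points))
  } else {
    grid <- seq(lo, hi, length.out = grid_points)
  }
  prob <- vapply(grid, function(g) {
    d <- features
    d[[feature]] <- g
    mean(stats::predict(report$model, d, type = "prob")[, "present"])
  }, numeric(1))
  structure(data.frame(value = unname(grid), prob = prob),
            feature = feature, class = c("pd_curve", "data.frame"))
}

#' Detect a response threshold in a partial-dependence curve
#'
#' The threshold is the midpoint of the grid interval with the largest
#' absolute first difference of the curve; the sign of that difference gives
#' the direction (probability of limitation increasing or decreasing with
#' the feature).
#'
#' @param curve A \code{pd_curve} (>= 3 grid points).
#' @return List with \code{detected}, \code{threshold}, \code{direction}
#'   ("increase"/"decrease") and \code{jump} (the probability change).
#' @export
detect_threshold <- function(curve) {
  if (nrow(curve) < 3L) stop("curve needs at least 3 grid points", call. = FALSE)
  d <- diff(curve$prob)
  if (max(abs(d)) < 1e-8) {
    return(list(detected = FALSE, threshold = NA_real_,
                direction = NA_character_, jump = 0))
  }
  i <- which.max(abs(d))
  list(detected = TRUE,
       threshold = (curve$value[i] + curve$value[i + 1L]) / 2,
       direction = if (d[i] > 0) "increase" else "decrease",
       jump = d[i])
}

#' Screen streams against threshold rules
#'
#' Counts and identifies the streams satisfying a conjunction of
#' variable/direction/cut clauses, optionally cross-tabulated against a
#' limitation label.
#'
#' @param covariates A \code{covariate_table} or wide data.frame.
#' @param rule A \code{threshold_rule}.
#' @param labels Optional logical limitation labels (named by stream or in
#'   row order).
#' @return List with \code{n}, \code{stream_ids}, and (when labels are
#'   given) \code{crosstab} of rule x limitation.
#' @export
screen_by_thresholds <- function(covariates, rule, labels = NULL) {
  wide <- if (inherits(covariates, "covariate_table")) {
    covariates_wide(covariates)
  } else as.data.frame(covariates)
  hold <- rule_holds(rule, wide)
  hold[is.na(hold)] <- FALSE
  out <- list(n = sum(hold), stream_ids = rownames(wide)[hold])
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[rownames(wide)]
    out$crosstab <- table(meets_rule = hold, limited = as.logical(labels))
  }
  out
}
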