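# fixed 6-significant-digit formatting so pipeline outputs are byte-stable
fmt_num <- function(x) {
  ifelse(is.na(x), "", formatC(x, digits = 6, format = "g"))
}

write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a synthetic NDS dataset bundle
#'
#' Generates a scenario cohort, its replicate biomass table, a covariate
#' table labelled by the iron rule, and a ground-truth sidecar, writing all
#' of them under \code{out_dir}. Re-running with the same configuration and
#' seed reproduces the bundle byte-for-byte.
#'
#' @param config List: \code{n_streams}, \code{year}, \code{seed},
#'   \code{sigma_log}, \code{n_rep}, \code{label_noise},
#'   \code{missing_rate}. Missing entries take the defaults shown in
#'   \code{\link{sample_cohort}} / \code{\link{generate_covariates}}.
#' @param out_dir Output directory (created if needed).
#' @return Invisible list of written paths plus the cohort objects.
#' @export
run_simulate <- function(config = list(), out_dir) {
  cfg <- utils::modifyList(
    list(n_streams = 41L, year = 2022L, seed = 1L, sigma_log = 0.2,
         n_rep = 5L, label_noise = 0.05, missing_rate = 0.015), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- design_for_year(cfg$year)
  scns <- sample_cohort(cfg$n_streams, year = cfg$year, seed = cfg$seed,
                        sigma_log = cfg$sigma_log, n_rep = cfg$n_rep)
  bio <- generate_biomass(scns, design, seed = cfg$seed)
  fe_limited <- vapply(scns, function(s) {
    s$category %in% c("single_limitation", "serial_limitation",
                      COLIMITATION_CATEGORIES) && "Fe" %in% s$elements &&
      !(s$category == "serial_limitation" && s$elements[2] == "Fe")
  }, logical(1))
  cov <- generate_covariates(names(scns), rule = fe_rule(),
                             labels = fe_limited,
                             label_noise = cfg$label_noise,
                             missing_rate = cfg$missing_rate, seed = cfg$seed)
  truth <- data.frame(
    stream_id = names(scns),
    category = vapply(scns, `[[`, character(1), "category"),
    # scenario order kept (serial lists primary first), not canonicalised
    elements = vapply(scns, function(s) paste(s$elements, collapse = "+"),
                      character(1)),
    fe_label = as.integer(cov$labels[names(scns)]),
    stringsAsFactors = FALSE)
  paths <- list(
    biomass = file.path(out_dir, "biomass.csv"),
    covariates = file.path(out_dir, "covariates.csv"),
    truth = file.path(out_dir, "truth.csv"))
  write_biomass(bio, paths$biomass)
  write_covariates(cov$covariates, paths$covariates)
  utils::write.csv(truth, paths$truth, row.names = FALSE, quote = FALSE)
  invisible(c(paths, list(design = design, scenarios = scns)))
}

#' Classify a biomass table and summarise the cohort
#'
#' Runs the ratio and classification pipeline on a biomass CSV and writes
#' the ratio table, per-contrast classification labels, the per-element
#' presence/absence matrix and the cohort summary. Excluded streams are
#' reported with their reasons.
#'
#' @param biomass_path CSV in the \code{\link{read_biomass}} schema.
#' @param year Design year the records belong to.
#' @param out_dir Output directory.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @param response_var Response variable for the cohort summary and the
#'   presence/absence export (default chl_a).
#' @return Invisible list: classifications, summary, written paths.
#' @export
run_classify <- function(biomass_path, year, out_dir,
                         thresholds = default_thresholds(),
                         response_var = "chl_a") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- design_for_year(year)
  bio <- read_biomass(biomass_path, design)
  flags <- analysability(bio)
  if (!any(flags$analysable)) {
    stop("no analysable streams in ", biomass_path, call. = FALSE)
  }
  excluded <- flags[!flags$analysable, ]
  for (i in seq_len(nrow(excluded))) {
    message("excluding ", excluded$stream_id[i], " / ",
            excluded$response_var[i], ": ", excluded$reason[i])
  }
  ratios <- compute_all_ratios(bio)
  cls <- classify_cohort(ratios, thresholds)
  rv_cls <- Filter(function(cl) cl$response_var == response_var, cls)
  summary <- summarize_cohort(rv_cls, thresholds)
  labels_df <- do.call(rbind, lapply(cls, function(cl) {
    if (is.null(cl$labels)) return(NULL)
    cbind(stream_id = cl$stream_id, response_var = cl$response_var,
          cl$labels)
  }))
  status_df <- do.call(rbind, lapply(cls, function(cl) {
    data.frame(stream_id = cl$stream_id, response_var = cl$response_var,
               t(cl$element_status), stringsAsFactors = FALSE)
  }))
  paths <- list(
    ratios = file.path(out_dir, "ratios.csv"),
    classification = file.path(out_dir, "classification.csv"),
    element_status = file.path(out_dir, "element_status.csv"),
    presence = file.path(out_dir, "element_presence.csv"),
    summary = file.path(out_dir, "summary.csv"))
  write_table(as.data.frame(ratios), paths$ratios)
  write_table(labels_df, paths$classification)
  write_table(status_df, paths$element_status)
  write_table(element_presence(rv_cls), paths$presence)
  el <- summary$elements
  el$pct_limited <- round(el$pct_limited)
  write_table(el, paths$summary)
  invisible(list(classifications = cls, summary = summary, paths = paths,
                 ratios = ratios))
}

#' Fit limitation predictor models from classification exports
#'
#' Imputes the covariate table, joins it to the per-element
#' presence/absence labels, fits one tuned random-forest model per
#' requested element, and writes each model report as JSON.
#' Partial-dependence curves (and detected thresholds) are computed and
#' written for well-performing models only.
#'
#' @param presence_path CSV written by \code{\link{run_classify}}
#'   (stream_id plus one 0/1 column per element).
#' @param covariates_path Long-format covariate CSV.
#' @param out_dir Output directory.
#' @param elements Elements to model (default those in the presence file).
#' @param seed Integer seed.
#' @param top_predictors Number of partial-dependence curves per model.
#' @param grid Optional tuning grid override.
#' @return Invisible named list of \code{predictor_report}s.
#' @export
run_predict <- function(presence_path, covariates_path, out_dir,
                        elements = NULL, seed = 1L, top_predictors = 2L,
                        grid = NULL) {
  if (!file.exists(presence_path) || !file.exists(covariates_path)) {
    stop("missing upstream artefacts; run the classify and simulate steps ",
         "first (need ", presence_path, " and ", covariates_path, ")",
         call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  presence <- utils::read.csv(presence_path, stringsAsFactors = FALSE)
  if (is.null(elements)) elements <- setdiff(names(presence), "stream_id")
  unknown <- setdiff(elements, names(presence))
  if (length(unknown) > 0L) {
    stop("element(s) never classified: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cov <- read_covariates(covariates_path)
  wide <- covariates_wide(impute_pmm(cov, seed = seed))
  wide <- wide[presence$stream_id, , drop = FALSE]
  reports <- list()
  for (el in elements) {
    labels <- presence[[el]] == 1L
    rep_el <- tryCatch({
      fit_presence_model(wide, labels, element = el,
                         grid = if (is.null(grid))
                           default_tuning_grid(ncol(wide)) else grid,
                         seed = seed)
    }, colimstat_degenerate_labels = function(e) NULL)
    if (is.null(rep_el)) {
      message("skipping ", el, ": labels contain a single class")
      next
    }
    reports[[el]] <- rep_el
    report_json <- list(
      element = el,
      tuning = as.list(rep_el$tuning),
      train_misclassification = rep_el$train_misclassification,
      test_accuracy = rep_el$test_accuracy,
      no_information_rate = rep_el$no_information_rate,
      well_performing = rep_el$well_performing,
      top_predictors = utils::head(rep_el$importance$variable, 10))
    if (rep_el$well_performing) {
      top <- utils::head(rep_el$importance$variable, top_predictors)
      thresholds <- list()
      for (feat in top) {
        curve <- partial_dependence(rep_el, feat)
        write_table(as.data.frame(curve),
                    file.path(out_dir, paste0("pd_", el, "_", feat, ".csv")))
        thr <- detect_threshold(curve)
        thresholds[[feat]] <- thr[c("detected", "threshold", "direction")]
      }
      report_json$thresholds <- thresholds
    }
    jsonlite::write_json(report_json,
                         file.path(out_dir, paste0("model_", el, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(reports)
}
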