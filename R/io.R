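COVARIATE_GROUPS <- c("water_quality", "landscape", "soil_metal_decile")

#' Construct and validate a biomass table
#'
#' Cup-level biomass records from an NDS deployment. Treatment labels are
#' canonicalised; unknown labels are rejected. Analysability is assessed per
#' stream x response variable against the supplied design: a stream is
#' analysable when every treatment present has at least two recovered cups
#' and at least 70\% of the design's cups were recovered.
#'
#' @param records data.frame with columns \code{stream_id},
#'   \code{response_var}, \code{treatment}, \code{replicate}, \code{biomass}.
#' @param design An \code{nds_design}.
#' @param units Biomass units carried as metadata (never converted; the
#'   analysis is ratio-based and scale-invariant).
#' @return data.frame of class \code{biomass_table} with canonical treatment
#'   labels and attributes \code{design}, \code{units} and
#'   \code{analysability} (per stream x response_var flags with reasons).
#' @export
biomass_table <- function(records, design, units = "ug/cm2") {
  req <- c("stream_id", "response_var", "treatment", "replicate", "biomass")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    stop("biomass table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[, req]
  records$biomass <- as.numeric(records$biomass)
  if (anyNA(records$biomass)) {
    stop("biomass values must be numeric and present", call. = FALSE)
  }
  if (any(records$biomass < 0)) {
    stop("negative biomass value(s) found; biomass must be >= 0", call. = FALSE)
  }
  bad_rv <- setdiff(unique(records$response_var), RESPONSE_VARS)
  if (length(bad_rv) > 0L) {
    stop("unknown response variable(s): ", paste(bad_rv, collapse = ", "),
         call. = FALSE)
  }
  records$treatment <- vapply(records$treatment, treatment_label, character(1),
                              USE.NAMES = FALSE)
  unknown <- setdiff(unique(records$treatment), design$treatments)
  if (length(unknown) > 0L) {
    stop("treatment(s) not in the ", design$year_variant, " design: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(records,
            design = design, units = units,
            analysability = assess_analysability(records, design),
            class = c("biomass_table", "data.frame"))
}

# per stream x response_var: >=2 cups per present treatment and >=70% of the
# design's cups recovered
assess_analysability <- function(records, design) {
  cells <- unique(records[, c("stream_id", "response_var")])
  total_cups <- length(design$treatments) * design$replicates_target
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- records[records$stream_id == cells$stream_id[i] &
                     records$response_var == cells$response_var[i], ]
    reps <- table(sub$treatment)
    reasons <- character(0)
    if (any(reps < 2L)) {
      reasons <- c(reasons, paste0("<2 replicates for: ",
                                   paste(names(reps)[reps < 2L], collapse = ", ")))
    }
    recovered <- nrow(sub) / total_cups
    if (recovered < 0.70) {
      reasons <- c(reasons, sprintf("only %.0f%% of design cups recovered",
                                    100 * recovered))
    }
    data.frame(stream_id = cells$stream_id[i],
               response_var = cells$response_var[i],
               analysable = length(reasons) == 0L,
               reason = paste(reasons, collapse = "; "))
  })
  do.call(rbind, out)
}

#' Analysability flags of a biomass table
#'
#' @param x A \code{biomass_table}.
#' @return data.frame with columns stream_id, response_var, analysable, reason.
#' @export
analysability <- function(x) attr(x, "analysability")

#' Read a biomass CSV
#'
#' @param path CSV with columns stream_id, response_var, treatment,
#'   replicate, biomass (comma-separated, UTF-8, header row, "." decimal).
#' @param design An \code{nds_design} the records are validated against.
#' @return A \code{biomass_table}.
#' @export
read_biomass <- function(path, design) {
  biomass_table(utils::read.csv(path, stringsAsFactors = FALSE), design)
}

#' Write a biomass table to CSV
#'
#' Round-trips bit-exactly through \code{read_biomass} (values written with
#' full precision).
#'
#' @param x A \code{biomass_table}.
#' @param path Output path.
#' @export
write_biomass <- function(x, path) {
  df <- as.data.frame(x)
  df$biomass <- format(df$biomass, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format covariate CSV
#'
#' Stream covariates in long format: one row per stream x variable, grouped
#' into water-quality analytes, watershed landscape metrics and soil-metal
#' concentration deciles. Blank cells are missing values; any non-numeric
#' non-blank cell is an error, as is a soil-metal decile outside 1..10.
#'
#' @param path CSV with columns stream_id, variable_name, value, group.
#' @return data.frame of class \code{covariate_table} with attribute
#'   \code{missingness}: per-variable missing fractions plus the overall
#'   fraction.
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  covariate_table(df)
}

#' @rdname read_covariates
#' @param records data.frame with columns stream_id, variable_name, value
#'   (numeric or blank/NA), group.
#' @export
covariate_table <- function(records) {
  req <- c("stream_id", "variable_name", "value", "group")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    stop("covariate table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- as.data.frame(records)[, req]
  bad_grp <- setdiff(unique(records$group), COVARIATE_GROUPS)
  if (length(bad_grp) > 0L) {
    stop("unknown covariate group(s): ", paste(bad_grp, collapse = ", "),
         call. = FALSE)
  }
  raw <- trimws(as.character(records$value))
  blank <- is.na(raw) | raw == ""
  num <- suppressWarnings(as.numeric(raw))
  if (any(!blank & is.na(num))) {
    bad <- records$variable_name[!blank & is.na(num)][1]
    stop("non-numeric covariate value for variable '", bad, "'", call. = FALSE)
  }
  records$value <- ifelse(blank, NA_real_, num)
  dec <- records$group == "soil_metal_decile" & !is.na(records$value)
  if (any(dec & (records$value < 1 | records$value > 10))) {
    stop("soil-metal deciles must lie in 1..10", call. = FALSE)
  }
  miss_by_var <- tapply(is.na(records$value), records$variable_name, mean)
  structure(records,
            missingness = list(
              by_variable = miss_by_var[order(names(miss_by_var))],
              overall = mean(is.na(records$value))
            ),
            class = c("covariate_table", "data.frame"))
}

#' Missingness summary of a covariate table
#'
#' @param x A \code{covariate_table}.
#' @return List with \code{by_variable} (named fractions) and \code{overall}.
#' @export
missingness <- function(x) attr(x, "missingness")

#' Write a covariate table to CSV
#'
#' @param x A \code{covariate_table}.
#' @param path Output path.
#' @export
write_covariates <- function(x, path) {
  df <- as.data.frame(x)
  df$value <- ifelse(is.na(df$value), "",
                     format(df$value, digits = 17, trim = TRUE, scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pivot a covariate table to a wide feature matrix
#'
#' @param x A \code{covariate_table}.
#' @return data.frame, one row per stream (rownames = stream_id), one column
#'   per variable.
#' @export
covariates_wide <- function(x) {
  streams <- sort(unique(x$stream_id))
  vars <- sort(unique(x$variable_name))
  m <- matrix(NA_real_, length(streams), length(vars),
              dimnames = list(streams, vars))
  m[cbind(match(x$stream_id, streams), match(x$variable_name, vars))] <- x$value
  as.data.frame(m)
}
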