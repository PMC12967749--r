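#' Log response ratio
#'
#' Effect size of an enrichment treatment relative to the unamended control:
#' \code{ln(mean_treatment / mean_control)}, on arithmetic treatment means.
#'
#' @param mean_treatment Mean biomass in the treatment (> 0).
#' @param mean_control Mean biomass in the control (> 0).
#' @return Log response ratio (numeric).
#' @examples
#' log_rr(2, 1)  # ln 2
#' @export
log_rr <- function(mean_treatment, mean_control) {
  if (!is.finite(mean_treatment) || mean_treatment <= 0) {
    stop_undefined_ratio("treatment")
  }
  if (!is.finite(mean_control) || mean_control <= 0) {
    stop_undefined_ratio("control")
  }
  log(mean_treatment / mean_control)
}

stop_undefined_ratio <- function(side) {
  cond <- structure(
    class = c("colimstat_undefined_ratio", "error", "condition"),
    list(message = paste0("log response ratio undefined: non-positive ",
                          side, " mean"),
         call = sys.call(-1), side = side)
  )
  stop(cond)
}

stop_degenerate_expectation <- function(expectation) {
  cond <- structure(
    class = c("colimstat_degenerate_expectation", "error", "condition"),
    list(message = sprintf(
      "additive expectation is non-positive (%.6g); interaction ratio undefined",
      expectation),
      call = sys.call(-1), expectation = expectation)
  )
  stop(cond)
}

#' Interaction response ratio for a two-element treatment
#'
#' Compares the combined treatment to the additive expectation built from
#' the single-element responses above control,
#' \code{ln( Y_AB / (Y_A + Y_B - Y_C) )}. Positive values indicate a
#' super-additive (synergistic) response, negative values sub-additive.
#'
#' @param mean_ab Combined-treatment mean (> 0).
#' @param mean_a,mean_b Single-treatment means (> 0).
#' @param mean_control Control mean (> 0).
#' @return Interaction response ratio (numeric). Errors with a
#'   degenerate-expectation condition when \code{Y_A + Y_B - Y_C <= 0}.
#' @export
interaction_rr_pair <- function(mean_ab, mean_a, mean_b, mean_control) {
  for (m in c(mean_ab, mean_a, mean_b, mean_control)) {
    if (!is.finite(m) || m <= 0) stop_undefined_ratio("treatment")
  }
  expectation <- mean_a + mean_b - mean_control
  if (expectation <= 0) stop_degenerate_expectation(expectation)
  log(mean_ab / expectation)
}

#' Interaction response ratio for a three-element treatment
#'
#' The three-element biomass is compared to the additive combination of an
#' appropriate two-element treatment and the remaining single element
#' (e.g. N+Fe+Zn against additive N+Fe and Zn):
#' \code{ln( Y_ABX / (Y_AB + Y_X - Y_C) )}.
#'
#' @param mean_abx Three-element treatment mean (> 0).
#' @param mean_ab Two-element block mean (> 0).
#' @param mean_x Single-element mean (> 0).
#' @param mean_control Control mean (> 0).
#' @return Interaction response ratio (numeric).
#' @export
interaction_rr_triple <- function(mean_abx, mean_ab, mean_x, mean_control) {
  interaction_rr_pair(mean_abx, mean_ab, mean_x, mean_control)
}

#' Marginal response to adding an element on top of a combination
#'
#' For combinations whose extra element is never supplied singly (Mo and Ni
#' ride on P+Fe), co-limitation evidence is the marginal log ratio
#' \code{ln(Y_ABX / Y_AB)} of the three-element treatment over its base.
#'
#' @param mean_abx Three-element treatment mean (> 0).
#' @param mean_ab Base two-element treatment mean (> 0).
#' @return Marginal log response ratio.
#' @export
added_element_rr <- function(mean_abx, mean_ab) {
  if (!is.finite(mean_abx) || mean_abx <= 0) stop_undefined_ratio("treatment")
  if (!is.finite(mean_ab) || mean_ab <= 0) stop_undefined_ratio("control")
  log(mean_abx / mean_ab)
}

#' Interaction-contrast registry for a design
#'
#' Enumerates the contrasts used to assess non-additivity: the N x P,
#' N x Fe (2022 only) and P x Fe pairs; the (N+P) x Fe and (N+Fe) x Zn
#' triples (in 2021, where the N+Fe arm was not deployed, the block response
#' for the Zn triple is synthesised from additivity of the N and Fe
#' singles); and the added-element contrasts P+Fe+Mo and P+Fe+Ni over P+Fe.
#'
#' @param design An \code{nds_design}.
#' @return data.frame with columns id, type (pair/triple/added), a (first
#'   axis: single element or block label), b (second axis), combined,
#'   synth_block.
#' @export
contrast_registry <- function(design) {
  y2022 <- design$year_variant == 2022L
  reg <- list(
    list(id = "NxP", type = "pair", a = "N", b = "P",
         combined = "N+P", synth_block = FALSE),
    if (y2022) list(id = "NxFe", type = "pair", a = "N", b = "Fe",
                    combined = "N+Fe", synth_block = FALSE),
    list(id = "PxFe", type = "pair", a = "P", b = "Fe",
         combined = "P+Fe", synth_block = FALSE),
    list(id = "(N+P)xFe", type = "triple", a = "N+P", b = "Fe",
         combined = "N+P+Fe", synth_block = FALSE),
    list(id = "(N+Fe)xZn", type = "triple", a = "N+Fe", b = "Zn",
         combined = "N+Fe+Zn", synth_block = !y2022),
    list(id = "(P+Fe)+Mo", type = "added", a = "P+Fe", b = "Mo",
         combined = "P+Fe+Mo", synth_block = FALSE),
    list(id = "(P+Fe)+Ni", type = "added", a = "P+Fe", b = "Ni",
         combined = "P+Fe+Ni", synth_block = FALSE)
  )
  reg <- reg[!vapply(reg, is.null, logical(1))]
  do.call(rbind, lapply(reg, as.data.frame))
}

#' Per-treatment arithmetic means
#'
#' Aggregates a biomass table to treatment means per stream x response
#' variable, mapping treatments to cross-year slots (Zn+Co -> Zn). Only
#' treatments with at least two replicates are retained.
#'
#' @param x A \code{biomass_table}.
#' @return data.frame with columns stream_id, response_var, treatment
#'   (slot label), n, mean.
#' @export
treatment_means <- function(x) {
  df <- as.data.frame(x)
  df$treatment <- vapply(df$treatment, treatment_slot, character(1),
                         USE.NAMES = FALSE)
  agg <- stats::aggregate(biomass ~ stream_id + response_var + treatment,
                          data = df,
                          FUN = function(v) c(n = length(v), mean = mean(v)))
  out <- data.frame(stream_id = agg$stream_id, response_var = agg$response_var,
                    treatment = agg$treatment,
                    n = as.integer(agg$biomass[, "n"]),
                    mean = agg$biomass[, "mean"],
                    stringsAsFactors = FALSE)
  out[out$n >= 2L, , drop = FALSE]
}

#' Compute all response and interaction ratios
#'
#' For every analysable stream x response variable: the log response ratio
#' of each non-control treatment against the control, and the interaction
#' (or added-element) ratio of every contrast in the design's registry.
#' Degenerate cases are carried as status markers, never silently dropped:
#' \describe{
#'   \item{collapse}{treatment mean 0 with positive control (conceptually
#'     RR = -Inf; classified as a negative response)}
#'   \item{degenerate}{additive expectation <= 0}
#'   \item{missing_arm}{a treatment the contrast needs is absent or has
#'     fewer than two replicates}
#' }
#' Streams x response variables whose control mean is zero or missing are
#' excluded and listed in the \code{unclassifiable} attribute with a reason.
#'
#' @param x A \code{biomass_table}.
#' @param design Defaults to the design attached to \code{x}.
#' @return data.frame of class \code{rr_set} with columns stream_id,
#'   response_var, contrast_type (single/interaction/added), label, value,
#'   status; attributes \code{registry}, \code{unclassifiable}.
#' @export
compute_all_ratios <- function(x, design = attr(x, "design")) {
  means <- treatment_means(x)
  registry <- contrast_registry(design)
  flags <- assess_analysability(as.data.frame(x), design)
  cells <- flags[flags$analysable, c("stream_id", "response_var")]
  rows <- list()
  unclass <- list()
  for (i in seq_len(nrow(cells))) {
    sid <- cells$stream_id[i]; rv <- cells$response_var[i]
    m <- means[means$stream_id == sid & means$response_var == rv, ]
    mu <- stats::setNames(m$mean, m$treatment)
    if (!CONTROL_LABEL %in% names(mu) || mu[[CONTROL_LABEL]] <= 0) {
      unclass[[length(unclass) + 1L]] <- data.frame(
        stream_id = sid, response_var = rv,
        reason = "control mean zero or missing")
      next
    }
    mu_c <- mu[[CONTROL_LABEL]]
    for (trt in setdiff(names(mu), CONTROL_LABEL)) {
      if (mu[[trt]] == 0) {
        rows[[length(rows) + 1L]] <- rr_row(sid, rv, "single", trt,
                                            NA_real_, "collapse")
      } else {
        rows[[length(rows) + 1L]] <- rr_row(sid, rv, "single", trt,
                                            log_rr(mu[[trt]], mu_c), "ok")
      }
    }
    for (j in seq_len(nrow(registry))) {
      rows[[length(rows) + 1L]] <- contrast_row(registry[j, ], mu, mu_c, sid, rv)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stream_id = character(0), response_var = character(0),
               contrast_type = character(0), label = character(0),
               value = numeric(0), status = character(0))
  structure(out, registry = registry,
            unclassifiable = if (length(unclass)) do.call(rbind, unclass) else NULL,
            thresholds_design = design,
            class = c("rr_set", "data.frame"))
}

rr_row <- function(sid, rv, type, label, value, status) {
  data.frame(stream_id = sid, response_var = rv, contrast_type = type,
             label = label, value = value, status = status,
             stringsAsFactors = FALSE)
}

# one interaction/added contrast for one stream x response variable
contrast_row <- function(entry, mu, mu_c, sid, rv) {
  type <- if (entry$type == "added") "added" else "interaction"
  get <- function(l) if (l %in% names(mu)) mu[[l]] else NA_real_
  comb <- get(entry$combined)
  if (entry$type == "added") {
    base <- get(entry$a)
    if (is.na(comb) || is.na(base)) {
      return(rr_row(sid, rv, type, entry$id, NA_real_, "missing_arm"))
    }
    if (comb == 0) return(rr_row(sid, rv, type, entry$id, NA_real_, "collapse"))
    if (base == 0) return(rr_row(sid, rv, type, entry$id, NA_real_, "degenerate"))
    return(rr_row(sid, rv, type, entry$id, added_element_rr(comb, base), "ok"))
  }
  if (entry$synth_block) {
    parts <- parse_treatment(entry$a)
    part_means <- vapply(parts, get, numeric(1))
    block <- if (anyNA(part_means)) NA_real_ else sum(part_means) - mu_c
  } else {
    block <- get(entry$a)
  }
  single <- get(entry$b)
  if (is.na(comb) || is.na(block) || is.na(single)) {
    return(rr_row(sid, rv, type, entry$id, NA_real_, "missing_arm"))
  }
  if (comb == 0) return(rr_row(sid, rv, type, entry$id, NA_real_, "collapse"))
  expectation <- block + single - mu_c
  if (expectation <= 0 || block <= 0 || single <= 0) {
    return(rr_row(sid, rv, type, entry$id, NA_real_, "degenerate"))
  }
  rr_row(sid, rv, type, entry$id, log(comb / expectation), "ok")
}
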