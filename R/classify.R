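LIMITATION_CATEGORIES <- c("no_response", "negative_response",
                           "single_limitation", "serial_limitation",
                           "independent_colimitation",
                           "simultaneous_colimitation")

COLIMITATION_CATEGORIES <- c("independent_colimitation",
                             "simultaneous_colimitation")

#' Classify one two-axis enrichment contrast
#'
#' Maps the response ratios of a registered contrast (two single elements,
#' or a two-element block paired with a single metal) to the limitation
#' taxonomy. With \code{S_X := RR_X > theta_single}:
#' \itemize{
#'   \item both axes stimulate -> independent co-limitation;
#'   \item exactly one stimulates and the combined treatment adds a further
#'     response (\code{RR_combined - RR_single > theta_single}) -> serial
#'     limitation (primary = the responding axis); otherwise single
#'     limitation;
#'   \item neither stimulates but the combination does
#'     (\code{RR_combined > theta_single}) -> simultaneous co-limitation;
#'   \item otherwise a negative response if any ratio falls below
#'     \code{-theta_single}, else no response.
#' }
#' The interaction class is super-additive when the interaction response
#' ratio exceeds \code{theta_interaction}, sub-additive below its negative,
#' additive between, and not applicable when the interaction ratio is
#' degenerate or unavailable. All threshold comparisons are strict. A
#' biomass collapse (treatment mean 0) enters as \code{-Inf}.
#'
#' @param rr_a,rr_b Log response ratios of the two axes (\code{-Inf}
#'   allowed for collapse; NA treated as no signal on that axis).
#' @param rr_combined Log response ratio of the combined treatment.
#' @param irr Interaction response ratio, or NA when degenerate.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @return List with \code{category}, \code{responding} (integer axis
#'   indices 1/2 whose single RR exceeded the threshold), \code{primary},
#'   \code{secondary} (axis indices, serial only) and
#'   \code{interaction_class}.
#' @export
classify_combination <- function(rr_a, rr_b, rr_combined, irr = NA_real_,
                                 thresholds = default_thresholds()) {
  ts <- thresholds$theta_single
  ti <- thresholds$theta_interaction
  val <- function(x) if (is.null(x) || is.na(x)) -Inf else x
  a <- val(rr_a); b <- val(rr_b); comb <- val(rr_combined)
  s_a <- a > ts; s_b <- b > ts
  primary <- NA_integer_; secondary <- NA_integer_
  if (s_a && s_b) {
    category <- "independent_colimitation"
  } else if (s_a || s_b) {
    resp <- if (s_a) a else b
    extra <- is.finite(comb) && (comb - resp > ts)
    if (extra) {
      category <- "serial_limitation"
      primary <- if (s_a) 1L else 2L
      secondary <- if (s_a) 2L else 1L
    } else {
      category <- "single_limitation"
    }
  } else if (comb > ts) {
    category <- "simultaneous_colimitation"
  } else if (a < -ts || b < -ts || comb < -ts) {
    category <- "negative_response"
  } else {
    category <- "no_response"
  }
  interaction_class <-
    if (is.na(irr) || !is.finite(irr)) "not_applicable"
    else if (irr > ti) "super_additive"
    else if (irr < -ti) "sub_additive"
    else "additive"
  list(category = category,
       responding = c(1L, 2L)[c(s_a, s_b)],
       primary = primary, secondary = secondary,
       interaction_class = interaction_class)
}

#' Classify one stream x response variable
#'
#' Labels every registered contrast of a stream's ratio set and rolls the
#' labels up to an element-level limitation status. An element is
#' \code{limited_or_colimited} when it appears in a single-limitation label,
#' as the primary of a serial label, in an independent or simultaneous
#' co-limitation label (for triples, the single-metal axis; block elements
#' earn their status through their own pair contrast, and a simultaneous
#' triple counts all three elements only when no registered sub-pair already
#' explains the signal), when its own single-supply response ratio exceeds
#' the threshold, or (for the added-element Mo/Ni contrasts) when the
#' marginal ratio over the responding base combination exceeds the
#' threshold. Serial secondaries are never counted as (co-)limited; they are
#' recorded as \code{serial_secondary_only}. Elements whose single-supply
#' ratio falls below the negative threshold are \code{negative} unless a
#' limited status was earned in another contrast.
#'
#' @param ratios An \code{rr_set} (rows for a single stream x response
#'   variable, e.g. one cell of \code{\link{compute_all_ratios}} output).
#' @param thresholds See \code{\link{default_thresholds}}.
#' @param registry Contrast registry; defaults to the one attached to
#'   \code{ratios}.
#' @return Object of class \code{stream_classification}: list with
#'   \code{stream_id}, \code{response_var}, \code{labels} (one row per
#'   contrast), \code{element_status} (named character over all elements),
#'   \code{ratios}, \code{thresholds}, \code{audit}.
#' @export
classify_stream <- function(ratios, thresholds = default_thresholds(),
                            registry = attr(ratios, "registry")) {
  cell <- unique(as.data.frame(ratios)[, c("stream_id", "response_var")])
  if (nrow(cell) != 1L) {
    stop("classify_stream expects ratios for exactly one stream x response variable",
         call. = FALSE)
  }
  rr <- as.data.frame(ratios)
  # single-treatment RR lookup; collapse -> -Inf
  singles <- rr[rr$contrast_type == "single", ]
  rr_of <- function(label) {
    i <- match(label, singles$label)
    if (is.na(i)) return(NA_real_)
    if (singles$status[i] == "collapse") return(-Inf)
    singles$value[i]
  }
  labels <- lapply(seq_len(nrow(registry)), function(j) {
    classify_contrast(registry[j, ], rr, rr_of, thresholds)
  })
  labels <- do.call(rbind, labels)
  # suppress the roll-up of a simultaneous triple explained by a sub-pair
  for (j in which(labels$kind == "triple" &
                  labels$category == "simultaneous_colimitation")) {
    trip_els <- parse_treatment(labels$elements[j])
    pairs <- labels$kind == "pair" &
      labels$category %in% COLIMITATION_CATEGORIES
    explained <- any(vapply(which(pairs), function(k) {
      all(parse_treatment(labels$elements[k]) %in% trip_els)
    }, logical(1)))
    if (explained) labels$rollup[j] <- ""
  }
  element_status <- roll_up_elements(labels, singles, thresholds)
  structure(
    list(stream_id = cell$stream_id, response_var = cell$response_var,
         labels = labels, element_status = element_status,
         ratios = rr, thresholds = thresholds, audit = ""),
    class = "stream_classification")
}

# classify one registry entry; returns a one-row labels data.frame
classify_contrast <- function(entry, rr, rr_of, thresholds) {
  ts <- thresholds$theta_single
  irow <- rr[rr$label == entry$id &
               rr$contrast_type %in% c("interaction", "added"), ]
  irr <- if (nrow(irow) == 1L && irow$status == "ok") irow$value else NA_real_
  lab <- function(category, elements, primary = "", secondary = "",
                  interaction_class = "not_applicable", rollup = "") {
    data.frame(contrast = entry$id, kind = entry$type, category = category,
               elements = treatment_label(elements), primary = primary,
               secondary = secondary, interaction_class = interaction_class,
               rollup = if (length(rollup) && any(nzchar(rollup)))
                 treatment_label(rollup[nzchar(rollup)]) else "",
               stringsAsFactors = FALSE)
  }
  if (entry$type == "added") {
    base_rr <- rr_of(entry$a)
    els <- c(parse_treatment(entry$a), entry$b)
    added <- if (nrow(irow) == 1L && irow$status %in% c("ok", "collapse")) {
      if (irow$status == "collapse") -Inf else irow$value
    } else NA_real_
    if (is.na(added)) return(lab("no_response", els))
    if (added > ts && !is.na(base_rr) && base_rr > ts) {
      return(lab("independent_colimitation", els, rollup = entry$b))
    }
    if (added > ts) {
      return(lab("simultaneous_colimitation", els, rollup = els))
    }
    if (added < -ts) return(lab("negative_response", els, primary = entry$b))
    return(lab("no_response", els))
  }
  a_els <- parse_treatment(entry$a)  # block elements for triples
  b_el <- entry$b
  els <- c(a_els, b_el)
  rr_a <- if (entry$synth_block) {
    parts <- vapply(a_els, rr_of, numeric(1))
    if (anyNA(parts)) NA_real_ else {
      expect <- sum(exp(parts)) - (length(parts) - 1)
      if (expect > 0) log(expect) else NA_real_
    }
  } else rr_of(entry$a)
  rr_b <- rr_of(entry$b)
  rr_comb <- rr_of(entry$combined)
  cls <- classify_combination(rr_a, rr_b, rr_comb, irr, thresholds)
  axes <- list(a_els, b_el)
  is_triple <- entry$type == "triple"
  rollup <- switch(cls$category,
    single_limitation = {
      resp <- axes[[cls$responding]]
      if (is_triple && cls$responding == 1L) character(0) else resp
    },
    serial_limitation = {
      prim <- axes[[cls$primary]]
      if (is_triple && cls$primary == 1L) character(0) else prim
    },
    independent_colimitation = if (is_triple) b_el else els,
    simultaneous_colimitation = els,  # triples may be suppressed by caller
    character(0))
  primary <- if (!is.na(cls$primary))
    treatment_label(axes[[cls$primary]]) else ""
  secondary <- if (!is.na(cls$secondary))
    treatment_label(axes[[cls$secondary]]) else ""
  lab(cls$category, els, primary = primary, secondary = secondary,
      interaction_class = cls$interaction_class, rollup = rollup)
}

# element-level status from the labels plus single-supply evidence
roll_up_elements <- function(labels, singles, thresholds) {
  ts <- thresholds$theta_single
  limited <- unique(unlist(lapply(labels$rollup, parse_treatment)))
  single_rr <- ifelse(singles$status == "collapse", -Inf, singles$value)
  single_els <- lapply(singles$label, parse_treatment)
  one_el <- lengths(single_els) == 1L
  stim <- unlist(single_els[one_el & !is.na(single_rr) & single_rr > ts])
  limited <- union(limited, stim)
  # block secondaries ("N+P") are ambiguous at element level and resolved by
  # the block's own pair contrast; only single-element secondaries recorded
  sec_lab <- labels$secondary[labels$category == "serial_limitation"]
  sec_els <- lapply(sec_lab, parse_treatment)
  secondaries <- unique(unlist(sec_els[lengths(sec_els) == 1L]))
  neg <- unlist(single_els[one_el & !is.na(single_rr) & single_rr < -ts])
  neg <- union(neg, unlist(lapply(
    labels$primary[labels$category == "negative_response" &
                     labels$kind == "added"], parse_treatment)))
  status <- stats::setNames(rep("none", length(ELEMENT_ORDER)), ELEMENT_ORDER)
  status[ELEMENT_ORDER %in% neg] <- "negative"
  status[ELEMENT_ORDER %in% secondaries] <- "serial_secondary_only"
  status[ELEMENT_ORDER %in% limited] <- "limited_or_colimited"
  status
}

#' Classify every stream x response variable of a ratio set
#'
#' @param ratios An \code{rr_set} from \code{\link{compute_all_ratios}}.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @return List of \code{stream_classification} objects; cells excluded as
#'   unclassifiable appear with all-\code{none} status and an audit reason.
#' @export
classify_cohort <- function(ratios, thresholds = default_thresholds()) {
  registry <- attr(ratios, "registry")
  cells <- unique(as.data.frame(ratios)[, c("stream_id", "response_var")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- ratios[ratios$stream_id == cells$stream_id[i] &
                    ratios$response_var == cells$response_var[i], ]
    attr(sub, "registry") <- registry
    classify_stream(sub, thresholds, registry = registry)
  })
  unclass_cells <- attr(ratios, "unclassifiable")
  if (!is.null(unclass_cells)) {
    extra <- lapply(seq_len(nrow(unclass_cells)), function(i) {
      structure(
        list(stream_id = unclass_cells$stream_id[i],
             response_var = unclass_cells$response_var[i],
             labels = NULL,
             element_status = stats::setNames(
               rep("none", length(ELEMENT_ORDER)), ELEMENT_ORDER),
             ratios = NULL, thresholds = thresholds,
             audit = unclass_cells$reason[i]),
        class = "stream_classification")
    })
    out <- c(out, extra)
  }
  out
}

#' Convert a log response ratio to a percent biomass change
#'
#' @param rr Log response ratio.
#' @return Percent change, \code{100 * (exp(rr) - 1)}; e.g. the 0.326
#'   stimulation threshold corresponds to +38.5\%.
#' @export
rr_to_percent <- function(rr) 100 * (exp(rr) - 1)

#' Summarise (co-)limitation across a cohort of streams
#'
#' Cohort roll-up for one response variable: per-element counts and percents
#' of streams (co-)limited, counts stimulated by single supply, the median
#' single-supply response ratio among limited streams (marginal added-element
#' ratio for Mo/Ni, which were never supplied singly), co-limitation counts
#' per element combination, and the distribution of interaction classes
#' among co-limitation labels.
#'
#' @param classifications List of \code{stream_classification} objects for a
#'   single response variable.
#' @param thresholds See \code{\link{default_thresholds}}.
#' @return Object of class \code{cohort_summary}: list with
#'   \code{n_streams}, \code{pct_any_response}, \code{elements},
#'   \code{combinations}, \code{interaction_classes}.
#' @export
summarize_cohort <- function(classifications, thresholds = default_thresholds()) {
  if (length(classifications) == 0L) stop("empty cohort", call. = FALSE)
  rv <- unique(vapply(classifications, `[[`, character(1), "response_var"))
  if (length(rv) != 1L) {
    stop("summarize_cohort works on one response variable at a time; got: ",
         paste(rv, collapse = ", "), call. = FALSE)
  }
  ts <- thresholds$theta_single
  n <- length(classifications)
  status <- t(vapply(classifications, `[[`, character(length(ELEMENT_ORDER)),
                     "element_status"))
  colnames(status) <- ELEMENT_ORDER
  limited <- status == "limited_or_colimited"
  # per-stream single-supply RR per element (added-element ratio for Mo/Ni)
  rr_single <- vapply(ELEMENT_ORDER, function(el) {
    vapply(classifications, function(cl) {
      if (is.null(cl$ratios)) return(NA_real_)
      r <- cl$ratios
      i <- which(r$contrast_type == "single" & r$label == el)
      if (length(i) == 1L) {
        return(if (r$status[i] == "collapse") -Inf else r$value[i])
      }
      i <- which(r$contrast_type == "added" &
                   grepl(paste0("\\+", el, "$"), r$label))
      if (length(i) == 1L && r$status[i] == "ok") r$value[i] else NA_real_
    }, numeric(1))
  }, numeric(n))
  elements_df <- data.frame(
    element = ELEMENT_ORDER,
    n_limited = colSums(limited),
    pct_limited = 100 * colSums(limited) / n,
    n_single_stimulated = vapply(ELEMENT_ORDER, function(el) {
      sum(!is.na(rr_single[, el]) & rr_single[, el] > ts &
            vapply(classifications, function(cl) {
              !is.null(cl$ratios) &&
                any(cl$ratios$contrast_type == "single" & cl$ratios$label == el)
            }, logical(1)))
    }, integer(1)),
    median_rr = vapply(ELEMENT_ORDER, function(el) {
      v <- rr_single[limited[, el], el]
      v <- v[is.finite(v)]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  # combination co-limitation counts and interaction classes
  colim_labels <- do.call(rbind, lapply(classifications, function(cl) {
    if (is.null(cl$labels)) return(NULL)
    keep <- cl$labels$category %in% COLIMITATION_CATEGORIES
    if (!any(keep)) return(NULL)
    cbind(stream_id = cl$stream_id, cl$labels[keep, , drop = FALSE])
  }))
  if (is.null(colim_labels) || nrow(colim_labels) == 0L) {
    combinations <- data.frame(combination = character(0),
                               n_colimited = integer(0))
    interaction_classes <- data.frame(interaction_class = character(0),
                                      n = integer(0), pct = numeric(0))
  } else {
    tab <- table(colim_labels$elements)
    combinations <- data.frame(combination = names(tab),
                               n_colimited = as.integer(tab),
                               stringsAsFactors = FALSE)
    itab <- table(colim_labels$interaction_class)
    interaction_classes <- data.frame(
      interaction_class = names(itab), n = as.integer(itab),
      pct = 100 * as.integer(itab) / sum(itab), stringsAsFactors = FALSE)
  }
  structure(
    list(n_streams = n, response_var = rv,
         pct_any_response = 100 * mean(rowSums(limited) > 0),
         elements = elements_df, combinations = combinations,
         interaction_classes = interaction_classes,
         thresholds = thresholds),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort (co-)limitation summary: ", x$n_streams, " streams, ",
      x$response_var, "\n", sep = "")
  cat(sprintf("  streams with any (co-)limitation response: %.0f%%\n",
              x$pct_any_response))
  df <- x$elements[x$elements$n_limited > 0 | x$elements$n_single_stimulated > 0, ]
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-2s (co-)limited in %d streams (%.0f%%), single-supply stimulation in %d; median RR %.2f (%+.0f%%)\n",
                df$element[i], df$n_limited[i], df$pct_limited[i],
                df$n_single_stimulated[i], df$median_rr[i],
                rr_to_percent(df$median_rr[i])))
  }
  if (nrow(x$combinations)) {
    cat("  co-limited combinations:\n")
    for (i in order(-x$combinations$n_colimited)) {
      cat(sprintf("    %-10s %d streams\n", x$combinations$combination[i],
                  x$combinations$n_colimited[i]))
    }
  }
  invisible(x)
}

#' Element presence/absence matrix from classifications
#'
#' Wide per-stream presence/absence of (co-)limitation, the response labels
#' consumed by the environmental-predictor stage.
#'
#' @param classifications List of \code{stream_classification} objects (one
#'   response variable).
#' @param elements Elements to report (default N, P, Fe, Zn).
#' @return data.frame: stream_id plus one 0/1 column per element.
#' @export
element_presence <- function(classifications, elements = c("N", "P", "Fe", "Zn")) {
  out <- data.frame(
    stream_id = vapply(classifications, `[[`, character(1), "stream_id"),
    stringsAsFactors = FALSE)
  for (el in elements) {
    out[[el]] <- vapply(classifications, function(cl) {
      as.integer(cl$element_status[[el]] == "limited_or_colimited")
    }, integer(1))
  }
  out
}
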