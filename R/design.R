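#' @keywords internal
"_PACKAGE"

# Canonical element order used everywhere a treatment label is printed.
ELEMENT_ORDER <- c("N", "P", "Fe", "Zn", "Co", "Mo", "Ni")

RESPONSE_VARS <- c("chl_a", "diatom", "cyanobacteria", "chlorophyte")

CONTROL_LABEL <- "CTRL"

#' Known elements of the NDS treatment system
#'
#' The closed set of elements that can appear in a treatment: the
#' macronutrients N and P and the trace metals Fe, Zn, Co, Mo and Ni.
#' Co is only deployed alongside Zn in 2021-style designs (the two metals
#' substitute for each other at the active site of carbonic anhydrase).
#'
#' @return Character vector of element symbols in canonical order.
#' @export
elements <- function() ELEMENT_ORDER

#' Response variables measured on each cup
#'
#' @return Character vector: lab-extracted chlorophyll a plus the three
#'   field-fluorometry pigment groups (diatom, cyanobacteria, chlorophyte).
#' @export
response_vars <- function() RESPONSE_VARS

assert_elements <- function(x) {
  bad <- setdiff(x, ELEMENT_ORDER)
  if (length(bad) > 0L) {
    stop("unknown element(s): ", paste(bad, collapse = ", "),
         " (valid: ", paste(ELEMENT_ORDER, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(x)
}

#' Canonical treatment label from an element set
#'
#' A treatment is identified by its element set alone. The label joins the
#' elements with "+" in the fixed order N, P, Fe, Zn, Co, Mo, Ni; the empty
#' set is the unamended control, labelled "CTRL". Canonicalisation is
#' idempotent and insensitive to input order ("Fe+N" -> "N+Fe").
#'
#' @param elements Character vector of element symbols (possibly empty), or a
#'   single "+"-joined label.
#' @return Single canonical label string.
#' @examples
#' treatment_label(c("Fe", "N"))  # "N+Fe"
#' treatment_label(character(0))  # "CTRL"
#' @export
treatment_label <- function(elements) {
  els <- parse_treatment(elements)
  if (length(els) == 0L) return(CONTROL_LABEL)
  paste(ELEMENT_ORDER[ELEMENT_ORDER %in% els], collapse = "+")
}

#' Parse a treatment label into its element set
#'
#' @param label A "+"-joined label (or "CTRL"), or an element character
#'   vector (returned canonicalised).
#' @return Character vector of elements in canonical order (length 0 for the
#'   control).
#' @export
parse_treatment <- function(label) {
  if (length(label) == 1L && (is.na(label) || identical(label, CONTROL_LABEL))) {
    return(character(0))
  }
  els <- if (length(label) == 1L) strsplit(label, "+", fixed = TRUE)[[1]] else label
  els <- unique(trimws(els))
  els <- els[nzchar(els) & els != CONTROL_LABEL]
  if (length(els) > 3L) {
    stop("treatments contain at most three elements, got: ",
         paste(els, collapse = "+"), call. = FALSE)
  }
  assert_elements(els)
  ELEMENT_ORDER[ELEMENT_ORDER %in% els]
}

#' Cross-year treatment slot
#'
#' The 2021 deployments supplied Co together with Zn because the two metals
#' play interchangeable roles in carbonic anhydrase; for cross-year
#' comparison the Zn+Co treatment occupies the "Zn" slot, with Co treated as
#' a passenger element. All other treatments map to themselves.
#'
#' @param label Canonical treatment label.
#' @return Slot label with any passenger Co removed.
#' @export
treatment_slot <- function(label) {
  els <- parse_treatment(label)
  if ("Co" %in% els && "Zn" %in% els) els <- setdiff(els, "Co")
  treatment_label(els)
}

#' Experimental design for a deployment year
#'
#' Both variants test 11 single and combined N, P and metal treatments plus
#' an unamended control, with two year-specific differences: 2021 supplied
#' Co alongside Zn (the Zn+Co treatment fills the Zn slot) and lacked the
#' N+Fe treatment, which was only deployed in 2022.
#'
#' @param year Deployment year, 2021 or 2022.
#' @param replicates_target Cups per treatment the design aims to deploy
#'   (default 5, one per L-bar).
#' @return An object of class \code{nds_design}: list with
#'   \code{year_variant}, \code{treatments} (canonical labels, control
#'   first), \code{replicates_target}.
#' @examples
#' design_for_year(2022)$treatments
#' @export
design_for_year <- function(year, replicates_target = 5L) {
  if (!year %in% c(2021L, 2022L)) {
    stop("design is defined for years 2021 and 2022 only", call. = FALSE)
  }
  if (replicates_target < 1L) stop("replicates_target must be positive", call. = FALSE)
  base <- list(
    character(0),
    "N", "P", "Fe",
    c("N", "P"), c("P", "Fe"),
    c("N", "P", "Fe"), c("N", "Fe", "Zn"),
    c("P", "Fe", "Ni"), c("P", "Fe", "Mo")
  )
  if (year == 2022L) {
    trts <- c(base, list("Zn", c("N", "Fe")))
  } else {
    trts <- c(base, list(c("Zn", "Co")))
  }
  labels <- vapply(trts, treatment_label, character(1))
  labels <- c(CONTROL_LABEL, sort_labels(setdiff(labels, CONTROL_LABEL)))
  structure(
    list(year_variant = as.integer(year), treatments = labels,
         replicates_target = as.integer(replicates_target)),
    class = "nds_design"
  )
}

# order labels by number of elements, then canonical element order
sort_labels <- function(labels) {
  key <- vapply(labels, function(l) {
    els <- parse_treatment(l)
    idx <- match(els, ELEMENT_ORDER)
    sprintf("%d-%s", length(els), paste(sprintf("%02d", idx), collapse = "."))
  }, character(1))
  labels[order(key)]
}

#' @export
print.nds_design <- function(x, ...) {
  cat("NDS experimental design, ", x$year_variant, " variant\n", sep = "")
  cat("  treatments (", length(x$treatments), "): ",
      paste(x$treatments, collapse = ", "), "\n", sep = "")
  cat("  target replicates per treatment: ", x$replicates_target, "\n", sep = "")
  invisible(x)
}

#' Default classification thresholds
#'
#' Effect-size cut-offs for the limitation classification: a log response
#' ratio above \code{theta_single} = 0.326 (a +38.5\% biomass increase)
#' indicates stimulation by a treatment, and an interaction response ratio
#' above \code{theta_interaction} = 0.385 indicates significant positive
#' non-additivity. Both comparisons are strict.
#'
#' @param theta_single Single-treatment stimulation threshold (log scale).
#' @param theta_interaction Non-additivity threshold (log scale).
#' @return List with components \code{theta_single}, \code{theta_interaction}.
#' @export
default_thresholds <- function(theta_single = 0.326, theta_interaction = 0.385) {
  if (theta_single <= 0 || theta_interaction <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  list(theta_single = theta_single, theta_interaction = theta_interaction)
}
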