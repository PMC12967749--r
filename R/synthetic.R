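# Baseline control means per response variable (ug/cm2 for chl_a; the
# fluorometry pigment groups sit lower, as in field data).
RV_BASELINE_SCALE <- c(chl_a = 1, diatom = 0.4, cyanobacteria = 0.2,
                       chlorophyte = 0.1)

#' Default multiplicative effect sizes
#'
#' Macronutrient stimulation defaults to exp(0.89) (a +144\% response, the
#' magnitude typical of N limitation) and trace-metal stimulation to
#' exp(0.6) (+82\%), echoing the weaker growth responses metals elicit.
#'
#' @param elements Character vector of elements.
#' @return Named numeric vector of multiplicative effects f > 1.
#' @export
default_effects <- function(elements) {
  stats::setNames(ifelse(elements %in% c("N", "P"), exp(0.89), exp(0.6)),
                  elements)
}

#' Construct a synthetic limitation scenario
#'
#' A scenario fixes the ground-truth response surface of one stream:
#' which elements limit biomass, by how much, and how they interact.
#'
#' @param category One of no_response, negative_response, single_limitation,
#'   serial_limitation (elements ordered primary, secondary),
#'   independent_colimitation, simultaneous_colimitation.
#' @param elements Limiting elements (empty for no_response; one for
#'   single/negative; ordered pair for serial).
#' @param effects Named multiplicative effects per element; defaults to
#'   \code{\link{default_effects}} (exp(-0.6) for negative scenarios).
#' @param g Interaction multiplier applied when all limiting elements are
#'   supplied together (independent scenarios; > 1 super-additive,
#'   < 1 sub-additive, 1 additive).
#' @param f_joint Joint effect for simultaneous scenarios (default exp(0.89)).
#' @param mu_c Control-mean chlorophyll a, ug/cm2 (default 5).
#' @param sigma_log Lognormal replicate noise SD on the log scale
#'   (default 0.2).
#' @param n_rep Replicates per treatment (default 5).
#' @return Object of class \code{nds_scenario}.
#' @export
scenario <- function(category, elements = character(0), effects = NULL,
                     g = 1, f_joint = exp(0.89), mu_c = 5,
                     sigma_log = 0.2, n_rep = 5L) {
  category <- match.arg(category, LIMITATION_CATEGORIES)
  elements <- as.character(elements)
  assert_elements(elements)
  n_el <- length(elements)
  ok <- switch(category,
    no_response = n_el == 0L,
    negative_response = n_el == 1L,
    single_limitation = n_el == 1L,
    serial_limitation = n_el == 2L,
    independent_colimitation = n_el >= 2L,
    simultaneous_colimitation = n_el >= 2L)
  if (!ok) {
    stop("category ", category, " is incompatible with ", n_el, " element(s)",
         call. = FALSE)
  }
  if (is.null(effects)) {
    effects <- if (category == "negative_response") {
      stats::setNames(rep(exp(-0.6), n_el), elements)
    } else {
      default_effects(elements)
    }
  }
  if (category != "negative_response" && any(effects <= 1)) {
    stop("stimulation effects must exceed 1", call. = FALSE)
  }
  if (mu_c <= 0 || sigma_log < 0 || n_rep < 1L) {
    stop("invalid scenario parameters", call. = FALSE)
  }
  structure(list(category = category, elements = elements, effects = effects,
                 g = g, f_joint = f_joint, mu_c = mu_c,
                 sigma_log = sigma_log, n_rep = as.integer(n_rep)),
            class = "nds_scenario")
}

#' Expected mean biomass of a treatment under a scenario
#'
#' Deterministic (noise-free) response surface:
#' \describe{
#'   \item{single}{\code{mu_c * f_E} when E is supplied, else \code{mu_c}.}
#'   \item{serial (E1 -> E2)}{\code{mu_c * f_E1} when E1 supplied, times
#'     \code{f_E2} only when both are.}
#'   \item{independent}{\code{mu_c} times the product of effects of the
#'     limiting elements supplied, times \code{g} when all of them are.}
#'   \item{simultaneous}{\code{mu_c * f_joint} only when every limiting
#'     element is supplied.}
#'   \item{negative}{\code{mu_c * f_E} with \code{f_E < 1} when supplied.}
#' }
#'
#' @param scn An \code{nds_scenario}.
#' @param treatment Treatment label or element vector.
#' @return Expected mean biomass (at the chl_a baseline).
#' @export
mean_surface <- function(scn, treatment) {
  trt <- parse_treatment(treatment)
  mu <- scn$mu_c
  els <- scn$elements
  supplied <- intersect(els, trt)
  switch(scn$category,
    no_response = mu,
    negative_response = ,
    single_limitation = mu * prod(scn$effects[supplied]),
    serial_limitation = {
      if (els[1] %in% trt) {
        mu * scn$effects[[els[1]]] *
          (if (els[2] %in% trt) scn$effects[[els[2]]] else 1)
      } else mu
    },
    independent_colimitation =
      mu * prod(scn$effects[supplied]) *
        (if (all(els %in% trt)) scn$g else 1),
    simultaneous_colimitation =
      if (all(els %in% trt)) mu * scn$f_joint else mu
  )
}

# deterministic per-stream seed below 2^31
stream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629)
}

#' Generate replicate biomass for a cohort of scenarios
#'
#' Replicate cup biomass is the scenario's expected mean surface times
#' multiplicative lognormal noise, \code{exp(N(0, sigma_log))}, so biomass
#' is strictly positive and log-scale effects are exact logs of the planted
#' multipliers. The four response variables share the stream's limitation
#' structure but differ in baseline and carry independent noise. Each stream
#' draws from a deterministic substream of the global seed, so extending a
#' cohort never perturbs existing streams.
#'
#' @param scenarios Named list of \code{nds_scenario} (names = stream ids).
#' @param design An \code{nds_design} (shared by the cohort).
#' @param seed Global integer seed.
#' @param response_vars Subset of \code{\link{response_vars}} to generate.
#' @return A \code{biomass_table}.
#' @export
generate_biomass <- function(scenarios, design, seed = 1L,
                             response_vars = RESPONSE_VARS) {
  if (is.null(names(scenarios))) {
    names(scenarios) <- sprintf("S%03d", seq_along(scenarios))
  }
  rows <- vector("list", length(scenarios))
  for (i in seq_along(scenarios)) {
    scn <- scenarios[[i]]
    sid <- names(scenarios)[i]
    set.seed(stream_seed(seed, i))
    per_rv <- lapply(response_vars, function(rv) {
      means <- vapply(design$treatments,
                      function(t) mean_surface(scn, t) * RV_BASELINE_SCALE[[rv]],
                      numeric(1))
      n <- scn$n_rep
      noise <- exp(stats::rnorm(n * length(means), 0, scn$sigma_log))
      data.frame(stream_id = sid, response_var = rv,
                 treatment = rep(design$treatments, each = n),
                 replicate = rep(seq_len(n), times = length(means)),
                 biomass = rep(means, each = n) * noise,
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, per_rv)
  }
  biomass_table(do.call(rbind, rows), design)
}

#' Scenario pool testable under a design
#'
#' Element combinations for each taxonomy category that the design's
#' contrast registry can resolve. The 2021 variant, lacking the N+Fe arm,
#' cannot distinguish N,Fe serial or simultaneous co-limitation (the
#' synthesised block of the Zn triple would mis-attribute the interaction),
#' so those combinations are excluded there; likewise Mo and Ni only appear
#' in combinations the added-element contrasts can see.
#'
#' @param year 2021 or 2022.
#' @return List of template scenarios (category + elements), without noise
#'   settings applied.
#' @export
scenario_pool <- function(year) {
  y2022 <- year == 2022L
  pairs <- list(c("N", "P"), c("P", "Fe"))
  if (y2022) pairs <- c(pairs, list(c("N", "Fe")))
  serials <- c(lapply(pairs, identity), lapply(pairs, rev))
  indep <- c(pairs, if (!y2022) list(c("N", "Fe")),
             list(c("N", "P", "Fe"), c("N", "Fe", "Zn"),
                  c("P", "Fe", "Mo"), c("P", "Fe", "Ni")))
  simul <- c(pairs, list(c("N", "P", "Fe"), c("N", "Fe", "Zn"),
                         c("P", "Fe", "Mo"), c("P", "Fe", "Ni")))
  singles <- c("N", "P", "Fe", "Zn")
  c(
    list(list(category = "no_response", elements = character(0))),
    lapply(singles, function(e) list(category = "single_limitation", elements = e)),
    lapply(singles, function(e) list(category = "negative_response", elements = e)),
    lapply(serials, function(p) list(category = "serial_limitation", elements = p)),
    lapply(indep, function(p) list(category = "independent_colimitation", elements = p)),
    lapply(simul, function(p) list(category = "simultaneous_colimitation", elements = p))
  )
}

#' Sample a cohort of scenarios
#'
#' Draws stream scenarios from the design's testable pool. The default
#' category mix leans towards single limitation and independent
#' co-limitation, the classes that dominate field NDS cohorts.
#'
#' @param n Number of streams.
#' @param year Design year.
#' @param seed Integer seed.
#' @param sigma_log,n_rep,mu_c Passed to \code{\link{scenario}}.
#' @param weights Named sampling weights over categories.
#' @return Named list of \code{nds_scenario}.
#' @export
sample_cohort <- function(n, year = 2022L, seed = 1L, sigma_log = 0.2,
                          n_rep = 5L, mu_c = 5,
                          weights = c(no_response = 0.12,
                                      negative_response = 0.08,
                                      single_limitation = 0.30,
                                      serial_limitation = 0.10,
                                      independent_colimitation = 0.28,
                                      simultaneous_colimitation = 0.12)) {
  pool <- scenario_pool(year)
  cats <- vapply(pool, `[[`, character(1), "category")
  set.seed(stream_seed(seed, 0L))
  picks <- sample(seq_along(pool), n, replace = TRUE,
                  prob = weights[cats] / table(cats)[cats])
  scns <- lapply(picks, function(i) {
    scenario(pool[[i]]$category, pool[[i]]$elements,
             sigma_log = sigma_log, n_rep = n_rep, mu_c = mu_c)
  })
  stats::setNames(scns, sprintf("S%03d", seq_len(n)))
}

#' Did classification recover a planted scenario?
#'
#' Exact recovery requires (a) the element-level status of all seven
#' elements to match the scenario's ground truth (limiting elements
#' limited_or_colimited, a serial secondary recorded as such, negative
#' elements negative, everything else none) and (b) the planted category to
#' be visible in the labels: a single-limitation label rolling up the
#' planted element, a serial label with the planted primary, a co-limitation
#' label whose element set equals the planted set (or, for independent
#' co-limitation, stimulation by single supply of every planted element),
#' a negative label, or -- for no_response -- no label of any other
#' category.
#'
#' @param cl A \code{stream_classification}.
#' @param scn The planted \code{nds_scenario}.
#' @return Logical.
#' @export
evaluate_recovery <- function(cl, scn) {
  expected <- stats::setNames(rep("none", length(ELEMENT_ORDER)), ELEMENT_ORDER)
  els <- scn$elements
  switch(scn$category,
    no_response = NULL,
    negative_response = expected[els] <- "negative",
    single_limitation = expected[els] <- "limited_or_colimited",
    serial_limitation = {
      expected[els[1]] <- "limited_or_colimited"
      expected[els[2]] <- "serial_secondary_only"
    },
    expected[els] <- "limited_or_colimited"  # both co-limitation classes
  )
  if (!identical(unname(cl$element_status[ELEMENT_ORDER]),
                 unname(expected[ELEMENT_ORDER]))) {
    return(FALSE)
  }
  labs <- cl$labels
  if (is.null(labs)) return(scn$category == "no_response")
  planted_label <- treatment_label(els)
  switch(scn$category,
    no_response = all(labs$category == "no_response"),
    negative_response = any(labs$category == "negative_response"),
    single_limitation = any(labs$category == "single_limitation" &
                              labs$rollup == planted_label),
    serial_limitation = any(labs$category == "serial_limitation" &
                              labs$primary == els[1]),
    independent_colimitation = {
      direct <- any(labs$category == "independent_colimitation" &
                      labs$elements == planted_label)
      singles <- cl$ratios[cl$ratios$contrast_type == "single", ]
      by_singles <- all(vapply(els, function(e) {
        i <- match(e, singles$label)
        !is.na(i) && singles$status[i] == "ok" &&
          singles$value[i] > cl$thresholds$theta_single
      }, logical(1)))
      direct || by_singles
    },
    simultaneous_colimitation = any(
      labs$category == "simultaneous_colimitation" &
        labs$elements == planted_label)
  )
}

#' Exact-recovery rate of a simulated cohort
#'
#' Generates a cohort, runs the full ratio + classification pipeline on
#' chlorophyll a, and reports the fraction of streams whose planted scenario
#' is exactly recovered.
#'
#' @param n Streams.
#' @param year Design year.
#' @param sigma_log Replicate noise.
#' @param seed Integer seed.
#' @param n_rep Replicates per treatment.
#' @param thresholds Classification thresholds.
#' @return List with \code{rate} (fraction in [0,1]), \code{n}, and the
#'   per-stream logical vector \code{recovered}.
#' @export
recovery_rate <- function(n = 500L, year = 2022L, sigma_log = 0.2, seed = 1L,
                          n_rep = 5L, thresholds = default_thresholds()) {
  scns <- sample_cohort(n, year = year, seed = seed, sigma_log = sigma_log,
                        n_rep = n_rep)
  design <- design_for_year(year)
  bio <- generate_biomass(scns, design, seed = seed, response_vars = "chl_a")
  ratios <- compute_all_ratios(bio)
  cls <- classify_cohort(ratios, thresholds)
  names(cls) <- vapply(cls, `[[`, character(1), "stream_id")
  recovered <- vapply(names(scns), function(sid) {
    evaluate_recovery(cls[[sid]], scns[[sid]])
  }, logical(1))
  list(rate = mean(recovered), n = n, recovered = recovered)
}

#' Threshold rule for labelling streams from covariates
#'
#' @param clauses List of clauses, each \code{list(var, dir, cut)} with dir
#'   ">" or "<"; a stream satisfies the rule when every clause holds.
#' @param element Element the rule labels (metadata).
#' @return Object of class \code{threshold_rule}.
#' @export
threshold_rule <- function(clauses, element = "Fe") {
  for (cl in clauses) {
    stopifnot(is.character(cl$var), cl$dir %in% c(">", "<"), is.numeric(cl$cut))
  }
  structure(list(clauses = clauses, element = element),
            class = "threshold_rule")
}

#' The iron-limitation reference rule
#'
#' Fe limitation is planted where dissolved reactive phosphorus is high and
#' watershed inorganic N deposition low: DRP > 5.6 ug/L and
#' N_DEP < 3.6 kg N/ha/yr.
#'
#' @return A \code{threshold_rule}.
#' @export
fe_rule <- function() {
  threshold_rule(list(list(var = "DRP", dir = ">", cut = 5.6),
                      list(var = "N_DEP", dir = "<", cut = 3.6)),
                 element = "Fe")
}

rule_holds <- function(rule, wide) {
  ok <- rep(TRUE, nrow(wide))
  for (cl in rule$clauses) {
    if (!cl$var %in% names(wide)) {
      stop("rule references unknown variable: ", cl$var, call. = FALSE)
    }
    v <- wide[[cl$var]]
    ok <- ok & (if (cl$dir == ">") v > cl$cut else v < cl$cut)
  }
  ok
}

# base covariate sampler: DRP lognormal around the rule cut, N_DEP uniform,
# nuisance variables standard lognormal/normal, soil deciles uniform 1..10
sample_covariate_row <- function(var_spec) {
  vapply(var_spec, function(s) {
    switch(s,
      drp = stats::rlnorm(1, log(6), 0.6),
      ndep = stats::runif(1, 0.5, 8),
      wq = stats::rlnorm(1, 0, 1),
      land = stats::rnorm(1, 0, 1),
      decile = as.numeric(sample.int(10, 1)))
  }, numeric(1))
}

covariate_spec <- function(n_wq = 27L, n_land = 52L, n_soil = 21L) {
  vars <- c("DRP", sprintf("WQ%02d", seq_len(n_wq - 1L)),
            "N_DEP", sprintf("LAND%02d", seq_len(n_land - 1L)),
            sprintf("SOIL%02d", seq_len(n_soil)))
  groups <- c(rep("water_quality", n_wq), rep("landscape", n_land),
              rep("soil_metal_decile", n_soil))
  spec <- c("drp", rep("wq", n_wq - 1L), "ndep", rep("land", n_land - 1L),
            rep("decile", n_soil))
  list(vars = vars, groups = groups, spec = stats::setNames(spec, vars))
}

#' Generate stream covariates with a planted label rule
#'
#' Draws a covariate table mirroring the field predictor set (27
#' water-quality analytes, 52 landscape variables, 21 soil-metal deciles;
#' nuisance variables independent of the labels by construction) and labels
#' each stream by the threshold rule, with optional label noise and
#' missing-completely-at-random blanks injected into the water-quality
#' block at the given rate.
#'
#' @param stream_ids Character vector of stream ids.
#' @param rule A \code{threshold_rule}.
#' @param labels Optional logical ground-truth labels to condition on (e.g.
#'   from a scenario cohort); covariates are then rejection-sampled so the
#'   noise-free rule reproduces them. Default NULL: labels are read off the
#'   sampled covariates.
#' @param label_noise Fraction of labels flipped after generation.
#' @param missing_rate MCAR missingness rate (default 0.015, the level
#'   typical of field chemistry tables).
#' @param missing_groups Covariate groups the blanks are injected into
#'   (default water_quality: landscape and soil variables come from
#'   complete databases).
#' @param seed Integer seed.
#' @return List: \code{covariates} (a \code{covariate_table}),
#'   \code{labels} (named logical), \code{truth} (pre-noise labels).
#' @export
generate_covariates <- function(stream_ids, rule = fe_rule(), labels = NULL,
                                label_noise = 0, missing_rate = 0.015,
                                missing_groups = "water_quality",
                                seed = 1L) {
  cs <- covariate_spec()
  for (cl in rule$clauses) {
    if (!cl$var %in% cs$vars) {
      stop("rule depends on a covariate absent from the generator: ", cl$var,
           call. = FALSE)
    }
  }
  set.seed(stream_seed(seed, 1L))
  n <- length(stream_ids)
  rows <- matrix(NA_real_, n, length(cs$vars),
                 dimnames = list(stream_ids, cs$vars))
  for (i in seq_len(n)) {
    repeat {
      rows[i, ] <- sample_covariate_row(cs$spec)
      if (is.null(labels)) break
      holds <- rule_holds(rule, as.data.frame(t(rows[i, , drop = TRUE])))
      if (holds == labels[[stream_ids[i]]]) break
    }
  }
  wide <- as.data.frame(rows)
  truth <- stats::setNames(rule_holds(rule, wide), stream_ids)
  lab <- truth
  if (label_noise > 0) {
    flip <- stats::runif(n) < label_noise
    lab[flip] <- !lab[flip]
  }
  long <- data.frame(
    stream_id = rep(stream_ids, times = length(cs$vars)),
    variable_name = rep(cs$vars, each = n),
    group = rep(cs$groups, each = n),
    value = as.vector(as.matrix(wide)),
    stringsAsFactors = FALSE)
  if (missing_rate > 0) {
    eligible <- which(long$group %in% missing_groups)
    drop_idx <- eligible[stats::runif(length(eligible)) < missing_rate]
    long$value[drop_idx] <- NA_real_
  }
  list(covariates = covariate_table(long[, c("stream_id", "variable_name",
                                             "value", "group")]),
       labels = lab, truth = truth)
}
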