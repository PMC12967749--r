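# Independent oracles, coded from first principles and kept free of any
# package internals.

# Vectorised decision-table oracle for the limitation taxonomy.
oracle_classify <- function(rr_a, rr_b, rr_ab, irr,
                            ts = 0.326, ti = 0.385) {
  a <- ifelse(is.na(rr_a), -Inf, rr_a)
  b <- ifelse(is.na(rr_b), -Inf, rr_b)
  ab <- ifelse(is.na(rr_ab), -Inf, rr_ab)
  s_a <- a > ts
  s_b <- b > ts
  both <- s_a & s_b
  one <- xor(s_a, s_b)
  resp <- ifelse(s_a, a, b)
  serial <- one & is.finite(ab) & (ab - resp > ts)
  single <- one & !serial
  simu <- !both & !one & ab > ts
  neg <- !both & !one & !simu & (a < -ts | b < -ts | ab < -ts)
  category <- rep("no_response", length(a))
  category[neg] <- "negative_response"
  category[simu] <- "simultaneous_colimitation"
  category[single] <- "single_limitation"
  category[serial] <- "serial_limitation"
  category[both] <- "independent_colimitation"
  icls <- ifelse(is.na(irr) | !is.finite(irr), "not_applicable",
                 ifelse(irr > ti, "super_additive",
                        ifelse(irr < -ti, "sub_additive", "additive")))
  list(category = category, interaction_class = icls)
}

# Brute-force ratio recomputation from a named vector of treatment means.
oracle_ratios_2022 <- function(mu) {
  c(rr_n = log(mu[["N"]] / mu[["CTRL"]]),
    irr_np = log(mu[["N+P"]] / (mu[["N"]] + mu[["P"]] - mu[["CTRL"]])),
    irr_nfe = log(mu[["N+Fe"]] / (mu[["N"]] + mu[["Fe"]] - mu[["CTRL"]])),
    irr_pfe = log(mu[["P+Fe"]] / (mu[["P"]] + mu[["Fe"]] - mu[["CTRL"]])),
    irr_npfe = log(mu[["N+P+Fe"]] / (mu[["N+P"]] + mu[["Fe"]] - mu[["CTRL"]])),
    irr_nfezn = log(mu[["N+Fe+Zn"]] / (mu[["N+Fe"]] + mu[["Zn"]] - mu[["CTRL"]])),
    add_mo = log(mu[["P+Fe+Mo"]] / mu[["P+Fe"]]),
    add_ni = log(mu[["P+Fe+Ni"]] / mu[["P+Fe"]]))
}

# Build a biomass table whose treatment means are exactly `mu` (two equal
# replicates per treatment).
biomass_from_means <- function(mu, design, stream_id = "S1",
                               response_var = "chl_a", n_rep = 5L) {
  df <- do.call(rbind, lapply(names(mu), function(t) {
    data.frame(stream_id = stream_id, response_var = response_var,
               treatment = t, replicate = seq_len(n_rep),
               biomass = mu[[t]], stringsAsFactors = FALSE)
  }))
  biomass_table(df, design)
}

first_classification <- function(bio, thresholds = default_thresholds()) {
  classify_cohort(compute_all_ratios(bio), thresholds)[[1]]
}
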