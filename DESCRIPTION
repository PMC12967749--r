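Package: colimstat
Title: Nutrient and Metal Co-Limitation Analysis for Stream Biofilm Enrichment Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing factorial nutrient-diffusing-substrate (NDS)
    enrichment experiments in streams. Computes log response ratios and
    interaction response ratios for single-, two- and three-element
    treatments, classifies each stream by (co-)limitation type (single,
    serial, independent and simultaneous co-limitation, with super- and
    sub-additive interaction classes), summarises limitation frequency
    across a cohort of streams, and fits tuned random-forest models that
    predict presence/absence of limitation from water-quality, landscape and
    soil covariates, including predictive-mean-matching imputation and
    partial-dependence threshold detection. A synthetic NDS generator with
    known ground-truth limitation structure supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
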