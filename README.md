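# colimstat

Nutrient and trace-metal (co-)limitation analysis for stream biofilm
enrichment experiments.

Nutrient-diffusing substrata (NDS) release single elements (N, P, Fe, Zn)
and combinations (N+P, N+Fe, P+Fe, N+P+Fe, N+Fe+Zn, P+Fe+Mo, P+Fe+Ni)
into streamwater while biofilm grows on the cups; comparing biomass across
treatments identifies which elements limit primary producers in a stream.
`colimstat` is for ecologists running such factorial deployments: it turns
cup-level biomass tables into effect sizes, limitation classifications,
cohort summaries, and environmental-prediction models, and ships a
synthetic generator with known ground truth so the whole chain is testable.

## What it computes

**Effect sizes.** Log response ratios of treatment means,
`RR_T = ln(Y_T / Y_C)`, and interaction response ratios against the
additive expectation built from responses above control,
`IRR_AB = ln( Y_AB / (Y_A + Y_B − Y_C) )` (three-element treatments
compare to an appropriate two-element block plus the remaining single,
e.g. N+Fe+Zn vs additive N+Fe and Zn). Mo and Ni, never supplied singly,
are judged by the marginal ratio `ln(Y_PFeX / Y_PFe)` over a responding
base.

**Classification.** A ratio above θ_single = 0.326 (+38.5 % biomass) is
stimulation; an interaction ratio above θ_interaction = 0.385 is positive
non-additivity. Each contrast lands in one of: no response, negative
response, single limitation, serial limitation (second element responds
only after the first is supplied — Liebig behaviour, not co-limitation),
independent co-limitation (each element responds alone), or simultaneous
co-limitation (response only to the combination), with a super-/
sub-additive interaction class. Labels roll up to per-element
limited/serial-secondary/negative status and to cohort summaries (counts,
percents, median response ratios, co-limited combinations).

**Prediction.** Per-element presence/absence of limitation is modelled
from water-quality, landscape and soil-metal covariates: predictive-mean-
matching imputation, a tuned random forest (80/20 stratified split, grid
over variables-per-split × max-nodes × trees, no-information-rate gate),
and partial-dependence threshold detection for well-performing models.

## Worked example

```r
library(colimstat)

design <- design_for_year(2022)
scns <- sample_cohort(41, year = 2022, seed = 1)          # planted truth
bio  <- generate_biomass(scns, design, seed = 1)           # cup biomass
cls  <- classify_cohort(compute_all_ratios(bio))
summarize_cohort(Filter(function(x) x$response_var == "chl_a", cls))
```

```
Cohort (co-)limitation summary: 41 streams, chl_a
  streams with any (co-)limitation response: 78%
  N  (co-)limited in 16 streams (39%), single-supply stimulation in 14; median RR 0.90 (+147%)
  P  (co-)limited in 12 streams (29%), single-supply stimulation in 11; median RR 0.97 (+163%)
  Fe (co-)limited in 16 streams (39%), single-supply stimulation in 14; median RR 0.59 (+81%)
  Zn (co-)limited in 7 streams (17%), single-supply stimulation in 6; median RR 0.55 (+74%)
  ...
  co-limited combinations:
    N+P+Fe     10 streams
    N+Fe       8 streams
    ...
```

Each line mirrors how field cohorts are reported: how many streams an
element limits (alone or in combination), how many respond to its single
supply, and the median log response ratio among limited streams with its
percent-change conversion (`rr_to_percent(0.89)` is +144 %).

The full workflow is laid out as numbered drivers:

```sh
Rscript analysis/01_simulate.R   # synthetic 41-stream deployment + truth
Rscript analysis/02_classify.R   # ratios, labels, cohort summary
Rscript analysis/03_predict.R    # imputation, tuned forest, thresholds
```

`02_classify` prints per-element agreement with the planted truth
(95–98 % at the default noise level); `03_predict` recovers the planted
iron rule — probability of Fe limitation rising above DRP ≈ 5.6 µg/L and
falling above N_DEP ≈ 3.6 kg N/ha/yr — and screens the cohort against it.
Outputs land under `results/`.

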