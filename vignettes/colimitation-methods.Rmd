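---
title: "Classifying nutrient and metal co-limitation from factorial enrichment experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying nutrient and metal co-limitation from factorial enrichment experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colimstat)
```

## The problem

Nutrient-diffusing substrata (NDS) are agar-filled cups whose porous tops
release an enrichment treatment into streamwater while biofilm grows on the
surface. Deploying a factorial set of cups — single elements, two- and
three-element combinations, and unamended controls — in a stream and
comparing biofilm biomass across treatments reveals which elements limit
primary producers there. `colimstat` implements the full analysis chain for
such experiments: effect sizes, a (co-)limitation taxonomy, cohort
summaries, and an environmental-prediction stage, together with a synthetic
generator that plants known limitation structure so every stage can be
validated against ground truth.

The treatment system covers the macronutrients N and P and the trace metals
Fe, Zn, Co, Mo and Ni. Two design variants are supported: the 2022 variant
(N, P, Fe, Zn singles; N+P, N+Fe, P+Fe; N+P+Fe, N+Fe+Zn, P+Fe+Mo, P+Fe+Ni;
control) and the 2021 variant, which supplied Co alongside Zn (the two
metals substitute at the active site of carbonic anhydrase) and lacked the
N+Fe treatment. For cross-year comparison the Zn+Co cup occupies the Zn
slot with Co carried as a passenger element; Zn-limitation evidence from
either variant is pooled under Zn.

## Effect sizes

All inference runs on log response ratios of arithmetic treatment means,

$$RR_T = \ln\left(\bar{Y}_T / \bar{Y}_C\right),$$

and on interaction response ratios that compare a combined treatment to the
additive expectation built from its parts' responses above control,

$$IRR_{AB} = \ln\left(\frac{\bar{Y}_{AB}}{\bar{Y}_A + \bar{Y}_B - \bar{Y}_C}\right),
\qquad
IRR_{ABX} = \ln\left(\frac{\bar{Y}_{ABX}}{\bar{Y}_{AB} + \bar{Y}_X - \bar{Y}_C}\right).$$

Two genuinely open choices are made here and exposed as hooks:

* **Means, not mean-of-logs.** Ratios use the log of the arithmetic mean
  rather than the mean of per-replicate logs, because the additive
  interaction expectation $\bar{Y}_A + \bar{Y}_B - \bar{Y}_C$ only makes
  sense on the arithmetic-mean scale.
* **Response-above-control additivity.** "Additive combination" is read as
  the control-corrected sum above; this is the central interpretive
  decision of the interaction analysis and is isolated in
  `interaction_rr_pair()` so an alternative expectation can be swapped in.

Mo and Ni are never supplied singly; their co-limitation evidence is the
marginal added-element ratio $\ln(\bar{Y}_{PFeX}/\bar{Y}_{PFe})$ judged
against the single-response threshold, with the requirement that the P+Fe
base itself responded.

In the 2021 variant the N+Fe+Zn triple has no N+Fe arm; the block response
is synthesised from additivity of the N and Fe singles
($RR_{block} = \ln(e^{RR_N} + e^{RR_{Fe}} - 1)$, equivalently expectation
$\bar{Y}_N + \bar{Y}_{Fe} + \bar{Y}_{Zn} - 2\bar{Y}_C$). When N and Fe
truly interact this synthesis misattributes part of the interaction to the
Zn axis, which is why the 2021 scenario pool excludes N,Fe serial and
simultaneous combinations (see *Limitations*).

Degenerate arithmetic never disappears silently: a zero treatment mean with
a positive control is carried as a `collapse` marker (conceptually
$RR = -\infty$, classified as a negative response, never exported as a
number); a non-positive additive expectation marks the contrast
`degenerate`; a zero control mean marks the whole stream x response
variable unclassifiable with an audit reason.

## The limitation taxonomy

Classification is threshold-based, not test-based: a log response ratio
above $\theta_s = 0.326$ (a +38.5% biomass increase) counts as stimulation,
and an interaction ratio above $\theta_i = 0.385$ as significant positive
non-additivity. Both comparisons are strict, matching the "greater than"
reading of the thresholds; a ratio exactly at the threshold is not a
response. For each registered contrast, with $S_X := RR_X > \theta_s$:

| Condition | Category |
|---|---|
| $S_A \wedge S_B$ | independent co-limitation |
| exactly one $S$, and $RR_{AB} - RR_{single} > \theta_s$ | serial limitation (primary = responder) |
| exactly one $S$, no extra combined response | single limitation |
| neither, $RR_{AB} > \theta_s$ | simultaneous co-limitation |
| neither, any ratio $< -\theta_s$ | negative response |
| otherwise | no response |

The serial "additional response" cut-off re-uses $\theta_s$; no separate
serial threshold is published, so the choice is documented here and
configurable. The interaction class (super-/sub-additive/additive) is
orthogonal to the category and `not_applicable` when the interaction ratio
is degenerate.

Triple contrasts treat the two-element block as one axis. Element-level
roll-up then needs care, and three decisions were made after finding that
naive alternatives mis-assign elements on noise-free synthetic data:

* **Independent triples add only the single-metal axis.** If the
  (N+P) x Fe contrast is independent, Fe is added; N and P earn their
  status from the N x P contrast. Attributing the whole block would mark P
  limited in a stream where only N and Fe respond.
* **Simultaneous triples add all three elements, unless explained by a
  sub-pair.** A simultaneous pair (say N,Fe) also fires the (N+P) x Fe
  triple; since the registered N x Fe pair already explains the signal
  with fewer elements, the triple's roll-up is suppressed.
* **Serial secondaries are recorded only when the secondary is a single
  element.** A block secondary ("N+P responds on top of Fe") is ambiguous
  at element level and is resolved by the block's own pair contrast.

Serial limitation is never counted as co-limitation — it follows ordinary
Liebig expectations — but the serial *primary* is counted as limited: by
construction its single-supply response exceeds the threshold. Secondaries
are reported separately as `serial_secondary_only`. An element whose
single-supply ratio exceeds $\theta_s$ is always limited regardless of
contrast bookkeeping, and a negative single response ($< -\theta_s$) is
recorded per element but never erases a limited status earned elsewhere.
Response variables (chlorophyll *a* and the three fluorometry pigment
groups) are classified fully independently.

One property worth stating explicitly: the number of limited elements is
**not** monotone in $\theta_s$. Raising the threshold can push both single
responses of a pair below it while the combined response stays above,
rerouting the contrast into the simultaneous branch and re-adding both
elements. That is the taxonomy working as intended — a combined-only
response *is* simultaneous co-limitation — and the test suite demonstrates
the reroute rather than asserting global monotonicity (which holds only
for the single-supply evidence).

## The synthetic generator

Scenarios are multiplicative: replicate biomass is the scenario's expected
mean surface times lognormal noise $e^{N(0,\sigma_{\log})}$, so biomass is
strictly positive and planted effects are exact logs of the multipliers
(an N effect of $e^{0.89}$ plants $RR_N = 0.89$ in the noise-free limit).
Default effect sizes are $e^{0.89}$ (+144%) for macronutrients and
$e^{0.6}$ (+82%) for metals, reproducing the magnitude contrast between
macronutrient- and metal-limited biofilms; negative scenarios use
$e^{-0.6}$. Default study conditions are 5 replicates per treatment,
$\sigma_{\log} = 0.2$, a control mean of 5 µg chl *a*/cm², and 41-stream
cohorts. The four response variables share the stream's limitation
structure, differing in baseline with independent noise. Per-stream
substreams are derived deterministically from one global seed, so
extending a cohort never perturbs existing streams.

Covariate tables mirror the field predictor set — 27 water-quality
analytes, 52 landscape variables, 21 soil-metal deciles — with missingness
injected completely at random at 1.5% into the water-quality block (the
landscape and soil variables come from complete databases; the
configuration allows table-wide MCAR). The iron label follows the
reference rule DRP > 5.6 µg/L and N_DEP < 3.6 kg N/ha/yr, either read off
sampled covariates or rejection-sampled to match an externally supplied
label vector; nuisance variables are independent of the labels by
construction. Informative missingness is deliberately not modelled — at
these rates there is nothing to learn from it.

What the generator does *not* emulate: spatial autocorrelation among
streams, correlated covariates, taxon interactions, seasonal drift, cup
dose kinetics, or observation error in the control mean beyond replicate
noise. Passing recovery tests therefore demonstrates correctness of the
analysis chain under the stated response model, not robustness to every
property of field data.

Validation sizes used throughout (chosen to make Monte-Carlo error small
relative to the margins being tested): 100 streams per taxonomy category
per design variant for noise-free recovery; 500-stream cohorts per noise
level for the recovery-vs-noise curve at
$\sigma_{\log} \in \{0, 0.1, 0.2, 0.4\}$; 200-stream cohorts for the
predictor stage. Exact recovery of a stream requires the element status of
all seven elements *and* a label of the planted category — strict enough
that a single spurious ratio fails the stream.

## The predictor stage

Missing covariates are imputed by type-1 predictive mean matching: a
linear regression on fully observed covariates (screened to the columns
most correlated with the target when the basis is wider than half the
observed rows) predicts observed and missing cells, and each missing cell
takes the observed value of one of $k = 5$ donors nearest in predicted
value. Imputed values are therefore always observed values; the only
exception is the observed-median fallback for variables with fewer than
$k+1$ observations. Donor draws are seeded; ties in donor distance break
by row order.

Presence/absence of (co-)limitation per element is then modelled with a
random forest: an 80/20 split stratified by label (at cohort sizes near 40
an unstratified split can leave the no-information rate meaningless), a
grid search over the three tuning parameters — variables per split
($\sqrt{p}$, $p/3$, $p/10$), maximum nodes (4, 8, 16, unlimited), trees
(250, 500, 1000) — selected by out-of-bag error on the training set. The
published candidate values of the grid are not available, so these
defaults are the package's own. Reported training misclassification is the
out-of-bag rate (an honest training-set figure for forests); "test
accuracy" is read as accuracy on the single held-out 20% rather than
k-fold cross-validation, the plainer reading of a train/test protocol, and
a fold-based alternative can be built on the exposed split indices. A
model is well-performing when training misclassification is below 30% and
holdout accuracy exceeds the no-information rate (the holdout
majority-class share); partial-dependence output is produced for
well-performing models only.

Partial dependence sweeps a feature over 50 evenly spaced points between
its 2.5th and 97.5th percentiles (trimming avoids tail artefacts from
isolated extreme streams) while every other feature keeps its observed
values; the curve is the mean predicted presence probability. Threshold
detection takes the midpoint of the grid interval with the largest
absolute first difference and reports the direction of change; a flat
curve (range below 1e-8) yields a no-threshold result. Importance defaults
to mean impurity decrease, with permutation importance behind a flag.

## Known limitations

* The 2021 design cannot resolve interactions confined to N and Fe
  (no N+Fe arm); the synthesised block can misattribute such interactions
  to the Zn axis of the N+Fe+Zn triple. The scenario pool excludes those
  combinations, and field analyses of 2021 deployments inherit the caveat.
* The added-element contrasts cannot distinguish a simultaneous
  {Fe, Mo}-type response from {P, Fe, Mo}: when the base does not respond
  and the three-element cup does, all three elements are credited.
* Classification is point-estimate based by design: no replicate-variance
  weighting, no confidence intervals, no multiplicity control. The
  thresholds carry the inferential burden.
* The imputation basis is a correlation-screened linear model; with
  near-constant covariates or tiny cohorts it degrades towards median
  imputation (with warnings).
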