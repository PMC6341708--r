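---
title: "Scoring facility quality and testing the score's appropriateness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring facility quality and testing the score's appropriateness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facscore)
```

## The composite score

Routine supportive supervision assesses a facility with a checklist of
weighted indicators grouped into nine sections: six quality dimensions
(QDs), with QD3 (professional knowledge, skills and ethics) split into four
sub-sections. An indicator is answered `yes`/`no`/`na` — several times for
the observation- and exit-interview-based sections — or on a graded scale
in [0, 1] for medicine availability.

The scoring model is deliberately simple. Per indicator, the fulfilment
fraction is the yes-share among yes/no answers (graded answers are
averaged), so repeated answers earn fractional credit. An all-or-nothing
rule was rejected: partial credit is what makes facilities with many
answers per indicator systematically harder to score perfectly, the
documented behaviour of this instrument. Per section set, the score is
`100 * sum(w_i f_i) / sum(w_i)`; the overall score is the plain mean of the
six QD scores, so small sections count as much as large ones.

Three decisions the instrument description leaves open:

* **QD3 aggregation.** The package pools all QD3A–D indicators into one
  weighted aggregate by default (`qd3 = "pooled"`), because the four
  sub-sections exist for factor-analytic and reporting purposes, not as
  separately equal contributions; `qd3 = "submean"` averages the four
  sub-scores instead, and both are exposed because external descriptions of
  the instrument do not disambiguate.
* **Undefined QDs.** A QD with no applicable assessed indicator (common at
  dispensaries, whose mandate excludes many services) drops out of the
  overall mean rather than scoring zero — the applicability mechanism
  exists precisely so that mandate differences are not penalised.
* **Ties and precision.** Ranks break ties lexicographically by facility
  id, so output is deterministic; percentages are computed at full
  precision and only rounded for display.

`fraction_met()` refuses lists mixing binary and graded answers; the graded
scale is implemented as equally spaced levels in [0, 1] (default 0, 0.5, 1)
because the instrument's exact medicine-availability scale is not
published.

## What the synthetic generator emulates

The generator reproduces the structure of a four-year (2011–2014)
multi-council supervision programme:

* a roster of 8 councils x 20 facilities, 65% dispensaries, 25% health
  centers, 10% hospitals; owners 60% public, 20% private-not-for-profit,
  15% private-for-profit, 5% parastatal — the approximate composition of
  the programme this instrument comes from;
* a catalog with section sizes (41, 17, 17, 19, 10, 12, 16, 21, 6) for
  (QD1, QD2, QD3A, QD3B, QD3C, QD3D, QD4, QD5, QD6), 159 indicators in
  total. Published per-section counts sum to 159 even though the instrument
  is described as having 183 indicators; the per-section counts are taken
  as authoritative and `total_indicators` rescales them proportionally when
  a different total is wanted;
* weights uniform on 1..5; 15% of indicators restricted to health centers
  and hospitals; 70% of QD4 on the graded medicine scale; one answer per
  indicator except the observation/exit-interview sections (QD3A–D, QD6),
  which draw 1–3 answers — chosen to land the average answers per indicator
  in the 1.4–1.9 range reported for real assessments.

Every answer is Bernoulli (graded: a scaled binomial with the same mean)
with success probability

`plogis(mu + year_t + level_f + owner_f + u_council + delta_{f,QD}
 + slope * (w_i - mean(w)) - difficulty_i)`

with `u ~ N(0, 0.3)`, `delta ~ N(0, 0.3)` and `difficulty ~ N(0, 1)` on the
logit scale. Effects are *configured in percentage points* — the scale
results are reported on — and converted to logit offsets by solving, with
Gauss–Hermite integration (40 nodes) over the latent normal spread, for the
offset whose marginal yes-probability gap equals the target. The default
magnitudes (+3.1/+6.5/+8.4 for 2012–2014, −7.7 dispensary, +1.8 hospital,
−5.5 private-for-profit, +1.8 public, −0.9 parastatal, baseline 67.3%) are
the published effect estimates for this instrument, so recovery tests
exercise realistic signal sizes. The variance defaults make the council
component dominate the facility-year residual, matching the reported
strong within-council correlation.

Two deliberate refinements:

* **Weight–difficulty decorrelation.** Indicator difficulties are
  residualised on weights within each section, so
  `weight_compliance_slope` is the *exact* weight–success coupling. Without
  this, the sampling covariance between weights and difficulties in a
  159-indicator catalog (sd ≈ 0.13 logit per section) would dominate the
  configured coupling (0.1 logit at the default slope 0.05) and the sign of
  the weighted-minus-unweighted score difference would be a property of the
  catalog draw rather than of the slope parameter. The default slope 0.05
  yields a weighted-vs-unweighted mean gap of about +0.7 percentage points,
  the size observed for the real instrument.
* **Exact recovery oracle.** `implied_effects()` integrates the response
  probabilities over the council and section deviations (using the realized
  difficulties and weights) and projects the exact expected scores onto the
  main-effects design. This is the true estimand of a linear model of the
  scores — slightly different from the nominal configured gaps because of
  logit-scale nonlinearity and the applicability filter — and it is what
  recovery tests compare estimates against.

The generator does **not** emulate courtesy bias in exit interviews,
informative missingness (only level-based inapplicability and an optional
facility-year dropout flag), seasonal or within-year assessment timing, or
the real, unpublished answer-count distributions. Passing recovery tests
therefore shows the pipeline's statistics are correct under a plausible
data-generating process, not that the instrument is valid in the field.

## Robustness analyses

The subset-robustness curve asks how scores and ranks would change had
fewer indicators been assessed: nested, section-stratified random subsets
(every section keeps at least one indicator at every size; nesting makes
the comparison a pure size effect), scored unweighted, compared to the
largest set by mean absolute per-facility score and rank difference.
Absolute differences are used because signed differences cancel across
facilities. The real instrument's historical subsets were fixed by tool
revisions and are not reproducible, so seeded random nesting is the
default and explicit id lists can be supplied instead. Trends are fitted
by least squares — second-order polynomial for the score curve, linear for
the rank curve, mirroring how these curves are conventionally summarised.

The weight ablation scores identical responses twice (catalog weights vs
all-equal) and reports mean scores and mean absolute score/rank
differences; with equal weights every difference is exactly zero, a test
anchor.

## Factor-analytic concordance

The facility-by-indicator matrix of 2014 fulfilment fractions is factored
with nine factors, and each indicator is allocated to the factor of its
largest *absolute* loading — weak if that loading is below 0.4,
cross-loaded if any other factor comes within 0.2 of it. Extraction is
principal-axis factoring (squared-multiple-correlation starts, iterated
communalities, tolerance 1e-4) with varimax rotation, implemented in the
package; the described workflow (allocation by maximal loading, orthogonal
factors ranked by explained variance) is an exploratory one, so
maximum-likelihood extraction is offered only as a cross-check
(`method = "ml"`). Missing cells are mean-imputed — the simplest
deterministic choice — and constant columns, which cannot enter a
correlation matrix, are dropped with a message. Factors are matched
one-to-one to the nine designed sections by exact exhaustive search over
the 9! assignments of the section-by-factor contingency table, and the
concordance table reports matched/unmatched counts with the same
denominators as the instrument's published comparison (per-section totals
for match rates, matched and unmatched counts for the respective
breakdowns).

At the default generator settings the realistic data yield modest
concordance: the common factor signal per section (`qd_sd = 0.3`) is small
against indicator-level binomial noise, which is itself informative — the
planted-structure recovery test (block loadings 0.8, noise 0.05, 300
facilities, ≥90% recovery required) separates the method's correctness
from the data's factorability.

## Effect estimation

Scores (percentage scale, untransformed) are modelled as
`score ~ year + level + owner + (1 | council)` with REML, Satterthwaite
p-values, and reference categories 2011 / health center /
private-not-for-profit. Interaction search starts from the full
`year * level * owner` factorial and removes, among the highest-order
interaction terms present, the largest Wald p-value first, until all
remaining interactions clear the configurable threshold (default 0.05);
each visited model's ML AIC is recorded and the trace replays
deterministically. Saturated models that are not estimable start from the
largest estimable model (rank-deficient columns are dropped and the Wald
tests are computed on the retained coefficients). A sensitivity check
refits the fixed part by OLS with council-clustered robust variance.
Two behaviours worth knowing:

* The cluster-robust SEs inflate relative to naive OLS only for
  between-council quantities (the intercept, owner/level contrasts at high
  council heterogeneity); for year contrasts, balanced within councils,
  they are rightly *smaller* than naive SEs, which pool the council
  variance into the residual.
* The generator's facility-by-section deviation is persistent across
  years, so scores of one facility are correlated beyond the council
  effect. The council-only model — kept as the default because it is the
  published specification — then understates between-facility SEs;
  recovery tests therefore fit with `facility_intercept = TRUE`, the model
  matching the generating process.

## Problem sizes and numerical choices

The test suite runs the full study conditions (160 facilities x 4 years x
159 indicators) where the check is about those conditions — 100 replicates
for effect-recovery coverage, 20 for the subset-robustness and
weight-ablation Monte-Carlos, 300 facilities for planted-factor recovery —
and reduced sizes (4–8 councils of 6–10 facilities, 23-indicator catalogs)
for property-style unit tests, which probe invariances that do not depend
on scale. Null-effect calibration uses 60 replicates at reduced size; at
that count the rejection-rate check is a sanity bound (observed rate below
2.5x nominal), not a sharp size test. Gauss–Hermite integration uses 40
nodes; calibration roots are solved to 1e-9; principal-axis iteration caps
at 200 steps; exact argmax ties in allocation break to the lower factor
index and are logged.

## Known limitations

Scores are analysed as Gaussian responses although they are bounded
averages of Bernoulli fractions; with ~159 indicators per facility this is
harmless for estimation but the homoscedasticity assumption is mildly
violated across years (higher scores have smaller binomial variance).
Mean imputation before factoring attenuates correlations when
applicability patterns are strongly structured. The concordance stage
requires as many factors as sections for its one-to-one matching. The
synthetic generator's defaults are plausible, not fitted: none of its
parameters were estimated from real supervision data.
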