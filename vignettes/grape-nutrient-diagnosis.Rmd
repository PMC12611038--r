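---
title: "Nutrient diagnosis and precision fertilization for facility-grown grape: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient diagnosis and precision fertilization for facility-grown grape: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinefert)
```

This vignette is the package's account of its methods: the models, the
parameters that matter (with units and defaults), what the synthetic
generator emulates and what it deliberately does not, the numerical
policies at degenerate inputs, and the design choices that were
genuinely open.

## 1. Fruit quality index

Quality is scored by TOPSIS over three benefit criteria: single fruit
weight (SFW, g), total soluble solids (TSS, %), and fruit firmness (FF,
g puncture force). Criterion columns are vector-normalized (divided by
their Euclidean norm), multiplied by the fixed weights
`c(SFW = 0.0470, TSS = 0.2089, FF = 0.1778)`, and each alternative is
scored by its closeness coefficient to the per-criterion ideal and
anti-ideal points. Choices worth stating:

* **Normalization scheme.** Classical TOPSIS uses vector normalization;
  min–max is available (`normalization = "minmax"`) for sensitivity
  checks. Re-scoring the verification season's printed trait means with
  vector normalization reproduces its published normalized-FQI column to
  about 1e-4, which supports the default.
* **Weights are not renormalized.** They sum to 0.4337; the closeness
  coefficient is invariant to common weight scaling, so renormalization
  would only obscure the provenance of the constants.
* **Cohorts.** TOPSIS scores are only comparable within the set they
  were computed in. `fqi_scores()` scores within each year by default
  (the trial reports per-year replicate scores averaged per treatment);
  `cohort = "pooled"` scores all records at once, which is what the
  80-treatment-year diagnosis uses. Whether the original analysis pooled
  years or scored per year is not documented; both are supported and the
  package default per use-site is stated above.
* **Degenerate inputs.** Two identical alternatives have
  `D⁺ = D⁻ = 0`; their score is defined as 0.5 with a warning. An
  all-zero criterion column cannot be vector-normalized and is a
  configuration error.

## 2. Orthogonal trial screening

The design is the fixed L16(4⁵) table: five factors (N, P₂O₅, K₂O, CaO,
MgO as annual kg/hm²) at four levels (0, ½×, 1×, 3/2× a reference
rate). `check_design()` verifies balance (each level 4×) and pairwise
orthogonality (every 4×4 level combination exactly once). Level-4 doses
are stored at definition precision (506.25 kg/hm², displayed as 506.3).

* **Level means** are computed from treatment means (each treatment
  weighted equally) so published treatment tables reproduce published
  level blocks; a raw-replicate weighting is available and identical on
  balanced data. The published level block itself is also shipped
  (`quality_level_means()`) because the published rounding chain
  (treatment means rounded, then level means rounded) cannot be exactly
  reconstructed from the rounded treatment means.
* **F values** come from the main-effects ANOVA with all five factors as
  4-level categoricals and the residual taken from replicate variation —
  the standard orthogonal-table choice when the original error stratum
  is unreported. With zero residual variance the mean squares are
  guarded (numeric dust is treated as zero) so orderings stay stable.
* **Ties** in best levels or F orderings break to the lowest level /
  design factor order with a warning; real data never tie exactly.
* **LSD letters** use Fisher's LSD on the pooled within-treatment mean
  square. Letters are assigned by maximal contiguous non-significant
  intervals on the sorted means, which is exact for balanced data (with
  equal n, the extreme pair of an interval is its widest contrast).

## 3. CND cutoffs and optimum ranges

The diagnosis selects, per element, the tissue × stage whose
concentration has the lowest coefficient of variation across treatments
(the most buffered sampling combination), then works variable by
variable:

1. Sort treatment-year units by normalized FQI, descending.
2. For each admissible split `j` (both subgroups at least
   `m_min = 3`; splits inside tied scores are skipped so tie groups
   stay together), compute `V_j = Var(top j) / Var(rest)` with sample
   (n−1) variances.
3. Report the cumulative curve `F_j = 100 · Σ V_i / Σ_all V_i` at
   `X_j`, the j-th unit's score, and fit `F = AX³ + BX² + CX + D` by
   ordinary least squares on all admissible points (no weighting).
4. The cutoff is the inflection `Y = −B/(3A)`; the high-FQI reference
   sub-population is every unit with score ≥ Y, and the optimum range
   is the min–max of the nutrient over it.

Policy decisions:

* **Orientation.** `Var(top)/Var(rest)` is the default; the reciprocal
  is available. The default reproduces the published curve shape
  (intercept near 100, decreasing in X).
* **m_min = 3**: a variance needs two points; three adds stability.
* **Communal cutoff.** Across the plant diagnostic variables the
  communal cutoff is the *maximum* of their cutoffs — the strictest
  single criterion, so the communal reference population is high-FQI
  under every variable's own curve. This is the only rule consistent
  with the published communal value equalling the largest plant-variable
  cutoff. In `cnd_diagnosis()` only cutoffs that actually select ≥ 2
  units are eligible (a fitted inflection can fall outside the observed
  score range, where it diagnoses nothing); if no plant cutoff
  qualifies the rule falls back to all variables.
* **A ≈ 0** (near-linear curves) leaves the cutoff undefined with a
  warning rather than a wild extrapolation; `R²` is reported so weak
  fits (the published table itself contains one fit with R² = 0.55) can
  be filtered by the caller — no hard threshold is imposed.
* Composite nutrient-ratio (`_R`) rows of the published table are
  carried as reporting constants only; their construction is not
  documented in the source material and they enter no computation.

## 4. Stage demand accounting

`AWP = Σ(concentration mg/g × dry mass g)/1000` (g per tree) per stage;
`DTS` is the interval difference (kept signed — late-season leaf fall
can remobilize); `RTS` is the interval share of the full-season demand
(an absolute-value variant exists because signed shares are
ill-behaved when intervals are negative). Fruit is harvested at
maturation, so when the final (deciduous) stage carries no fruit rows
its maturation content is carried into the final total — otherwise the
season's books would not balance. Per-year summaries are computed first
and then averaged, matching how multi-season means are reported.

## 5. Precision fertilization model

Per interval × element, the dose is

```
PFA = (a·x + b) · [(1 − FR) + FR·EY/1500]   if x < X_max,   else 0
```

with `x` the start-stage soil test (mg/g), `(a, b)` the shipped linear
response (`fertilization_models()`, all slopes negative: richer soil,
less fertilizer), `FR` the element's fruit-to-whole-plant uptake ratio
(defaults `N 0.2531, P 0.1775, K 0.4465, Ca 0.1640, Mg 0.1795`), and
`EY` the expected yield (kg) on the 1500 kg reference basis. `X_max` is
the upper bound of the communal-cutoff optimum range of the start-stage
*soil* variable (plant ranges are diagnostic, not gates). Decisions:

* **Negative responses.** Some shipped models give `a·x + b < 0` before
  the gate; doses are floored at 0 with a warning (the gate only
  addresses `x ≥ X_max`, and a negative fertilizer amount is
  meaningless).
* **Units.** The model's `y` is calibrated to the 1500 kg yield unit;
  the area/plant basis of the original calibration is not documented,
  so no per-hectare conversion is hard-wired — callers convert.
* **Annual FR.** The `(1 − FR)` term uses each element's season-level
  fruit ratio, not stage-specific ratios, which are not available.
* **Blends.** `solve_blend()` is a non-negative least-squares inversion
  of the product × nutrient-fraction matrix (via `pracma::lsqnonneg`);
  residuals are reported honestly rather than forced to zero, since the
  8-product catalog cannot hit every target exactly.
* The oxide basis (N, P₂O₅, K₂O, CaO, MgO) is used throughout the model
  I/O to match the design tables; element↔oxide converters use standard
  stoichiometry (P₂O₅ = 2.2914 P, K₂O = 1.2046 K, CaO = 1.3992 Ca,
  MgO = 1.6583 Mg).

## 6. The synthetic experiment

The generator exists so every stage of the chain is testable end to end.
It emulates:

* **Quality records** (16 treatments × 5 years × 3 replicates): trait =
  grand mean + additive factor-level effects + additive year shift +
  Gaussian noise, truncated-redrawn at a floor (a warning fires if the
  floor absorbs > 1% of draws — a sign of mis-calibration). Defaults:
  grand means (4.77 g, 18.79 %, 411.9 g), level effects equal to the
  published level means centred per factor, year shifts comparable to
  the reported inter-annual variability, residual SDs (0.45 g, 1.2 %,
  40 g) in line with the published treatment SDs. Year effects are
  additive shifts, not interactions — inter-annual variability is
  reported in the source material without an interaction model.
* **Nutrient observations** per treatment-year: concentration =
  (baseline + response × applied dose of the element) × log-normal
  noise. Multiplicative noise keeps concentrations positive, matching
  mg/g data; quality noise is additive Gaussian, matching ±SD
  reporting. Soil baselines sit at the midpoints of the published
  optimum ranges; the five diagnostic plant variables sit at their
  range midpoints and carry the lowest relative noise of their element
  (so CV-based selection recovers them), with the published dynamic
  patterns (high leaf N before maturation, rising petiole K, high
  leaf/petiole Ca, falling fruit Mg) shaping the rest.
  Replicate-level variance of the original nutrient data is not
  published; these noise levels are declared calibration, not fits.
* **Harvest series** (7 stages × 7 tissues × 3 trees × 3 seasons):
  whole-plant content follows a closed-form trajectory — a spring
  reserve (half the annual uptake) plus interval increments
  proportional to the measured stage demand proportions, totalling the
  published per-yield uptake at a 10 kg/tree yield; the fruit share
  ramps to the published fruit uptake ratio. Dry masses grow by a
  monotone logistic profile per tissue with one log-normal size factor
  per tree × tissue (3%), so whole-plant mass is non-decreasing per
  tree by construction; concentrations carry 3% multiplicative noise.
  Leaf mass is kept non-decreasing through leaf fall — the accounting
  treats the deciduous stage as a bookkeeping endpoint, not a
  biological one.
* **RNG.** One scenario seed with fixed per-generator offsets
  (quality +0, nutrients +1, harvest +2, planted-window +3), Mersenne-
  Twister, vectorized row-major draws — each table regenerates
  independently and bit-identically.

### The planted-window scenario

`simulate_cnd_window()` builds the structure the cutoff machinery is
designed to detect, for the end-to-end recovery checks: a distinct
high-FQI sub-population (top 20% of 80 units, separated by a gap in the
normalized-score distribution — clearly visible in the published
verification season, where the scores jump from 0.59 to 0.87) whose
nutrient sits in a narrow sufficiency window (14–16 mg/g), and below
the boundary a deficiency gradient: the nutrient shortfall grows
linearly as quality falls (10 mg/g per unit of normalized FQI), with
1.2 mg/g residual scatter. Two structural facts motivate this design:

* Under a deficiency gradient the between-subpopulation variance ratio
  grows roughly quadratically with split depth, so the cumulative curve
  is genuinely cubic-like and the OLS cubic's inflection is a nearly
  unbiased estimator of the boundary (bias < 0.02 in the noiseless
  limit). An unstructured low group (values scattered with no
  quality coupling) produces a ramp-plus-plateau curve whose cubic
  inflection is unstable — visible in the trial-scale synthetic runs,
  where uncoupled variables get out-of-range cutoffs.
* The score gap makes recovery robust: any cutoff landing in the gap
  selects exactly the planted sub-population.

What passing these checks shows is that the machinery inverts the
structure it assumes; it does not show that real vineyard data carry
that structure — that is an agronomic claim the original trial makes
and this package only encodes.

## 7. Problem sizes and limitations

The shipped tests and the acceptance checks run the trial at its
natural size (80 treatment-years, 2 205 harvest rows) and the
stochastic properties at 100 seeds; everything completes in a few
minutes on one core. Known limitations: no interaction effects in the
orthogonal analysis (main effects only, as in the source analysis); no
weather mechanism behind year effects; no CND-clr multivariate
log-ratio indices (the diagnosis here is the cutoff/sub-population
machinery); no economic optimization of blends; and no multi-year
carry-over of soil nutrients.
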