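---
title: "Methods: models, calibration and design choices in fibrostage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in fibrostage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrostage)
```

## The diagnostic problem

In NAFLD, histological fibrosis stage (F0–F4) drives prognosis, and the two
clinically decisive targets are advanced fibrosis (F34) and cirrhosis (F4).
Seven non-invasive tests are in routine use: two simple blood scores (FIB-4,
NAFLD fibrosis score), two patented specialized blood tests (FibroMeterV3G
targeting F34, CirrhoMeterV3G targeting F4), liver stiffness by VCTE, and
two elastography–blood composites (Agile3+ targeting F34, Agile4 targeting
F4). `fibrostage` implements a sequential framework that (1) stratifies
patients into four groups per test couple, (2) combines the two couples into
a four-diagnosis algorithm (F0-2 / Biopsy / F34 / F4), and (3) fits joint
risk charts for individual probability estimates — together with the
statistics needed to validate all of it.

Because the patient-level cohorts behind this class of algorithms are
available only on request, the package treats a calibrated synthetic cohort
generator as a first-class component: every downstream behaviour can be
exercised, at desk scale, on cohorts whose marginal properties match the
published summary statistics.

## The synthetic cohort generator

### Latent model

Each subject draws a biopsy stage $s \in \{0,\dots,4\}$ from a stage
distribution. The published stage percentages (12.1, 22.6, 27.1, 26.2, 12.1)
sum to 100.1 because of rounding; the package renormalizes them by their sum
so the default distribution is exact (F4 becomes 12.088%, F34 38.262% —
differences far below sampling noise at the cohort sizes used).

Each test $t$ has a latent severity
$z_t = m_{t,s} + \varepsilon_t,\qquad \varepsilon \sim N(0, R),$
with unit marginal noise variance and stage means parameterised as
$m_{t,s} = b_t\, s + c_t\, \mathbf{1}[s = 4]$, $b_t, c_t \ge 0$.
This is the minimal monotone model with two degrees of freedom: one slope
for the graded F0→F3 progression and one cirrhosis-specific offset, exactly
identified by the two published AUROC targets per test (F34 vs F0-2 and F4
vs F0-3). The analytic forward map is the prevalence-weighted mixture of
pairwise binormal terms,
$\mathrm{AUROC} = \sum_{s \in P}\sum_{u \in N} w_s w_u\,
\Phi\!\big((m_s - m_u)/\sqrt{2}\big),$
and `calibrate_test()` inverts it by nested 1-D root-finding (inner: $c$
given $b$ against the F4 target, monotone; outer: $b$ against the F34
target), with residuals required below $10^{-6}$. Targets of exactly 0.5
degenerate to $b = c = 0$; an F4 target *below* what the F34 target already
implies at $c = 0$ is unattainable under monotonicity and raises an error
naming the test rather than silently clamping.

### Native scales: quantile links

The latent scale must be mapped to each test's native scale so that the
simulated marginal quartiles equal the published ones. A two-parameter
location/scale logistic or log link cannot interpolate three quartiles in
general, so the package uses a quantile link: the analytic latent mixture
CDF $F(z)$ converts the latent value to a uniform grade, and a strictly
monotone Fritsch–Carlson spline through the anchors
$(0, \mathrm{lo}), (0.25, q_{25}), (0.5, q_{50}), (0.75, q_{75}),
(1, \mathrm{hi})$ converts the grade to the native scale (on the log scale
for positively skewed scales). Because the grade is exactly uniform, the
simulated quartiles match the anchors exactly in distribution; monotonicity
guarantees that AUROCs and all rank statistics are unchanged by the link.

Support bounds are fixed, field-realistic choices: unit-interval scores on
[0, 1]; VCTE on the device range [1.5, 75] kPa; FIB-4 on [0.2, 25] (adult
FIB-4 essentially never falls below 0.2 — the lower anchor matters because
raw labs are back-solved from FIB-4); NFS on [-8, 8].

### Correlation across tests

The study prints only marginal AUROCs and quartiles; the joint structure of
the seven tests is not published. The generator therefore assumes a
Gaussian copula over the latent noise with residual correlation 0.6 within
a modality (elastography-based: VCTE, Agile3+, Agile4; blood-based: FIB-4,
NFS, FMV3G, CMV3G) and 0.4 across modalities — tests are complementary but
correlated — on top of the correlation already induced by the shared stage.
These values are declared assumptions, configurable in `sim_config()`, and
they are the binding limitation of the generator (see *Limitations*).

Agile4 is calibrated independently by default (so its own AUROC targets are
met); the exponentially shaped relation with Agile3+ emerges from the two
quantile links. An optional `agile4_mode = "latent-link"` instead derives
Agile4 deterministically as a convex power $u^k$ ($k > 1$, default 2) of
the Agile3+ latent grade, which reproduces the deterministic-looking
published scatter at the cost of forcing Agile4's rank statistics to equal
Agile3+'s.

### Morphometry and raw labs

Biopsy morphometry (area of fibrosis, area of portal fibrosis, %) is
log-normal around fixed stage medians (2/4/6/10/22% and 0.6/1.2/2.5/5/12%).
Only the noise scale matters for the stage correlation, and it is solved by
1-D root-finding on the analytic large-sample Spearman correlation
$\rho(\sigma) = \sqrt{12}\,\mathrm{cov}(U_X, U_S)/\mathrm{sd}(U_S)$, where
$U_X$ is the trait's uniform grade and $U_S$ the stage midrank grade. The
noise-free limit is the maximal Spearman attainable given stage ties
($\approx$ `r round(fibrostage:::max_spearman_with_stage(stage_distribution()), 3)`
under the default distribution); targets at or above it are rejected.
Default targets: 0.548 (whole area), 0.711 (portal area).

Raw labs are interface plumbing, not calibrated joint data: age, ALT and
platelets are drawn from the printed marginals and AST is solved from the
FIB-4 identity (with a platelet fallback where the physiological AST clamp
binds), so recomputing FIB-4 from the labs reproduces the simulated score
bit-for-bit. The cohort carries a `labs_backfilled` flag; NFS recomputed
from these labs will *not* match the simulated NFS.

### Reproducibility

One root seed governs a run; every stochastic operation (stages, copula
noise, morphometry, labs) uses its own derived stream
(`derive_seed(root, index)`, a fixed multiplicative-hash rule modulo
$2^{31}-1$), so the same `sim_config()` is bit-reproducible and adding
draws to one stage never perturbs another.

## Classification and the sequential algorithm

Thresholds are the published ones and boundary conventions are literal:
Agile3+ groups split at 0.451 and 0.679 (a score of exactly 0.679 is in the
rule-in interval), Agile4 at > 0.474 (0.474 itself stays in group 3), FMV3G
at 0.31 and > 0.76, CMV3G at > 0.40. Group assignment is scale-exact — no
rounding is applied, and perturbations below 1e-9 away from a boundary never
change the group.

The sequential algorithm short-circuits Agile group 1 to F0-2 without blood
testing; for groups 2–4 the FM/CM group is crossed with the Agile group
through a 12-cell combination map. The published 16-cell crossing is shown
only graphically, so the default map encodes agreement logic: F4 only on
double rule-in (both group 4); F34 when one axis is at F34 level or above
and the other is not ruling out; F0-2 when blood testing rules out against a
merely grey Agile result; everything discordant or doubly grey goes to
Biopsy. The map is shipped as data (`default_combination_map()`), versioned
through the run configuration, and fully overridable.

The guideline-style comparator (`easl_pathway()`) uses config-supplied tier
thresholds with defaults FIB-4 1.3, stiffness 8 and 12 kPa, FMV3G 0.76 —
the guideline values — because the study's own supplementary detail is not
available. For cirrhosis triage, F0-2 and Biopsy/grey results count as the
rule-out zone, F34 as undetermined, F4 as rule-in (`cirrhosis_zones()`).

## Risk charts

The published charts show the joint effect of the two couples as contours on
composite axes that switch scale at Agile3+ 0.678 and FMV3G 0.76. The
functional form behind them is not printed, so the package declares one: a
linear logistic model with hinge activations at the switch points. The
second-line score enters only beyond its companion's switch point, matching
how the charts are read. Fitting is plain maximum likelihood (`stats::glm`,
convergence 1e-10, 100 iterations); complete or quasi-complete separation is
detected via boundary fitted values and refused rather than reported as a
fit. Band boundaries default to 5/10/20/40/60/80% for F4 (7 bands) and
deciles 10–90% for F34 (10 bands), matching the published band counts;
bands are half-open `[low, high)` with boundary risks assigned upward.

The chart grid parameterises each composite axis on [0, 1]; beyond the
switch point the coordinate is the rescaled second-line score with the
first-line score pinned just above its switch value. The fitted surface has
a small jump at the switch (the hinge activates), which is inherent to the
hinge form; the axis itself orders severity continuously.

## Evaluation conventions

- AUROC uses the midrank Mann-Whitney estimator (ties count 1/2 — clinical
  scores are rounded to 2–3 decimals, so ties are real), with DeLong
  placement variance for the CI and the paired test. Placements are computed
  by the rank decomposition, O(n log n).
- Calibration tables bin predictions into fixed 10%-wide bins by default;
  empty bins are kept and counted, never dropped. The mean signed difference
  (predicted minus observed, unweighted across non-empty bins) is the
  headline summary; a count-weighted version is also returned.
- The accuracy report declares its correctness convention explicitly because
  the published "correctly diagnosed" figure does not formalise how the
  Biopsy category enters: F0-2 ↔ stage ≤ 2, F34 ↔ stage ∈ {3, 4}, F4 ↔
  stage 4; Biopsy patients are excluded from the accuracy numerator and
  reported as the biopsy rate, and an inclusive accuracy (Biopsy counted
  incorrect) is also emitted. Off-by-one errors are counted on the ordered
  grouping {F0-2, F3, F4}. With every prediction Biopsy, accuracy is 0/0 and
  reported as NaN.
- Descriptive comparisons use Mann-Whitney for continuous variables and
  chi-squared for categorical ones, switching to Fisher's exact test when
  any expected cell count is below 5.

## What the generator does and does not emulate

Passing the package's conformance checks shows that the *marginal*
behaviour of the synthetic cohorts — stage mix, score quartiles, per-test
discrimination, morphometry-stage correlation — matches the published
summary statistics, and that every algorithmic component behaves correctly
on such data. It does not show that the *joint* distribution of the seven
tests matches the real cohorts: that structure is not published, and the
copula defaults are assumptions. The visible consequence is the worked
example on the cirrhosis chart: at Agile3+ 0.85, Agile4 0.68, FMV3G 0.91,
CMV3G 0.40 the published chart reads 60–80% cirrhosis risk, while models
fitted on the synthetic cohorts predict about 52% — and the synthetic
cohorts' own empirical conditional prevalence near that profile is also
about 53%, i.e. the model is faithful to the data it sees; the profile is
simply less cirrhosis-specific under the assumed joint structure than in
reality. The advanced-fibrosis side of the same example (> 90%) reproduces
robustly. Other non-emulated features: longitudinal outcomes, treatment
effects, biopsy sampling error, and the joint lab–score distribution beyond
the FIB-4 identity.

## Numerical choices and problem sizes

Root-finding uses `stats::uniroot` at tolerance 1e-13 (calibration) and
1e-12 (morphometry noise); calibration residuals are verified below 1e-6
and re-evaluating the analytic forward map at the solution returns the
targets. Default calibrations are cached per session — they are
deterministic, so caching cannot change results. The test suite and the
acceptance script use cohorts of 100,000 (prevalences, medians, morphometry,
risk-model fits over five seeds) and 200,000 (empirical AUROC recovery,
where the Monte-Carlo standard error is about 0.001, comfortably inside the
±0.005 conformance band); parameter-recovery checks use n = 50,000, where
three standard errors give a sharp yet stable criterion.

## Known limitations

- The copula correlations, the combination map, the EASL tier thresholds,
  the risk-model functional form and the band cutpoints are all declared
  assumptions where the source material prints none; all are configurable.
- FibroMeterV3G/CirrhoMeterV3G and the Agile formulas are proprietary or
  externally published; the package consumes them as inputs and never
  approximates their coefficient sets.
- The generator matches marginals, not the joint distribution (see above);
  absolute risk levels read off synthetic-fit charts should not be
  interpreted clinically.
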