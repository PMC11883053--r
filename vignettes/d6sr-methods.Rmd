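---
title: "Modelling tree-ring D6SR isotopomer ratios: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tree-ring D6SR isotopomer ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoring)
```

## The proxy and the question

The D6SR ratio — the abundance ratio of the two deuterium isotopomers of
tree-ring glucose that differ at the C6 position — reflects the balance of
photorespiration (which feeds the D6S position) and photosynthesis (D6R) in
the canopy. Because chloroplast CO2 rises with atmospheric CO2 (Ca) and the
Rubisco oxygenation-to-carboxylation ratio falls as `2 Γ*/Cc`, a centennial
Ca rise should lower D6SR; growing crown exposure works the other way. The
package models D6SR measured on pooled, dated wood samples as a function of
Ca, stem diameter, and growing-season climate, with full propagation of the
nested measurement structure.

## From raw series to per-sample covariates

Monthly climate is reduced to a growing season defined as the months with
precipitation *strictly above* 100 mm — the printed threshold rule taken
literally, so a 100.0 mm month is excluded. Day temperature is
`Tday = (1/3) Tmin + (2/3) Tmax`, computed per month and averaged
*unweighted* across the retained months; the source climatology is silent on
within-season weighting, and an unweighted mean adds no assumptions. Years
with no qualifying month are kept and flagged (`n_months = 0`, missing
`tday`) rather than dropped.

For Southern-hemisphere sites the ring year runs July–June and is labelled
by its starting calendar year (the Schulman convention); `shift_ring_year()`
implements the relabelling for any start month.

A pooled wood sample physically contains more material from wide rings, so
annual covariates (Ca, Tday, precipitation) are pooled with weights
proportional to ring width. Diameter is the unweighted mean reconstructed
DBH over the pooled years: it is a state variable of the tree rather than a
constituent of the wood, so mass-weighting has no physical rationale there.

Covariates are standardized (mean 0, SD 1, n−1 denominator) across the 40
samples before fitting; the scaling records are stored with the fit so that
scenario covariates are transformed identically and predictions can be
mapped back to natural units.

**Diameter transform.** The half-saturation of a Michaelis–Menten curve must
stay positive, and a centered diameter would put negative values into the
denominator for small trees. The default therefore divides diameter by its
sample SD without centering (`scaled`); `raw` (cm) and `zscore` are
selectable. Published estimates of the half-saturation on a transformed
scale (≈ 0.9 with a wide interval) are consistent with this choice, but the
original transform is not stated; both options are supported rather than
guessed at.

## The hierarchical model

For replicate *l* of sample *k* of tree *j* of site *i*:

```
D6SR_ijkl ~ Normal(mu_ijk, sigma)
mu_ijk    = a_ijk * D_k / (b_ijk + D_k)                      (gMM form)
a_ijk     = a0 + β_ca z_ca + β_t z_tday + β_p z_precip
            + u^a_site(i) + u^a_tree(ij) + u^a_sample(ijk)
b_ijk     = b0 + u^b_site(i) + u^b_tree(ij) + u^b_sample(ijk)
```

All random intercepts are independent zero-mean normals with level-specific
SDs, separately for `a` and `b` — the simplest structure consistent with
"nested random effects on the intercept for both parameters". No
correlations between the `a` and `b` deviations are modelled. Linear and
log-linear alternatives replace the saturating curve by
`intercept + slope · zD` with `zD` the z-scored (log) diameter and keep the
random-intercept structure on the single intercept.

**Half-saturation floor.** Additive deviations can push `b_ijk` negative.
The generator truncates the sampled half-saturation at `0.05 · b0`; the
fitted model applies the same floor as a smooth softplus (width 0.01 in
scaled-diameter units) so the posterior stays differentiable for the
gradient-based sampler. With the default weakly informative SD priors the
floor is essentially never active; it exists to keep the mean function
defined in the tails.

**Priors** (all configurable via `d6sr_priors()`): asymptote
Normal(1, 0.25) truncated positive — D6SR ratios sit near 1 by construction;
half-saturation half-Normal(1) on the scaled-diameter axis; slopes
Normal(0, 0.1) — a 1 SD covariate shift moving the asymptote by more than
±0.2 would exceed anything plausibly seen in the data; random-effect SDs and
the residual SD half-Normal(0.1), matching the few-percent noise scale of
replicate deuterium NMR measurements. The original study's exact priors are
not published; these are the package's own weakly informative choices at the
observed data scale.

**Sampling.** The posterior is explored with a Hamiltonian Monte Carlo
sampler implemented in the package (C++ gradient, R driver): non-centered
random effects, positive parameters on the log scale with Jacobian
corrections, dual-averaged step size targeting 0.9 acceptance, windowed
diagonal mass-matrix adaptation during warmup, and trajectory lengths of 3.5
units in mass-standardized space with ±30% jitter (capped at 128 leapfrog
steps). The fairly high acceptance target and long trajectories are chosen
for the mild funnel geometry of the sample-level variance components, which
otherwise dominate the worst-case split-Rhat. The default run is 4 chains × 4000 iterations with the first 2000
discarded as warmup. Single-site samplers (tested first) cannot traverse the
strong posterior ridge between the asymptote and the half-saturation that
this curve family produces; joint gradient-based proposals handle it, giving
split-Rhat ≈ 1.00 and zero divergences at the default settings. Given a
seed, chains are bitwise reproducible.

**Summaries.** Posterior medians with 95% quantile credible intervals;
for slopes the posterior sign probability PP — the share of draws sharing
the sign of the posterior median, with draws exactly at zero counted half
(equivalently, the larger of the two tail masses). PP is not reported for
intercepts or SDs, where a sign comparison is meaningless. Convergence is
monitored with split-Rhat and a Geyer initial-monotone-sequence effective
sample size; a fit warns (never silently passes) when Rhat exceeds 1.05 or
divergent trajectories occur.

**Sample means.** Pre-averaging replicates per sample is common practice in
isotope work, so every model can also be fitted to per-sample means
(`use_sample_means = TRUE`). With one row per sample the sample-level
deviation is not identifiable and is absorbed into the residual. Mean-based
fits give compatible slope medians with narrower intervals — they ignore
replicate variability, which also makes their certainty optimistic; the
replicate-level fit is the default for inference.

**Model comparison.** WAIC and PSIS-LOO are computed from the pointwise
log-likelihood matrix; the PSIS tail is smoothed with a generalized Pareto
fit (Zhang–Stephens profile estimator with small-sample shrinkage), and
Pareto shapes above 0.7 are flagged. Bayesian R² is the per-draw
`var(fitted) / (var(fitted) + sigma²)`, reported for the full structured
mean and with random effects zeroed (fixed-effects-only). Both are validated
in the test suite against exact small-n oracles (a hand-computed WAIC and
closed-form leave-one-out refits in a conjugate normal model).

## Scenario predictions

Predictions marginalize random effects at zero (population level), matching
how effect displays are usually drawn; posterior uncertainty is shown as
200 draw curves by default. Three displays are provided: single-covariate
response curves, families of diameter curves at constant Ca, and the joint
trajectory of a hypothetical tree growing at constant increment through a
historically shaped Ca rise. Under a negative Ca slope and accelerating Ca,
the joint path rises (saturating diameter effect), peaks once, and then
declines (Ca effect no longer compensated); `find_trajectory_maximum()`
locates the peak, resolving ties to the smallest diameter. The *location* of
the peak depends on the fitted magnitudes and on trajectory settings
(starting diameter and increment are not published for the original
display; the defaults start at 10 cm and reach ≈ 120 cm over the series).
The package asserts the qualitative structure — existence and uniqueness of
an interior maximum — not a numeric peak position; the scenario property
tests use a Ca slope at the stronger end of the plausible range (−0.03 per
SD) so the crossover falls safely inside the simulated diameter span.

## The Farquhar / β interpretation layer

With chloroplast CO2 equal to intercellular CO2 (infinite mesophyll
conductance) and Ci/Ca constant — the standard first-order approximations —
`Vo/Vc = 2 Γ*/Ci` is exactly inversely proportional to Ci. A 36% Ci rise
therefore cuts Vo/Vc by `1 − 1/1.36 ≈ 26%`, and the Walker-style sensitivity
`β = ln(1+Δx)/ln(1+ΔCa)` equals −1 exactly; the conventional −0.98 arises
when the rounded 26% figure is re-entered into the formula. Both behaviours
are asserted in the tests. Carboxylation uses the Rubisco-limited rate with
Bernacchi-style 25 °C constants (Γ* = 42.75 µbar, Kc = 404.9 µbar,
Ko = 278.4 mbar, O = 210 mbar, all configurable); an optional
electron-transport capacity activates the RuBP-regeneration limit. Gross
photosynthesis is `Vc (1 − Γ*/Ci) = Vc − Vo/2`. Because the exact kinetic
constants behind published percentage figures are not available, the
package's computed gross-photosynthesis increase for the historical Ci step
brackets ≈ 28–34% rather than reproducing one printed value; reproductions
that depend on those unpublished constants are treated as approximate.

The empirical mapping from D6SR to Vo/Vc (a crop-plant calibration whose
coefficients are not published) is deliberately **not** baked in: it enters
only as a user-supplied slope/intercept if desired.

## The synthetic-data generator

The generator is first-class, tested code that reproduces the study
conditions: 3 climatically distinct sites × 3 trees × 3–5 pooled samples per
tree (14/14/12 per site, 40 samples) × 5–6 NMR replicates, ≈ 220
observations; pooling 10 years per sample except 7 at the youngest-tree
site; sample windows placed at approximately equidistant Ca along each
tree's life, starting once reconstructed DBH reaches 20 cm; resulting sample
DBH ≈ 20–115 cm and pooled Ca ≈ 298–405 ppm. The Ca trajectory is piecewise —
linear rise before 1959, exponential after — calibrated to 298 ppm in 1905
and 405 ppm in 2016; only its shape matters for recovery tests. Replicate
noise defaults to σ = 0.03 (≈ 3% of D6SR ≈ 1), the "few percent" scale of
deuterium NMR. Within- and between-sample variance magnitudes are not
published; the defaults put 2% SDs on the asymptote deviations at every
level (5% on the half-saturation), chosen once as a realistic split and not
revisited. One master seed drives deterministic per-site/per-tree
sub-streams, so identical seeds give byte-identical datasets.

What the generator does *not* emulate: NMR spectra and their deconvolution,
wood chemistry, cross-dating error, missing rings, disturbance-driven growth
suppressions, or temporal autocorrelation in ring widths beyond the tree's
mean growth level. Passing recovery tests therefore demonstrate that the
estimator is correct under the stated generative assumptions — not that
those assumptions exhaust real tree-ring data.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: empty year ranges, all-dry years,
zero ring widths, zero-variance covariates, and non-positive gMM
denominators raise errors or flagged records rather than propagating NaN.
Quantile intervals use the standard type-7 order-statistic interpolation.
The test suite runs its pilot fits at 2000 iterations (1000 warmup) and the
parameter-recovery study at the full 4 × 4000 design across 20 replicate
datasets — the replicate count balances binomial resolution on a 95%
coverage claim against simulation cost. The interval-coverage criterion
(≥ 18 of 20 replicates covering the generating CO2 slope) and the Rhat bound
(1.01) follow the planned analysis, not post-hoc inspection.

## Known limitations

* Exact reproduction of published real-data estimates requires the archived
  field dataset and the original (unpublished) priors; the package's claims
  about the real study are qualitative (signs, orders of magnitude,
  structure), while its quantitative guarantees are about its own generative
  model.
* The random-effect structure assumes independence between the asymptote and
  half-saturation deviations; a correlated structure is not implemented.
* PSIS-LOO relies on finite-variance importance ratios; the Pareto-k
  diagnostic flags failures but refitting without the offending observation
  is left to the user.
* Temperature responses of the Farquhar kinetic constants (Arrhenius
  corrections) are not applied; constants are interpreted at 25 °C.
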