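# isoring

Bayesian analysis of tree-ring deuterium isotopomer ratios as a proxy for the
photorespiration-to-photosynthesis balance of forest canopy trees.

## The science

The ratio of the two deuterium isotopomers of tree-ring-derived glucose that
differ at the C6 position (D6S : D6R, "D6SR") tracks the ratio of
photorespiration to photosynthesis in the leaf: Rubisco oxygenation feeds the
D6S position, carboxylation the D6R position. Measured along dated rings, D6SR
therefore reconstructs how photosynthetic efficiency responded to the
centennial rise of atmospheric CO2 (Ca), to growing tree size (a proxy for
crown exposure), and to climate.

`isoring` implements the full analysis chain:

1. **Covariates** — growing-season day temperature
   `Tday = (1/3) Tmin + (2/3) Tmax`, growing season defined as months with
   > 100 mm precipitation, a mid-year ring-year start for Southern-hemisphere
   sites, stem diameter reconstructed from cumulative ring widths, and
   pooling of annual covariates over multi-year wood samples with
   ring-width-proportional weights.
2. **Hierarchical model** — the generalized Michaelis–Menten (gMM) curve

   `D6SR = a · D / (b + D)`

   with asymptote `a` depending linearly on standardized Ca, Tday and
   precipitation, nested random intercepts (site / tree-in-site /
   sample-in-tree) on both `a` and `b`, and a Normal replicate error for the
   NMR re-measurements. Linear and log-linear diameter effects are fitted as
   robustness alternatives. Sampling uses the package's own Hamiltonian Monte
   Carlo backend (Rcpp), with Stan-style warmup adaptation and non-centered
   random effects.
3. **Model evaluation** — posterior medians and 95% quantile credible
   intervals, posterior sign probabilities (PP), split-Rhat and effective
   sample size, WAIC, PSIS-LOO, Bayesian R² (full and fixed-effects-only),
   posterior predictive checks.
4. **Scenarios** — covariate response curves with posterior draw envelopes,
   families of diameter curves at constant Ca, and joint trajectories of a
   tree growing at constant increment through the historical Ca rise,
   including the location of the D6SR maximum such trajectories exhibit.
5. **Farquhar / β layer** — oxygenation-to-carboxylation ratio
   `Vo/Vc = 2 Γ* / Ci`, Rubisco-limited carboxylation, gross photosynthesis,
   and Walker-style CO2 sensitivity coefficients
   `β = ln(1 + Δx) / ln(1 + ΔCa)`.
6. **Synthetic data** — a generator that reproduces the nested study layout
   (3 sites × 3 trees × 3–5 pooled samples × 5–6 NMR replicates, ≈ 220
   observations, DBH ≈ 20–115 cm, Ca ≈ 298–405 ppm) with known ground-truth
   parameters, so every stage is testable without any external download.

## Worked example

```r
library(isoring)

ds  <- simulate_d6sr_dataset(true_params(seed = 7))   # known truth: a0 = 1,
fit <- fit_d6sr(ds, mcmc = mcmc_settings(seed = 42))  # beta_ca = -0.009, ...
fit
#> Bayesian hierarchical D6SR model (gmm form)
#>   220 observations, 40 samples; 4 chains x 2000 draws
#>             term estimate conf.low conf.high    pp rhat  ess
#>        asymptote  1.00245  0.87278    1.1379    NA    1 2016
#>  half_saturation  0.85294  0.61268    1.1315    NA    1 2026
#>             b_ca -0.01449 -0.04465    0.0138 0.842    1 1853
#>           b_tday  0.00721 -0.09306    0.0794 0.575    1 3301
#>         b_precip  0.00997 -0.05960    0.1161 0.607    1 3029
#>        ...
#>            sigma  0.02885  0.02611    0.0321    NA    1 8000
```

The asymptote (the D6SR a fully exposed large tree attains) is recovered near
its true value 1.0, the half-saturation near 0.89 on the scaled-diameter
axis, and the replicate SD near the 3% NMR noise used to generate the data.
The CO2 slope `b_ca` is the change in the asymptote per standard deviation of
pooled Ca; its 95% interval covers the generating value −0.009.

Downstream:

```r
glance(fit)                                   # WAIC, LOOIC, R2, diagnostics
tidy(fit)                                     # Table-style parameter summary
predict_constant_ca(fit)                      # curve family at fixed Ca levels
tr <- predict_joint_trajectory(fit, make_ca_series(1900:2019))
find_trajectory_maximum(tr)                   # where D6SR peaks along the path
farquhar_response(298, 405)                   # Vo/Vc, Vc, Ag changes + betas
beta_value(-0.26, 0.36)                       # -0.98
```

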