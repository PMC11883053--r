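#' Generalized Michaelis--Menten mean function
#'
#' Saturating curve `a * d / (b + d)` linking the D6SR ratio to stem diameter:
#' `a` is the asymptote (the D6SR a fully exposed, large-diameter tree
#' attains) and `b` the half-saturation, the diameter at which D6SR is halfway
#' to the asymptote.
#'
#' @param diameter Diameter (any consistent transform; must keep `b + d > 0`).
#' @param a Asymptote.
#' @param b Half-saturation.
#' @return The mean D6SR, vectorised over the inputs.
#' @examples
#' gmm_mean(0.89, 1.016, 0.89) # half the asymptote
#' @export
gmm_mean <- function(diameter, a, b) {
  if (any(b + diameter <= 0)) {
    stop("`b + diameter` must be positive.", call. = FALSE)
  }
  a * diameter / (b + diameter)
}

#' Model specification for D6SR fits
#'
#' @param form Mean structure for the diameter effect: `"gmm"` (saturating
#'   generalized Michaelis--Menten), `"linear"`, or `"log_linear"` (linear in
#'   log diameter).
#' @param asymptote_covariates Covariates allowed to shift the asymptote
#'   (or the intercept, for the linear forms); any subset of
#'   `c("ca", "tday", "precip")`.
#' @param random_levels Nested random-intercept levels, outermost first.
#' @param use_sample_means Fit on per-sample mean D6SR instead of all
#'   replicates? The sample-level deviation is then absorbed into the
#'   residual (it is not identifiable with one row per sample).
#' @param diameter_transform How diameter enters the gMM denominator:
#'   `"scaled"` (divided by the sample SD, not centered, so it stays
#'   positive), `"zscore"`, or `"raw"` (cm). The linear forms use a z-scored
#'   (log) diameter regardless.
#' @return List of class `d6sr_model_spec`.
#' @export
d6sr_model_spec <- function(form = c("gmm", "linear", "log_linear"),
                            asymptote_covariates = c("ca", "tday", "precip"),
                            random_levels = c("site", "tree", "sample"),
                            use_sample_means = FALSE,
                            diameter_transform = c("scaled", "zscore", "raw")) {
  form <- match.arg(form)
  diameter_transform <- match.arg(diameter_transform)
  stopifnot(all(asymptote_covariates %in% c("ca", "tday", "precip")),
            all(random_levels %in% c("site", "tree", "sample")))
  if (form == "gmm" && diameter_transform == "zscore") {
    warning("a centered diameter can make the Michaelis-Menten denominator ",
            "non-positive for small trees; \"scaled\" keeps it positive.",
            call. = FALSE)
  }
  structure(list(form = form, asymptote_covariates = asymptote_covariates,
                 random_levels = random_levels,
                 use_sample_means = use_sample_means,
                 diameter_transform = diameter_transform),
            class = "d6sr_model_spec")
}

#' Prior hyperparameters
#'
#' Weakly informative priors on the scale of the data (D6SR near 1 with
#' few-percent noise): the asymptote/intercept gets a Normal(1, 0.25) prior
#' (truncated positive for the gMM asymptote), the half-saturation a
#' half-Normal(1), slopes Normal(0, 0.1), random-effect SDs half-Normal(0.1)
#' and the residual SD half-Normal(0.1). All are configurable. The simulated
#' half-saturation floor (`floor_frac * b0`, smoothed over `floor_smooth`)
#' keeps the saturating mean defined when sampled deviations would push the
#' half-saturation non-positive.
#'
#' @param intercept_mean,intercept_sd Normal prior on the asymptote (gMM) or
#'   general intercept (linear forms).
#' @param b0_sd Half-normal scale for the half-saturation.
#' @param slope_sd Normal SD for the asymptote covariate slopes.
#' @param diameter_slope_sd Normal SD for the diameter slope (linear forms).
#' @param re_sd_scale Half-normal scale for all random-effect SDs.
#' @param sigma_sd Half-normal scale for the residual SD.
#' @param floor_frac,floor_smooth Smooth lower floor on the per-sample
#'   half-saturation, as a fraction of `b0`.
#' @return List of class `d6sr_priors`.
#' @export
d6sr_priors <- function(intercept_mean = 1, intercept_sd = 0.25, b0_sd = 1,
                        slope_sd = 0.1, diameter_slope_sd = 0.1,
                        re_sd_scale = 0.1, sigma_sd = 0.1,
                        floor_frac = 0.05, floor_smooth = 0.01) {
  stopifnot(intercept_sd > 0, b0_sd > 0, slope_sd > 0, diameter_slope_sd > 0,
            re_sd_scale > 0, sigma_sd > 0, floor_frac >= 0, floor_smooth > 0)
  structure(list(intercept_mean = intercept_mean, intercept_sd = intercept_sd,
                 b0_sd = b0_sd, slope_sd = slope_sd,
                 diameter_slope_sd = diameter_slope_sd,
                 re_sd_scale = re_sd_scale, sigma_sd = sigma_sd,
                 floor_frac = floor_frac, floor_smooth = floor_smooth),
            class = "d6sr_priors")
}

#' MCMC settings
#'
#' @param chains Number of chains (at least 2 for convergence diagnostics).
#' @param iter Iterations per chain, including warmup.
#' @param warmup Warmup (adaptation) iterations discarded from each chain.
#' @param seed Seed; per-chain streams are derived from it.
#' @param target_accept Target acceptance statistic for step-size adaptation.
#' @param sim_length Trajectory length of each Hamiltonian proposal in
#'   mass-standardised parameter space.
#' @param max_leapfrog Cap on leapfrog steps per proposal.
#' @param init_step Initial leapfrog step size before adaptation.
#' @return List of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 4, iter = 4000, warmup = 2000, seed = 1L,
                          target_accept = 0.9, sim_length = 3.5,
                          max_leapfrog = 128, init_step = 0.01) {
  stopifnot(chains >= 1, warmup < iter, warmup >= 200,
            target_accept > 0, target_accept < 1)
  if (chains < 2) {
    warning("fewer than 2 chains: Rhat and between-chain diagnostics are ",
            "unavailable.", call. = FALSE)
  }
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 target_accept = target_accept, sim_length = sim_length,
                 max_leapfrog = as.integer(max_leapfrog),
                 init_step = init_step),
            class = "mcmc_settings")
}

#' Average replicate measurements within samples
#'
#' Collapses the NMR re-measurements of each wood sample to their mean, the
#' common pre-averaging practice in isotope work. Fitting on means discards
#' within-sample variability, so slope estimates come out similar but with
#' narrower intervals.
#'
#' @param d6sr Tibble with `site`, `tree`, `sample`, `d6sr` columns (a
#'   `d6sr_dataset` is also accepted).
#' @return Tibble with one row per sample: `site`, `tree`, `sample`,
#'   `n_replicates`, `d6sr` (the mean).
#' @export
aggregate_to_means <- function(d6sr) {
  if (inherits(d6sr, "d6sr_dataset")) d6sr <- d6sr$d6sr
  stopifnot(is.data.frame(d6sr))
  d6sr |>
    dplyr::group_by(.data$site, .data$tree, .data$sample) |>
    dplyr::summarise(n_replicates = dplyr::n(), d6sr = mean(.data$d6sr),
                     .groups = "drop")
}

# assemble the flat data list consumed by the C++ sampler
build_model_data <- function(obs, covariates, spec, priors) {
  cv <- covariates$covariates
  scal <- covariates$scaling$dbh
  dbh_sd <- scal$scale
  Dgmm <- switch(spec$diameter_transform,
                 raw = cv$dbh,
                 scaled = cv$dbh / dbh_sd,
                 zscore = (cv$dbh - mean(cv$dbh)) / stats::sd(cv$dbh))
  D <- switch(spec$form,
              gmm = Dgmm,
              linear = as.vector(scale(cv$dbh)),
              log_linear = as.vector(scale(log(cv$dbh))))
  if (spec$form == "log_linear" && any(cv$dbh <= 0)) {
    stop("log-linear form needs positive raw diameters.", call. = FALSE)
  }
  if (spec$form == "gmm" && any(D <= 0)) {
    stop("gMM requires strictly positive transformed diameters; use the ",
         "\"scaled\" or \"raw\" transform.", call. = FALSE)
  }
  Xcols <- paste0("z_", spec$asymptote_covariates)
  X <- as.matrix(cv[, Xcols, drop = FALSE])
  samp_idx <- match(obs$sample, cv$sample)
  if (anyNA(samp_idx)) stop("observations reference unknown samples.", call. = FALSE)
  sites <- sort(unique(cv$site))
  trees <- sort(unique(cv$tree))
  lev <- c(site = "site" %in% spec$random_levels,
           tree = "tree" %in% spec$random_levels,
           sample = "sample" %in% spec$random_levels && !spec$use_sample_means)
  list(form = ifelse(spec$form == "gmm", 0L, 1L),
       y = obs$d6sr, samp = samp_idx, D = D, X = X,
       site = match(cv$site, sites), tree = match(cv$tree, trees),
       S = length(sites), T = length(trees),
       lev_site = as.integer(lev[["site"]]),
       lev_tree = as.integer(lev[["tree"]]),
       lev_samp = as.integer(lev[["sample"]]),
       priors = unclass(priors),
       site_labels = sites, tree_labels = trees, sample_labels = cv$sample)
}

# natural-scale parameter names and the transform for each column of the
# unconstrained draw matrix
param_table <- function(dat, spec) {
  lay <- .hmc_layout(dat[!(names(dat) %in%
                             c("site_labels", "tree_labels", "sample_labels"))])
  P <- ncol(dat$X)
  covs <- spec$asymptote_covariates
  nm <- character(lay$np)
  tf <- character(lay$np)   # "exp" or "id"
  if (spec$form == "gmm") {
    nm[1] <- "asymptote"; tf[1] <- "exp"
    nm[2] <- "half_saturation"; tf[2] <- "exp"
  } else {
    nm[1] <- "intercept"; tf[1] <- "id"
    nm[2] <- if (spec$form == "linear") "b_diameter" else "b_log_diameter"
    tf[2] <- "id"
  }
  nm[lay$o_beta + seq_len(P)] <- paste0("b_", covs)
  tf[lay$o_beta + seq_len(P)] <- "id"
  lev_names <- c("site", "tree", "sample")[c(dat$lev_site, dat$lev_tree,
                                             dat$lev_samp) == 1L]
  nsd <- length(lev_names)
  nm[lay$o_lsd_a + seq_len(nsd)] <- paste0("sd_", lev_names, "_a")
  tf[lay$o_lsd_a + seq_len(nsd)] <- "exp"
  if (spec$form == "gmm") {
    nm[lay$o_lsd_b + seq_len(nsd)] <- paste0("sd_", lev_names, "_b")
    tf[lay$o_lsd_b + seq_len(nsd)] <- "exp"
  }
  nm[lay$o_lsig + 1] <- "sigma"; tf[lay$o_lsig + 1] <- "exp"
  zblock <- function(off, n, label, who) {
    if (n > 0) {
      nm[off + seq_len(n)] <<- paste0("z_", label, "[", who, "]")
      tf[off + seq_len(n)] <<- "id"
    }
  }
  if (dat$lev_site) zblock(lay$o_zs_a, dat$S, "site_a", dat$site_labels)
  if (dat$lev_tree) zblock(lay$o_zt_a, dat$T, "tree_a", dat$tree_labels)
  if (dat$lev_samp) zblock(lay$o_zk_a, length(dat$D), "sample_a", dat$sample_labels)
  if (spec$form == "gmm") {
    if (dat$lev_site) zblock(lay$o_zs_b, dat$S, "site_b", dat$site_labels)
    if (dat$lev_tree) zblock(lay$o_zt_b, dat$T, "tree_b", dat$tree_labels)
    if (dat$lev_samp) zblock(lay$o_zk_b, length(dat$D), "sample_b", dat$sample_labels)
  }
  list(names = nm, transform = tf, layout = lay)
}

#' Fit a Bayesian hierarchical D6SR model
#'
#' Fits the generalized Michaelis--Menten (or linear / log-linear) model of
#' D6SR against diameter with covariate-dependent asymptote and nested
#' site/tree/sample random intercepts, using the package's Hamiltonian Monte
#' Carlo sampler (non-centered random effects; dual-averaged step size and
#' windowed diagonal mass adaptation during warmup). Draws are reproducible
#' for a given seed.
#'
#' @param data A `d6sr_dataset` from [simulate_d6sr_dataset()], or a tibble of
#'   observations (`site`, `tree`, `sample`, `d6sr`) if `covariates` is given.
#' @param covariates A `d6sr_covariates` object from [sample_covariates()];
#'   taken from `data` when that is a `d6sr_dataset`.
#' @param spec A [d6sr_model_spec()].
#' @param priors A [d6sr_priors()].
#' @param mcmc An [mcmc_settings()].
#' @return Object of class `d6sr_fit`; see [tidy.d6sr_fit()],
#'   [glance.d6sr_fit()], [log_lik()], [posterior_predictive()],
#'   [model_compare()].
#' @export
fit_d6sr <- function(data, covariates = NULL, spec = d6sr_model_spec(),
                     priors = d6sr_priors(), mcmc = mcmc_settings()) {
  stopifnot(inherits(spec, "d6sr_model_spec"), inherits(priors, "d6sr_priors"),
            inherits(mcmc, "mcmc_settings"))
  if (inherits(data, "d6sr_dataset")) {
    covariates <- data$covariates
    obs <- data$d6sr
  } else {
    obs <- tibble::as_tibble(data)
  }
  if (is.null(covariates)) stop("`covariates` is required.", call. = FALSE)
  if (nrow(obs) == 0) stop("no observations.", call. = FALSE)
  if (spec$use_sample_means) obs <- aggregate_to_means(obs)

  dat <- build_model_data(obs, covariates, spec, priors)
  cdat <- dat[!(names(dat) %in% c("site_labels", "tree_labels", "sample_labels"))]
  pt <- param_table(dat, spec)
  np <- pt$layout$np
  n_sample <- mcmc$iter - mcmc$warmup

  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(substream_seed(mcmc$seed, 55, ch))
    init <- rnorm(np, 0, 0.1)
    init[1] <- if (spec$form == "gmm") log(priors$intercept_mean) + rnorm(1, 0, 0.1)
               else priors$intercept_mean + rnorm(1, 0, 0.1)
    if (spec$form == "gmm") init[2] <- rnorm(1, 0, 0.3)
    init[pt$layout$o_lsig + 1] <- log(0.05) + rnorm(1, 0, 0.2)
    chains[[ch]] <- .hmc_chain(cdat, init, mcmc$warmup, n_sample,
                               mcmc$target_accept, mcmc$sim_length,
                               mcmc$max_leapfrog, mcmc$init_step)
  }

  draws <- array(NA_real_, dim = c(n_sample, mcmc$chains, np),
                 dimnames = list(NULL, NULL, pt$names))
  for (ch in seq_len(mcmc$chains)) {
    m <- chains[[ch]]$draws
    for (j in seq_len(np)) {
      draws[, ch, j] <- if (pt$transform[j] == "exp") exp(m[, j]) else m[, j]
    }
  }
  diag <- tibble::tibble(
    chain = seq_len(mcmc$chains),
    accept_rate = vapply(chains, `[[`, numeric(1), "accept_rate"),
    divergences = vapply(chains, `[[`, numeric(1), "divergences"),
    step_size = vapply(chains, `[[`, numeric(1), "step_size")
  )
  fit <- structure(list(
    draws = draws, param_names = pt$names, layout = pt$layout,
    obs = obs, data = dat, spec = spec, priors = priors, mcmc = mcmc,
    scaling = covariates$scaling,
    diameter_transform = covariates$diameter_transform,
    diagnostics = diag), class = "d6sr_fit")
  sm <- tidy(fit)
  bad <- sm$rhat[!is.na(sm$rhat)] > 1.05
  if (any(bad) || sum(diag$divergences) > 0) {
    warning(sprintf(
      "possible convergence problems: %d parameter(s) with Rhat > 1.05 (max %.3f), %d divergent transition(s).",
      sum(bad), max(sm$rhat, na.rm = TRUE), sum(diag$divergences)),
      call. = FALSE)
  }
  fit
}

# flattened draws (all chains stacked) as a matrix [draw, param]
flat_draws <- function(fit) {
  d <- fit$draws
  matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3],
         dimnames = list(NULL, dimnames(d)[[3]]))
}

# per-sample curve parameters and mean for each draw: returns list of
# matrices [draw, K]
fit_sample_means <- function(fit, include_random = TRUE) {
  dm <- flat_draws(fit)
  dat <- fit$data
  K <- length(dat$D)
  covs <- fit$spec$asymptote_covariates
  fixed_a <- if (fit$spec$form == "gmm") dm[, "asymptote"] else dm[, "intercept"]
  a <- matrix(fixed_a, nrow(dm), K)
  for (cc in covs) a <- a + outer(dm[, paste0("b_", cc)], dat$X[, paste0("z_", cc)])
  if (fit$spec$form != "gmm") {
    slope <- if (fit$spec$form == "linear") dm[, "b_diameter"] else dm[, "b_log_diameter"]
    a <- a + outer(slope, dat$D)
  }
  add_dev <- function(mat, side) {
    for (lv in c("site", "tree", "sample")) {
      use <- switch(lv, site = dat$lev_site, tree = dat$lev_tree,
                    sample = dat$lev_samp)
      if (!use) next
      sdcol <- paste0("sd_", lv, "_", side)
      labs <- switch(lv, site = dat$site_labels[dat$site],
                     tree = dat$tree_labels[dat$tree],
                     sample = dat$sample_labels)
      zcols <- paste0("z_", lv, "_", side, "[", labs, "]")
      mat <- mat + dm[, sdcol] * dm[, zcols, drop = FALSE]
    }
    mat
  }
  if (include_random) a <- add_dev(a, "a")
  if (fit$spec$form == "gmm") {
    b <- matrix(dm[, "half_saturation"], nrow(dm), K)
    if (include_random) b <- add_dev(b, "b")
    lo <- fit$priors$floor_frac * dm[, "half_saturation"]
    t <- fit$priors$floor_smooth
    u <- (b - lo) / t
    bb <- lo + t * ifelse(u > 30, u, log1p(exp(u)))
    mu <- a * matrix(dat$D, nrow(dm), K, byrow = TRUE) /
      (bb + matrix(dat$D, nrow(dm), K, byrow = TRUE))
  } else {
    mu <- a
  }
  list(mu = mu, sigma = dm[, "sigma"])
}

#' Pointwise log-likelihood of a fit
#'
#' Normal log density of every observation about its fitted structured mean,
#' for every posterior draw. This is the pointwise decomposition WAIC and
#' PSIS-LOO operate on.
#'
#' @param fit A `d6sr_fit`.
#' @return Matrix with one row per posterior draw (chains stacked) and one
#'   column per observation.
#' @export
log_lik <- function(fit) {
  stopifnot(inherits(fit, "d6sr_fit"))
  fm <- fit_sample_means(fit)
  mu_obs <- fm$mu[, fit$data$samp, drop = FALSE]
  dnorm(matrix(fit$obs$d6sr, nrow(mu_obs), ncol(mu_obs), byrow = TRUE),
        mu_obs, fm$sigma, log = TRUE)
}

#' Posterior predictive replicates
#'
#' Simulates replicated D6SR observations from the fitted model, one
#' replicated dataset per retained posterior draw, for posterior predictive
#' checking (e.g. density overlays of replicated vs observed data).
#'
#' @param fit A `d6sr_fit`.
#' @param ndraws Number of posterior draws to simulate from (default all).
#' @param seed Seed for the predictive noise.
#' @return Matrix `ndraws` x observations of replicated D6SR values.
#' @export
posterior_predictive <- function(fit, ndraws = NULL, seed = 1L) {
  stopifnot(inherits(fit, "d6sr_fit"))
  fm <- fit_sample_means(fit)
  S <- nrow(fm$mu)
  idx <- if (is.null(ndraws)) seq_len(S) else {
    stopifnot(ndraws >= 1)
    seq(1, S, length.out = min(ndraws, S))
  }
  mu_obs <- fm$mu[idx, fit$data$samp, drop = FALSE]
  set.seed(seed)
  yrep <- mu_obs + rnorm(length(mu_obs)) * fm$sigma[idx]
  dim(yrep) <- dim(mu_obs)
  yrep
}

#' @export
print.d6sr_fit <- function(x, ...) {
  cat("Bayesian hierarchical D6SR model (", x$spec$form, " form)\n", sep = "")
  cat(sprintf("  %d observations, %d samples; %d chains x %d draws\n",
              nrow(x$obs), length(x$data$D), dim(x$draws)[2], dim(x$draws)[1]))
  sm <- tidy(x)
  print(as.data.frame(sm), digits = 3, row.names = FALSE)
  invisible(x)
}
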