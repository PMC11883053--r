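# split-Rhat: potential scale reduction after splitting each chain in half
split_rhat <- function(m) {
  # m: iterations x chains
  h <- floor(nrow(m) / 2)
  if (h < 2 || ncol(m) < 1) return(NA_real_)
  sub <- cbind(m[seq_len(h), , drop = FALSE],
               m[(h + 1):(2 * h), , drop = FALSE])
  W <- mean(apply(sub, 2, var))
  B <- h * var(colMeans(sub))
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((h - 1) / h * W + B / h) / W)
}

# effective sample size via Geyer's initial monotone positive sequence,
# computed on split chains with chain-mean removal
ess_basic <- function(m) {
  h <- floor(nrow(m) / 2)
  if (h < 4) return(NA_real_)
  sub <- cbind(m[seq_len(h), , drop = FALSE],
               m[(h + 1):(2 * h), , drop = FALSE])
  nc <- ncol(sub)
  cent <- sweep(sub, 2, colMeans(sub))
  W <- mean(apply(sub, 2, var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- h * var(colMeans(sub))
  varp <- (h - 1) / h * W + B / h
  max_lag <- min(h - 1, 500)
  rho <- numeric(max_lag)
  for (lag in seq_len(max_lag)) {
    acov <- mean(vapply(seq_len(nc), function(c) {
      mean(cent[seq_len(h - lag), c] * cent[(lag + 1):h, c])
    }, numeric(1)))
    rho[lag] <- 1 - (W - acov) / varp
  }
  # sum over pairs while positive and monotone
  s <- 0; prev <- Inf
  lag <- 1
  while (lag + 1 <= max_lag) {
    pair <- rho[lag] + rho[lag + 1]
    if (pair < 0) break
    pair <- min(pair, prev)
    s <- s + pair
    prev <- pair
    lag <- lag + 2
  }
  ess <- nc * h / (1 + 2 * s + (if (lag <= max_lag) 0 else 0))
  max(ess, 1)
}

# posterior sign probability: share of draws with the sign of the posterior
# median; draws exactly at zero count half
posterior_sign_probability <- function(x) {
  md <- median(x)
  s <- sign(md)
  if (s == 0) return(0.5)
  (sum(sign(x) == s) + 0.5 * sum(x == 0)) / length(x)
}

#' Summarise a fitted D6SR model
#'
#' One row per model parameter with the posterior median, equal-tailed 95%
#' credible interval (quantiles), the posterior sign probability `pp` for
#' slope parameters (the share of draws sharing the sign of the posterior
#' median; not meaningful for intercepts and SDs, where it is `NA`),
#' split-Rhat and effective sample size. Random-effect z-scores are omitted
#' unless `all_parameters = TRUE`.
#'
#' @param x A `d6sr_fit`.
#' @param conf.level Credible-interval mass.
#' @param all_parameters Include the per-unit random-effect z-scores?
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (median), `conf.low`, `conf.high`,
#'   `pp`, `rhat`, `ess`.
#' @export
tidy.d6sr_fit <- function(x, conf.level = 0.95, all_parameters = FALSE, ...) {
  keep <- if (all_parameters) seq_along(x$param_names) else
    which(!startsWith(x$param_names, "z_"))
  al <- (1 - conf.level) / 2
  slopes <- startsWith(x$param_names, "b_")
  rows <- lapply(keep, function(j) {
    m <- x$draws[, , j, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    v <- as.vector(m)
    tibble::tibble(
      term = x$param_names[j],
      estimate = median(v),
      conf.low = quantile(v, al, names = FALSE),
      conf.high = quantile(v, 1 - al, names = FALSE),
      pp = if (slopes[j]) posterior_sign_probability(v) else NA_real_,
      rhat = split_rhat(m),
      ess = ess_basic(m)
    )
  })
  dplyr::bind_rows(rows)
}

#' One-line model summary
#'
#' Model-level goodness-of-fit and information criteria: WAIC, PSIS-LOO
#' LOOIC, Bayesian R2 (full model and fixed effects only), residual SD, and
#' the worst convergence diagnostics across parameters.
#'
#' @param x A `d6sr_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.d6sr_fit <- function(x, ...) {
  ll <- log_lik(x)
  w <- waic(ll)
  l <- loo_psis(ll)
  rsq <- bayes_r2(x)
  sm <- tidy(x)
  tibble::tibble(
    nobs = nrow(x$obs), n_samples = length(x$data$D),
    waic = w$waic, p_waic = w$p_waic,
    looic = l$looic, p_loo = l$p_loo, max_pareto_k = max(l$pareto_k),
    r2 = rsq$r2, r2_fixed = rsq$r2_fixed,
    sigma = sm$estimate[sm$term == "sigma"],
    max_rhat = max(sm$rhat, na.rm = TRUE),
    min_ess = min(sm$ess, na.rm = TRUE),
    divergences = sum(x$diagnostics$divergences)
  )
}
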