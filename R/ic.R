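# numerically stable log(mean(exp(x)))
log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Widely applicable information criterion
#'
#' WAIC from a pointwise log-likelihood matrix: the log pointwise predictive
#' density `lppd = sum_i log mean_s exp(ll_si)` penalised by the effective
#' number of parameters `p_waic = sum_i var_s(ll_si)`;
#' `WAIC = -2 (lppd - p_waic)`.
#'
#' @param ll Matrix of pointwise log-likelihoods, draws x observations
#'   (see [log_lik()]).
#' @return List with `waic`, `elpd_waic`, `p_waic`, `lppd`, and the pointwise
#'   `elpd_i`.
#' @export
waic <- function(ll) {
  stopifnot(is.matrix(ll), nrow(ll) >= 2)
  lppd_i <- apply(ll, 2, log_mean_exp)
  p_i <- apply(ll, 2, var)
  elpd_i <- lppd_i - p_i
  list(waic = -2 * sum(elpd_i), elpd_waic = sum(elpd_i),
       p_waic = sum(p_i), lppd = sum(lppd_i), elpd_i = elpd_i)
}

# generalized Pareto fit to exceedances (profile quasi-Bayes estimator of
# Zhang & Stephens 2009), returning shape k and scale sigma
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || x[n] <= 0) return(list(k = NA_real_, sigma = NA_real_))
  m <- 30 + floor(sqrt(n))
  prior_b <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (seq_len(m) - 0.5))) / (3 * prior_b)
  prof <- vapply(theta, function(th) {
    k <- -mean(log1p(-th * x))
    n * (log(th / k) + k - 1)
  }, numeric(1))
  w <- exp(prof - max(prof))
  w <- w / sum(w)
  th_hat <- sum(theta * w)
  k <- -mean(log1p(-th_hat * x))
  sigma <- k / th_hat
  # small-sample shrinkage of k toward 0.5 (stabilises tail estimates)
  k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smoothed importance sampling of one log-weight vector; returns
# smoothed log weights (unnormalised) and the tail shape estimate
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) return(list(lw = lw, k = -Inf))
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1):S]
  cut <- exp(lw[ord[S - M]])
  exceed <- exp(lw[tail_ids]) - cut
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k)) return(list(lw = lw, k = NA_real_))
  # replace tail by expected order statistics of the fitted gPD
  p <- (rank(lw[tail_ids]) - 0.5) / M
  sm <- log(qgpd(p, fit$k, fit$sigma) + cut)
  sm <- pmin(sm, 0)           # cap at the largest raw weight (0 after shift)
  lw[tail_ids] <- sm
  list(lw = lw, k = fit$k)
}

#' PSIS leave-one-out cross-validation
#'
#' Approximate leave-one-out expected log predictive density from posterior
#' draws via Pareto-smoothed importance sampling: for each observation the
#' importance ratios `1/p(y_i | theta_s)` are tail-smoothed with a fitted
#' generalized Pareto distribution, and the LOO predictive density is a
#' weighted average over draws. Pareto shape values above 0.7 flag
#' observations whose LOO estimate is unreliable.
#'
#' @param ll Matrix of pointwise log-likelihoods, draws x observations.
#' @return List with `looic`, `elpd_loo`, `p_loo`, pointwise `elpd_i` and
#'   `pareto_k`.
#' @export
loo_psis <- function(ll) {
  stopifnot(is.matrix(ll), nrow(ll) >= 2)
  lppd_i <- apply(ll, 2, log_mean_exp)
  res <- apply(ll, 2, function(l) {
    s <- psis_smooth(-l)
    c(elpd = log_mean_exp(l + s$lw) - log_mean_exp(s$lw), k = s$k)
  })
  elpd_i <- res["elpd", ]
  ks <- res["k", ]
  if (any(is.finite(ks) & ks > 0.7)) {
    warning(sprintf("%d observation(s) with Pareto k > 0.7; LOO estimates may be unreliable.",
                    sum(ks > 0.7, na.rm = TRUE)), call. = FALSE)
  }
  list(looic = -2 * sum(elpd_i), elpd_loo = sum(elpd_i),
       p_loo = sum(lppd_i - elpd_i), elpd_i = elpd_i, pareto_k = ks)
}

#' Bayesian R-squared
#'
#' Per-draw ratio `var(fitted) / (var(fitted) + sigma^2)` summarised by its
#' posterior median, once with the full structured mean (random effects
#' included) and once with random effects set to zero (fixed effects only).
#'
#' @param fit A `d6sr_fit`.
#' @return List with `r2` (full), `r2_fixed`, and the per-draw vectors.
#' @export
bayes_r2 <- function(fit) {
  stopifnot(inherits(fit, "d6sr_fit"))
  full <- fit_sample_means(fit, include_random = TRUE)
  fx <- fit_sample_means(fit, include_random = FALSE)
  vr <- function(mu_k) apply(mu_k[, fit$data$samp, drop = FALSE], 1, var)
  r2_full <- vr(full$mu) / (vr(full$mu) + full$sigma^2)
  r2_fx <- vr(fx$mu) / (vr(fx$mu) + fx$sigma^2)
  list(r2 = median(r2_full), r2_fixed = median(r2_fx),
       r2_draws = r2_full, r2_fixed_draws = r2_fx)
}

#' Compare fitted D6SR models
#'
#' Information criteria and variance explained for a set of models fitted to
#' the same observations: WAIC, PSIS-LOO LOOIC (with the worst Pareto shape),
#' and Bayesian R2 (full and fixed-effects-only).
#'
#' @param ... Named `d6sr_fit` objects sharing the same observation vector.
#' @return Tibble, one row per model, ordered by LOOIC.
#' @export
model_compare <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) && !inherits(fits[[1]], "d6sr_fit")) {
    fits <- fits[[1]]
  }
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "d6sr_fit")))
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- paste0("model", seq_along(fits))
  }
  y0 <- fits[[1]]$obs$d6sr
  same <- vapply(fits, function(f) {
    length(f$obs$d6sr) == length(y0) && all(f$obs$d6sr == y0)
  }, logical(1))
  if (!all(same)) {
    stop("models were not fitted to the same observations.", call. = FALSE)
  }
  rows <- purrr::imap(fits, function(f, nm) {
    ll <- log_lik(f)
    w <- waic(ll)
    l <- loo_psis(ll)
    rsq <- bayes_r2(f)
    tibble::tibble(model = nm, form = f$spec$form,
                   waic = w$waic, p_waic = w$p_waic,
                   looic = l$looic, p_loo = l$p_loo,
                   max_pareto_k = max(l$pareto_k),
                   r2 = rsq$r2, r2_fixed = rsq$r2_fixed)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$looic)
}
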