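test_that("gMM mean obeys the half-saturation and asymptote identities", {
  expect_equal(gmm_mean(0.89, 1.016, 0.89), 1.016 / 2)  # d = b gives a/2
  expect_equal(gmm_mean(1e9, 1.016, 0.89), 1.016, tolerance = 1e-8)
  d <- runif(20, 0.1, 5)
  expect_equal(gmm_mean(d, 2, d), rep(1, 20))
  expect_error(gmm_mean(-1, 1, 0.5), "positive")
})

test_that("posterior sign probability counts draws on the median's side", {
  psp <- isoring:::posterior_sign_probability
  expect_equal(psp(c(-1, -2, -3, 1)), 0.75)
  expect_equal(psp(c(-2, -1, 0, 1, 2)), 0.5)       # median exactly zero
  expect_equal(psp(c(-1, -1, 0, 2)), (2 + 0.5) / 4) # a zero draw counts half
  set.seed(1)
  x <- rnorm(20000)
  expect_lt(abs(psp(x) - 0.5), 0.02)               # symmetric about zero
  expect_equal(psp(abs(x) + 1), 1)
})

test_that("credible intervals match an independent order-statistics computation", {
  fit <- quick_fit()
  sm <- tidy(fit)
  # type-7 interpolation written out by hand
  manual_q <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  for (term in c("asymptote", "b_ca", "sigma")) {
    v <- as.vector(fit$draws[, , term])
    expect_equal(sm$estimate[sm$term == term], manual_q(v, 0.5))
    expect_equal(sm$conf.low[sm$term == term], manual_q(v, 0.025))
    expect_equal(sm$conf.high[sm$term == term], manual_q(v, 0.975))
  }
})

test_that("pointwise log likelihood matches a brute-force density evaluation", {
  fit <- quick_fit()
  ll <- log_lik(fit)
  expect_equal(dim(ll), c(prod(dim(fit$draws)[1:2]), nrow(fit$obs)))
  # rebuild the structured mean by hand for a few draws and observations
  dm <- isoring:::flat_draws(fit)
  dat <- fit$data
  cvd <- fit$data$D
  set.seed(4)
  for (s in sample.int(nrow(dm), 3)) {
    for (n in sample.int(nrow(fit$obs), 5)) {
      k <- dat$samp[n]
      a <- dm[s, "asymptote"] +
        dm[s, "b_ca"] * dat$X[k, "z_ca"] +
        dm[s, "b_tday"] * dat$X[k, "z_tday"] +
        dm[s, "b_precip"] * dat$X[k, "z_precip"] +
        dm[s, "sd_site_a"] * dm[s, paste0("z_site_a[", dat$site_labels[dat$site[k]], "]")] +
        dm[s, "sd_tree_a"] * dm[s, paste0("z_tree_a[", dat$tree_labels[dat$tree[k]], "]")] +
        dm[s, "sd_sample_a"] * dm[s, paste0("z_sample_a[", dat$sample_labels[k], "]")]
      braw <- dm[s, "half_saturation"] +
        dm[s, "sd_site_b"] * dm[s, paste0("z_site_b[", dat$site_labels[dat$site[k]], "]")] +
        dm[s, "sd_tree_b"] * dm[s, paste0("z_tree_b[", dat$tree_labels[dat$tree[k]], "]")] +
        dm[s, "sd_sample_b"] * dm[s, paste0("z_sample_b[", dat$sample_labels[k], "]")]
      lo <- fit$priors$floor_frac * dm[s, "half_saturation"]
      t <- fit$priors$floor_smooth
      bb <- lo + t * log1p(exp((braw - lo) / t))
      mu <- a * cvd[k] / (bb + cvd[k])
      sg <- dm[s, "sigma"]
      expected <- -0.5 * log(2 * pi * sg^2) -
        (fit$obs$d6sr[n] - mu)^2 / (2 * sg^2)
      expect_equal(ll[s, n], unname(expected), tolerance = 1e-10)
    }
  }
})

test_that("replicate averaging yields one row per sample", {
  d6sr <- tibble::tibble(site = "A", tree = "A1",
                         sample = c("s1", "s1", "s2"),
                         replicate = c(1, 2, 1), d6sr = c(1.0, 1.2, 0.9))
  m <- aggregate_to_means(d6sr)
  expect_equal(nrow(m), 2)
  expect_equal(m$d6sr[m$sample == "s1"], 1.1)
  expect_equal(m$d6sr[m$sample == "s2"], 0.9)  # single replicate: itself
  # the default design has 40 distinct samples
  expect_equal(nrow(aggregate_to_means(default_dataset())), 40)
})

test_that("posterior predictive replicates have the right shape and calibration", {
  fit <- quick_fit()
  yrep <- posterior_predictive(fit, ndraws = 25)
  expect_equal(dim(yrep), c(25, nrow(fit$obs)))
  # replicated grand mean close to the observed grand mean for this
  # well-specified fit
  expect_lt(abs(mean(yrep) - mean(fit$obs$d6sr)), 0.02)
  # reproducible under the same seed
  expect_identical(posterior_predictive(fit, ndraws = 5, seed = 3),
                   posterior_predictive(fit, ndraws = 5, seed = 3))
})

test_that("the sampler's analytic gradient matches finite differences", {
  ds <- default_dataset()
  for (form in c("gmm", "linear")) {
    spec <- d6sr_model_spec(form = form)
    dat <- isoring:::build_model_data(ds$d6sr, ds$covariates, spec, d6sr_priors())
    cdat <- dat[!(names(dat) %in% c("site_labels", "tree_labels", "sample_labels"))]
    np <- isoring:::.hmc_layout(cdat)$np
    set.seed(6)
    th <- rnorm(np, 0, 0.3)
    th[1] <- if (form == "gmm") 0 else 1
    got <- isoring:::.hmc_lp_grad(th, cdat)
    eps <- 1e-6
    idx <- c(1:13, np - 3, np)   # fixed effects, SDs, a few z scores
    for (i in idx) {
      tp <- th; tm <- th
      tp[i] <- tp[i] + eps; tm[i] <- tm[i] - eps
      fd <- (isoring:::.hmc_lp_grad(tp, cdat)$lp -
               isoring:::.hmc_lp_grad(tm, cdat)$lp) / (2 * eps)
      expect_equal(got$grad[i], fd, tolerance = 1e-4)
    }
  }
})
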