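test_that("synthetic CO2 trajectory matches the sampled historical range", {
  s <- make_ca_series(1905:2016)
  expect_equal(min(s$ca), 298, tolerance = 0.01)
  expect_equal(max(s$ca), 405, tolerance = 0.01)
  expect_true(all(diff(s$ca) >= 0))            # monotone nondecreasing
  expect_equal(nrow(make_ca_series(1960)), 1)  # single year
  flat <- make_ca_series(1900:1950, flat_ppm = 300)
  expect_true(all(flat$ca == 300))
  expect_error(make_ca_series(integer(0)), "empty")
  expect_error(make_ca_series(1700:1800), "1850")
})

test_that("simulated tree rings accumulate into the target DBH span", {
  design <- study_design()
  rings <- simulate_tree_rings(design, seed = 3)
  # strictly increasing cumulative diameter within every tree
  by_tree <- split(rings, rings$tree)
  expect_true(all(vapply(by_tree, function(tr) all(diff(tr$dbh_cm) > 0), TRUE)))
  # default design covers roughly the 20-114 cm span of sampled trees
  finals <- vapply(by_tree, function(tr) max(tr$dbh_cm), numeric(1))
  expect_gt(max(finals), 100)
  starts <- vapply(by_tree, function(tr) min(tr$dbh_cm), numeric(1))
  expect_lt(min(starts), 20)
  # constant 2.5 mm rings over 100 years: cumulative radius 250 mm
  d0 <- study_design(ring_width_sd_mm = 0, ring_width_mean_mm = 2.5,
                     birth_years = list(c(1901, 1901, 1901), c(1901, 1901, 1901),
                                        c(1901, 1901, 1901)),
                     collection_years = c(2000, 2000, 2000),
                     pith_offset_mm = 0)
  r0 <- simulate_tree_rings(d0, seed = 1)
  one <- r0[r0$tree == "A1", ]
  expect_equal(sum(one$width_mm), 250)
  expect_equal(max(one$dbh_cm), 50)
  # zero-variance increments are reproducible and identical across seeds
  expect_identical(simulate_tree_rings(d0, seed = 1), simulate_tree_rings(d0, seed = 1))
})

test_that("default dataset reproduces the nested study layout", {
  ds <- default_dataset()
  cv <- ds$covariates$covariates
  expect_equal(dplyr::n_distinct(cv$site), 3)
  expect_equal(dplyr::n_distinct(cv$tree), 9)
  expect_equal(nrow(cv), 40)                       # pooled samples
  per_site <- table(cv$site)
  expect_true(all(per_site >= 12 & per_site <= 14))
  # replicates: 5-6 per sample, total near 223
  per_sample <- table(ds$d6sr$sample)
  expect_true(all(per_sample %in% 5:6))
  expect_gt(nrow(ds$d6sr), 200)
  expect_lt(nrow(ds$d6sr), 245)
  # covariate ranges near the historical window
  expect_lt(min(cv$dbh), 30); expect_gt(max(cv$dbh), 100)
  expect_lt(min(cv$ca), 305); expect_gt(max(cv$ca), 395)
  # strict nesting: every sample in one tree, every tree in one site
  expect_true(all(colSums(table(ds$d6sr$tree, ds$d6sr$sample) > 0) == 1))
  expect_true(all(colSums(table(ds$d6sr$site, ds$d6sr$tree) > 0) == 1))
})

test_that("the generator is deterministic in the master seed", {
  a <- simulate_d6sr_dataset(true_params(seed = 11))
  b <- simulate_d6sr_dataset(true_params(seed = 11))
  expect_identical(a$d6sr, b$d6sr)
  expect_identical(a$covariates$covariates, b$covariates$covariates)
  c <- simulate_d6sr_dataset(true_params(seed = 12))
  expect_false(identical(a$d6sr$d6sr, c$d6sr$d6sr))
})

test_that("zero-variance truth collapses replicates onto the gMM mean", {
  pars <- true_params(sd_site_a = 0, sd_tree_a = 0, sd_sample_a = 0,
                      sd_site_b = 0, sd_tree_b = 0, sd_sample_b = 0,
                      sigma = 0, seed = 5)
  ds <- simulate_d6sr_dataset(pars)
  cv <- ds$covariates$covariates
  mu <- gmm_mean(cv$z_dbh,
                 pars$a0 + pars$beta_ca * cv$z_ca + pars$beta_tday * cv$z_tday +
                   pars$beta_precip * cv$z_precip,
                 pars$b0)
  got <- ds$d6sr$d6sr
  expect_equal(got, mu[match(ds$d6sr$sample, cv$sample)], tolerance = 1e-12)
})

test_that("replicate noise converges to the nominal NMR sigma", {
  # many replicates per sample: pooled within-sample SD approaches sigma
  pars <- true_params(sigma = 0.03, seed = 9)
  design <- study_design(replicate_range = c(60, 60))
  ds <- simulate_d6sr_dataset(pars, design)
  within_sd <- ds$d6sr |>
    dplyr::group_by(sample) |>
    dplyr::summarise(s2 = var(d6sr), n = dplyr::n())
  pooled <- sqrt(mean(within_sd$s2))
  # 3-SE Monte Carlo band for a pooled SD estimate
  se <- pars$sigma / sqrt(2 * sum(within_sd$n - 1))
  expect_lt(abs(pooled - pars$sigma), 3 * se)
})

test_that("disabling the half-saturation floor errors on nonpositive draws", {
  pars <- true_params(sd_sample_b = 3, seed = 2)  # deviations overwhelm b0
  expect_error(simulate_d6sr_dataset(pars, floor_b = FALSE), "half-saturation")
  ds <- simulate_d6sr_dataset(pars, floor_b = TRUE)
  expect_true(all(ds$truth$b_k >= 0.05 * pars$b0))
})
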