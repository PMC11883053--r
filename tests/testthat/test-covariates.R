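test_that("day temperature weights tmin and tmax 1:2", {
  expect_equal(compute_tday(20, 32), 28)
  expect_equal(compute_tday(15, 30), 25)
  expect_equal(compute_tday(17, 17), 17)  # identity when tmin == tmax
  expect_equal(compute_tday(c(20, 15), c(32, 30)), c(28, 25))
  expect_error(compute_tday(30, 15), "tmin")
})

test_that("ring-year relabelling follows the mid-year start convention", {
  clim <- tidyr::expand_grid(year = 2000:2001, month = 1:12) |>
    dplyr::mutate(tmin = 15, tmax = 30, precip = 150)
  # start_month 1 is the identity
  expect_equal(shift_ring_year(clim, 1)$ring_year, clim$year)
  # enumerate all 12 months: Jul-Dec of Y -> Y, Jan-Jun of Y+1 -> Y
  shifted <- shift_ring_year(clim, 7)
  for (m in 1:12) {
    expected <- ifelse(m >= 7, 2000, 1999)
    got <- shifted$ring_year[shifted$year == 2000 & shifted$month == m]
    expect_equal(got, expected, ignore_attr = TRUE)
  }
  expect_equal(shifted$ring_year[shifted$year == 2001 & shifted$month == 3], 2000)
  expect_error(shift_ring_year(clim, 13), "start_month")
})

test_that("growing season keeps months strictly above the precipitation threshold", {
  clim <- tibble::tibble(year = 2000, month = 1:4, tmin = 20, tmax = 30,
                         precip = c(120, 90, 100, 200))
  gs <- growing_season_summary(clim)
  # 100 mm exactly is excluded: strict inequality
  expect_equal(gs$n_months, 2)
  expect_equal(gs$precip_sum, 320)
  # dry year: flagged, not dropped
  dry <- growing_season_summary(dplyr::mutate(clim, precip = c(50, 90, 100, 10)))
  expect_equal(dry$n_months, 0)
  expect_true(is.na(dry$tday))
  expect_equal(dry$precip_sum, 0)
  # 12 wet months at constant conditions
  full <- tibble::tibble(year = 2000, month = 1:12, tmin = 22.5, tmax = 26.25,
                         precip = 150)
  gfull <- growing_season_summary(full)
  expect_equal(gfull$tday, 25)
  expect_equal(gfull$precip_sum, 1800)
  expect_equal(gfull$n_months, 12)
})

test_that("growing-season summary is invariant to month ordering", {
  clim <- tibble::tibble(year = 2000, month = 1:6,
                         tmin = c(18, 20, 21, 19, 22, 17),
                         tmax = c(28, 31, 33, 30, 29, 27),
                         precip = c(120, 90, 160, 40, 210, 101))
  shuf <- clim[sample.int(6), ]
  expect_equal(growing_season_summary(shuf), growing_season_summary(clim))
})

test_that("ring-width weighting is a convex combination", {
  expect_equal(weighted_sample_covariate(c(1, 3), c(10, 20)), 17.5)
  expect_equal(weighted_sample_covariate(c(2, 2, 2), c(1, 2, 3)), 2)  # equal = mean
  expect_equal(weighted_sample_covariate(c(2, 0), c(5, 99)), 5)       # zero-width ignored
  # constant series maps to that constant whatever the weights
  w <- runif(10, 0.1, 5)
  expect_equal(weighted_sample_covariate(w, rep(7.3, 10)), 7.3)
  expect_error(weighted_sample_covariate(c(0, 0), c(1, 2)), "zero")
  expect_error(weighted_sample_covariate(1:2, 1:3), "length")
})

test_that("DBH reconstruction doubles cumulative radius and rescales to bark", {
  expect_equal(reconstruct_dbh(c(10, 10)), c(2, 4))
  expect_equal(reconstruct_dbh(numeric(0), pith_offset_mm = 50), 10)
  # monotone nondecreasing for any nonnegative widths
  w <- runif(30, 0, 8)
  expect_true(all(diff(reconstruct_dbh(w, 5)) >= 0))
  # bark DBH equal to the unadjusted final value leaves the series unchanged
  base <- reconstruct_dbh(c(10, 10))
  expect_equal(reconstruct_dbh(c(10, 10), bark_dbh_cm = 4), base)
  # otherwise proportional rescale
  expect_equal(reconstruct_dbh(c(10, 10), bark_dbh_cm = 8), c(4, 8))
  expect_error(reconstruct_dbh(c(1, 2), pith_offset_mm = -1))
})

test_that("standardization round-trips and has unit scale", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$z, c(-1, 0, 1))
  x <- rnorm(50, 10, 3)
  s2 <- standardize(x)
  expect_equal(mean(s2$z), 0)
  expect_equal(sd(s2$z), 1)
  expect_equal(unstandardize(s2, s2$z), x)
  expect_equal(restandardize(s2, x), s2$z)
  # scale-only transform keeps positivity
  s3 <- standardize(x, center = FALSE)
  expect_true(all(s3$z > 0))
  expect_error(standardize(rep(1, 5)), "standard deviation")
})

test_that("pooled sample covariates use width weights and carry scaling", {
  samples <- tibble::tibble(
    site = "A", tree = "A1", sample = rep(c("A1_1", "A1_2"), each = 2),
    year = c(2000, 2001, 2005, 2006),
    width_mm = c(1, 3, 2, 2), dbh_cm = c(10, 12, 30, 34))
  gs <- tibble::tibble(site = "A", ring_year = c(2000, 2001, 2005, 2006),
                       tday = c(24, 26, 25, 27), precip_sum = c(1000, 1400, 1200, 1300))
  ca <- tibble::tibble(year = c(2000, 2001, 2005, 2006), ca = c(370, 372, 380, 382))
  cov <- sample_covariates(samples, gs, ca)
  cv <- cov$covariates
  expect_equal(cv$ca[cv$sample == "A1_1"], (1 * 370 + 3 * 372) / 4)
  expect_equal(cv$tday[cv$sample == "A1_1"], (1 * 24 + 3 * 26) / 4)
  expect_equal(cv$dbh, c(11, 32))
  # scaled diameter transform: positive, no centering
  expect_true(all(cv$z_dbh > 0))
  expect_equal(cv$z_dbh, cv$dbh / sd(cv$dbh))
  # z-scores carry an invertible scaling record
  expect_equal(unstandardize(cov$scaling$ca, cv$z_ca), cv$ca)
  expect_error(sample_covariates(samples, gs, ca[1:2, ]), "cover")
})
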