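point_params <- function(beta_ca = -0.03, b0 = 0.89, dbh_sd = 25) {
  list(a0 = 1, b0 = b0, beta_ca = beta_ca, beta_tday = 0, beta_precip = 0,
       scaling = point_scaling(dbh_sd), diameter_transform = "scaled")
}

test_that("point-parameter curves compose the gMM mean exactly", {
  p <- point_params(beta_ca = 0)
  grid <- seq(10, 120, by = 5)
  pc <- predict_curve(p, "diameter", grid)
  expect_equal(pc$estimate, gmm_mean(grid / 25, 1, 0.89))
  # all slopes zero: covariate curves are flat
  flat <- predict_curve(p, "ca", seq(300, 400, 10))
  expect_true(all(abs(diff(flat$estimate)) < 1e-12))
})

test_that("fit-based curves return the requested number of posterior draws", {
  pc <- predict_curve(quick_fit(), "ca", seq(300, 400, 10), n_draws = 200)
  dr <- attr(pc, "draws")
  expect_equal(dplyr::n_distinct(dr$draw), 200)
  expect_true(all(pc$conf.low <= pc$estimate & pc$estimate <= pc$conf.high))
})

test_that("constant-CO2 curve families are ordered by the CO2 effect", {
  p <- point_params(beta_ca = -0.03)
  fam <- predict_constant_ca(p, diameter_grid = seq(5, 150, 5),
                             ca_levels = c(300, 350, 400))
  wide <- tidyr::pivot_wider(fam, id_cols = "diameter", names_from = "ca",
                             values_from = "estimate")
  # negative CO2 slope: higher CO2 strictly below at every diameter
  expect_true(all(wide$`400` < wide$`350`))
  expect_true(all(wide$`350` < wide$`300`))
  # each curve approaches its own asymptote
  far <- predict_constant_ca(p, diameter_grid = 1e5, ca_levels = c(300, 400))
  expect_equal(far$estimate, far$asymptote, tolerance = 1e-3)
  # zero slope: all curves identical
  fam0 <- predict_constant_ca(point_params(beta_ca = 0),
                              diameter_grid = seq(5, 150, 5),
                              ca_levels = c(300, 400))
  expect_equal(fam0$estimate[fam0$ca == 300], fam0$estimate[fam0$ca == 400])
  # vertical spacing scales linearly with the CO2 slope
  gap <- function(bca) {
    f <- predict_constant_ca(point_params(beta_ca = bca), diameter_grid = 60,
                             ca_levels = c(300, 400))
    diff(f$asymptote)
  }
  expect_equal(gap(-0.06), 2 * gap(-0.03), tolerance = 1e-12)
})

test_that("diameter response is nondecreasing at fixed CO2", {
  fam <- predict_constant_ca(point_params(), seq(1, 200, 1), ca_levels = 350)
  expect_true(all(diff(fam$estimate) >= 0))
})

test_that("joint trajectories rise, peak once, then fall under accelerating CO2", {
  ca <- make_ca_series(1900:2019)
  tr <- predict_joint_trajectory(point_params(beta_ca = -0.03), ca,
                                 initial_dbh = 10)
  expect_equal(nrow(tr), 120)
  expect_true(all(diff(tr$diameter) > 0))
  mx <- find_trajectory_maximum(tr)
  expect_true(mx$interior)
  # exactly one sign change in the discrete differences
  d <- diff(tr$estimate)
  expect_equal(sum(diff(sign(d)) != 0), 1)
  # constant CO2: pure saturating diameter response, no interior maximum
  tr_flat <- predict_joint_trajectory(point_params(beta_ca = -0.03),
                                      make_ca_series(1900:2019, flat_ppm = 350),
                                      initial_dbh = 10)
  expect_true(all(diff(tr_flat$estimate) > 0))
  expect_false(find_trajectory_maximum(tr_flat)$interior)
  # zero increment: the path is driven by CO2 alone and declines monotonically
  tr_ca <- predict_joint_trajectory(point_params(beta_ca = -0.03), ca,
                                    initial_dbh = 40, annual_increment = 0)
  expect_true(all(diff(tr_ca$estimate) < 0))
})

test_that("trajectory maxima follow the exhaustive-scan oracle and tie rule", {
  path <- tibble::tibble(diameter = seq(10, 100, length.out = 61),
                         estimate = -(seq(-3, 3, length.out = 61))^2)
  mx <- find_trajectory_maximum(path)
  # exhaustive scan oracle
  best <- -Inf; best_i <- NA
  for (i in seq_len(nrow(path))) {
    if (path$estimate[i] > best) { best <- path$estimate[i]; best_i <- i }
  }
  expect_equal(mx$diameter, path$diameter[best_i])
  expect_equal(mx$d6sr_max, best)
  # monotone increasing: last point; constant: first point
  inc <- tibble::tibble(diameter = 1:10, estimate = 1:10 / 10)
  expect_equal(find_trajectory_maximum(inc)$diameter, 10)
  cst <- tibble::tibble(diameter = 1:10, estimate = rep(1, 10))
  expect_equal(find_trajectory_maximum(cst)$diameter, 1)
})

test_that("fit-based trajectories carry an uncertainty envelope", {
  tr <- predict_joint_trajectory(quick_fit(), make_ca_series(1900:2019),
                                 initial_dbh = 10, n_draws = 100)
  expect_true(all(tr$conf.low <= tr$estimate & tr$estimate <= tr$conf.high))
})
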