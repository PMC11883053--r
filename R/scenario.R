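# population-level parameter draws and scaling from a fit or a point-params
# list (list(a0, b0, beta_ca, beta_tday, beta_precip) plus `scaling`)
scenario_params <- function(object) {
  if (inherits(object, "d6sr_fit")) {
    if (object$spec$form != "gmm") {
      stop("scenario predictions are implemented for the gMM form.", call. = FALSE)
    }
    dm <- flat_draws(object)
    covs <- object$spec$asymptote_covariates
    beta <- setNames(rep(0, 3), c("ca", "tday", "precip"))
    bmed <- setNames(rep(0, 3), c("ca", "tday", "precip"))
    draws <- list(a0 = dm[, "asymptote"], b0 = dm[, "half_saturation"])
    for (cc in covs) {
      draws[[paste0("beta_", cc)]] <- dm[, paste0("b_", cc)]
      bmed[cc] <- median(dm[, paste0("b_", cc)])
    }
    list(point = list(a0 = median(dm[, "asymptote"]),
                      b0 = median(dm[, "half_saturation"]),
                      beta_ca = bmed[["ca"]], beta_tday = bmed[["tday"]],
                      beta_precip = bmed[["precip"]]),
         draws = draws, n_draws = nrow(dm),
         scaling = object$scaling,
         diameter_transform = object$spec$diameter_transform)
  } else {
    stopifnot(is.list(object), !is.null(object$a0), !is.null(object$b0),
              !is.null(object$scaling))
    pt <- list(a0 = object$a0, b0 = object$b0,
               beta_ca = object$beta_ca %||% 0,
               beta_tday = object$beta_tday %||% 0,
               beta_precip = object$beta_precip %||% 0)
    list(point = pt, draws = NULL, n_draws = 0, scaling = object$scaling,
         diameter_transform = object$diameter_transform %||% "scaled")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

transform_diameter <- function(dbh_cm, scaling, transform) {
  switch(transform,
         raw = dbh_cm,
         scaled = dbh_cm / scaling$dbh$scale,
         zscore = restandardize(scaling$dbh, dbh_cm))
}

# asymptote at given covariate z-scores for a parameter set (vectorised over
# draws when a0 etc. are vectors)
asymptote_at <- function(p, z_ca = 0, z_tday = 0, z_precip = 0) {
  p$a0 + p$beta_ca * z_ca + p$beta_tday * z_tday + p$beta_precip * z_precip
}

#' Predicted D6SR response curves with posterior uncertainty
#'
#' Population-level predicted D6SR over a grid of one covariate (atmospheric
#' CO2, day temperature, precipitation, or diameter), the other covariates
#' held at the fitted dataset's mean and random effects at zero. Alongside
#' the posterior-median curve, a configurable number of individual posterior
#' draw curves is returned for spaghetti-style uncertainty display.
#'
#' @param object A `d6sr_fit` (gMM form), or a point-parameter list
#'   (`a0`, `b0`, slopes, `scaling`), in which case only the point curve is
#'   returned.
#' @param covariate One of `"ca"`, `"tday"`, `"precip"`, `"diameter"`.
#' @param grid Covariate values in natural units (ppm, degrees C, mm, cm).
#' @param n_draws Number of posterior draw curves (200 by default).
#' @param at_diameter Diameter (cm) the covariate curves are evaluated at;
#'   default the mean sample diameter of the fitted data.
#' @return Tibble of class `d6sr_prediction`: `covariate`, `x`, `estimate`,
#'   `conf.low`, `conf.high`, plus `draw` curves in the `draws` attribute.
#' @export
predict_curve <- function(object, covariate = c("ca", "diameter", "tday", "precip"),
                          grid, n_draws = 200, at_diameter = NULL) {
  covariate <- match.arg(covariate)
  p <- scenario_params(object)
  if (length(grid) == 0) stop("`grid` is empty.", call. = FALSE)
  if (is.null(at_diameter)) at_diameter <- p$scaling$dbh$center +
      p$scaling$dbh$scale * 1.5   # a mid-sized canopy tree when not centered
  z_of <- function(cov, x) restandardize(p$scaling[[cov]], x)
  eval_curve <- function(pt) {
    if (covariate == "diameter") {
      D <- transform_diameter(grid, p$scaling, p$diameter_transform)
      if (any(pt$b0 + D <= 0)) stop("non-positive gMM denominator.", call. = FALSE)
      gmm_mean(D, asymptote_at(pt), pt$b0)
    } else {
      D <- transform_diameter(at_diameter, p$scaling, p$diameter_transform)
      z <- z_of(covariate, grid)
      a <- switch(covariate,
                  ca = asymptote_at(pt, z_ca = z),
                  tday = asymptote_at(pt, z_tday = z),
                  precip = asymptote_at(pt, z_precip = z))
      gmm_mean(D, a, pt$b0)
    }
  }
  est <- eval_curve(p$point)
  out <- tibble::tibble(covariate = covariate, x = grid, estimate = est,
                        conf.low = NA_real_, conf.high = NA_real_)
  draws_tbl <- NULL
  if (!is.null(p$draws)) {
    ids <- unique(round(seq(1, p$n_draws, length.out = min(n_draws, p$n_draws))))
    mat <- vapply(ids, function(s) {
      pt <- lapply(p$draws, `[`, s)
      eval_curve(pt)
    }, numeric(length(grid)))
    mat <- matrix(mat, nrow = length(grid))
    out$conf.low <- apply(mat, 1, quantile, 0.025)
    out$conf.high <- apply(mat, 1, quantile, 0.975)
    draws_tbl <- tibble::tibble(
      covariate = covariate,
      x = rep(grid, times = length(ids)),
      draw = rep(seq_along(ids), each = length(grid)),
      value = as.vector(mat))
  }
  structure(out, draws = draws_tbl, class = c("d6sr_prediction", class(out)))
}

#' Constant-CO2 families of diameter curves
#'
#' One saturating D6SR--diameter curve per fixed atmospheric CO2 level,
#' random effects at zero and the climate covariates at their fitted means.
#' With a negative CO2 slope the curves are vertically ordered: higher CO2,
#' lower asymptote.
#'
#' @param object A `d6sr_fit` (gMM) or point-parameter list.
#' @param diameter_grid Diameters in cm.
#' @param ca_levels CO2 levels in ppm (e.g. `seq(300, 400, by = 20)`).
#' @return Tibble: `ca`, `diameter`, `estimate`, `asymptote`.
#' @export
predict_constant_ca <- function(object, diameter_grid = seq(5, 150, by = 1),
                                ca_levels = seq(300, 400, by = 20)) {
  p <- scenario_params(object)
  D <- transform_diameter(diameter_grid, p$scaling, p$diameter_transform)
  purrr::map_dfr(ca_levels, function(ca) {
    z <- restandardize(p$scaling$ca, ca)
    a <- asymptote_at(p$point, z_ca = z)
    tibble::tibble(ca = ca, diameter = diameter_grid,
                   estimate = gmm_mean(D, a, p$point$b0), asymptote = a)
  })
}

#' Joint diameter and CO2 trajectory
#'
#' Predicted D6SR for a hypothetical tree growing at a constant diameter
#' increment through a period of rising atmospheric CO2 (historical-shaped by
#' default): diameter and CO2 advance together year by year and D6SR is
#' evaluated along the joint path. With a negative CO2 slope and accelerating
#' CO2 the path rises with diameter, peaks, and then declines as the CO2
#' effect overtakes the saturating diameter effect.
#'
#' @param object A `d6sr_fit` (gMM) or point-parameter list.
#' @param ca_series Tibble `year`, `ca` covering the trajectory years (e.g.
#'   [make_ca_series()]).
#' @param initial_dbh Starting diameter (cm).
#' @param annual_increment Constant diameter increment (cm/yr); default
#'   reaches about 120 cm over the CO2 series length.
#' @param n_draws Posterior draw paths for the uncertainty envelope (fits
#'   only).
#' @return Tibble of class `d6sr_trajectory`: `year`, `diameter`, `ca`,
#'   `estimate`, `conf.low`, `conf.high`.
#' @export
predict_joint_trajectory <- function(object, ca_series,
                                     initial_dbh = 10,
                                     annual_increment = NULL, n_draws = 200) {
  p <- scenario_params(object)
  ca_series <- tibble::as_tibble(ca_series)
  stopifnot(all(c("year", "ca") %in% names(ca_series)), nrow(ca_series) >= 2)
  ny <- nrow(ca_series)
  if (is.null(annual_increment)) annual_increment <- (120 - initial_dbh) / (ny - 1)
  if (annual_increment < 0) stop("`annual_increment` must be >= 0.", call. = FALSE)
  dbh <- initial_dbh + annual_increment * (seq_len(ny) - 1)
  D <- transform_diameter(dbh, p$scaling, p$diameter_transform)
  z <- restandardize(p$scaling$ca, ca_series$ca)
  path <- function(pt) gmm_mean(D, asymptote_at(pt, z_ca = z), pt$b0)
  out <- tibble::tibble(year = ca_series$year, diameter = dbh,
                        ca = ca_series$ca, estimate = path(p$point),
                        conf.low = NA_real_, conf.high = NA_real_)
  if (!is.null(p$draws)) {
    ids <- unique(round(seq(1, p$n_draws, length.out = min(n_draws, p$n_draws))))
    mat <- vapply(ids, function(s) path(lapply(p$draws, `[`, s)), numeric(ny))
    out$conf.low <- apply(mat, 1, quantile, 0.025)
    out$conf.high <- apply(mat, 1, quantile, 0.975)
  }
  structure(out, class = c("d6sr_trajectory", class(out)))
}

#' Locate the maximum of a predicted trajectory
#'
#' Argmax of the predicted D6SR along a trajectory; ties are resolved to the
#' smallest diameter.
#'
#' @param trajectory A `d6sr_trajectory` (or any tibble with `diameter` and
#'   `estimate`).
#' @return One-row tibble: `diameter`, `d6sr_max`, `year` (if present),
#'   `interior` (whether the maximum is away from both path ends).
#' @export
find_trajectory_maximum <- function(trajectory) {
  stopifnot(is.data.frame(trajectory), nrow(trajectory) >= 1,
            all(c("diameter", "estimate") %in% names(trajectory)))
  i <- which.max(trajectory$estimate)   # first index on ties = smallest diameter
  tibble::tibble(
    diameter = trajectory$diameter[i],
    d6sr_max = trajectory$estimate[i],
    year = if ("year" %in% names(trajectory)) trajectory$year[i] else NA_integer_,
    interior = i > 1 && i < nrow(trajectory)
  )
}
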