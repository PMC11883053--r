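#' Growing-season day temperature
#'
#' Computes the day temperature used for growing-season climatology as a
#' weighted combination of the monthly minimum and maximum temperature,
#' `Tday = (1/3) Tmin + (2/3) Tmax`. The weighting reflects that leaf-level
#' photosynthesis and photorespiration occur in daytime, when temperatures sit
#' closer to the daily maximum.
#'
#' @param tmin Monthly minimum temperature (degrees C). Vectorised.
#' @param tmax Monthly maximum temperature (degrees C). Same length as `tmin`.
#' @return Numeric vector of day temperatures (degrees C).
#' @examples
#' compute_tday(20, 32) # 28
#' @export
compute_tday <- function(tmin, tmax) {
  if (any(tmin > tmax, na.rm = TRUE)) {
    stop("`tmin` must not exceed `tmax`.", call. = FALSE)
  }
  tmin / 3 + 2 * tmax / 3
}

#' Relabel calendar months to ring years
#'
#' Tree rings of Southern-hemisphere trees start forming mid calendar year and
#' growth continues into the next; under the Schulman convention a ring is
#' labelled with the calendar year in which its growth began. With
#' `start_month = 7`, July--December of calendar year Y and January--June of
#' Y + 1 are assigned `ring_year` Y. `start_month = 1` leaves labels unchanged.
#'
#' @param climate Data frame with at least `year` and `month` (1--12) columns,
#'   e.g. a monthly climate table.
#' @param start_month First month of the ring year (1--12).
#' @return The input as a tibble with an added `ring_year` column.
#' @examples
#' clim <- tibble::tibble(year = 2000:2001, month = c(7, 3),
#'                        tmin = 15, tmax = 30, precip = 120)
#' shift_ring_year(clim, start_month = 7)$ring_year # both 2000
#' @export
shift_ring_year <- function(climate, start_month = 7) {
  stopifnot(is.data.frame(climate))
  if (!is.numeric(start_month) || length(start_month) != 1 ||
      start_month < 1 || start_month > 12) {
    stop("`start_month` must be a single month in 1..12.", call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(climate),
    ring_year = .data$year - as.integer(.data$month < start_month)
  )
}

#' Summarise the growing season for each ring year
#'
#' Retains the months with precipitation strictly above `threshold_mm`
#' (the growing season; dry months are excluded because deciduous trees carry
#' no leaves then), and summarises each ring year by the unweighted mean day
#' temperature over the retained months and the summed precipitation of those
#' months. The season length is allowed to vary between years. Years in which
#' no month passes the threshold are kept with `n_months = 0` and a missing
#' `tday` rather than silently dropped.
#'
#' @param climate Monthly climate table with columns `tmin`, `tmax`, `precip`
#'   and either `ring_year` or `year` (plus any grouping columns such as
#'   `site`, which are preserved).
#' @param threshold_mm Monthly precipitation threshold (mm); strictly greater
#'   values count as growing season.
#' @return Tibble with one row per (grouping columns, ring_year): `tday`
#'   (degrees C, `NA` when no month qualifies), `precip_sum` (mm) and
#'   `n_months`.
#' @export
growing_season_summary <- function(climate, threshold_mm = 100) {
  stopifnot(is.data.frame(climate))
  climate <- tibble::as_tibble(climate)
  if (!"ring_year" %in% names(climate)) {
    climate <- dplyr::mutate(climate, ring_year = .data$year)
  }
  grp_cols <- intersect(c("site", "tree"), names(climate))
  climate |>
    dplyr::mutate(
      .tday = compute_tday(.data$tmin, .data$tmax),
      .in_season = .data$precip > threshold_mm
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp_cols, "ring_year")))) |>
    dplyr::summarise(
      tday = ifelse(any(.data$.in_season),
                    mean(.data$.tday[.data$.in_season]), NA_real_),
      precip_sum = sum(.data$precip[.data$.in_season]),
      n_months = sum(.data$.in_season),
      .groups = "drop"
    )
}

#' Ring-width weighted mean of an annual covariate
#'
#' A wood sample pooled over several rings contains more material from wide
#' rings, so each ring's annual covariate contributes in proportion to its
#' width: the pooled value is `sum(w_i * x_i)` with `w_i = width_i /
#' sum(widths)`.
#'
#' @param widths Ring widths (mm) for the pooled years; non-negative, at least
#'   one positive.
#' @param values Annual covariate values, same length as `widths`.
#' @return The weighted mean (scalar).
#' @examples
#' weighted_sample_covariate(c(1, 3), c(10, 20)) # 17.5
#' @export
weighted_sample_covariate <- function(widths, values) {
  if (length(widths) != length(values)) {
    stop("`widths` and `values` must have the same length.", call. = FALSE)
  }
  if (any(widths < 0)) stop("`widths` must be non-negative.", call. = FALSE)
  tot <- sum(widths)
  if (tot == 0) stop("all ring widths are zero; weights undefined.", call. = FALSE)
  sum(widths * values) / tot
}

#' Reconstruct stem diameter from ring widths
#'
#' Diameter at breast height for the year each ring formed, from cumulative
#' ring widths plus an estimate of the distance from the innermost measured
#' ring to the pith: `DBH(y) = 2 * (pith_offset + cumulative width)`. If a
#' field-measured diameter (over bark) for the final year is supplied, the
#' whole series is rescaled so the final year matches it, absorbing bark
#' thickness and missing-ring error proportionally.
#'
#' @param ring_widths Ring widths in mm, ordered oldest to youngest.
#' @param pith_offset_mm Distance from pith to the innermost ring (mm).
#' @param bark_dbh_cm Optional measured DBH (cm) for the final ring year.
#' @return Numeric vector of DBH in cm, one value per ring year.
#' @examples
#' reconstruct_dbh(c(10, 10)) # 2, 4 cm
#' @export
reconstruct_dbh <- function(ring_widths, pith_offset_mm = 0, bark_dbh_cm = NULL) {
  if (pith_offset_mm < 0) stop("`pith_offset_mm` must be >= 0.", call. = FALSE)
  if (any(ring_widths < 0)) stop("ring widths must be >= 0.", call. = FALSE)
  if (length(ring_widths) == 0) {
    return(2 * pith_offset_mm / 10)
  }
  dbh <- 2 * (pith_offset_mm + cumsum(ring_widths)) / 10
  if (!is.null(bark_dbh_cm)) {
    final <- dbh[length(dbh)]
    if (final <= 0) stop("cannot rescale a zero-diameter series.", call. = FALSE)
    dbh <- dbh * bark_dbh_cm / final
  }
  dbh
}

#' Standardize a covariate, keeping the scaling for later inversion
#'
#' Centers by the mean and divides by the sample standard deviation
#' (n - 1 denominator). The returned record stores the scaling so that new
#' values (e.g. scenario covariates) can be transformed identically and
#' z-scores can be mapped back to the original units.
#'
#' @param x Numeric vector with at least two distinct values.
#' @param center Center before scaling? Diameter entering a Michaelis--Menten
#'   denominator is usually scaled without centering (`center = FALSE`) so it
#'   stays positive.
#' @return An object of class `std_scale`: list with `z` (transformed values),
#'   `center` and `scale`.
#' @seealso [restandardize()], [unstandardize()]
#' @export
standardize <- function(x, center = TRUE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("cannot standardize: zero or undefined standard deviation.", call. = FALSE)
  }
  ctr <- if (center) mean(x) else 0
  structure(list(z = (x - ctr) / s, center = ctr, scale = s),
            class = "std_scale")
}

#' Apply a stored standardization to new values
#' @param scaling A `std_scale` record from [standardize()].
#' @param x New values on the original scale.
#' @return Transformed values.
#' @export
restandardize <- function(scaling, x) {
  stopifnot(inherits(scaling, "std_scale"))
  (x - scaling$center) / scaling$scale
}

#' Invert a stored standardization
#' @param scaling A `std_scale` record from [standardize()].
#' @param z Values on the transformed scale.
#' @return Values on the original scale.
#' @export
unstandardize <- function(scaling, z) {
  stopifnot(inherits(scaling, "std_scale"))
  z * scaling$scale + scaling$center
}

#' Build per-sample covariates from climate, CO2 and ring widths
#'
#' For each pooled wood sample, computes the ring-width weighted mean of
#' atmospheric CO2 and of the growing-season day temperature and precipitation
#' over the pooled ring years, and the unweighted mean reconstructed DBH, then
#' standardizes each covariate across samples. Diameter is by default scaled
#' without centering so the Michaelis--Menten denominator stays positive.
#'
#' @param samples Tibble with one row per (sample, pooled year):
#'   columns `site`, `tree`, `sample`, `year`, `width_mm`, `dbh_cm`.
#' @param growing_season Output of [growing_season_summary()] with a `site`
#'   column: `site`, `ring_year`, `tday`, `precip_sum`.
#' @param ca_series Tibble `year`, `ca` (ppm), annual.
#' @param diameter_transform One of `"scaled"` (divide by SD, keep positive),
#'   `"zscore"`, `"raw"`.
#' @return A list of class `d6sr_covariates`: `covariates` (tibble, one row
#'   per sample with pooled and standardized values) and `scaling` (named list
#'   of `std_scale` records for `ca`, `tday`, `precip`, `dbh`).
#' @export
sample_covariates <- function(samples, growing_season, ca_series,
                              diameter_transform = c("scaled", "zscore", "raw")) {
  diameter_transform <- match.arg(diameter_transform)
  stopifnot(is.data.frame(samples), is.data.frame(growing_season),
            is.data.frame(ca_series))
  joined <- samples |>
    dplyr::left_join(growing_season, by = c("site", "year" = "ring_year")) |>
    dplyr::left_join(dplyr::select(tibble::as_tibble(ca_series), "year", "ca"),
                     by = "year")
  if (anyNA(joined$ca)) {
    stop("CO2 series does not cover all pooled sample years.", call. = FALSE)
  }
  pooled <- joined |>
    dplyr::group_by(.data$site, .data$tree, .data$sample) |>
    dplyr::summarise(
      year_from = min(.data$year),
      year_to = max(.data$year),
      ca = weighted_sample_covariate(.data$width_mm, .data$ca),
      tday = weighted_sample_covariate(.data$width_mm, .data$tday),
      precip = weighted_sample_covariate(.data$width_mm, .data$precip_sum),
      dbh = mean(.data$dbh_cm),
      .groups = "drop"
    )
  scaling <- list(
    ca = standardize(pooled$ca),
    tday = standardize(pooled$tday),
    precip = standardize(pooled$precip),
    dbh = standardize(pooled$dbh,
                      center = diameter_transform == "zscore")
  )
  pooled <- pooled |>
    dplyr::mutate(
      z_ca = scaling$ca$z,
      z_tday = scaling$tday$z,
      z_precip = scaling$precip$z,
      z_dbh = switch(diameter_transform,
                     raw = .data$dbh,
                     scaled = ,
                     zscore = scaling$dbh$z)
    )
  structure(list(covariates = pooled, scaling = scaling,
                 diameter_transform = diameter_transform),
            class = "d6sr_covariates")
}
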