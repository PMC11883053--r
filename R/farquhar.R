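#' Farquhar-model photosynthetic parameters
#'
#' Kinetic constants for the Farquhar--von Caemmerer--Berry model of C3
#' photosynthesis used to translate CO2 changes into oxygenation /
#' carboxylation responses. Defaults are Bernacchi-style 25 degree values.
#' Chloroplast CO2 is taken equal to intercellular CO2 (infinite mesophyll
#' conductance).
#'
#' @param gamma_star CO2 photocompensation point in the absence of day
#'   respiration (ubar).
#' @param vcmax Maximal carboxylation rate (umol m-2 s-1).
#' @param kc Michaelis constant of Rubisco for CO2 (ubar).
#' @param ko Michaelis constant of Rubisco for O2 (mbar).
#' @param o2 Oxygen partial pressure (mbar).
#' @param j Optional electron-transport capacity (umol m-2 s-1); when given,
#'   carboxylation is the minimum of the Rubisco- and RuBP-limited rates.
#' @return List of class `farquhar_params`.
#' @export
farquhar_params <- function(gamma_star = 42.75, vcmax = 60, kc = 404.9,
                            ko = 278.4, o2 = 210, j = NULL) {
  stopifnot(gamma_star > 0, vcmax > 0, kc > 0, ko > 0, o2 > 0,
            is.null(j) || j > 0)
  structure(list(gamma_star = gamma_star, vcmax = vcmax, kc = kc, ko = ko,
                 o2 = o2, j = j), class = "farquhar_params")
}

#' Oxygenation-to-carboxylation ratio
#'
#' In the Farquhar model the ratio of Rubisco oxygenation to carboxylation is
#' `Vo/Vc = 2 * gamma_star / Cc`; with chloroplast CO2 equal to intercellular
#' CO2 this is inversely proportional to Ci, so a proportional Ci rise
#' produces an exactly reciprocal Vo/Vc decline.
#'
#' @param ci Intercellular CO2 partial pressure (ubar); > 0.
#' @param gamma_star CO2 photocompensation point (ubar).
#' @return The dimensionless ratio, vectorised over `ci`.
#' @examples
#' vo_vc_ratio(430, 43) # 0.2
#' @export
vo_vc_ratio <- function(ci, gamma_star = 42.75) {
  if (any(ci <= 0)) stop("`ci` must be positive.", call. = FALSE)
  2 * gamma_star / ci
}

#' Carboxylation rate
#'
#' Rubisco-limited carboxylation
#' `Wc = Vcmax * Ci / (Ci + Kc (1 + O/Ko))`; when an electron-transport
#' capacity `j` is supplied, the realised rate is the minimum of `Wc` and the
#' RuBP-regeneration-limited `Wj = J * Ci / (4 Ci + 8 gamma_star)`.
#'
#' @param ci Intercellular CO2 (ubar); > 0.
#' @param params A [farquhar_params()].
#' @return Carboxylation rate (umol m-2 s-1), vectorised over `ci`.
#' @export
carboxylation_rate <- function(ci, params = farquhar_params()) {
  stopifnot(inherits(params, "farquhar_params"))
  if (any(ci <= 0)) stop("`ci` must be positive.", call. = FALSE)
  wc <- params$vcmax * ci / (ci + params$kc * (1 + params$o2 / params$ko))
  if (!is.null(params$j)) {
    wj <- params$j * ci / (4 * ci + 8 * params$gamma_star)
    pmin(wc, wj)
  } else {
    wc
  }
}

#' Gross photosynthesis
#'
#' `Ag = Vc * (1 - gamma_star / Ci)`, identically equal to
#' `Vc - 0.5 * Vo` since `Vo = (2 gamma_star / Ci) * Vc`. Zero at the
#' compensation point and strictly increasing in Ci in the Rubisco-limited
#' regime.
#'
#' @inheritParams carboxylation_rate
#' @return Gross photosynthesis (umol m-2 s-1), vectorised over `ci`.
#' @export
gross_photosynthesis <- function(ci, params = farquhar_params()) {
  carboxylation_rate(ci, params) * (1 - params$gamma_star / ci)
}

#' Relative change
#'
#' `(after - before) / before`, the fractional change used throughout the
#' CO2-sensitivity calculations.
#'
#' @param before,after Quantity values; `before` must be nonzero.
#' @return Fractional change (0.36 for a 36% increase).
#' @export
relative_change <- function(before, after) {
  if (any(before == 0)) stop("zero baseline in `relative_change()`.", call. = FALSE)
  (after - before) / before
}

#' CO2 sensitivity coefficient (beta)
#'
#' Log-ratio sensitivity of a quantity X to atmospheric CO2 following the
#' Walker convention: `beta = log(X2/X1) / log(Ca2/Ca1)`, expressed here
#' through the fractional changes, `beta = log(1 + dX) / log(1 + dCa)`.
#' `beta = 1` means a directly proportional response; the sign follows the
#' response.
#'
#' @param x_change Fractional change of the quantity (e.g. -0.26 for a 26%
#'   decrease).
#' @param ca_change Fractional change of CO2 (e.g. 0.36); nonzero.
#' @return The dimensionless sensitivity, vectorised.
#' @examples
#' beta_value(-0.26, 0.36) # about -0.98
#' @export
beta_value <- function(x_change, ca_change) {
  if (any(1 + x_change <= 0) || any(1 + ca_change <= 0)) {
    stop("relative changes must keep the ratios positive.", call. = FALSE)
  }
  if (any(ca_change == 0)) stop("`ca_change` must be nonzero.", call. = FALSE)
  log1p(x_change) / log1p(ca_change)
}

#' Photosynthetic response table for a CO2 step
#'
#' Evaluates the Farquhar-model response of the oxygenation-to-carboxylation
#' ratio, carboxylation and gross photosynthesis to a change in intercellular
#' CO2 (taken proportional to the atmospheric change), with relative changes
#' and beta sensitivity coefficients for each quantity.
#'
#' @param ci_before,ci_after Intercellular CO2 (ubar) before and after.
#' @param params A [farquhar_params()].
#' @return Tibble: one row per quantity (`vo_vc`, `vc`, `gross_photosynthesis`)
#'   with `before`, `after`, `rel_change`, `beta`.
#' @export
farquhar_response <- function(ci_before, ci_after, params = farquhar_params()) {
  ca_change <- relative_change(ci_before, ci_after)
  q <- list(
    vo_vc = vo_vc_ratio(c(ci_before, ci_after), params$gamma_star),
    vc = carboxylation_rate(c(ci_before, ci_after), params),
    gross_photosynthesis = gross_photosynthesis(c(ci_before, ci_after), params)
  )
  purrr::imap_dfr(q, function(v, nm) {
    d <- relative_change(v[1], v[2])
    tibble::tibble(quantity = nm, before = v[1], after = v[2],
                   rel_change = d, beta = beta_value(d, ca_change))
  })
}
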