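#' Ground-truth parameters for synthetic D6SR data
#'
#' Defines the generative parameters of the hierarchical generalized
#' Michaelis--Menten model used by [simulate_d6sr_dataset()]: the baseline
#' asymptote of the D6SR ratio, the asymptote slopes per standard deviation of
#' each standardized covariate, the half-saturation on the scaled-diameter
#' axis, nested random-intercept SDs on both curve parameters, and the
#' replicate (NMR re-measurement) residual SD.
#'
#' Defaults mirror the scale of published tree-ring D6SR estimates: asymptote
#' near 1, CO2 slope -0.009 per SD of pooled CO2, half-saturation 0.89 on the
#' scaled diameter axis, and a residual SD of 0.03 (about 3% of a D6SR of 1,
#' matching the "few percent" uncertainty typical of deuterium NMR).
#'
#' @param a0 Baseline asymptote (D6SR units, > 0).
#' @param beta_ca,beta_tday,beta_precip Asymptote change per 1 SD of the
#'   standardized covariate.
#' @param b0 Half-saturation in scaled-diameter units (> 0).
#' @param sd_site_a,sd_tree_a,sd_sample_a Random-intercept SDs on the
#'   asymptote at the site, tree-within-site, sample-within-tree levels.
#' @param sd_site_b,sd_tree_b,sd_sample_b Same for the half-saturation.
#' @param sigma Replicate residual SD (>= 0; zero gives the deterministic
#'   degenerate control in which every replicate equals its structured mean).
#' @param seed Master seed; all sub-streams (climate, rings, effects,
#'   replicates) are derived from it deterministically.
#' @return List of class `d6sr_truth`.
#' @export
true_params <- function(a0 = 1.0, beta_ca = -0.009, beta_tday = 0.013,
                        beta_precip = 0.003, b0 = 0.89,
                        sd_site_a = 0.02, sd_tree_a = 0.02, sd_sample_a = 0.02,
                        sd_site_b = 0.05, sd_tree_b = 0.05, sd_sample_b = 0.05,
                        sigma = 0.03, seed = 1L) {
  stopifnot(a0 > 0, b0 > 0, sigma >= 0,
            sd_site_a >= 0, sd_tree_a >= 0, sd_sample_a >= 0,
            sd_site_b >= 0, sd_tree_b >= 0, sd_sample_b >= 0)
  structure(list(a0 = a0, beta_ca = beta_ca, beta_tday = beta_tday,
                 beta_precip = beta_precip, b0 = b0,
                 sd_site_a = sd_site_a, sd_tree_a = sd_tree_a,
                 sd_sample_a = sd_sample_a, sd_site_b = sd_site_b,
                 sd_tree_b = sd_tree_b, sd_sample_b = sd_sample_b,
                 sigma = sigma, seed = as.integer(seed)),
            class = "d6sr_truth")
}

#' Study design for synthetic D6SR data
#'
#' Describes the nested sampling layout the generator reproduces: three
#' climatically distinct sites, three trees per site, three to five pooled
#' wood samples per tree taken as a time series along the tree's life, and
#' five to six NMR re-measurements per sample (40 samples, roughly 223
#' observations under the default layout). Sample windows pool `pooling_years`
#' consecutive rings (one site pools 7 yr, standing in for the site where
#' younger trees forced shorter pools) and are placed at approximately
#' equidistant atmospheric CO2 levels along each tree's usable lifespan,
#' starting once the reconstructed stem diameter reaches
#' `min_first_sample_dbh`.
#'
#' @param sites Site labels.
#' @param trees_per_site Trees per site.
#' @param samples_per_tree Integer matrix-like list: per site, a vector of
#'   sample counts per tree (3--5).
#' @param replicate_range Range (min, max) of NMR re-measurements per sample.
#' @param pooling_years Per-site number of pooled ring years.
#' @param year_range Calendar years covered by the simulated climate.
#' @param collection_years Per-site core collection year.
#' @param birth_years Per-site vector of tree establishment years.
#' @param start_month Per-site first month of the ring year (7 = Schulman
#'   convention for the Southern-hemisphere site).
#' @param site_climatology Tibble with one row per site: mean growing-season
#'   day temperature `tday_mean` (C), its interannual SD, wet-season calendar
#'   months (list-column `wet_months`), mean wet-month and dry-month
#'   precipitation (mm).
#' @param ring_width_mean_mm,ring_width_sd_mm Gamma-distributed annual ring
#'   widths (radial increment, mm); SD 0 gives constant widths.
#' @param pith_offset_mm Distance from the pith to the innermost ring.
#' @param min_first_sample_dbh First sample placed once mean DBH (cm) reaches
#'   this value, focusing the series on canopy trees.
#' @return List of class `d6sr_design`.
#' @export
study_design <- function(
    sites = c("A", "B", "C"),
    trees_per_site = 3,
    samples_per_tree = list(c(5, 5, 4), c(5, 5, 4), c(4, 4, 4)),
    replicate_range = c(5, 6),
    pooling_years = c(10, 10, 7),
    year_range = c(1900, 2016),
    collection_years = c(2000, 2014, 2016),
    birth_years = list(c(1886, 1900, 1915), c(1906, 1925, 1945),
                       c(1941, 1955, 1966)),
    start_month = c(7, 1, 1),
    site_climatology = tibble::tibble(
      site = c("A", "B", "C"),
      tday_mean = c(22, 27, 25),
      tday_sd = c(0.5, 0.5, 0.5),
      wet_months = list(c(12, 1:3), c(5:10), c(3:10)),
      wet_precip_mm = c(230, 220, 260),
      dry_precip_mm = c(45, 40, 60)
    ),
    ring_width_mean_mm = 5,
    ring_width_sd_mm = 1.5,
    pith_offset_mm = 10,
    min_first_sample_dbh = 20) {
  n_sites <- length(sites)
  stopifnot(n_sites >= 1, trees_per_site >= 1, all(pooling_years >= 1),
            length(year_range) == 2, year_range[2] >= year_range[1],
            all(replicate_range >= 1), ring_width_mean_mm > 0,
            ring_width_sd_mm >= 0)
  pooling_years <- rep_len(pooling_years, n_sites)
  collection_years <- rep_len(collection_years, n_sites)
  start_month <- rep_len(start_month, n_sites)
  structure(list(sites = sites, trees_per_site = trees_per_site,
                 samples_per_tree = samples_per_tree,
                 replicate_range = replicate_range,
                 pooling_years = pooling_years, year_range = year_range,
                 collection_years = collection_years,
                 birth_years = birth_years, start_month = start_month,
                 site_climatology = site_climatology,
                 ring_width_mean_mm = ring_width_mean_mm,
                 ring_width_sd_mm = ring_width_sd_mm,
                 pith_offset_mm = pith_offset_mm,
                 min_first_sample_dbh = min_first_sample_dbh),
            class = "d6sr_design")
}

#' Synthetic annual atmospheric CO2 series
#'
#' Piecewise trajectory with the qualitative shape of the spliced
#' ice-core/observatory record: a slow linear rise before 1959 and an
#' exponential rise thereafter, calibrated so that 1905 gives about 298 ppm
#' and 2016 about 405 ppm. A flat mode returns a constant series for use as a
#' degenerate control.
#'
#' @param years Integer vector of years within 1850--2100.
#' @param flat_ppm If non-`NULL`, every year gets this constant value.
#' @return Tibble with `year` and `ca` (ppm), nondecreasing in `year`.
#' @examples
#' rng <- make_ca_series(1905:2016)
#' range(rng$ca) # about 298 to 405
#' @export
make_ca_series <- function(years, flat_ppm = NULL) {
  if (length(years) == 0) stop("`years` is empty.", call. = FALSE)
  if (any(years < 1850 | years > 2100)) {
    stop("`years` must lie within 1850..2100.", call. = FALSE)
  }
  if (!is.null(flat_ppm)) {
    return(tibble::tibble(year = as.integer(years), ca = flat_ppm))
  }
  slope <- 0.33                       # ppm per year before 1959
  ca1905 <- 298
  ca1959 <- ca1905 + slope * (1959 - 1905)
  rate <- log(405 / ca1959) / (2016 - 1959)
  ca <- ifelse(years <= 1959,
               ca1905 + slope * (years - 1905),
               ca1959 * exp(rate * (years - 1959)))
  tibble::tibble(year = as.integer(years), ca = ca)
}

#' Simulate monthly climate for the study sites
#'
#' Draws monthly minimum/maximum temperature and precipitation for each site
#' over the design's year range. Wet-season months receive gamma-distributed
#' precipitation around the site's wet-month mean (virtually always above the
#' 100 mm growing-season threshold); dry months fall well below it. Day
#' temperatures vary between years by the site's interannual SD.
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return Tibble `site`, `year`, `month`, `tmin`, `tmax`, `precip`.
#' @export
simulate_climate <- function(design, seed = 1L) {
  stopifnot(inherits(design, "d6sr_design"))
  years <- seq(design$year_range[1], design$year_range[2])
  purrr::map_dfr(seq_along(design$sites), function(i) {
    set.seed(substream_seed(seed, 11, i))
    clim <- design$site_climatology[design$site_climatology$site == design$sites[i], ]
    grid <- tidyr::expand_grid(year = years, month = 1:12)
    wet <- grid$month %in% clim$wet_months[[1]]
    # annual anomaly shared by all months of a year
    anom <- rnorm(length(years), 0, clim$tday_sd)[match(grid$year, years)]
    tmax <- clim$tday_mean + 2 + anom + rnorm(nrow(grid), 0, 0.8)
    tmin <- tmax - 9 + rnorm(nrow(grid), 0, 0.5)
    shp <- 25
    precip <- ifelse(wet,
                     rgamma(nrow(grid), shape = shp, rate = shp / clim$wet_precip_mm),
                     rgamma(nrow(grid), shape = shp, rate = shp / clim$dry_precip_mm))
    tibble::tibble(site = design$sites[i], year = grid$year, month = grid$month,
                   tmin = tmin, tmax = tmax, precip = precip)
  })
}

#' Simulate ring-width series and reconstructed DBH per tree
#'
#' Annual radial increments are gamma distributed around the design's mean
#' ring width (constant when the SD is zero); DBH is reconstructed from
#' cumulative widths plus the pith offset via [reconstruct_dbh()]. The default
#' design spans roughly 20--114 cm DBH across the sampled windows.
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return Tibble `site`, `tree`, `year`, `width_mm`, `dbh_cm`; rows ordered
#'   oldest to youngest within tree.
#' @export
simulate_tree_rings <- function(design, seed = 1L) {
  stopifnot(inherits(design, "d6sr_design"))
  purrr::map_dfr(seq_along(design$sites), function(i) {
    purrr::map_dfr(seq_len(design$trees_per_site), function(j) {
      set.seed(substream_seed(seed, 22, i, j))
      yrs <- seq(design$birth_years[[i]][j], design$collection_years[i])
      mu <- design$ring_width_mean_mm
      sdv <- design$ring_width_sd_mm
      w <- if (sdv == 0) rep(mu, length(yrs)) else {
        shp <- (mu / sdv)^2
        rgamma(length(yrs), shape = shp, rate = shp / mu)
      }
      tibble::tibble(site = design$sites[i], tree = paste0(design$sites[i], j),
                     year = yrs, width_mm = w,
                     dbh_cm = reconstruct_dbh(w, design$pith_offset_mm))
    })
  })
}

# place n non-overlapping pooled windows at approximately equidistant CO2
# levels between the first eligible year and the collection year
place_sample_windows <- function(eligible_years, n, pool, ca_series) {
  cand <- eligible_years[eligible_years + pool - 1 <= max(eligible_years)]
  if (length(cand) < 1) stop("no room for sample windows", call. = FALSE)
  ca_mid <- ca_series$ca[match(round(cand + (pool - 1) / 2), ca_series$year)]
  targets <- seq(ca_mid[1], ca_mid[length(ca_mid)], length.out = n)
  starts <- integer(n)
  prev <- -Inf
  for (s in seq_len(n)) {
    k <- which.min(abs(ca_mid - targets[s]))
    y <- cand[k]
    y <- max(y, prev + pool)                          # no overlap
    y <- min(y, max(cand) - (n - s) * pool)           # room for the rest
    starts[s] <- y
    prev <- y
  }
  starts
}

#' Simulate a complete synthetic D6SR dataset
#'
#' Generates climate, atmospheric CO2 and ring widths according to the design,
#' builds the per-sample covariates exactly as the analysis does (growing
#' season above 100 mm, ring-width weighted pooling, standardization), and
#' draws D6SR replicates from the hierarchical generalized Michaelis--Menten
#' model at the supplied ground-truth parameters: for replicate l of sample k
#' of tree j of site i,
#' `D6SR ~ Normal(a_ijk * D_k / (b_ijk + D_k), sigma)`, where `a_ijk` is the
#' baseline asymptote plus covariate effects plus nested normal deviations and
#' `b_ijk` the half-saturation plus nested deviations, truncated from below at
#' `0.05 * b0` (`floor_b = TRUE`) to keep the mean defined.
#'
#' Identical `params$seed` yields a byte-identical dataset; sub-streams per
#' site/tree are derived from the master seed so components can be regenerated
#' independently.
#'
#' @param params A [true_params()].
#' @param design A [study_design()].
#' @param floor_b Truncate half-saturation deviations at `0.05 * b0`? If
#'   `FALSE`, a non-positive simulated half-saturation is an error.
#' @return List of class `d6sr_dataset`: `d6sr` (tibble site, tree, sample,
#'   replicate, d6sr), `covariates` (a `d6sr_covariates` object), `samples`
#'   (pooled window membership), `rings`, `climate`, `ca`, and `truth`
#'   (the parameters plus per-unit effects actually drawn).
#' @export
simulate_d6sr_dataset <- function(params = true_params(),
                                  design = study_design(),
                                  floor_b = TRUE) {
  stopifnot(inherits(params, "d6sr_truth"), inherits(design, "d6sr_design"))
  seed <- params$seed
  climate <- simulate_climate(design, seed)
  rings <- simulate_tree_rings(design, seed)
  ca <- make_ca_series(seq(design$year_range[1], design$year_range[2]))

  # growing-season climatology per site (ring-year relabelled per site)
  gseason <- purrr::map_dfr(seq_along(design$sites), function(i) {
    climate |>
      dplyr::filter(.data$site == design$sites[i]) |>
      shift_ring_year(start_month = design$start_month[i]) |>
      growing_season_summary()
  })

  # place pooled sample windows per tree
  samples <- purrr::map_dfr(seq_along(design$sites), function(i) {
    pool <- design$pooling_years[i]
    purrr::map_dfr(seq_len(design$trees_per_site), function(j) {
      tr <- rings[rings$site == design$sites[i] &
                    rings$tree == paste0(design$sites[i], j), ]
      eligible <- tr$year[tr$dbh_cm >= design$min_first_sample_dbh &
                            tr$year >= design$year_range[1]]
      n_s <- design$samples_per_tree[[i]][j]
      starts <- place_sample_windows(eligible, n_s, pool, ca)
      purrr::map_dfr(seq_along(starts), function(s) {
        win <- tr[tr$year >= starts[s] & tr$year <= starts[s] + pool - 1, ]
        dplyr::mutate(win, sample = paste0(.data$tree, "_", s))
      })
    })
  })

  cov <- sample_covariates(samples, gseason, ca, diameter_transform = "scaled")
  cv <- cov$covariates

  # nested random intercepts (non-centered truth), sub-streams per level
  set.seed(substream_seed(seed, 33))
  sites <- design$sites
  trees <- unique(cv$tree)
  u_site_a <- setNames(rnorm(length(sites), 0, params$sd_site_a), sites)
  u_tree_a <- setNames(rnorm(length(trees), 0, params$sd_tree_a), trees)
  u_samp_a <- setNames(rnorm(nrow(cv), 0, params$sd_sample_a), cv$sample)
  u_site_b <- setNames(rnorm(length(sites), 0, params$sd_site_b), sites)
  u_tree_b <- setNames(rnorm(length(trees), 0, params$sd_tree_b), trees)
  u_samp_b <- setNames(rnorm(nrow(cv), 0, params$sd_sample_b), cv$sample)

  a_k <- params$a0 + params$beta_ca * cv$z_ca + params$beta_tday * cv$z_tday +
    params$beta_precip * cv$z_precip +
    u_site_a[cv$site] + u_tree_a[cv$tree] + u_samp_a[cv$sample]
  b_k <- params$b0 + u_site_b[cv$site] + u_tree_b[cv$tree] + u_samp_b[cv$sample]
  if (floor_b) {
    b_k <- pmax(b_k, 0.05 * params$b0)
  } else if (any(b_k <= 0)) {
    stop("simulated half-saturation <= 0 with `floor_b = FALSE`.", call. = FALSE)
  }
  mu_k <- gmm_mean(cv$z_dbh, a_k, b_k)

  set.seed(substream_seed(seed, 44))
  n_rep <- sample(seq(design$replicate_range[1], design$replicate_range[2]),
                  nrow(cv), replace = TRUE)
  d6sr <- tibble::tibble(
    site = rep(cv$site, n_rep),
    tree = rep(cv$tree, n_rep),
    sample = rep(cv$sample, n_rep),
    replicate = unlist(lapply(n_rep, seq_len), use.names = FALSE),
    d6sr = rnorm(sum(n_rep), rep(mu_k, n_rep), params$sigma)
  )

  structure(list(
    d6sr = d6sr, covariates = cov, samples = samples, rings = rings,
    climate = climate, ca = ca,
    truth = c(unclass(params),
              list(a_k = a_k, b_k = b_k, mu_k = mu_k,
                   u_site_a = u_site_a, u_tree_a = u_tree_a,
                   u_samp_a = u_samp_a, u_site_b = u_site_b,
                   u_tree_b = u_tree_b, u_samp_b = u_samp_b))),
    class = "d6sr_dataset")
}

#' @export
print.d6sr_dataset <- function(x, ...) {
  cat("Synthetic D6SR dataset:\n")
  cat("  ", dplyr::n_distinct(x$d6sr$site), "sites,",
      dplyr::n_distinct(x$d6sr$tree), "trees,",
      dplyr::n_distinct(x$d6sr$sample), "samples,",
      nrow(x$d6sr), "replicate observations\n")
  cat("  DBH of samples:",
      paste(round(range(x$covariates$covariates$dbh), 1), collapse = "-"), "cm;",
      "CO2:", paste(round(range(x$covariates$covariates$ca)), collapse = "-"),
      "ppm\n")
  invisible(x)
}
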