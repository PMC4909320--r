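#' Specification of a synthetic nutrient spot table
#'
#' Emulates spot measurements of nutrient concentration across the growth
#' sheet, with an annotated distance to the nearest root. Concentrations
#' are lognormal — concentrations cannot be negative, and at the moderate
#' dispersions of interest (CV around 0.11) the lognormal is essentially
#' indistinguishable from a normal — parameterized so that the arithmetic
#' mean and coefficient of variation match the request exactly. Spots
#' closer to the root than `cutoff` have their mean shifted by the
#' fractional `near_effect`, giving a dial for the near-root
#' depletion/accumulation the analysis is designed to detect.
#'
#' @param seed Integer seed.
#' @param n_spots Spots per nutrient (default 48, split near/far by
#'   `fraction_near`).
#' @param mean_concentration Named numeric vector: mean concentration in
#'   mg/L per nutrient. Default: phosphorus at 19.375 mg/L (0.625 mM x 31
#'   g/mol, half-strength MS).
#' @param point_cv Point-to-point coefficient of variation (>= 0; default
#'   0.11).
#' @param near_effect Fractional shift of the near-spot mean (e.g. -0.5 =
#'   50% depletion; default 0).
#' @param cutoff Near/far distance threshold in mm (default 5).
#' @param fraction_near Proportion of spots near the root (default 0.5).
#' @return List of class `spot_spec`.
#' @export
spot_spec <- function(seed = 1, n_spots = 48,
                      mean_concentration = c(phosphorus = 19.375),
                      point_cv = 0.11, near_effect = 0, cutoff = 5,
                      fraction_near = 0.5) {
  if (any(mean_concentration <= 0)) abort("mean concentrations must be positive.")
  if (is.null(names(mean_concentration))) {
    names(mean_concentration) <- paste0("nutrient", seq_along(mean_concentration))
  }
  if (point_cv < 0) abort("point_cv must be >= 0.")
  if (n_spots < 2) abort("n_spots must be >= 2.")
  if (fraction_near < 0 || fraction_near > 1) abort("fraction_near must be in [0, 1].")
  check_positive_scalar(cutoff, "cutoff")
  structure(
    list(seed = as.integer(seed), n_spots = as.integer(n_spots),
         mean_concentration = mean_concentration, point_cv = point_cv,
         near_effect = near_effect, cutoff = cutoff,
         fraction_near = fraction_near),
    class = "spot_spec"
  )
}

#' Generate a synthetic nutrient spot table
#'
#' @param spec A [spot_spec()].
#' @param sheet_size_mm Side length of the square growth sheet used for the
#'   decorative spot coordinates (default 120 mm).
#' @return Tibble with columns `spot_id`, `x_mm`, `y_mm`,
#'   `distance_to_root_mm`, `nutrient`, `concentration_mg_per_L`.
#' @examples
#' tab <- generate_spot_table(spot_spec(seed = 1, point_cv = 0.11))
#' heterogeneity_cv(tab)
#' @export
generate_spot_table <- function(spec, sheet_size_mm = 120) {
  stopifnot(inherits(spec, "spot_spec"))
  withr::with_seed(spec$seed, {
    purrr::imap_dfr(as.list(spec$mean_concentration), function(m, nut) {
      n <- spec$n_spots
      n_near <- round(spec$fraction_near * n)
      near <- c(rep(TRUE, n_near), rep(FALSE, n - n_near))
      dist <- ifelse(near,
                     runif(n, 0, spec$cutoff),
                     runif(n, spec$cutoff, 5 * spec$cutoff))
      mu_eff <- ifelse(near, m * (1 + spec$near_effect), m)
      if (any(mu_eff <= 0)) abort("near_effect drives the near mean non-positive.")
      sdlog <- sqrt(log(1 + spec$point_cv^2))
      meanlog <- log(mu_eff) - sdlog^2 / 2
      tibble(
        spot_id = paste0(nut, "_", seq_len(n)),
        x_mm = runif(n, 0, sheet_size_mm),
        y_mm = runif(n, 0, sheet_size_mm),
        distance_to_root_mm = dist,
        nutrient = nut,
        concentration_mg_per_L = stats::rlnorm(n, meanlog, sdlog)
      )
    })
  })
}

#' Generate a noisy relative-humidity time series
#'
#' The humidity model of [simulate_humidity()] plus i.i.d. Gaussian
#' observation noise (hygrometer error), clipped to `[0, 100]` %RH.
#'
#' @param params A [humidity_params()].
#' @param duration Days.
#' @param dt Sampling interval in hours (default 1).
#' @param noise_sd Observation noise SD in %RH (default 1).
#' @param seed Integer seed.
#' @param rh0 Initial %RH passed to the simulator.
#' @return Tibble with `time_h` and `rh_percent` (plus `rh_true`, the
#'   noise-free model output).
#' @export
generate_rh_series <- function(params, duration, dt = 1, noise_sd = 1,
                               seed = 1, rh0 = NULL) {
  check_positive_scalar(noise_sd, "noise_sd", allow_zero = TRUE)
  sim <- simulate_humidity(params, duration = duration, dt = dt, rh0 = rh0)
  noisy <- withr::with_seed(seed, sim$rh_percent + rnorm(nrow(sim), 0, noise_sd))
  tibble(
    time_h = sim$time_d * 24,
    rh_percent = pmin(100, pmax(0, noisy)),
    rh_true = sim$rh_percent
  )
}

#' Sample areas from a continuous power law
#'
#' Inverse-CDF sampling from the Pareto density
#' `p(x) = (alpha - 1) / xmin * (x / xmin)^-alpha`, `x >= xmin` — the
#' reference distribution for testing the power-law tail machinery on
#' void-area-like samples.
#'
#' @param alpha Exponent, must exceed 1 (the density is not normalizable
#'   otherwise).
#' @param xmin Lower support bound, cm2.
#' @param n Sample size.
#' @param seed Integer seed.
#' @return Numeric vector of `n` areas, all `>= xmin`.
#' @export
sample_powerlaw_areas <- function(alpha, xmin, n, seed = 1) {
  if (alpha <= 1) abort("alpha must exceed 1: the power law is non-normalizable otherwise.")
  check_positive_scalar(xmin, "xmin")
  if (n < 1) abort("n must be >= 1.")
  withr::with_seed(seed, xmin * runif(n)^(-1 / (alpha - 1)))
}
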