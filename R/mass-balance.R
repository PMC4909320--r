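#' Mass-balance parameters for nutrient transport to the growth sheet
#'
#' Bundles the fluxes and transport constants of the vertical nutrient
#' balance between the nutrient cup and the growth sheet. Water wicked to
#' the sheet evaporates (and is transpired), carrying nutrients upward at
#' the advective rate; the resulting concentration excess at the sheet
#' drives a diffusive return flux through the saturated paper column of
#' height `h`.
#'
#' @param J_water Combined evaporation + transpiration water flux per unit
#'   growth-sheet area, ml/cm2/day (default 0.05, the measured operating
#'   value of the reference chamber).
#' @param C_cup Nutrient molarity in the cup, mol/L. Default 6.25e-4
#'   (phosphorus in half-strength MS medium: 1.25 mM KH2PO4 at full
#'   strength).
#' @param FW Formula weight of the tracked nutrient, g/mol (default 31,
#'   elemental phosphorus).
#' @param D Diffusivity of the nutrient in water, cm2/s (default 0.89e-5,
#'   phosphate).
#' @param h Distance between nutrient-solution surface and growth-sheet
#'   surface, cm. Typically 0.1 cm; 0.2 cm is a deliberate overestimate.
#'   Values above 0.3 cm trigger a warning: the chamber design requires a
#'   short wicking column.
#' @param uptake_rate Plant nutrient uptake, mg/day (default 0: neglecting
#'   uptake makes the steady-state enrichment an overestimate).
#' @param cup_volume Nutrient cup volume in L (default 0.25).
#' @return A list of class `flux_params`.
#' @export
flux_params <- function(J_water = 0.05, C_cup = 6.25e-4, FW = 31,
                        D = 0.89e-5, h = 0.2, uptake_rate = 0,
                        cup_volume = 0.25) {
  for (nm in c("J_water", "C_cup", "FW", "D", "h", "cup_volume")) {
    check_positive_scalar(get(nm), nm)
  }
  check_positive_scalar(uptake_rate, "uptake_rate", allow_zero = TRUE)
  if (h > 0.3) {
    warn("h > 0.3 cm: the wicking column should be short (typically 0.1-0.2 cm).")
  }
  structure(
    list(J_water = J_water, C_cup = C_cup, FW = FW, D = D, h = h,
         uptake_rate = uptake_rate, cup_volume = cup_volume),
    class = "flux_params"
  )
}

#' Advective nutrient flux to the growth sheet
#'
#' Water leaving the system by evaporation and transpiration carries
#' dissolved nutrients to the growth sheet, where the water departs but the
#' nutrients stay. The mass flux follows directly from unit bookkeeping:
#' `J_water [ml/cm2/day] x C_cup [mol/L] x FW [g/mol]` is already in
#' mg/cm2/day, because 1 ml x 1 mol/L x 1 g/mol = 1 mg.
#'
#' @param J_water Water flux, ml/cm2/day.
#' @param C_cup Nutrient molarity, mol/L.
#' @param FW Formula weight, g/mol.
#' @return Nutrient mass flux in mg/cm2/day.
#' @examples
#' # phosphorus in half-strength MS at the reference operating water flux
#' nutrient_flux_to_sheet(0.05, 6.25e-4, 31) # ~0.001 mg/cm2/day
#' @export
nutrient_flux_to_sheet <- function(J_water, C_cup, FW) {
  check_positive_scalar(J_water, "J_water", allow_zero = TRUE)
  check_positive_scalar(C_cup, "C_cup")
  check_positive_scalar(FW, "FW")
  J_water * C_cup * FW
}

#' Steady-state nutrient enrichment at the growth sheet
#'
#' At steady state the upward advective nutrient flux is matched by
#' diffusion back down the wicking column: `J_diff = D * dC / h`. Solving
#' for `dC` gives the concentration excess at the growth sheet over the
#' cup. Plant uptake is deliberately neglected (every nutrient brought up
#' is assumed to accumulate), so the result is an upper bound on the real
#' enrichment.
#'
#' @param params A [flux_params()] object.
#' @return A tibble of class `nutrient_steady_state` with columns
#'   `J_nutrient` (mg/cm2/day), `delta_C` (mg/L), `C_cup_mg_L` (mg/L) and
#'   `relative_enrichment` (% of the cup concentration).
#' @examples
#' steady_state_enrichment(flux_params()) # ~1.3 % enrichment
#' @export
steady_state_enrichment <- function(params) {
  stopifnot(inherits(params, "flux_params"))
  if (params$D <= 0) abort("D must be positive.")
  J_nutrient <- nutrient_flux_to_sheet(params$J_water, params$C_cup, params$FW)
  J_per_s <- J_nutrient / 86400                    # mg/cm2/s
  delta_C_cm3 <- J_per_s * params$h / params$D     # mg/cm3
  delta_C <- delta_C_cm3 * 1000                    # mg/L
  C_cup_mg_L <- params$C_cup * params$FW * 1000    # mol/L * g/mol -> g/L -> mg/L
  structure(
    tibble(
      J_nutrient = J_nutrient,
      delta_C = delta_C,
      C_cup_mg_L = C_cup_mg_L,
      relative_enrichment = 100 * delta_C / C_cup_mg_L
    ),
    class = c("nutrient_steady_state", class(tibble()))
  )
}

#' Nutrient-cup concentration under plant uptake with DI-water refill
#'
#' The cup's liquid level is re-established with deionized water, so the
#' cup volume is constant and no nutrients enter the system; plant uptake
#' is then the only sink: `dC/dt = -uptake_rate / cup_volume`. With zero
#' uptake the series is flat — the null expectation behind the observation
#' that nutrients do not accumulate in the cup over two weeks of growth.
#'
#' @param params A [flux_params()] object (`uptake_rate` mg/day,
#'   `cup_volume` L, `C_cup` mol/L, `FW` g/mol).
#' @param duration Days to simulate.
#' @param dt Output time step in days (default 0.25).
#' @param uptake Optional uptake schedule overriding `params$uptake_rate`:
#'   either a constant (mg/day) or a function of time `u(t)` in mg/day
#'   (e.g. a piecewise schedule tracking plant growth), integrated by
#'   trapezoidal quadrature on a grid 100x finer than `dt`.
#' @return Tibble with `time_d` and `concentration_mg_per_L` (floored at 0).
#' @export
simulate_cup_depletion <- function(params, duration, dt = 0.25, uptake = NULL) {
  stopifnot(inherits(params, "flux_params"))
  check_positive_scalar(duration, "duration")
  check_positive_scalar(dt, "dt")
  t <- seq(0, duration, by = dt)
  C0 <- params$C_cup * params$FW * 1000
  uptake <- uptake %||% params$uptake_rate
  removed_mg <- if (is.function(uptake)) {
    tf <- seq(0, duration, length.out = length(t) * 100 + 1)
    u <- vapply(tf, uptake, numeric(1))
    cum <- c(0, cumsum((u[-1] + u[-length(u)]) / 2 * diff(tf)))
    stats::approx(tf, cum, xout = t)$y
  } else {
    uptake * t
  }
  conc <- pmax(0, C0 - removed_mg / params$cup_volume)
  tibble(time_d = t, concentration_mg_per_L = conc)
}
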