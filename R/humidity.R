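#' Equilibrium relative humidity of supersaturated salt solutions
#'
#' A supersaturated salt solution pins the water-vapour pressure above it,
#' and therefore the relative humidity of a closed chamber, at a
#' salt-specific equilibrium value for as long as undissolved solid
#' remains. The bundled table holds standard literature equilibrium %RH
#' values near room temperature for the salts spanning roughly 11-98 %RH.
#'
#' @param name Salt name, e.g. `"NaCl"`. Matching ignores case and
#'   subscript digits.
#' @param temperature Temperature in Celsius, used as a lookup key only
#'   (default 20). The nearest tabulated temperature is used, with a
#'   warning when it is not exact.
#' @return Equilibrium %RH.
#' @examples
#' salt_lookup("LiCl")   # ~11 %RH
#' salt_lookup("Na2SO4") # ~95 %RH
#' @export
salt_lookup <- function(name, temperature = 20) {
  tab <- salt_table()
  key <- toupper(gsub("[^A-Za-z0-9]", "", name))
  hit <- tab[toupper(tab$salt_key) == key, ]
  if (nrow(hit) == 0) {
    abort(paste0("unknown salt '", name, "'. Available: ",
                 paste(unique(tab$salt), collapse = ", ")))
  }
  i <- which.min(abs(hit$temperature_c - temperature))
  if (abs(hit$temperature_c[i] - temperature) > 0.5) {
    warn(sprintf("no entry for %s at %g C; using nearest tabulated %g C.",
                 name, temperature, hit$temperature_c[i]))
  }
  hit$rh_eq[i]
}

#' @rdname salt_lookup
#' @export
salt_table <- function() {
  tibble(
    salt = c("LiCl", "MgCl2", "K2CO3", "Mg(NO3)2", "NaCl", "KCl",
             "KNO3", "Na2SO4", "K2SO4"),
    salt_key = c("LICL", "MGCL2", "K2CO3", "MGNO32", "NACL", "KCL",
                 "KNO3", "NA2SO4", "K2SO4"),
    temperature_c = 20,
    rh_eq = c(11.3, 33.1, 43.2, 54.4, 75.5, 85.1, 94.6, 95.0, 97.6)
  )
}

#' Humidity-balance parameters of the shoot compartment
#'
#' The shoot compartment receives water vapour from evaporation off the
#' root environment and transpiration by the leaves (`phi_in`), exchanges
#' vapour with the laboratory through enclosure leaks (conductance
#' `k_leak`), and loses vapour to a supersaturated salt sink whose
#' absorption rate is, to first order, proportional to the exposed solution
#' area (conductance `k_salt`) and to the RH excess over the salt's
#' equilibrium value. The salt sink operates only while solid salt remains:
#' once it has absorbed `salt_capacity` ml of water it is fully dissolved
#' and switches off.
#'
#' @param salt Salt name (sets `rh_eq_salt` via [salt_lookup()]) or `NULL`
#'   when `rh_eq_salt` is given directly.
#' @param rh_eq_salt Equilibrium %RH of the supersaturated solution.
#' @param phi_in Water-vapour input, ml/day (default 5: the reference
#'   chamber's measured evaporation + transpiration of 4 + 1 ml/day).
#' @param k_salt Salt absorption conductance, ml/day per %RH (default 2).
#' @param k_leak Enclosure leak conductance, ml/day per %RH (default 0.05).
#' @param rh_ambient Laboratory %RH (default 50).
#' @param salt_capacity Water the salt can absorb before complete
#'   dissolution, ml (`Inf` = inexhaustible).
#' @param chamber_volume Shoot-compartment air volume, L (default 20).
#' @param temperature Celsius; a lookup key for the salt table and for the
#'   saturation vapour density (default 20).
#' @return List of class `humidity_params`.
#' @export
humidity_params <- function(salt = NULL, rh_eq_salt = NULL, phi_in = 5,
                            k_salt = 2, k_leak = 0.05, rh_ambient = 50,
                            salt_capacity = Inf, chamber_volume = 20,
                            temperature = 20) {
  if (is.null(rh_eq_salt)) {
    if (is.null(salt)) abort("give either `salt` or `rh_eq_salt`.")
    rh_eq_salt <- salt_lookup(salt, temperature)
  }
  if (rh_eq_salt < 0 || rh_eq_salt > 100) abort("rh_eq_salt must be in [0, 100].")
  if (rh_ambient < 0 || rh_ambient > 100) abort("rh_ambient must be in [0, 100].")
  for (nm in c("phi_in", "k_salt", "k_leak")) {
    check_positive_scalar(get(nm), nm, allow_zero = TRUE)
  }
  if (!is.numeric(salt_capacity) || length(salt_capacity) != 1 ||
      is.na(salt_capacity) || salt_capacity < 0) {
    abort("`salt_capacity` must be >= 0 (Inf = inexhaustible).")
  }
  check_positive_scalar(chamber_volume, "chamber_volume")
  structure(
    list(salt = salt, rh_eq_salt = rh_eq_salt, phi_in = phi_in,
         k_salt = k_salt, k_leak = k_leak, rh_ambient = rh_ambient,
         salt_capacity = salt_capacity, chamber_volume = chamber_volume,
         temperature = temperature),
    class = "humidity_params"
  )
}

# saturation water-vapour density at 20 C, as ml of liquid water per litre
# of air per 100 %RH (17.3 g/m3 -> 0.0173 ml/L)
SAT_VAPOR_ML_PER_L <- 0.0173

#' Steady-state relative humidity of the shoot compartment
#'
#' Solves the linear vapour balance
#' `phi_in + k_leak * (rh_ambient - RH) = k_salt * max(RH - rh_eq_salt, 0)`
#' for RH. While the salt sink is active the steady state sits above the
#' salt's equilibrium RH by `(phi_in + k_leak * (rh_ambient - RH)) / k_salt`
#' — the kinetic limitation: a finite absorption rate cannot pull the
#' chamber all the way down to thermodynamic equilibrium. When the balance
#' would settle below `rh_eq_salt` the salt does not release water and the
#' sink term vanishes.
#'
#' @param params A [humidity_params()] object.
#' @return Steady-state %RH, clipped to `[0, 100]`. If there is no sink at
#'   all (`k_salt = k_leak = 0`) while `phi_in > 0`, the compartment
#'   saturates: 100 %RH with a warning.
#' @export
humidity_steady_state <- function(params) {
  stopifnot(inherits(params, "humidity_params"))
  with(params, {
    if (k_salt + k_leak == 0) {
      if (phi_in > 0) {
        warn("no vapour sink: compartment saturates at 100 %RH.")
        return(100)
      }
      return(min(100, max(0, rh_ambient)))
    }
    # assume the salt sink is active
    rh_active <- (phi_in + k_leak * rh_ambient + k_salt * rh_eq_salt) /
      (k_leak + k_salt)
    rh <- if (k_salt > 0 && rh_active >= rh_eq_salt) {
      rh_active
    } else if (k_leak > 0) {
      rh_ambient + phi_in / k_leak # salt inactive: leak balance only
    } else {
      100 # salt inactive, no leak, positive input
    }
    min(100, max(0, rh))
  })
}

#' Simulate shoot-compartment relative humidity over time
#'
#' Forward integration of the vapour balance. The chamber's vapour
#' inventory (ml of water equivalent, via the saturation vapour density at
#' 20 C) converts flux imbalance into RH change; absorbed water accumulates
#' against `salt_capacity`, and when the capacity is exhausted the salt has
#' fully dissolved — the sink switches off permanently and the RH relaxes
#' up to the leak-determined level. The chamber's vapour time constant is
#' typically minutes, so the integrator sub-steps each output interval
#' automatically to stay stable.
#'
#' @param params A [humidity_params()] object.
#' @param duration Days to simulate.
#' @param dt Output time step in hours (default 1).
#' @param rh0 Initial %RH (default `rh_ambient`).
#' @return Tibble of class `rh_series` with columns `time_d`, `rh_percent`,
#'   `absorbed_ml` (cumulative water taken up by the salt), `depleted`, and
#'   the cumulative bookkeeping columns `input_ml` (vapour introduced) and
#'   `leak_in_ml` (net vapour gained through leaks; negative when the
#'   chamber is more humid than the laboratory), so that water conservation
#'   can be audited directly from the output.
#' @export
simulate_humidity <- function(params, duration, dt = 1, rh0 = NULL) {
  stopifnot(inherits(params, "humidity_params"))
  check_positive_scalar(duration, "duration")
  check_positive_scalar(dt, "dt")
  dt_d <- dt / 24
  cap_ml_per_rh <- SAT_VAPOR_ML_PER_L * params$chamber_volume / 100
  rate <- (params$k_leak + params$k_salt) / cap_ml_per_rh # 1/day
  n_sub <- max(1L, ceiling(dt_d * rate / 0.2))
  h <- dt_d / n_sub
  times <- seq(0, duration, by = dt_d)
  rh <- if (is.null(rh0)) params$rh_ambient else rh0
  absorbed <- 0; input <- 0; leaked_in <- 0
  depleted <- params$salt_capacity <= 0
  nt <- length(times)
  out_rh <- numeric(nt); out_abs <- numeric(nt); out_dep <- logical(nt)
  out_in <- numeric(nt); out_leak <- numeric(nt)
  out_rh[1] <- rh
  for (i in seq_along(times)[-1]) {
    for (s in seq_len(n_sub)) {
      j_salt <- if (depleted) 0 else params$k_salt * max(rh - params$rh_eq_salt, 0)
      # in the substep where the salt finishes dissolving it can only absorb
      # what capacity remains
      if (!depleted && absorbed + j_salt * h >= params$salt_capacity) {
        j_salt <- (params$salt_capacity - absorbed) / h
        depleted <- TRUE
      }
      j_leak <- params$k_leak * (params$rh_ambient - rh)
      flux <- params$phi_in + j_leak - j_salt
      rh <- min(100, max(0, rh + flux * h / cap_ml_per_rh))
      input <- input + params$phi_in * h
      leaked_in <- leaked_in + j_leak * h
      absorbed <- absorbed + j_salt * h
    }
    out_rh[i] <- rh; out_abs[i] <- absorbed; out_dep[i] <- depleted
    out_in[i] <- input; out_leak[i] <- leaked_in
  }
  structure(
    tibble(time_d = times, rh_percent = out_rh, absorbed_ml = out_abs,
           depleted = out_dep, input_ml = out_in, leak_in_ml = out_leak),
    class = c("rh_series", class(tibble()))
  )
}

#' Time at which the salt sink is exhausted
#'
#' @param series An `rh_series` tibble from [simulate_humidity()].
#' @return First time (days) with `depleted = TRUE`, or `NA` if the salt
#'   never dissolves completely within the simulated window.
#' @export
depletion_time <- function(series) {
  i <- which(series$depleted)
  if (length(i) == 0) NA_real_ else series$time_d[min(i)]
}
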