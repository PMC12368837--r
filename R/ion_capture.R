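#' Ring-electrode ion guide model
#'
#' The commercial ion guide is abstracted as a DC axial gradient plus an
#' effective radial pseudopotential well: axial force `q E_z`, radial force
#' `-2 q U_star r / r0^2` (harmonic well of depth `U_star` at the inner
#' radius `r0`), in a stationary background gas at the guide pressure.
#' Defaults are declared package values, not instrument measurements.
#'
#' @param entrance_z,exit_z Axial extent of the guide, m.
#' @param r0 Inner radius, m.
#' @param E_z DC axial field, V/m (positive pushes positive ions to the exit).
#' @param U_star Pseudopotential well depth, V.
#' @param pressure,temperature Background gas state, Pa and K.
#' @param gas Gas property list, see [gas_nitrogen()].
#' @return An object of class `ion_guide`.
#' @export
ion_guide <- function(entrance_z = 0, exit_z = 0.035, r0 = 2.5e-3,
                      E_z = 3000, U_star = 2, pressure = 100,
                      temperature = 300, gas = gas_nitrogen()) {
  abort_if(!(exit_z > entrance_z), "guide exit must lie beyond its entrance")
  abort_if(!(r0 > 0), "guide inner radius must be positive")
  abort_if(U_star < 0, "pseudopotential depth must be non-negative")
  bg <- uniform_flow_field(0, temperature, pressure, gas)$uniform
  structure(list(entrance_z = entrance_z, exit_z = exit_z, r0 = r0,
                 E_z = E_z, U_star = U_star, background = bg),
            class = "ion_guide")
}

#' Trace charged particles through the ion guide
#'
#' Semi-implicit integration of drag against the stationary background gas,
#' the DC axial force, the harmonic radial pseudopotential force, and
#' Brownian kicks (ions are nanometre-scale, so Brownian motion is on by
#' default). An ion is captured when it crosses `exit_z` with radius below
#' `r0`, lost if its radius reaches `r0` first, and timed out otherwise.
#'
#' @param ions Particle tibble (all rows must carry non-zero charge).
#' @param guide An [ion_guide()].
#' @param rng_seed Integer seed for the Brownian kicks.
#' @param dt Time step, s; default `tau/20` clamped to `[1e-9, 1e-6]`.
#' @param t_max Maximum traced time, s.
#' @param brownian Logical, default `TRUE` for sub-100 nm ions.
#' @return A tibble with one row per ion: `fate` (`captured`, `lost_wall`,
#'   `timed_out`), exit radius `r`, transit `steps`.
#' @export
trace_ions <- function(ions, guide, rng_seed = 1, dt = NULL, t_max = 5e-4,
                       brownian = NULL) {
  abort_if(any(ions$charge == 0), "ion guide requires charge")
  n <- nrow(ions)
  if (n == 0) {
    return(tibble::tibble(fate = character(0), r = numeric(0),
                          steps = integer(0)))
  }
  bg <- guide$background
  tau <- tau_drag(ions$diameter, ions$density, bg$mean_free_path, bg$viscosity)
  if (is.null(dt)) dt <- default_dt(stats::median(tau))
  if (is.null(brownian)) brownian <- any(ions$diameter < 1e-7)
  set.seed(as.integer(rng_seed %% .Machine$integer.max))

  q <- ions$charge * .e_charge
  m <- ions$mass
  az <- q * guide$E_z / m                  # constant axial acceleration
  kr <- 2 * q * guide$U_star / (guide$r0^2 * m)  # radial spring rate
  x <- ions$x; y <- ions$y; z <- ions$z
  vx <- ions$vx; vy <- ions$vy; vz <- ions$vz
  alive <- rep(TRUE, n)
  fate <- rep(NA_character_, n)
  steps <- rep(0L, n)
  n_steps <- ceiling(t_max / dt)
  sd_k <- if (brownian) sqrt(2 * .kB * bg$temperature /
                               (m * pmax(tau, 1e-15)) * dt) else 0

  for (k in seq_len(n_steps)) {
    ia <- which(alive)
    if (!length(ia)) break
    vx[ia] <- step_velocity(vx[ia], 0, tau[ia], -kr[ia] * x[ia], dt)
    vy[ia] <- step_velocity(vy[ia], 0, tau[ia], -kr[ia] * y[ia], dt)
    vz[ia] <- step_velocity(vz[ia], 0, tau[ia], az[ia], dt)
    if (brownian) {
      vx[ia] <- vx[ia] + stats::rnorm(length(ia), 0, sd_k[ia])
      vy[ia] <- vy[ia] + stats::rnorm(length(ia), 0, sd_k[ia])
      vz[ia] <- vz[ia] + stats::rnorm(length(ia), 0, sd_k[ia])
    }
    x[ia] <- x[ia] + dt * vx[ia]
    y[ia] <- y[ia] + dt * vy[ia]
    z[ia] <- z[ia] + dt * vz[ia]
    r2 <- x[ia]^2 + y[ia]^2
    out_r <- r2 >= guide$r0^2
    through <- !out_r & z[ia] >= guide$exit_z
    done <- out_r | through
    if (any(done)) {
      gi <- ia[done]
      fate[gi] <- ifelse(out_r[done], "lost_wall", "captured")
      steps[gi] <- k
      alive[gi] <- FALSE
    }
    steps[alive] <- k
  }
  fate[is.na(fate)] <- "timed_out"
  tibble::tibble(fate = fate, r = sqrt(x^2 + y^2), steps = steps)
}

#' Trace a single ion through the guide
#'
#' @inheritParams trace_ions
#' @param ion One-row particle tibble.
#' @return The fate string: `"captured"`, `"lost_wall"` or `"timed_out"`.
#' @export
trace_ion <- function(ion, guide, rng_seed = 1, dt = NULL, t_max = 5e-4,
                      brownian = NULL) {
  stopifnot(nrow(ion) == 1)
  trace_ions(ion, guide, rng_seed = rng_seed, dt = dt, t_max = t_max,
             brownian = brownian)$fate[1]
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Numeric `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  abort_if(n <= 0, "Wilson interval needs at least one trial")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Summarise capture efficiency of an ion ensemble
#'
#' @param fates Character vector of fates from [trace_ions()].
#' @return A one-row tibble: `n_emitted`, `n_captured`, `efficiency`, and
#'   the Wilson 95 percent interval (`ci_lower`, `ci_upper`).
#' @export
capture_efficiency <- function(fates) {
  abort_if(length(fates) == 0, "capture efficiency of an empty ensemble")
  k <- sum(fates == "captured")
  n <- length(fates)
  ci <- wilson_ci(k, n)
  tibble::tibble(n_emitted = n, n_captured = k, efficiency = k / n,
                 ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
}
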