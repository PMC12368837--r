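#' Cunningham slip correction factor
#'
#' Correction to Stokes drag for particles whose size is comparable to the
#' gas mean free path: `Cc = 1 + Kn (1.257 + 0.4 exp(-1.1/Kn))`, continuous
#' at `Kn = 0` where it reduces to 1.
#'
#' @param Kn Knudsen number(s), `2 * mean_free_path / diameter`, >= 0.
#' @return The slip correction factor(s), >= 1.
#' @export
cunningham_correction <- function(Kn) {
  abort_if(any(Kn < 0), "Knudsen number must be non-negative")
  ifelse(Kn == 0, 1, 1 + Kn * (1.257 + 0.4 * exp(-1.1 / Kn)))
}

#' Construct particles as a tibble
#'
#' One row per particle. Droplets are described by diameter and material
#' density; mass defaults to the volume-equivalent sphere. Charge is in
#' elementary charges.
#'
#' @param diameter Particle diameter(s), m.
#' @param density Material density, kg/m^3.
#' @param mass Mass in kg; defaults to `density * pi/6 * diameter^3`.
#' @param charge Integer elementary charges (0 for neutral droplets).
#' @param x,y,z Initial position, m (axis along z).
#' @param vx,vy,vz Initial velocity, m/s.
#' @return A tibble with class `lareims_particles`.
#' @export
particles <- function(diameter, density = 1000,
                      mass = density * pi / 6 * diameter^3,
                      charge = 0, x = 0, y = 0, z = 0,
                      vx = 0, vy = 0, vz = 0) {
  abort_if(any(mass <= 0), "particle mass must be positive")
  abort_if(any(diameter < 0), "particle diameter must be non-negative")
  abort_if(any(density <= 0), "material density must be positive")
  out <- tibble::tibble(diameter = diameter, density = density, mass = mass,
                        charge = as.integer(charge),
                        x = x, y = y, z = z, vx = vx, vy = vy, vz = vz)
  class(out) <- c("lareims_particles", class(out))
  out
}

#' Momentum relaxation time of a particle in a gas
#'
#' `tau = density * diameter^2 * Cc(Kn) / (18 mu)` with `Kn = 2 lambda /
#' diameter`. A zero-diameter particle is treated as ballistic (`tau = 0`,
#' meaning drag acts instantaneously toward the gas velocity is never the
#' case; the integrator interprets `tau = 0` as drag-free).
#'
#' @param p One-row particle tibble (or vectors recycled against `state`).
#' @param state Gas state tibble as returned by [flow_state()].
#' @return Relaxation time(s), s.
#' @export
relaxation_time <- function(p, state) {
  tau_drag(p$diameter, p$density, state$mean_free_path, state$viscosity)
}

tau_drag <- function(diameter, density, lambda, mu) {
  ifelse(diameter <= 0, 0, {
    Kn <- 2 * lambda / diameter
    density * diameter^2 * cunningham_correction(Kn) / (18 * mu)
  })
}

default_dt <- function(tau) clamp(tau / 20, 1e-9, 1e-6)

# One semi-implicit Euler step for linear drag plus external acceleration,
# vectorised over particles. Unconditionally stable for stiff drag (dt >> tau
# simply relaxes the velocity onto gas velocity + terminal drift).
# st: list of vectors x, y, z, vx, vy, vz; u: gas velocity components;
# tau: relaxation times; acc: external acceleration components.
step_velocity <- function(v, u, tau, acc, dt) {
  ifelse(tau <= 0, v, (v + dt * (u / tau + acc)) / (1 + dt / tau))
}

#' Integrate one particle trajectory through a flow field
#'
#' Semi-implicit Euler integration of `dv/dt = (u_gas - v)/tau` with optional
#' Brownian velocity kicks (variance `2 kB T dt / (m tau)` per axis, enabled
#' by default for particles below 100 nm). The trajectory terminates on
#' surface impact, on leaving the domain (wall loss), or at `t_max`.
#'
#' @param p A one-row particle tibble from [particles()].
#' @param field A [build_flow_field()] object.
#' @param surface Optional [collision_surface()].
#' @param rng_seed Integer seed for the Brownian kicks.
#' @param dt Time step, s; default `tau/20` at the launch state, clamped to
#'   `[1e-9, 1e-6]`.
#' @param t_max Maximum simulated time, s.
#' @param brownian Logical; default `diameter < 1e-7` m.
#' @param record_path If `TRUE`, keep the sampled positions.
#' @return A list of class `trajectory_result`: `fate` (one of
#'   `impacted_surface`, `lost_wall`, `timed_out`), `impact_point`,
#'   `impact_speed`, `steps`, final `state`, and optionally `path`.
#' @export
simulate_trajectory <- function(p, field, surface = NULL, rng_seed = 1,
                                dt = NULL, t_max = 1e-3, brownian = NULL,
                                record_path = FALSE) {
  stopifnot(nrow(p) == 1)
  res <- transport_ensemble(p, field, surface, seed = rng_seed, dt = dt,
                            t_max = t_max, brownian = brownian,
                            record_path = record_path)
  out <- list(
    fate = res$fates$fate[1],
    impact_point = if (res$fates$fate[1] == "impacted_surface")
      c(x = res$fates$impact_x[1], y = res$fates$impact_y[1],
        z = res$fates$impact_z[1]) else NULL,
    impact_speed = if (res$fates$fate[1] == "impacted_surface")
      res$fates$impact_speed[1] else NULL,
    steps = res$fates$steps[1],
    state = res$fates[1, c("x", "y", "z", "vx", "vy", "vz")]
  )
  if (record_path) out$path <- res$path
  structure(out, class = "trajectory_result")
}

#' Integrate an ensemble of particle trajectories
#'
#' Vectorised counterpart of [simulate_trajectory()]: all particles advance
#' synchronously through the shared flow field. With Brownian motion off
#' (micron droplets) the integration is deterministic; with it on, kicks are
#' drawn from `rng_seed` so runs are reproducible.
#'
#' @inheritParams simulate_trajectory
#' @param parts Particle tibble, one row per particle.
#' @param seed Integer seed.
#' @return A list with `fates`, a tibble (one row per particle: `fate`,
#'   impact point/speed/radius, `steps`, final phase-space coordinates), and
#'   optionally `path`.
#' @export
transport_ensemble <- function(parts, field, surface = NULL, seed = 1,
                               dt = NULL, t_max = 1e-3, brownian = NULL,
                               record_path = FALSE) {
  n <- nrow(parts)
  st0 <- flow_state(field, pmax(parts$z, 0), sqrt(parts$x^2 + parts$y^2))
  abort_if(any(parts$z < 0 | parts$z > field$domain$z_max |
                 sqrt(parts$x^2 + parts$y^2) > field$domain$r_max),
           "particle initialized outside the flow domain")
  if (is.null(dt)) {
    tau0 <- tau_drag(parts$diameter, parts$density,
                     st0$mean_free_path, st0$viscosity)
    tau_pos <- tau0[tau0 > 0]
    dt <- if (length(tau_pos)) default_dt(stats::median(tau_pos)) else 1e-7
  }
  if (is.null(brownian)) brownian <- any(parts$diameter < 1e-7)
  set.seed(as.integer(seed %% .Machine$integer.max))

  x <- parts$x; y <- parts$y; z <- parts$z
  vx <- parts$vx; vy <- parts$vy; vz <- parts$vz
  alive <- rep(TRUE, n)
  fate <- rep(NA_character_, n)
  imp_x <- imp_y <- imp_z <- imp_v <- rep(NA_real_, n)
  steps <- rep(0L, n)
  n_steps <- ceiling(t_max / dt)
  path <- if (record_path) vector("list", n_steps + 1) else NULL
  if (record_path) path[[1]] <- tibble::tibble(t = 0, x = x, y = y, z = z)

  for (k in seq_len(n_steps)) {
    if (!any(alive)) break
    ia <- which(alive)
    r <- sqrt(x[ia]^2 + y[ia]^2)
    gs <- flow_eval(field, z[ia], r)
    tau <- tau_drag(parts$diameter[ia], parts$density[ia],
                    gs$mean_free_path, gs$viscosity)
    vx[ia] <- step_velocity(vx[ia], 0, tau, 0, dt)
    vy[ia] <- step_velocity(vy[ia], 0, tau, 0, dt)
    vz[ia] <- step_velocity(vz[ia], gs$velocity_z, tau, 0, dt)
    if (brownian) {
      sd_k <- sqrt(2 * .kB * gs$temperature /
                     (parts$mass[ia] * pmax(tau, 1e-12)) * dt)
      vx[ia] <- vx[ia] + stats::rnorm(length(ia), 0, sd_k)
      vy[ia] <- vy[ia] + stats::rnorm(length(ia), 0, sd_k)
      vz[ia] <- vz[ia] + stats::rnorm(length(ia), 0, sd_k)
    }
    x1 <- x[ia] + dt * vx[ia]
    y1 <- y[ia] + dt * vy[ia]
    z1 <- z[ia] + dt * vz[ia]

    if (!is.null(surface)) {
      hit <- detect_impact_segments(x[ia], y[ia], z[ia], x1, y1, z1, surface)
      hi <- which(!is.na(hit$t_hit))
      if (length(hi)) {
        gi <- ia[hi]
        imp_x[gi] <- hit$x[hi]; imp_y[gi] <- hit$y[hi]; imp_z[gi] <- hit$z[hi]
        imp_v[gi] <- sqrt(vx[gi]^2 + vy[gi]^2 + vz[gi]^2)
        fate[gi] <- "impacted_surface"
        steps[gi] <- k
        alive[gi] <- FALSE
      }
    }
    x[ia] <- x1; y[ia] <- y1; z[ia] <- z1
    out_dom <- alive[ia] & (z1 < 0 | z1 > field$domain$z_max |
                              sqrt(x1^2 + y1^2) > field$domain$r_max)
    if (any(out_dom)) {
      gi <- ia[out_dom]
      fate[gi] <- "lost_wall"; steps[gi] <- k; alive[gi] <- FALSE
    }
    steps[alive] <- k
    if (record_path) path[[k + 1]] <- tibble::tibble(t = k * dt, x = x, y = y, z = z)
  }
  fate[is.na(fate)] <- "timed_out"

  fates <- tibble::tibble(
    fate = fate, steps = steps,
    impact_x = imp_x, impact_y = imp_y, impact_z = imp_z,
    impact_r = sqrt(imp_x^2 + imp_y^2), impact_speed = imp_v,
    x = x, y = y, z = z, vx = vx, vy = vy, vz = vz
  )
  out <- list(fates = fates, dt = dt)
  if (record_path) out$path <- dplyr::bind_rows(path)
  out
}
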