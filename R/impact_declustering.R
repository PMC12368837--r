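#' Collision surface of the atmospheric interface
#'
#' The heated impactor on which aerosol droplets decluster into secondary
#' ions. `z_s` is the stand-off distance: the axial position of the
#' surface's nearest (upstream-facing) point, so a sphere of radius `R` has
#' its center at `z_s + R`, and a 45-degree cone has its apex at `z_s`.
#'
#' @param shape One of `"sphere"`, `"plane"`, `"cone"`.
#' @param z_s Stand-off distance from the capillary exit, m.
#' @param temperature Surface temperature, K.
#' @param radius Characteristic radius, m (sphere radius; cone base radius;
#'   unused for the infinite plane).
#' @return An object of class `collision_surface`.
#' @export
collision_surface <- function(shape = c("sphere", "plane", "cone"),
                              z_s = 5e-3, temperature = 1000,
                              radius = 1.5e-3) {
  shape <- match.arg(shape)
  abort_if(!(z_s > 0), "surface stand-off z_s must be positive")
  abort_if(!(temperature > 0), "surface temperature must be positive")
  if (shape != "plane") abort_if(!(radius > 0),
                                 "sphere/cone characteristic radius must be positive")
  structure(list(shape = shape, z_s = z_s, temperature = temperature,
                 radius = radius),
            class = "collision_surface")
}

# Vectorised first-intersection of straight segments with the surface.
# Returns t_hit in [0, 1] (NA for no hit) and the impact coordinates.
detect_impact_segments <- function(x0, y0, z0, x1, y1, z1, surface) {
  n <- length(x0)
  t_hit <- rep(NA_real_, n)
  if (surface$shape == "plane") {
    dz <- z1 - z0
    cross <- (z0 < surface$z_s & z1 >= surface$z_s)
    t_hit[cross] <- (surface$z_s - z0[cross]) / dz[cross]
  } else if (surface$shape == "sphere") {
    cz <- surface$z_s + surface$radius
    dx <- x1 - x0; dy <- y1 - y0; dz <- z1 - z0
    fx <- x0; fy <- y0; fz <- z0 - cz
    a <- dx^2 + dy^2 + dz^2
    b <- 2 * (fx * dx + fy * dy + fz * dz)
    cc <- fx^2 + fy^2 + fz^2 - surface$radius^2
    disc <- b^2 - 4 * a * cc
    ok <- disc >= 0 & a > 0
    sq <- sqrt(pmax(disc, 0))
    t1 <- (-b - sq) / (2 * a)
    t2 <- (-b + sq) / (2 * a)
    tt <- ifelse(t1 >= 0 & t1 <= 1, t1, ifelse(t2 >= 0 & t2 <= 1, t2, NA_real_))
    t_hit[ok] <- tt[ok]
  } else { # cone: apex at z_s on axis, 45-degree half-angle, base radius R
    # signed distance function g(t) = r(t) - (z(t) - z_s) on the truncated
    # cone; root bracketed then refined by bisection to 1e-12 m.
    g_of <- function(t) {
      xt <- x0 + t * (x1 - x0); yt <- y0 + t * (y1 - y0)
      zt <- z0 + t * (z1 - z0)
      r <- sqrt(xt^2 + yt^2)
      ifelse(zt >= surface$z_s & zt <= surface$z_s + surface$radius,
             r - (zt - surface$z_s), NA_real_)
    }
    ts <- seq(0, 1, length.out = 33)
    gv <- vapply(ts, g_of, numeric(n))
    if (n == 1) gv <- matrix(gv, nrow = 1)
    for (i in seq_len(n)) {
      gi <- gv[i, ]
      idx <- which(!is.na(gi[-length(gi)]) & !is.na(gi[-1]) &
                     gi[-length(gi)] > 0 & gi[-1] <= 0)
      if (!length(idx)) next
      lo <- ts[idx[1]]; hi <- ts[idx[1] + 1]
      for (k in 1:60) {
        mid <- (lo + hi) / 2
        gm <- g_of(mid)[i]
        if (is.na(gm) || gm > 0) lo <- mid else hi <- mid
        if ((hi - lo) * sqrt((x1[i] - x0[i])^2 + (y1[i] - y0[i])^2 +
                               (z1[i] - z0[i])^2) < 1e-12) break
      }
      t_hit[i] <- (lo + hi) / 2
    }
  }
  list(
    t_hit = t_hit,
    x = x0 + t_hit * (x1 - x0),
    y = y0 + t_hit * (y1 - y0),
    z = z0 + t_hit * (z1 - z0)
  )
}

#' First intersection of a segment with a collision surface
#'
#' Exact for plane and sphere (quadratic); bisection to 1e-12 m for the
#' cone.
#'
#' @param from,to Numeric length-3 vectors `(x, y, z)` in metres.
#' @param surface A [collision_surface()].
#' @return A named numeric impact point `(x, y, z)`, or `NULL` if the
#'   segment does not intersect the surface.
#' @export
detect_impact <- function(from, to, surface) {
  abort_if(!all(is.finite(c(from, to))), "segment endpoints must be finite")
  hit <- detect_impact_segments(from[1], from[2], from[3],
                                to[1], to[2], to[3], surface)
  if (is.na(hit$t_hit)) return(NULL)
  c(x = hit$x, y = hit$y, z = hit$z)
}

# Outward (upstream-facing) unit normal at impact points on the surface.
surface_normal <- function(x, y, z, surface) {
  if (surface$shape == "plane") {
    cbind(nx = 0 * x, ny = 0 * x, nz = -1 + 0 * x)
  } else if (surface$shape == "sphere") {
    cz <- surface$z_s + surface$radius
    nx <- x; ny <- y; nz <- z - cz
    nn <- sqrt(nx^2 + ny^2 + nz^2)
    nn[nn == 0] <- 1
    cbind(nx = nx / nn, ny = ny / nn, nz = nz / nn)
  } else {
    r <- sqrt(x^2 + y^2)
    ux <- ifelse(r > 0, x / r, 1)
    uy <- ifelse(r > 0, y / r, 0)
    cbind(nx = ux / sqrt(2), ny = uy / sqrt(2), nz = -1 / sqrt(2) + 0 * x)
  }
}

#' Impact declustering yield model
#'
#' Declared parametric model for the probability that a droplet impact
#' liberates a secondary ion: a logistic thermal activation (midpoint
#' `T50 = T50_ref - alpha * impact_speed^2`, width `dT`) multiplied by a
#' power-law thermal degradation envelope `exp(-(T_s/degradation_T)^p)`.
#' Defaults are calibrated so the net yield over surface temperature has an
#' interior optimum near 1000 K; they are package calibration constants, not
#' first-principles values.
#'
#' @param Y_max Maximum yield (probability), in (0, 1].
#' @param T50_ref Activation midpoint at zero impact speed, K.
#' @param dT Logistic width, K.
#' @param alpha Kinetic coupling, K per (m/s)^2: faster impacts decluster at
#'   lower surface temperature.
#' @param degradation_T Thermal degradation scale, K.
#' @param degradation_power Degradation exponent.
#' @return An object of class `declustering_model`.
#' @export
declustering_model <- function(Y_max = 1, T50_ref = 700, dT = 80,
                               alpha = 1e-3, degradation_T = 1600,
                               degradation_power = 4) {
  abort_if(!(Y_max > 0 && Y_max <= 1), "Y_max must be in (0, 1]")
  abort_if(!(dT > 0), "logistic width dT must be positive")
  structure(list(Y_max = Y_max, T50_ref = T50_ref, dT = dT, alpha = alpha,
                 degradation_T = degradation_T,
                 degradation_power = degradation_power),
            class = "declustering_model")
}

#' Secondary-ion emission probability of a droplet impact
#'
#' @param model A [declustering_model()].
#' @param T_s Surface temperature(s), K.
#' @param impact_speed Impact speed(s), m/s.
#' @return Emission probability in `[0, Y_max]` (vectorised).
#' @export
declustering_yield <- function(model, T_s, impact_speed = 0) {
  abort_if(any(T_s <= 0), "surface temperature must be positive")
  abort_if(any(impact_speed < 0), "impact speed must be non-negative")
  T50 <- model$T50_ref - model$alpha * impact_speed^2
  model$Y_max * stats::plogis((T_s - T50) / model$dT) *
    exp(-(T_s / model$degradation_T)^model$degradation_power)
}

#' Secondary-ion specification
#'
#' The species generated on the collision surface: by default singly charged
#' 1 kDa particles of 2.2 nm diameter, emitted with a cosine-law direction
#' about the local surface normal and Maxwell-Boltzmann thermal speed at the
#' surface temperature.
#'
#' @param mass_da Ion mass, Da.
#' @param diameter Ion diameter, m.
#' @param charge Integer elementary charges (non-zero).
#' @return An object of class `secondary_ion_spec`.
#' @export
secondary_ion_spec <- function(mass_da = 1000, diameter = 2.2e-9, charge = 1L) {
  abort_if(charge == 0, "secondary ion charge must be non-zero")
  structure(list(mass_da = mass_da, diameter = diameter,
                 charge = as.integer(charge)),
            class = "secondary_ion_spec")
}

# Cosine-law unit directions about unit normals (rows of nrm), using
# pre-drawn uniforms u1 (polar) and u2 (azimuth in [0,1)).
cosine_directions <- function(nrm, u1, u2) {
  sin_t <- sqrt(u1)
  cos_t <- sqrt(1 - u1)
  phi <- 2 * pi * u2
  # build an orthonormal frame around each normal
  ref <- cbind(1, 0, 0)
  swap <- abs(nrm[, 1]) > 0.9
  refm <- matrix(rep(c(1, 0, 0), each = nrow(nrm)), ncol = 3)
  refm[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  t1 <- cbind(nrm[, 2] * refm[, 3] - nrm[, 3] * refm[, 2],
              nrm[, 3] * refm[, 1] - nrm[, 1] * refm[, 3],
              nrm[, 1] * refm[, 2] - nrm[, 2] * refm[, 1])
  t1 <- t1 / sqrt(rowSums(t1^2))
  t2 <- cbind(nrm[, 2] * t1[, 3] - nrm[, 3] * t1[, 2],
              nrm[, 3] * t1[, 1] - nrm[, 1] * t1[, 3],
              nrm[, 1] * t1[, 2] - nrm[, 2] * t1[, 1])
  nrm * cos_t + t1 * (sin_t * cos(phi)) + t2 * (sin_t * sin(phi))
}

#' Emit secondary ions from droplet impacts
#'
#' Bernoulli emission with probability given by [declustering_yield()] at
#' the surface temperature and each impact's speed; each successful impact
#' emits exactly one ion with cosine-law direction about the local surface
#' normal and Maxwell-Boltzmann thermal speed at `T_s`.
#'
#' @param impacts Tibble of impacts with columns `impact_x`, `impact_y`,
#'   `impact_z`, `impact_speed` (as produced by [transport_ensemble()]).
#' @param model A [declustering_model()].
#' @param surface The [collision_surface()] that was struck.
#' @param spec A [secondary_ion_spec()].
#' @param rng_seed Integer seed.
#' @return A particle tibble of emitted ions (possibly zero rows), carrying
#'   a `source_index` column that maps each ion back to its impact row.
#' @export
emit_secondary_ions <- function(impacts, model, surface,
                                spec = secondary_ion_spec(), rng_seed = 1) {
  n <- nrow(impacts)
  if (n == 0) return(ion_particles(spec, numeric(0)))
  set.seed(as.integer(rng_seed %% .Machine$integer.max))
  Y <- declustering_yield(model, surface$temperature, impacts$impact_speed)
  emit <- stats::runif(n) < Y
  idx <- which(emit)
  m <- da_to_kg(spec$mass_da)
  nrm <- surface_normal(impacts$impact_x[idx], impacts$impact_y[idx],
                        impacts$impact_z[idx], surface)
  dirs <- cosine_directions(nrm, stats::runif(length(idx)),
                            stats::runif(length(idx)))
  # Maxwell-Boltzmann speed at the surface temperature
  vth <- sqrt(.kB * surface$temperature / m)
  speed <- vth * sqrt(stats::rnorm(length(idx))^2 +
                        stats::rnorm(length(idx))^2 +
                        stats::rnorm(length(idx))^2)
  out <- ion_particles(spec, seq_along(idx))
  out$x <- impacts$impact_x[idx]; out$y <- impacts$impact_y[idx]
  out$z <- impacts$impact_z[idx]
  out$vx <- dirs[, 1] * speed; out$vy <- dirs[, 2] * speed
  out$vz <- dirs[, 3] * speed
  out$source_index <- idx
  out
}

# Ion particle tibble skeleton with the right mass/diameter/charge.
ion_particles <- function(spec, rows) {
  n <- length(rows)
  out <- particles(diameter = rep(spec$diameter, n),
                   density = rep(da_to_kg(spec$mass_da) /
                                   (pi / 6 * spec$diameter^3), max(n, 0)),
                   mass = rep(da_to_kg(spec$mass_da), n),
                   charge = rep(spec$charge, n))
  out$source_index <- integer(n)
  out
}
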