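#' Nitrogen gas properties
#'
#' Default carrier gas for the atmospheric interface: molar mass,
#' heat-capacity ratio, dynamic viscosity and kinetic molecular diameter.
#'
#' @return A named list with `molar_mass` (kg/mol), `gamma`, `viscosity`
#'   (Pa s) and `molecular_diameter` (m).
#' @export
gas_nitrogen <- function() {
  list(
    molar_mass = 0.028,
    gamma = 1.4,
    viscosity = 1.8e-5,
    molecular_diameter = 3.7e-10
  )
}

#' Stagnation and background conditions of the free-jet expansion
#'
#' Describes the gas expanding from the inlet capillary (stagnation state
#' `P0`, `T0`, bore `d`) into the first vacuum stage at background pressure
#' `P1`. Defaults describe an atmospheric inlet into a rough-vacuum stage and
#' are calibrated defaults of this package, not measured source values.
#'
#' @param P0 Stagnation (upstream) pressure, Pa.
#' @param P1 Background (downstream) pressure, Pa.
#' @param d Capillary bore diameter, m.
#' @param T0 Stagnation temperature, K.
#' @param gas Gas property list, see [gas_nitrogen()].
#' @return An object of class `source_conditions`.
#' @export
source_conditions <- function(P0 = 101325, P1 = 600, d = 0.6e-3, T0 = 300,
                              gas = gas_nitrogen()) {
  abort_if(!(P0 > P1 && P1 > 0), "invalid pressures: need P0 > P1 > 0")
  abort_if(!(d >= 0), "capillary diameter must be non-negative")
  abort_if(!(T0 > 0), "stagnation temperature must be positive")
  abort_if(!(gas$gamma > 1), "heat capacity ratio gamma must exceed 1")
  structure(
    list(P0 = P0, P1 = P1, d = d, T0 = T0, gas = gas),
    class = "source_conditions"
  )
}

critical_pressure_ratio <- function(gamma) {
  ((gamma + 1) / 2)^(gamma / (gamma - 1))
}

#' Mach disk location of an underexpanded free jet
#'
#' Position of the normal shock terminating the supersonic core, measured
#' from the capillary exit along the jet axis, using the standard empirical
#' correlation `x_M = 0.67 d sqrt(P0/P1)`.
#'
#' @param source A [source_conditions()] object.
#' @return Axial Mach-disk position in metres.
#' @export
mach_disk_position <- function(source) {
  stopifnot(inherits(source, "source_conditions"))
  if (source$d == 0) return(0)
  ratio <- source$P0 / source$P1
  abort_if(ratio <= critical_pressure_ratio(source$gas$gamma),
           "no supersonic expansion: pressure ratio is subcritical")
  0.67 * source$d * sqrt(ratio)
}

# Ashkenas-Sherman far-field centerline correlation constants (gamma = 1.4).
.as_A <- 3.65
.as_z0_over_d <- 0.40

# Axial position where the far-field correlation reaches M = 1; below it the
# centerline Mach number is ramped linearly to 0 at the capillary exit so the
# stagnation limit T -> T0 is recovered at z = 0.
sonic_z <- function(source) {
  g <- source$gas$gamma
  source$d * (.as_z0_over_d + (1 / .as_A)^(1 / (g - 1)))
}

# Centerline Mach number upstream of the Mach disk (vectorised in z).
centerline_mach <- function(z, source) {
  g <- source$gas$gamma
  zs <- sonic_z(source)
  ifelse(z <= zs,
         pmax(z, 0) / zs,
         .as_A * (z / source$d - .as_z0_over_d)^(g - 1))
}

# Normal-shock (Rankine-Hugoniot) state downstream of the Mach disk, computed
# from the pre-shock centerline Mach number. Total temperature is conserved.
shock_state <- function(source) {
  g <- source$gas$gamma
  xm <- mach_disk_position(source)
  M1 <- centerline_mach(xm, source)
  M2 <- sqrt(((g - 1) * M1^2 + 2) / (2 * g * M1^2 - (g - 1)))
  T1 <- source$T0 / (1 + (g - 1) / 2 * M1^2)
  p1 <- source$P0 * (T1 / source$T0)^(g / (g - 1))
  p2 <- p1 * (2 * g * M1^2 - (g - 1)) / (g + 1)
  # post-shock stagnation pressure (entropy jump across the shock)
  p0_2 <- p2 * (1 + (g - 1) / 2 * M2^2)^(g / (g - 1))
  list(M1 = M1, M2 = M2, p0 = p0_2)
}

# Mean free path from kinetic theory (hard-sphere).
mean_free_path <- function(pressure, temperature, molecular_diameter) {
  .kB * temperature / (sqrt(2) * pi * molecular_diameter^2 * pressure)
}

# Isentropic state variables at given Mach number and effective stagnation
# pressure. Total temperature is T0 everywhere (conserved across the shock),
# so T (1 + (gamma-1)/2 M^2) = T0 holds at every evaluated point.
# Returns a plain list of vectors (fast path for the transport inner loop).
state_from_mach_list <- function(M, p0_eff, source) {
  g <- source$gas$gamma
  Rs <- .R_gas / source$gas$molar_mass
  Tg <- source$T0 / (1 + (g - 1) / 2 * M^2)
  p <- p0_eff * (Tg / source$T0)^(g / (g - 1))
  a <- sqrt(g * Rs * Tg)
  list(
    mach = M,
    temperature = Tg,
    pressure = p,
    density = p / (Rs * Tg),
    sound_speed = a,
    velocity_z = M * a,
    velocity_r = rep(0, length(M)),
    mean_free_path = mean_free_path(p, Tg, source$gas$molecular_diameter),
    viscosity = rep(source$gas$viscosity, length(M))
  )
}

state_from_mach <- function(M, p0_eff, source) {
  tibble::as_tibble(state_from_mach_list(M, p0_eff, source))
}

# Fast evaluator used inside integration loops: plain list, no tibble.
flow_eval <- function(field, z, r) {
  if (!is.null(field$uniform)) {
    u <- field$uniform
    n <- length(z)
    return(list(velocity_z = rep(u$velocity_z, n),
                temperature = rep(u$temperature, n),
                pressure = rep(u$pressure, n),
                mean_free_path = rep(u$mean_free_path, n),
                viscosity = rep(u$viscosity, n)))
  }
  src <- field$source
  pre <- z < field$mach_disk_z
  Mc <- ifelse(pre, centerline_mach(z, src), field$shock$M2)
  p0 <- ifelse(pre, src$P0, field$shock$p0)
  w <- src$d / 2 + field$spread * z
  st <- state_from_mach_list(Mc * exp(-r^2 / (2 * w^2)), p0, src)
  st[c("velocity_z", "temperature", "pressure", "mean_free_path",
       "viscosity")]
}

#' Centerline gas state of the free jet
#'
#' Gas state on the jet axis: Ashkenas-Sherman Mach number upstream of the
#' Mach disk, uniform subsonic post-normal-shock drift downstream, with
#' temperature, pressure, density and mean free path from the isentropic
#' relations at conserved total temperature.
#'
#' @param z Axial position(s) from the capillary exit, m. Must be >= 0.
#' @param source A [source_conditions()] object.
#' @return A tibble with one row per `z`: `z`, `mach`, `temperature` (K),
#'   `pressure` (Pa), `density` (kg/m^3), `sound_speed`, `velocity_z`,
#'   `velocity_r` (m/s), `mean_free_path` (m) and `viscosity` (Pa s).
#' @export
centerline_state <- function(z, source) {
  abort_if(any(z < 0), "axial position z must be non-negative")
  xm <- mach_disk_position(source)
  sh <- shock_state(source)
  pre <- z < xm
  M <- ifelse(pre, centerline_mach(z, source), sh$M2)
  p0 <- ifelse(pre, source$P0, sh$p0)
  dplyr::bind_cols(tibble::tibble(z = z), state_from_mach(M, p0, source))
}

#' Build an axisymmetric free-jet flow field
#'
#' Assembles the evaluable flow field used as the background gas for particle
#' transport. The centerline follows [centerline_state()]; off axis, the Mach
#' number decays with a Gaussian radial similarity profile whose half-width
#' grows linearly with axial distance (`half_width = d/2 + spread * z`), and
#' all thermodynamic variables follow from the local Mach number, so the
#' field is axially symmetric and satisfies the isentropic total-temperature
#' identity everywhere.
#'
#' @param source A [source_conditions()] object.
#' @param z_max,r_max Domain extent, m.
#' @param spread Radial half-width growth slope (dimensionless), default 0.2.
#' @return An object of class `flow_field` with elements `source`,
#'   `mach_disk_z`, `domain` and the precomputed shock state.
#' @export
build_flow_field <- function(source = source_conditions(),
                             z_max = 0.05, r_max = 0.02, spread = 0.2) {
  abort_if(!(z_max > 0 && r_max > 0), "flow field domain must be positive")
  structure(
    list(
      source = source,
      mach_disk_z = mach_disk_position(source),
      shock = shock_state(source),
      domain = list(z_max = z_max, r_max = r_max),
      spread = spread
    ),
    class = "flow_field"
  )
}

#' Evaluate a flow field at axial/radial coordinates
#'
#' @param field A [build_flow_field()] object.
#' @param z,r Coordinates in metres (vectorised, recycled to common length).
#'   `r` may be negative; the field is symmetric in `r`.
#' @return A tibble of gas states, one row per coordinate pair.
#' @export
flow_state <- function(field, z, r = 0) {
  stopifnot(inherits(field, "flow_field"))
  n <- max(length(z), length(r))
  z <- rep_len(z, n); r <- rep_len(r, n)
  if (!is.null(field$uniform)) {
    return(dplyr::bind_cols(tibble::tibble(z = z, r = r),
                            field$uniform[rep(1, n), ]))
  }
  abort_if(any(z < 0), "axial position z must be non-negative")
  src <- field$source
  pre <- z < field$mach_disk_z
  Mc <- ifelse(pre, centerline_mach(z, src), field$shock$M2)
  p0 <- ifelse(pre, src$P0, field$shock$p0)
  w <- src$d / 2 + field$spread * z
  Mr <- Mc * exp(-r^2 / (2 * w^2))
  dplyr::bind_cols(tibble::tibble(z = z, r = r), state_from_mach(Mr, p0, src))
}

#' Uniform (constant-state) flow field
#'
#' A degenerate flow field with a spatially constant gas state, mainly for
#' validating the transport integrator against closed-form drag solutions.
#'
#' @param velocity_z Axial gas velocity, m/s.
#' @param temperature Gas temperature, K.
#' @param pressure Gas pressure, Pa.
#' @param gas Gas property list.
#' @param z_max,r_max Domain extent, m.
#' @return A `flow_field` object whose state is constant everywhere.
#' @export
uniform_flow_field <- function(velocity_z = 0, temperature = 300,
                               pressure = 101325, gas = gas_nitrogen(),
                               z_max = 1, r_max = 1) {
  Rs <- .R_gas / gas$molar_mass
  st <- tibble::tibble(
    mach = velocity_z / sqrt(gas$gamma * Rs * temperature),
    temperature = temperature,
    pressure = pressure,
    density = pressure / (Rs * temperature),
    sound_speed = sqrt(gas$gamma * Rs * temperature),
    velocity_z = velocity_z,
    velocity_r = 0,
    mean_free_path = mean_free_path(pressure, temperature,
                                    gas$molecular_diameter),
    viscosity = gas$viscosity
  )
  structure(
    list(source = NULL, mach_disk_z = Inf, uniform = st,
         domain = list(z_max = z_max, r_max = r_max)),
    class = "flow_field"
  )
}

#' Centerline summary table of a flow field
#'
#' @param field A [build_flow_field()] object.
#' @param n Number of axial sample points.
#' @return A tibble of centerline states from 0 to the domain end.
#' @export
centerline_table <- function(field, n = 200) {
  stopifnot(inherits(field, "flow_field"))
  centerline_state(seq(0, field$domain$z_max, length.out = n), field$source)
}

#' @export
print.flow_field <- function(x, ...) {
  cat("<flow_field>\n")
  cat(sprintf("  gas: N2-like (gamma = %.2f), P0 = %.0f Pa, P1 = %.0f Pa, d = %.2g m\n",
              x$source$gas$gamma, x$source$P0, x$source$P1, x$source$d))
  cat(sprintf("  Mach disk at z = %.3f mm (pre-shock M = %.2f)\n",
              1e3 * x$mach_disk_z, x$shock$M1))
  cat(sprintf("  domain: z <= %.3g m, r <= %.3g m\n",
              x$domain$z_max, x$domain$r_max))
  invisible(x)
}
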