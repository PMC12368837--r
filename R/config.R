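#' Default interface configuration
#'
#' All tunable constants of the simulator wing in one nested list: source
#' conditions, aerosol population, declustering model, collisional
#' stabilization, per-shape stagnation retention, ion spec and guide. These
#' are the package's declared study conditions; overriding individual
#' entries (or loading a YAML file with [read_config()]) replaces them.
#'
#' @return A nested list of configuration blocks.
#' @export
default_config <- function() {
  list(
    source = list(P0 = 101325, P1 = 600, d = 0.6e-3, T0 = 300),
    aerosol = list(median_diameter = 0.8e-6, gsd = 1.6, density = 1000,
                   z0 = 0, jitter_sd = 2),
    declustering = list(Y_max = 1, T50_ref = 700, dT = 80, alpha = 1e-3,
                        degradation_T = 1600, degradation_power = 4),
    # collisional stabilization of nascent ions: survival = p/(p + p_half)
    # with p the local gas pressure at the emission point
    stabilization = list(p_half = 100),
    # impact-speed retention by shape: bluff (flat-faced) surfaces carry a
    # thicker stagnation cushion that decelerates incoming droplets
    retention = list(sphere = 0.95, cone = 0.85, plane = 0.75),
    ion = list(mass_da = 1000, diameter = 2.2e-9, charge = 1),
    guide = list(entrance_z = 0, exit_z = 0.035, r0 = 2.5e-3, E_z = 3000,
                 U_star = 2, pressure = 100, temperature = 300),
    transport = list(t_max = 3e-4, ion_dt = 2e-7, ion_t_max = 5e-4)
  )
}

#' Read a YAML configuration, merged over the defaults
#'
#' @param path Path to a YAML file whose top-level blocks mirror
#'   [default_config()].
#' @return A configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modify_defaults(default_config(), user)
}

modify_defaults <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_defaults(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

config_source <- function(config) {
  do.call(source_conditions, config$source)
}

config_model <- function(config) {
  do.call(declustering_model, config$declustering)
}

config_guide <- function(config) {
  do.call(ion_guide, config$guide)
}

config_ion_spec <- function(config) {
  secondary_ion_spec(config$ion$mass_da, config$ion$diameter,
                     config$ion$charge)
}
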