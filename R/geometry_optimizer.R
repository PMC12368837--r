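#' Specification of a surface geometry/temperature sweep
#'
#' Grid of interface designs for [run_sweep()]: surface shapes, axial
#' stand-off positions and surface temperatures, with a fixed droplet
#' ensemble per cell. The same droplet population and the same per-droplet
#' random numbers are reused in every cell (common random numbers), so
#' differences between cells reflect the design, not Monte Carlo noise.
#'
#' @param shapes Subset of `c("sphere", "plane", "cone")`.
#' @param z_grid Stand-off positions, m.
#' @param T_grid Surface temperatures, K.
#' @param n_droplets Droplets launched per cell.
#' @param seed Integer seed.
#' @param surface_radius Characteristic radius for sphere/cone, m.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(shapes = c("sphere", "plane"),
                       z_grid = seq(2e-3, 12e-3, by = 1e-3),
                       T_grid = seq(400, 1500, by = 100),
                       n_droplets = 2000, seed = 17,
                       surface_radius = 1.5e-3) {
  abort_if(!length(z_grid) || !length(T_grid) || !length(shapes),
           "sweep grids must be non-empty")
  abort_if(n_droplets < 1, "need at least one droplet per cell")
  shapes <- match.arg(shapes, c("sphere", "plane", "cone"),
                      several.ok = TRUE)
  structure(list(shapes = shapes, z_grid = z_grid, T_grid = T_grid,
                 n_droplets = n_droplets, seed = as.integer(seed),
                 surface_radius = surface_radius),
            class = "sweep_spec")
}

# Collisional stabilization of nascent secondary ions: survival probability
# as a saturating function of the local gas pressure at the emission point.
stabilization_survival <- function(p_local, p_half) {
  p_local / (p_local + p_half)
}

#' Run an end-to-end efficiency sweep of the interface geometry
#'
#' For every cell (shape, stand-off `z_s`, surface temperature `T_s`) the
#' full chain is simulated: droplet generation, transport through the free
#' jet, surface impact, declustering yield at the retained impact speed,
#' collisional stabilization of the nascent ion at the local gas pressure,
#' and ion-guide capture. End-to-end efficiency is captured ions over
#' launched droplets. The droplet population and the per-droplet uniforms
#' for yield and stabilization are shared across all cells (common random
#' numbers), and transport is reused across the temperature grid (the
#' frozen flow field does not feel the surface temperature).
#'
#' @param spec A [sweep_spec()].
#' @param config Configuration list, see [default_config()]. The optional
#'   `config$overrides` list may carry `yield_fun(T_s, speed)`,
#'   `survival_fun(p_local)` or `capture_fun(shape, z_s, T_s, n_ions)`
#'   replacements, used for validating the sweep bookkeeping against stub
#'   physics.
#' @return An `efficiency_map`: a tibble with one row per cell (`shape`,
#'   `z_s`, `T_s`, `n_droplets`, `impact_fraction`, `mean_impact_speed`,
#'   `yield_fraction`, `survival_fraction`, `capture_fraction`,
#'   `end_to_end`, Wilson `ci_lower`/`ci_upper`), with the Mach-disk
#'   position and the spec attached as attributes.
#' @export
run_sweep <- function(spec = sweep_spec(), config = default_config()) {
  stopifnot(inherits(spec, "sweep_spec"))
  source <- config_source(config)
  field <- build_flow_field(source)
  model <- config_model(config)
  guide <- config_guide(config)
  ion_spec <- config_ion_spec(config)
  ov <- config$overrides %||% list()

  n <- spec$n_droplets
  aer <- do.call(aerosol_spec, c(list(n = n, seed = spec$seed),
                                 config$aerosol))
  droplets <- gen_aerosol(aer, field)

  # common random numbers shared by every cell
  set.seed(spec$seed)
  u_yield <- stats::runif(n)
  u_surv <- stats::runif(n)
  u_dir1 <- stats::runif(n)
  u_dir2 <- stats::runif(n)
  z_speed <- matrix(stats::rnorm(3 * n), ncol = 3)

  m_ion <- da_to_kg(ion_spec$mass_da)
  cells <- tidyr::expand_grid(shape = spec$shapes, z_s = spec$z_grid,
                              T_s = spec$T_grid)

  transported <- list()
  for (shape in spec$shapes) {
    for (z_s in spec$z_grid) {
      surf <- collision_surface(shape, z_s = z_s, temperature = 1000,
                                radius = spec$surface_radius)
      tr <- transport_ensemble(droplets, field, surf, seed = spec$seed,
                               t_max = config$transport$t_max)
      transported[[paste(shape, signif(z_s, 10))]] <- tr$fates
    }
  }

  one_cell <- function(shape, z_s, T_s) {
    fates <- transported[[paste(shape, signif(z_s, 10))]]
    hit <- fates$fate == "impacted_surface"
    n_hit <- sum(hit)
    if (n_hit == 0) {
      return(tibble::tibble(impact_fraction = 0, mean_impact_speed = NA_real_,
                            yield_fraction = 0, survival_fraction = 0,
                            capture_fraction = 0, end_to_end = 0,
                            ci_lower = 0,
                            ci_upper = wilson_ci(0, n)[["upper"]]))
    }
    v_eff <- fates$impact_speed[hit] * config$retention[[shape]]
    Y <- if (is.null(ov$yield_fun)) declustering_yield(model, T_s, v_eff)
         else ov$yield_fun(T_s, v_eff)
    emitted <- u_yield[hit] < Y
    # collisional stabilization at the local gas pressure
    p_loc <- flow_state(field, fates$impact_z[hit],
                        fates$impact_r[hit])$pressure
    p_surv <- if (is.null(ov$survival_fun))
      stabilization_survival(p_loc, config$stabilization$p_half)
    else ov$survival_fun(p_loc)
    surviving <- emitted & (u_surv[hit] < p_surv)
    n_sur <- sum(surviving)
    if (n_sur == 0) {
      return(tibble::tibble(impact_fraction = n_hit / n,
                            mean_impact_speed = mean(fates$impact_speed[hit]),
                            yield_fraction = mean(Y),
                            survival_fraction = 0, capture_fraction = 0,
                            end_to_end = 0, ci_lower = 0,
                            ci_upper = wilson_ci(0, n)[["upper"]]))
    }
    if (!is.null(ov$capture_fun)) {
      captured <- sum(ov$capture_fun(shape, z_s, T_s, n_sur))
    } else {
      surf <- collision_surface(shape, z_s = z_s, temperature = T_s,
                                radius = spec$surface_radius)
      sel <- which(hit)[surviving]
      nrm <- surface_normal(fates$impact_x[sel], fates$impact_y[sel],
                            fates$impact_z[sel], surf)
      dirs <- cosine_directions(nrm, u_dir1[sel], u_dir2[sel])
      vth <- sqrt(.kB * T_s / m_ion)
      speed <- vth * sqrt(rowSums(z_speed[sel, , drop = FALSE]^2))
      ions <- ion_particles(ion_spec, seq_len(n_sur))
      ions$x <- fates$impact_x[sel]; ions$y <- fates$impact_y[sel]
      ions$z <- fates$impact_z[sel]
      ions$vx <- dirs[, 1] * speed; ions$vy <- dirs[, 2] * speed
      ions$vz <- dirs[, 3] * speed
      tr <- trace_ions(ions, guide, rng_seed = spec$seed,
                       dt = config$transport$ion_dt,
                       t_max = config$transport$ion_t_max)
      captured <- sum(tr$fate == "captured")
    }
    ci <- wilson_ci(captured, n)
    tibble::tibble(impact_fraction = n_hit / n,
                   mean_impact_speed = mean(fates$impact_speed[hit]),
                   yield_fraction = mean(Y),
                   survival_fraction = n_sur / max(sum(emitted), 1),
                   capture_fraction = captured / n_sur,
                   end_to_end = captured / n,
                   ci_lower = ci[["lower"]], ci_upper = ci[["upper"]])
  }

  res <- purrr::pmap(cells, one_cell)
  map <- dplyr::bind_cols(cells, dplyr::bind_rows(res))
  map$n_droplets <- n
  attr(map, "mach_disk_z") <- field$mach_disk_z
  attr(map, "sweep_spec") <- spec
  class(map) <- c("efficiency_map", class(map))
  map
}

#' Locate the optimal cell of an efficiency map
#'
#' Argmax of end-to-end efficiency; ties are broken toward smaller
#' stand-off, then lower surface temperature, then shape order
#' sphere < plane < cone.
#'
#' @param map An `efficiency_map` from [run_sweep()].
#' @return The optimal one-row cell.
#' @export
find_optimum <- function(map) {
  abort_if(nrow(map) == 0, "empty efficiency map")
  shape_rank <- match(map$shape, c("sphere", "plane", "cone"))
  ord <- order(-map$end_to_end, map$z_s, map$T_s, shape_rank)
  map[ord[1], ]
}

#' Heat-map of sweep efficiency over position and temperature
#'
#' @param object An `efficiency_map`.
#' @param ... Unused.
#' @return A ggplot: `z_s` vs `T_s` tiles filled by end-to-end efficiency,
#'   faceted by shape, with the Mach-disk position marked.
#' @export
autoplot.efficiency_map <- function(object, ...) {
  xm <- attr(object, "mach_disk_z")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z_s * 1e3, y = .data$T_s,
                                       fill = .data$end_to_end)) +
    ggplot2::geom_tile() +
    ggplot2::geom_vline(xintercept = xm * 1e3, linetype = 2,
                        colour = "white") +
    ggplot2::facet_wrap(~shape) +
    ggplot2::scale_fill_viridis_c(name = "end-to-end\nefficiency") +
    ggplot2::labs(x = "surface stand-off z_s (mm)",
                  y = "surface temperature T_s (K)")
}
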