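#' Aerosol population specification
#'
#' Lognormal droplet size distribution launched at the capillary exit
#' plane. Defaults describe the micron-scale droplet population produced by
#' infrared laser ablation of wet tissue: median diameter 0.8 um, geometric
#' SD 1.6, unit density. Initial axial speed is sampled from the local gas
#' speed at the launch plane, plus isotropic velocity jitter.
#'
#' @param n Number of droplets.
#' @param median_diameter Median diameter, m.
#' @param gsd Geometric standard deviation (>= 1).
#' @param density Droplet material density, kg/m^3.
#' @param z0 Launch plane, m from the capillary exit.
#' @param jitter_sd Isotropic velocity jitter SD, m/s.
#' @param seed Integer seed.
#' @return An object of class `aerosol_spec`.
#' @export
aerosol_spec <- function(n, median_diameter = 0.8e-6, gsd = 1.6,
                         density = 1000, z0 = 0, jitter_sd = 2, seed = 1) {
  abort_if(median_diameter <= 0, "median diameter must be positive")
  abort_if(gsd < 1, "geometric SD must be >= 1")
  structure(list(n = n, median_diameter = median_diameter, gsd = gsd,
                 density = density, z0 = z0, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "aerosol_spec")
}

#' Generate an aerosol droplet population
#'
#' Droplets with lognormal diameters, launched across the capillary bore at
#' the launch plane with the local gas velocity plus isotropic thermal
#' jitter. Pure function of (spec, seed): identical output for identical
#' inputs.
#'
#' @param spec An [aerosol_spec()].
#' @param field A [build_flow_field()] object (supplies launch-plane gas
#'   speed and the capillary bore).
#' @return A particle tibble, one row per droplet.
#' @export
gen_aerosol <- function(spec, field) {
  stopifnot(inherits(spec, "aerosol_spec"))
  n <- spec$n
  if (n == 0) return(particles(numeric(0)))
  set.seed(spec$seed)
  d <- stats::rlnorm(n, log(spec$median_diameter), log(spec$gsd))
  bore <- (field$source$d %||% 2e-4) / 2
  rr <- bore * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  x <- rr * cos(th); y <- rr * sin(th)
  gas <- flow_state(field, rep(spec$z0, n), rr)
  # axial jitter is half-normal (forward): the aerosol emerges from the
  # capillary moving into the expansion, never back into the bore
  particles(diameter = d, density = spec$density,
            charge = 0, x = x, y = y, z = spec$z0,
            vx = stats::rnorm(n, 0, spec$jitter_sd),
            vy = stats::rnorm(n, 0, spec$jitter_sd),
            vz = gas$velocity_z + abs(stats::rnorm(n, 0, spec$jitter_sd)))
}

#' Laser dose arithmetic
#'
#' Average power from pulse energy and repetition rate, and fluence from
#' pulse energy and focal spot diameter.
#'
#' @param pulse_energy Pulse energy, J.
#' @param rep_rate Repetition rate, Hz.
#' @param spot_diameter Focal spot diameter, m (`NA` skips the fluence).
#' @return A one-row tibble: `average_power` (W) and `fluence` (J/cm^2).
#' @examples
#' laser_dose(12e-9, 8.3e6, 10e-6)
#' @export
laser_dose <- function(pulse_energy, rep_rate, spot_diameter = NA) {
  abort_if(pulse_energy < 0 || rep_rate < 0, "dose inputs must be non-negative")
  power <- pulse_energy * rep_rate
  fluence <- if (is.na(spot_diameter)) {
    NA_real_
  } else if (pulse_energy == 0) {
    abort_if(spot_diameter < 0, "spot diameter must be positive for fluence")
    0
  } else {
    abort_if(spot_diameter <= 0, "spot diameter must be positive for fluence")
    pulse_energy / (pi * (spot_diameter / 2 * 100)^2)  # per cm^2
  }
  tibble::tibble(average_power = power, fluence = fluence)
}

#' Generate a labeled tissue phantom
#'
#' Deterministic 2-D label image standing in for an annotated tissue
#' section, with tumor / normal / fibrous regions (and `"background"` for
#' the nested layout's border).
#'
#' @param rows,cols Grid size (pixels).
#' @param layout `"stripes"` (equal vertical bands), `"nested"` (concentric
#'   rectangles on background), or `"blobs"` (seeded Voronoi patches).
#' @param classes Class names.
#' @param seed Integer seed (used by the blob layout).
#' @return An object of class `phantom_truth`: `labels` (rows x cols
#'   character matrix), `classes`, `layout`, `seed`.
#' @export
gen_phantom <- function(rows, cols, layout = c("stripes", "nested", "blobs"),
                        classes = c("tumor", "normal", "fibrous"),
                        seed = 17) {
  layout <- match.arg(layout)
  nc <- length(classes)
  abort_if(rows < nc || cols < nc,
           "grid too small for the requested layout")
  lab <- matrix(NA_character_, rows, cols)
  if (layout == "stripes") {
    band <- ceiling(seq_len(cols) / cols * nc)
    for (j in seq_len(cols)) lab[, j] <- classes[band[j]]
  } else if (layout == "nested") {
    abort_if(min(rows, cols) < 2 * nc + 2,
             "grid too small for the nested layout")
    lab[] <- "background"
    ci <- (rows + 1) / 2; cj <- (cols + 1) / 2
    for (k in seq_len(nc)) {
      h <- floor(rows / 2 * (nc - k + 1) / (nc + 1))
      w <- floor(cols / 2 * (nc - k + 1) / (nc + 1))
      lab[round(ci - h):round(ci + h), round(cj - w):round(cj + w)] <-
        classes[k]
    }
  } else {
    set.seed(seed)
    n_seeds <- 3 * nc
    si <- stats::runif(n_seeds, 1, rows)
    sj <- stats::runif(n_seeds, 1, cols)
    sc <- rep(classes, length.out = n_seeds)
    for (i in seq_len(rows)) {
      d2 <- outer(rep(i, cols), si, function(a, b) (a - b)^2) +
        outer(seq_len(cols), sj, function(a, b) (a - b)^2)
      lab[i, ] <- sc[max.col(-d2, ties.method = "first")]
    }
  }
  structure(list(labels = lab, classes = classes, layout = layout,
                 seed = as.integer(seed)),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d x %d pixels, layout %s\n",
              nrow(x$labels), ncol(x$labels), x$layout))
  print(table(x$labels))
  invisible(x)
}

# Species panel and class multipliers of the synthetic tissue model. The
# fibrous class is triglyceride-rich and phospholipid-poor; the tumor class
# is mildly nucleobase-enriched (below the volcano fold threshold) and
# carries the planted differential bins at the configured fold change.
phantom_profiles <- function(planted_fold = 4) {
  ann <- annotation_table()
  sp <- tibble::tibble(
    name = c(ann$name, "planted_1", "planted_2", "planted_3", "planted_4"),
    mz = c(ann$mz, 310.25, 455.35, 610.45, 820.55),
    base = c(60, 55, 40, 45, 80, 70, 90, 25, 100, 30, 30, 30, 30),
    planted = c(rep(FALSE, nrow(ann)), rep(TRUE, 4))
  )
  mult <- list(
    tumor = stats::setNames(rep(1, nrow(sp)), sp$name),
    normal = stats::setNames(rep(1, nrow(sp)), sp$name),
    fibrous = stats::setNames(rep(1, nrow(sp)), sp$name)
  )
  mult$tumor[c("adenine", "guanine")] <- 1.5
  mult$tumor[sp$name[sp$planted]] <- planted_fold
  mult$fibrous[c("PE(36:1)", "PE(36:2)", "PE(38:4)")] <- 0.4
  mult$fibrous["TG(52:2)"] <- 6
  list(species = sp, multipliers = mult,
       lockmass = ann$mz[ann$name == "leucine enkephalin"])
}

# Per-species multiplicative gain of a modality (reference modality: gain 1).
modality_gains <- function(species, modality, modality_sigma, seed) {
  if (modality == "laser" || modality_sigma == 0) {
    return(stats::setNames(rep(1, nrow(species)), species$name))
  }
  set.seed(as.integer((seed + sum(utf8ToInt(modality))) %% .Machine$integer.max))
  stats::setNames(stats::rlnorm(nrow(species), 0, modality_sigma),
                  species$name)
}

# One synthetic scan: class profile peaks (multiplicative lognormal noise),
# additive low-level noise peaks, ppm drift, lock-mass peak included.
gen_scan <- function(class, scan_idx, drift_ppm_now, prof, gains,
                     noise_sigma, n_noise, mz_range) {
  sp <- prof$species
  mult <- prof$multipliers[[class]]
  inten <- sp$base * mult[sp$name] * gains[sp$name] *
    stats::rlnorm(nrow(sp), 0, noise_sigma)
  mz <- sp$mz
  if (n_noise > 0) {
    mz <- c(mz, stats::runif(n_noise, mz_range[1], mz_range[2]))
    inten <- c(inten, stats::rexp(n_noise, rate = 1 / 1.5))
  }
  mz <- mz * (1 + drift_ppm_now * 1e-6)
  ord <- order(mz)
  spectrum(mz[ord], inten[ord], scan_index = scan_idx)
}

#' Generate a synthetic MSI dataset from a phantom
#'
#' Emulates a raster acquisition over the phantom: each pixel receives its
#' class's spectral profile (marker species plus planted differential
#' bins), multiplicative lognormal peak noise, additive low-level noise
#' peaks, a slow sinusoidal ppm mass drift across the scan index, a
#' lock-mass peak, and optionally a modality-specific per-species gain.
#' Ground truth (labels, planted bins, drift profile) is returned
#' alongside.
#'
#' @param truth A [gen_phantom()] object.
#' @param noise_sigma Multiplicative lognormal sigma (default 0.3 for the
#'   laser modality, 0.4 for diathermy).
#' @param drift_ppm Drift amplitude, ppm (sinusoidal over the acquisition).
#' @param modality `"laser"` or `"diathermy"`.
#' @param modality_sigma Lognormal sigma of the per-species modality gain.
#' @param planted_fold Fold change of the planted tumor bins.
#' @param n_noise Additive noise peaks per scan.
#' @param pixel_size Pixel pitch, um.
#' @param seed Integer seed (defaults to the phantom's).
#' @return A list: `stream` (a [scan_stream()]) and `truth` (the phantom
#'   augmented with `species`, `planted_mz`, `drift_ppm` per scan,
#'   `modality`).
#' @export
gen_msi_dataset <- function(truth, noise_sigma = NULL, drift_ppm = 30,
                            modality = "laser", modality_sigma = 0.1,
                            planted_fold = 4, n_noise = 25,
                            pixel_size = 5, seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  seed <- seed %||% truth$seed
  noise_sigma <- noise_sigma %||% (if (modality == "diathermy") 0.4 else 0.3)
  prof <- phantom_profiles(planted_fold)
  gains <- modality_gains(prof$species, modality, modality_sigma, seed)
  lab <- as.vector(t(truth$labels))
  n_scan <- length(lab)
  drift <- drift_ppm * sin(2 * pi * seq_len(n_scan) / n_scan)
  set.seed(as.integer(seed))
  spectra <- vector("list", n_scan)
  for (i in seq_len(n_scan)) {
    cls <- if (lab[i] %in% names(prof$multipliers)) lab[i] else "normal"
    spectra[[i]] <- gen_scan(cls, i, drift[i], prof, gains,
                             noise_sigma, n_noise, c(50, 1199))
  }
  truth$species <- prof$species
  truth$planted_mz <- prof$species$mz[prof$species$planted]
  truth$drift_ppm <- drift
  truth$modality <- modality
  list(stream = scan_stream(spectra, nrow(truth$labels), ncol(truth$labels),
                            pixel_size, modality),
       truth = truth)
}

#' Generate bulk (non-imaging) class spectra as a feature matrix
#'
#' Same generative model as [gen_msi_dataset()] without the spatial layout:
#' `n_per_class` spectra per class, preprocessed through the standard
#' pipeline (lock-mass correction, 0.1 Da binning, TIC normalization).
#'
#' @param classes Class names (must be among tumor/normal/fibrous).
#' @param n_per_class Spectra per class.
#' @param modality,modality_sigma,noise_sigma,drift_ppm,planted_fold,n_noise
#'   As in [gen_msi_dataset()].
#' @param seed Integer seed.
#' @param width,range Binning parameters.
#' @return A [feature_matrix()] with labels and modality tags.
#' @export
gen_bulk_spectra <- function(classes = c("tumor", "normal"), n_per_class = 40,
                             modality = "laser", modality_sigma = 0.1,
                             noise_sigma = NULL, drift_ppm = 30,
                             planted_fold = 4, n_noise = 25, seed = 17,
                             width = 0.1, range = c(50, 1200)) {
  abort_if(n_per_class < 1, "need at least one spectrum per class")
  noise_sigma <- noise_sigma %||% (if (modality == "diathermy") 0.4 else 0.3)
  prof <- phantom_profiles(planted_fold)
  gains <- modality_gains(prof$species, modality, modality_sigma, seed)
  lab <- rep(classes, each = n_per_class)
  n_scan <- length(lab)
  drift <- drift_ppm * sin(2 * pi * seq_len(n_scan) / n_scan)
  set.seed(as.integer(seed))
  axis <- bin_axis(width, range)
  values <- matrix(0, n_scan, length(axis))
  factor <- NULL
  for (i in seq_len(n_scan)) {
    s <- gen_scan(lab[i], i, drift[i], prof, gains, noise_sigma, n_noise,
                  c(range[1], range[2] - 1))
    s <- lockmass_correct(s, prior_factor = factor)
    factor <- attr(s, "lock_factor")
    values[i, ] <- tic_normalize(bin_vector(s$mz, s$intensity, width, range))
  }
  feature_matrix(values, axis, lab, modality = modality)
}
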