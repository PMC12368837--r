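#' Construct a single mass spectrum
#'
#' Centroided stick spectrum: strictly increasing m/z with non-negative
#' intensities.
#'
#' @param mz Numeric vector of m/z values, strictly increasing.
#' @param intensity Non-negative intensities, same length.
#' @param scan_index,modality Optional metadata carried as attributes.
#' @return A tibble of class `mass_spectrum` with columns `mz`, `intensity`.
#' @export
spectrum <- function(mz, intensity, scan_index = NA_integer_,
                     modality = NA_character_) {
  abort_if(length(mz) != length(intensity),
           "mz and intensity must have the same length")
  abort_if(any(diff(mz) <= 0), "mz axis must be strictly increasing")
  abort_if(any(intensity < 0), "intensities must be non-negative")
  out <- tibble::tibble(mz = as.numeric(mz), intensity = as.numeric(intensity))
  attr(out, "scan_index") <- scan_index
  attr(out, "modality") <- modality
  class(out) <- c("mass_spectrum", class(out))
  out
}

#' Lock-mass recalibration of a spectrum
#'
#' Single-point multiplicative recalibration against a reference compound
#' (by default the leucine enkephalin negative-mode lock mass at m/z
#' 554.2615): the most intense peak within the search window is taken as
#' the observed lock, and the whole m/z axis is multiplied by
#' `reference/observed`. If no peak lies in the window, the supplied
#' carry-forward factor (identity if none) is reused and a warning is
#' raised.
#'
#' @param s A [spectrum()].
#' @param reference Reference lock m/z. The conventional literature value
#'   554.2615 is used verbatim as the calibration constant (the isotope-mass
#'   sum for the lock compound gives 554.2620; the package does not derive
#'   the constant from [compute_mz()]).
#' @param window Half-width of the search window, Da.
#' @param prior_factor Carry-forward factor from the previous scan, or
#'   `NULL`.
#' @return The corrected spectrum, with the applied factor in attribute
#'   `"lock_factor"` and a logical attribute `"lock_found"`.
#' @export
lockmass_correct <- function(s, reference = 554.2615, window = 0.5,
                             prior_factor = NULL) {
  in_win <- which(s$mz >= reference - window & s$mz <= reference + window)
  if (length(in_win)) {
    observed <- s$mz[in_win[which.max(s$intensity[in_win])]]
    factor <- reference / observed
    found <- TRUE
  } else {
    factor <- prior_factor %||% 1
    found <- FALSE
    rlang::warn("no lock-mass peak in window; reusing last valid factor")
  }
  out <- s
  out$mz <- s$mz * factor
  attr(out, "lock_factor") <- factor
  attr(out, "lock_found") <- found
  out
}

#' Bin axis lower edges
#'
#' @param width Bin width, Da.
#' @param range Half-open m/z range `[lo, hi)`.
#' @return Numeric vector of bin lower edges.
#' @export
bin_axis <- function(width = 0.1, range = c(50, 1200)) {
  abort_if(width <= 0, "bin width must be positive")
  seq(range[1], range[2] - width / 2, by = width)
}

# Fast path: numeric intensity vector over the bin axis.
bin_vector <- function(mz, intensity, width = 0.1, range = c(50, 1200)) {
  abort_if(width <= 0, "bin width must be positive")
  nb <- length(bin_axis(width, range))
  keep <- mz >= range[1] & mz < range[2]
  # the small offset keeps values that sit exactly on a bin edge (up to
  # floating-point representation) in the upper, half-open bin
  idx <- floor((mz[keep] - range[1]) / width + 1e-9) + 1L
  idx <- pmin(idx, nb)
  out <- numeric(nb)
  if (any(keep)) {
    agg <- tapply(intensity[keep], idx, sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' Bin a spectrum to a fixed-width axis
#'
#' Half-open bins `[lo, lo + width)` identified by their lower edge;
#' intensities are summed within bins, conserving total in-range intensity
#' exactly.
#'
#' @param s A [spectrum()].
#' @param width Bin width, Da (0.1 Da default).
#' @param range Half-open m/z range.
#' @return A tibble with `bin_lo` and `intensity`, one row per bin.
#' @export
bin_spectrum <- function(s, width = 0.1, range = c(50, 1200)) {
  tibble::tibble(bin_lo = bin_axis(width, range),
                 intensity = bin_vector(s$mz, s$intensity, width, range))
}

#' Total-ion-current normalization
#'
#' @param v Non-negative intensity vector.
#' @return `v / sum(v)`, summing to 1.
#' @export
tic_normalize <- function(v) {
  tot <- sum(v)
  abort_if(!(tot > 0), "empty spectrum: total ion current is zero")
  v / tot
}

#' Assemble a raster scan stream
#'
#' @param spectra A list of [spectrum()] objects in acquisition order.
#' @param rows,cols Raster dimensions.
#' @param pixel_size Pixel pitch, micrometres.
#' @param modality Modality tag (e.g. `"laser"` or `"diathermy"`).
#' @return An object of class `scan_stream`.
#' @export
scan_stream <- function(spectra, rows, cols, pixel_size = 5,
                        modality = "laser") {
  structure(list(spectra = spectra, rows = rows, cols = cols,
                 pixel_size = pixel_size, modality = modality),
            class = "scan_stream")
}

#' @export
print.scan_stream <- function(x, ...) {
  cat(sprintf("<scan_stream> %d spectra, %d x %d raster at %g um (%s)\n",
              length(x$spectra), x$rows, x$cols, x$pixel_size, x$modality))
  invisible(x)
}

#' Reconstruct an image grid from a raster scan stream
#'
#' Spectra are assigned to pixels in unidirectional row-major raster order
#' (row flyback; serpentine available behind a flag). Each pixel holds the
#' lock-mass-corrected, binned, TIC-normalized intensity vector; the
#' lock-mass factor carries forward across scans when a lock peak is
#' missing.
#'
#' @param stream A [scan_stream()]; its spectrum count must equal
#'   `rows * cols`.
#' @param lockmass Reference lock m/z (`NULL` disables correction).
#' @param width,range Binning parameters, see [bin_spectrum()].
#' @param normalize TIC-normalize each pixel (default `TRUE`).
#' @param serpentine If `TRUE`, every other row is reversed.
#' @return An object of class `image_grid`: `values` (pixels x bins matrix
#'   in row-major pixel order), `bin_lo`, `rows`, `cols`, `pixel_size`.
#' @export
reconstruct_image <- function(stream, lockmass = 554.2615, width = 0.1,
                              range = c(50, 1200), normalize = TRUE,
                              serpentine = FALSE) {
  n_expected <- stream$rows * stream$cols
  n_got <- length(stream$spectra)
  abort_if(n_expected != n_got,
           sprintf("incomplete stream: expected %d spectra (%d x %d), got %d",
                   n_expected, stream$rows, stream$cols, n_got))
  axis <- bin_axis(width, range)
  values <- matrix(0, nrow = n_got, ncol = length(axis))
  factor <- NULL
  for (i in seq_len(n_got)) {
    s <- stream$spectra[[i]]
    if (!is.null(lockmass)) {
      s <- lockmass_correct(s, reference = lockmass, prior_factor = factor)
      factor <- attr(s, "lock_factor")
    }
    v <- bin_vector(s$mz, s$intensity, width, range)
    if (normalize) v <- tic_normalize(v)
    values[i, ] <- v
  }
  if (serpentine) {
    for (r in seq_len(stream$rows)) {
      if (r %% 2 == 0) {
        idx <- ((r - 1) * stream$cols + 1):(r * stream$cols)
        values[idx, ] <- values[rev(idx), ]
      }
    }
  }
  structure(list(values = values, bin_lo = axis, bin_width = width,
                 rows = stream$rows, cols = stream$cols,
                 pixel_size = stream$pixel_size,
                 modality = stream$modality),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d pixels at %g um, %d bins [%g, %g)\n",
              x$rows, x$cols, x$pixel_size, length(x$bin_lo),
              min(x$bin_lo), max(x$bin_lo) + x$bin_width))
  invisible(x)
}

#' Extract a single-ion image
#'
#' Per-pixel sum of the bins overlapping the half-open m/z window.
#'
#' @param grid An [reconstruct_image()] grid.
#' @param mz_window Numeric `c(lo, hi)`.
#' @return A `rows x cols` intensity matrix.
#' @export
extract_ion_image <- function(grid, mz_window) {
  sel <- grid$bin_lo < mz_window[2] &
    (grid$bin_lo + grid$bin_width) > mz_window[1]
  v <- if (any(sel)) rowSums(grid$values[, sel, drop = FALSE])
       else numeric(nrow(grid$values))
  matrix(v, nrow = grid$rows, ncol = grid$cols, byrow = TRUE)
}

#' Compose an RGB image from three ion images
#'
#' Each channel is scaled to `[0, 1]` by its own 99th percentile (values
#' above it are clipped), then stacked.
#'
#' @param r,g,b Intensity matrices of identical dimensions.
#' @return A `rows x cols x 3` array in `[0, 1]`.
#' @export
composite_rgb <- function(r, g, b) {
  abort_if(!all(dim(r) == dim(g)) || !all(dim(r) == dim(b)),
           "channel dimensions differ")
  scale1 <- function(m) {
    q <- stats::quantile(m, 0.99, names = FALSE)
    if (q <= 0) return(m * 0)
    pmin(m / q, 1)
  }
  out <- array(0, dim = c(dim(r), 3))
  out[, , 1] <- scale1(r); out[, , 2] <- scale1(g); out[, , 3] <- scale1(b)
  out
}

#' Hyperspectral correlation map against a reference region
#'
#' Pearson correlation between every pixel's binned spectrum and the mean
#' spectrum of the reference region.
#'
#' @param grid An [reconstruct_image()] grid.
#' @param mask Logical `rows x cols` matrix marking the reference region.
#' @return A `rows x cols` matrix of correlations in `[-1, 1]` (`NA` for
#'   constant pixels).
#' @export
region_correlation_map <- function(grid, mask) {
  abort_if(!any(mask), "reference mask is empty")
  # grid$values rows are row-major: pixel (i, j) -> (i-1)*cols + j
  sel <- as.vector(t(mask))
  ref <- colMeans(grid$values[sel, , drop = FALSE])
  cors <- suppressWarnings(
    as.vector(stats::cor(t(grid$values), ref))
  )
  matrix(cors, nrow = grid$rows, ncol = grid$cols, byrow = TRUE)
}

#' Plot an ion image
#'
#' @param img Intensity matrix from [extract_ion_image()].
#' @param title Optional plot title.
#' @return A ggplot heat map.
#' @export
plot_ion_image <- function(img, title = NULL) {
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$intensity <- img[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL)
}
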