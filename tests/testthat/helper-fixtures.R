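# Shared fixtures, all built in code at test time.

default_source <- function() source_conditions()

# Independent isotope-mass table for cross-checking compute_mz, transcribed
# separately (5-6 decimal precision) from standard monoisotopic mass tables.
oracle_masses <- c(
  H = 1.007825, C = 12.0, N = 14.003074, O = 15.994915, P = 30.973762,
  S = 31.972071, Cl = 34.968853, Na = 22.98977, K = 38.963707
)

oracle_neutral_mass <- function(formula) {
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  el <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                           sub("^[A-Za-z]+", "", tokens), "1"))
  sum(oracle_masses[el] * cnt)
}

oracle_mz_mh <- function(formula) {
  # [M-H]-: remove a hydrogen atom, keep its electron
  oracle_neutral_mass(formula) - 1.007825 + 0.000549
}

# A tiny deterministic image grid built from two synthetic spectrum types.
toy_grid <- function(rows = 2, cols = 3) {
  sA <- spectrum(c(100.05, 200.05), c(10, 5))
  sB <- spectrum(c(150.05, 300.05), c(8, 2))
  spectra <- lapply(seq_len(rows * cols), function(i) {
    if (i %% 2 == 1) sA else sB
  })
  reconstruct_image(scan_stream(spectra, rows, cols), lockmass = NULL,
                    range = c(50, 400))
}

# Gaussian class data for classifier tests.
gaussian_classes <- function(n_per_class = 20, p = 12, sep = 10, seed = 3,
                             classes = c("a", "b")) {
  set.seed(seed)
  mus <- seq(0, sep * (length(classes) - 1), by = sep)
  X <- do.call(rbind, lapply(seq_along(classes), function(i) {
    matrix(stats::rnorm(n_per_class * p, mean = mus[i]), n_per_class, p)
  }))
  # constant shift keeps the geometry and makes intensities non-negative
  list(X = X - min(X), labels = rep(classes, each = n_per_class))
}
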