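test_that("lock-mass correction rescales the whole axis multiplicatively", {
  s <- spectrum(c(300.1, 554.3000, 766.5930), c(5, 100, 20))
  out <- lockmass_correct(s)
  expect_equal(out$mz[2], 554.2615, tolerance = 1e-9)
  expect_equal(out$mz[3], 766.5930 * 554.2615 / 554.3000, tolerance = 1e-9)
  expect_equal(round(out$mz[3], 4), 766.5398)

  exact <- spectrum(c(300.1, 554.2615), c(5, 100))
  expect_equal(lockmass_correct(exact)$mz, exact$mz)

  # the most intense peak in the window is the lock, not the nearest
  two <- spectrum(c(554.20, 554.30), c(10, 90))
  expect_equal(attr(lockmass_correct(two), "lock_factor"),
               554.2615 / 554.30)
})

test_that("a missing lock peak reuses the carried factor with a warning", {
  s <- spectrum(c(100.0, 200.0), c(1, 1))
  expect_warning(out <- lockmass_correct(s), "no lock-mass peak")
  expect_equal(out$mz, s$mz)  # identity when no prior factor
  expect_warning(out2 <- lockmass_correct(s, prior_factor = 1.001))
  expect_equal(out2$mz, s$mz * 1.001)
})

test_that("binning is half-open, lower-edge labelled, and conservative", {
  s <- spectrum(c(100.04, 100.06), c(5, 7))
  b <- bin_spectrum(s, range = c(50, 1200))
  expect_equal(b$intensity[b$bin_lo == 100.0], 12)

  edge <- spectrum(100.1, 3)
  be <- bin_spectrum(edge, range = c(50, 1200))
  expect_equal(be$intensity[abs(be$bin_lo - 100.1) < 1e-9], 3)
  expect_equal(be$intensity[abs(be$bin_lo - 100.0) < 1e-9], 0)

  set.seed(4)
  rnd <- spectrum(sort(runif(500, 60, 1100)), rexp(500))
  br <- bin_spectrum(rnd)
  expect_lt(abs(sum(br$intensity) - sum(rnd$intensity)) /
              sum(rnd$intensity), 1e-9)
  expect_error(bin_spectrum(rnd, width = 0), "positive")
})

test_that("TIC normalization is idempotent and rejects empty spectra", {
  expect_equal(tic_normalize(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  v <- runif(10)
  expect_equal(tic_normalize(tic_normalize(v)), tic_normalize(v))
  expect_error(tic_normalize(c(0, 0, 0)), "empty spectrum")
})

test_that("raster reconstruction is row-major with exact count checking", {
  spectra <- lapply(1:6, function(i) spectrum(100.05 * i, 1))
  g <- reconstruct_image(scan_stream(spectra, 2, 3), lockmass = NULL,
                         range = c(50, 700), normalize = FALSE)
  # 6th spectrum lands in pixel (2, 3): row-major order
  img6 <- extract_ion_image(g, c(600.0, 600.4))
  expect_equal(which(img6 > 0, arr.ind = TRUE),
               cbind(row = 2L, col = 3L), ignore_attr = TRUE)

  expect_error(reconstruct_image(scan_stream(spectra[1:5], 2, 3),
                                 lockmass = NULL),
               "expected 6 .* got 5")
})

test_that("serpentine reconstruction reverses alternate rows", {
  spectra <- lapply(1:6, function(i) spectrum(100.05 * i, 1))
  g <- reconstruct_image(scan_stream(spectra, 2, 3), lockmass = NULL,
                         range = c(50, 700), normalize = FALSE,
                         serpentine = TRUE)
  img4 <- extract_ion_image(g, c(400.0, 400.4))  # 4th scan
  expect_equal(which(img4 > 0, arr.ind = TRUE),
               cbind(row = 2L, col = 3L), ignore_attr = TRUE)
})

test_that("ion images sum the bins overlapping the window", {
  g <- toy_grid()
  imgA <- extract_ion_image(g, c(100.0, 100.1))
  expect_equal(dim(imgA), c(2, 3))
  # type-A spectra occupy the odd pixels (row-major)
  expect_true(all(imgA[matrix(c(1, 1, 1, 3, 2, 2), ncol = 2, byrow = TRUE)] > 0))
  expect_equal(imgA[1, 2], 0)
  none <- extract_ion_image(g, c(390, 399))
  expect_true(all(none == 0))
})

test_that("RGB composites scale channels independently", {
  r <- matrix(runif(12), 3, 4)
  zero <- matrix(0, 3, 4)
  img <- composite_rgb(r, zero, r)
  expect_true(all(img[, , 2] == 0))
  expect_true(all(img >= 0 & img <= 1))

  const <- matrix(5, 3, 4)
  img2 <- composite_rgb(const, const, const)
  expect_true(all(img2 == 1))

  a <- matrix(runif(12), 3, 4); b <- matrix(runif(12), 3, 4)
  c3 <- matrix(runif(12), 3, 4)
  p1 <- composite_rgb(a, b, c3); p2 <- composite_rgb(b, c3, a)
  expect_equal(p1[, , 1], p2[, , 3])
  expect_error(composite_rgb(a, b, matrix(0, 2, 2)), "dimensions")
})

test_that("correlation maps are 1 inside a homogeneous reference region", {
  g <- toy_grid()
  mask <- matrix(FALSE, 2, 3); mask[1, 1] <- TRUE; mask[1, 3] <- TRUE
  cm <- region_correlation_map(g, mask)
  expect_equal(dim(cm), c(2, 3))
  expect_equal(cm[1, 1], 1)
  expect_equal(cm[2, 2], 1)          # same type-A spectrum
  expect_lte(cm[1, 2], 0)            # disjoint peaks: anti-correlated bins
  expect_error(region_correlation_map(g, matrix(FALSE, 2, 3)), "empty")
})

test_that("processing is independent of scan order given per-scan locks", {
  spectra <- lapply(1:8, function(i) {
    set.seed(100 + i)
    lock <- 554.2615 * (1 + runif(1, -2e-5, 2e-5))
    mz <- sort(c(lock, runif(20, 60, 520)))
    inten <- ifelse(abs(mz - lock) < 1e-12, 50, 1)
    spectrum(mz, inten)
  })
  g1 <- reconstruct_image(scan_stream(spectra, 2, 4))
  ord <- c(5, 2, 7, 1, 8, 3, 6, 4)
  g2 <- reconstruct_image(scan_stream(spectra[ord], 2, 4))
  expect_equal(g1$values[ord, ], g2$values)
})

test_that("imzML continuous files round-trip the binned matrices", {
  g <- toy_grid(3, 4)
  path <- file.path(withr::local_tempdir(), "toy.imzML")
  write_imzml(g, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("imzML$", "ibd", path)))
  back <- read_imzml(path)
  expect_equal(back$rows, 3)
  expect_equal(back$cols, 4)
  expect_lt(max(abs(back$values - g$values)), 1e-9)
  expect_equal(back$mz, g$bin_lo + g$bin_width / 2)
})
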