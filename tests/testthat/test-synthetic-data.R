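test_that("aerosol generation reproduces the lognormal size spec", {
  field <- build_flow_field(default_source())
  empty <- gen_aerosol(aerosol_spec(0), field)
  expect_equal(nrow(empty), 0)

  spec <- aerosol_spec(10000, seed = 5)
  dr <- gen_aerosol(spec, field)
  expect_equal(nrow(dr), 10000)
  expect_lt(abs(median(dr$diameter) - 0.8e-6) / 0.8e-6, 0.05)
  expect_true(all(dr$vz >= 0))  # forward launch out of the capillary
  expect_true(all(sqrt(dr$x^2 + dr$y^2) <= 0.3e-3 + 1e-12))

  dr2 <- gen_aerosol(spec, field)
  expect_identical(dr, dr2)
})

test_that("laser dose arithmetic matches the closed forms", {
  d <- laser_dose(12e-9, 8.3e6, 10e-6)
  expect_equal(d$average_power, 12e-9 * 8.3e6, tolerance = 1e-12)
  expect_equal(d$average_power * 1e3, 99.6)         # mW
  expect_equal(signif(d$average_power * 1e3, 2), 100)
  expect_equal(d$fluence, 12e-9 / (pi * (5e-4)^2), tolerance = 1e-12)
  expect_equal(round(d$fluence, 4), 0.0153)

  z <- laser_dose(0, 8.3e6, 10e-6)
  expect_equal(c(z$average_power, z$fluence), c(0, 0))
  expect_error(laser_dose(1e-9, 1e6, 0), "spot diameter")
})

test_that("phantom layouts are deterministic with the stated proportions", {
  ph <- gen_phantom(30, 30, "stripes")
  counts <- table(ph$labels)
  expect_true(all(counts >= 300))
  expect_true(all(abs(counts / 900 - 1 / 3) < 0.02))

  expect_identical(gen_phantom(20, 20, "blobs", seed = 4)$labels,
                   gen_phantom(20, 20, "blobs", seed = 4)$labels)
  nested <- gen_phantom(20, 20, "nested")
  expect_setequal(unique(as.vector(nested$labels)),
                  c("tumor", "normal", "fibrous", "background"))
  expect_error(gen_phantom(2, 2, "stripes"), "too small")
})

test_that("noise-free pixels of one class share the identical spectrum", {
  ph <- gen_phantom(6, 6, "stripes")
  ds <- gen_msi_dataset(ph, noise_sigma = 0, drift_ppm = 0, n_noise = 0,
                        modality_sigma = 0, seed = 1)
  tumor_idx <- which(as.vector(t(ph$labels)) == "tumor")
  s1 <- ds$stream$spectra[[tumor_idx[1]]]
  s2 <- ds$stream$spectra[[tumor_idx[2]]]
  expect_equal(s1$mz, s2$mz)
  expect_equal(s1$intensity, s2$intensity)
})

test_that("mass drift is imposed and removed by lock-mass correction", {
  ph <- gen_phantom(6, 6, "stripes")
  ds <- gen_msi_dataset(ph, drift_ppm = 30, seed = 2)
  lock_theory <- annotation_table()$mz[
    annotation_table()$name == "leucine enkephalin"]
  raw_dev <- vapply(seq_along(ds$stream$spectra), function(i) {
    s <- ds$stream$spectra[[i]]
    w <- which(abs(s$mz - 554.2615) < 0.5)
    obs <- s$mz[w[which.max(s$intensity[w])]]
    (obs - lock_theory) / lock_theory * 1e6
  }, numeric(1))
  expect_gt(max(abs(raw_dev)), 15)   # drift visible in the raw stream
  expect_lt(max(abs(raw_dev)), 31)

  corrected <- vapply(ds$stream$spectra, function(s) {
    cs <- lockmass_correct(s)
    w <- which(abs(cs$mz - 554.2615) < 0.5)
    obs <- cs$mz[w[which.max(cs$intensity[w])]]
    abs(obs - 554.2615) / 554.2615 * 1e6
  }, numeric(1))
  expect_lt(max(corrected), 1)       # residual under 1 ppm
})

test_that("planted tumor bins are exactly the volcano-significant set", {
  ph <- gen_phantom(18, 18, "stripes", seed = 17)
  ds <- gen_msi_dataset(ph, seed = 17)
  grid <- reconstruct_image(ds$stream)
  fm <- as_feature_matrix(grid, ds$truth$labels)
  sub <- fm$labels %in% c("tumor", "normal")
  v <- volcano(fm$values[sub, ], factor(fm$labels[sub],
                                        c("tumor", "normal")))
  hits <- fm$bin_lo[v$significant]
  planted_bins <- floor(ds$truth$planted_mz * 10) / 10
  expect_setequal(round(hits, 1), round(planted_bins, 1))
})

test_that("bulk spectra share the generative model across modalities", {
  a <- gen_bulk_spectra(n_per_class = 5, modality = "laser",
                        modality_sigma = 0, noise_sigma = 0.3, seed = 11)
  b <- gen_bulk_spectra(n_per_class = 5, modality = "diathermy",
                        modality_sigma = 0, noise_sigma = 0.3, seed = 11)
  expect_equal(a$values, b$values)
  expect_equal(as.character(a$labels), rep(c("tumor", "normal"), each = 5))

  cc <- gen_bulk_spectra(n_per_class = 5, modality = "diathermy",
                         modality_sigma = 0.1, noise_sigma = 0.3, seed = 11)
  expect_false(isTRUE(all.equal(a$values, cc$values)))
  expect_error(gen_bulk_spectra(n_per_class = 0), "at least one")
})

test_that("class-mean separation scales with the planted fold change", {
  sep_of <- function(fold) {
    fmx <- gen_bulk_spectra(n_per_class = 15, planted_fold = fold,
                            drift_ppm = 0, modality_sigma = 0, seed = 21)
    planted <- floor(c(310.25, 455.35, 610.45, 820.55) * 10) / 10
    cols <- which(round(fmx$bin_lo, 1) %in% round(planted, 1))
    lock_col <- which(round(fmx$bin_lo, 1) == 554.2)
    # ratio to the lock bin removes the TIC scaling, isolating the fold
    rel <- fmx$values[, cols] / fmx$values[, lock_col]
    mean(colMeans(rel[fmx$labels == "tumor", ])) /
      mean(colMeans(rel[fmx$labels == "normal", ]))
  }
  expect_equal(sep_of(2), 2, tolerance = 0.2)
  expect_equal(sep_of(4), 4, tolerance = 0.2)
})
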