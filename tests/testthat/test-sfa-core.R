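# Kernel enumeration, spectra, highpass filter, spectral parameters.

spc <- 6.6 / 96  # default pixel spacing, mm

test_that("sfa_config validates its fields", {
  expect_error(sfa_config(kernel_px = 0), class = "sfamuscle_validation_error")
  expect_error(sfa_config(kernel_px = 96, pad_px = 64),
               class = "sfamuscle_validation_error")
  expect_error(sfa_config(stride_px = 0), class = "sfamuscle_validation_error")
  expect_error(sfa_config(hp_cutoff = -1), class = "sfamuscle_validation_error")
})

test_that("kernel enumeration counts exact and sliding fits", {
  cfg <- sfa_config()
  expect_equal(nrow(enumerate_kernels(matrix(TRUE, 96, 96), cfg)), 1L)
  expect_equal(nrow(enumerate_kernels(matrix(TRUE, 100, 100), cfg)), 25L)
  expect_equal(nrow(enumerate_kernels(matrix(TRUE, 95, 200), cfg)), 0L)
  # row-major order on the stride grid
  pos <- enumerate_kernels(matrix(TRUE, 98, 97), cfg)
  expect_equal(pos, cbind(row = c(1L, 1L, 2L, 2L, 3L, 3L),
                          col = rep(1:2, 3)))
})

test_that("kernel enumeration matches the exhaustive containment oracle", {
  set.seed(31)
  for (rep in 1:40) {
    nr <- sample(10:35, 1); nc <- sample(10:35, 1)
    k <- sample(3:8, 1); stride <- sample(1:3, 1)
    # random blob: union of a few rectangles, then random holes
    m <- matrix(FALSE, nr, nc)
    for (b in 1:3) {
      r0 <- sample(nr, 1); c0 <- sample(nc, 1)
      r1 <- min(nr, r0 + sample(3:15, 1)); c1 <- min(nc, c0 + sample(3:15, 1))
      m[r0:r1, c0:c1] <- TRUE
    }
    m[matrix(runif(nr * nc) < 0.03, nr, nc)] <- FALSE
    cfg <- sfa_config(kernel_px = k, pad_px = max(k, 8), stride_px = stride)
    expect_equal(unname(enumerate_kernels(m, cfg)),
                 oracle_enumerate(m, k, stride),
                 label = sprintf("blob rep %d", rep))
  }
})

test_that("constant kernel matches the closed-form padded-block DFT", {
  cfg <- sfa_config()
  img <- bmode_image(matrix(3, 96, 96), spc, spc)
  sp <- kernel_spectrum(img, c(1, 1), cfg)
  o <- sp$origin_index
  expect_equal(sp$magnitude[o["row"], o["col"]], 96 * 96 * 3)
  # Dirichlet-kernel modulus: |F(m1, m2)| = c * D(m1) * D(m2),
  # D(m) = |sin(pi K m / P) / sin(pi m / P)|, K = 96, P = 128
  D <- function(m) ifelse(m %% 128 == 0, 96,
                          abs(sin(pi * 96 * m / 128) / sin(pi * m / 128)))
  for (m1 in c(-5, 0, 2, 17)) {
    for (m2 in c(-9, 1, 30)) {
      expect_equal(sp$magnitude[o["row"] + m1, o["col"] + m2],
                   3 * D(m1) * D(m2), tolerance = 1e-9)
    }
  }
  # frequency axes: symmetric about DC, bin width 1/(pad*spacing)
  expect_equal(sp$freq_u[o["col"]], 0)
  expect_equal(diff(sp$freq_u)[1], 1 / (128 * spc))
  expect_equal(sp$freq_v, sp$freq_u)
})

test_that("all-zero kernel gives an all-zero spectrum", {
  img <- bmode_image(matrix(0, 96, 96), spc, spc)
  sp <- kernel_spectrum(img, c(1, 1), sfa_config())
  expect_true(all(sp$magnitude == 0))
})

test_that("a cosine at an exact post-padding bin peaks at +/- that bin", {
  cfg <- sfa_config()
  f <- 10 / (128 * spc)  # lateral bin 10
  x <- (0:95) * spc
  img <- bmode_image(outer(rep(1, 96), 100 + 40 * cos(2 * pi * f * x)),
                     spc, spc)
  # unfiltered: the padded DC ridge dominates near the origin, so the
  # highpass is part of the pipeline under test here
  sp <- highpass_filter(kernel_spectrum(img, c(1, 1), cfg), cfg)
  o <- sp$origin_index
  top2 <- order(sp$magnitude, decreasing = TRUE)[1:2]
  peaks <- arrayInd(top2, dim(sp$magnitude))
  expect_equal(peaks[, 1], c(o[["row"]], o[["row"]]))
  expect_setequal(peaks[, 2], c(o[["col"]] - 10, o[["col"]] + 10))
  # and spectral_parameters sees exactly that radius
  pars <- spectral_parameters(sp)
  expect_equal(pars$psfr, f, tolerance = 1e-12)
})

test_that("kernel position is validated against image bounds", {
  img <- bmode_image(matrix(1, 100, 100), spc, spc)
  expect_error(kernel_spectrum(img, c(6, 1), sfa_config()),
               class = "sfamuscle_validation_error")
  expect_error(kernel_spectrum(img, c(0, 1), sfa_config()),
               class = "sfamuscle_validation_error")
})

test_that("Butterworth highpass hits -3.0103 dB at cutoff and ~1 beyond", {
  g2 <- butterworth_highpass_gain(1.0, 1.0, 2)^2
  expect_lt(abs(10 * log10(g2) - (-3.0103)), 0.01)
  expect_equal(butterworth_highpass_gain(0, 1, 2), 0)
  # closed form at half cutoff, order 2: 1/sqrt(1 + 2^4)
  expect_equal(butterworth_highpass_gain(0.5, 1, 2), 1 / sqrt(17),
               tolerance = 1e-12)
  # largest representable radius of the default grid
  rmax <- sqrt(2) * 64 / (128 * spc)
  expect_gte(butterworth_highpass_gain(rmax, 1, 2), 0.99)
  # monotone non-decreasing
  r <- seq(0, 8, by = 0.01)
  expect_true(all(diff(butterworth_highpass_gain(r, 1, 2)) >= 0))
})

test_that("highpass_filter nulls DC and applies the radial gain", {
  img <- bmode_image(matrix(runif(96 * 96, 0, 255), 96, 96), spc, spc)
  sp <- kernel_spectrum(img, c(1, 1), sfa_config())
  fl <- highpass_filter(sp, sfa_config())
  o <- sp$origin_index
  expect_equal(fl$magnitude[o["row"], o["col"]], 0)
  r <- sqrt(outer(sp$freq_v^2, sp$freq_u^2, `+`))
  expect_equal(fl$magnitude,
               sp$magnitude * butterworth_highpass_gain(r, 1, 2),
               tolerance = 1e-12)
  expect_true(fl$filtered)
})

test_that("a one-component spectrum yields the hand-computed parameters", {
  p <- 128
  mag <- matrix(0, p, p)
  # spacing 1/16 mm puts 0.5 mm^-1 exactly on bin 4 of the padded grid
  sp <- sfamuscle:::new_kernel_spectrum(mag, p, 0.0625, 0.0625,
                                        filtered = TRUE)
  o <- sp$origin_index
  iu <- which(abs(sp$freq_u - 0.5) < 1e-9)
  expect_length(iu, 1L)
  mag[o["row"], iu] <- 7                       # (u, v) = (0.5, 0)
  mag[o["row"], 2 * o["col"] - iu] <- 7        # conjugate mirror
  sp$magnitude <- mag
  pars <- spectral_parameters(sp)
  expect_equal(pars$psfr, 0.5, tolerance = 1e-12)
  expect_equal(pars$mmax, 7)
  expect_equal(pars$sum, 14)
  expect_equal(pars$mmax_pct, 50)
})

test_that("parameters match a brute-force scan and the Mmax% identity", {
  set.seed(41)
  cfg <- sfa_config()
  img <- bmode_image(matrix(runif(110 * 110, 0, 255), 110, 110), spc, spc)
  for (pos in list(c(1, 1), c(8, 13))) {
    sp <- highpass_filter(kernel_spectrum(img, pos, cfg), cfg)
    pars <- spectral_parameters(sp)
    # exhaustive scan oracle
    o <- sp$origin_index
    best <- -Inf; total <- 0; bestr <- NA
    for (i in 1:128) {
      for (j in 1:128) {
        v <- sp$magnitude[i, j]
        total <- total + v
        if (i == o["row"] && j == o["col"]) next
        if (v > best) {
          best <- v
          bestr <- sqrt(sp$freq_v[i]^2 + sp$freq_u[j]^2)
        }
      }
    }
    expect_equal(pars$mmax, best, tolerance = 1e-12)
    expect_equal(pars$sum, total, tolerance = 1e-12)
    expect_equal(pars$psfr, bestr, tolerance = 1e-12)
    expect_equal(pars$mmax_pct, 100 * pars$mmax / pars$sum,
                 tolerance = 1e-9)
  }
})

test_that("degenerate all-zero spectrum returns zero parameters", {
  sp <- sfamuscle:::new_kernel_spectrum(matrix(0, 128, 128), 128, spc, spc,
                                        filtered = TRUE)
  pars <- spectral_parameters(sp)
  expect_true(pars$degenerate)
  expect_equal(c(pars$psfr, pars$mmax, pars$mmax_pct, pars$sum),
               c(0, 0, 0, 0))
})

test_that("intensity scaling scales Mmax/Sum and fixes PSFR/Mmax%", {
  set.seed(42)
  cfg <- sfa_config()
  base <- matrix(runif(96 * 96, 10, 200), 96, 96)
  p1 <- spectral_parameters(highpass_filter(
    kernel_spectrum(bmode_image(base, spc, spc), c(1, 1), cfg), cfg))
  p2 <- spectral_parameters(highpass_filter(
    kernel_spectrum(bmode_image(2.5 * base, spc, spc), c(1, 1), cfg), cfg))
  expect_equal(p2$mmax, 2.5 * p1$mmax, tolerance = 1e-9)
  expect_equal(p2$sum, 2.5 * p1$sum, tolerance = 1e-9)
  expect_equal(p2$psfr, p1$psfr)
  expect_equal(p2$mmax_pct, p1$mmax_pct, tolerance = 1e-9)
})

test_that("analyze_roi of a single-kernel ROI equals the kernel pipeline", {
  set.seed(43)
  cfg <- sfa_config()
  img <- bmode_image(matrix(runif(96 * 96, 0, 255), 96, 96), spc, spc)
  mask <- matrix(TRUE, 96, 96)
  roi <- analyze_roi(img, mask, cfg)
  single <- spectral_parameters(highpass_filter(
    kernel_spectrum(img, c(1, 1), cfg), cfg))
  expect_equal(roi$n_kernels, 1L)
  for (fld in c("psfr", "mmax", "mmax_pct", "sum"))
    expect_equal(roi[[fld]], single[[fld]], tolerance = 1e-12)
})

test_that("merged disjoint ROIs average as the kernel-count-weighted mean", {
  set.seed(44)
  cfg <- sfa_config(kernel_px = 16, pad_px = 32)
  img <- bmode_image(matrix(runif(60 * 60, 0, 255), 60, 60), spc, spc)
  mask_a <- matrix(FALSE, 60, 60); mask_a[1:20, 1:24] <- TRUE
  mask_b <- matrix(FALSE, 60, 60); mask_b[35:60, 30:60] <- TRUE
  a <- analyze_roi(img, mask_a, cfg)
  b <- analyze_roi(img, mask_b, cfg)
  both <- analyze_roi(img, mask_a | mask_b, cfg)
  expect_equal(both$n_kernels, a$n_kernels + b$n_kernels)
  for (fld in c("psfr", "mmax", "mmax_pct", "sum")) {
    expect_equal(both[[fld]],
                 (a$n_kernels * a[[fld]] + b$n_kernels * b[[fld]]) /
                   both$n_kernels,
                 tolerance = 1e-12)
  }
})

test_that("analyze_roi names the minimum size when the ROI is too small", {
  img <- bmode_image(matrix(1, 50, 50), spc, spc)
  err <- expect_error(analyze_roi(img, matrix(TRUE, 50, 50), sfa_config()),
                      class = "sfamuscle_validation_error")
  expect_match(conditionMessage(err), "96 x 96")
  expect_match(conditionMessage(err), "ROI too small")
})

test_that("homogeneous texture gives similar parameters in two random ROIs", {
  cfg <- sfa_config(stride_px = 4)
  ph <- generate_phantom(phantom_spec(shape = c(340L, 340L), seed = 77))
  img <- ph$image
  mask1 <- matrix(FALSE, 340, 340); mask1[21:140, 21:140] <- TRUE
  mask2 <- matrix(FALSE, 340, 340); mask2[201:320, 201:320] <- TRUE
  a <- analyze_roi(img, mask1, cfg)
  b <- analyze_roi(img, mask2, cfg)
  # stationarity: same-texture difference is small next to the change when
  # the banding is removed entirely
  flat <- generate_phantom(phantom_spec(shape = c(340L, 340L),
                                        band_contrast = 0, seed = 77))
  c0 <- analyze_roi(flat$image, mask1, cfg)
  expect_lt(abs(a$mmax_pct - b$mmax_pct), abs(a$mmax_pct - c0$mmax_pct))
  expect_lt(abs(a$psfr - b$psfr), 2 * bin_width())
})
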