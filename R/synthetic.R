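# Ground-truth generators: banded speckle phantoms that mimic the
# hypoechoic-fiber / hyperechoic-perimysium striation of longitudinal
# muscle scans, and two-way ratings tables with a known true ICC.

#' Specification of a banded speckle phantom
#'
#' The phantom is a multiplicative speckle field (exponential envelope
#' smoothed by a Gaussian point-spread function) modulated by
#' `1 + contrast * cos(2 * pi * band_freq * s)`, `s` being the coordinate
#' (mm) along the band normal.  Defaults mimic a longitudinal muscle scan:
#' square pixels of 6.6/96 mm, a band every ~1.3 mm (0.75 mm^-1, the
#' scale of fascicular striation), moderate band contrast, and a 0.3 mm
#' speckle correlation length (the resolution-cell scale of a 2-10 MHz
#' linear array).
#'
#' @param shape `(rows, cols)` in pixels; the default 300 x 300 spans
#'   about 20.6 x 20.6 mm and admits a 13 x 13 grid of default kernels.
#' @param spacing Pixel spacing in mm (both axes; default 6.6/96).
#' @param band_freq Band spatial frequency in mm^-1, below Nyquist
#'   `1/(2 * spacing)`.
#' @param band_orientation Band-normal angle in degrees from the lateral
#'   axis; 0 means bands run laterally (modulation along depth), as
#'   fascicles roughly do in longitudinal scans.
#' @param band_contrast Modulation depth in `[0, 1]`.
#' @param speckle_scale Gaussian PSF smoothing length in mm.
#' @param mean_intensity Mean gray level of the phantom.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(300L, 300L), spacing = 6.6 / 96,
                         band_freq = 0.75, band_orientation = 0,
                         band_contrast = 0.6, speckle_scale = 0.3,
                         mean_intensity = 120, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop_validation("shape must be positive (rows, cols)")
  check_scalar_positive(spacing, "spacing")
  check_scalar_positive(band_freq, "band_freq")
  if (band_freq >= 1 / (2 * spacing))
    stop_validation("band_freq %.3g mm^-1 is at/above Nyquist %.3g mm^-1",
                    band_freq, 1 / (2 * spacing))
  if (!is_scalar_number(band_contrast) || band_contrast < 0 ||
      band_contrast > 1)
    stop_validation("band_contrast must be in [0, 1]")
  check_scalar_positive(speckle_scale, "speckle_scale")
  check_scalar_positive(mean_intensity, "mean_intensity")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 band_freq = as.numeric(band_freq),
                 band_orientation = as.numeric(band_orientation),
                 band_contrast = as.numeric(band_contrast),
                 speckle_scale = as.numeric(speckle_scale),
                 mean_intensity = as.numeric(mean_intensity),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a speckle phantom with a known banded structure
#'
#' Returns the phantom image together with a rectangular ROI polygon inset
#' one kernel length (96 px) from every image edge, so all admissible
#' kernels sit well away from the border.
#'
#' @param spec A [phantom_spec()].
#' @param roi_margin_px Inset of the rectangular ROI from the image edges.
#' @return List with `image` ([bmode_image()]) and `roi`
#'   ([roi_polygon()]).
#' @export
generate_phantom <- function(spec, roi_margin_px = 96L) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$shape[1]; nc <- spec$shape[2]
  px <- with_seed(spec$seed, {
    envelope <- matrix(rexp(nr * nc), nr, nc)
    envelope <- gaussian_smooth(envelope, spec$speckle_scale / spec$spacing)
    envelope <- envelope / mean(envelope)
    theta <- spec$band_orientation * pi / 180
    x_mm <- (seq_len(nc) - 1) * spec$spacing
    y_mm <- (seq_len(nr) - 1) * spec$spacing
    s <- outer(y_mm * cos(theta), x_mm * sin(theta), `+`)
    band <- 1 + spec$band_contrast * cos(2 * pi * spec$band_freq * s)
    pmax(spec$mean_intensity * envelope * band, 0)
  })
  img <- bmode_image(px, spec$spacing, spec$spacing,
                     source_id = sprintf("phantom-seed%d", spec$seed))
  m <- roi_margin_px
  if (nr - 1 - m <= m || nc - 1 - m <= m)
    stop_validation("phantom %dx%d too small for ROI margin %d px",
                    nr, nc, m)
  roi <- roi_polygon(rbind(c(m, m), c(nc - 1 - m, m),
                           c(nc - 1 - m, nr - 1 - m), c(m, nr - 1 - m)),
                     image_id = img$source_id)
  list(image = img, roi = roi)
}

# Separable Gaussian smoothing with reflective borders; sigma in pixels.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(-half:half)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  smooth_axis <- function(mat) {
    n <- nrow(mat)
    padded <- rbind(mat[half:1, , drop = FALSE], mat,
                    mat[n:(n - half + 1L), , drop = FALSE])
    out <- matrix(0, n, ncol(mat))
    for (t in seq_along(kern)) {
      out <- out + kern[t] * padded[(t - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(smooth_axis(t(smooth_axis(m))))
}

#' Specification of a simulated two-way ratings table
#'
#' Measurements follow `y_ij = grand_mean + b_i + r_j + e_ij` with
#' independent normal subject effects `b_i` (SD `subject_sd`), rater
#' effects `r_j` (SD `rater_sd`) and residuals (SD `error_sd`), so the
#' true consistency ICC is `subject_sd^2 / (subject_sd^2 + error_sd^2)`.
#'
#' @param n_subjects,k_raters Table dimensions (>= 2 each).
#' @param grand_mean Overall mean level.
#' @param subject_sd,rater_sd,error_sd Component SDs, >= 0.
#' @param seed Integer seed.
#' @return List of class `ratings_spec` with the derived `true_icc`.
#' @export
ratings_spec <- function(n_subjects = 10L, k_raters = 2L, grand_mean = 100,
                         subject_sd = 10, rater_sd = 0, error_sd = 5,
                         seed = 1L) {
  n_subjects <- as.integer(n_subjects); k_raters <- as.integer(k_raters)
  if (n_subjects < 2L || k_raters < 2L)
    stop_validation("need n_subjects >= 2 and k_raters >= 2")
  for (nm in c("subject_sd", "rater_sd", "error_sd")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 0)
      stop_validation("%s must be >= 0", nm)
  }
  denom <- subject_sd^2 + error_sd^2
  structure(list(n_subjects = n_subjects, k_raters = k_raters,
                 grand_mean = as.numeric(grand_mean),
                 subject_sd = as.numeric(subject_sd),
                 rater_sd = as.numeric(rater_sd),
                 error_sd = as.numeric(error_sd),
                 true_icc = if (denom > 0) subject_sd^2 / denom else NA_real_,
                 seed = as.integer(seed)),
            class = "ratings_spec")
}

#' Simulate a ratings table with known reliability
#'
#' @param spec A [ratings_spec()].
#' @param parameter Parameter name carried on the resulting table.
#' @return A [ratings_table()].
#' @export
generate_ratings <- function(spec, parameter = "simulated") {
  stopifnot(inherits(spec, "ratings_spec"))
  n <- spec$n_subjects; k <- spec$k_raters
  vals <- with_seed(spec$seed, {
    b <- rnorm(n, 0, spec$subject_sd)
    r <- rnorm(k, 0, spec$rater_sd)
    e <- matrix(rnorm(n * k, 0, spec$error_sd), n, k)
    spec$grand_mean + outer(b, rep(1, k)) + outer(rep(1, n), r) + e
  })
  ratings_table(vals, parameter = parameter)
}
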