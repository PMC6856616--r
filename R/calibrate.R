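## PSF contrast restoration.
##
## Membranes are thinner than the PSF, so the rendered crista / IBM (or
## vesicle / IBM) intensity ratio mixes membrane signal with matrix and
## cytosol and biases apparent potential differences toward 0.  Rather
## than deconvolving, we calibrate: render noise-free phantoms matching
## the measured geometry across a grid of true offsets, push them through
## the *same* measurement code, and invert the resulting monotone
## apparent->true relation.  This is a calibration against the package's
## own forward model (documented as such), not a deconvolution.

.mv_cache <- new.env(parent = emptyenv())

.linear_interp_extra <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  function(v) {
    out <- stats::approx(x, y, xout = v, rule = 2)$y
    lo <- v < x[1L]; hi <- v > x[length(x)]
    if (any(lo)) {
      s <- (y[2L] - y[1L]) / (x[2L] - x[1L])
      out[lo] <- y[1L] + s * (v[lo] - x[1L])
    }
    if (any(hi)) {
      n <- length(x)
      s <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
      out[hi] <- y[n] + s * (v[hi] - x[n])
    }
    out
  }
}

## Measure the mean raw crista-IBM (or vesicle-IBM) apparent difference on
## one noise-free rendered scenario, using the standard analysis path.
.apparent_delta <- function(scenario, config, target = "crista") {
  sim <- simulate_timelapse(scenario, noise = FALSE)
  struct <- sim$stack$pixels[1, 1, , ]
  pot <- sim$stack$pixels[1, 2, , ]
  objs <- segment_mitochondria(struct, scenario$pixel_size_nm, config)
  if (!length(objs)) return(NA_real_)
  mito <- objs[[1L]]
  axis <- extract_axis(mito, scenario$pixel_size_nm)
  prof <- axial_profile(struct, mito, axis, config$band_halfwidth_px)
  cr <- detect_cristae(prof, config$min_prominence_frac,
                       config$min_spacing_nm, scenario$pixel_size_nm)
  cls <- classify_pixels(mito, axis, prof, cr, config)
  if (target == "crista") {
    if (!nrow(cr)) return(NA_real_)
    tab <- delta_psi_cr_ibm(pot, axis, prof, cr, cls, config = config,
                            contrast_map = NULL)
    mean(tab$delta_psi_raw_mv, na.rm = TRUE)
  } else {
    ves <- detect_vesicles(pot, cls, scenario$pixel_size_nm, config)
    if (length(ves$dropped_cristae)) {
      cr <- cr[-ves$dropped_cristae, , drop = FALSE]
      cls <- classify_pixels(mito, axis, prof, cr, config)
      ves <- detect_vesicles(pot, cls, scenario$pixel_size_nm, config)
    }
    if (!length(ves$vesicles)) return(NA_real_)
    fi_v <- .vesicle_fi(pot, ves$vesicles[[1L]])
    fi_i <- mean(pot[cls$ibm_quant])
    nernst_delta_psi(fi_v, fi_i, config$temperature_K)
  }
}

#' Crista contrast-restoration map
#'
#' Builds (and memoizes) a monotone map from apparent crista-IBM potential
#' differences to calibrated ones, for a given organelle width, crista
#' spacing and optics. See the package vignette for what this calibration
#' does and does not correct.
#'
#' @param width_um Measured organelle width (um; rounded to 0.1 um for
#'   memoization).
#' @param spacing_um Measured median crista spacing (um; rounded to
#'   0.05 um).
#' @param pixel_size_nm,psf_fwhm_nm Optics of the acquisition.
#' @param config An `mv_config` (assumed matrix/IBM potentials, analysis
#'   parameters).
#' @param offsets_mv Grid of true offsets rendered for the calibration.
#' @return Function mapping apparent mV to calibrated mV (linear
#'   extrapolation beyond the grid).
#' @export
crista_contrast_map <- function(width_um, spacing_um, pixel_size_nm,
                                psf_fwhm_nm = NULL,
                                config = default_config(),
                                offsets_mv = c(1, 2.5, 5, 7.5, 10, 15, 20,
                                               30, 40)) {
  psf_fwhm_nm <- psf_fwhm_nm %||% config$psf_fwhm_nm
  width_um <- round(width_um, 1)
  spacing_um <- max(round(spacing_um / 0.05) * 0.05, 0.15)
  key <- paste("cr", width_um, spacing_um, pixel_size_nm, psf_fwhm_nm,
               config$temperature_K, config$assumed_psi_matrix_mv,
               config$assumed_psi_ibm_offset_mv, sep = "_")
  if (!is.null(.mv_cache[[key]])) return(.mv_cache[[key]])
  n_cr <- 5L
  len <- max(2.5, (n_cr + 1) * spacing_um + width_um + 0.5)
  apparent <- vapply(offsets_mv, function(off) {
    sc <- sim_scenario(name = "calib", length_um = len, width_um = width_um,
                       n_cristae = n_cr, crista_spacing_um = spacing_um,
                       psi_matrix_mv = config$assumed_psi_matrix_mv,
                       psi_ibm_offset_mv = config$assumed_psi_ibm_offset_mv,
                       psi_crista_offset_mv = off,
                       independent_fraction = 0,
                       pixel_size_nm = pixel_size_nm,
                       psf_fwhm_nm = psf_fwhm_nm,
                       temperature_K = config$temperature_K,
                       n_frames = 1L, rng_seed = 1L)
    .apparent_delta(sc, config, "crista")
  }, numeric(1))
  ok <- is.finite(apparent)
  if (sum(ok) < 3L) {
    warning("crista_contrast_map: calibration failed; returning identity")
    fn <- identity
  } else {
    fn <- .linear_interp_extra(apparent[ok], offsets_mv[ok])
  }
  .mv_cache[[key]] <- fn
  fn
}

#' Vesicle contrast-restoration map
#'
#' As [crista_contrast_map()] but for detached vesicles of a given radius.
#'
#' @param radius_um Measured vesicle radius (um; rounded to the pixel).
#' @inheritParams crista_contrast_map
#' @return Function mapping apparent mV to calibrated mV.
#' @export
vesicle_contrast_map <- function(radius_um, width_um, pixel_size_nm,
                                 psf_fwhm_nm = NULL,
                                 config = default_config(),
                                 offsets_mv = c(5, 10, 15, 20, 25, 30, 40,
                                                50)) {
  psf_fwhm_nm <- psf_fwhm_nm %||% config$psf_fwhm_nm
  px <- pixel_size_nm / 1000
  radius_um <- max(round(radius_um / px) * px, 2 * px)
  width_um <- round(width_um, 1)
  key <- paste("ves", radius_um, width_um, pixel_size_nm, psf_fwhm_nm,
               config$temperature_K, config$assumed_psi_matrix_mv,
               config$assumed_psi_ibm_offset_mv, sep = "_")
  if (!is.null(.mv_cache[[key]])) return(.mv_cache[[key]])
  len <- max(3, 6 * radius_um + width_um)
  apparent <- vapply(offsets_mv, function(off) {
    sc <- sim_scenario(name = "calib", length_um = len, width_um = width_um,
                       n_cristae = 0L,
                       psi_matrix_mv = config$assumed_psi_matrix_mv,
                       psi_ibm_offset_mv = config$assumed_psi_ibm_offset_mv,
                       vesicles = list(list(position_um = len / 2,
                                            radius_um = radius_um,
                                            psi_offset_mv = off)),
                       independent_fraction = 0,
                       pixel_size_nm = pixel_size_nm,
                       psf_fwhm_nm = psf_fwhm_nm,
                       temperature_K = config$temperature_K,
                       n_frames = 1L, rng_seed = 1L)
    .apparent_delta(sc, config, "vesicle")
  }, numeric(1))
  ok <- is.finite(apparent)
  if (sum(ok) < 3L) {
    warning("vesicle_contrast_map: calibration failed; returning identity")
    fn <- identity
  } else {
    fn <- .linear_interp_extra(apparent[ok], offsets_mv[ok])
  }
  .mv_cache[[key]] <- fn
  fn
}
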