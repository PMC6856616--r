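## Separable Gaussian blur with replicate (edge-clamp) padding, so constant
## images stay exactly constant.
.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

.conv_sep <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- .gauss_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  ny <- nrow(img); nx <- ncol(img)
  ## rows (vertical)
  pad <- img[c(rep(1L, r), seq_len(ny), rep(ny, r)), , drop = FALSE]
  out <- matrix(0, ny, nx)
  for (s in seq_along(k)) out <- out + k[s] * pad[(s - 1L) + seq_len(ny), , drop = FALSE]
  ## cols (horizontal)
  pad <- out[, c(rep(1L, r), seq_len(nx), rep(nx, r)), drop = FALSE]
  out2 <- matrix(0, ny, nx)
  for (s in seq_along(k)) out2 <- out2 + k[s] * pad[, (s - 1L) + seq_len(nx), drop = FALSE]
  out2
}

#' Gaussian point-spread blur of a frame
#'
#' @param img Numeric matrix.
#' @param fwhm_nm PSF full width at half maximum in nm.
#' @param pixel_size_nm Pixel size in nm.
#' @return Blurred matrix (replicate edge padding; constants preserved).
#' @export
psf_blur <- function(img, fwhm_nm, pixel_size_nm) {
  sigma_px <- (fwhm_nm / 2.3548200450309493) / pixel_size_nm
  .conv_sep(img, sigma_px)
}

#' Render a concentration map into a noisy camera frame
#'
#' Applies the Gaussian PSF, scales by `photons_per_unit`, then adds
#' Poisson shot noise and Gaussian read noise and clips at zero. With
#' `noise = FALSE` the expected (noise-free) frame is returned. Noise draws
#' come from the current RNG stream, so renders are deterministic given a
#' seed.
#'
#' @param conc Numeric concentration matrix (one channel).
#' @param scenario The [sim_scenario()] providing optics and noise levels.
#' @param noise Add shot and read noise? Default TRUE.
#' @return Numeric matrix of photon counts.
#' @export
render_frame <- function(conc, scenario, noise = TRUE) {
  if (any(!is.finite(conc))) {
    stop("render_frame: non-finite concentrations", call. = FALSE)
  }
  expected <- psf_blur(conc, scenario$psf_fwhm_nm, scenario$pixel_size_nm) *
    scenario$photons_per_unit
  if (!noise) return(expected)
  shot <- matrix(stats::rpois(length(expected), pmax(expected, 0)),
                 nrow(expected), ncol(expected))
  out <- shot + matrix(stats::rnorm(length(expected), 0,
                                    scenario$read_noise_sd),
                       nrow(expected), ncol(expected))
  pmax(out, 0)
}

#' Simulate a ground-truthed two-channel time-lapse
#'
#' For each frame the baseline potential field is modified by the
#' scenario's events (flicker, wave, partial depolarization) and per-crista
#' jitter, the dye re-equilibrates instantaneously, and both channels are
#' rendered through the optics/noise model. Ground truth (label map,
#' per-frame true potential fields, crista registry, event log) is emitted
#' alongside.
#'
#' @param scenario A [sim_scenario()].
#' @param noise Add noise (default TRUE); FALSE gives expected frames.
#' @return List with `stack` (a [frame_stack()] of shape t x 2 x y x x,
#'   channels `struct`, `pot`) and `truth` (class `mv_truth`: `labels`,
#'   `psi` array t x y x x, `registry`, `geometry`, `events`, `scenario`).
#' @export
simulate_timelapse <- function(scenario, noise = TRUE) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$rng_seed)
  geom <- build_geometry(scenario)
  ny <- nrow(geom$labels); nx <- ncol(geom$labels)
  nt <- scenario$n_frames
  pixels <- array(0, dim = c(nt, 2L, ny, nx))
  psi_true <- array(0, dim = c(nt, ny, nx))
  n_cr <- scenario$n_cristae
  for (i in seq_len(nt)) {
    t <- (i - 1) * scenario$frame_interval_s
    jit <- if (scenario$psi_crista_jitter_sd_mv > 0 && n_cr > 0) {
      stats::rnorm(n_cr, 0, scenario$psi_crista_jitter_sd_mv)
    } else NULL
    psi <- .psi_at_time(geom, scenario, t, jitter_mv = jit)
    maps <- equilibrium_dye_map(geom, scenario, psi = psi)
    pixels[i, 1L, , ] <- render_frame(maps$struct, scenario, noise = noise)
    pixels[i, 2L, , ] <- render_frame(maps$pot, scenario, noise = noise)
    psi_true[i, , ] <- psi
  }
  stack <- frame_stack(pixels, pixel_size_nm = scenario$pixel_size_nm,
                       frame_interval_s = scenario$frame_interval_s,
                       channel_names = c("struct", "pot"))
  truth <- structure(list(labels = geom$labels, psi = psi_true,
                          registry = geom$registry, geometry = geom,
                          events = scenario$events, scenario = scenario),
                     class = "mv_truth")
  list(stack = stack, truth = truth)
}
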