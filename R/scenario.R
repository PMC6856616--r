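#' Describe a time-lapse perturbation event
#'
#' Events modify the per-pixel potential field of a simulation over a time
#' window. Three kinds are supported:
#' \describe{
#'   \item{flicker}{transient whole-organelle depolarization/repolarization;
#'     all potentials are scaled by `1 - depth` during the window.}
#'   \item{wave}{laser-induced depolarization propagating from `site_um`
#'     along the organelle axis at `speed_um_per_s`; pixels behind the front
#'     have their potential scaled by `1 - depth` and stay depolarized until
#'     `t_end_s`.}
#'   \item{partial_depolarization}{only `target_crista_ids` lose their
#'     crista-versus-IBM offset (scaled by `1 - depth`); the rest of the
#'     organelle is untouched.}
#' }
#'
#' @param kind One of "flicker", "wave", "partial_depolarization".
#' @param t_start_s,t_end_s Event window in seconds (start < end).
#' @param site_um Axial coordinate (um, from the left tip) of the laser
#'   perturbation; wave only.
#' @param speed_um_per_s Front speed in um/s; wave only.
#' @param target_crista_ids Integer crista ids (1-based registry ids);
#'   partial_depolarization only.
#' @param depth Fraction of the potential lost in `[0, 1]`.
#' @return An object of class `sim_event`.
#' @export
sim_event <- function(kind = c("flicker", "wave", "partial_depolarization"),
                      t_start_s, t_end_s, site_um = NULL,
                      speed_um_per_s = NULL, target_crista_ids = NULL,
                      depth = 1) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(t_start_s), is.numeric(t_end_s))
  if (!(t_start_s < t_end_s)) {
    stop("sim_event: t_start_s must be < t_end_s", call. = FALSE)
  }
  if (!is.numeric(depth) || depth < 0 || depth > 1) {
    stop("sim_event: depth must lie in [0, 1]", call. = FALSE)
  }
  if (kind == "wave") {
    if (is.null(site_um) || is.null(speed_um_per_s)) {
      stop("sim_event: wave events need site_um and speed_um_per_s",
           call. = FALSE)
    }
    stopifnot(speed_um_per_s > 0, site_um >= 0)
  }
  if (kind == "partial_depolarization" && is.null(target_crista_ids)) {
    stop("sim_event: partial_depolarization needs target_crista_ids",
         call. = FALSE)
  }
  structure(list(kind = kind, t_start_s = t_start_s, t_end_s = t_end_s,
                 site_um = site_um, speed_um_per_s = speed_um_per_s,
                 target_crista_ids = as.integer(target_crista_ids),
                 depth = depth),
            class = "sim_event")
}

#' Define a synthetic imaging scenario
#'
#' A `sim_scenario` is the complete generative description of a phantom:
#' capsule geometry, per-compartment membrane potentials, dye model, optics,
#' noise and time-lapse events. Rendering the same scenario with the same
#' seed is bit-reproducible.
#'
#' Potentials follow the sign convention "positive mV = hyperpolarized
#' relative to cytosol" and offsets add: matrix sits at `psi_matrix_mv`,
#' the inner boundary membrane (IBM) at `psi_matrix_mv + psi_ibm_offset_mv`,
#' crista *i* at IBM `+ psi_crista_offset_mv + per_crista_offsets_mv[i]`,
#' and a vesicle at IBM `+` its own offset. The scenario's true
#' crista-versus-IBM difference is therefore
#' `psi_crista_offset_mv + per_crista_offsets_mv`.
#'
#' The potential-independent (membrane-bound) dye fraction
#' `independent_fraction` is expressed as a fraction of the *baseline total*
#' signal of each pixel: during a full depolarization exactly that fraction
#' of the baseline fluorescence remains.
#'
#' @param name Scenario name.
#' @param length_um,width_um Capsule length and diameter in um.
#' @param n_cristae Number of transverse cristae.
#' @param crista_spacing_um Center-to-center crista spacing in um.
#' @param psi_matrix_mv Matrix polarization versus cytosol (mV, positive =
#'   polarized).
#' @param psi_ibm_offset_mv IBM minus matrix (mV).
#' @param psi_crista_offset_mv Crista minus IBM (mV); the scenario's true
#'   delta-psi(Cr-IBM).
#' @param per_crista_offsets_mv Per-crista deviations from
#'   `psi_crista_offset_mv` (length `n_cristae`, default all 0).
#' @param psi_crista_jitter_sd_mv SD (mV) of independent per-frame,
#'   per-crista Gaussian jitter added to the crista offset (default 0).
#' @param vesicles List of `list(position_um =, radius_um =, psi_offset_mv =)`
#'   detached inner-membrane vesicles; `psi_offset_mv` is versus IBM.
#' @param independent_fraction Potential-independent bound-dye fraction of
#'   baseline signal, in `[0, 1)`.
#' @param membrane_density_struct Named relative structural-dye density per
#'   label (cytosol, matrix, ibm, crista, vesicle).
#' @param pixel_size_nm Pixel size (default 40 nm, Airyscan-like).
#' @param psf_fwhm_nm Gaussian PSF full width at half maximum (default
#'   140 nm).
#' @param photons_per_unit Photon gain: expected photons per concentration
#'   unit (cytosol free dye = 1 unit).
#' @param read_noise_sd Additive Gaussian read noise SD (photons).
#' @param temperature_K Temperature for the Nernstian partition.
#' @param frame_interval_s Frame interval in seconds.
#' @param n_frames Number of frames.
#' @param events List of [sim_event()] objects.
#' @param rng_seed Integer seed making renders reproducible.
#' @return Object of class `sim_scenario`.
#' @seealso [preset_scenario()], [simulate_timelapse()]
#' @export
sim_scenario <- function(name = "custom",
                         length_um = 6, width_um = 0.8,
                         n_cristae = 8, crista_spacing_um = 0.3,
                         psi_matrix_mv = 150, psi_ibm_offset_mv = 5,
                         psi_crista_offset_mv = 10.11,
                         per_crista_offsets_mv = NULL,
                         psi_crista_jitter_sd_mv = 0,
                         vesicles = list(),
                         independent_fraction = 0.05,
                         membrane_density_struct = c(cytosol = 5, matrix = 80,
                                                     ibm = 260, crista = 320,
                                                     vesicle = 300),
                         pixel_size_nm = 40, psf_fwhm_nm = 140,
                         photons_per_unit = 2, read_noise_sd = 2,
                         temperature_K = 310.15,
                         frame_interval_s = 0.5, n_frames = 10,
                         events = list(), rng_seed = 1L) {
  stopifnot(length_um > 0, width_um > 0, n_cristae >= 0,
            crista_spacing_um > 0, pixel_size_nm > 0, psf_fwhm_nm > 0,
            photons_per_unit > 0, read_noise_sd >= 0,
            frame_interval_s > 0, n_frames >= 1)
  if (psf_fwhm_nm < pixel_size_nm) {
    stop("sim_scenario: psf_fwhm_nm must be >= pixel_size_nm", call. = FALSE)
  }
  if (independent_fraction < 0 || independent_fraction >= 1) {
    stop("sim_scenario: independent_fraction must lie in [0, 1)",
         call. = FALSE)
  }
  if (is.null(per_crista_offsets_mv)) {
    per_crista_offsets_mv <- rep(0, n_cristae)
  }
  if (length(per_crista_offsets_mv) != n_cristae) {
    stop("sim_scenario: per_crista_offsets_mv must have length n_cristae",
         call. = FALSE)
  }
  need <- c("cytosol", "matrix", "ibm", "crista", "vesicle")
  if (!all(need %in% names(membrane_density_struct))) {
    stop("sim_scenario: membrane_density_struct must name ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (n_cristae > 0 &&
      (n_cristae - 1) * crista_spacing_um > length_um - width_um) {
    stop("sim_scenario: cristae span exceeds the cylindrical section; ",
         "reduce n_cristae or crista_spacing_um", call. = FALSE)
  }
  duration <- n_frames * frame_interval_s
  for (ev in events) {
    if (!inherits(ev, "sim_event")) {
      stop("sim_scenario: events must be sim_event objects", call. = FALSE)
    }
    if (ev$t_start_s >= duration) {
      stop("sim_scenario: event starts after the series ends", call. = FALSE)
    }
    if (ev$kind == "wave" && (ev$site_um < 0 || ev$site_um > length_um)) {
      stop("sim_scenario: wave site_um must lie within the mitochondrion",
           call. = FALSE)
    }
    if (ev$kind == "partial_depolarization" &&
        any(ev$target_crista_ids < 1 | ev$target_crista_ids > n_cristae)) {
      stop("sim_scenario: target_crista_ids outside 1..n_cristae",
           call. = FALSE)
    }
  }
  for (v in vesicles) {
    stopifnot(is.list(v), v$radius_um > 0)
    if (v$position_um < 0 || v$position_um > length_um) {
      stop("sim_scenario: vesicle position outside mitochondrion",
           call. = FALSE)
    }
  }
  structure(list(name = name, length_um = length_um, width_um = width_um,
                 n_cristae = as.integer(n_cristae),
                 crista_spacing_um = crista_spacing_um,
                 psi_matrix_mv = psi_matrix_mv,
                 psi_ibm_offset_mv = psi_ibm_offset_mv,
                 psi_crista_offset_mv = psi_crista_offset_mv,
                 per_crista_offsets_mv = per_crista_offsets_mv,
                 psi_crista_jitter_sd_mv = psi_crista_jitter_sd_mv,
                 vesicles = vesicles,
                 independent_fraction = independent_fraction,
                 membrane_density_struct = membrane_density_struct,
                 pixel_size_nm = pixel_size_nm, psf_fwhm_nm = psf_fwhm_nm,
                 photons_per_unit = photons_per_unit,
                 read_noise_sd = read_noise_sd,
                 temperature_K = temperature_K,
                 frame_interval_s = frame_interval_s,
                 n_frames = as.integer(n_frames),
                 events = events, rng_seed = as.integer(rng_seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("<sim_scenario '%s'> %.1f x %.1f um, %d cristae, %d frames @ %.2g s\n",
              x$name, x$length_um, x$width_um, x$n_cristae, x$n_frames,
              x$frame_interval_s))
  cat(sprintf("  psi: matrix %.4g mV, IBM offset %.4g mV, crista offset %.4g mV; %d event(s)\n",
              x$psi_matrix_mv, x$psi_ibm_offset_mv, x$psi_crista_offset_mv,
              length(x$events)))
  invisible(x)
}

#' Modify a scenario
#'
#' Returns a copy of `scenario` with the named fields replaced and the
#' result re-validated.
#'
#' @param scenario A [sim_scenario()].
#' @param ... Fields to override.
#' @return A new `sim_scenario`.
#' @export
scenario_update <- function(scenario, ...) {
  stopifnot(inherits(scenario, "sim_scenario"))
  args <- unclass(scenario)
  over <- list(...)
  bad <- setdiff(names(over), names(args))
  if (length(bad)) {
    stop("scenario_update: unknown field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  if ("n_cristae" %in% names(over) &&
      !"per_crista_offsets_mv" %in% names(over)) {
    args$per_crista_offsets_mv <- NULL   # re-defaulted to zeros
  }
  do.call(sim_scenario, args)
}
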