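#' Run the full analysis pipeline on a stack
#'
#' Per frame: rolling-ball background subtraction of both channels,
#' segmentation on the structural channel (never the potentiometric one,
#' to avoid bias when depolarized), axis extraction, crista detection,
#' pixel classification, vesicle detection, and Nernstian potential
#' tables. Geometry detected on the first frame anchors the axial
#' coordinate system for profiles and traces; cristae are additionally
#' re-detected per frame for tracking.
#'
#' @param stack A [frame_stack()] with channels `struct` and `pot` (a
#'   single-channel stack is used for both with a warning).
#' @param config An `mv_config`.
#' @param verbose Log per-stage object counts.
#' @return List of class `mv_results`:
#' \describe{
#'   \item{morphometrics}{per-object, per-frame shape table.}
#'   \item{potentials}{per-compartment potential table
#'     ([compartment_potentials()]).}
#'   \item{cristae}{per-crista, per-frame delta-psi(Cr-IBM) table.}
#'   \item{detail}{per-object internals: axis, per-frame potentiometric
#'     and structural profiles (on the frame-1 axis), whole-object
#'     potentiometric trace, frame-1 classification and vesicles.}
#' }
#' @export
analyze_stack <- function(stack, config = default_config(), verbose = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  ch_struct <- match("struct", stack$channel_names)
  ch_pot <- match("pot", stack$channel_names)
  if (is.na(ch_struct) || is.na(ch_pot)) {
    if (dim(stack$pixels)[2L] == 1L) {
      warning("analyze_stack: single channel used as both struct and pot")
      ch_struct <- ch_pot <- 1L
    } else {
      ch_struct <- 1L; ch_pot <- 2L
    }
  }
  px_nm <- stack$pixel_size_nm
  nt <- n_frames(stack)
  log_msg <- function(...) if (verbose) message(sprintf(...))

  ## ---- frame 1: anchor geometry
  s1 <- subtract_background(get_frame(stack, 1L, ch_struct),
                            config$background_radius_px,
                            config$background_shrink)
  objs <- segment_mitochondria(s1, px_nm, config)
  log_msg("frame 1: %d object(s) segmented", length(objs))
  morpho <- list(); potentials <- list(); cristae_tab <- list()
  detail <- list()

  pot_frames <- lapply(seq_len(nt), function(t)
    subtract_background(get_frame(stack, t, ch_pot),
                        config$background_radius_px,
                        config$background_shrink))
  struct_frames <- c(list(s1), if (nt > 1L)
    lapply(2:nt, function(t)
      subtract_background(get_frame(stack, t, ch_struct),
                          config$background_radius_px,
                          config$background_shrink)))

  for (oi in seq_along(objs)) {
    mito <- objs[[oi]]
    axis <- extract_axis(mito, px_nm)
    if (axis$low_elongation) {
      log_msg("object %d: low elongation, profiles flagged", oi)
    }
    prof1 <- axial_profile(s1, mito, axis, config$band_halfwidth_px)
    cr1 <- detect_cristae(prof1, config$min_prominence_frac,
                          config$min_spacing_nm, px_nm)
    cls <- classify_pixels(mito, axis, prof1, cr1, config)
    ves <- detect_vesicles(pot_frames[[1L]], cls, px_nm, config)
    if (length(ves$dropped_cristae)) {
      ## structural peaks that are really vesicles: rebuild without them
      cr1 <- cr1[-ves$dropped_cristae, , drop = FALSE]
      cls <- classify_pixels(mito, axis, prof1, cr1, config)
      ves <- detect_vesicles(pot_frames[[1L]], cls, px_nm, config)
    }
    cls$labels <- ves$labels
    log_msg("object %d: %d cristae, %d vesicle(s)", oi, nrow(cr1),
            length(ves$vesicles))

    cr_map <- NULL
    ves_map <- NULL
    if (isTRUE(config$calibrate_contrast)) {
      width_um <- 2 * sqrt(mito$area_um2 /
                             (pi + 4 * max(mito$aspect_ratio - 1, 0)))
      spacing_um <- if (nrow(cr1) >= 2L) stats::median(diff(cr1$position_um))
        else 0.3
      cr_map <- crista_contrast_map(width_um, spacing_um, px_nm,
                                    config$psf_fwhm_nm, config)
      if (length(ves$vesicles)) {
        r_um <- sqrt(length(ves$vesicles[[1L]]) / pi) * px_nm / 1000
        ves_map <- vesicle_contrast_map(r_um, width_um, px_nm,
                                        config$psf_fwhm_nm, config)
      }
    }

    prof_pot <- matrix(NA_real_, nt, length(axis$arclength_um))
    prof_struct <- matrix(NA_real_, nt, length(axis$arclength_um))
    trace <- numeric(nt)
    comp_traces <- matrix(NA_real_, nt, 4L,
                          dimnames = list(NULL, c("matrix", "ibm", "crista",
                                                  "vesicle")))
    for (t in seq_len(nt)) {
      pott <- pot_frames[[t]]
      st <- struct_frames[[t]]
      comp_traces[t, ] <- .compartment_fi(pott, cls, ves$vesicles)
      pp <- axial_profile(pott, mito, axis, config$band_halfwidth_px)
      prof_pot[t, ] <- pp$intensity
      prof_struct[t, ] <- axial_profile(st, mito, axis,
                                        config$band_halfwidth_px)$intensity
      trace[t] <- mean(pott[mito$pixels])
      morpho[[length(morpho) + 1L]] <- data.frame(
        mito_id = oi, frame = t, area_um2 = mito$area_um2,
        perimeter_um = mito$perimeter_um, circularity = mito$circularity,
        aspect_ratio = mito$aspect_ratio)
      pt <- compartment_potentials(pott, cls, ves$vesicles, mito_id = oi,
                                   frame = t, config = config)
      if (!is.null(pt)) {
        if (!is.null(ves_map) && any(pt$compartment == "vesicle")) {
          vrow <- pt$compartment == "vesicle"
          pt$delta_psi_mv[vrow] <- ves_map(pt$delta_psi_mv[vrow])
        }
        potentials[[length(potentials) + 1L]] <- pt
      }
      ## per-frame crista re-detection (tracking support), delta on frame-1
      ## bands for potential stability
      crt <- detect_cristae(
        axial_profile(st, mito, axis, config$band_halfwidth_px),
        config$min_prominence_frac, config$min_spacing_nm, px_nm)
      dtab <- delta_psi_cr_ibm(pott, axis, prof1, cr1, cls, frame = t,
                               mito_id = oi, config = config,
                               contrast_map = cr_map)
      if (nrow(dtab)) {
        dtab$position_frame_um <- if (nrow(crt) == nrow(dtab))
          crt$position_um else dtab$position_um
        cristae_tab[[length(cristae_tab) + 1L]] <- dtab
      }
    }
    detail[[oi]] <- list(mito = mito, axis = axis, cristae = cr1,
                         classification = cls, vesicles = ves$vesicles,
                         profiles_pot = prof_pot,
                         profiles_struct = prof_struct,
                         trace = trace,
                         compartment_traces = comp_traces,
                         arclength_um = axis$arclength_um,
                         contrast_map = cr_map,
                         vesicle_contrast_map = ves_map)
  }
  structure(list(
    morphometrics = if (length(morpho)) do.call(rbind, morpho) else NULL,
    potentials = if (length(potentials)) do.call(rbind, potentials) else NULL,
    cristae = if (length(cristae_tab)) do.call(rbind, cristae_tab) else NULL,
    detail = detail,
    frame_interval_s = stack$frame_interval_s,
    pixel_size_nm = px_nm,
    config = config), class = "mv_results")
}

#' @export
print.mv_results <- function(x, ...) {
  cat(sprintf("<mv_results> %d object(s); %s crista rows; %s potential rows\n",
              length(x$detail),
              if (is.null(x$cristae)) 0L else nrow(x$cristae),
              if (is.null(x$potentials)) 0L else nrow(x$potentials)))
  invisible(x)
}
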