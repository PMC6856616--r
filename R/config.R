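#' Default pipeline configuration
#'
#' All tunables of every analysis stage with their defaults. The config
#' fully determines the pipeline output for given inputs: same config +
#' same stack = identical tables.
#'
#' @return Nested list of class `mv_config`.
#' @section Fields:
#' \describe{
#'   \item{background_radius_px}{rolling-ball radius (50, as in standard
#'     practice for this assay).}
#'   \item{min_area_um2}{minimum object area kept by segmentation.}
#'   \item{discard_edge_objects}{drop objects touching the frame edge.}
#'   \item{band_halfwidth_px}{transverse half-width used for axial
#'     profiles.}
#'   \item{min_prominence_frac}{crista peak prominence as a fraction of the
#'     profile dynamic range.}
#'   \item{min_spacing_nm}{minimum crista peak spacing (resolution limit).}
#'   \item{ibm_shell_px}{IBM boundary-shell thickness in px.}
#'   \item{ibm_inset_px}{inward shift of the shell compensating the
#'     threshold-mask halo produced by the PSF.}
#'   \item{ibm_exclude_halfwidth_px}{axial half-window around each crista
#'     excluded from IBM quantification (pixels stay labelled IBM).}
#'   \item{vesicle_k}{vesicle brightness threshold, multiple of the median
#'     matrix intensity.}
#'   \item{vesicle_min_area_um2}{minimum vesicle area.}
#'   \item{temperature_K}{temperature for the Nernstian slope.}
#'   \item{reference_mode}{"adjacent_IBM", "mito_mean" or "cytosol".}
#'   \item{independent_fraction}{assumed potential-independent dye fraction
#'     subtracted before conversion (published bound fraction < 5%).}
#'   \item{ibm_window_um}{axial half-window defining "adjacent IBM".}
#'   \item{calibrate_contrast}{apply the simulator-derived PSF
#'     contrast-restoration map to crista/vesicle potentials.}
#'   \item{track_max_jump_um, track_max_gap}{crista tracking limits.}
#'   \item{flicker_drop, flicker_recover}{flicker detection thresholds as
#'     fractions of baseline.}
#'   \item{wave_front_frac}{profile fraction of baseline defining the
#'     depolarization front.}
#'   \item{wave_proximal_um, wave_distal_um}{proximal/distal band limits.}
#'   \item{baseline_frames}{frames before onset used as baseline.}
#' }
#' @export
default_config <- function() {
  structure(list(
    background_radius_px = 50, background_shrink = "auto",
    min_area_um2 = 0.2, discard_edge_objects = TRUE,
    band_halfwidth_px = 2L,
    min_prominence_frac = 0.1, min_spacing_nm = 120,
    ibm_shell_px = 1L, ibm_inset_px = 1L, ibm_exclude_halfwidth_px = 1L,
    vesicle_k = 2, vesicle_min_area_um2 = 0.01,
    temperature_K = 310.15,
    reference_mode = "adjacent_IBM",
    independent_fraction = 0.05,
    ibm_window_um = 0.25,
    calibrate_contrast = TRUE,
    assumed_psi_matrix_mv = 150, assumed_psi_ibm_offset_mv = 5,
    psf_fwhm_nm = 140,
    track_max_jump_um = 0.15, track_max_gap = 2L,
    flicker_drop = 0.5, flicker_recover = 0.8,
    partial_depol_frac = 0.3,
    wave_front_frac = 0.5, wave_proximal_um = 1, wave_distal_um = 10,
    baseline_frames = 5L,
    seed = 1L
  ), class = "mv_config")
}

#' Merge overrides into a configuration
#' @param ... Named overrides of [default_config()] fields.
#' @param base Configuration to start from.
#' @return `mv_config` list.
#' @export
mv_config <- function(..., base = default_config()) {
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) {
    stop("mv_config: unknown option(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(utils::modifyList(unclass(base), over), class = "mv_config")
}

#' Read / write configuration as JSON
#'
#' Round-trips losslessly: `read_config(write_config(cfg, f))` equals
#' `cfg`.
#'
#' @param config An `mv_config`.
#' @param path JSON file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   an `mv_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  for (nm in intersect(names(raw), names(base))) {
    if (is.integer(base[[nm]])) raw[[nm]] <- as.integer(raw[[nm]])
  }
  do.call(mv_config, raw)
}
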