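## Named scenario presets emulating the experimental conditions the package
## is designed to quantify.  Crista/vesicle offsets are the published point
## estimates for the matching condition; geometry, absolute matrix
## polarization, optics and noise are plausible defaults (no acquisition
## parameters are published) and are documented in the methods vignette.

.preset_builders <- list(
  control = function(seed) sim_scenario(
    name = "control", psi_crista_offset_mv = 10.11, rng_seed = seed),

  control_mef = function(seed) sim_scenario(
    name = "control_mef", psi_crista_offset_mv = 10.67, rng_seed = seed),

  ## F0F1-ATP-synthase inhibition (oligomycin 10 uM) hyperpolarizes and
  ## raises the crista-IBM contrast; 18 mV is a plausible raised value
  ## (only the direction is published).
  oligomycin = function(seed) sim_scenario(
    name = "oligomycin", psi_matrix_mv = 165, psi_crista_offset_mv = 18,
    rng_seed = seed),

  ## Uncoupling (FCCP 10 uM) collapses potentials toward 0 and fragments
  ## the network into shorter, rounder organelles.
  fccp = function(seed) sim_scenario(
    name = "fccp", length_um = 2.2, width_um = 1.1, n_cristae = 3,
    psi_matrix_mv = 40, psi_ibm_offset_mv = 1.5, psi_crista_offset_mv = 3,
    rng_seed = seed),

  mic13_ko = function(seed) sim_scenario(
    name = "mic13_ko", n_cristae = 3, psi_crista_offset_mv = 2,
    rng_seed = seed),

  mic60_ko = function(seed) sim_scenario(
    name = "mic60_ko", n_cristae = 3, psi_crista_offset_mv = 2.5,
    rng_seed = seed),

  opa1_ko = function(seed) sim_scenario(
    name = "opa1_ko", n_cristae = 4, psi_crista_offset_mv = 3,
    rng_seed = seed),

  ## Crista-junction loss detaches hyperpolarized inner-membrane vesicles.
  mic10_ko = function(seed) sim_scenario(
    name = "mic10_ko", n_cristae = 3, psi_crista_offset_mv = 2,
    vesicles = list(list(position_um = 4.2, radius_um = 0.16,
                         psi_offset_mv = 25.85)),
    rng_seed = seed),

  opa1_drp1_dko = function(seed) sim_scenario(
    name = "opa1_drp1_dko", n_cristae = 3, psi_crista_offset_mv = 2,
    vesicles = list(list(position_um = 4.2, radius_um = 0.16,
                         psi_offset_mv = 39.55)),
    rng_seed = seed),

  ## Full-depth flicker with a 15% bound-dye fraction: depolarizes at 9 s,
  ## repolarizes at 16 s under continuous illumination.
  flicker = function(seed) sim_scenario(
    name = "flicker", independent_fraction = 0.15, n_frames = 44,
    frame_interval_s = 0.5,
    events = list(sim_event("flicker", t_start_s = 9, t_end_s = 16,
                            depth = 1)),
    rng_seed = seed),

  ## Laser-induced depolarization wave on a long organelle; tip exposure.
  wave = function(seed) sim_scenario(
    name = "wave", length_um = 10, n_cristae = 12, n_frames = 40,
    frame_interval_s = 0.3,
    events = list(sim_event("wave", t_start_s = 3, t_end_s = 12,
                            site_um = 0.5, speed_um_per_s = 5, depth = 1)),
    rng_seed = seed),

  ## Uncoordinated depolarization: two of four cristae collapse.
  partial = function(seed) sim_scenario(
    name = "partial", n_cristae = 4, crista_spacing_um = 0.5,
    n_frames = 30, frame_interval_s = 0.5,
    events = list(sim_event("partial_depolarization", t_start_s = 6,
                            t_end_s = 12, target_crista_ids = c(2L, 4L),
                            depth = 1)),
    rng_seed = seed),

  ## Stable per-crista heterogeneity: two weak and two strong cristae with
  ## 1 mV temporal jitter.
  variability = function(seed) sim_scenario(
    name = "variability", n_cristae = 4, crista_spacing_um = 0.5,
    psi_crista_offset_mv = 0, per_crista_offsets_mv = c(5, 5, 12, 12),
    psi_crista_jitter_sd_mv = 1, n_frames = 20, rng_seed = seed)
)

#' Names of the built-in scenario presets
#' @return Character vector of preset names.
#' @export
preset_names <- function() names(.preset_builders)

#' Retrieve a built-in scenario preset
#'
#' Presets emulate the experimental conditions of interest: `control`
#' (crista-IBM difference 10.11 mV), `control_mef` (10.67 mV), `oligomycin`
#' (raised contrast), `fccp` (collapsed potentials, fragmented geometry),
#' `mic13_ko`/`mic60_ko`/`opa1_ko` (few cristae, contrast near 0),
#' `mic10_ko` (detached vesicle +25.85 mV versus IBM), `opa1_drp1_dko`
#' (vesicle +39.55 mV), plus dynamic scenarios `flicker`, `wave`, `partial`
#' and `variability`.
#'
#' @param name Preset name (see [preset_names()]).
#' @param seed Integer RNG seed stored in the scenario.
#' @return A [sim_scenario()].
#' @export
preset_scenario <- function(name, seed = 1L) {
  if (!name %in% names(.preset_builders)) {
    stop("unknown preset '", name, "'; available: ",
         paste(preset_names(), collapse = ", "), call. = FALSE)
  }
  .preset_builders[[name]](as.integer(seed))
}

#' All presets at once
#' @param seed Integer RNG seed applied to every preset.
#' @return Named list of [sim_scenario()] objects.
#' @export
preset_scenarios <- function(seed = 1L) {
  lapply(.preset_builders, function(f) f(as.integer(seed)))
}

#' Machine-readable preset manifest
#'
#' One row per preset with the generative parameters that differ across
#' conditions, suitable for writing alongside simulated data.
#'
#' @return A data.frame.
#' @export
preset_manifest <- function() {
  rows <- lapply(preset_names(), function(nm) {
    s <- preset_scenario(nm)
    data.frame(name = nm, length_um = s$length_um, width_um = s$width_um,
               n_cristae = s$n_cristae,
               psi_matrix_mv = s$psi_matrix_mv,
               psi_ibm_offset_mv = s$psi_ibm_offset_mv,
               psi_crista_offset_mv = s$psi_crista_offset_mv,
               n_vesicles = length(s$vesicles),
               vesicle_psi_offset_mv = if (length(s$vesicles))
                 s$vesicles[[1]]$psi_offset_mv else NA_real_,
               independent_fraction = s$independent_fraction,
               n_events = length(s$events),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
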