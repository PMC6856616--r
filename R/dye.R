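#' Equilibrium dye concentration maps
#'
#' Converts a potential field into the two dye channels the microscope
#' sees, before optics and noise:
#' \itemize{
#'   \item potentiometric channel: free dye partitions Nernstianly,
#'     `exp(psi / kappa)` with the cytosol concentration normalized to 1,
#'     plus a potential-independent bound component frozen at
#'     `independent_fraction` of the *baseline* total signal of the pixel
#'     (bound dye does not leave on depolarization);
#'   \item structural channel: proportional to the per-label membrane dye
#'     density `membrane_density_struct`, independent of potential.
#' }
#'
#' @param geometry A [build_geometry()] result.
#' @param scenario The matching [sim_scenario()].
#' @param psi Optional potential field (mV matrix) to use for the free dye,
#'   e.g. an event-modified field; defaults to the baseline
#'   [potential_map()].
#' @return List with numeric matrices `struct` and `pot` (concentration
#'   units; cytosol free dye = 1).
#' @export
equilibrium_dye_map <- function(geometry, scenario, psi = NULL) {
  stopifnot(inherits(geometry, "mv_geometry"))
  kappa <- nernst_kappa(scenario$temperature_K)
  psi0 <- potential_map(geometry, scenario)
  if (is.null(psi)) psi <- psi0
  if (any(!is.finite(psi))) {
    stop("equilibrium_dye_map: non-finite potentials", call. = FALSE)
  }
  f <- scenario$independent_fraction
  free <- exp(psi / kappa)
  ## bound term: f/(1-f) * baseline free concentration, so that at full
  ## depolarization the remaining signal is ~ f of the baseline total
  bound <- (f / (1 - f)) * exp(psi0 / kappa)
  pot <- free + bound

  dens <- scenario$membrane_density_struct
  lab <- geometry$labels
  struct <- matrix(dens[["cytosol"]], nrow(lab), ncol(lab))
  struct[lab == LABELS[["background"]]] <- 0
  struct[lab == LABELS[["matrix"]]] <- dens[["matrix"]]
  struct[lab == LABELS[["ibm"]]] <- dens[["ibm"]]
  struct[lab == LABELS[["crista"]]] <- dens[["crista"]]
  struct[lab == LABELS[["vesicle"]]] <- dens[["vesicle"]]

  list(struct = struct, pot = pot)
}

## Event-modified potential field at acquisition time t (seconds).
## Events are applied in list order; later events override per pixel.
.psi_at_time <- function(geometry, scenario, t, jitter_mv = NULL) {
  psi <- potential_map(geometry, scenario)
  if (!is.null(jitter_mv)) {
    for (k in seq_along(geometry$crista_pixels)) {
      psi[geometry$crista_pixels[[k]]] <-
        psi[geometry$crista_pixels[[k]]] + jitter_mv[[k]]
    }
  }
  psi_ibm <- scenario$psi_matrix_mv + scenario$psi_ibm_offset_mv
  for (ev in scenario$events) {
    if (ev$kind == "flicker") {
      if (t >= ev$t_start_s && t < ev$t_end_s) {
        psi <- psi * (1 - ev$depth)
      }
    } else if (ev$kind == "wave") {
      if (t >= ev$t_start_s) {
        ## front advances until t_end, then freezes; depolarization persists
        dt <- min(t, ev$t_end_s) - ev$t_start_s
        front <- ev$speed_um_per_s * dt
        behind <- !is.na(geometry$axial_um) &
          abs(geometry$axial_um - ev$site_um) <= front
        psi[behind] <- psi[behind] * (1 - ev$depth)
      }
    } else if (ev$kind == "partial_depolarization") {
      if (t >= ev$t_start_s && t < ev$t_end_s) {
        for (k in ev$target_crista_ids) {
          idx <- geometry$crista_pixels[[k]]
          ## the crista loses its offset above the IBM, not the whole psi
          psi[idx] <- psi_ibm + (psi[idx] - psi_ibm) * (1 - ev$depth)
        }
      }
    }
  }
  psi
}
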