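#' Nernstian potential difference from two fluorescence intensities
#'
#' For a monovalent cationic probe at equilibrium, the potential difference
#' between two compartments follows from their free-dye concentrations:
#' `delta_psi = kappa * ln(FI_a / FI_b)` with `kappa = 1000 R T / F` mV.
#' Positive means compartment *a* is more polarized than *b*.
#'
#' @param fi_a,fi_b Positive background-subtracted (and bound-fraction
#'   corrected) intensities.
#' @param temperature_K Temperature (default 310.15 K).
#' @return Potential difference in mV.
#' @examples
#' nernst_delta_psi(1000, 100)  # 61.54 mV (one decade at 37 C)
#' @export
nernst_delta_psi <- function(fi_a, fi_b, temperature_K = 310.15) {
  if (any(fi_a <= 0)) {
    stop("nernst_delta_psi: nonpositive intensity in compartment a",
         call. = FALSE)
  }
  if (any(fi_b <= 0)) {
    stop("nernst_delta_psi: nonpositive intensity in compartment b",
         call. = FALSE)
  }
  ## log difference rather than log of the ratio: antisymmetry is then
  ## exact in floating point
  nernst_kappa(temperature_K) * (log(fi_a) - log(fi_b))
}

#' Remove the potential-independent dye component
#'
#' Subtracts the bound (potential-insensitive) signal from a measured
#' intensity before Nernstian conversion. When the independent component is
#' at least as large as the measurement the result is undefined: NA is
#' returned with a warning.
#'
#' @param fi Measured intensity (post background subtraction).
#' @param fi_independent The potential-independent component, either
#'   estimated from fully depolarized flicker frames or a configured
#'   fraction of baseline.
#' @return `fi - fi_independent`, or NA when `fi_independent >= fi`.
#' @export
correct_independent_fraction <- function(fi, fi_independent) {
  out <- fi - fi_independent
  bad <- fi_independent >= fi | fi_independent < 0
  if (any(bad)) {
    warning("correct_independent_fraction: independent component >= signal; ",
            "flagged missing")
    out[bad] <- NA_real_
  }
  out
}

## vesicle FI: mean over the brightest quartile of the component (the
## central plateau), insensitive to how far the detection threshold grows
## the component into the blurred edge
.vesicle_fi <- function(frame_pot, idx) {
  v <- sort(frame_pot[idx], decreasing = TRUE)
  mean(v[seq_len(max(4L, ceiling(length(v) / 4)))])
}

## mean potentiometric FI per compartment for one frame of one object
.compartment_fi <- function(frame_pot, classification, vesicles = list()) {
  lab <- classification$labels
  fis <- c(
    matrix = mean(frame_pot[lab == LABELS[["matrix"]]]),
    ibm = mean(frame_pot[classification$ibm_quant]),
    crista = if (any(lab == LABELS[["crista"]]))
      mean(frame_pot[lab == LABELS[["crista"]]]) else NA_real_,
    vesicle = if (length(vesicles))
      mean(vapply(vesicles, function(ix) .vesicle_fi(frame_pot, ix),
                  numeric(1))) else NA_real_)
  fis
}

#' Per-compartment potential table
#'
#' Converts mean compartment intensities of the potentiometric channel into
#' mV against a reference: the whole-mitochondrion mean intensity
#' (`mito_mean`, the multi-electrode-style reference), the median cytosol
#' intensity (`cytosol`) or the object's IBM (`adjacent_IBM`). The assumed
#' potential-independent fraction is subtracted from every compartment
#' first (it cancels in ratios of equally-corrected compartments but
#' matters against the cytosol).
#'
#' @param frame_pot Background-subtracted potentiometric frame.
#' @param classification [classify_pixels()] (optionally after
#'   [detect_vesicles()] relabelling) for one object.
#' @param vesicles List of vesicle pixel index vectors.
#' @param mito_id Integer id echoed into the table.
#' @param frame Frame index echoed into the table.
#' @param config An `mv_config` (reference mode, temperature, independent
#'   fraction).
#' @return data.frame rows `(mito_id, object_id, compartment, frame,
#'   mean_FI, reference_mode, delta_psi_mv, temperature_K)`.
#' @export
compartment_potentials <- function(frame_pot, classification,
                                   vesicles = list(), mito_id = 1L,
                                   frame = 1L, config = default_config()) {
  f <- config$independent_fraction
  fis <- .compartment_fi(frame_pot, classification, vesicles)
  fis_corr <- fis * (1 - f)
  lab <- classification$labels
  obj <- lab %in% LABELS[c("matrix", "ibm", "crista", "vesicle")]
  ref <- switch(config$reference_mode,
    mito_mean = mean(frame_pot[obj]) * (1 - f),
    cytosol = stats::median(frame_pot[lab %in% LABELS[c("background",
                                                        "cytosol")]]),
    adjacent_IBM = fis_corr[["ibm"]],
    stop("compartment_potentials: unknown reference_mode", call. = FALSE))
  if (!is.finite(ref) || ref <= 0) {
    return(NULL)  # frame unusable for this reference; caller logs
  }
  comp <- names(fis)
  ok <- is.finite(fis_corr) & fis_corr > 0
  data.frame(mito_id = mito_id, object_id = mito_id,
             compartment = comp[ok], frame = frame,
             mean_FI = as.numeric(fis[ok]),
             reference_mode = config$reference_mode,
             delta_psi_mv = nernst_delta_psi(as.numeric(fis_corr[ok]), ref,
                                             config$temperature_K),
             temperature_K = config$temperature_K,
             stringsAsFactors = FALSE)
}

#' Per-crista potential difference versus adjacent IBM
#'
#' For each detected crista, `kappa * ln(FI_crista / FI_adjacent_IBM)`
#' where the adjacent IBM is the quantification-mask IBM pixels within an
#' axial window (default +/- 0.25 um) of the crista position. Optionally
#' corrected through a PSF contrast-restoration map (see
#' [crista_contrast_map()]).
#'
#' @param frame_pot Background-subtracted potentiometric frame.
#' @param axis,profile,cristae,classification Results of the upstream
#'   stages for one object.
#' @param frame Frame index echoed into the table.
#' @param mito_id Object id echoed into the table.
#' @param config An `mv_config`.
#' @param contrast_map Optional function apparent-mV -> corrected-mV; when
#'   NULL and `config$calibrate_contrast` is TRUE one is built (and
#'   memoized) from the frame geometry.
#' @return data.frame `(mito_id, crista_id, frame, position_um, prominence,
#'   delta_psi_cr_ibm_mv, delta_psi_raw_mv)`; cristae without adjacent IBM
#'   pixels get NA and a `flagged` marker.
#' @export
delta_psi_cr_ibm <- function(frame_pot, axis, profile, cristae,
                             classification, frame = 1L, mito_id = 1L,
                             config = default_config(),
                             contrast_map = NULL) {
  if (!nrow(cristae)) {
    return(data.frame(mito_id = integer(0), crista_id = integer(0),
                      frame = integer(0), position_um = numeric(0),
                      prominence = numeric(0),
                      delta_psi_cr_ibm_mv = numeric(0),
                      delta_psi_raw_mv = numeric(0), flagged = logical(0)))
  }
  ibm_idx <- which(classification$ibm_quant)
  ny <- nrow(frame_pot)
  ## axial position of each quantifiable IBM pixel via the profile mapping
  mito_pixels <- which(classification$labels != LABELS[["background"]])
  rows <- lapply(seq_len(nrow(cristae)), function(k) {
    band <- classification$crista_pixels[[k]]
    fi_cr <- mean(frame_pot[band])
    near_idx <- ibm_idx[abs(.pixel_arclength(ibm_idx, axis, ny) -
                              cristae$position_um[k]) <= config$ibm_window_um]
    flagged <- length(near_idx) == 0L
    fi_ibm <- if (flagged) NA_real_ else mean(frame_pot[near_idx])
    raw <- if (flagged || fi_cr <= 0 || fi_ibm <= 0) NA_real_ else
      nernst_delta_psi(fi_cr, fi_ibm, config$temperature_K)
    corr <- if (!is.null(contrast_map) && is.finite(raw))
      contrast_map(raw) else raw
    data.frame(mito_id = mito_id, crista_id = cristae$crista_id[k],
               frame = frame, position_um = cristae$position_um[k],
               prominence = cristae$prominence[k],
               delta_psi_cr_ibm_mv = corr, delta_psi_raw_mv = raw,
               flagged = flagged)
  })
  do.call(rbind, rows)
}

## arclength (um) of arbitrary pixels: nearest axis point
.pixel_arclength <- function(idx, axis, ny) {
  pr <- (idx - 1L) %% ny + 1L
  pc <- (idx - 1L) %/% ny + 1L
  d2 <- outer(pr, axis$rows, `-`)^2 + outer(pc, axis$cols, `-`)^2
  axis$arclength_um[max.col(-d2, ties.method = "first")]
}

#' Two-group comparison with per-experiment averaging
#'
#' Values are first averaged within independent experiments, then the
#' experiment means are compared with a two-tailed two-sample Student
#' t-test (pooled variance by default; Welch optional).
#'
#' @param values_a,values_b Numeric vectors.
#' @param experiments_a,experiments_b Experiment identifiers, same lengths;
#'   default one experiment per value.
#' @param var_equal Pooled-variance t-test (TRUE, default) or Welch.
#' @return data.frame with group means, `t`, `df`, `p_value`, and the
#'   number of experiments per group.
#' @export
group_compare <- function(values_a, values_b,
                          experiments_a = seq_along(values_a),
                          experiments_b = seq_along(values_b),
                          var_equal = TRUE) {
  ma <- tapply(values_a, experiments_a, mean)
  mb <- tapply(values_b, experiments_b, mean)
  if (length(ma) < 2L || length(mb) < 2L) {
    stop("group_compare: need >= 2 experiments per group", call. = FALSE)
  }
  if (stats::sd(c(ma)) == 0 && stats::sd(c(mb)) == 0 &&
      mean(ma) == mean(mb)) {
    ## identical degenerate groups: t = 0, p = 1 by convention
    return(data.frame(mean_a = mean(ma), mean_b = mean(mb), t = 0,
                      df = length(ma) + length(mb) - 2, p_value = 1,
                      n_exp_a = length(ma), n_exp_b = length(mb)))
  }
  tt <- stats::t.test(ma, mb, var.equal = var_equal)
  data.frame(mean_a = mean(ma), mean_b = mean(mb),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value,
             n_exp_a = length(ma), n_exp_b = length(mb))
}
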