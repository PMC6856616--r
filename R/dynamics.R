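#' Link per-frame crista detections into tracks
#'
#' Greedy nearest-neighbour linking on axial position. At each frame,
#' candidate (track, detection) pairs within `max_jump_um` are linked in
#' order of increasing displacement (which resolves crossing ambiguities by
#' minimal total displacement); unmatched detections start new tracks;
#' tracks missing for more than `max_gap` frames are closed. Output
#' ordering is deterministic (by first position).
#'
#' @param cristae data.frame with columns `frame`, `crista_id`,
#'   `position_um` and optionally `delta_psi_cr_ibm_mv` (e.g. the `cristae`
#'   table of [analyze_stack()], using `position_frame_um` when present).
#' @param max_jump_um Maximum per-frame axial displacement.
#' @param max_gap Maximum number of consecutive missed frames.
#' @return List of `crista_track`s: `track_id`, `frames`, `position_um`,
#'   `delta_psi_mv`, `mean_delta_psi_mv`, `sd_over_time_mv`.
#' @export
track_cristae <- function(cristae, max_jump_um = 0.15, max_gap = 2L) {
  if (is.null(cristae) || !nrow(cristae)) return(list())
  pos_col <- if ("position_frame_um" %in% names(cristae))
    "position_frame_um" else "position_um"
  dp_col <- if ("delta_psi_cr_ibm_mv" %in% names(cristae))
    "delta_psi_cr_ibm_mv" else NULL
  frames <- sort(unique(cristae$frame))
  tracks <- list()   # each: list(frames, pos, dp, last_frame, open)
  for (fr in frames) {
    det <- cristae[cristae$frame == fr, , drop = FALSE]
    det <- det[order(det[[pos_col]]), , drop = FALSE]
    open <- which(vapply(tracks, function(tr)
      fr - tr$last_frame <= max_gap + 1L, logical(1)))
    ## all candidate pairs within the jump limit, closest first
    if (length(open) && nrow(det)) {
      cand <- expand.grid(ti = open, di = seq_len(nrow(det)))
      cand$dist <- abs(vapply(seq_len(nrow(cand)), function(r) {
        tr <- tracks[[cand$ti[r]]]
        tr$pos[length(tr$pos)] - det[[pos_col]][cand$di[r]]
      }, numeric(1)))
      ## jump limit scales with the number of frames bridged
      cand$span <- vapply(cand$ti, function(ti)
        fr - tracks[[ti]]$last_frame, numeric(1))
      cand <- cand[cand$dist <= max_jump_um * cand$span, , drop = FALSE]
      cand <- cand[order(cand$dist, cand$ti), , drop = FALSE]
      used_t <- integer(0); used_d <- integer(0)
      for (r in seq_len(nrow(cand))) {
        ti <- cand$ti[r]; di <- cand$di[r]
        if (ti %in% used_t || di %in% used_d) next
        tr <- tracks[[ti]]
        tr$frames <- c(tr$frames, fr)
        tr$pos <- c(tr$pos, det[[pos_col]][di])
        tr$dp <- c(tr$dp, if (is.null(dp_col)) NA_real_ else det[[dp_col]][di])
        tr$last_frame <- fr
        tracks[[ti]] <- tr
        used_t <- c(used_t, ti); used_d <- c(used_d, di)
      }
      new_det <- setdiff(seq_len(nrow(det)), used_d)
    } else new_det <- seq_len(nrow(det))
    for (di in new_det) {
      tracks[[length(tracks) + 1L]] <- list(
        frames = fr, pos = det[[pos_col]][di],
        dp = if (is.null(dp_col)) NA_real_ else det[[dp_col]][di],
        last_frame = fr)
    }
  }
  tracks <- tracks[order(vapply(tracks, function(tr) tr$pos[1L], numeric(1)))]
  lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    structure(list(track_id = i, frames = tr$frames, position_um = tr$pos,
                   delta_psi_mv = tr$dp,
                   mean_delta_psi_mv = mean(tr$dp, na.rm = TRUE),
                   sd_over_time_mv = stats::sd(tr$dp[is.finite(tr$dp)])),
              class = "crista_track")
  })
}

#' Detect flicker events on a whole-mitochondrion intensity trace
#'
#' An event opens when the potentiometric trace falls below
#' `drop_threshold` times the running baseline (median of the preceding
#' non-event frames, at least `baseline_frames` of them) and closes when it
#' recovers above `recovery_threshold` times that baseline. The measured
#' depth is the potential-dependent signal loss
#' `1 - plateau / baseline`; the plateau mean is also reported as the
#' potential-independent fraction estimate.
#'
#' @param trace Numeric whole-object mean potentiometric trace (>= 10
#'   frames).
#' @param frame_interval_s Seconds per frame.
#' @param drop_threshold,recovery_threshold Fractions of baseline.
#' @param baseline_frames Frames used for the initial baseline.
#' @return List of `flicker_event`s: `t_depol_s`, `t_repol_s` (NA when the
#'   trace ends depolarized), `frames`, `depth_fraction`,
#'   `independent_fraction_est`, `baseline`.
#' @export
detect_flicker <- function(trace, frame_interval_s = 1,
                           drop_threshold = 0.5, recovery_threshold = 0.8,
                           baseline_frames = 5L) {
  n <- length(trace)
  if (n < 10L) stop("detect_flicker: need >= 10 frames", call. = FALSE)
  events <- list()
  base_pool <- trace[seq_len(min(baseline_frames, n))]
  i <- 1L
  in_event <- FALSE
  start <- NA_integer_
  baseline <- stats::median(base_pool)
  while (i <= n) {
    if (!in_event) {
      if (trace[i] < drop_threshold * baseline) {
        in_event <- TRUE
        start <- i
      } else {
        base_pool <- c(base_pool, trace[i])
        if (length(base_pool) > 4 * baseline_frames) {
          base_pool <- base_pool[-1L]
        }
        baseline <- stats::median(base_pool)
      }
    } else if (trace[i] > recovery_threshold * baseline) {
      plateau_frames <- start:(i - 1L)
      events[[length(events) + 1L]] <- .flicker_event(
        start, i, plateau_frames, trace, baseline, frame_interval_s)
      in_event <- FALSE
    }
    i <- i + 1L
  }
  if (in_event) {
    events[[length(events) + 1L]] <- .flicker_event(
      start, NA_integer_, start:n, trace, baseline, frame_interval_s)
  }
  events
}

.flicker_event <- function(start, end, plateau_frames, trace, baseline,
                           dt) {
  plateau <- mean(trace[plateau_frames])
  structure(list(
    t_depol_s = (start - 1L) * dt,
    t_repol_s = if (is.na(end)) NA_real_ else (end - 1L) * dt,
    frames = plateau_frames,
    depth_fraction = 1 - plateau / baseline,
    independent_fraction_est = plateau / baseline,
    baseline = baseline), class = "flicker_event")
}

#' Decompose a flicker into dependent and independent components
#'
#' During a full-depth flicker the remaining signal is the
#' potential-independent (bound) dye; the dependent component is the
#' baseline minus that plateau. Computed per compartment from crista and
#' matrix traces; when both plateaus are given the function also reports
#' their agreement (they should match when the bound fraction is shared).
#'
#' @param crista_trace,matrix_trace Mean-intensity traces of the two
#'   compartments.
#' @param event A `flicker_event` from [detect_flicker()].
#' @param baseline_frames Frames before the event used as baseline.
#' @return List with per-compartment `baseline`, `independent` (plateau),
#'   `dependent` and `plateau_agreement` (|crista - matrix| plateau
#'   difference as a fraction of the crista baseline).
#' @export
decompose_flicker <- function(crista_trace, matrix_trace, event,
                              baseline_frames = 5L) {
  if (!inherits(event, "flicker_event")) {
    stop("decompose_flicker: no flicker event supplied", call. = FALSE)
  }
  if (length(event$frames) < 2L) {
    stop("decompose_flicker: event too short (< 2 plateau frames)",
         call. = FALSE)
  }
  pre <- seq_len(min(baseline_frames, min(event$frames) - 1L))
  if (!length(pre)) {
    stop("decompose_flicker: no pre-event baseline frames", call. = FALSE)
  }
  out <- lapply(list(crista = crista_trace, matrix = matrix_trace),
                function(tr) {
    base <- mean(tr[pre])
    ind <- mean(tr[event$frames])
    list(baseline = base, independent = ind, dependent = base - ind)
  })
  out$plateau_agreement <- abs(out$crista$independent -
                                 out$matrix$independent) /
    out$crista$baseline
  out
}

#' Within- versus between-crista potential variability
#'
#' `sd_within`: temporal SD of delta-psi(Cr-IBM) per track.
#' `sd_between`: per-frame SD across tracks, averaged over frames. The
#' published observation is that individual cristae are stable over time
#' (small within) while differing from each other (larger between).
#'
#' @param tracks List of `crista_track`s (>= 2, each >= 5 frames).
#' @return List with `sd_within` (per track), `sd_between_per_frame`,
#'   `sd_between` (mean over frames), `mean_sd_within`.
#' @export
crista_variability <- function(tracks) {
  if (length(tracks) < 2L) {
    stop("crista_variability: need >= 2 tracks", call. = FALSE)
  }
  if (any(vapply(tracks, function(tr) sum(is.finite(tr$delta_psi_mv)),
                 integer(1)) < 5L)) {
    stop("crista_variability: each track needs >= 5 frames", call. = FALSE)
  }
  sd_within <- vapply(tracks, function(tr)
    stats::sd(tr$delta_psi_mv[is.finite(tr$delta_psi_mv)]), numeric(1))
  frames <- sort(unique(unlist(lapply(tracks, `[[`, "frames"))))
  sd_between_per_frame <- vapply(frames, function(fr) {
    vals <- vapply(tracks, function(tr) {
      k <- match(fr, tr$frames)
      if (is.na(k)) NA_real_ else tr$delta_psi_mv[k]
    }, numeric(1))
    vals <- vals[is.finite(vals)]
    if (length(vals) >= 2L) stats::sd(vals) else NA_real_
  }, numeric(1))
  list(sd_within = sd_within,
       mean_sd_within = mean(sd_within),
       sd_between_per_frame = sd_between_per_frame,
       sd_between = mean(sd_between_per_frame, na.rm = TRUE))
}

#' Split cristae into polarized and depolarized sets during an event
#'
#' During the event frames a crista counts as depolarized when its
#' delta-psi(Cr-IBM) falls below `frac` of its own pre-event baseline.
#'
#' @param tracks List of `crista_track`s.
#' @param event_frames Integer frames of the event.
#' @param frac Depolarization threshold as fraction of baseline.
#' @return List with `depolarized` / `polarized` (track ids), per-track
#'   `event_mean_mv` and `baseline_mv`, and `contrast_mv` (mean polarized
#'   minus mean depolarized delta-psi during the event).
#' @export
detect_partial_depolarization <- function(tracks, event_frames, frac = 0.3) {
  stats_per <- lapply(tracks, function(tr) {
    pre <- tr$delta_psi_mv[!(tr$frames %in% event_frames)]
    dur <- tr$delta_psi_mv[tr$frames %in% event_frames]
    base <- mean(pre[is.finite(pre)])
    evm <- mean(dur[is.finite(dur)])
    list(id = tr$track_id, baseline = base, event_mean = evm,
         depol = is.finite(evm) && is.finite(base) && evm < frac * base)
  })
  dep <- vapply(stats_per, `[[`, logical(1), "depol")
  ids <- vapply(stats_per, `[[`, integer(1), "id")
  evm <- vapply(stats_per, `[[`, numeric(1), "event_mean")
  list(depolarized = ids[dep], polarized = ids[!dep],
       baseline_mv = vapply(stats_per, `[[`, numeric(1), "baseline"),
       event_mean_mv = evm,
       contrast_mv = if (any(dep) && any(!dep))
         mean(evm[!dep]) - mean(evm[dep]) else NA_real_)
}

#' Quantify a laser-induced depolarization wave
#'
#' From the per-frame potentiometric axial profiles of one object:
#' \enumerate{
#'   \item proximal (arclength within `wave_proximal_um` of the site) and
#'     distal (beyond `wave_distal_um`, or beyond 0.6 x length for shorter
#'     objects) band means per frame, normalized to the pre-onset
#'     baseline;
#'   \item front position per frame: the farthest arclength such that the
#'     contiguous stretch from the site has fallen below
#'     `wave_front_frac` of baseline;
#'   \item front speed by least-squares fit of front position against
#'     time over frames where the front is advancing;
#'   \item class: `instantaneous` when >= 90% of the axis is depolarized
#'     within one frame of onset, `wavelike` when the front needs >= 2
#'     frames to cross, `none` otherwise.
#' }
#'
#' @param results An `mv_results` from [analyze_stack()].
#' @param site_um Axial position of the perturbation (um, along the
#'   frame-1 axis).
#' @param t0_s Onset time in seconds.
#' @param object Object index in `results$detail`.
#' @param config An `mv_config`.
#' @return A `wave_event`: `site_um`, `t0_s`, `front_position_um`,
#'   `speed_um_per_s`, `class`, `proximal`, `distal` (normalized traces),
#'   `frames_crossing`.
#' @export
analyze_wave <- function(results, site_um, t0_s, object = 1L,
                         config = default_config()) {
  det <- results$detail[[object]]
  arc <- det$arclength_um
  prof <- det$profiles_pot
  nt <- nrow(prof)
  dt <- results$frame_interval_s
  onset_frame <- as.integer(ceiling(t0_s / dt - 1e-9)) + 1L
  if (onset_frame < 1L || onset_frame > nt) {
    stop("analyze_wave: onset frame outside series", call. = FALSE)
  }
  pre <- max(1L, onset_frame - config$baseline_frames):max(1L, onset_frame - 1L)
  baseline <- colMeans(prof[pre, , drop = FALSE])
  baseline[baseline <= 0] <- NA_real_
  norm <- sweep(prof, 2L, baseline, `/`)
  dist_from_site <- abs(arc - site_um)
  L <- max(arc)

  prox_sel <- dist_from_site <= config$wave_proximal_um
  distal_cut <- if (L - min(dist_from_site) >= config$wave_distal_um)
    config$wave_distal_um else 0.6 * L   # fallback for short objects
  dist_sel <- dist_from_site >= distal_cut
  proximal <- rowMeans(norm[, prox_sel, drop = FALSE], na.rm = TRUE)
  distal <- rowMeans(norm[, dist_sel, drop = FALSE], na.rm = TRUE)

  ## front: contiguous depolarized run starting at the site
  ord <- order(dist_from_site)
  front <- vapply(seq_len(nt), function(t) {
    below <- norm[t, ord] < config$wave_front_frac
    below[!is.finite(below)] <- FALSE
    run <- which(!below)
    if (!length(run)) return(max(dist_from_site))
    if (run[1L] == 1L) return(0)
    dist_from_site[ord][run[1L] - 1L]
  }, numeric(1))
  front[seq_len(min(onset_frame - 1L, nt))] <- 0

  max_reach <- max(dist_from_site)
  crossing <- which(front > 0 & front < 0.95 * max_reach)
  crossing <- crossing[crossing >= onset_frame]
  frac_depol_next <- {
    t1 <- min(onset_frame + 1L, nt)
    mean(norm[t1, ] < config$wave_front_frac, na.rm = TRUE)
  }
  speed <- if (length(crossing) >= 2L) {
    unname(stats::coef(stats::lm(front[crossing] ~
                                   I((crossing - 1L) * dt)))[2L])
  } else if (length(crossing) == 1L) {
    front[crossing] / ((crossing - onset_frame) * dt + dt / 2)
  } else NA_real_
  cls <- if (frac_depol_next >= 0.9 && length(crossing) < 2L)
    "instantaneous"
  else if (length(crossing) >= 2L) "wavelike"
  else if (frac_depol_next >= 0.9) "instantaneous"
  else "none"
  structure(list(site_um = site_um, t0_s = t0_s,
                 front_position_um = front, speed_um_per_s = speed,
                 class = cls, proximal = proximal, distal = distal,
                 frames_crossing = crossing), class = "wave_event")
}
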