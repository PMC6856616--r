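## Synthetic detection tables (no imaging) for the tracker.
make_detections <- function(pos_by_frame) {
  do.call(rbind, lapply(seq_along(pos_by_frame), function(fr) {
    p <- pos_by_frame[[fr]]
    if (!length(p)) return(NULL)
    data.frame(frame = fr, crista_id = seq_along(p), position_um = p,
               delta_psi_cr_ibm_mv = 10)
  }))
}

test_that("crista tracking links, drifts, gaps and breaks ties", {
  ## static detections: one track per crista, full length
  static <- make_detections(rep(list(c(1, 1.5, 2)), 6))
  tr <- track_cristae(static)
  expect_length(tr, 3L)
  expect_true(all(vapply(tr, function(t) length(t$frames), integer(1)) == 6))

  ## uniform drift within the jump limit: single monotone track
  drift <- make_detections(lapply(0:9, function(k) 1 + k * 0.04))
  tr_d <- track_cristae(drift)
  expect_length(tr_d, 1L)
  expect_true(all(diff(tr_d[[1]]$position_um) > 0))

  ## a gap of one frame is bridged; a long gap starts a new track
  gappy <- make_detections(list(1, 1, numeric(0), 1, 1))
  expect_length(track_cristae(gappy, max_gap = 2L), 1L)
  expect_length(track_cristae(gappy, max_gap = 0L), 2L)

  ## near-crossing: assignment minimizes total displacement
  crossing <- make_detections(list(c(1.00, 1.10), c(1.04, 1.06)))
  tr_x <- track_cristae(crossing)
  expect_length(tr_x, 2L)
  expect_equal(tr_x[[1]]$position_um, c(1.00, 1.04))
  expect_equal(tr_x[[2]]$position_um, c(1.10, 1.06))
})

test_that("flicker detection finds events and measures their depth", {
  expect_length(detect_flicker(rep(100, 20)), 0L)
  expect_error(detect_flicker(rep(100, 5)), "frames")

  ## two sequential synthetic flickers, correct order and depth
  tr <- c(rep(100, 6), rep(20, 4), rep(100, 5), rep(40, 3), rep(100, 4))
  ev <- detect_flicker(tr, frame_interval_s = 1)
  expect_length(ev, 2L)
  expect_lt(ev[[1]]$t_depol_s, ev[[2]]$t_depol_s)
  expect_equal(ev[[1]]$depth_fraction, 0.8, tolerance = 1e-6)
  expect_equal(ev[[2]]$depth_fraction, 0.6, tolerance = 1e-6)

  ## simulated full-depth flicker with 15% bound dye: measured
  ## potential-dependent loss 0.85 +/- 0.03 (the published decomposition)
  sim <- simulate_timelapse(preset_scenario("flicker", seed = 3))
  res <- quiet_analyze(sim$stack, mv_config(calibrate_contrast = FALSE))
  evs <- detect_flicker(res$detail[[1]]$trace, 0.5)
  expect_length(evs, 1L)
  expect_equal(evs[[1]]$depth_fraction, 0.85, tolerance = 0.03 / 0.85)
  expect_equal(evs[[1]]$t_depol_s, 9, tolerance = 0.15)
  expect_equal(evs[[1]]$t_repol_s, 16, tolerance = 0.15)
})

test_that("flicker decomposition splits dependent and independent dye", {
  base <- c(rep(100, 5), rep(15, 6), rep(100, 5))
  ev <- detect_flicker(base, 1)[[1]]
  dc <- decompose_flicker(base, base * 0.6, ev)
  expect_equal(dc$crista$independent, 15)
  expect_equal(dc$crista$dependent, 85)
  expect_error(decompose_flicker(base, base, "not an event"), "event")

  ## simulated shared bound fraction: crista and matrix plateaus agree
  sim <- simulate_timelapse(preset_scenario("flicker", seed = 5))
  res <- quiet_analyze(sim$stack, mv_config(calibrate_contrast = FALSE))
  det <- res$detail[[1]]
  ev2 <- detect_flicker(det$trace, 0.5)[[1]]
  dc2 <- decompose_flicker(det$compartment_traces[, "crista"],
                           det$compartment_traces[, "matrix"], ev2)
  expect_lt(dc2$plateau_agreement, 0.05)
})

test_that("within-crista variability is below between-crista variability", {
  set.seed(21)
  mk_track <- function(id, mu) structure(
    list(track_id = id, frames = 1:12, position_um = rep(id, 12),
         delta_psi_mv = rnorm(12, mu, 1),
         mean_delta_psi_mv = mu, sd_over_time_mv = 1),
    class = "crista_track")
  tracks <- Map(mk_track, 1:4, c(5, 5, 12, 12))
  v <- crista_variability(tracks)
  expect_equal(v$mean_sd_within, 1, tolerance = 0.4)
  ## sd({5,5,12,12}) = 3.5 (population) to 4.04 (sample), jitter-inflated
  expect_gt(v$sd_between, 3)
  expect_lt(v$sd_between, 5)
  expect_gt(v$sd_between, v$mean_sd_within)

  const <- Map(function(id) structure(
    list(track_id = id, frames = 1:6, position_um = rep(id, 6),
         delta_psi_mv = rep(8, 6), mean_delta_psi_mv = 8,
         sd_over_time_mv = 0), class = "crista_track"), 1:3)
  v0 <- crista_variability(const)
  expect_equal(v0$mean_sd_within, 0)
  expect_equal(v0$sd_between, 0)
  expect_error(crista_variability(const[1]), "tracks")
})

test_that("partial depolarization recovers the targeted crista set", {
  sim <- simulate_timelapse(preset_scenario("partial", seed = 5))
  res <- quiet_analyze(sim$stack)
  tracks <- track_cristae(res$cristae)
  expect_length(tracks, 4L)
  ## event 6-12 s at 0.5 s/frame: frames 13..24
  pd <- detect_partial_depolarization(tracks, event_frames = 13:24)
  expect_setequal(pd$depolarized, c(2L, 4L))
  expect_setequal(pd$polarized, c(1L, 3L))
  expect_gt(pd$contrast_mv, 5)

  ## no event frames in range: everything polarized
  pd0 <- detect_partial_depolarization(tracks, event_frames = integer(0))
  expect_length(pd0$depolarized, 0L)
})

test_that("wave analysis recovers speed and classifies by frame rate", {
  cfg <- mv_config(calibrate_contrast = FALSE)
  base <- preset_scenario("wave", seed = 8)

  ## moderate speed at fast acquisition: wavelike, speed within 20%
  res5 <- quiet_analyze(simulate_timelapse(base)$stack, cfg)
  wv5 <- analyze_wave(res5, site_um = 0.5, t0_s = 3, config = cfg)
  expect_equal(wv5$class, "wavelike")
  expect_equal(wv5$speed_um_per_s, 5, tolerance = 0.2)
  ## first post-onset frame: proximal collapsed, distal still polarized
  post <- min(wv5$frames_crossing)
  expect_lte(wv5$proximal[post], 0.5)
  expect_gte(wv5$distal[post], 0.9)

  ## near-instantaneous physics: classified instantaneous, prox ~ dist
  sc_fast <- scenario_update(base, events = list(
    sim_event("wave", 3, 12, site_um = 0.5, speed_um_per_s = 100,
              depth = 1)))
  res_f <- quiet_analyze(simulate_timelapse(sc_fast)$stack, cfg)
  wv_f <- analyze_wave(res_f, site_um = 0.5, t0_s = 3, config = cfg)
  expect_equal(wv_f$class, "instantaneous")
  t1 <- 12L  # first frame after onset
  expect_lt(abs(wv_f$proximal[t1] - wv_f$distal[t1]), 0.15)

  ## the same 2 um/s physics: wavelike at 0.3 s frames, instantaneous at
  ## 5 s frames (temporal resolution masks the wave)
  sc_slowframe <- scenario_update(base, frame_interval_s = 5, n_frames = 6,
                                  events = list(sim_event(
                                    "wave", 6, 25, site_um = 0.5,
                                    speed_um_per_s = 2, depth = 1)))
  res_sf <- quiet_analyze(simulate_timelapse(sc_slowframe)$stack, cfg)
  wv_sf <- analyze_wave(res_sf, site_um = 0.5, t0_s = 6, config = cfg)
  expect_equal(wv_sf$class, "instantaneous")

  sc_fastframe <- scenario_update(base, events = list(sim_event(
    "wave", 3, 12, site_um = 0.5, speed_um_per_s = 2, depth = 1)))
  res_ff <- quiet_analyze(simulate_timelapse(sc_fastframe)$stack, cfg)
  wv_ff <- analyze_wave(res_ff, site_um = 0.5, t0_s = 3, config = cfg)
  expect_equal(wv_ff$class, "wavelike")
  expect_equal(wv_ff$speed_um_per_s, 2, tolerance = 0.2)

  ## front positions never retreat while the wave runs
  fr <- wv_ff$front_position_um
  run <- seq(min(wv_ff$frames_crossing), max(wv_ff$frames_crossing))
  expect_true(all(diff(fr[run]) >= -1e-9))

  expect_error(analyze_wave(res_ff, 0.5, t0_s = 1e4), "onset")
})
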