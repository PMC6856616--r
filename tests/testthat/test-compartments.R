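## One shared noise-free control-like phantom for several blocks.
sim_nf <- simulate_timelapse(tiny_scenario(), noise = FALSE)
res_nf <- quiet_analyze(sim_nf$stack)

test_that("axial profiles behave on constant and structured frames", {
  det <- res_nf$detail[[1]]
  const <- matrix(7, nrow(det$mito$mask), ncol(det$mito$mask))
  prof <- axial_profile(const, det$mito, det$axis, 2L)
  expect_true(all(abs(prof$intensity - 7) < 1e-12))
  expect_error(axial_profile(const, det$mito,
                             list(rows = 1L, cols = 1L, arclength_um = 0),
                             2L),
               "axis")

  ## peaks at ground-truth crista columns (noise-free), +/- 1 px
  dc <- detected_cols(res_nf)
  expect_equal(length(dc), 5L)
  expect_true(all(vapply(sim_nf$truth$registry$col,
                         function(x) min(abs(dc - x)) <= 1, logical(1))))

  ## band half-width 0 vs 2: same peak positions on the noise-free phantom
  s1 <- subtract_background(sim_nf$stack$pixels[1, 1, , ], 50)
  p0 <- axial_profile(s1, det$mito, det$axis, 0L)
  p2 <- axial_profile(s1, det$mito, det$axis, 2L)
  c0 <- detect_cristae(p0, pixel_size_nm = 40)
  c2 <- detect_cristae(p2, pixel_size_nm = 40)
  expect_equal(c0$axis_idx, c2$axis_idx)
})

test_that("crista detection is robust, sparse when structure is lost", {
  ## flat profile: no cristae
  flat <- list(arclength_um = seq(0, 2, by = 0.04),
               intensity = rep(5, 51), pixel_axis_idx = NULL)
  expect_equal(nrow(detect_cristae(flat)), 0L)

  ## default-noise phantom: all cristae found within 1 px over seeds
  hits <- vapply(1:3, function(s) {
    sim <- simulate_timelapse(tiny_scenario(rng_seed = s))
    res <- quiet_analyze(sim$stack)
    dc <- detected_cols(res)
    length(dc) == 5L &&
      all(vapply(sim$truth$registry$col,
                 function(x) min(abs(dc - x)) <= 1, logical(1)))
  }, logical(1))
  expect_true(all(hits))

  ## fewer cristae detected when the scenario has fewer (KO-like)
  sim_ko <- simulate_timelapse(preset_scenario("mic13_ko", seed = 1))
  res_ko <- quiet_analyze(sim_ko$stack)
  expect_lt(nrow(res_ko$detail[[1]]$cristae), 5L)
  expect_equal(nrow(res_ko$detail[[1]]$cristae), 3L)
})

test_that("peak positions are equivariant under translation and rotation", {
  sim <- simulate_timelapse(tiny_scenario(rng_seed = 11))
  base <- quiet_analyze(sim$stack)
  dc <- sort(detected_cols(base))

  px <- sim$stack$pixels
  ## translate by 6 columns
  shifted <- px
  shifted[, , , ] <- 0
  shifted[, , , 7:dim(px)[4]] <- px[, , , 1:(dim(px)[4] - 6)]
  st_sh <- frame_stack(shifted, 40, 0.5, c("struct", "pot"))
  expect_equal(sort(detected_cols(quiet_analyze(st_sh))), dc + 6,
               tolerance = 1e-9)

  ## 180 degree rotation
  rot <- px
  for (t in 1:dim(px)[1]) for (c in 1:2) {
    rot[t, c, , ] <- px[t, c, rev(seq_len(dim(px)[3])),
                        rev(seq_len(dim(px)[4]))]
  }
  st_rot <- frame_stack(rot, 40, 0.5, c("struct", "pot"))
  expect_equal(sort(detected_cols(quiet_analyze(st_rot))),
               sort(dim(px)[4] + 1 - dc), tolerance = 1e-9)
})

test_that("pixel classification partitions the object and matches truth", {
  cls <- res_nf$detail[[1]]$classification
  codes <- compartment_labels()
  ## labels partition the object pixels exactly
  obj_px <- res_nf$detail[[1]]$mito$pixels
  expect_true(all(cls$labels[obj_px] %in%
                    codes[c("cytosol", "matrix", "ibm", "crista",
                            "vesicle")]))
  expect_true(all(cls$labels[-obj_px] == codes[["background"]]))

  ## noise-free agreement with ground truth >= 90% per class
  rec <- label_recall(res_nf, sim_nf$truth)
  expect_true(all(rec >= 0.9))

  ## zero cristae: interior is matrix only
  sim0 <- simulate_timelapse(tiny_scenario(n_cristae = 0), noise = FALSE)
  res0 <- quiet_analyze(sim0$stack)
  lab0 <- res0$detail[[1]]$classification$labels
  expect_false(any(lab0 == codes[["crista"]]))
  expect_gt(sum(lab0 == codes[["matrix"]]), 0)
})

test_that("vesicle detection obeys brightness, size and detachment rules", {
  ## control: none
  expect_length(res_nf$detail[[1]]$vesicles, 0L)

  ## mic10 KO: exactly the simulated vesicle
  simv <- simulate_timelapse(preset_scenario("mic10_ko", seed = 2))
  resv <- quiet_analyze(simv$stack)
  expect_length(resv$detail[[1]]$vesicles, 1L)
  codes <- compartment_labels()
  tru_v <- which(simv$truth$labels == codes[["vesicle"]])
  est_v <- resv$detail[[1]]$vesicles[[1]]
  expect_gt(length(intersect(est_v, tru_v)) / length(tru_v), 0.5)

  ## an equally bright blob touching the IBM is rejected (attached)
  det <- res_nf$detail[[1]]
  cls <- det$classification
  frame <- sim_nf$stack$pixels[1, 2, , ]
  ibm_px <- which(cls$labels == codes[["ibm"]])
  ny <- nrow(frame)
  seed_px <- ibm_px[1] + ny  # one column inward from an IBM pixel
  blob <- c(seed_px, seed_px + ny, seed_px + 1, seed_px + ny + 1,
            seed_px + 2, seed_px + ny + 2, seed_px + 3, seed_px + ny + 3)
  frame2 <- frame
  frame2[blob] <- max(frame) * 10
  out <- detect_vesicles(frame2, cls, 40)
  expect_length(out$vesicles, 0L)
})

test_that("profile correlation is Pearson with a zero-variance guard", {
  a <- c(1, 3, 2, 5, 4)
  expect_equal(profile_correlation(a, a), 1)
  expect_equal(profile_correlation(a, -a + 10), -1)
  expect_true(is.na(profile_correlation(rep(1, 5), a)))
  expect_error(profile_correlation(a, 1:4), "length")
  set.seed(123)
  r <- profile_correlation(rnorm(1000), rnorm(1000))
  expect_lt(abs(r), 0.1)
  ## structural and potentiometric profiles co-vary on phantoms
  det <- res_nf$detail[[1]]
  expect_gt(profile_correlation(det$profiles_struct[1, ],
                                det$profiles_pot[1, ]), 0.5)
})
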