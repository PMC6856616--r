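codes <- compartment_labels()

test_that("build_geometry draws the stated compartments", {
  ## no cristae, no vesicles: only cytosol / IBM / matrix
  g0 <- build_geometry(tiny_scenario(n_cristae = 0))
  expect_setequal(unique(as.vector(g0$labels)),
                  codes[c("cytosol", "ibm", "matrix")])

  ## 10 cristae at 0.3 um / 40 nm px: 10 disjoint components, centers
  ## 7-8 px apart
  g <- build_geometry(sim_scenario(length_um = 6, n_cristae = 10,
                                   crista_spacing_um = 0.3))
  comp <- mitovolt:::cpp_label(g$labels == codes[["crista"]])
  expect_equal(max(comp), 10L)
  centers <- sort(g$registry$col)
  expect_true(all(diff(centers) %in% 7:8))

  ## vesicle: one component, no pixel 8-adjacent to IBM
  gv <- build_geometry(tiny_scenario(n_cristae = 0, vesicles = list(
    list(position_um = 2, radius_um = 0.1, psi_offset_mv = 20))))
  vmask <- gv$labels == codes[["vesicle"]]
  expect_equal(max(mitovolt:::cpp_label(vmask)), 1L)
  grown <- mitovolt:::.dilate8(vmask)
  expect_false(any(grown & (gv$labels == codes[["ibm"]])))

  ## vesicle overlapping the IBM is rejected
  expect_error(build_geometry(tiny_scenario(n_cristae = 0, vesicles = list(
    list(position_um = 2, radius_um = 0.39, psi_offset_mv = 20)))),
    "vesicle")
})

test_that("equilibrium dye map is Nernstian", {
  sc <- tiny_scenario(n_cristae = 0, psi_matrix_mv = 0, psi_ibm_offset_mv = 0,
                      independent_fraction = 0)
  g <- build_geometry(sc)
  maps <- equilibrium_dye_map(g, sc)
  expect_true(all(abs(maps$pot - 1) < 1e-12))

  ## 61.54 mV at 310.15 K is one concentration decade
  sc10 <- tiny_scenario(n_cristae = 0, psi_matrix_mv = 61.54,
                        psi_ibm_offset_mv = 0, independent_fraction = 0)
  g10 <- build_geometry(sc10)
  m10 <- equilibrium_dye_map(g10, sc10)
  ratio <- m10$pot[g10$labels == codes[["matrix"]]][1] /
    m10$pot[g10$labels == codes[["cytosol"]]][1]
  expect_equal(ratio, 10, tolerance = 1e-3)

  ## 25.85 mV crista-IBM offset: concentration ratio exp(25.85/kappa) ~ 2.63
  sc_cr <- tiny_scenario(psi_crista_offset_mv = 25.85,
                         independent_fraction = 0)
  g_cr <- build_geometry(sc_cr)
  m_cr <- equilibrium_dye_map(g_cr, sc_cr)
  r <- m_cr$pot[g_cr$crista_pixels[[1]][1]] /
    m_cr$pot[g_cr$labels == codes[["ibm"]]][1]
  expect_equal(r, 2.63, tolerance = 5e-3)

  expect_error(equilibrium_dye_map(g_cr, sc_cr,
                                   psi = matrix(NaN, nrow(g_cr$labels),
                                                ncol(g_cr$labels))),
               "non-finite")
})

test_that("noise-free crista/IBM intensity ratio is monotone in the offset", {
  ratios <- vapply(c(5, 10, 20), function(off) {
    sc <- tiny_scenario(psi_crista_offset_mv = off, independent_fraction = 0)
    sim <- simulate_timelapse(sc, noise = FALSE)
    g <- sim$truth$geometry
    pot <- sim$stack$pixels[1, 2, , ]
    mean(pot[unlist(g$crista_pixels)]) /
      mean(pot[g$labels == codes[["ibm"]]])
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("rendering preserves constants, is deterministic, conserves signal", {
  sc <- tiny_scenario()
  const <- matrix(3.7, 40, 60)
  blurred <- render_frame(const, sc, noise = FALSE)
  expect_equal(blurred, const * sc$photons_per_unit, tolerance = 1e-12)

  f1 <- { set.seed(9); render_frame(const, sc) }
  f2 <- { set.seed(9); render_frame(const, sc) }
  expect_identical(f1, f2)
  expect_error(render_frame(matrix(Inf, 4, 4), sc), "non-finite")

  ## identical scenario + seed: identical stack bytes
  s1 <- simulate_timelapse(tiny_scenario())
  s2 <- simulate_timelapse(tiny_scenario())
  expect_identical(serialize(s1$stack$pixels, NULL),
                   serialize(s2$stack$pixels, NULL))

  ## no events: noise-free total signal constant across frames
  simn <- simulate_timelapse(tiny_scenario(n_frames = 4), noise = FALSE)
  sums <- apply(simn$stack$pixels[, 2, , ], 1, sum)
  expect_lt(max(abs(sums - sums[1])), 1e-6 * sums[1])
})

test_that("flicker plateau retains the independent fraction of baseline", {
  sc <- tiny_scenario(independent_fraction = 0.15, n_frames = 20,
                      frame_interval_s = 0.5,
                      events = list(sim_event("flicker", t_start_s = 3,
                                              t_end_s = 8, depth = 1)))
  sim <- simulate_timelapse(sc, noise = FALSE)
  g <- sim$truth$geometry
  cr_px <- unlist(g$crista_pixels)
  baseline <- mean(sim$stack$pixels[2, 2, , ][cr_px])
  plateau <- mean(sim$stack$pixels[10, 2, , ][cr_px])
  ## ~85% of the potentiometric signal is lost; ~15% (bound dye) remains
  ## 0.01 absolute: the residual free dye at psi = 0 adds ~ 0.3%
  expect_equal(plateau / baseline, 0.15, tolerance = 0.01 / 0.15)
})

test_that("wave events produce intermediate partially-depolarized frames", {
  sc <- sim_scenario(length_um = 10, n_cristae = 0, n_frames = 14,
                     frame_interval_s = 0.3,
                     events = list(sim_event("wave", t_start_s = 0.3,
                                             t_end_s = 4, site_um = 0,
                                             speed_um_per_s = 5, depth = 1)))
  sim <- simulate_timelapse(sc, noise = FALSE)
  g <- sim$truth$geometry
  mat <- g$labels == codes[["matrix"]]
  ax <- g$axial_um
  prox <- mat & !is.na(ax) & ax < 4
  dist <- mat & !is.na(ax) & ax > 6
  base_p <- mean(sim$stack$pixels[1, 2, , ][prox])
  base_d <- mean(sim$stack$pixels[1, 2, , ][dist])
  half_depol <- vapply(seq_len(14), function(t) {
    f <- sim$stack$pixels[t, 2, , ]
    mean(f[prox]) / base_p < 0.5 && mean(f[dist]) / base_d > 0.9
  }, logical(1))
  expect_gte(sum(half_depol), 2L)
})
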