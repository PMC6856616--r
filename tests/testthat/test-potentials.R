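test_that("the Nernstian slope and conversion reproduce physical constants", {
  expect_equal(nernst_kappa(310.15), 26.73, tolerance = 0.01 / 26.73)
  expect_equal(nernst_delta_psi(100, 100), 0)
  x <- 37.3
  expect_equal(nernst_delta_psi(x * exp(1), x), 26.73, tolerance = 4e-4)
  expect_equal(nernst_delta_psi(1000, 100), 61.54, tolerance = 4e-4)
  expect_error(nernst_delta_psi(-1, 10), "compartment a")
  expect_error(nernst_delta_psi(10, 0), "compartment b")
})

test_that("Nernst analytics: antisymmetry, additivity, scale invariance", {
  set.seed(7)
  for (i in 1:20) {
    fis <- runif(3, 1, 1e4)
    expect_identical(nernst_delta_psi(fis[1], fis[2]),
                     -nernst_delta_psi(fis[2], fis[1]))
    expect_lt(abs(nernst_delta_psi(fis[1], fis[3]) -
                    nernst_delta_psi(fis[1], fis[2]) -
                    nernst_delta_psi(fis[2], fis[3])), 1e-9)
    g <- runif(1, 0.1, 50)
    expect_equal(nernst_delta_psi(g * fis[1], g * fis[2]),
                 nernst_delta_psi(fis[1], fis[2]), tolerance = 1e-12)
  }
})

test_that("independent-fraction correction subtracts and guards", {
  expect_equal(correct_independent_fraction(100, 15), 85)
  expect_equal(correct_independent_fraction(100, 0), 100)
  expect_warning(out <- correct_independent_fraction(10, 15), "flagged")
  expect_true(is.na(out))
})

test_that("whole-frame gain leaves potential differences unchanged", {
  sim <- simulate_timelapse(tiny_scenario(), noise = FALSE)
  res1 <- quiet_analyze(sim$stack)
  px3 <- sim$stack$pixels * 3
  res3 <- quiet_analyze(frame_stack(px3, 40, 0.5, c("struct", "pot")))
  ## identical up to segmentation/rolling-ball discretization (< 0.01 mV)
  expect_equal(res3$cristae$delta_psi_raw_mv, res1$cristae$delta_psi_raw_mv,
               tolerance = 1e-3)
})

test_that("uniform-potential phantoms yield a null crista-IBM difference", {
  sc <- tiny_scenario(psi_ibm_offset_mv = 0, psi_crista_offset_mv = 0,
                      independent_fraction = 0)
  sim <- simulate_timelapse(sc, noise = FALSE)
  res <- quiet_analyze(sim$stack,
                       mv_config(reference_mode = "mito_mean",
                                 independent_fraction = 0,
                                 assumed_psi_ibm_offset_mv = 0))
  ## calibrated per-crista values recover the true 0 mV within 1 mV
  expect_lt(max(abs(res$cristae$delta_psi_cr_ibm_mv)), 1)
  ## interior compartments (matrix vs crista) agree; the IBM raw mean is
  ## PSF-diluted toward the cytosol by construction (see vignette), so it
  ## is excluded from this null comparison
  pot <- res$potentials[res$potentials$frame == 1, ]
  expect_lt(abs(pot$delta_psi_mv[pot$compartment == "crista"] -
                  pot$delta_psi_mv[pot$compartment == "matrix"]), 2)
})

test_that("per-crista offsets are recovered in order and magnitude", {
  sc <- tiny_scenario(n_cristae = 4, crista_spacing_um = 0.5,
                      psi_crista_offset_mv = 0,
                      per_crista_offsets_mv = c(5, 5, 12, 12),
                      n_frames = 3)
  sim <- simulate_timelapse(sc, noise = FALSE)
  res <- quiet_analyze(sim$stack)
  agg <- tapply(res$cristae$delta_psi_cr_ibm_mv, res$cristae$crista_id, mean)
  expect_equal(as.numeric(agg), c(5, 5, 12, 12), tolerance = 2 / 5)
  expect_true(all(agg[3:4] > agg[1:2]))
})

test_that("group_compare averages within experiment then applies Student t", {
  out <- group_compare(c(1, 2, 3), c(2, 3, 4))
  expect_equal(out$t, -1.224745, tolerance = 1e-5)
  expect_equal(out$df, 4)
  expect_equal(out$p_value, 0.2879, tolerance = 1e-3)

  same <- group_compare(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  shifted <- group_compare(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1),
                           rep(1:5, 2), rep(1:5, 2))
  expect_lt(shifted$p_value, 0.001)
  expect_equal(shifted$n_exp_a, 5L)

  expect_error(group_compare(1, c(2, 3)), "experiments")

  ## per-experiment averaging matters: replicated values within one
  ## experiment do not inflate degrees of freedom
  out2 <- group_compare(c(1, 1, 2, 3), c(2, 3, 4),
                        experiments_a = c(1, 1, 2, 3))
  expect_equal(out2$df, 4)
})
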