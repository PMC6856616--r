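test_that("rolling-ball background subtraction matches the opening oracle", {
  set.seed(1)
  ## constant image: residual ~ 0
  const <- matrix(80, 40, 50)
  expect_lt(max(abs(subtract_background(const, 15, shrink = 1))), 1e-6 * 80)

  ## bright disk (diameter < radius) on constant background: amplitude
  ## preserved within 5%, and equal to the direct opening oracle
  img <- matrix(20, 50, 60)
  disk <- outer(1:50, 1:60, function(i, j) sqrt((i - 25)^2 + (j - 30)^2)) <= 5
  img[disk] <- 120
  sub <- subtract_background(img, 15, shrink = 1)
  expect_equal(max(sub), 100, tolerance = 0.05)
  oracle <- pmax(img - oracle_rolling_ball(img, 15), 0)
  expect_equal(sub, oracle, tolerance = 1e-10)

  ## tilted plane + disk: plane removed within ball-geometry tolerance
  plane <- outer(1:50, 1:60, function(i, j) 10 + 0.3 * j)
  img2 <- plane
  img2[disk] <- img2[disk] + 100
  sub2 <- subtract_background(img2, 15, shrink = 1)
  oracle2 <- pmax(img2 - oracle_rolling_ball(img2, 15), 0)
  expect_equal(sub2, oracle2, tolerance = 1e-10)
  expect_lt(stats::median(sub2[!disk]), 2.5)  # plane mostly gone
  expect_gt(max(sub2[disk]), 80)

  expect_error(subtract_background(matrix(0, 10, 10), 12), "larger")
})

test_that("subtract_background is idempotent within tolerance", {
  set.seed(2)
  img <- matrix(30 + rnorm(2000, 0, 2), 40, 50)
  once <- subtract_background(img, 15, shrink = 1)
  twice <- subtract_background(once, 15, shrink = 1)
  expect_lt(mean(abs(twice - once)), 1)  # well below the noise SD of 2
})

test_that("the shrink speed-up approximates the exact rolling ball", {
  set.seed(3)
  img <- matrix(50 + rnorm(80 * 90, 0, 3), 80, 90)
  img[30:40, 40:55] <- img[30:40, 40:55] + 200
  exact <- subtract_background(img, 24, shrink = 1)
  fast <- subtract_background(img, 24, shrink = 4)
  expect_lt(mean(abs(exact - fast)), 3)
})

test_that("segmentation reports textbook morphometrics", {
  cfg <- mv_config(min_area_um2 = 0.001, discard_edge_objects = FALSE)
  mk <- function(mask) { f <- matrix(0, nrow(mask), ncol(mask)); f[mask] <- 10; f }

  ## digital disk, radius 50 px: circularity ~ 1 (within digitization)
  d <- outer(1:121, 1:121, function(i, j) sqrt((i - 61)^2 + (j - 61)^2)) <= 50
  obj <- segment_mitochondria(mk(d), 1000, cfg)[[1]]
  expect_gte(obj$circularity, 0.9)
  expect_lte(obj$circularity, 1.1)
  expect_equal(obj$aspect_ratio, 1, tolerance = 0.05)

  ## 100 x 10 px rectangle: circularity 4*pi*1000/220^2 ~ 0.26; AR ~ 10
  r <- matrix(FALSE, 30, 120); r[11:20, 11:110] <- TRUE
  obj2 <- segment_mitochondria(mk(r), 1000, cfg)[[1]]
  expect_equal(obj2$circularity, 0.26, tolerance = 0.05)
  expect_equal(obj2$aspect_ratio, 10, tolerance = 0.5)

  ## empty segmentation: empty list, not an error
  expect_identical(segment_mitochondria(matrix(0, 20, 20), 40, cfg,
                                        threshold = 1), list())
  ## min-area filter removes specks
  sp <- matrix(0, 20, 20); sp[10, 10] <- 10
  expect_identical(segment_mitochondria(sp, 40,
                                        mv_config(min_area_um2 = 0.2)),
                   list())
})

test_that("extract_axis finds the single longest skeleton path", {
  cfg <- mv_config(min_area_um2 = 0.001, discard_edge_objects = FALSE)
  mk <- function(mask) { f <- matrix(0, nrow(mask), ncol(mask)); f[mask] <- 10; f }

  ## straight capsule, 5 um at 40 nm px: arclength 5 +/- 0.2 um minus caps
  g <- build_geometry(sim_scenario(length_um = 5, width_um = 0.6,
                                   n_cristae = 0))
  obj <- segment_mitochondria(mk(g$mask), 40, cfg)[[1]]
  ax <- extract_axis(obj, 40)
  expect_equal(max(ax$arclength_um), 5 - 0.6, tolerance = 0.2)
  expect_false(ax$low_elongation)
  ## canonical orientation: arclength 0 at the leftmost end
  expect_lt(ax$cols[1], ax$cols[length(ax$cols)])

  ## disk: degenerate, flagged low elongation
  d <- outer(1:41, 1:41, function(i, j) sqrt((i - 21)^2 + (j - 21)^2)) <= 15
  objd <- segment_mitochondria(mk(d), 40, cfg)[[1]]
  expect_true(extract_axis(objd, 40)$low_elongation)

  ## L-shaped object: one longest path, no branches, length equal to the
  ## exhaustive longest-path oracle on the same skeleton
  L <- matrix(FALSE, 40, 40)
  L[5:35, 5:7] <- TRUE
  L[33:35, 5:30] <- TRUE
  objL <- segment_mitochondria(mk(L), 1000, cfg)[[1]]
  axL <- extract_axis(objL, 1000)
  steps <- sqrt(diff(axL$rows)^2 + diff(axL$cols)^2)
  expect_true(all(steps %in% c(1, sqrt(2))))  # a path, not a branched set
  skel <- mitovolt:::cpp_thin(objL$mask)
  expect_equal(max(axL$arclength_um), oracle_longest_path(skel),
               tolerance = 1e-9)
})
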