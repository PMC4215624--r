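test_that("prediction with the plant's own kernels equals noiseless simulation", {
  plant <- plant_model(make_ground_truth_stafs(), noise_sigma = 0)
  tri <- make_trisweep(90, n_cycles = 2)
  pred <- predict_response(plant$G_em, plant$G_fm, tri)
  sim <- simulate_response(plant, tri, noiseless = TRUE)
  expect_equal(pred$y, sim$y, tolerance = 1e-12)
})

test_that("initial-position term: zero from front center, asymptote off-center", {
  plant <- plant_model(make_ground_truth_stafs(), noise_sigma = 0)
  g <- display_geometry()
  still <- trajectory(rep(0, 200), rep(0, 200), initial_azimuth = 0)
  expect_equal(predict_response(plant$G_em, plant$G_fm, still)$y,
               rep(0, 200))
  still45 <- trajectory(rep(0, 200), rep(0, 200), initial_azimuth = 45)
  y <- predict_response(plant$G_em, plant$G_fm, still45)$y
  asym <- plant$G_fm$grid[nrow(plant$G_fm$grid), ]
  expected <- sum(asym[match(round((1:12) * g$pixel_pitch, 6),
                             round(plant$G_fm$azimuth_axis, 6))])
  expect_equal(y[200], expected, tolerance = 1e-9)
  # mirrored start gives the sign-flipped steps along the other arc
  still_m <- trajectory(rep(0, 200), rep(0, 200), initial_azimuth = -45)
  ym <- predict_response(plant$G_em, plant$G_fm, still_m)$y
  expected_m <- -sum(asym[match(round(-(1:12) * g$pixel_pitch, 6),
                                round(plant$G_fm$azimuth_axis, 6))])
  expect_equal(ym[200], expected_m, tolerance = 1e-9)
})

test_that("prediction is linear in STAF amplitude and in the step trace", {
  plant1 <- fix_flat_plant()
  plant2 <- fix_flat_plant(em_scale = 3, fm_scale = 3)
  tri <- make_trisweep(90)
  y1 <- predict_response(plant1$G_em, plant1$G_fm, tri)$y
  y3 <- predict_response(plant2$G_em, plant2$G_fm, tri)$y
  expect_equal(y3, 3 * y1, tolerance = 1e-12)
  # halving the steps (flat kernels, so position dependence drops out)
  tr_full <- trajectory(c(0, rep(1, 20)), numeric(21))
  tr_half <- trajectory(c(0, rep(0.5, 20)), numeric(21))
  expect_equal(predict_response(plant1$G_em, plant1$G_fm, tr_half)$y,
               0.5 * predict_response(plant1$G_em, plant1$G_fm, tr_full)$y,
               tolerance = 1e-9)
})

test_that("a mirror-symmetric STAF pair negates mirrored trajectories", {
  # the default ground-truth fields are even in azimuth, i.e. the
  # modelled animal is left-right symmetric: flipping both the stimulus
  # path and the step directions about front center must flip the sign
  # of the predicted steering effort
  plant <- plant_model(make_ground_truth_stafs(), noise_sigma = 0)
  steps <- c(0, rep(1, 30), rep(-1, 15))
  tr <- trajectory(steps, steps, initial_azimuth = 30)
  tr_m <- trajectory(-steps, -steps, initial_azimuth = -30)
  y <- predict_response(plant$G_em, plant$G_fm, tr)$y
  ym <- predict_response(plant$G_em, plant$G_fm, tr_m)$y
  expect_equal(ym, -y, tolerance = 1e-9)
})

test_that("constant-rotation sum/difference isolates position and motion parts", {
  plant <- plant_model(make_ground_truth_stafs(), noise_sigma = 0)
  g <- display_geometry()
  n <- 96 * 2   # two full revolutions
  cw <- trajectory(c(0, rep(1, n)), c(0, rep(1, n)), initial_azimuth = 0)
  ccw <- trajectory(c(0, rep(-1, n)), c(0, rep(-1, n)), initial_azimuth = 0)
  y_cw <- predict_response(plant$G_em, plant$G_fm, cw)$y
  y_ccw <- predict_response(plant$G_em, plant$G_fm, ccw)$y
  s <- y_cw + y_ccw
  d <- y_cw - y_ccw
  expect_length(s, n + 1)
  expect_true(all(is.finite(c(s, d))))
  # the difference retains the direction-locked (motion) component
  expect_gt(stats::sd(d), stats::sd(s) * 0.1)
})

test_that("out-of-calibration step sizes warn but still predict", {
  plant <- fix_flat_plant()
  tr <- trajectory(c(0, rep(2, 10)), numeric(11))
  expect_warning(predict_response(plant$G_em, plant$G_fm, tr),
                 "calibration")
  expect_error(predict_response(plant$G_fm, plant$G_em, make_trisweep(45)),
               "EM STAF")
})

test_that("r_squared matches its definition and edge cases", {
  set.seed(31)
  x <- rnorm(300)
  expect_equal(r_squared(x, x), 1)
  y <- 2 * x + rnorm(300)
  expect_equal(r_squared(y, x), stats::cor(x, y)^2, tolerance = 1e-12)
  noise <- rnorm(1e4)
  target <- rnorm(1e4)
  expect_lt(r_squared(noise, target), 0.01)
  expect_error(r_squared(rnorm(10), rep(1, 10)), "constant")
  expect_error(r_squared(rnorm(10), rnorm(11)), "equal length")
})

test_that("transfer functions obey DFT identities", {
  gt <- make_ground_truth_stafs()
  tf <- staf_transfer_function(gt$G_em)
  # zero-frequency bin = temporal sum of the kernel, per azimuth
  expect_equal(Re(tf$gain[1, ]), colSums(gt$G_em$grid), tolerance = 1e-9)
  expect_equal(Im(tf$gain[1, ]), rep(0, ncol(gt$G_em$grid)),
               tolerance = 1e-9)
  # Parseval: energy matches between domains
  n_t <- nrow(gt$G_em$grid)
  expect_equal(colSums(abs(tf$gain)^2) / n_t, colSums(gt$G_em$grid^2),
               tolerance = 1e-9)
  # a single-sample impulse kernel has a flat magnitude spectrum
  imp <- staf(matrix(c(1, rep(0, 31)), ncol = 1), (0:31) / 25, 0,
              kind = "EM")
  expect_equal(abs(staf_transfer_function(imp)$gain[, 1]), rep(1, 32))
  expect_error(staf_transfer_function(
    staf(matrix(rnorm(6), 3), c(0, 1, 3), c(0, 10), kind = "EM")),
    "uniform")
})

test_that("trajectories round-trip through CSV + JSON", {
  tr <- trajectory(c(0, 1, 1, -1), c(0, -1, 0, 1), initial_azimuth = 30)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$fm_steps, tr$fm_steps)
  expect_equal(tr2$em_steps, tr$em_steps)
  expect_equal(tr2$initial_azimuth, 30)
})
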