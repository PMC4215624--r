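test_that("identical paired traces give a zero EM kernel; zero traces give zero FM", {
  pair <- fix_pair7()
  y <- rnorm(127 * 2)
  k <- estimate_em_kernel(y, y, pair$m_em)
  expect_equal(k$values, rep(0, 127))
  z <- rep(0, 127 * 2)
  kf <- estimate_fm_kernel(z, z, pair$m_fm)
  expect_equal(kf$values, rep(0, 127))
})

test_that("noiseless EM recovery is exact up to the documented dc term", {
  plant <- fix_flat_plant()
  run <- fix_paired_run(plant)
  truth <- fix_true_columns(plant)
  k <- estimate_em_kernel(run$y1, run$y2, fix_pair7()$m_em,
                          gamma = run$gamma)
  # raw estimate carries the known -sum(g)/(p+1) sequence dc error
  expect_equal(k$values, truth$em - sum(truth$em) / 128, tolerance = 1e-10)
  # exact inversion of that dc term
  k2 <- estimate_em_kernel(run$y1, run$y2, fix_pair7()$m_em,
                           estimation_config(em_dc_correct = TRUE),
                           gamma = run$gamma)
  expect_equal(k2$values, truth$em, tolerance = 1e-10)
})

test_that("an FM-only plant yields a near-zero EM kernel", {
  plant <- fix_flat_plant(em_scale = 0)
  run <- fix_paired_run(plant)
  k <- estimate_em_kernel(run$y1, run$y2, fix_pair7()$m_em,
                          gamma = run$gamma)
  expect_lt(max(abs(k$values)), 1e-10)
})

test_that("dc correction recovers the FM step asymptote; uncorrected sum cancels", {
  plant <- fix_flat_plant()
  run <- fix_paired_run(plant)
  truth <- fix_true_columns(plant)
  A_true <- truth$fm[length(truth$fm)]
  expect_gt(abs(A_true), 0.1)
  # uncorrected cumulative sum nearly cancels by lag p-1 ...
  k_raw <- estimate_fm_kernel(run$y1, run$y2, fix_pair7()$m_fm,
                              estimation_config(dc_method = "none"),
                              gamma = run$gamma)
  expect_lt(abs(k_raw$values[127]), abs(A_true) / 50)
  # ... the closed-form inversion restores it exactly (noiseless)
  k_cf <- estimate_fm_kernel(run$y1, run$y2, fix_pair7()$m_fm,
                             gamma = run$gamma)
  expect_equal(k_cf$values, truth$fm, tolerance = 1e-10)
  expect_equal(k_cf$values[127], A_true, tolerance = 1e-10)
  # the literal window-mean reading under-corrects (the window average
  # of the cumulative sum still carries the accumulating error slope),
  # but it improves on no correction; the closed form beats both
  k_lit <- estimate_fm_kernel(run$y1, run$y2, fix_pair7()$m_fm,
                              estimation_config(dc_method = "literal"),
                              gamma = run$gamma)
  err <- function(k) abs(k$values[127] - A_true)
  expect_lt(err(k_lit), err(k_raw))
  expect_lt(err(k_cf), err(k_lit))
  expect_error(
    estimate_fm_kernel(run$y1, run$y2, fix_pair7()$m_fm,
                       estimation_config(dc_window = c(2, 6))),
    "period")
})

test_that("sign-flip pairing beats unpaired estimation by an order of magnitude", {
  plant <- fix_flat_plant()
  run <- fix_paired_run(plant, start_azimuth = 45)
  truth <- fix_true_columns(plant)
  m_em <- fix_pair7()$m_em
  cfg <- estimation_config(em_dc_correct = TRUE)
  paired <- estimate_em_kernel(run$y1, run$y2, m_em, cfg, gamma = run$gamma)
  # unpaired estimation of the same data: feeding (y1, -y1) makes the
  # estimator reduce to the plain single-run cross-correlation with y1,
  # so the FM-driven component (dc position response and m_FM cross-talk)
  # stays in the estimate
  unpaired <- estimate_em_kernel(run$y1, -run$y1$y, m_em, cfg,
                                 gamma = run$gamma)
  res_paired <- max(abs(paired$values - truth$em))
  res_unpaired <- max(abs(unpaired$values - truth$em))
  expect_lt(res_paired * 10, res_unpaired)
})

test_that("kernel estimates scale linearly with plant gain", {
  run1 <- fix_paired_run(fix_flat_plant())
  run2 <- fix_paired_run(fix_flat_plant(em_scale = 2, fm_scale = 2))
  pair <- fix_pair7()
  e1 <- estimate_em_kernel(run1$y1, run1$y2, pair$m_em, gamma = run1$gamma)
  e2 <- estimate_em_kernel(run2$y1, run2$y2, pair$m_em, gamma = run2$gamma)
  expect_equal(e2$values, 2 * e1$values, tolerance = 1e-10)
  f1 <- estimate_fm_kernel(run1$y1, run1$y2, pair$m_fm, gamma = run1$gamma)
  f2 <- estimate_fm_kernel(run2$y1, run2$y2, pair$m_fm, gamma = run2$gamma)
  expect_equal(f2$values, 2 * f1$values, tolerance = 1e-10)
})

test_that("kernel centroids sit at the mean figure position", {
  plant <- fix_flat_plant()
  run <- fix_paired_run(plant, start_azimuth = 30)
  k <- estimate_em_kernel(run$y1, run$y2, fix_pair7()$m_em,
                          gamma = run$gamma)
  analyzed <- run$gamma[-(1:128)]   # pre-motion frame + transient period
  expect_equal(k$centroid_azimuth,
               atan2(mean(sin(analyzed * pi / 180)),
                     mean(cos(analyzed * pi / 180))) * 180 / pi,
               tolerance = 1e-9)
  # the mean position stays inside the excursion range of the drive
  # (it can sit several pixels from the start azimuth for a given
  # polynomial/seed, but never outside the visited range)
  dev <- abs(wrap_azimuth(analyzed - 30))
  expect_lte(abs(wrap_azimuth(k$centroid_azimuth - 30)), max(dev) + 1e-9)
})

test_that("assemble_staf places, averages and smooths kernels", {
  g <- display_geometry()
  cfg <- estimation_config()
  mk <- function(vals, cent) structure(
    list(values = vals, raw_crosscorr = vals, centroid_azimuth = cent,
         kind = "EM", frame_rate = 25, p = length(vals)),
    class = "staf_kernel")
  # identical kernel everywhere -> constant along azimuth, smoothing no-op
  ks <- lapply(seq(-180 + 15, 180, by = 15), function(a) mk(sin(1:50), a))
  s <- assemble_staf(ks, g, cfg)
  expect_equal(apply(s$grid, 1, stats::sd), rep(0, 50), tolerance = 1e-12)
  expect_equal(s$grid[, 1], sin(1:50))
  # boxcar preserves the azimuthal mean of every time slice (pixel-dense
  # axis so the 4-pixel window spans 4 samples and really smooths)
  ks2 <- lapply(seq(-180 + 3.75, 180, by = 3.75),
                function(a) mk(rnorm(50), a))
  s2 <- assemble_staf(ks2, g, cfg)
  raw <- vapply(ks2, `[[`, numeric(50), "values")
  expect_equal(rowMeans(s2$grid), rowMeans(raw), tolerance = 1e-10)
  expect_gt(max(abs(s2$grid - raw)), 0.1)   # smoothing actually happened
  # repeats at one centroid are averaged
  s3 <- assemble_staf(c(ks, ks), g, cfg)
  expect_equal(s3$grid, s$grid, tolerance = 1e-12)
  expect_error(assemble_staf(list(mk(1:5, 0)), g, cfg), "distinct")
  expect_error(assemble_staf(c(ks[1:2], list(structure(
    list(values = 1:50, centroid_azimuth = 0, kind = "FM", frame_rate = 25,
         p = 50), class = "staf_kernel"))), g, cfg), "kind")
})

test_that("block fit recovers both ground-truth fields end to end (noiseless)", {
  plant <- plant_model(make_ground_truth_stafs(), noise_sigma = 0)
  fit <- staf_fit(plant, azimuth_grid = seq(-180 + 15, 180, by = 15),
                  n_repeats = 1L, config = estimation_config(
                    em_dc_correct = TRUE), seed = 1)
  # compare against ground truth processed with the same smoothing and
  # sampled at the fitted azimuths
  for (kind in c("em", "fm")) {
    est <- fit[[paste0("staf_", kind)]]
    tru <- if (kind == "em") plant$G_em else plant$G_fm
    tru_cols <- vapply(est$azimuth_axis,
                       function(a) tru$grid[, which(tru$azimuth_axis == a)],
                       numeric(nrow(tru$grid)))
    tru_s <- staf_smooth(staf(tru_cols, tru$time_axis, est$azimuth_axis,
                              kind = toupper(kind)), 4)
    # tolerance reflects the spatial-linearization error inherent to the
    # method: a kernel estimated over a period mixes positions across the
    # ~12-degree excursion, weighted by step occurrence rather than the
    # time mean, so steep parts of the spatial envelope shift by a few
    # percent of peak
    scale <- max(abs(tru_s$grid))
    expect_lt(max(abs(est$grid - tru_s$grid)) / scale, 0.15)
  }
})

test_that("EM-only plant gives a near-zero FM STAF through the full fit", {
  plant <- fix_flat_plant(fm_scale = 0)
  fit <- staf_fit(plant, azimuth_grid = c(-45, 0, 45), n_repeats = 1L,
                  seed = 2)
  # noiseless plant: noise_sigma = 0 in fixture
  expect_lt(max(abs(fit$staf_fm$grid)), 1e-9)
  expect_gt(max(abs(fit$staf_em$grid)), 0.5)
})

test_that("block and sliding-window modes agree on one continuous record", {
  plant <- fix_flat_plant()
  pair <- fix_pair7()
  g <- display_geometry()
  r1 <- build_compound_protocol(pair$m_fm, pair$m_em, +1L, 0, g, 6)
  r2 <- build_compound_protocol(pair$m_fm, pair$m_em, -1L, 0, g, 6)
  y1 <- simulate_response(plant, r1, noiseless = TRUE)
  y2 <- simulate_response(plant, r2, noiseless = TRUE)
  runs <- list(list(y1 = y1, y2 = y2, gamma = r1$gamma))
  # centroids cover only the drifted arc, so azimuthal smoothing is
  # skipped (boxcar width 1) rather than warned about
  cfg <- estimation_config(boxcar_width = 1)
  # block segmentation of the record: consecutive single-period windows
  fit_b <- staf_fit(runs, pair$m_fm, pair$m_em, g, mode = "sliding",
                    window_step = 127L, config = cfg)
  # sliding with half-period overlap
  fit_s <- staf_fit(runs, pair$m_fm, pair$m_em, g, mode = "sliding",
                    window_step = 63L, config = cfg)
  # same kernels, possibly different azimuth binning; compare overlap
  common <- intersect(fit_b$staf_em$azimuth_axis, fit_s$staf_em$azimuth_axis)
  expect_gte(length(common), 2)
  for (kind in c("staf_em", "staf_fm")) {
    gb <- fit_b[[kind]]$grid[, match(common, fit_b[[kind]]$azimuth_axis)]
    gs <- fit_s[[kind]]$grid[, match(common, fit_s[[kind]]$azimuth_axis)]
    expect_lt(max(abs(gb - gs)) / max(abs(gb)), 0.1)
  }
})

test_that("fit methods behave: print, summary, coef, predict", {
  plant <- fix_flat_plant()
  fit <- staf_fit(plant, azimuth_grid = c(-30, 0, 30), n_repeats = 1L,
                  seed = 3)
  expect_output(print(fit), "STAF")
  expect_output(print(summary(fit)), "asymptote")
  cf <- coef(fit)
  expect_named(cf, c("EM", "FM"))
  pred <- predict(fit, make_trisweep(45, n_cycles = 1))
  expect_s3_class(pred, "response_trace")
  expect_equal(length(pred$y), 1 + 2 * 45 / 3.75)
})
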