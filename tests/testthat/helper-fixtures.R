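# Shared fixtures: small sequence pairs, plants, and paired-protocol
# simulations used across test files. Everything is generated in code.

fix_geom <- function() display_geometry()

fix_pair7 <- function() list(m_fm = m_sequence(7, primitive_taps(7)[[1]]),
                             m_em = m_sequence(7, primitive_taps(7)[[2]]))

# Ground-truth plant whose kernels do not vary with azimuth (each column
# equals the front-center column): makes noiseless estimation exact, so
# decontamination and dc-correction claims can be tested at float
# tolerance without spatial-linearization error.
fix_flat_plant <- function(noise_sigma = 0, em_scale = 1, fm_scale = 1) {
  gt <- make_ground_truth_stafs(fix_geom())
  j0 <- which.min(abs(gt$G_em$azimuth_axis))
  gt$G_em$grid <- em_scale *
    matrix(gt$G_em$grid[, j0], nrow(gt$G_em$grid), ncol(gt$G_em$grid))
  gt$G_fm$grid <- fm_scale *
    matrix(gt$G_fm$grid[, j0], nrow(gt$G_fm$grid), ncol(gt$G_fm$grid))
  plant_model(gt, noise_sigma = noise_sigma)
}

# One noiseless paired run (+/- texture drive) at a given start azimuth.
fix_paired_run <- function(plant, start_azimuth = 0, n_periods = 2,
                           pair = fix_pair7(), geom = fix_geom()) {
  r1 <- build_compound_protocol(pair$m_fm, pair$m_em, +1L, start_azimuth,
                                geom, n_periods)
  r2 <- build_compound_protocol(pair$m_fm, pair$m_em, -1L, start_azimuth,
                                geom, n_periods)
  list(y1 = simulate_response(plant, r1, noiseless = TRUE),
       y2 = simulate_response(plant, r2, noiseless = TRUE),
       r1 = r1, r2 = r2, gamma = r1$gamma)
}

# Front-center ground-truth kernel columns of a plant.
fix_true_columns <- function(plant) {
  j0 <- which.min(abs(plant$G_em$azimuth_axis))
  list(em = plant$G_em$grid[, j0], fm = plant$G_fm$grid[, j0])
}

# Independent brute-force circular cross-correlation (triple-checked
# oracle for the FFT implementation).
oracle_circ_xcorr <- function(a, b) {
  n <- length(a)
  sapply(0:(n - 1), function(k) sum(a * b[((seq_len(n) - 1 + k) %% n) + 1]))
}

# Independent Benjamini-Hochberg step-up oracle.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= seq_len(m) * q / m)))
  rej <- rep(FALSE, m)
  if (is.finite(k)) rej[p <= ps[k]] <- TRUE
  rej
}
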