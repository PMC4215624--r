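#' Ground-truth STAF pair for the synthetic behavioral plant
#'
#' Builds the two separable kernels that define the simulated fly: an
#' elementary-motion (EM) field `G_em(t, gamma) = A_em(gamma) * alpha(t)`
#' with an alpha-function time course (short onset delay, fast rise,
#' decay to a zero asymptote) and a broad frontal Gaussian spatial
#' envelope; and a figure-motion (FM) field `G_fm(t, gamma) = A_fm(gamma)
#' * s(t)` with a delayed smoothstep time course that saturates exactly at
#' `fm_t_sat` (an incremental step response, persistent at long lags) and
#' a center-surround difference-of-Gaussians spatial profile whose
#' discrete azimuthal sum is exactly zero. These shapes mirror the
#' qualitative structure reported for tethered flight behavior; the
#' amplitudes are fixture values for simulation, not measured quantities.
#'
#' @param geometry A [display_geometry()]; sets the azimuth grid (one
#'   column per display pixel) and the kernel time base.
#' @param n_lags Number of temporal lag samples (default 127, one
#'   7th-order period at 25 Hz).
#' @param em_amplitude Peak EM gain at front center, dWBA per pixel-step.
#' @param em_delay,em_tau EM onset delay and alpha-function time constant
#'   (s); the kernel peaks at `em_delay + em_tau`.
#' @param em_halfwidth Half-width at half maximum of the frontal EM
#'   envelope, degrees.
#' @param fm_amplitude FM center gain scale, dWBA per pixel-step.
#' @param fm_delay,fm_t_sat FM onset delay and exact saturation time (s).
#' @param fm_sigma_center,fm_sigma_surround Center / surround widths of
#'   the FM difference-of-Gaussians, degrees; the surround weight is set
#'   so the azimuthal sum over the pixel grid is exactly zero.
#' @return List with elements `G_em` and `G_fm`, both [staf()] objects.
#' @export
make_ground_truth_stafs <- function(geometry = display_geometry(),
                                    n_lags = 127L,
                                    em_amplitude = 1, em_delay = 0.04,
                                    em_tau = 0.1, em_halfwidth = 60,
                                    fm_amplitude = 1, fm_delay = 0.2,
                                    fm_t_sat = 2,
                                    fm_sigma_center = 50,
                                    fm_sigma_surround = 130) {
  if (em_tau <= 0 || fm_t_sat <= fm_delay)
    stop("time constants must be positive (em_tau > 0, fm_t_sat > fm_delay)")
  fs <- geometry$frame_rate
  t <- (seq_len(n_lags) - 1) / fs
  az <- sort(wrap_azimuth((seq_len(geometry$n_pixels) - 1) *
                            geometry$pixel_pitch))

  # EM: alpha function, peak 1 at em_delay + em_tau
  u <- pmax(0, t - em_delay) / em_tau
  alpha_t <- u * exp(1 - u)
  sig_em <- em_halfwidth / sqrt(2 * log(2))
  a_em <- em_amplitude * exp(-az^2 / (2 * sig_em^2))

  # FM: smoothstep reaching exactly 1 at fm_t_sat (so kernel increments
  # have compact support shorter than one sequence period)
  v <- pmin(1, pmax(0, (t - fm_delay) / (fm_t_sat - fm_delay)))
  step_t <- v^2 * (3 - 2 * v)
  g_c <- exp(-az^2 / (2 * fm_sigma_center^2))
  g_s <- exp(-az^2 / (2 * fm_sigma_surround^2))
  a_fm <- fm_amplitude * (g_c - (sum(g_c) / sum(g_s)) * g_s)

  list(G_em = staf(outer(alpha_t, a_em), t, az, kind = "EM",
                   provenance = list(source = "synthetic ground truth")),
       G_fm = staf(outer(step_t, a_fm), t, az, kind = "FM",
                   provenance = list(source = "synthetic ground truth")))
}

#' Synthetic quasi-linear behavioral plant
#'
#' The plant turns a stimulus realization into a simulated steering trace
#' (dWBA, positive = rightward effort) as the superposition of its two
#' ground-truth kernel fields, plus optional additive Gaussian noise, slow
#' baseline drift and a static output nonlinearity. It exists so every
#' downstream estimation and prediction stage can be validated against a
#' known ground truth without animal data.
#'
#' @param stafs List with `G_em` and `G_fm` [staf()] grids; default
#'   [make_ground_truth_stafs()].
#' @param noise_sigma SD of additive white Gaussian noise on dWBA
#'   (default 0.5: single-run kernel estimates are visibly noisy, 20-run
#'   averages are clean).
#' @param drift_amplitude Amplitude of an optional slow (0.05 Hz,
#'   random-phase) baseline drift; 0 disables it.
#' @param nonlinearity Optional function applied to the noiseless
#'   superposition output (e.g. `tanh`); `NULL` keeps the plant linear.
#' @return An object of class `plant_model`.
#' @export
plant_model <- function(stafs = make_ground_truth_stafs(),
                        noise_sigma = 0.5, drift_amplitude = 0,
                        nonlinearity = NULL) {
  stopifnot(inherits(stafs$G_em, "staf"), inherits(stafs$G_fm, "staf"))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(G_em = stafs$G_em, G_fm = stafs$G_fm,
                 noise_sigma = noise_sigma,
                 drift_amplitude = drift_amplitude,
                 nonlinearity = nonlinearity),
            class = "plant_model")
}

#' @export
print.plant_model <- function(x, ...) {
  cat("two-stream quasi-linear plant\n")
  cat(sprintf("  EM kernel peak %.3g, FM asymptote peak %.3g (dWBA/px-step)\n",
              max(abs(x$G_em$grid)), max(abs(x$G_fm$grid[nrow(x$G_fm$grid), ]))))
  cat(sprintf("  noise sd %.3g, drift %.3g, nonlinearity: %s\n",
              x$noise_sigma, x$drift_amplitude,
              if (is.null(x$nonlinearity)) "none" else "static"))
  invisible(x)
}

new_response_trace <- function(y, frame_rate, alignment = 1L) {
  if (any(!is.finite(y))) stop("response trace must be finite")
  structure(list(y = as.numeric(y), frame_rate = frame_rate,
                 alignment = as.integer(alignment)),
            class = "response_trace")
}

#' @export
print.response_trace <- function(x, ...) {
  cat(sprintf("response trace: %d frames @ %g Hz (%.3g s), dWBA sd %.4g\n",
              length(x$y), x$frame_rate, length(x$y) / x$frame_rate,
              stats::sd(x$y)))
  invisible(x)
}

#' Simulate the plant's steering response to a stimulus
#'
#' Evaluates the discrete two-stream superposition
#' `y(t) = sum_tau [G_fm(t-tau, gamma(tau)) dFM(tau) +
#' G_em(t-tau, gamma(tau)) dEM(tau)]` plus the initial-position term (the
#' FM field summed over one-pixel position increments along the shorter
#' arc from front center to the starting azimuth), then applies the
#' plant's nonlinearity, drift and noise. Kernel values off the stored
#' grids use linear interpolation with circular azimuth wrap; lags beyond
#' the stored time axis hold the terminal kernel value.
#'
#' @param plant A [plant_model()].
#' @param realization A `stimulus_realization` (see
#'   [build_compound_protocol()], [make_trisweep()]).
#' @param geometry A [display_geometry()]; defaults to the realization's.
#' @param noiseless If `TRUE`, skip noise and drift (the deterministic
#'   quasi-linear response).
#' @param rng_seed Optional seed for the noise/drift draw.
#' @return A `response_trace` aligned to the stimulus frames.
#' @export
simulate_response <- function(plant, realization,
                              geometry = realization$geometry,
                              noiseless = FALSE, rng_seed = NULL) {
  stopifnot(inherits(plant, "plant_model"),
            inherits(realization, "stimulus_realization"))
  y <- staf_superpose(plant$G_em, plant$G_fm,
                      realization$delta_fm, realization$delta_em,
                      realization$gamma, realization$start_azimuth,
                      geometry)
  if (!is.null(plant$nonlinearity)) y <- plant$nonlinearity(y)
  if (!noiseless) {
    y <- y + with_seed(rng_seed, {
      T_ <- length(y)
      extra <- stats::rnorm(T_, 0, plant$noise_sigma)
      if (plant$drift_amplitude > 0) {
        ph <- stats::runif(1, 0, 2 * pi)
        extra <- extra + plant$drift_amplitude *
          sin(2 * pi * 0.05 * (seq_len(T_) - 1) / geometry$frame_rate + ph)
      }
      extra
    })
  }
  new_response_trace(y, geometry$frame_rate)
}

#' Write / read a response trace as CSV
#'
#' Columns `frame_index`, `time_s`, `dwba`; full-precision text.
#'
#' @param x A `response_trace`.
#' @param path CSV file path.
#' @export
write_response_trace <- function(x, path) {
  stopifnot(inherits(x, "response_trace"))
  n <- length(x$y)
  lines <- c("frame_index,time_s,dwba",
             sprintf("%d,%s,%s", seq_len(n),
                     fmt_dbl((seq_len(n) - 1) / x$frame_rate),
                     fmt_dbl(x$y)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_response_trace
#' @export
read_response_trace <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("frame_index", "time_s", "dwba") %in% names(d)))
    stop("trace file ", path, " lacks frame_index/time_s/dwba columns")
  if (anyNA(d$dwba)) stop("trace file ", path, " contains missing samples")
  fs <- if (nrow(d) > 1) 1 / (d$time_s[2] - d$time_s[1]) else 25
  new_response_trace(d$dwba, fs)
}
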