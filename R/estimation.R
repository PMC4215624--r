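#' Kernel estimation configuration
#'
#' @param dc_window Two-element time interval (seconds) over which the
#'   cumulative FM cross-correlation is averaged to estimate the kernel
#'   asymptote for dc-error correction. Default 2-5 s, within one
#'   5.08 s period; the FM step response has saturated there so its
#'   slope is ~0.
#' @param normalization Cross-correlation divisor convention. `"p_plus_1"`
#'   (default) divides by p + 1, so a plant that echoes the input steps
#'   with unit gain yields a unit-peak kernel; `"p"` divides by the
#'   period.
#' @param dc_method How the FM dc error is removed. `"closed_form"`
#'   (default) inverts the accumulating error exactly: the raw cumulative
#'   sum obeys `c(k) = g(k) - (k+1) A / (p+1)`, so the asymptote is
#'   `A = mean(c over window) / (1 - (kbar+1)/(p+1))` and
#'   `g(k) = c(k) + (k+1) A / (p+1)`. `"literal"` adds the window-mean
#'   asymptote divided by the period to the differentiated
#'   cross-correlation before integration; `"none"` skips correction
#'   (the uncorrected cumulative sum nearly cancels at lag p-1).
#' @param em_dc_correct Also invert the (small) dc error of the EM
#'   kernel, `g = u + sum(u)`; default `FALSE` (impulse-like kernels
#'   carry a negligible dc term).
#' @param boxcar_width Azimuthal smoothing width in display pixels
#'   applied when kernels are assembled into a STAF (default 4).
#' @param drop_first_period Discard the first period of every run as a
#'   transient before (period-averaged) circular analysis.
#' @return An object of class `estimation_config`.
#' @export
estimation_config <- function(dc_window = c(2, 5),
                              normalization = c("p_plus_1", "p"),
                              dc_method = c("closed_form", "literal", "none"),
                              em_dc_correct = FALSE,
                              boxcar_width = 4,
                              drop_first_period = TRUE) {
  if (length(dc_window) != 2L || dc_window[1] >= dc_window[2] ||
      dc_window[1] < 0)
    stop("dc_window must be an increasing nonnegative time interval")
  if (boxcar_width < 1) stop("boxcar_width must be >= 1 pixel")
  structure(list(dc_window = dc_window,
                 normalization = match.arg(normalization),
                 dc_method = match.arg(dc_method),
                 em_dc_correct = isTRUE(em_dc_correct),
                 boxcar_width = boxcar_width,
                 drop_first_period = isTRUE(drop_first_period)),
            class = "estimation_config")
}

norm_divisor <- function(p, config) {
  if (config$normalization == "p_plus_1") p + 1 else p
}

# Fold a trace into one period: drop the pre-motion frame if present
# (length p*n + 1), optionally drop the transient first period, average
# the remaining periods. Returns a length-p vector.
fold_periods <- function(y, p, config) {
  n <- length(y)
  if (n %% p == 1L) { y <- y[-1L]; n <- n - 1L }
  if (n %% p != 0L)
    stop("trace length ", n, " is not an integer number of periods (p = ",
         p, ")")
  k <- n %/% p
  m <- matrix(y, nrow = p)
  if (config$drop_first_period && k > 1L) m <- m[, -1L, drop = FALSE]
  rowMeans(m)
}

trace_values <- function(y) {
  if (inherits(y, "response_trace")) y$y else as.numeric(y)
}

new_kernel <- function(values, raw, centroid, kind, frame_rate) {
  structure(list(values = values, raw_crosscorr = raw,
                 centroid_azimuth = centroid, kind = kind,
                 frame_rate = frame_rate, p = length(values)),
            class = "staf_kernel")
}

#' @export
print.staf_kernel <- function(x, ...) {
  cat(sprintf("%s kernel: %d lags @ %g Hz, centroid %.2f deg, peak %.4g\n",
              x$kind, x$p, x$frame_rate, x$centroid_azimuth,
              x$values[which.max(abs(x$values))]))
  invisible(x)
}

#' Estimate the elementary-motion (EM) kernel from a protocol pair
#'
#' Given the steering traces `y1` (from the (m_FM, m_EM) run) and `y2`
#' (from the paired (m_FM, -m_EM) run with identical figure drive), the
#' EM kernel is half the difference of the circular cross-correlations of
#' the texture sequence with the two traces: the FM-driven response,
#' including the dc figure-position component, is common to both runs and
#' cancels, and so does the finite m_FM x m_EM cross-talk. The result is
#' an impulse-response estimate (no integration), normalized per the
#' config divisor.
#'
#' @param y1,y2 Paired traces (`response_trace` or numeric), equal
#'   lengths covering an integer number of periods (an extra leading
#'   pre-motion frame is tolerated and dropped).
#' @param m_em The texture-drive [m_sequence()].
#' @param config An [estimation_config()].
#' @param frame_rate Sampling rate, Hz.
#' @param gamma Optional per-frame centroid azimuth track (degrees) used
#'   to attribute the kernel to its mean figure position.
#' @return A `staf_kernel` of kind "EM".
#' @export
estimate_em_kernel <- function(y1, y2, m_em,
                               config = estimation_config(),
                               frame_rate = 25, gamma = NULL) {
  v1 <- trace_values(y1); v2 <- trace_values(y2)
  if (length(v1) != length(v2))
    stop("paired traces must have equal length")
  p <- m_em$p
  s1 <- fold_periods(v1, p, config)
  s2 <- fold_periods(v2, p, config)
  m <- as.numeric(m_em$values)
  u <- 0.5 * (circ_xcorr(m, s1) - circ_xcorr(m, s2)) / norm_divisor(p, config)
  g <- if (config$em_dc_correct) u + sum(u) else u
  new_kernel(g, u, kernel_centroid(gamma, length(v1), p, config),
             "EM", frame_rate)
}

kernel_centroid <- function(gamma, n, p, config) {
  if (is.null(gamma)) return(NA_real_)
  if (length(gamma) %% p == 1L) gamma <- gamma[-1L]
  k <- length(gamma) %/% p
  if (config$drop_first_period && k > 1L)
    gamma <- gamma[-seq_len(p)]
  circular_mean_deg(gamma)
}

#' Estimate the figure-motion (FM) kernel with dc-error correction
#'
#' The FM channel behaves like a step response: it may hold a nonzero
#' value for the rest of the period, so its kernel cannot be read off a
#' direct cross-correlation (the assumption that responses die out within
#' a period fails). Instead the traces are differentiated (circular first
#' difference times the frame rate), cross-correlated with the figure
#' sequence -- summing the pair so the EM components cancel -- and the
#' result integrated back. The m-sequence dc error, once integrated,
#' accumulates linearly and nearly cancels the kernel by lag p-1; it is
#' removed using the saturated-window asymptote estimate selected by
#' `config$dc_method`. The returned kernel is the incremental step
#' response per one-pixel figure step.
#'
#' @inheritParams estimate_em_kernel
#' @param m_fm The figure-drive [m_sequence()].
#' @return A `staf_kernel` of kind "FM".
#' @export
estimate_fm_kernel <- function(y1, y2, m_fm,
                               config = estimation_config(),
                               frame_rate = 25, gamma = NULL) {
  v1 <- trace_values(y1); v2 <- trace_values(y2)
  if (length(v1) != length(v2))
    stop("paired traces must have equal length")
  p <- m_fm$p
  win <- which((seq_len(p) - 1) / frame_rate >= config$dc_window[1] &
                 (seq_len(p) - 1) / frame_rate <= config$dc_window[2])
  if (length(win) == 0L)
    stop("dc_window contains no sample within one period")
  if (config$dc_window[2] > (p - 1) / frame_rate)
    stop("dc_window extends beyond one sequence period (",
         format((p - 1) / frame_rate), " s)")
  # Differentiate the continuous record before folding: the FM response
  # carries a net drift of one asymptote-unit per period (the m-sequence
  # leaves the figure displaced one pixel), and a circular difference
  # inside one period would turn that drift into a spurious impulse at
  # the wrap sample. The first difference of the full trace is exactly
  # periodic in steady state. Single-period inputs fall back to the
  # circular difference.
  dfull <- function(v) {
    if (length(v) == p) (v - v[c(p, seq_len(p - 1L))]) * frame_rate
    else c(v[1L], diff(v)) * frame_rate
  }
  s1 <- fold_periods(dfull(v1), p, config)
  s2 <- fold_periods(dfull(v2), p, config)
  m <- as.numeric(m_fm$values)
  u <- 0.5 * (circ_xcorr(m, s1) + circ_xcorr(m, s2)) /
    norm_divisor(p, config)
  cum <- cumsum(u) / frame_rate
  k <- seq_len(p) - 1          # lag index, 0-based
  g <- switch(config$dc_method,
    none = cum,
    closed_form = {
      kbar <- mean(k[win])
      A <- mean(cum[win]) / (1 - (kbar + 1) / (p + 1))
      cum + (k + 1) * A / (p + 1)
    },
    literal = {
      A <- mean(cum[win])
      cumsum(u + A * frame_rate / (p + 1)) / frame_rate
    })
  new_kernel(g, u, kernel_centroid(gamma, length(v1), p, config),
             "FM", frame_rate)
}

#' Assemble kernels into a STAF
#'
#' Places kernels on the azimuth axis at their centroid positions
#' (rounded to the display pixel grid; repeats at one position are
#' averaged), then smooths every time slice along azimuth with a
#' circular boxcar of `config$boxcar_width` pixels.
#'
#' @param kernels List of `staf_kernel` objects of one kind with
#'   centroids covering >= 2 distinct azimuths.
#' @param geometry A [display_geometry()].
#' @param config An [estimation_config()].
#' @return A [staf()].
#' @export
assemble_staf <- function(kernels, geometry = display_geometry(),
                          config = estimation_config()) {
  if (length(kernels) == 0L) stop("no kernels to assemble")
  kinds <- vapply(kernels, `[[`, "", "kind")
  if (length(unique(kinds)) != 1L)
    stop("kernels of conflicting kinds (EM vs FM) cannot share a STAF")
  cents <- vapply(kernels, `[[`, 0, "centroid_azimuth")
  if (anyNA(cents)) stop("every kernel needs a centroid azimuth")
  px <- az_to_pixel(cents, geometry)
  az <- wrap_azimuth(px * geometry$pixel_pitch)
  u_az <- sort(unique(az))
  if (length(u_az) < 2L)
    stop("need kernels at >= 2 distinct centroid azimuths")
  grid <- vapply(u_az, function(a) {
    rowMeans(do.call(cbind,
                     lapply(kernels[az == a], `[[`, "values")))
  }, numeric(kernels[[1L]]$p))
  fr <- kernels[[1L]]$frame_rate
  out <- staf(grid, (seq_len(nrow(grid)) - 1) / fr, u_az,
              kind = kinds[1L],
              provenance = list(n_kernels = length(kernels),
                                p = kernels[[1L]]$p))
  staf_smooth(out, config$boxcar_width, geometry)
}

#' Fit a STAF pair from the full paired m-sequence protocol
#'
#' The central estimator. In simulation mode it runs the complete study
#' on a synthetic plant: for every start azimuth on the grid it builds
#' the paired (+m_EM / -m_EM) compound protocols, simulates noisy
#' steering traces for `n_repeats` repeats, estimates the EM and FM
#' kernels per repeat, and assembles repeat-averaged kernels into the two
#' STAFs. In data mode it consumes recorded paired traces. A
#' sliding-window mode segments one long continuous paired record into
#' single-period windows, attributing each window's kernels to the mean
#' figure position within it.
#'
#' @param object A [plant_model()] (simulation mode) or a list of runs
#'   (data mode), each run a list with elements `y1`, `y2`
#'   (`response_trace` or numeric) and `gamma` (per-frame centroid track,
#'   degrees).
#' @param m_fm,m_em Distinct [m_sequence()] drives (defaults: the first
#'   two 7th-order primitive polynomials).
#' @param geometry A [display_geometry()].
#' @param azimuth_grid Start azimuths (degrees) of the block design;
#'   default every 4 pixels (15 deg) around the full circle.
#' @param n_repeats Paired repeats per start azimuth (default 20).
#' @param n_periods Periods per run (default 2; the first is discarded
#'   as a transient by the default config).
#' @param config An [estimation_config()].
#' @param mode `"block"` (independent runs per azimuth) or `"sliding"`
#'   (data mode only: overlapping single-period windows stepped by
#'   `window_step` frames through one continuous record).
#' @param window_step Sliding-window step in frames (default one period,
#'   i.e. non-overlapping).
#' @param seed Integer seed making the whole fit bit-reproducible.
#' @return An object of class `staf_fit` with components `staf_em`,
#'   `staf_fm`, the configuration and protocol metadata. Methods:
#'   `print`, `summary`, `coef` (list of the two grids), `predict`
#'   (forward response to a trajectory), `plot`.
#' @examples
#' \donttest{
#' plant <- plant_model()
#' fit <- staf_fit(plant, n_repeats = 2, azimuth_grid = c(-30, 0, 30),
#'                 seed = 1)
#' pred <- predict(fit, make_trisweep(90))
#' }
#' @export
staf_fit <- function(object, m_fm = m_sequence(7, primitive_taps(7)[[1]]),
                     m_em = m_sequence(7, primitive_taps(7)[[2]]),
                     geometry = display_geometry(),
                     azimuth_grid = NULL, n_repeats = 20L, n_periods = 2L,
                     config = estimation_config(),
                     mode = c("block", "sliding"), window_step = NULL,
                     seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(azimuth_grid))
    azimuth_grid <- wrap_azimuth(seq(0, 359, by = 4 * geometry$pixel_pitch))
  fr <- geometry$frame_rate

  kernels_em <- list(); kernels_fm <- list()
  add <- function(y1, y2, gamma) {
    ke <- estimate_em_kernel(y1, y2, m_em, config, fr, gamma)
    kf <- estimate_fm_kernel(y1, y2, m_fm, config, fr, gamma)
    kernels_em[[length(kernels_em) + 1L]] <<- ke
    kernels_fm[[length(kernels_fm) + 1L]] <<- kf
  }

  if (inherits(object, "plant_model")) {
    with_seed(seed, {
      for (a in azimuth_grid) {
        r1 <- build_compound_protocol(m_fm, m_em, +1L, a, geometry, n_periods)
        r2 <- build_compound_protocol(m_fm, m_em, -1L, a, geometry, n_periods)
        for (r in seq_len(n_repeats)) {
          y1 <- simulate_response(object, r1)
          y2 <- simulate_response(object, r2)
          add(y1, y2, r1$gamma)
        }
      }
    })
  } else if (is.list(object)) {
    if (mode == "sliding") {
      # each window sees the periodic drive at a different phase, so the
      # reference sequences must be rotated by the window offset or the
      # estimated kernels would come out cyclically shifted
      rot <- function(m, d) {
        m$values <- m$values[((seq_len(m$p) - 1L + d) %% m$p) + 1L]
        m
      }
      cfg1 <- config; cfg1$drop_first_period <- FALSE
      p <- m_fm$p
      for (run in object) {
        v1 <- trace_values(run$y1); v2 <- trace_values(run$y2)
        off <- if (length(v1) %% p == 1L) 1L else 0L
        step <- as.integer(window_step %||% p)
        starts <- seq(off + 1L, length(v1) - p + 1L, by = step)
        for (s0 in starts) {
          idx <- s0:(s0 + p - 1L)
          d <- (s0 - off - 1L) %% p
          ke <- estimate_em_kernel(v1[idx], v2[idx], rot(m_em, d),
                                   cfg1, fr, run$gamma[idx])
          kf <- estimate_fm_kernel(v1[idx], v2[idx], rot(m_fm, d),
                                   cfg1, fr, run$gamma[idx])
          kernels_em[[length(kernels_em) + 1L]] <- ke
          kernels_fm[[length(kernels_fm) + 1L]] <- kf
        }
      }
    } else {
      for (run in object) add(run$y1, run$y2, run$gamma)
    }
  } else stop("`object` must be a plant_model or a list of paired runs")

  prov <- list(order = m_fm$order, n_repeats = n_repeats, mode = mode)
  s_em <- assemble_staf(kernels_em, geometry, config)
  s_fm <- assemble_staf(kernels_fm, geometry, config)
  s_em$provenance <- utils::modifyList(s_em$provenance, prov)
  s_fm$provenance <- utils::modifyList(s_fm$provenance, prov)
  structure(list(staf_em = s_em, staf_fm = s_fm, config = config,
                 geometry = geometry, mode = mode, seed = seed,
                 n_repeats = n_repeats, azimuth_grid = azimuth_grid,
                 m_fm_taps = m_fm$taps, m_em_taps = m_em$taps,
                 call = match.call()),
            class = "staf_fit")
}

#' @export
print.staf_fit <- function(x, ...) {
  cat("STAF fit (paired sign-flip m-sequence protocol)\n")
  print(x$staf_em); print(x$staf_fm)
  invisible(x)
}

#' @export
summary.staf_fit <- function(object, ...) {
  em <- object$staf_em; fm <- object$staf_fm
  fm_asym <- fm$grid[nrow(fm$grid), ]
  out <- list(
    em_peak = max(abs(em$grid)),
    em_peak_azimuth = em$azimuth_axis[which.max(apply(abs(em$grid), 2, max))],
    fm_asymptote_front = fm_asym[which.min(abs(fm$azimuth_axis))],
    fm_asymptote_integral = sum(fm_asym),
    n_azimuths = length(em$azimuth_axis),
    n_repeats = object$n_repeats, mode = object$mode)
  class(out) <- "summary.staf_fit"
  out
}

#' @export
print.summary.staf_fit <- function(x, ...) {
  cat(sprintf(
    paste0("STAF fit summary (%s mode, %d repeats, %d azimuths)\n",
           "  EM kernel peak %.4g at %.1f deg\n",
           "  FM asymptote at front %.4g; azimuthal sum of asymptote %.4g\n"),
    x$mode, x$n_repeats, x$n_azimuths, x$em_peak, x$em_peak_azimuth,
    x$fm_asymptote_front, x$fm_asymptote_integral))
  invisible(x)
}

#' @export
coef.staf_fit <- function(object, ...) {
  list(EM = object$staf_em$grid, FM = object$staf_fm$grid)
}

#' @export
#' @param object A `staf_fit`.
#' @param traj A [trajectory()] or `stimulus_realization`.
#' @rdname staf_fit
predict.staf_fit <- function(object, traj, ...) {
  predict_response(object$staf_em, object$staf_fm, traj)
}

#' @export
plot.staf_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$staf_em, ...)
  plot(x$staf_fm, ...)
  invisible(x)
}
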