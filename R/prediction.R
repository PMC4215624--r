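# Forward model: discrete two-stream superposition shared by the plant
# simulator and STAF-based prediction, so "predict with the plant's own
# kernels" and "simulate noiselessly" are literally the same arithmetic.

# y[t] = sum_{tau<=t} [G_fm(t-tau, gamma[tau]) dfm[tau] +
#                      G_em(t-tau, gamma[tau]) dem[tau]]
#        + sum_theta G_fm(t, theta) dF(theta)
# gamma[tau] is the post-step centroid azimuth; the initial-position term
# walks one-pixel increments along the shorter arc from 0 to gamma0.
staf_superpose <- function(staf_em, staf_fm, delta_fm, delta_em, gamma,
                           gamma0, geometry) {
  T_ <- length(delta_fm)
  fs <- geometry$frame_rate
  t_out <- (seq_len(T_) - 1) / fs
  y <- numeric(T_)
  # steps grouped by the (pixel-grid) azimuth at which they occur: one
  # causal convolution per distinct azimuth and stream
  key <- round(gamma, 9)
  for (u in unique(key)) {
    sel <- key == u
    xf <- delta_fm * sel
    xe <- delta_em * sel
    if (any(xf != 0))
      y <- y + causal_conv(xf, resample_kernel(staf_column(staf_fm, u),
                                               staf_fm$time_axis, t_out))
    if (any(xe != 0))
      y <- y + causal_conv(xe, resample_kernel(staf_column(staf_em, u),
                                               staf_em$time_axis, t_out))
  }
  # initial-position term
  k0 <- as.integer(round(wrap_azimuth(gamma0) / geometry$pixel_pitch))
  if (k0 != 0L) {
    s <- sign(k0)
    for (j in seq_len(abs(k0))) {
      th <- s * j * geometry$pixel_pitch
      y <- y + s * resample_kernel(staf_column(staf_fm, th),
                                   staf_fm$time_axis, t_out)
    }
  }
  y
}

#' Figure trajectory for forward prediction
#'
#' Bundles per-frame figure (`fm_steps`) and internal-texture (`em_steps`)
#' position steps in pixels with the starting azimuth and frame rate. The
#' initial-position decomposition (one step per azimuth-grid pixel along
#' the shorter arc from front center to `initial_azimuth`, signed like the
#' starting azimuth) is derived internally by the predictor.
#'
#' @param fm_steps,em_steps Numeric step traces, pixels per frame.
#' @param initial_azimuth Figure centroid azimuth at the first frame,
#'   degrees.
#' @param frame_rate Frames per second.
#' @param geometry A [display_geometry()].
#' @return An object of class `staf_trajectory`.
#' @export
trajectory <- function(fm_steps, em_steps = NULL, initial_azimuth = 0,
                       frame_rate = 25, geometry = display_geometry()) {
  if (is.null(em_steps)) em_steps <- numeric(length(fm_steps))
  if (length(em_steps) != length(fm_steps))
    stop("fm_steps and em_steps must have equal length")
  structure(list(fm_steps = as.numeric(fm_steps),
                 em_steps = as.numeric(em_steps),
                 initial_azimuth = wrap_azimuth(initial_azimuth),
                 frame_rate = frame_rate, geometry = geometry),
            class = "staf_trajectory")
}

#' @export
#' @rdname trajectory
#' @param x A `stimulus_realization` to convert.
as_trajectory <- function(x) {
  stopifnot(inherits(x, "stimulus_realization"))
  trajectory(x$delta_fm, x$delta_em, x$start_azimuth,
             x$geometry$frame_rate, x$geometry)
}

#' Predict a steering response from a STAF pair
#'
#' Evaluates the discrete superposition model on an arbitrary figure
#' trajectory: each one-pixel step is convolved with the kernel column at
#' the azimuth where it occurred (linear interpolation, circular wrap),
#' and the initial-position term adds the FM field summed over position
#' increments from front center to the starting azimuth. Step magnitudes
#' larger than the one-pixel calibration step leave the quasi-linear
#' validity domain of the kernels and trigger a warning, not an error.
#'
#' @param staf_em,staf_fm [staf()] objects of kinds "EM" and "FM".
#' @param traj A [trajectory()] (or a `stimulus_realization`, converted
#'   via [as_trajectory()]).
#' @return A `response_trace` at the trajectory's frame rate.
#' @export
predict_response <- function(staf_em, staf_fm, traj) {
  if (inherits(traj, "stimulus_realization")) traj <- as_trajectory(traj)
  stopifnot(inherits(traj, "staf_trajectory"))
  if (!inherits(staf_em, "staf") || !inherits(staf_fm, "staf") ||
      staf_em$kind != "EM" || staf_fm$kind != "FM")
    stop("predict_response needs an EM STAF and an FM STAF, in that order")
  if (max(abs(traj$fm_steps), abs(traj$em_steps)) > 1 + 1e-9)
    warning("trajectory steps exceed the one-pixel calibration step; ",
            "the quasi-linear kernels may not extrapolate to these speeds")
  geom <- traj$geometry
  gamma <- wrap_azimuth(traj$initial_azimuth +
                          cumsum(traj$fm_steps) * geom$pixel_pitch)
  y <- staf_superpose(staf_em, staf_fm, traj$fm_steps, traj$em_steps,
                      gamma, traj$initial_azimuth, geom)
  new_response_trace(y, traj$frame_rate)
}

#' Coefficient of determination between two traces
#'
#' Squared Pearson correlation of predicted vs measured steering traces,
#' the standard score for STAF forward-prediction validity.
#'
#' @param predicted,measured `response_trace` objects or numeric vectors
#'   of equal length.
#' @return A single number in \[0, 1\].
#' @export
r_squared <- function(predicted, measured) {
  p <- if (inherits(predicted, "response_trace")) predicted$y else
    as.numeric(predicted)
  m <- if (inherits(measured, "response_trace")) measured$y else
    as.numeric(measured)
  if (length(p) != length(m))
    stop("predicted and measured traces must have equal length")
  if (stats::sd(m) == 0)
    stop("measured trace is constant; correlation undefined")
  stats::cor(p, m)^2
}

#' Write / read a trajectory (CSV steps + JSON header)
#'
#' @param x A [trajectory()].
#' @param path CSV path (columns frame_index, delta_fm_px, delta_em_px);
#'   header JSON goes to `paste0(path, ".json")`.
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "staf_trajectory"))
  n <- length(x$fm_steps)
  writeLines(c("frame_index,delta_fm_px,delta_em_px",
               sprintf("%d,%s,%s", seq_len(n), fmt_dbl(x$fm_steps),
                       fmt_dbl(x$em_steps))), path)
  jsonlite::write_json(list(initial_azimuth = x$initial_azimuth,
                            frame_rate = x$frame_rate,
                            n_pixels = x$geometry$n_pixels,
                            pixel_pitch = x$geometry$pixel_pitch),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  d <- utils::read.csv(path)
  h <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- display_geometry(n_pixels = h$n_pixels,
                           pixel_pitch = h$pixel_pitch,
                           frame_rate = h$frame_rate)
  trajectory(d$delta_fm_px, d$delta_em_px, h$initial_azimuth,
             h$frame_rate, geom)
}
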