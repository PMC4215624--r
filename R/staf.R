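#' Spatio-temporal action field (STAF) objects
#'
#' A STAF is a grid G(t, gamma) of temporal kernel values indexed by lag
#' time t (rows, seconds) and figure azimuth gamma (columns, degrees in
#' (-180, 180]): the reverse-correlation estimate of the steering response
#' to a one-pixel step delivered with the figure at that azimuth. `kind`
#' distinguishes the elementary-motion field ("EM", an impulse response
#' that decays back to zero) from the figure-motion field ("FM", an
#' incremental step response that may stay nonzero at long lags).
#'
#' @param grid Numeric matrix, time along rows, azimuth along columns.
#' @param time_axis Lag times in seconds, uniformly increasing from 0.
#' @param azimuth_axis Azimuths in degrees, strictly increasing within
#'   (-180, 180].
#' @param kind "EM" or "FM".
#' @param smoothing Optional list of smoothing metadata (boxcar width).
#' @param provenance Optional list (sequence order, repeats, ...).
#' @return An object of class `staf`.
#' @export
staf <- function(grid, time_axis, azimuth_axis, kind = c("EM", "FM"),
                 smoothing = NULL, provenance = NULL) {
  kind <- match.arg(kind)
  grid <- as.matrix(grid)
  if (nrow(grid) != length(time_axis) || ncol(grid) != length(azimuth_axis))
    stop("grid dimensions must match time and azimuth axes")
  if (any(!is.finite(grid))) stop("STAF grid must be finite everywhere")
  if (any(diff(azimuth_axis) <= 0) || any(azimuth_axis <= -180) ||
      any(azimuth_axis > 180))
    stop("azimuth_axis must be strictly increasing within (-180, 180]")
  structure(list(grid = grid, time_axis = as.numeric(time_axis),
                 azimuth_axis = as.numeric(azimuth_axis), kind = kind,
                 smoothing = smoothing, provenance = provenance),
            class = "staf")
}

#' @export
print.staf <- function(x, ...) {
  cat(sprintf("%s STAF: %d lags (0..%.3g s) x %d azimuths (%.1f..%.1f deg)\n",
              x$kind, nrow(x$grid), max(x$time_axis), ncol(x$grid),
              min(x$azimuth_axis), max(x$azimuth_axis)))
  cat(sprintf("  value range [%.4g, %.4g]", min(x$grid), max(x$grid)))
  if (!is.null(x$smoothing))
    cat(sprintf("; boxcar %s px", format(x$smoothing$boxcar_width)))
  cat("\n")
  invisible(x)
}

#' @export
plot.staf <- function(x, main = NULL, ...) {
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(x$time_axis, x$azimuth_axis, x$grid, col = pal,
                  xlab = "lag (s)", ylab = "azimuth (deg)",
                  main = main %||% paste(x$kind, "STAF"), ...)
  invisible(x)
}

# Temporal kernel at an arbitrary azimuth: columns interpolated linearly
# with circular wrap across the +/-180 deg seam. Returns a length-n_t
# vector on the STAF's own time axis.
staf_column <- function(x, azimuth) {
  az <- x$azimuth_axis
  n <- length(az)
  a <- wrap_azimuth(azimuth)
  if (n == 1L) return(x$grid[, 1L])
  j <- findInterval(a, az)
  if (j >= 1L && j < n) {
    lo <- j; hi <- j + 1L; span <- az[hi] - az[lo]; frac <- (a - az[lo]) / span
  } else {
    # wrap segment between the last and first grid azimuths
    lo <- n; hi <- 1L
    span <- (az[1L] + 360) - az[n]
    d <- if (a < az[1L]) a + 360 - az[n] else a - az[n]
    frac <- d / span
  }
  (1 - frac) * x$grid[, lo] + frac * x$grid[, hi]
}

# Sample a temporal kernel column onto lag times `t_out` (seconds):
# linear interpolation on the STAF time axis, 0 before t = 0, terminal
# value held beyond the last lag (an EM kernel has decayed to ~0 there, an
# FM kernel holds its asymptote).
resample_kernel <- function(values, time_axis, t_out) {
  yr <- stats::approx(time_axis, values, xout = t_out, method = "linear",
                      yleft = 0, yright = values[length(values)])$y
  yr
}

#' Azimuthal boxcar smoothing of a STAF
#'
#' Applies a circular unit-sum moving average of `width_px` display pixels
#' along the azimuth axis to every time slice. The window size in grid
#' samples is `width_px * pixel_pitch / axis spacing` (at least one
#' sample); the azimuthal mean of every slice is preserved exactly.
#'
#' @param x A [staf()].
#' @param width_px Boxcar width in display pixels (default 4, ~15 deg).
#' @param geometry A [display_geometry()] supplying the pixel pitch.
#' @return A smoothed `staf` with updated smoothing metadata.
#' @export
staf_smooth <- function(x, width_px = 4, geometry = display_geometry()) {
  stopifnot(inherits(x, "staf"))
  n_az <- ncol(x$grid)
  if (n_az > 1L) {
    sp <- diff(x$azimuth_axis)
    full <- c(sp, 360 - sum(sp))
    if (max(full) - min(full) > 1e-6 * mean(full)) {
      # uneven axis (e.g. centroids covering only an arc): a window wider
      # than the closest sample spacing cannot be applied consistently
      if (width_px * geometry$pixel_pitch > min(sp) * (1 + 1e-9))
        warning("azimuth axis is not evenly spaced around the circle; ",
                "skipping boxcar smoothing")
      x$smoothing <- list(boxcar_width = NA_real_)
      return(x)
    }
    n_w <- max(1L, as.integer(round(width_px * geometry$pixel_pitch / full[1])))
    if (n_w > 1L)
      x$grid <- t(apply(x$grid, 1L, circ_boxcar, n_w = n_w))
  }
  x$smoothing <- list(boxcar_width = width_px)
  x
}

#' Per-azimuth frequency-domain transfer function of a STAF
#'
#' Discrete Fourier transform of the temporal kernel at every azimuth,
#' giving the frequency-domain gain/phase of the quasi-linear channel
#' parameterized by figure position. Descriptive only: the underlying
#' kernels are valid near the calibration step size and update rate, so
#' these spectra are not general models of the behavior.
#'
#' @param x A [staf()] with a uniform time axis.
#' @return List with `gain` (complex frequency x azimuth matrix),
#'   `frequency_hz` and `azimuth_axis`.
#' @export
staf_transfer_function <- function(x) {
  stopifnot(inherits(x, "staf"))
  dt <- diff(x$time_axis)
  if (length(dt) == 0L) stop("transfer function needs >= 2 time samples")
  if (max(dt) - min(dt) > 1e-9 * mean(dt))
    stop("transfer function requires a uniform time axis")
  n_t <- nrow(x$grid)
  gain <- stats::mvfft(x$grid)
  list(gain = gain,
       frequency_hz = (seq_len(n_t) - 1) / (n_t * dt[1]),
       azimuth_axis = x$azimuth_axis)
}

#' Persist / load a STAF as text (CSV grid + JSON sidecar)
#'
#' The grid is written as CSV (one row per time sample) with full
#' `%.17g` precision so doubles round-trip bit-identically; axes and
#' metadata go to `<path>.json`.
#'
#' @param x A [staf()].
#' @param path CSV file path; the sidecar is `paste0(path, ".json")`.
#' @export
write_staf <- function(x, path) {
  stopifnot(inherits(x, "staf"))
  rows <- apply(x$grid, 1L, function(r) paste(fmt_dbl(r), collapse = ","))
  writeLines(rows, path)
  jsonlite::write_json(
    list(time_axis = fmt_dbl(x$time_axis),
         azimuth_axis = fmt_dbl(x$azimuth_axis),
         kind = x$kind, smoothing = x$smoothing,
         provenance = x$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_staf
#' @export
read_staf <- function(path) {
  rows <- readLines(path)
  grid <- do.call(rbind, lapply(strsplit(rows, ","), as.numeric))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sm <- meta$smoothing
  if (length(sm) == 0L) sm <- NULL
  pv <- meta$provenance
  if (length(pv) == 0L) pv <- NULL
  staf(grid, as.numeric(meta$time_axis), as.numeric(meta$azimuth_axis),
       kind = meta$kind, smoothing = sm, provenance = pv)
}
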