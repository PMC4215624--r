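#' Panoramic display geometry
#'
#' Describes the cylindrical LED-style display on which the figure moves:
#' a ring of `n_pixels` azimuthal pixel columns at `pixel_pitch` degrees
#' per pixel (the product must be 360), a figure window `figure_width`
#' pixels wide, and a frame/update rate. The physical display has a rear
#' access gap of `rear_gap` pixels; simulation uses the full 360 deg
#' logical ring by default, with the gap retained as metadata for optional
#' masking.
#'
#' @param n_pixels Azimuthal pixel count (default 96).
#' @param pixel_pitch Degrees per pixel (default 3.75).
#' @param figure_width Figure window width in pixels (default 8, i.e. 30
#'   deg); must be >= 3 so the window has an interior between its two
#'   boundary columns.
#' @param frame_rate Stimulus update rate in frames per second (default
#'   25, making one 127-element period 5.08 s).
#' @param rear_gap Width in pixels of the physical rear gap (metadata).
#' @return An object of class `display_geometry`.
#' @export
display_geometry <- function(n_pixels = 96L, pixel_pitch = 3.75,
                             figure_width = 8L, frame_rate = 25,
                             rear_gap = 8L) {
  if (abs(n_pixels * pixel_pitch - 360) > 1e-9)
    stop("n_pixels * pixel_pitch must equal 360 degrees")
  if (figure_width < 3) stop("figure_width must be >= 3 pixels")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  structure(list(n_pixels = as.integer(n_pixels), pixel_pitch = pixel_pitch,
                 figure_width = as.integer(figure_width),
                 frame_rate = frame_rate, rear_gap = as.integer(rear_gap)),
            class = "display_geometry")
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf(
    "display: %d px x %.4g deg/px (360 deg), figure %d px (%.3g deg), %g Hz\n",
    x$n_pixels, x$pixel_pitch, x$figure_width,
    x$figure_width * x$pixel_pitch, x$frame_rate))
  invisible(x)
}

#' Random binary background pattern
#'
#' One panoramic row of ON/OFF pixels, each ON with probability 0.5
#' (the background and the figure's internal texture share these spatial
#' statistics, so the figure is invisible when stationary).
#'
#' @param geometry A [display_geometry()].
#' @param rng_seed Optional integer seed; the draw is reproducible for a
#'   fixed seed and leaves the caller's RNG untouched.
#' @return Integer 0/1 vector of length `geometry$n_pixels`.
#' @export
make_background <- function(geometry = display_geometry(), rng_seed = NULL) {
  stopifnot(inherits(geometry, "display_geometry"))
  with_seed(rng_seed, as.integer(stats::runif(geometry$n_pixels) < 0.5))
}

new_realization <- function(delta_fm, delta_em, start_azimuth, geometry,
                            sign_flag, n_periods, period,
                            drift_balanced = FALSE) {
  gamma <- wrap_azimuth(start_azimuth + cumsum(delta_fm) * geometry$pixel_pitch)
  structure(list(
    delta_fm = delta_fm, delta_em = delta_em, gamma = gamma,
    figure_velocity = delta_fm * geometry$pixel_pitch * geometry$frame_rate,
    em_velocity = delta_em * geometry$pixel_pitch * geometry$frame_rate,
    sign_flag = sign_flag, start_azimuth = wrap_azimuth(start_azimuth),
    n_periods = n_periods, period = period, geometry = geometry,
    drift_balanced = drift_balanced), class = "stimulus_realization")
}

#' Compound two-sequence stimulus protocol
#'
#' Builds one run of the decoupling protocol: the figure window is stepped
#' by one m-sequence (`m_fm`, figure motion) while the texture inside the
#' window is stepped by a second, distinct m-sequence (`m_em`, elementary
#' motion), either as given (`sign_flag = +1`) or with the texture
#' sequence negated (`sign_flag = -1`). The paired +/- runs are what allow
#' the two kernels to be decontaminated from one another at analysis time;
#' identical sequences would make that impossible and are rejected.
#'
#' Frame 1 is the pre-motion state (both step traces start at 0); the step
#' recorded at frame t moves the figure between frames t-1 and t, and
#' `gamma` stores the post-step figure centroid azimuth.
#'
#' @param m_fm,m_em Distinct [m_sequence()] objects of equal period.
#' @param sign_flag +1 or -1, selecting the (m_FM, m_EM) or (m_FM, -m_EM)
#'   member of the protocol pair.
#' @param start_azimuth Figure centroid azimuth at frame 1, degrees.
#' @param geometry A [display_geometry()].
#' @param n_periods Number of m-sequence repetitions in the run.
#' @param drift_balanced If `TRUE` the interior texture is re-randomized
#'   wholesale every frame at render time (no coherent first-order motion);
#'   `delta_em` is then forced to zero.
#' @return A `stimulus_realization` with per-frame step traces `delta_fm`,
#'   `delta_em` (pixels), centroid track `gamma` (degrees, wrapped) and
#'   protocol metadata.
#' @export
build_compound_protocol <- function(m_fm, m_em, sign_flag = 1L,
                                    start_azimuth = 0,
                                    geometry = display_geometry(),
                                    n_periods = 1L,
                                    drift_balanced = FALSE) {
  stopifnot(inherits(m_fm, "m_sequence"), inherits(m_em, "m_sequence"))
  if (!sign_flag %in% c(-1, 1)) stop("sign_flag must be +1 or -1")
  if (m_fm$p != m_em$p) stop("m_fm and m_em must share one period length")
  if (identical(m_fm$values, m_em$values))
    stop("m_fm and m_em must be distinct m-sequences: the sign-flip ",
         "decontamination of the EM and FM kernels requires two ",
         "independent drives")
  p <- m_fm$p
  delta_fm <- c(0, rep(as.numeric(m_fm$values), n_periods))
  delta_em <- if (drift_balanced) numeric(length(delta_fm)) else
    c(0, rep(sign_flag * as.numeric(m_em$values), n_periods))
  new_realization(delta_fm, delta_em, start_azimuth, geometry,
                  as.integer(sign_flag), as.integer(n_periods), p,
                  drift_balanced)
}

#' Triangle-sweep ("trisweep") Fourier-bar trajectory
#'
#' A solid Fourier bar (internal texture moving coherently with the
#' window, `delta_em == delta_fm`) swept back and forth at one pixel per
#' frame between `-amplitude_deg/2` and `+amplitude_deg/2`. With the
#' default geometry a 90 deg amplitude gives 24 steps per half-sweep and a
#' net displacement of zero per cycle. This is the standard validation
#' stimulus for STAF-based forward prediction.
#'
#' @param amplitude_deg Peak-to-peak sweep extent, degrees; must be a
#'   multiple of `pixel_pitch`.
#' @param geometry A [display_geometry()].
#' @param n_cycles Number of full up-down cycles.
#' @return A `stimulus_realization` starting at `-amplitude_deg/2`.
#' @export
make_trisweep <- function(amplitude_deg = 90, geometry = display_geometry(),
                          n_cycles = 1L) {
  half <- amplitude_deg / geometry$pixel_pitch
  if (abs(half - round(half)) > 1e-9)
    stop("amplitude_deg must be a multiple of pixel_pitch (",
         geometry$pixel_pitch, " deg)")
  half <- as.integer(round(half))
  if (half < 1) stop("amplitude_deg must cover at least one pixel")
  cyc <- c(rep(1, half), rep(-1, half))
  delta <- c(0, rep(cyc, n_cycles))
  new_realization(delta, delta, -amplitude_deg / 2, geometry,
                  1L, as.integer(n_cycles), length(cyc))
}

az_to_pixel <- function(az, geometry) {
  as.integer(round(az / geometry$pixel_pitch)) %% geometry$n_pixels
}

#' Render a stimulus realization into panoramic frames
#'
#' Produces the frame-by-frame ON/OFF pixel grid shown on the display. The
#' figure window overwrites the background at the current azimuth; the
#' interior texture scrolls by `delta_em` per frame in window-relative
#' coordinates (or is redrawn wholesale every frame in drift-balanced
#' mode). Two statistical hygiene measures from the protocol are applied:
#' on every syndirectional step (figure and texture stepping the same
#' nonzero direction) both boundary columns of the window are redrawn at
#' random, so syndirectional and antidirectional steps drive coherent
#' motion across the same number of interior pixel boundaries; and the
#' random background is replaced at the start of every third m-sequence
#' period, limiting chance figure-ground correlations.
#'
#' @param realization A `stimulus_realization`.
#' @param geometry A [display_geometry()]; defaults to the realization's.
#' @param rng_seed Optional seed; rendering is bit-reproducible for a
#'   fixed seed.
#' @return An object of class `frame_sequence`: `frames` (frames x pixels
#'   0/1 matrix), `background` (the final background pattern) and
#'   `refresh_log` (frame indices at which the background was (re)drawn).
#' @export
render_frames <- function(realization, geometry = realization$geometry,
                          rng_seed = NULL) {
  stopifnot(inherits(realization, "stimulus_realization"))
  np <- geometry$n_pixels
  w <- geometry$figure_width
  if (w > np) stop("figure window wider than the display")
  T_ <- length(realization$delta_fm)
  p <- realization$period

  with_seed(rng_seed, {
    background <- as.integer(stats::runif(np) < 0.5)
    refresh_log <- 1L
    # window-relative texture memory: texture[j] is the pattern cell
    # currently aligned with texture coordinate j (circular, length np)
    texture <- as.integer(stats::runif(np) < 0.5)
    em_off <- 0L   # texture coordinate offset accumulated from delta_em
    frames <- matrix(0L, nrow = T_, ncol = np)
    win_pix0 <- az_to_pixel(realization$gamma[1], geometry) -
      (w %/% 2L)  # leftmost window pixel at frame 1 (0-based)

    for (t in seq_len(T_)) {
      dfm <- realization$delta_fm[t]
      dem <- realization$delta_em[t]
      if (t > 1L) {
        # background replacement every three periods (first frame of
        # periods 4, 7, ...; frame 1 holds the pre-motion state)
        if ((t - 2L) %% (3L * p) == 0L && t > 2L) {
          background <- as.integer(stats::runif(np) < 0.5)
          refresh_log <- c(refresh_log, t)
        }
        win_pix0 <- (win_pix0 + as.integer(dfm)) %% np
        em_off <- (em_off + as.integer(dem)) %% np
        if (realization$drift_balanced) {
          texture <- as.integer(stats::runif(np) < 0.5)
        } else if (dfm != 0 && dfm == dem) {
          # syndirectional step: redraw both boundary columns' texture
          # cells; interior cells are untouched
          edges <- c(0L, w - 1L)
          idx <- ((edges - em_off) %% np) + 1L
          texture[idx] <- as.integer(stats::runif(2L) < 0.5)
        }
      }
      fr <- background
      cols <- ((win_pix0 + 0:(w - 1L)) %% np) + 1L
      tex_idx <- (((0:(w - 1L)) - em_off) %% np) + 1L
      fr[cols] <- texture[tex_idx]
      frames[t, ] <- fr
    }
    structure(list(frames = frames, background = background,
                   refresh_log = refresh_log),
              class = "frame_sequence")
  })
}
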