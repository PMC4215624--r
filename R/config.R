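#' Run configuration (load / save / validate)
#'
#' A run configuration collects everything needed to reproduce a full
#' protocol from a single global seed: display geometry, the two
#' m-sequence generators, the protocol schedule and the estimation
#' settings. Stored as YAML key/value text so configurations are
#' inspectable and diffable; `read_config(write_config(x)) == x`.
#'
#' @param geometry A [display_geometry()].
#' @param order M-sequence order (shared by both drives).
#' @param fm_taps,em_taps Tap sets of the two (distinct) primitive
#'   polynomials; defaults are the first two table entries for `order`.
#' @param azimuth_grid Start azimuths of the block schedule, degrees.
#' @param n_repeats,n_periods Protocol schedule parameters.
#' @param mode "block" or "sliding".
#' @param estimation An [estimation_config()].
#' @param seed Global RNG seed.
#' @return An object of class `staf_config`.
#' @export
staf_config <- function(geometry = display_geometry(), order = 7L,
                        fm_taps = primitive_taps(order)[[1]],
                        em_taps = primitive_taps(order)[[2]],
                        azimuth_grid = NULL, n_repeats = 20L,
                        n_periods = 2L, mode = "block",
                        estimation = estimation_config(), seed = 1L) {
  if (is.null(azimuth_grid))
    azimuth_grid <- wrap_azimuth(seq(0, 359, by = 4 * geometry$pixel_pitch))
  structure(list(geometry = geometry, order = as.integer(order),
                 fm_taps = as.integer(fm_taps),
                 em_taps = as.integer(em_taps),
                 azimuth_grid = azimuth_grid,
                 n_repeats = as.integer(n_repeats),
                 n_periods = as.integer(n_periods), mode = mode,
                 estimation = estimation, seed = as.integer(seed)),
            class = "staf_config")
}

#' @rdname staf_config
#' @param x A `staf_config`.
#' @param path YAML file path.
#' @export
write_config <- function(x, path) {
  stopifnot(inherits(x, "staf_config"))
  flat <- list(
    geometry = unclass(x$geometry),
    order = x$order, fm_taps = x$fm_taps, em_taps = x$em_taps,
    azimuth_grid = x$azimuth_grid, n_repeats = x$n_repeats,
    n_periods = x$n_periods, mode = x$mode,
    estimation = unclass(x$estimation), seed = x$seed)
  yaml::write_yaml(flat, path)
  invisible(path)
}

config_fields <- list(
  geometry = c("n_pixels", "pixel_pitch", "figure_width", "frame_rate",
               "rear_gap"),
  estimation = c("dc_window", "normalization", "dc_method",
                 "em_dc_correct", "boxcar_width", "drop_first_period"),
  top = c("geometry", "order", "fm_taps", "em_taps", "azimuth_grid",
          "n_repeats", "n_periods", "mode", "estimation", "seed"))

#' @rdname staf_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  miss <- setdiff(config_fields$top, names(raw))
  if (length(miss))
    stop("config ", path, " is missing required field(s): ",
         paste(miss, collapse = ", "))
  for (grp in c("geometry", "estimation")) {
    gm <- setdiff(config_fields[[grp]], names(raw[[grp]]))
    if (length(gm))
      stop("config ", path, " is missing required field(s): ",
           paste(paste0(grp, ".", gm), collapse = ", "))
  }
  g <- raw$geometry
  e <- raw$estimation
  staf_config(
    geometry = display_geometry(g$n_pixels, g$pixel_pitch, g$figure_width,
                                g$frame_rate, g$rear_gap),
    order = raw$order, fm_taps = raw$fm_taps, em_taps = raw$em_taps,
    azimuth_grid = raw$azimuth_grid, n_repeats = raw$n_repeats,
    n_periods = raw$n_periods, mode = raw$mode,
    estimation = estimation_config(e$dc_window, e$normalization,
                                   e$dc_method, e$em_dc_correct,
                                   e$boxcar_width, e$drop_first_period),
    seed = raw$seed)
}
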