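#' Maximal-length shift-register sequences (m-sequences)
#'
#' An m-sequence is the +/-1-valued output of an n-stage linear-feedback
#' shift register (LFSR) driven by a primitive feedback polynomial over
#' GF(2). Its period is p = 2^n - 1, it is balanced (counts of +1 and -1
#' differ by exactly one), and its unnormalized circular autocorrelation is
#' p at lag 0 and -1 at every other lag -- a near-delta function, which is
#' what makes reverse-correlation kernel estimation work.
#'
#' Conventions: Fibonacci-style register; `taps` are polynomial exponents
#' (the feedback bit is the XOR of the register stages listed in `taps`,
#' which must include `order`); the output is taken from the last stage;
#' register bit 1 maps to +1 and bit 0 to -1.
#'
#' @param order LFSR register length n (>= 2); period is 2^n - 1.
#' @param taps Integer vector of tap positions (polynomial exponents,
#'   must include `order`). Default: the first entry of
#'   [primitive_taps()] for this order.
#' @param initial_state Nonzero 0/1 vector of length `order` giving the
#'   starting register contents. Default: all ones.
#' @return An object of class `m_sequence` with fields `order`, `taps`,
#'   `initial_state`, `values` (integer +/-1 vector of length 2^order - 1)
#'   and `p` (the period).
#' @examples
#' m <- m_sequence(7)
#' length(m$values)                      # 127
#' sum(m$values)                         # +1 or -1 (balance)
#' circular_autocorrelation(m)[1]        # 127 at lag 0
#' @export
m_sequence <- function(order, taps = NULL, initial_state = NULL) {
  if (!is.numeric(order) || length(order) != 1L || order < 2 ||
      order != round(order))
    stop("`order` must be a single integer >= 2")
  order <- as.integer(order)
  if (is.null(taps)) taps <- primitive_taps(order)[[1L]]
  taps <- sort(unique(as.integer(taps)))
  if (any(taps < 1L) || any(taps > order) || !(order %in% taps))
    stop("`taps` must be exponents in 1..order and include `order` itself")
  if (is.null(initial_state)) initial_state <- rep(1L, order)
  initial_state <- as.integer(initial_state)
  if (length(initial_state) != order || any(!initial_state %in% c(0L, 1L)))
    stop("`initial_state` must be a 0/1 vector of length `order`")
  if (all(initial_state == 0L))
    stop("`initial_state` must be nonzero (the all-zero state is absorbing)")

  p <- as.integer(2^order - 1)
  state <- initial_state
  bits <- integer(p)
  period <- NA_integer_
  for (k in seq_len(p)) {
    bits[k] <- state[order]
    fb <- sum(state[taps]) %% 2L
    state <- c(fb, state[-order])
    if (is.na(period) && all(state == initial_state)) period <- k
  }
  if (is.na(period) || period != p)
    stop(sprintf(
      "taps (%s) do not define a primitive polynomial of degree %d: LFSR period %s != %d",
      paste(taps, collapse = ","), order,
      ifelse(is.na(period), paste0(">", p), period), p))

  out <- list(order = order, taps = taps, initial_state = initial_state,
              values = ifelse(bits == 1L, 1L, -1L), p = p)
  class(out) <- "m_sequence"
  out
}

#' @export
print.m_sequence <- function(x, ...) {
  cat(sprintf("m-sequence: order %d, period %d, taps {%s}\n",
              x$order, x$p, paste(x$taps, collapse = ",")))
  cat(sprintf("  net sum %+d; first 16 steps: %s ...\n", sum(x$values),
              paste(sprintf("%+d", utils::head(x$values, 16)), collapse = " ")))
  invisible(x)
}

#' Built-in primitive polynomial tap sets
#'
#' Tap sets (polynomial exponents, Fibonacci convention) of primitive
#' polynomials over GF(2) for degrees 3 to 10. Degree 7 lists all 18
#' primitive polynomials, so distinct-sequence pairs and whole-family
#' statistics (e.g. the figure-excursion spread across every degree-7
#' drive) are available without search; other degrees list two or three.
#' Every entry is validated empirically: [m_sequence()] fails unless the
#' LFSR period equals 2^n - 1.
#'
#' @param order Polynomial degree, in 3..10.
#' @return A list of integer tap vectors.
#' @export
primitive_taps <- function(order) {
  tab <- list(
    `3`  = list(c(1L, 3L), c(2L, 3L)),
    `4`  = list(c(1L, 4L), c(3L, 4L)),
    `5`  = list(c(2L, 5L), c(3L, 5L), c(1L, 2L, 3L, 5L)),
    `6`  = list(c(1L, 6L), c(5L, 6L), c(1L, 2L, 5L, 6L)),
    `7`  = list(
      c(1L, 7L), c(3L, 7L), c(4L, 7L), c(6L, 7L),
      c(1L, 2L, 3L, 7L), c(1L, 2L, 5L, 7L), c(1L, 3L, 5L, 7L),
      c(1L, 3L, 6L, 7L), c(1L, 4L, 6L, 7L), c(2L, 3L, 4L, 7L),
      c(2L, 4L, 6L, 7L), c(2L, 5L, 6L, 7L), c(3L, 4L, 5L, 7L),
      c(4L, 5L, 6L, 7L), c(1L, 2L, 3L, 4L, 5L, 7L),
      c(1L, 2L, 3L, 5L, 6L, 7L), c(1L, 2L, 4L, 5L, 6L, 7L),
      c(2L, 3L, 4L, 5L, 6L, 7L)),
    `8`  = list(c(1L, 2L, 7L, 8L), c(1L, 3L, 5L, 8L), c(1L, 5L, 6L, 8L)),
    `9`  = list(c(4L, 9L), c(5L, 9L), c(1L, 2L, 7L, 9L)),
    `10` = list(c(3L, 10L), c(7L, 10L), c(1L, 2L, 5L, 10L))
  )
  key <- as.character(order)
  if (!key %in% names(tab))
    stop("no built-in primitive polynomials for degree ", order,
         " (table covers 3..10)")
  tab[[key]]
}

seq_values <- function(x) {
  if (inherits(x, "m_sequence")) return(as.numeric(x$values))
  as.numeric(x)
}

#' Circular autocorrelation of an m-sequence
#'
#' For a true m-sequence of period p the unnormalized circular
#' autocorrelation is p at lag 0 and exactly -1 at every nonzero lag.
#'
#' @param seq An `m_sequence` or a +/-1 vector of length 2^n - 1.
#' @param normalized Divide by the period p (default `FALSE`).
#' @return Numeric vector of length p, lags 0 .. p-1.
#' @export
circular_autocorrelation <- function(seq, normalized = FALSE) {
  v <- seq_values(seq)
  n <- length(v)
  if (n < 3 || log2(n + 1) != round(log2(n + 1)))
    stop("sequence length ", n, " is not of m-sequence form 2^n - 1")
  r <- circ_xcorr(v, v)
  if (normalized) r / n else r
}

#' Circular cross-correlation of two sequences
#'
#' `r[k+1] = sum_t a[t] b[t+k]` with circular indexing. Distinct
#' m-sequences of the same order have near-zero cross-correlation at every
#' lag, which bounds the cross-channel contamination of two-input
#' reverse-correlation estimates.
#'
#' @param seq_a,seq_b `m_sequence` objects or numeric vectors of equal
#'   length.
#' @param normalized Divide by the common length.
#' @return Numeric vector of lag values, lags 0 .. n-1.
#' @export
circular_crosscorrelation <- function(seq_a, seq_b, normalized = FALSE) {
  a <- seq_values(seq_a); b <- seq_values(seq_b)
  r <- circ_xcorr(a, b)
  if (normalized) r / length(a) else r
}

#' Displacement statistics of a step sequence
#'
#' Treats a +/-1 sequence as one-pixel position steps, forms the cumulative
#' position trajectory over exactly one period (starting from 0, positions
#' recorded after each step) and reports the net displacement and the
#' spread of the trajectory about its time mean. For any m-sequence the net
#' step is exactly 1 pixel (balance); for 7th-order sequences the spread is
#' a little over 3 pixels (~12-15 deg at 3.75 deg/pixel), which is what
#' keeps the figure localized during a period so each kernel can be
#' attributed to a single azimuth.
#'
#' @param seq An `m_sequence` or +/-1 step vector.
#' @return List with `net_step` (|sum of steps|, pixels) and
#'   `excursion_std` (population standard deviation of the cumulative
#'   trajectory about its mean, pixels).
#' @export
displacement_statistics <- function(seq) {
  v <- seq_values(seq)
  if (length(v) == 0L) stop("empty step sequence")
  pos <- cumsum(v)
  list(net_step = abs(sum(v)),
       excursion_std = sqrt(mean((pos - mean(pos))^2)))
}

#' Write / read an m-sequence as CSV plus JSON sidecar
#'
#' The sequence itself is a single-column CSV of +/-1 integers; generator
#' metadata (order, taps, initial state) goes to `<path>.json`. Reading
#' regenerates nothing: the stored values are used, but metadata is
#' validated against them.
#'
#' @param x An `m_sequence`.
#' @param path CSV file path; the sidecar is `paste0(path, ".json")`.
#' @return `write_msequence` returns `path` invisibly; `read_msequence`
#'   returns an `m_sequence`.
#' @export
write_msequence <- function(x, path) {
  stopifnot(inherits(x, "m_sequence"))
  utils::write.table(data.frame(value = x$values), path, sep = ",",
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  jsonlite::write_json(
    list(order = x$order, taps = x$taps, initial_state = x$initial_state),
    paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_msequence
#' @export
read_msequence <- function(path) {
  vals <- utils::read.csv(path)$value
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  out <- m_sequence(meta$order, meta$taps, meta$initial_state)
  if (!identical(as.integer(vals), out$values))
    stop("stored sequence values disagree with generator metadata in ", path)
  out
}
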