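# Shared internal helpers: seeded RNG scoping, circular arithmetic,
# circular correlation/convolution primitives used across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's
# RNG state afterwards. seed = NULL runs `code` in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Wrap azimuth angles (degrees) into (-180, 180].
wrap_azimuth <- function(x) {
  w <- x %% 360
  ifelse(w > 180, w - 360, w)
}

# Circular mean of angles in degrees, returned in (-180, 180].
circular_mean_deg <- function(x) {
  r <- x * pi / 180
  wrap_azimuth(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

# Unnormalized circular cross-correlation:
#   r[k + 1] = sum_t a[t] * b[(t + k - 1) %% n + 1],  k = 0 .. n-1.
# Computed by FFT; a and b must have equal length.
circ_xcorr <- function(a, b) {
  n <- length(a)
  if (length(b) != n)
    stop("circular cross-correlation requires equal lengths (", n,
         " vs ", length(b), ")")
  out <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / n
  # fold tiny imaginary residue; result is exact to float tolerance
  out
}

# Causal linear (non-circular) convolution truncated to length(x):
#   y[t] = sum_{tau <= t} x[tau] * k[t - tau + 1]
causal_conv <- function(x, k) {
  n <- length(x)
  m <- stats::nextn(n + length(k) - 1L, 2)
  xf <- stats::fft(c(x, rep(0, m - n)))
  kf <- stats::fft(c(k, rep(0, m - length(k))))
  Re(stats::fft(xf * kf, inverse = TRUE) / m)[seq_len(n)]
}

# Circular moving average along a vector with an n_w-point unit-sum window
# (anchor at floor((n_w + 1) / 2)); preserves the mean exactly.
circ_boxcar <- function(x, n_w) {
  n <- length(x)
  if (n_w <= 1L) return(x)
  anchor <- floor((n_w + 1) / 2)
  offs <- seq_len(n_w) - anchor
  acc <- numeric(n)
  for (o in offs) acc <- acc + x[((seq_len(n) - 1 + o) %% n) + 1]
  acc / n_w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full-precision numeric formatting for text persistence (%.17g round-trips
# IEEE doubles exactly).
fmt_dbl <- function(x) sprintf("%.17g", x)
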