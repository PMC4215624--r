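#' STAF population container
#'
#' A set of same-shaped STAF grids, one per individual, for group-level
#' inference (pixelwise paired t maps, dimensionality analysis).
#'
#' @param members List of [staf()] objects or numeric matrices sharing
#'   one shape.
#' @param group_label Optional label for the group.
#' @return An object of class `staf_population`.
#' @export
staf_population <- function(members, group_label = NULL) {
  grids <- lapply(members, function(m) if (inherits(m, "staf")) m$grid else
    as.matrix(m))
  if (length(grids) < 2L) stop("a population needs n >= 2 members")
  d <- dim(grids[[1L]])
  if (!all(vapply(grids, function(g) identical(dim(g), d), TRUE)))
    stop("all members must share one grid shape")
  structure(list(members = grids, group_label = group_label, dim = d),
            class = "staf_population")
}

#' @export
print.staf_population <- function(x, ...) {
  cat(sprintf("STAF population '%s': n = %d members, %d x %d grids\n",
              x$group_label %||% "", length(x$members), x$dim[1], x$dim[2]))
  invisible(x)
}

#' Pixelwise paired t map between two STAF populations
#'
#' For each (time, azimuth) pixel, a paired two-tailed t test across the
#' n individuals (members are paired by list position; df = n - 1). No
#' variance pooling across pixels.
#'
#' @param pop_a,pop_b [staf_population()]s with equal n and shape.
#' @return An object of class `staf_comparison` with matrices `t_map`
#'   and `p_map` and the pair count `n`.
#' @export
paired_t_map <- function(pop_a, pop_b) {
  stopifnot(inherits(pop_a, "staf_population"),
            inherits(pop_b, "staf_population"))
  n <- length(pop_a$members)
  if (length(pop_b$members) != n)
    stop("populations must have equal n for a paired test")
  if (!identical(pop_a$dim, pop_b$dim)) stop("grid shapes differ")
  if (n < 2L) stop("paired t test needs n >= 2")
  diffs <- vapply(seq_len(n),
                  function(i) pop_a$members[[i]] - pop_b$members[[i]],
                  matrix(0, pop_a$dim[1], pop_a$dim[2]))
  dim(diffs) <- c(prod(pop_a$dim), n)
  mbar <- rowMeans(diffs)
  sdev <- sqrt(rowSums((diffs - mbar)^2) / (n - 1))
  tval <- mbar / (sdev / sqrt(n))
  tval[sdev == 0 & mbar == 0] <- 0          # identical pairs: no effect
  pval <- 2 * stats::pt(-abs(tval), df = n - 1)
  pval[is.na(pval)] <- 1                    # zero-variance nonzero mean -> t = Inf handled below
  pval[is.infinite(tval)] <- 0
  structure(list(t_map = matrix(tval, pop_a$dim[1], pop_a$dim[2]),
                 p_map = matrix(pval, pop_a$dim[1], pop_a$dim[2]),
                 n = n),
            class = "staf_comparison")
}

#' Benjamini-Hochberg FDR rejection set
#'
#' Step-up procedure: with m sorted p-values, find the largest k with
#' `p_(k) <= k q / m` and reject the k smallest (ties with the threshold
#' p-value are all rejected). Implemented via the equivalent adjusted
#' p-value route (`stats::p.adjust(method = "BH") <= q`). Appropriate for
#' STAF pixel maps, where neighboring pixels are positively correlated.
#'
#' @param p_values Numeric vector/matrix of p-values in \[0, 1\].
#' @param q Target false discovery rate in (0, 1).
#' @return Logical rejection mask, same shape as `p_values`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value set")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  rej <- stats::p.adjust(as.numeric(p_values), method = "BH") <= q
  if (is.matrix(p_values)) dim(rej) <- dim(p_values)
  rej
}

#' Compare two STAF populations with FDR control
#'
#' Convenience wrapper: pixelwise paired t map, then Benjamini-Hochberg
#' correction at level `q`.
#'
#' @inheritParams paired_t_map
#' @param q FDR level (default 0.05).
#' @return A `staf_comparison` with `t_map`, `p_map`, `q` and
#'   `rejection_mask`.
#' @export
staf_compare <- function(pop_a, pop_b, q = 0.05) {
  cmp <- paired_t_map(pop_a, pop_b)
  cmp$q <- q
  cmp$rejection_mask <- bh_fdr(cmp$p_map, q)
  cmp
}

#' @export
print.staf_comparison <- function(x, ...) {
  cat(sprintf("STAF comparison: paired t over %d pairs, %d x %d pixels\n",
              x$n, nrow(x$t_map), ncol(x$t_map)))
  if (!is.null(x$rejection_mask))
    cat(sprintf("  BH at q = %g: %d of %d pixels rejected\n", x$q,
                sum(x$rejection_mask), length(x$rejection_mask)))
  invisible(x)
}

#' Dimensionality of a STAF population by SVD
#'
#' Flattens each member grid into a row, stacks them and takes the
#' singular value decomposition. The variance fractions (squared singular
#' values, normalized to sum to 1) measure how many modes the population
#' really spans; a dominant first fraction means individuals are near
#' scalar multiples of one shared field. Members are not mean-centered by
#' default (the fractions then describe the fields themselves, not their
#' deviations from the group mean); `center = TRUE` gives the PCA-style
#' alternative.
#'
#' @param population A [staf_population()].
#' @param center Subtract the population mean grid first (default
#'   `FALSE`).
#' @return List with `components` (right singular vectors, one mode per
#'   column, each reshaped to the grid on demand via `dim`),
#'   `singular_values` and `variance_fractions` (sums to 1).
#' @export
staf_population_svd <- function(population, center = FALSE) {
  stopifnot(inherits(population, "staf_population"))
  X <- do.call(rbind, lapply(population$members, as.numeric))
  if (center) X <- sweep(X, 2L, colMeans(X))
  if (all(X == 0)) stop("degenerate population: all members are zero")
  s <- svd(X)
  vf <- s$d^2 / sum(s$d^2)
  list(components = s$v, singular_values = s$d, variance_fractions = vf,
       grid_dim = population$dim)
}

#' Persist / load a comparison result as text
#'
#' t map, p map and rejection mask as CSV blocks plus a JSON sidecar.
#'
#' @param x A `staf_comparison`.
#' @param path Base CSV path; writes `<path>` (t map), `<path>.p.csv`,
#'   `<path>.mask.csv` and `<path>.json`.
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "staf_comparison"))
  wm <- function(m, f) writeLines(
    apply(m, 1L, function(r) paste(fmt_dbl(as.numeric(r)), collapse = ",")), f)
  wm(x$t_map, path)
  wm(x$p_map, paste0(path, ".p.csv"))
  if (!is.null(x$rejection_mask))
    wm(x$rejection_mask + 0, paste0(path, ".mask.csv"))
  jsonlite::write_json(list(n = x$n, q = x$q %||% NA),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
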