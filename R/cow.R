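#' Correlation optimized warping (COW) of one signal onto a reference
#'
#' Aligns `signal` to `reference` by piecewise-linear warping: the signal
#' is divided into segments whose boundary nodes may shift by at most
#' `slack` grid points, and dynamic programming finds the monotone warp
#' (endpoints fixed) maximizing the sum of per-segment Pearson
#' correlations between the linearly interpolated, warped signal and the
#' reference. Constant segments contribute a similarity of 0. Ties are
#' broken toward the identity warp.
#'
#' @param signal numeric vector to warp.
#' @param reference numeric vector of the same length.
#' @param segment_len segment length in grid points (2 <= segment_len <
#'   N; default ~N/100). A short trailing remainder is absorbed into the
#'   last segment.
#' @param slack maximal node shift in grid points (0 <= slack <
#'   segment_len). `slack = 0` returns the input unchanged.
#' @return object of class `cow_warp`: list with `warped` (signal
#'   resampled onto the reference grid), `shifts` (integer node shifts,
#'   endpoints 0), `boundaries` (1-based node positions on the grid),
#'   `score` (total correlation) and `segment_scores`.
#' @export
cow_align <- function(signal, reference,
                      segment_len = max(10, round(length(signal) / 100)),
                      slack = 15) {
  n <- length(signal)
  if (length(reference) != n) {
    stop("'signal' and 'reference' must have the same length")
  }
  if (any(!is.finite(signal)) || any(!is.finite(reference))) {
    stop("signals must be finite")
  }
  segment_len <- as.integer(segment_len)
  slack <- as.integer(slack)
  if (segment_len < 2 || segment_len >= n) {
    stop("'segment_len' must satisfy 2 <= segment_len < length(signal)")
  }
  if (slack < 0 || slack >= segment_len) {
    stop("'slack' must satisfy 0 <= slack < segment_len")
  }

  b <- cow_boundaries(n, segment_len)
  if (slack == 0) {
    res <- list(warped = signal, shifts = integer(length(b)), score = NA_real_,
                segment_scores = rep(NA_real_, length(b) - 1))
  } else {
    res <- cow_dp(signal, reference, b - 1L, slack)
  }
  structure(list(warped = res$warped, shifts = as.integer(res$shifts),
                 boundaries = b, score = res$score,
                 segment_scores = res$segment_scores),
            class = "cow_warp")
}

# 1-based segment boundary nodes: multiples of segment_len, with the final
# node forced to N; a trailing remainder shorter than 2 points is merged
# into the last segment.
cow_boundaries <- function(n, segment_len) {
  b <- seq(1L, n, by = segment_len)
  if (b[length(b)] != n) {
    if (n - b[length(b)] >= 2) b <- c(b, n) else b[length(b)] <- n
  }
  if (length(b) < 2) b <- c(1L, n)
  as.integer(b)
}

#' @export
print.cow_warp <- function(x, ...) {
  cat(sprintf("COW warp: %d segments, node shifts in [%d, %d], total score %s\n",
              length(x$boundaries) - 1, min(x$shifts), max(x$shifts),
              format(x$score)))
  invisible(x)
}
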