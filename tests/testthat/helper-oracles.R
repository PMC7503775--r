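# Independent oracles used by the property tests. These deliberately avoid
# the package's own code paths: plain-R interpolation/correlation for COW,
# assignment enumeration for the clustering objective, and lattice
# enumeration for neutral-loss decomposition.

# Per-segment Pearson correlation, R implementation (constant segments -> 0).
seg_corr_oracle <- function(signal, reference, b0, b1, ss, se) {
  L <- b1 - b0
  pos <- ss + (se - ss) * (0:L) / L
  pos <- pmin(pmax(pos, 1), length(signal))
  x <- stats::approx(seq_along(signal), signal, pos)$y
  y <- reference[b0:b1]
  # same degeneracy contract as the implementation: segments whose summed
  # squared deviation is negligible relative to their energy score 0
  n <- length(x)
  vx <- sum(x^2) - sum(x)^2 / n
  vy <- sum(y^2) - sum(y)^2 / n
  if (vx <= 1e-12 * max(1, sum(x^2)) || vy <= 1e-12 * max(1, sum(y^2))) {
    return(0)
  }
  stats::cor(x, y)
}

cow_score_oracle <- function(signal, reference, boundaries, shifts) {
  tot <- 0
  for (k in seq_len(length(boundaries) - 1)) {
    ss <- boundaries[k] + shifts[k]
    se <- boundaries[k + 1] + shifts[k + 1]
    if (se <= ss) return(-Inf)
    tot <- tot + seg_corr_oracle(signal, reference, boundaries[k],
                                 boundaries[k + 1], ss, se)
  }
  tot
}

# Exhaustive search over all feasible node-shift vectors.
cow_exhaustive <- function(signal, reference, segment_len, slack) {
  b <- seq(1L, length(signal), by = segment_len)
  if (b[length(b)] != length(signal)) {
    if (length(signal) - b[length(b)] >= 2) {
      b <- c(b, length(signal))
    } else {
      b[length(b)] <- length(signal)
    }
  }
  ni <- length(b) - 2
  grid <- expand.grid(rep(list(-slack:slack), ni))
  best <- -Inf
  best_shifts <- NULL
  for (r in seq_len(nrow(grid))) {
    sh <- c(0L, as.integer(grid[r, ]), 0L)
    sc <- cow_score_oracle(signal, reference, b, sh)
    if (sc > best) {
      best <- sc
      best_shifts <- sh
    }
  }
  list(score = best, shifts = best_shifts, boundaries = b)
}

# Minimum within-group SS over every surjective assignment of n profiles to
# k groups, fully vectorised over the 4^n assignment rows.
partition_oracle_min_ss <- function(profiles, k) {
  n <- nrow(profiles)
  A <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  keep <- rowSums(sapply(seq_len(k), function(g) {
    rowSums(A == g) > 0
  })) == k
  A <- A[keep, , drop = FALSE]
  total <- sum(profiles^2)
  between_part <- 0
  for (g in seq_len(k)) {
    mask <- (A == g) * 1
    counts <- rowSums(mask)
    gs <- mask %*% profiles
    between_part <- between_part + rowSums(gs^2) / counts
  }
  min(total - between_part)
}

# All residue multisets of size <= max_n summing to delta, by filtering
# non-decreasing index tuples (independent of the package's DFS).
decompose_oracle <- function(delta, max_n, residues) {
  nms <- sort(names(residues))
  ms <- unname(residues[nms])
  out <- list()
  if (delta == 0) out[[1]] <- character(0)
  for (s in seq_len(max_n)) {
    tuples <- as.matrix(expand.grid(rep(list(seq_along(nms)), s)))
    nondec <- rowSums(tuples[, -1, drop = FALSE] >=
                        tuples[, -s, drop = FALSE]) == (s - 1)
    tuples <- tuples[nondec, , drop = FALSE]
    sums <- matrix(ms[tuples], nrow(tuples), s)
    hits <- which(rowSums(sums) == delta)
    for (h in hits) out[[length(out) + 1]] <- nms[tuples[h, ]]
  }
  out
}

canon_multisets <- function(lst) {
  sort(vapply(lst, function(x) paste(sort(x), collapse = "+"), character(1)))
}
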