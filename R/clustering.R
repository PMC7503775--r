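#' Cluster effect time profiles by maximum between-group sum of squares
#'
#' Partitions metabolite time profiles (days as variables) into `k`
#' groups maximizing the between-group sum of squares - equivalently,
#' minimizing the within-group sum of squares, the k-means objective. For
#' at most `exhaustive_limit` profiles the optimum is found by exhaustive
#' enumeration of all partitions into exactly `k` non-empty groups
#' (restricted growth strings); above that, `stats::kmeans` with
#' `n_restarts` random starts is used under a fixed seed. Cluster labels
#' `A`-`D` (or up to `k`) are assigned by descending cluster mean at the
#' first day, which makes labelling deterministic.
#'
#' @param profiles numeric matrix, profiles in rows (e.g. from
#'   [effect_time_profiles()]), time points in columns.
#' @param k number of groups (default 4).
#' @param n_restarts random restarts for the k-means search.
#' @param seed integer seed for the k-means path.
#' @param exhaustive_limit maximum number of profiles for exhaustive
#'   search.
#' @return object of class `cluster_result`: list with `assignment`
#'   (named factor of cluster letters), `centers` (k x days), `within_ss`,
#'   `between_ss`, `total_ss`, `profiles`, `k`.
#' @export
cluster_time_profiles <- function(profiles, k = 4, n_restarts = 50,
                                  seed = 1, exhaustive_limit = 12) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < k) stop("need at least k = ", k, " profiles")
  if (any(!is.finite(profiles))) stop("profiles must be finite")
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("profile", seq_len(n))
  }
  grand <- colMeans(profiles)
  total_ss <- sum(sweep(profiles, 2, grand)^2)

  if (n <= exhaustive_limit) {
    assign_idx <- best_partition_exhaustive(profiles, k)
  } else {
    set.seed(seed)
    km <- stats::kmeans(profiles, centers = k, nstart = n_restarts,
                        iter.max = 100)
    assign_idx <- km$cluster
  }

  centers <- t(vapply(seq_len(k), function(g) {
    colMeans(profiles[assign_idx == g, , drop = FALSE])
  }, numeric(ncol(profiles))))
  within_ss <- sum(vapply(seq_len(k), function(g) {
    sum(sweep(profiles[assign_idx == g, , drop = FALSE], 2, centers[g, ])^2)
  }, numeric(1)))

  # Deterministic labels: descending center value at the first day.
  ord <- order(centers[, 1], decreasing = TRUE)
  labels <- LETTERS[seq_len(k)]
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  assignment <- factor(labels[relabel[assign_idx]], levels = labels)
  names(assignment) <- rownames(profiles)
  centers <- centers[ord, , drop = FALSE]
  rownames(centers) <- labels
  colnames(centers) <- colnames(profiles)

  structure(list(assignment = assignment, centers = centers,
                 within_ss = within_ss, between_ss = total_ss - within_ss,
                 total_ss = total_ss, profiles = profiles, k = k),
            class = "cluster_result")
}

# Exhaustive minimum within-group SS over all partitions of n profiles
# into exactly k non-empty groups, enumerated as restricted growth
# strings. Returns the best assignment vector (1..k).
best_partition_exhaustive <- function(profiles, k) {
  n <- nrow(profiles)
  best <- new.env(parent = emptyenv())
  best$ss <- Inf
  best$assign <- NULL
  assign <- integer(n)

  recurse <- function(i, used) {
    if (n - i + 1 < k - used) return(invisible(NULL))  # cannot fill k groups
    if (i > n) {
      if (used == k) {
        ss <- partition_within_ss(profiles, assign, k)
        if (ss < best$ss) {
          best$ss <- ss
          best$assign <- assign
        }
      }
      return(invisible(NULL))
    }
    for (g in seq_len(min(used + 1, k))) {
      assign[i] <<- g
      recurse(i + 1, max(used, g))
    }
    invisible(NULL)
  }
  recurse(1, 0)
  best$assign
}

partition_within_ss <- function(profiles, assign, k) {
  ss <- 0
  for (g in seq_len(k)) {
    rows <- profiles[assign == g, , drop = FALSE]
    ss <- ss + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  ss
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("profile clustering: %d profiles in %d groups; between-SS %.4g / total-SS %.4g (%.1f%%)\n",
              nrow(x$profiles), x$k, x$between_ss, x$total_ss,
              100 * x$between_ss / x$total_ss))
  print(table(x$assignment))
  invisible(x)
}

#' Mahalanobis distances between cluster mean profiles
#'
#' `d(i, j) = sqrt((mu_i - mu_j)' S^-1 (mu_i - mu_j))` with `S` the
#' pooled within-cluster covariance. When `S` is singular (few profiles
#' or collinear days) a ridge of `1e-8 * trace(S) / p` is added to the
#' diagonal, unless `ridge = FALSE`, in which case singularity is an
#' error.
#'
#' @param cluster_result a `cluster_result`.
#' @param ridge logical; allow the ridge fallback.
#' @return symmetric k x k distance matrix with zero diagonal.
#' @export
mahalanobis_between_clusters <- function(cluster_result, ridge = TRUE) {
  stopifnot(inherits(cluster_result, "cluster_result"))
  profiles <- cluster_result$profiles
  assign <- cluster_result$assignment
  k <- cluster_result$k
  p <- ncol(profiles)
  n <- nrow(profiles)
  if (n - k < 1) stop("no degrees of freedom for the pooled covariance")

  S <- matrix(0, p, p)
  for (g in levels(assign)) {
    rows <- profiles[assign == g, , drop = FALSE]
    if (nrow(rows) > 1) {
      S <- S + crossprod(sweep(rows, 2, colMeans(rows)))
    }
  }
  S <- S / (n - k)

  inv <- tryCatch(solve(S), error = function(e) NULL)
  if (is.null(inv)) {
    if (!ridge) stop("pooled within-cluster covariance is singular")
    S <- S + diag(1e-8 * max(sum(diag(S)), .Machine$double.eps) / p, p)
    inv <- solve(S)
  }

  centers <- cluster_result$centers
  d <- matrix(0, k, k, dimnames = list(rownames(centers), rownames(centers)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      delta <- centers[i, ] - centers[j, ]
      d[i, j] <- d[j, i] <- sqrt(drop(t(delta) %*% inv %*% delta))
    }
  }
  d
}
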