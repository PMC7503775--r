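#' Contingency table of metabolite categories per treatment
#'
#' Cross-tabulates the per-treatment drought-response categories into a
#' treatments x 6 table whose row sums equal the number of metabolites.
#'
#' @param classification an `effect_classification` (or a `data.frame`
#'   with columns `treatment` and `category`).
#' @return integer matrix, treatments in rows, the six categories in
#'   columns.
#' @export
category_table <- function(classification) {
  cats <- if (inherits(classification, "effect_classification")) {
    classification$categories
  } else classification
  stopifnot(all(c("treatment", "category") %in% names(cats)))
  lev <- category_levels()
  tab <- table(factor(cats$treatment, levels = unique(cats$treatment)),
               factor(cats$category, levels = lev))
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  names(dimnames(m)) <- c("treatment", "category")
  m
}

#' Permutation chi-square test for independence on a contingency table
#'
#' Computes the Pearson chi-square statistic and a Monte-Carlo
#' permutation p-value by sampling `n_perm` tables with both margins
#' fixed (Patefield's algorithm via `r2dtable`):
#' `p = (1 + #\{X2_perm >= X2_obs\}) / (1 + n_perm)`.
#'
#' @param counts non-negative integer matrix with positive margins.
#' @param n_perm number of Monte-Carlo tables.
#' @param seed integer seed.
#' @return object of class `htest` with `statistic` (X-squared) and
#'   `p.value`.
#' @export
permutation_chisq <- function(counts, n_perm = 100000, seed = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all-zero table")
  rs <- rowSums(counts)
  cs <- colSums(counts)
  keep_r <- rs > 0
  keep_c <- cs > 0
  counts_eff <- counts[keep_r, keep_c, drop = FALSE]
  rs <- rs[keep_r]
  cs <- cs[keep_c]

  chisq_stat <- function(tab, expected) sum((tab - expected)^2 / expected)
  expected <- outer(rs, cs) / sum(counts_eff)
  observed <- chisq_stat(counts_eff, expected)

  set.seed(seed)
  n_ge <- 0L
  chunk <- 20000L
  left <- as.integer(n_perm)
  while (left > 0) {
    b <- min(chunk, left)
    tabs <- stats::r2dtable(b, rs, cs)
    stats_b <- vapply(tabs, chisq_stat, numeric(1), expected = expected)
    n_ge <- n_ge + sum(stats_b >= observed - 1e-12)
    left <- left - b
  }
  p <- (1 + n_ge) / (1 + n_perm)

  structure(list(
    statistic = c("X-squared" = observed),
    parameter = c("n_perm" = n_perm),
    p.value = p,
    method = "Pearson chi-square test for independence with fixed-margin permutation p-value",
    data.name = deparse(substitute(counts))
  ), class = "htest")
}
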