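#' Log-transform a metabolite table
#'
#' Applies `log2(1e9 * v)` to every value, putting integrated peak values
#' (AU*min per unit mass, typically tiny) on an interpretable positive
#' log2 scale where planted multiplicative effects become additive.
#' Zeros are replaced by half the smallest positive value of the same
#' variable (with a warning); negative values are an error.
#'
#' @param table a `metabolite_table`, or a numeric matrix.
#' @return the input with transformed values.
#' @export
log_transform <- function(table) {
  v <- if (inherits(table, "metabolite_table")) table$values else table
  if (any(v < 0)) stop("metabolite values must be non-negative")
  zeros <- which(v == 0, arr.ind = TRUE)
  if (nrow(zeros) > 0) {
    warning(nrow(zeros), " zero value(s) replaced by half the smallest ",
            "positive value of their variable")
    for (j in unique(zeros[, 2])) {
      pos <- v[, j][v[, j] > 0]
      if (length(pos) == 0) {
        stop("variable ", j, " is identically zero and cannot be log-transformed")
      }
      v[v[, j] == 0, j] <- min(pos) / 2
    }
  }
  v <- log2(1e9 * v)
  if (inherits(table, "metabolite_table")) {
    table$values <- v
    attr(table, "log2_transformed") <- TRUE
    table
  } else {
    v
  }
}

# Resolve (values matrix, design data.frame) from the flexible inputs the
# statistics functions accept.
resolve_table <- function(table, design = NULL) {
  if (inherits(table, "metabolite_table")) {
    if (is.null(design)) design <- table$design
    values <- table$values
  } else {
    values <- as.matrix(table)
  }
  if (is.null(design)) stop("a design table is required")
  if (nrow(values) != nrow(design)) {
    stop("values and design disagree on the number of samples")
  }
  list(values = values, design = design)
}

# F-tests for every term of the full factorial V*T*D model, fitted jointly
# for all metabolite columns through one QR decomposition of the shared
# model matrix. Requires a balanced (orthogonal) design, where sequential
# sums of squares are order-invariant and equal the classical ANOVA SS.
factorial_anova_matrix <- function(Y, variety, day, condition) {
  V <- factor(variety)
  Tm <- factor(day)
  D <- factor(condition)
  if (nlevels(V) < 2 || nlevels(Tm) < 2 || nlevels(D) < 2) {
    stop("each of variety, day and condition needs at least 2 levels")
  }
  cells <- table(V, Tm, D)
  if (any(cells < 1)) stop("every (variety, day, condition) cell needs at least 1 replicate")
  if (length(unique(as.vector(cells))) != 1) {
    stop("the factorial design must be balanced")
  }
  mm <- stats::model.matrix(~ V * Tm * D)
  asgn <- attr(mm, "assign")
  labels <- c("V", "T", "D", "VT", "VD", "TD", "VTD")
  qr_x <- qr(mm)
  if (qr_x$rank < ncol(mm)) {
    aliased <- labels[unique(asgn[qr_x$pivot[(qr_x$rank + 1):ncol(mm)]])]
    stop("rank-deficient design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  qty <- qr.qty(qr_x, Y)
  n <- nrow(Y)
  p <- ncol(mm)
  df_res <- n - p
  if (df_res < 1) stop("no residual degrees of freedom")
  ss_res <- colSums(qty[(p + 1):n, , drop = FALSE]^2)

  pvals <- matrix(NA_real_, ncol(Y), length(labels),
                  dimnames = list(colnames(Y), labels))
  fstat <- pvals
  for (k in seq_along(labels)) {
    rows <- which(asgn == k)
    df_k <- length(rows)
    ss_k <- colSums(qty[rows, , drop = FALSE]^2)
    f <- (ss_k / df_k) / (ss_res / df_res)
    fstat[, k] <- f
    pvals[, k] <- stats::pf(f, df_k, df_res, lower.tail = FALSE)
  }
  list(p = pvals, f = fstat, df_res = df_res)
}

#' Classify metabolite drought effects by factorial ANOVA
#'
#' Per treatment, fits the full fixed-effects factorial model variety x
#' time x condition (V*T*D) to every metabolite on the log2 scale and
#' computes F-tests for all seven terms. Within each drought-effect
#' family (D, VD, TD, VTD) significance is declared at `p <
#' alpha_fwer / m` across the `m` metabolites (Bonferroni, family-wise
#' error rate below `alpha_fwer` independently per family). The category
#' is then assigned by precedence: VTD significant -> `VTD`; else both VD
#' and TD -> `VD_TD`; else TD -> `TD`; else VD -> `VD`; else D -> `D`;
#' else `NoEffect`.
#'
#' @param table log2-transformed `metabolite_table`, or a numeric matrix
#'   (samples x metabolites).
#' @param design matching `design_table` (taken from the table when
#'   attached).
#' @param alpha_fwer family-wise error rate per effect family.
#' @return object of class `effect_classification`: list with
#'   `categories` (`data.frame`: `metabolite`, `treatment`, `category`),
#'   `pvalues` (per-treatment matrices metabolites x terms),
#'   `alpha_fwer`, `m`.
#' @export
classify_effects <- function(table, design = NULL, alpha_fwer = 0.05) {
  rt <- resolve_table(table, design)
  values <- rt$values
  design <- rt$design
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  }
  m <- ncol(values)
  treatments <- unique(design$treatment)
  lev <- category_levels()

  pvalues <- list()
  cats <- list()
  for (tr in treatments) {
    sel <- design$treatment == tr
    an <- factorial_anova_matrix(values[sel, , drop = FALSE],
                                 design$variety[sel], design$day[sel],
                                 design$condition[sel])
    p <- an$p
    thr <- alpha_fwer / m
    sig <- p < thr
    category <- rep("NoEffect", m)
    category[sig[, "D"]] <- "D"
    category[sig[, "VD"] & !sig[, "TD"]] <- "VD"
    category[sig[, "TD"] & !sig[, "VD"]] <- "TD"
    category[sig[, "VD"] & sig[, "TD"]] <- "VD_TD"
    category[sig[, "VTD"]] <- "VTD"
    pvalues[[tr]] <- p
    cats[[tr]] <- data.frame(metabolite = colnames(values), treatment = tr,
                             category = factor(category, levels = lev),
                             stringsAsFactors = FALSE)
  }
  categories <- do.call(rbind, cats)
  rownames(categories) <- NULL
  structure(list(categories = categories, pvalues = pvalues,
                 alpha_fwer = alpha_fwer, m = m),
            class = "effect_classification")
}

#' @export
print.effect_classification <- function(x, ...) {
  cat(sprintf("effect classification: %d metabolites, FWER %.3g per family (Bonferroni p < %.2e)\n",
              x$m, x$alpha_fwer, x$alpha_fwer / x$m))
  print(table(x$categories$treatment, x$categories$category))
  invisible(x)
}

#' Treatment effects per experimental combination
#'
#' The effect of moisture deficit for a metabolite in a (variety, day)
#' cell is the drought cell mean minus the matched control cell mean on
#' the (log2) scale of the input. Cells without a matched control are
#' flagged missing.
#'
#' @inheritParams classify_effects
#' @return object of class `effect_profile`: `data.frame` with columns
#'   `metabolite`, `treatment`, `variety`, `day`, `effect`.
#' @export
compute_effects <- function(table, design = NULL) {
  rt <- resolve_table(table, design)
  values <- rt$values
  design <- rt$design
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  }
  key <- interaction(design$treatment, design$variety, design$day,
                     drop = TRUE)
  out <- list()
  for (cell in levels(key)) {
    rows <- key == cell
    dr <- rows & design$condition == "drought"
    co <- rows & design$condition == "control"
    tr <- design$treatment[rows][1]
    v <- design$variety[rows][1]
    d <- design$day[rows][1]
    eff <- if (any(dr) && any(co)) {
      colMeans(values[dr, , drop = FALSE]) -
        colMeans(values[co, , drop = FALSE])
    } else rep(NA_real_, ncol(values))
    out[[cell]] <- data.frame(metabolite = colnames(values), treatment = tr,
                              variety = v, day = d, effect = unname(eff),
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("effect_profile", "data.frame")
  res
}

#' Time profiles of effects, averaged over varieties
#'
#' @param effects an `effect_profile` from [compute_effects()].
#' @param treatment treatment label.
#' @param metabolites optional subset of metabolite ids.
#' @return matrix metabolites x days of mean effects (missing cells
#'   excluded from the means).
#' @export
effect_time_profiles <- function(effects, treatment, metabolites = NULL) {
  e <- effects[effects$treatment == treatment, ]
  if (!is.null(metabolites)) e <- e[e$metabolite %in% metabolites, ]
  if (nrow(e) == 0) stop("no effects for treatment ", treatment)
  days <- sort(unique(e$day))
  mets <- unique(e$metabolite)
  m <- matrix(NA_real_, length(mets), length(days),
              dimnames = list(mets, as.character(days)))
  agg <- stats::aggregate(effect ~ metabolite + day, data = e, FUN = mean,
                          na.rm = TRUE, na.action = stats::na.pass)
  m[cbind(match(agg$metabolite, mets), match(agg$day, days))] <- agg$effect
  m
}

#' Variety-specific effects, averaged over days (or at one day)
#'
#' @param effects an `effect_profile`.
#' @param treatment treatment label.
#' @param day `"mean"` for the day-averaged effect, `"last"` for the
#'   final sampling day, or a specific day.
#' @param metabolites optional subset of metabolite ids.
#' @return matrix varieties x metabolites of effects.
#' @export
effect_by_variety <- function(effects, treatment, day = "mean",
                              metabolites = NULL) {
  e <- effects[effects$treatment == treatment, ]
  if (!is.null(metabolites)) e <- e[e$metabolite %in% metabolites, ]
  if (nrow(e) == 0) stop("no effects for treatment ", treatment)
  if (identical(day, "last")) day <- max(e$day)
  if (!identical(day, "mean")) e <- e[e$day == day, ]
  agg <- stats::aggregate(effect ~ metabolite + variety, data = e,
                          FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  varieties <- unique(e$variety)
  mets <- unique(e$metabolite)
  m <- matrix(NA_real_, length(varieties), length(mets),
              dimnames = list(varieties, mets))
  m[cbind(match(agg$variety, varieties), match(agg$metabolite, mets))] <-
    agg$effect
  m
}
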