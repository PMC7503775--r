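#' Classify phenotype trait responses to moisture deficit
#'
#' Per treatment, subsets the phenotype table to the control group plus
#' that treatment's group and fits the fixed two-way model variety x
#' drought (V*D) to every trait. A trait is `VD` (variety-specific
#' drought effect) when the interaction F-test has `p < alpha`; else `D`
#' (mean drought effect) when the drought main effect has `p < alpha`;
#' else `none`.
#'
#' @param pheno phenotype `data.frame`: columns `variety`, `treatment`
#'   (levels: `control` plus the treatment labels), `replicate`, and one
#'   numeric column per trait.
#' @param alpha significance level of the F-tests (default 0.01).
#' @return `data.frame` with columns `trait`, `treatment`, `class`
#'   (`none`/`D`/`VD`), `p_D`, `p_VD`.
#' @export
classify_trait_effects <- function(pheno, alpha = 0.01) {
  traits <- trait_columns(pheno)
  treatments <- setdiff(unique(pheno$treatment), "control")
  if (!"control" %in% pheno$treatment) stop("control rows are required")
  out <- list()
  for (tr in treatments) {
    sel <- pheno$treatment %in% c("control", tr)
    sub <- pheno[sel, , drop = FALSE]
    reps <- table(sub$variety, sub$treatment != "control")
    if (any(reps < 2)) stop("need >= 2 replicates per (variety, treatment) cell")
    V <- factor(sub$variety)
    D <- factor(ifelse(sub$treatment == "control", "control", "drought"))
    Y <- as.matrix(sub[, traits, drop = FALSE])
    an <- twoway_anova_matrix(Y, V, D)
    cls <- ifelse(an$p[, "VD"] < alpha, "VD",
                  ifelse(an$p[, "D"] < alpha, "D", "none"))
    out[[tr]] <- data.frame(trait = traits, treatment = tr, class = cls,
                            p_D = an$p[, "D"], p_VD = an$p[, "VD"],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Fixed-effects two-way ANOVA (V, D, V:D) for a response matrix, via one
# QR of the shared model matrix; requires a balanced design.
twoway_anova_matrix <- function(Y, V, D) {
  cells <- table(V, D)
  if (any(cells < 1)) stop("empty (variety, condition) cell")
  if (length(unique(as.vector(cells))) != 1) {
    stop("the two-way design must be balanced")
  }
  mm <- stats::model.matrix(~ V * D)
  asgn <- attr(mm, "assign")
  labels <- c("V", "D", "VD")
  qr_x <- qr(mm)
  if (qr_x$rank < ncol(mm)) stop("rank-deficient phenotype design")
  qty <- qr.qty(qr_x, Y)
  n <- nrow(Y)
  p <- ncol(mm)
  df_res <- n - p
  if (df_res < 1) stop("no residual degrees of freedom")
  ss_res <- colSums(qty[(p + 1):n, , drop = FALSE]^2)
  pvals <- matrix(NA_real_, ncol(Y), length(labels),
                  dimnames = list(colnames(Y), labels))
  for (k in seq_along(labels)) {
    rows <- which(asgn == k)
    f <- (colSums(qty[rows, , drop = FALSE]^2) / length(rows)) /
      (ss_res / df_res)
    pvals[, k] <- stats::pf(f, length(rows), df_res, lower.tail = FALSE)
  }
  list(p = pvals, df_res = df_res)
}

trait_columns <- function(pheno) {
  setdiff(names(pheno), c("variety", "treatment", "replicate"))
}

#' Mean and variety-specific treatment effects on phenotype traits
#'
#' Effects are drought group mean minus control group mean, overall or
#' per variety; with `as_percent_of_control` they are expressed as
#' percent of the control mean.
#'
#' @param pheno phenotype `data.frame` (see [classify_trait_effects()]).
#' @param as_percent_of_control express effects as percent of the
#'   control mean.
#' @param by_variety compute variety-specific effects.
#' @return `data.frame` with columns `trait`, `treatment`, (`variety`,)
#'   `effect` (and `percent` when requested).
#' @export
trait_effects <- function(pheno, as_percent_of_control = FALSE,
                          by_variety = FALSE) {
  traits <- trait_columns(pheno)
  treatments <- setdiff(unique(pheno$treatment), "control")
  if (!"control" %in% pheno$treatment) stop("control rows are required")
  out <- list()
  for (tr in treatments) {
    for (trait in traits) {
      if (by_variety) {
        for (v in unique(pheno$variety)) {
          ctrl <- pheno[[trait]][pheno$treatment == "control" &
                                   pheno$variety == v]
          drt <- pheno[[trait]][pheno$treatment == tr & pheno$variety == v]
          out[[length(out) + 1]] <- effect_row(trait, tr, v, drt, ctrl,
                                               as_percent_of_control)
        }
      } else {
        ctrl <- pheno[[trait]][pheno$treatment == "control"]
        drt <- pheno[[trait]][pheno$treatment == tr]
        out[[length(out) + 1]] <- effect_row(trait, tr, NA, drt, ctrl,
                                             as_percent_of_control)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (!by_variety) res$variety <- NULL
  res
}

effect_row <- function(trait, treatment, variety, drought, control,
                       percent) {
  cm <- mean(control)
  eff <- mean(drought) - cm
  row <- data.frame(trait = trait, treatment = treatment, variety = variety,
                    effect = eff, stringsAsFactors = FALSE)
  if (percent) {
    if (cm == 0) stop("zero control mean for trait ", trait,
                      ": percent scaling undefined")
    row$percent <- 100 * eff / cm
  }
  row
}

#' Principal-component biplot coordinates of an effect matrix
#'
#' Column-centers the varieties x traits effect matrix and takes the
#' rank-2 singular value decomposition: variety scores are the left
#' singular vectors scaled by the singular values, trait loadings are the
#' right singular vectors (principal-component biplot). With
#' `scaling = "symmetric"` both sides carry `sqrt` of the singular
#' values.
#'
#' @param effect_matrix numeric matrix, varieties in rows, traits in
#'   columns (>= 2 of each).
#' @param scaling `"pc"` (default) or `"symmetric"`.
#' @return object of class `biplot_coords`: list with `scores` (varieties
#'   x 2), `loadings` (traits x 2), `variance_explained` (length 2).
#' @export
biplot_coords <- function(effect_matrix, scaling = c("pc", "symmetric")) {
  scaling <- match.arg(scaling)
  M <- as.matrix(effect_matrix)
  if (nrow(M) < 2 || ncol(M) < 2) stop("need at least 2 varieties and 2 traits")
  C <- sweep(M, 2, colMeans(M))
  if (all(abs(C) < .Machine$double.eps * 100)) {
    stop("effect matrix has zero variance after centering")
  }
  s <- svd(C)
  d2 <- s$d^2
  ve <- d2[1:2] / sum(d2)
  scores <- switch(scaling,
    pc = s$u[, 1:2, drop = FALSE] %*% diag(s$d[1:2], 2),
    symmetric = s$u[, 1:2, drop = FALSE] %*% diag(sqrt(s$d[1:2]), 2))
  loadings <- switch(scaling,
    pc = s$v[, 1:2, drop = FALSE],
    symmetric = s$v[, 1:2, drop = FALSE] %*% diag(sqrt(s$d[1:2]), 2))
  rownames(scores) <- rownames(M)
  rownames(loadings) <- colnames(M)
  colnames(scores) <- colnames(loadings) <- c("axis1", "axis2")
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve, scaling = scaling),
            class = "biplot_coords")
}

#' @export
print.biplot_coords <- function(x, ...) {
  cat(sprintf("biplot (%s scaling): axes explain %.1f%% and %.1f%% of variance\n",
              x$scaling, 100 * x$variance_explained[1],
              100 * x$variance_explained[2]))
  invisible(x)
}

#' Pearson correlation of variety-specific metabolite and trait effects
#'
#' Correlates every metabolite effect vector with every trait effect
#' vector across varieties; two-sided p-values come from the t transform
#' with n-2 degrees of freedom. Pairs involving a zero-variance vector
#' get `NA` with `degenerate = TRUE`.
#'
#' @param metabolite_effects numeric matrix, varieties x metabolites
#'   (e.g. from [effect_by_variety()]).
#' @param trait_effects numeric matrix, varieties x traits, same variety
#'   rows.
#' @param levels two significance levels to flag (default 0.01 and
#'   0.05).
#' @return `data.frame` with columns `metabolite`, `trait`, `r`, `p`,
#'   `sig01`, `sig05`, `degenerate`.
#' @export
correlate_effects <- function(metabolite_effects, trait_effects,
                              levels = c(0.01, 0.05)) {
  M <- as.matrix(metabolite_effects)
  P <- as.matrix(trait_effects)
  if (nrow(M) != nrow(P)) stop("effect matrices must share the variety rows")
  if (!is.null(rownames(M)) && !is.null(rownames(P)) &&
      !identical(rownames(M), rownames(P))) {
    if (!setequal(rownames(M), rownames(P))) {
      stop("effect matrices must be indexed by the same varieties")
    }
    P <- P[rownames(M), , drop = FALSE]
  }
  n <- nrow(M)
  if (n < 3) stop("need at least 3 varieties")
  if (is.null(colnames(M))) colnames(M) <- paste0("M", seq_len(ncol(M)))
  if (is.null(colnames(P))) colnames(P) <- paste0("F", seq_len(ncol(P)))

  out <- expand.grid(metabolite = colnames(M), trait = colnames(P),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- NA_real_
  out$p <- NA_real_
  out$degenerate <- FALSE
  for (i in seq_len(nrow(out))) {
    x <- M[, out$metabolite[i]]
    y <- P[, out$trait[i]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      out$degenerate[i] <- TRUE
      next
    }
    r <- stats::cor(x, y)
    out$r[i] <- r
    if (abs(r) >= 1) {
      out$p[i] <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      out$p[i] <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    }
  }
  out$sig01 <- !is.na(out$p) & out$p < levels[1]
  out$sig05 <- !is.na(out$p) & out$p < levels[2]
  out
}
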