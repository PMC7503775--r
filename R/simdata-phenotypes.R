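#' Default phenotype trait specifications
#'
#' Fifteen maturity traits (tiller counts, biomass and grain weights, stem
#' and spike lengths and counts) with plausible baselines, between-variety
#' spread, and a common drought effect expressed as a fraction of the
#' baseline (negative: moisture deficit reduces yield-related traits).
#'
#' @return `data.frame` with columns `trait`, `baseline`, `variety_sd`,
#'   `effect_frac`.
#' @export
default_trait_specs <- function() {
  data.frame(
    trait = paste0("F", 1:15),
    baseline = c(22, 18, 30, 25, 45, 70, 9, 24, 22, 1.2,
                 55, 7, 18, 16, 0.8),
    variety_sd = c(3, 2.5, 4, 3.5, 4, 6, 1, 3, 3, 0.15,
                   5, 0.8, 2.5, 2.2, 0.1),
    effect_frac = c(0.05, -0.15, -0.15, -0.20, 0, -0.10, -0.12, -0.10,
                    -0.12, -0.15, -0.08, -0.10, -0.18, -0.18, -0.20),
    stringsAsFactors = FALSE
  )
}

#' Simulate maturity phenotypes linked to planted metabolite effects
#'
#' Builds a phenotype table over variety x treatment group (a shared
#' control plus one group per moisture-deficit treatment) x replicate.
#' Trait values are `variety baseline + treatment effect + noise`. For
#' traits listed in `link`, the variety-specific treatment effect is
#' `slope * (metabolite's variety-specific planted effect, averaged over
#' days) + N(0, perturb_sd)`, so the cross-variety Pearson correlation
#' between metabolite and trait effects is planted and recoverable. The
#' helper [perturb_sd_for_r()] converts a target correlation into the
#' perturbation scale.
#'
#' @param design metabolome `design_table` (supplies varieties and
#'   treatment labels).
#' @param ground_truth `ground_truth` from [simulate_experiment()] (needed
#'   when `link` is non-empty).
#' @param trait_specs see [default_trait_specs()].
#' @param link `data.frame` with columns `trait`, `metabolite`,
#'   `treatment`, `slope`, `perturb_sd`, or `NULL` for no links.
#' @param n_reps replicates per (variety, treatment group) (study design:
#'   2 phenotyping replicates).
#' @param noise_sd replicate noise, expressed as a fraction of each
#'   trait's baseline.
#' @param seed integer seed.
#' @return list with `phenotypes` (`data.frame`: `variety`, `treatment`
#'   with levels control/I/II/..., `replicate`, one column per trait) and
#'   `ground_truth` (input ground truth with `phenotype_effects` filled:
#'   `trait`, `treatment`, `variety`, `effect`).
#' @export
simulate_phenotypes <- function(design, ground_truth = NULL,
                                trait_specs = default_trait_specs(),
                                link = NULL, n_reps = 2,
                                noise_sd = 0.03, seed = 1) {
  varieties <- unique(design$variety)
  treatments <- unique(design$treatment)
  if (!is.null(link)) {
    needed <- c("trait", "metabolite", "treatment", "slope", "perturb_sd")
    if (!all(needed %in% names(link))) {
      stop("'link' needs columns: ", paste(needed, collapse = ", "))
    }
    if (is.null(ground_truth)) {
      stop("'ground_truth' is required when 'link' is given")
    }
    bad <- !link$metabolite %in% ground_truth$metabolites$metabolite
    if (any(bad)) {
      stop("unknown linked metabolite(s): ",
           paste(unique(link$metabolite[bad]), collapse = ", "))
    }
  }

  set.seed(seed)
  nv <- length(varieties)

  # Per-trait variety baselines (shared across treatment groups).
  baselines <- sapply(seq_len(nrow(trait_specs)), function(j) {
    trait_specs$baseline[j] + stats::rnorm(nv, 0, trait_specs$variety_sd[j])
  })
  dimnames(baselines) <- list(varieties, trait_specs$trait)

  # Variety-specific treatment effects per trait x treatment.
  eff_rows <- list()
  for (tr in treatments) {
    for (j in seq_len(nrow(trait_specs))) {
      trait <- trait_specs$trait[j]
      common <- trait_specs$effect_frac[j] * trait_specs$baseline[j]
      lrow <- if (is.null(link)) NULL else {
        link[link$trait == trait & link$treatment == tr, , drop = FALSE]
      }
      if (!is.null(lrow) && nrow(lrow) > 0) {
        lrow <- lrow[1, ]
        em <- true_effect_matrix(ground_truth, lrow$metabolite, tr)
        met_v <- rowMeans(em)[varieties]
        eff <- lrow$slope * met_v + stats::rnorm(nv, 0, lrow$perturb_sd)
      } else {
        eff <- rep(common, nv)
      }
      eff_rows[[paste(tr, trait)]] <- data.frame(
        trait = trait, treatment = tr, variety = varieties,
        effect = unname(eff), stringsAsFactors = FALSE)
    }
  }
  pheno_effects <- do.call(rbind, eff_rows)
  rownames(pheno_effects) <- NULL

  groups <- c("control", treatments)
  tab <- expand.grid(variety = varieties, treatment = groups,
                     replicate = seq_len(n_reps),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(nrow(trait_specs))) {
    trait <- trait_specs$trait[j]
    vals <- baselines[tab$variety, trait]
    for (tr in treatments) {
      sel <- tab$treatment == tr
      key <- pheno_effects$trait == trait & pheno_effects$treatment == tr
      eff <- stats::setNames(pheno_effects$effect[key],
                             pheno_effects$variety[key])
      vals[sel] <- vals[sel] + eff[tab$variety[sel]]
    }
    vals <- vals + stats::rnorm(nrow(tab),
                                0, noise_sd * trait_specs$baseline[j])
    tab[[trait]] <- unname(vals)
  }

  if (!is.null(ground_truth)) {
    ground_truth$phenotype_effects <- pheno_effects
  } else {
    ground_truth <- structure(list(phenotype_effects = pheno_effects),
                              class = "ground_truth")
  }
  list(phenotypes = tab, ground_truth = ground_truth)
}

#' Perturbation scale that plants a target effect correlation
#'
#' For a linked trait whose variety effect is `slope * met_effect +
#' N(0, sd)`, the cross-variety correlation with the metabolite effect is
#' `r = slope * sd(met) / sqrt(slope^2 var(met) + sd^2)`. This inverts
#' that relation.
#'
#' @param met_effects numeric vector of variety-specific metabolite
#'   effects.
#' @param slope linear link slope.
#' @param r target absolute Pearson correlation (0 < r <= 1).
#' @return perturbation standard deviation.
#' @export
perturb_sd_for_r <- function(met_effects, slope, r) {
  stopifnot(r > 0, r <= 1)
  s <- stats::sd(met_effects)
  if (s == 0) stop("metabolite effects have zero variance")
  abs(slope) * s * sqrt(1 / r^2 - 1)
}
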