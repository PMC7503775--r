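#' Full pipeline configuration
#'
#' All tunable parameters of the simulate -> preprocess -> effects ->
#' phenotypes pipeline in one validated list. Defaults emulate the
#' full-size study design (8 varieties, three moisture-deficit
#' treatments, 4 metabolome replicates, ~10000-point chromatograms);
#' reduce `n_points`, `n_varieties` or the day sets for quick runs.
#'
#' @param seed master seed for every random stage.
#' @param n_varieties,treatments,days,n_reps,mass_range design, see
#'   [make_design()].
#' @param n_metabolites,effect_size,warp_magnitude,noise_sd,baseline_magnitude,rt_range,n_points,amplitude_range,peak_width,peak_tau
#'   generator, see [simulate_experiment()].
#' @param segment_len,slack,n_knots,intensity_tolerance,c1,reference
#'   preprocessing, see [preprocess_config()].
#' @param alpha_fwer metabolite family-wise error rate (Bonferroni per
#'   effect family).
#' @param pheno_alpha phenotype trait significance level.
#' @param cluster_k number of time-profile clusters.
#' @param n_perm permutations for the category-table chi-square test.
#' @param pheno_reps phenotyping replicates.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            n_varieties = 8,
                            treatments = c("I", "II", "I+II"),
                            days = default_days(),
                            n_reps = 4,
                            mass_range = c(90, 110),
                            n_metabolites = 20,
                            effect_size = 1,
                            warp_magnitude = 0.02,
                            noise_sd = 0.02,
                            baseline_magnitude = 0.5,
                            rt_range = c(0, 25),
                            n_points = 10000,
                            amplitude_range = c(1, 3),
                            peak_width = 0.05,
                            peak_tau = 0,
                            segment_len = NULL,
                            slack = 15,
                            n_knots = NULL,
                            intensity_tolerance = 0.0005,
                            c1 = NULL,
                            reference = "median",
                            alpha_fwer = 0.05,
                            pheno_alpha = 0.01,
                            cluster_k = 4,
                            n_perm = 100000,
                            pheno_reps = 2) {
  cfg <- as.list(environment())
  seg <- if (is.null(segment_len)) max(10, round(n_points / 100)) else segment_len
  if (slack >= seg) {
    stop("'slack' (", slack, ") must be below the COW segment length (",
         seg, ")")
  }
  if (n_points < 100) stop("'n_points' must be >= 100")
  if (alpha_fwer <= 0 || alpha_fwer >= 1) stop("'alpha_fwer' must be in (0, 1)")
  if (pheno_alpha <= 0 || pheno_alpha >= 1) stop("'pheno_alpha' must be in (0, 1)")
  if (cluster_k < 2) stop("'cluster_k' must be >= 2")
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic-experiment analysis pipeline
#'
#' Simulates a dual-wavelength chromatographic experiment and linked
#' phenotypes, preprocesses the chromatograms into a metabolite table,
#' classifies drought effects and computes effect profiles, clusters the
#' time profiles of time-modified metabolites, tests the category table
#' for independence, classifies trait effects, computes biplot
#' coordinates, and correlates variety-specific metabolite and trait
#' effects. All result tables (and a machine-readable run manifest) are
#' written as TSV/JSON under `out_dir` when given.
#'
#' @param config a `pipeline_config`.
#' @param out_dir optional output directory.
#' @param verbose print per-stage progress.
#' @return list (invisibly when writing) with `chrom_set`, `table`
#'   (log2), `classification`, `effects`, `clusters` (per treatment or
#'   `NULL`), `category_table`, `chisq`, `phenotypes`,
#'   `trait_classification`, `trait_effects`, `biplots`, `correlations`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("stage simulate: design + chromatograms + phenotypes")
  design <- stage("simulate", make_design(
    n_varieties = config$n_varieties, treatments = config$treatments,
    days_per_treatment = config$days, n_reps = config$n_reps,
    mass_range = config$mass_range, seed = config$seed))
  chrom_set <- stage("simulate", simulate_experiment(
    design, n_metabolites = config$n_metabolites,
    effect_size = config$effect_size,
    warp_magnitude = config$warp_magnitude, noise_sd = config$noise_sd,
    baseline_magnitude = config$baseline_magnitude,
    rt_range = config$rt_range, n_points = config$n_points,
    amplitude_range = config$amplitude_range,
    peak_width = config$peak_width, peak_tau = config$peak_tau,
    seed = config$seed))

  # Link a couple of traits to variety-modified metabolites so the
  # correlation screen has planted structure to find.
  gt <- chrom_set$ground_truth
  link <- NULL
  vs_cats <- gt$categories[gt$categories$category %in%
                             c("VD", "VD_TD", "VTD"), , drop = FALSE]
  if (nrow(vs_cats) > 0) {
    pick <- vs_cats[1, ]
    em <- true_effect_matrix(gt, pick$metabolite, pick$treatment)
    met_v <- rowMeans(em)
    if (stats::sd(met_v) > 0) {
      link <- data.frame(trait = "F15", metabolite = pick$metabolite,
                         treatment = pick$treatment, slope = -0.2,
                         perturb_sd = perturb_sd_for_r(met_v, -0.2, 0.8),
                         stringsAsFactors = FALSE)
    }
  }
  sim_ph <- stage("simulate", simulate_phenotypes(
    design, gt, link = link, n_reps = config$pheno_reps,
    seed = config$seed + 1))
  chrom_set$ground_truth <- sim_ph$ground_truth

  say("stage preprocess: %d chromatograms", length(chrom_set$chromatograms))
  pre_cfg <- preprocess_config(
    segment_len = config$segment_len, slack = config$slack,
    n_knots = config$n_knots,
    intensity_tolerance = config$intensity_tolerance, c1 = config$c1,
    reference = config$reference)
  table_raw <- stage("preprocess",
                     run_preprocessing(chrom_set, pre_cfg,
                                       name_peaks = "ground_truth",
                                       verbose = verbose))

  say("stage effects: classification + profiles")
  table_log <- stage("effects", log_transform(table_raw))
  classification <- stage("effects", classify_effects(
    table_log, alpha_fwer = config$alpha_fwer))
  effects <- stage("effects", compute_effects(table_log))

  clusters <- list()
  for (tr in unique(design$treatment)) {
    td_mets <- classification$categories$metabolite[
      classification$categories$treatment == tr &
        classification$categories$category %in% c("TD", "VD_TD", "VTD")]
    clusters[[tr]] <- if (length(td_mets) >= config$cluster_k) {
      stage("cluster", cluster_time_profiles(
        effect_time_profiles(effects, tr, td_mets), k = config$cluster_k,
        seed = config$seed))
    } else NULL
  }

  cat_tab <- stage("category", category_table(classification))
  chisq <- if (nrow(cat_tab) >= 2 && sum(cat_tab) > 0) {
    stage("category", permutation_chisq(cat_tab, n_perm = config$n_perm,
                                        seed = config$seed))
  } else NULL

  say("stage phenotypes: trait classification + correlations")
  pheno <- sim_ph$phenotypes
  trait_class <- stage("phenotypes", classify_trait_effects(
    pheno, alpha = config$pheno_alpha))
  tr_eff <- stage("phenotypes", trait_effects(pheno, by_variety = TRUE))

  biplots <- list()
  correlations <- list()
  for (tr in unique(design$treatment)) {
    vd_traits <- trait_class$trait[trait_class$treatment == tr &
                                     trait_class$class == "VD"]
    eff_tr <- tr_eff[tr_eff$treatment == tr, ]
    eff_mat <- stats::reshape(eff_tr[, c("variety", "trait", "effect")],
                              idvar = "variety", timevar = "trait",
                              direction = "wide")
    rn <- eff_mat$variety
    eff_mat <- as.matrix(eff_mat[, -1, drop = FALSE])
    rownames(eff_mat) <- rn
    colnames(eff_mat) <- sub("^effect\\.", "", colnames(eff_mat))
    biplots[[tr]] <- if (length(vd_traits) >= 2) {
      stage("phenotypes",
            biplot_coords(eff_mat[, vd_traits, drop = FALSE]))
    } else NULL

    vs_mets <- classification$categories$metabolite[
      classification$categories$treatment == tr &
        classification$categories$category %in% c("VD", "VD_TD", "VTD")]
    correlations[[tr]] <- if (length(vs_mets) > 0) {
      met_v <- effect_by_variety(effects, tr, day = "mean",
                                 metabolites = vs_mets)
      stage("phenotypes",
            correlate_effects(met_v, eff_mat[rownames(met_v), ,
                                             drop = FALSE]))
    } else NULL
  }

  manifest <- list(
    package = "phenolomics",
    package_version = as.character(utils::packageVersion("phenolomics")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    parameters = unclass(config),
    stages = list(
      chromatograms = length(chrom_set$chromatograms),
      stage_log = attr(table_raw, "stage_log"),
      variables = ncol(table_raw$values),
      categories = as.list(as.data.frame(cat_tab)),
      clustered_treatments = names(Filter(Negate(is.null), clusters))
    )
  )

  res <- list(chrom_set = chrom_set, table = table_log,
              classification = classification, effects = effects,
              clusters = clusters, category_table = cat_tab, chisq = chisq,
              phenotypes = pheno, trait_classification = trait_class,
              trait_effects = tr_eff, biplots = biplots,
              correlations = correlations, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_metabolite_table(table_raw, file.path(out_dir, "metabolite_table.tsv"))
    write_tsv(classification$categories,
              file.path(out_dir, "classification.tsv"))
    write_tsv(effects, file.path(out_dir, "effects.tsv"))
    write_tsv(as.data.frame.table(cat_tab, responseName = "count"),
              file.path(out_dir, "category_table.tsv"))
    write_tsv(trait_class, file.path(out_dir, "trait_classification.tsv"))
    write_tsv(tr_eff, file.path(out_dir, "trait_effects.tsv"))
    corr_all <- do.call(rbind, lapply(names(correlations), function(tr) {
      if (is.null(correlations[[tr]])) return(NULL)
      cbind(treatment = tr, correlations[[tr]])
    }))
    if (!is.null(corr_all)) {
      write_tsv(corr_all, file.path(out_dir, "correlations.tsv"))
    }
    for (tr in names(clusters)) {
      if (!is.null(clusters[[tr]])) {
        cl <- clusters[[tr]]
        write_tsv(data.frame(metabolite = names(cl$assignment),
                             cluster = as.character(cl$assignment)),
                  file.path(out_dir, sprintf("clusters_%s.tsv",
                                             gsub("[^A-Za-z0-9]", "", tr))))
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(res))
  }
  res
}
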