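# Shared fixtures, built in code at test time.

# Small two-variety experiment used by several chromproc tests.
small_experiment <- function(seed = 42, n_metabolites = 12, noise_sd = 0.02,
                             warp_magnitude = 0.02, baseline_magnitude = 0.5,
                             effect_size = 1, n_points = 2000,
                             category_probs = NULL) {
  des <- make_design(2, "I", list(I = c(3, 6)), n_reps = 2, seed = seed)
  probs <- if (is.null(category_probs)) default_category_probs() else category_probs
  simulate_experiment(des, n_metabolites = n_metabolites,
                      category_probs = probs,
                      effect_size = effect_size,
                      warp_magnitude = warp_magnitude, noise_sd = noise_sd,
                      baseline_magnitude = baseline_magnitude,
                      rt_range = c(0, 20), n_points = n_points,
                      peak_width = 0.08, seed = seed)
}

# The default synthetic recovery benchmark: 20 well-separated metabolites,
# SNR >= 25 (amplitudes 1-3 AU against 0.02 AU noise, mass ~100 mg),
# retention-time warps of up to 3 grid points against a COW slack of 8.
synthetic_benchmark <- function(seed = 7) {
  des <- make_design(2, "I", list(I = c(3, 6, 10)), n_reps = 2, seed = seed)
  cs <- simulate_experiment(des, n_metabolites = 20,
                            effect_size = 1,
                            warp_magnitude = 0.03, noise_sd = 0.02,
                            baseline_magnitude = 0.5,
                            rt_range = c(0, 20), n_points = 2000,
                            amplitude_range = c(1, 3),
                            peak_width = 0.08, seed = seed)
  cfg <- preprocess_config(segment_len = 20, slack = 8, n_knots = 400)
  list(chrom_set = cs, config = cfg)
}

# Balanced single-treatment design for direct metabolite-matrix tests.
stats_design <- function(n_varieties = 8, days = c(3, 6, 10), n_reps = 4,
                         seed = 1) {
  make_design(n_varieties, "I", list(I = days), n_reps, seed = seed)
}

# Null log2 metabolite matrix on a design.
null_table <- function(design, m, sd = 0.25, mean = 10) {
  Y <- matrix(stats::rnorm(nrow(design) * m, mean, sd), nrow(design), m)
  colnames(Y) <- sprintf("M%03d", seq_len(m))
  Y
}

# Add a planted drought effect (variety x day pattern) to drought rows of
# one metabolite column.
plant_effect <- function(Y, design, col, pattern) {
  dr <- design$condition == "drought"
  key <- cbind(match(design$variety[dr], rownames(pattern)),
               match(as.character(design$day[dr]), colnames(pattern)))
  Y[dr, col] <- Y[dr, col] + pattern[key]
  Y
}

# Canonical planted patterns of magnitude `e` for each category.
planted_pattern <- function(category, varieties, days, e = 2) {
  nv <- length(varieties)
  nd <- length(days)
  zv <- seq(-1, 1, length.out = nv)
  zd <- seq(-1, 1, length.out = nd)
  m <- switch(category,
    D = matrix(e, nv, nd),
    VD = matrix(e * zv, nv, nd),
    TD = matrix(e * zd, nv, nd, byrow = TRUE),
    VD_TD = outer(e * zv, rep(1, nd)) + outer(rep(1, nv), e * zd),
    VTD = outer(zv, zd) * 2 * e,
    stop("bad category"))
  dimnames(m) <- list(varieties, as.character(days))
  m
}

# Minimal ground truth carrying one variety-modified metabolite, for
# phenotype-link tests.
link_ground_truth <- function(varieties, days = c(3, 6, 10), seed = 5) {
  set.seed(seed)
  eff <- expand.grid(variety = varieties, day = days,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ve <- stats::setNames(seq(-1.5, 1.5, length.out = length(varieties)),
                        varieties)
  eff$metabolite <- "M001"
  eff$treatment <- "I"
  eff$effect <- ve[eff$variety]
  structure(list(
    metabolites = data.frame(metabolite = "M001", rt = 5, width = 0.05,
                             stringsAsFactors = FALSE),
    categories = data.frame(metabolite = "M001", treatment = "I",
                            category = "VD", stringsAsFactors = FALSE),
    effects = eff[, c("metabolite", "treatment", "variety", "day", "effect")],
    warps = NULL, phenotype_effects = NULL, params = list()
  ), class = "ground_truth")
}
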