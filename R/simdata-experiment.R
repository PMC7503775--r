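#' Default planted category proportions per treatment
#'
#' Proportions of the six drought-response categories planted by
#' [simulate_experiment()], per treatment. The defaults reproduce the
#' category frequencies observed for the 104 metabolites of the barley
#' moisture-deficit study (per-treatment counts divided by 104), so the
#' generator's default run emulates the study's conditions.
#'
#' @return named list (one element per treatment) of named probability
#'   vectors over `NoEffect`, `D`, `VD`, `TD`, `VD_TD`, `VTD`.
#' @export
default_category_probs <- function() {
  lev <- c("NoEffect", "D", "VD", "TD", "VD_TD", "VTD")
  mk <- function(x) stats::setNames(x / sum(x), lev)
  list("I" = mk(c(36, 25, 0, 32, 1, 10)),
       "II" = mk(c(61, 12, 1, 26, 2, 2)),
       "I+II" = mk(c(54, 33, 0, 16, 0, 1)))
}

#' Category levels for drought-response classification
#' @return character vector of the six category labels.
#' @export
category_levels <- function() {
  c("NoEffect", "D", "VD", "TD", "VD_TD", "VTD")
}

# Draw a (variety x day) matrix of log2 effects consistent with a category.
# D: constant; VD: varies by variety only; TD: by day only; VD_TD: additive
# variety + day components; VTD: a product (non-additive) pattern.
plant_effect_matrix <- function(category, varieties, days, effect_size) {
  nv <- length(varieties)
  nd <- length(days)
  m <- switch(category,
    NoEffect = matrix(0, nv, nd),
    D = matrix(effect_size, nv, nd),
    VD = matrix(effect_size * stats::runif(nv, -1, 1), nv, nd),
    TD = matrix(effect_size * stats::runif(nd, -1, 1), nv, nd, byrow = TRUE),
    VD_TD = outer(effect_size * stats::runif(nv, -1, 1), rep(1, nd)) +
      outer(rep(1, nv), effect_size * stats::runif(nd, -1, 1)),
    VTD = outer(stats::runif(nv, -1, 1), stats::runif(nd, -1, 1)) * effect_size,
    stop("unknown category: ", category)
  )
  dimnames(m) <- list(varieties, as.character(days))
  m
}

#' Simulate a dual-wavelength chromatographic experiment with ground truth
#'
#' Every metabolite is a chromatographic peak at a fixed latent retention
#' time, present at both detection wavelengths (280 and 330 nm) with
#' metabolite-specific response factors. In drought samples, peak areas
#' are multiplied by `2^effect` where the (variety, day) effect matrix is
#' planted according to the metabolite's category; effects are therefore
#' additive in log2 units after the downstream log transform. Each sample
#' receives its own smooth monotone retention-time warp (shared by the two
#' wavelengths, as both channels come from one injection), a random
#' polynomial baseline, and iid Gaussian noise.
#'
#' @param design a `design_table` from [make_design()].
#' @param n_metabolites number of planted metabolites (>= 1).
#' @param category_probs named probability vector over the six categories,
#'   or a list of such vectors keyed by treatment (see
#'   [default_category_probs()]). Categories are drawn independently per
#'   treatment.
#' @param effect_size base magnitude of planted effects, log2 units.
#' @param warp_magnitude maximal retention-time displacement, minutes.
#' @param noise_sd additive noise standard deviation, AU.
#' @param baseline_magnitude scale of the random polynomial baseline, AU
#'   (0 disables baselines).
#' @param rt_range chromatographic run window, minutes.
#' @param n_points grid size (uniform grid).
#' @param amplitude_range uniform bounds for per-metabolite base
#'   amplitudes, AU.
#' @param peak_width Gaussian peak standard deviation, minutes.
#' @param peak_tau EMG tail constant, minutes (0 for pure Gaussians).
#' @param seed integer seed; fixed seeds give bit-identical output.
#' @return object of class `chromatogram_set`: list with `chromatograms`
#'   (named list, one `chromatogram` per sample x wavelength), `design`,
#'   `grid`, `wavelengths` and `ground_truth` (class `ground_truth`).
#' @export
simulate_experiment <- function(design,
                                n_metabolites = 20,
                                category_probs = default_category_probs(),
                                effect_size = 1,
                                warp_magnitude = 0.02,
                                noise_sd = 0.02,
                                baseline_magnitude = 0.5,
                                rt_range = c(0, 25),
                                n_points = 10000,
                                amplitude_range = c(1, 3),
                                peak_width = 0.05,
                                peak_tau = 0,
                                seed = 1) {
  if (n_metabolites < 1) stop("'n_metabolites' must be >= 1")
  stopifnot(inherits(design, "data.frame"), nrow(design) > 0)
  treatments <- unique(design$treatment)
  varieties <- unique(design$variety)
  lev <- category_levels()

  probs_for <- function(tr) {
    p <- if (is.list(category_probs)) {
      if (!is.null(category_probs[[tr]])) {
        category_probs[[tr]]
      } else {
        Reduce(`+`, category_probs) / length(category_probs)
      }
    } else category_probs
    if (is.null(names(p)) || !setequal(names(p), lev)) {
      stop("category probabilities must be named over: ",
           paste(lev, collapse = ", "))
    }
    if (abs(sum(p) - 1) > 1e-8) stop("category proportions must sum to 1")
    p[lev]
  }

  set.seed(seed)
  grid <- seq(rt_range[1], rt_range[2], length.out = n_points)

  # Latent retention times: jittered even spacing inside a 1-min margin,
  # keeping peaks well separated relative to their width.
  margin <- min(1, diff(rt_range) / 10)
  base_rt <- seq(rt_range[1] + margin, rt_range[2] - margin,
                 length.out = n_metabolites)
  spacing <- if (n_metabolites > 1) diff(base_rt[1:2]) else diff(rt_range) / 2
  rt_lat <- base_rt + stats::runif(n_metabolites, -0.2, 0.2) * spacing
  met_ids <- sprintf("M%03d", seq_len(n_metabolites))

  metabolites <- data.frame(
    metabolite = met_ids,
    rt = rt_lat,
    width = peak_width,
    tau = peak_tau,
    shape = if (peak_tau > 0) "emg" else "gaussian",
    amp280 = stats::runif(n_metabolites, amplitude_range[1], amplitude_range[2]),
    amp330 = stats::runif(n_metabolites, amplitude_range[1], amplitude_range[2]),
    stringsAsFactors = FALSE
  )

  categories <- do.call(rbind, lapply(treatments, function(tr) {
    data.frame(metabolite = met_ids, treatment = tr,
               category = sample(lev, n_metabolites, replace = TRUE,
                                 prob = probs_for(tr)),
               stringsAsFactors = FALSE)
  }))

  effects <- do.call(rbind, lapply(treatments, function(tr) {
    days <- sort(unique(design$day[design$treatment == tr]))
    do.call(rbind, lapply(seq_len(n_metabolites), function(m) {
      cat_m <- categories$category[categories$metabolite == met_ids[m] &
                                     categories$treatment == tr]
      em <- plant_effect_matrix(cat_m, varieties, days, effect_size)
      data.frame(metabolite = met_ids[m], treatment = tr,
                 variety = rep(varieties, times = length(days)),
                 day = rep(days, each = length(varieties)),
                 effect = as.vector(em), stringsAsFactors = FALSE)
    }))
  }))

  eff_lookup <- stats::setNames(
    effects$effect,
    paste(effects$metabolite, effects$treatment, effects$variety,
          effects$day, sep = "|"))

  span <- diff(rt_range)
  chroms <- list()
  warps <- list()
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    warp <- if (warp_magnitude > 0) {
      make_warp(rt_range, warp_magnitude)
    } else NULL
    warps[[row$sample_id]] <- if (is.null(warp)) NULL else attr(warp, "nodes")
    base_coef <- if (baseline_magnitude > 0) {
      baseline_magnitude * c(stats::runif(1, 0, 1),
                             stats::runif(1, -1, 1) / span,
                             stats::runif(1, -1, 1) / span^2)
    } else 0
    mult <- if (row$condition == "drought") {
      key <- paste(met_ids, row$treatment, row$variety, row$day, sep = "|")
      2^unname(eff_lookup[key])
    } else rep(1, n_metabolites)
    for (wl in c(280, 330)) {
      amp <- if (wl == 280) metabolites$amp280 else metabolites$amp330
      pk <- peak_spec(metabolites$rt, metabolites$width, amp * mult,
                      metabolites$shape, metabolites$tau)
      ch <- simulate_chromatogram(grid, pk, base_coef, warp, noise_sd,
                                  seed = NULL, wavelength = wl,
                                  sample_id = row$sample_id,
                                  sample_mass = row$sample_mass)
      chroms[[paste(row$sample_id, wl, sep = "_")]] <- ch
    }
  }

  gt <- structure(list(
    metabolites = metabolites,
    categories = categories,
    effects = effects,
    warps = warps,
    phenotype_effects = NULL,
    params = list(effect_size = effect_size, warp_magnitude = warp_magnitude,
                  noise_sd = noise_sd, baseline_magnitude = baseline_magnitude,
                  seed = seed)
  ), class = "ground_truth")

  structure(list(chromatograms = chroms, design = design, grid = grid,
                 wavelengths = c(280, 330), ground_truth = gt),
            class = "chromatogram_set")
}

#' @export
print.chromatogram_set <- function(x, ...) {
  cat(sprintf("chromatogram set: %d traces (%d samples x %d wavelengths), %d grid points\n",
              length(x$chromatograms), nrow(x$design), length(x$wavelengths),
              length(x$grid)))
  invisible(x)
}

#' Planted (variety x day) effect matrix for one metabolite and treatment
#'
#' @param ground_truth a `ground_truth` object.
#' @param metabolite metabolite id.
#' @param treatment treatment label.
#' @return numeric matrix, varieties in rows, days in columns.
#' @export
true_effect_matrix <- function(ground_truth, metabolite, treatment) {
  e <- ground_truth$effects
  e <- e[e$metabolite == metabolite & e$treatment == treatment, ]
  if (nrow(e) == 0) stop("no planted effects for ", metabolite, " / ", treatment)
  days <- sort(unique(e$day))
  varieties <- unique(e$variety)
  m <- matrix(NA_real_, length(varieties), length(days),
              dimnames = list(varieties, as.character(days)))
  m[cbind(match(e$variety, varieties), match(e$day, days))] <- e$effect
  m
}
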