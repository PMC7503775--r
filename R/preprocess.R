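#' Preprocessing configuration
#'
#' Parameters for [run_preprocessing()]. Defaults follow the published
#' pipeline where stated (520 spline knots, 0.0005 intensity tolerance)
#' and standard COW practice otherwise.
#'
#' @param segment_len COW segment length in grid points (`NULL`: ~N/100).
#' @param slack COW node slack in grid points.
#' @param n_knots smoothing-spline knots for the second derivative
#'   (`NULL`: 520, capped below the grid size).
#' @param intensity_tolerance peak intensity filter on the differentiated
#'   scale.
#' @param c1 minimum chromatograms per common peak (`NULL`: half the
#'   chromatograms, rounded up).
#' @param reference `"median"` for the pointwise median trace, or a
#'   sample id.
#' @param match_tolerance grid steps allowed between a planted retention
#'   time and a common-peak interval when naming peaks from ground truth.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(segment_len = NULL, slack = 15,
                              n_knots = NULL,
                              intensity_tolerance = 0.0005,
                              c1 = NULL, reference = "median",
                              match_tolerance = 3) {
  structure(list(segment_len = segment_len, slack = slack,
                 n_knots = n_knots,
                 intensity_tolerance = intensity_tolerance,
                 c1 = c1, reference = reference,
                 match_tolerance = match_tolerance),
            class = "preprocess_config")
}

#' Run the chromatographic preprocessing chain
#'
#' Applies, per wavelength: (a) normalization by sample mass, (b)
#' baseline removal by numerical differentiation, (c) retention-time
#' alignment by correlation optimized warping against the pointwise
#' median trace, (d) peak detection on spline-smoothed second
#' derivatives, followed by common-peak construction, integration, and
#' merging of the two wavelengths into a metabolite table.
#'
#' @param chrom_set a `chromatogram_set` (see [simulate_experiment()] or
#'   [read_chromatogram_set()]).
#' @param config a `preprocess_config`.
#' @param name_peaks `"ground_truth"` to name common peaks by matching
#'   their intervals against the planted retention times (requires ground
#'   truth in the set), `"none"` to leave peaks unnamed, or a `name_map`
#'   list as accepted by [merge_wavelengths()].
#' @param verbose print per-stage summary counts.
#' @return `metabolite_table` with the design attached, plus attributes
#'   `peak_tables` (per-wavelength `peak_table` objects) and `stage_log`
#'   (per-stage counts).
#' @export
run_preprocessing <- function(chrom_set, config = preprocess_config(),
                              name_peaks = c("ground_truth", "none"),
                              verbose = FALSE) {
  stopifnot(inherits(chrom_set, "chromatogram_set"))
  if (length(chrom_set$chromatograms) == 0) stop("empty chromatogram set")
  if (!is.list(name_peaks)) name_peaks <- match.arg(name_peaks)
  if (identical(name_peaks, "ground_truth") &&
      is.null(chrom_set$ground_truth)) {
    name_peaks <- "none"
  }

  grid <- chrom_set$grid
  n <- length(grid)
  lens <- vapply(chrom_set$chromatograms, function(ch) length(ch$intensity),
                 integer(1))
  if (any(lens != n)) stop("all chromatograms must share the grid length")

  seg_len <- if (is.null(config$segment_len)) {
    max(10L, as.integer(round(n / 100)))
  } else as.integer(config$segment_len)
  knots <- if (is.null(config$n_knots)) min(520L, n - 1L) else config$n_knots

  log <- list()
  peak_tables <- list()
  for (wl in chrom_set$wavelengths) {
    chroms <- Filter(function(ch) ch$wavelength == wl,
                     chrom_set$chromatograms)
    if (length(chroms) == 0) stop("no chromatograms at ", wl, " nm")
    ids <- unname(vapply(chroms, `[[`, character(1), "sample_id"))

    normed <- lapply(chroms, normalize_by_mass)
    diffed <- t(vapply(normed, remove_baseline_by_differentiation,
                       numeric(n)))
    rownames(diffed) <- ids

    reference <- if (identical(config$reference, "median")) {
      apply(diffed, 2, stats::median)
    } else {
      if (!config$reference %in% ids) {
        stop("reference sample ", config$reference, " not found at ",
             wl, " nm")
      }
      diffed[config$reference, ]
    }

    warped <- diffed
    for (i in seq_len(nrow(diffed))) {
      warped[i, ] <- cow_align(diffed[i, ], reference,
                               segment_len = seg_len,
                               slack = config$slack)$warped
    }

    d2 <- t(apply(warped, 1, smooth_second_derivative, n_knots = knots))
    intervals <- lapply(seq_len(nrow(warped)), function(i) {
      detect_peaks(d2[i, ], warped[i, ], config$intensity_tolerance)
    })
    names(intervals) <- ids
    n_indiv <- sum(vapply(intervals, nrow, integer(1)))

    c1 <- if (is.null(config$c1)) ceiling(length(chroms) / 2) else config$c1
    common <- build_common_peaks(intervals, c1 = c1)

    # Apex of a common peak: most concave point of the cross-sample
    # median second derivative inside the interval.
    med_d2 <- apply(d2, 2, stats::median)
    common$apex <- vapply(seq_len(nrow(common)), function(j) {
      idx <- common$start[j]:(common$end[j] - 1)
      idx[which.min(med_d2[idx])]
    }, integer(1))

    values <- integrate_peaks(warped, common, grid)
    common$start_rt <- grid[common$start]
    common$end_rt <- grid[pmin(common$end, n)]
    common$apex_rt <- grid[common$apex]
    common$wavelength <- wl

    peak_tables[[as.character(wl)]] <- structure(
      list(values = values, peaks = common, rt = grid, wavelength = wl),
      class = "peak_table")
    log[[as.character(wl)]] <- list(chromatograms = length(chroms),
                                    individual_peaks = n_indiv,
                                    common_peaks = nrow(common), c1 = c1)
    if (verbose) {
      message(sprintf("[%g nm] %d chromatograms, %d individual peaks, %d common peaks (c1 = %d)",
                      wl, length(chroms), n_indiv, nrow(common), c1))
    }
  }

  name_map <- NULL
  if (identical(name_peaks, "none")) {
    name_map <- NULL
  } else if (identical(name_peaks, "ground_truth")) {
    name_map <- lapply(peak_tables, function(pt) {
      match_peaks_to_truth(pt$peaks, chrom_set$ground_truth, grid,
                           config$match_tolerance)
    })
  } else {
    name_map <- name_peaks
  }

  tab <- merge_wavelengths(peak_tables[["280"]], peak_tables[["330"]],
                           name_map = name_map)
  design <- chrom_set$design
  tab$design <- design[match(rownames(tab$values), design$sample_id), ]
  attr(tab, "peak_tables") <- peak_tables
  attr(tab, "stage_log") <- log
  if (verbose) {
    message(sprintf("merged table: %d samples x %d variables",
                    nrow(tab$values), ncol(tab$values)))
  }
  tab
}

# Name common peaks by the planted metabolite whose latent retention time
# falls inside (or within tol grid steps of) the peak interval.
match_peaks_to_truth <- function(common, ground_truth, grid, tol = 3) {
  out <- list()
  if (nrow(common) == 0) return(out)
  met <- ground_truth$metabolites
  met_idx <- vapply(met$rt, function(r) which.min(abs(grid - r)), integer(1))
  for (j in seq_len(nrow(common))) {
    hit <- met$metabolite[met_idx >= common$start[j] - tol &
                            met_idx <= common$end[j] - 1 + tol]
    if (length(hit) > 0) out[[common$peak_id[j]]] <- hit
  }
  out
}
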