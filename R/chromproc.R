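#' Normalize a chromatogram by sample mass
#'
#' Divides every intensity value by the extracted sample mass, making
#' traces comparable across samples of different weighed-in tissue
#' amounts.
#'
#' @param chrom a `chromatogram`.
#' @return the chromatogram with `intensity / sample_mass` and
#'   `sample_mass` reset to 1 (so normalization is idempotent).
#' @export
normalize_by_mass <- function(chrom) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (!is.finite(chrom$sample_mass) || chrom$sample_mass <= 0) {
    stop("sample mass must be positive (sample ", chrom$sample_id, ")")
  }
  chrom$intensity <- chrom$intensity / chrom$sample_mass
  chrom$sample_mass <- 1
  chrom
}

#' Remove the baseline by numerical differentiation
#'
#' Returns the first finite-difference derivative of the intensity with
#' respect to the grid index (central differences in the interior,
#' one-sided at the ends). Differentiation removes baselines without
#' estimating them: a constant baseline maps to zero and a linear one to
#' a constant offset, which the downstream second-derivative detection
#' ignores.
#'
#' @param chrom a `chromatogram` or a numeric intensity vector.
#' @return numeric vector of per-index derivatives, same length as the
#'   input.
#' @export
remove_baseline_by_differentiation <- function(chrom) {
  y <- if (inherits(chrom, "chromatogram")) chrom$intensity else chrom
  n <- length(y)
  if (n < 3) stop("need at least 3 grid points to differentiate")
  d <- numeric(n)
  d[1] <- y[2] - y[1]
  d[n] <- y[n] - y[n - 1]
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / 2
  d
}

#' Smoothed second derivative via a cubic smoothing spline
#'
#' Fits a cubic smoothing spline with `n_knots` knots to an
#' already-differentiated signal (indexed by grid position) and returns
#' the spline's analytic first derivative - i.e. the second derivative of
#' the original trace, smoothed. Peaks appear as pronounced negative
#' (concave) excursions.
#'
#' @param signal numeric vector, the differentiated trace.
#' @param n_knots number of spline knots (>= 4, < `length(signal)`;
#'   default 520, suited to ~10000-point grids).
#' @return numeric vector of the smoothed second derivative (per index
#'   squared).
#' @export
smooth_second_derivative <- function(signal, n_knots = 520) {
  n <- length(signal)
  if (n_knots < 4) stop("'n_knots' must be >= 4")
  if (n_knots >= n) stop("'n_knots' must be below the signal length")
  if (any(!is.finite(signal))) stop("signal must be finite")
  fit <- stats::smooth.spline(seq_len(n), signal, nknots = n_knots,
                              cv = FALSE, keep.data = FALSE)
  stats::predict(fit, seq_len(n), deriv = 1)$y
}

#' Detect peaks as concave runs of the smoothed second derivative
#'
#' Candidate peaks are maximal runs where the smoothed second derivative
#' is negative. Two classes of irrelevant candidates are removed: runs of
#' length 1 (covering a single retention-time point), and runs whose
#' maximum absolute differentiated-signal value stays below
#' `intensity_tolerance` (low-intensity ripples after differentiation and
#' warping). The apex is the most concave point of the run.
#'
#' @param d2_profile smoothed second derivative (from
#'   [smooth_second_derivative()]).
#' @param signal the differentiated (and warped) signal on the same grid,
#'   used by the intensity filter.
#' @param intensity_tolerance intensity filter threshold on the
#'   differentiated-signal scale (default 0.0005).
#' @return `data.frame` of half-open, 1-based intervals: columns `start`,
#'   `end` (exclusive), `apex`; zero rows when nothing is detected.
#'   Intervals are sorted and pairwise disjoint.
#' @export
detect_peaks <- function(d2_profile, signal,
                         intensity_tolerance = 0.0005) {
  stopifnot(length(d2_profile) == length(signal))
  if (any(!is.finite(d2_profile))) stop("second-derivative profile must be finite")
  neg <- d2_profile < 0
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= 2
  starts <- starts[keep]
  ends <- ends[keep] + 1  # half-open
  if (length(starts) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      apex = integer(0)))
  }
  ok <- logical(length(starts))
  apex <- integer(length(starts))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(ends[i] - 1)
    ok[i] <- max(abs(signal[idx])) >= intensity_tolerance
    apex[i] <- idx[which.min(d2_profile[idx])]
  }
  data.frame(start = starts[ok], end = ends[ok], apex = apex[ok])
}

#' Build common peaks across chromatograms by interval addition
#'
#' Merges the per-sample peak intervals of all chromatograms by interval
#' union (transitive closure of overlap on the aligned grid). Each merged
#' interval's support is the number of distinct chromatograms that
#' contributed an individual peak; merged intervals supported by fewer
#' than `c1` chromatograms are dropped.
#'
#' @param per_sample_intervals named list (one element per chromatogram)
#'   of interval `data.frame`s as returned by [detect_peaks()].
#' @param c1 minimum number of contributing chromatograms (>= 1).
#' @return `data.frame` of disjoint, sorted common peaks: `peak_id`,
#'   `start`, `end`, `support`.
#' @export
build_common_peaks <- function(per_sample_intervals, c1 = 1) {
  stopifnot(c1 >= 1)
  n_samples <- length(per_sample_intervals)
  if (c1 > n_samples) {
    warning("c1 (", c1, ") exceeds the number of chromatograms (",
            n_samples, "): no common peaks can be formed")
  }
  if (is.null(names(per_sample_intervals))) {
    names(per_sample_intervals) <- paste0("sample", seq_len(n_samples))
  }
  all_iv <- do.call(rbind, lapply(names(per_sample_intervals), function(s) {
    iv <- per_sample_intervals[[s]]
    if (is.null(iv) || nrow(iv) == 0) return(NULL)
    data.frame(sample = s, start = iv$start, end = iv$end,
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(peak_id = character(0), start = integer(0),
                      end = integer(0), support = integer(0))
  if (is.null(all_iv) || nrow(all_iv) == 0) return(empty)

  all_iv <- all_iv[order(all_iv$start, all_iv$end), ]
  merged <- list()
  cur_start <- all_iv$start[1]
  cur_end <- all_iv$end[1]
  cur_samples <- all_iv$sample[1]
  for (i in seq_len(nrow(all_iv))[-1]) {
    if (all_iv$start[i] < cur_end) {  # half-open overlap
      cur_end <- max(cur_end, all_iv$end[i])
      cur_samples <- c(cur_samples, all_iv$sample[i])
    } else {
      merged[[length(merged) + 1]] <-
        list(start = cur_start, end = cur_end,
             support = length(unique(cur_samples)))
      cur_start <- all_iv$start[i]
      cur_end <- all_iv$end[i]
      cur_samples <- all_iv$sample[i]
    }
  }
  merged[[length(merged) + 1]] <-
    list(start = cur_start, end = cur_end,
         support = length(unique(cur_samples)))

  out <- data.frame(
    start = vapply(merged, `[[`, numeric(1), "start"),
    end = vapply(merged, `[[`, numeric(1), "end"),
    support = vapply(merged, `[[`, numeric(1), "support")
  )
  out <- out[out$support >= c1, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  out$peak_id <- sprintf("P%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("peak_id", "start", "end", "support")]
}

#' Integrate common peaks over the rectified differentiated signals
#'
#' For every chromatogram and every common peak, the value is the
#' trapezoidal integral (over retention time) of the rectified
#' differentiated signal `max(signal, 0)` across the peak interval. For a
#' clean peak the rectified derivative integrates to the rise from
#' baseline to apex, so the value is monotone in peak area for a fixed
#' peak shape and needs no baseline estimate.
#'
#' @param signals numeric matrix, chromatograms in rows, grid positions
#'   in columns (aligned, differentiated signals).
#' @param common_peaks `data.frame` from [build_common_peaks()].
#' @param rt retention-time grid (minutes); the grid step converts the
#'   per-index trapezoid into AU*min.
#' @return numeric matrix, chromatograms x peaks (non-negative values).
#' @export
integrate_peaks <- function(signals, common_peaks, rt) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  n <- ncol(signals)
  stopifnot(length(rt) == n)
  if (nrow(common_peaks) > 0 &&
      (min(common_peaks$start) < 1 || max(common_peaks$end) > n + 1)) {
    stop("peak interval outside the grid")
  }
  dt <- mean(diff(rt))
  out <- matrix(0, nrow(signals), nrow(common_peaks),
                dimnames = list(rownames(signals), common_peaks$peak_id))
  for (j in seq_len(nrow(common_peaks))) {
    idx <- common_peaks$start[j]:(common_peaks$end[j] - 1)
    seg <- pmax(signals[, idx, drop = FALSE], 0)
    if (length(idx) >= 2) {
      out[, j] <- dt * rowSums((seg[, -1, drop = FALSE] +
                                  seg[, -length(idx), drop = FALSE]) / 2)
    }
  }
  out
}

#' Merge dual-wavelength peak tables into a metabolite table
#'
#' Variables sharing a metabolite name across the two wavelengths are
#' summed into one variable (metabolites with two absorption maxima are
#' quantified as the sum of their two peaks); co-eluting peaks carrying
#' several names keep a joint `"name1;name2"` label; unnamed peaks pass
#' through as `<wavelength>nm_<peak_id>`.
#'
#' @param peak_table_280,peak_table_330 objects of class `peak_table`
#'   (see [run_preprocessing()]): lists with `values` (samples x peaks),
#'   `peaks` manifest and `wavelength`.
#' @param name_map optional named list mapping `peak_id` to a character
#'   vector of metabolite names, applied per wavelength as
#'   `name_map[["280"]]`, `name_map[["330"]]`. A name may appear at most
#'   once per wavelength.
#' @return object of class `metabolite_table`: list with `values`
#'   (samples x variables), `variables` manifest (`variable`, `names`,
#'   `wavelengths`, `peak_ids`), `design` (`NULL` until attached).
#' @export
merge_wavelengths <- function(peak_table_280, peak_table_330,
                              name_map = NULL) {
  pts <- list("280" = peak_table_280, "330" = peak_table_330)
  samp <- rownames(peak_table_280$values)
  if (!identical(samp, rownames(peak_table_330$values))) {
    stop("the two peak tables must share the same sample set")
  }

  entries <- list()
  for (wl in names(pts)) {
    pt <- pts[[wl]]
    nm_wl <- if (is.null(name_map)) NULL else name_map[[wl]]
    seen <- character(0)
    for (j in seq_len(nrow(pt$peaks))) {
      pid <- pt$peaks$peak_id[j]
      nms <- if (!is.null(nm_wl) && pid %in% names(nm_wl)) {
        sort(unique(nm_wl[[pid]]))
      } else character(0)
      if (length(nms) > 0) {
        clash <- intersect(nms, seen)
        if (length(clash) > 0) {
          stop("name(s) ", paste(clash, collapse = ", "),
               " mapped to more than one peak at ", wl, " nm")
        }
        seen <- c(seen, nms)
        key <- paste(nms, collapse = ";")
      } else {
        key <- paste0(wl, "nm_", pid)
      }
      entries[[length(entries) + 1]] <- list(
        key = key, named = length(nms) > 0, wl = wl, pid = pid,
        values = pt$values[, j])
    }
  }

  keys <- vapply(entries, `[[`, character(1), "key")
  uniq <- unique(keys)
  values <- matrix(0, length(samp), length(uniq),
                   dimnames = list(samp, uniq))
  vars <- data.frame(variable = uniq, names = NA_character_,
                     wavelengths = "", peak_ids = "",
                     stringsAsFactors = FALSE)
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    k <- match(e$key, uniq)
    values[, k] <- values[, k] + e$values
    vars$names[k] <- if (e$named) e$key else NA_character_
    vars$wavelengths[k] <- paste(c(strsplit(vars$wavelengths[k], ",")[[1]],
                                   e$wl), collapse = ",")
    vars$peak_ids[k] <- paste(c(strsplit(vars$peak_ids[k], ",")[[1]],
                                paste0(e$wl, ":", e$pid)), collapse = ",")
  }
  vars$wavelengths <- sub("^,", "", vars$wavelengths)
  vars$peak_ids <- sub("^,", "", vars$peak_ids)

  structure(list(values = values, variables = vars, design = NULL),
            class = "metabolite_table")
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat(sprintf("metabolite table: %d samples x %d variables%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$design)) "" else " (design attached)"))
  invisible(x)
}
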