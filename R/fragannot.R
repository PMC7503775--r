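#' Nominal neutral-loss residue masses
#'
#' Returns the table of nominal (integer, amu) neutral-loss masses used for
#' decomposing mass differences in negative-mode MSn spectra of flavonoid
#' glycoconjugates. Glycosyl residues lose their full dehydrated mass when
#' O-linked (hexose 162, deoxyhexose 146, pentose 132); C-linked sugars
#' fragment across the ring (120/90 amu) or, in combination with an acyl
#' ketene, as composite losses. Acyl residues cover the hydroxycinnamic
#' acids observed in barley (feruloyl 176, hydroxyferuloyl 192, sinapoyl
#' 206, sinapic acid 224 as the free acid, coumaroyl 146) plus the
#' malonyl-specific losses (CO2 44, ketene 42, malonyl+hexose composite
#' 204).
#'
#' Note the deliberate 146-amu ambiguity: deoxyhexose (rhamnose) and
#' coumaroyl have the same nominal mass; both are reported by
#' [decompose_loss()] and downstream interpretation must use elution
#' behaviour (glycosides elute early) to choose.
#'
#' @param extra named numeric vector of additional residue masses to append
#'   (names must not clash with the defaults).
#' @return named numeric vector of residue masses in amu.
#' @export
residue_table <- function(extra = NULL) {
  base <- c(
    hexose = 162, deoxyhexose = 146, pentose = 132,
    feruloyl = 176, hydroxyferuloyl = 192,
    sinapoyl = 206, sinapic_acid = 224, coumaroyl = 146,
    malonyl_CO2 = 44, malonyl_ketene = 204, ketene = 42, water = 18,
    C_glycoside_cross_ring = 120, C_glycoside_cross_ring_minor = 90,
    C_glycoside_full = 162
  )
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra)))) {
      stop("'extra' residues must be named")
    }
    if (any(names(extra) %in% names(base))) {
      stop("'extra' residue names clash with the default table")
    }
    if (any(!is.finite(extra)) || any(extra <= 0)) {
      stop("residue masses must be positive and finite")
    }
    base <- c(base, extra)
  }
  base
}

#' Deprotonated nominal m/z of flavonoid aglycones
#'
#' [M-H]- nominal m/z values derived from the molecular formulas:
#' apigenin C15H10O5 (270-1), luteolin C15H10O6, chrysoeriol C16H12O6,
#' quercetin C15H10O7, naringenin C15H12O5, tricin C17H14O7.
#'
#' @param extra named integer vector of additional aglycone m/z values.
#' @return named numeric vector of deprotonated nominal m/z.
#' @export
aglycone_library <- function(extra = NULL) {
  base <- c(
    apigenin = 269, luteolin = 285, chrysoeriol = 299,
    quercetin = 301, naringenin = 271, tricin = 329
  )
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra)))) {
      stop("'extra' aglycones must be named")
    }
    base <- c(base, extra)
  }
  base
}

#' Predict a fragment m/z from a precursor and a sequence of neutral losses
#'
#' Integer mass arithmetic on nominal residue masses: the fragment is the
#' precursor minus the summed losses.
#'
#' @param precursor_mz precursor ion nominal m/z.
#' @param losses character vector of residue names (may repeat; empty gives
#'   the precursor back).
#' @param residues residue mass table, see [residue_table()].
#' @return fragment nominal m/z (numeric scalar).
#' @examples
#' predict_fragment(741, c("deoxyhexose", "pentose", "hexose"))  # 301
#' @export
predict_fragment <- function(precursor_mz, losses = character(),
                             residues = residue_table()) {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1)
  losses <- as.character(losses)
  unknown <- setdiff(losses, names(residues))
  if (length(unknown) > 0) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  }
  precursor_mz - sum(residues[losses])
}

#' Decompose a neutral-loss mass into residue multisets
#'
#' Enumerates every multiset of at most `max_residues` residues from
#' `allowed` whose nominal masses sum exactly to `delta_mass`, by bounded
#' depth-first search over residue names in alphabetical order. The result
#' order is deterministic (lexicographic in the name sequence, shorter
#' prefixes first).
#'
#' @param delta_mass non-negative mass difference (amu).
#' @param max_residues maximum multiset size (>= 1).
#' @param allowed residue mass table, see [residue_table()].
#' @return list of character vectors (each a sorted residue multiset);
#'   `delta_mass = 0` yields `list(character(0))`, and an empty list means
#'   the loss cannot be explained.
#' @examples
#' decompose_loss(294, 2)  # contains c("hexose", "pentose")
#' @export
decompose_loss <- function(delta_mass, max_residues, allowed = residue_table()) {
  stopifnot(length(delta_mass) == 1, is.finite(delta_mass))
  if (delta_mass < 0) stop("'delta_mass' must be non-negative")
  if (max_residues < 1) stop("'max_residues' must be >= 1")
  nms <- sort(names(allowed))
  ms <- unname(allowed[nms])
  out <- vector("list", 0)
  recurse <- function(start, remaining, depth, acc) {
    if (remaining == 0) {
      out[[length(out) + 1]] <<- acc
      return(invisible(NULL))
    }
    if (depth == 0) return(invisible(NULL))
    for (i in seq(start, length(nms))) {
      if (ms[i] <= remaining) {
        recurse(i, remaining - ms[i], depth - 1, c(acc, nms[i]))
      }
    }
    invisible(NULL)
  }
  recurse(1, delta_mass, max_residues, character(0))
  out
}

#' Diagnostic marker ion for C-glycosylflavones
#'
#' The [Agly+(42-18)-H]- ion characteristic of flavone 2''-O-glycosides of
#' C-glucosides: the aglycone deprotonated m/z plus the residual C2H2O
#' fragment (42) minus water (18).
#'
#' @param aglycone aglycone name present in `library`.
#' @param library aglycone m/z table, see [aglycone_library()].
#' @return marker ion nominal m/z.
#' @examples
#' marker_ion("apigenin")  # 293
#' @export
marker_ion <- function(aglycone, library = aglycone_library()) {
  stopifnot(length(aglycone) == 1)
  if (!aglycone %in% names(library)) {
    stop("unknown aglycone: ", aglycone)
  }
  unname(library[[aglycone]] + 42 - 18)
}

#' Annotate an MSn fragment chain by neutral-loss decomposition
#'
#' Walks the precursor-to-terminal fragment chain, decomposes every
#' consecutive mass difference into residue multisets with
#' [decompose_loss()], and matches the terminal fragment against the
#' aglycone library, both directly ([Agly-H]-) and via the
#' [Agly+(42-18)-H]- marker offset (+24). All consistent annotation paths
#' (one decomposition choice per step) are returned, ranked by the total
#' number of residues and then lexicographically; steps with no
#' decomposition are reported as unexplained rather than failing.
#'
#' @param precursor precursor [M-H]- nominal m/z.
#' @param fragments numeric vector of fragment m/z, sorted strictly
#'   descending, all smaller than `precursor`. May be empty.
#' @param allowed residue mass table.
#' @param library aglycone m/z table.
#' @param max_residues_per_step maximum residues explaining one loss step.
#' @param max_paths cap on the number of enumerated paths (combinatorial
#'   guard; decompositions per step are always complete).
#' @return object of class `spectrum_annotation`: list with `precursor`,
#'   `fragments`, `steps` (per-step delta and decomposition list),
#'   `paths` (ranked list of per-step residue choices), `aglycone_matches`
#'   and `marker_matches` on the terminal ion.
#' @export
annotate_spectrum <- function(precursor, fragments = numeric(),
                              allowed = residue_table(),
                              library = aglycone_library(),
                              max_residues_per_step = 3,
                              max_paths = 1000) {
  stopifnot(is.numeric(precursor), length(precursor) == 1)
  fragments <- as.numeric(fragments)
  if (length(fragments) > 0) {
    if (any(diff(fragments) >= 0)) {
      stop("'fragments' must be sorted strictly descending")
    }
    if (any(fragments >= precursor)) {
      stop("all fragments must be smaller than the precursor")
    }
  }
  chain <- c(precursor, fragments)
  n_steps <- length(chain) - 1
  steps <- vector("list", n_steps)
  if (n_steps > 0) {
    for (k in seq_len(n_steps)) {
      delta <- chain[k] - chain[k + 1]
      dec <- decompose_loss(delta, max_residues_per_step, allowed)
      steps[[k]] <- list(delta = delta, decompositions = dec,
                         explained = length(dec) > 0)
    }
  }

  # Enumerate paths: one decomposition per explained step; unexplained
  # steps contribute the placeholder NA entry.
  choice_sets <- lapply(steps, function(s) {
    if (s$explained) seq_along(s$decompositions) else NA_integer_
  })
  paths <- list()
  if (n_steps == 0) {
    paths <- list(list())
  } else {
    idx <- expand.grid(rev(choice_sets), KEEP.OUT.ATTRS = FALSE)
    idx <- idx[, rev(seq_len(ncol(idx))), drop = FALSE]
    if (nrow(idx) > max_paths) idx <- idx[seq_len(max_paths), , drop = FALSE]
    paths <- lapply(seq_len(nrow(idx)), function(r) {
      lapply(seq_len(n_steps), function(k) {
        j <- idx[r, k]
        if (is.na(j)) NULL else steps[[k]]$decompositions[[j]]
      })
    })
    # Rank: fewest total residues, then lexicographic on the flattened names.
    keys <- vapply(paths, function(p) {
      res <- unlist(p, use.names = FALSE)
      sprintf("%04d|%s", length(res), paste(res, collapse = ","))
    }, character(1))
    paths <- paths[order(keys)]
  }

  terminal <- chain[length(chain)]
  agly <- names(library)[library == terminal]
  mark <- names(library)[library + 24 == terminal]
  structure(list(
    precursor = precursor,
    fragments = fragments,
    steps = steps,
    paths = paths,
    terminal = terminal,
    aglycone_matches = agly,
    marker_matches = mark
  ), class = "spectrum_annotation")
}

#' @export
print.spectrum_annotation <- function(x, ...) {
  cat("MSn spectrum annotation\n")
  cat(sprintf("  precursor [M-H]- m/z %s; %d fragment(s)\n",
              format(x$precursor), length(x$fragments)))
  if (length(x$steps) > 0) {
    for (k in seq_along(x$steps)) {
      s <- x$steps[[k]]
      lab <- if (s$explained) {
        paste(vapply(s$decompositions, paste, character(1), collapse = "+"),
              collapse = " | ")
      } else "unexplained"
      cat(sprintf("  step %d: loss %g amu -> %s\n", k, s$delta, lab))
    }
  }
  if (length(x$aglycone_matches) > 0) {
    cat("  terminal aglycone [Agly-H]-:",
        paste(x$aglycone_matches, collapse = ", "), "\n")
  }
  if (length(x$marker_matches) > 0) {
    cat("  terminal marker [Agly+(42-18)-H]-:",
        paste(x$marker_matches, collapse = ", "), "\n")
  }
  invisible(x)
}
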