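#' Barley variety names used as generator defaults
#'
#' Five European spring barley varieties and three Syrian accessions, the
#' panel studied in the moisture-deficit experiment the generator emulates.
#' @return character vector of length 8.
#' @export
default_varieties <- function() {
  c("Georgie", "Maresi", "Sebastian", "Lubuski", "Stratus",
    "CamB1CI", "Harmal", "MDingo")
}

#' Default sampling days per moisture-deficit treatment
#'
#' Leaves are sampled after 3, 6 and 10 days of moisture deficit; the
#' combined treatment I+II is additionally sampled after 1 day.
#' @return named list of integer day vectors.
#' @export
default_days <- function() {
  list("I" = c(3, 6, 10), "II" = c(3, 6, 10), "I+II" = c(1, 3, 6, 10))
}

#' Build a balanced metabolome sampling design
#'
#' Full factorial over variety x condition (control vs drought) x sampling
#' day x replicate, within each treatment. Control plants are sampled on
#' the same days as the stressed ones, so every drought cell has a matched
#' control cell. Sample masses (mg of extracted leaf tissue) are drawn
#' uniformly from `mass_range`.
#'
#' @param n_varieties number of varieties (>= 2; the first `n_varieties`
#'   of `varieties` are used).
#' @param treatments character vector of treatment labels (non-empty).
#' @param days_per_treatment named list mapping each treatment to its
#'   integer vector of sampling days.
#' @param n_reps biological replicates per cell (>= 2).
#' @param mass_range length-2 positive numeric, uniform bounds for sample
#'   mass in mg.
#' @param seed integer seed (sample masses are the only random element).
#' @param varieties optional character vector of variety names.
#' @return `data.frame` of class `design_table` with columns `sample_id`,
#'   `variety`, `treatment`, `condition`, `day`, `replicate`,
#'   `sample_mass`.
#' @examples
#' d <- make_design(n_varieties = 8, treatments = "I",
#'                  days_per_treatment = list("I" = c(3, 6, 10)),
#'                  n_reps = 4, seed = 1)
#' nrow(d)  # 8 * 2 * 3 * 4 = 192
#' @export
make_design <- function(n_varieties = 8,
                        treatments = c("I", "II", "I+II"),
                        days_per_treatment = default_days(),
                        n_reps = 4,
                        mass_range = c(90, 110),
                        seed = 1,
                        varieties = default_varieties()) {
  if (length(treatments) == 0) stop("'treatments' must be non-empty")
  if (n_varieties < 2) stop("'n_varieties' must be >= 2")
  if (n_reps < 2) stop("'n_reps' must be >= 2")
  if (length(mass_range) != 2 || any(!is.finite(mass_range)) ||
      any(mass_range <= 0) || mass_range[2] < mass_range[1]) {
    stop("'mass_range' must be positive finite bounds")
  }
  missing_days <- setdiff(treatments, names(days_per_treatment))
  if (length(missing_days) > 0) {
    stop("no day set for treatment(s): ", paste(missing_days, collapse = ", "))
  }
  if (any(vapply(days_per_treatment[treatments], length, integer(1)) == 0)) {
    stop("every treatment needs a non-empty day set")
  }
  if (n_varieties > length(varieties)) {
    varieties <- c(varieties, paste0("V", seq_len(n_varieties)))
  }
  varieties <- varieties[seq_len(n_varieties)]

  rows <- do.call(rbind, lapply(treatments, function(tr) {
    expand.grid(
      variety = varieties,
      condition = c("control", "drought"),
      day = as.integer(days_per_treatment[[tr]]),
      replicate = seq_len(n_reps),
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )[, c(1, 2, 3, 4)] |>
      (\(g) cbind(treatment = tr, g))()
  }))
  rows <- rows[, c("variety", "treatment", "condition", "day", "replicate")]
  set.seed(seed)
  rows$sample_mass <- stats::runif(nrow(rows), mass_range[1], mass_range[2])
  rows$sample_id <- sprintf("S%04d", seq_len(nrow(rows)))
  rows <- rows[, c("sample_id", "variety", "treatment", "condition",
                   "day", "replicate", "sample_mass")]
  class(rows) <- c("design_table", "data.frame")
  rows
}
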