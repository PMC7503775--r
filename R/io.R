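#' Write a chromatogram set as delimited text files
#'
#' One TSV per sample and wavelength (`<sample_id>_<wavelength>nm.tsv`
#' with columns `rt_minutes`, `intensity_AU`), the design table as
#' `design.tsv`, and the ground truth (when present) as
#' `ground_truth.json`.
#'
#' @param chrom_set a `chromatogram_set`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_chromatogram_set <- function(chrom_set, dir) {
  stopifnot(inherits(chrom_set, "chromatogram_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in chrom_set$chromatograms) {
    f <- file.path(dir, sprintf("%s_%gnm.tsv", ch$sample_id, ch$wavelength))
    utils::write.table(
      data.frame(rt_minutes = ch$rt, intensity_AU = ch$intensity),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv(as.data.frame(chrom_set$design), file.path(dir, "design.tsv"))
  if (!is.null(chrom_set$ground_truth)) {
    gt <- chrom_set$ground_truth
    gt$warps <- NULL  # node tables are bulky and reconstructible from seed
    jsonlite::write_json(unclass(gt), file.path(dir, "ground_truth.json"),
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read a chromatogram set written by [write_chromatogram_set()]
#'
#' Every sample listed in the design must have a file per wavelength
#' (missing files are an error naming the sample); files in the
#' directory that match no design row produce a warning and are ignored.
#' All traces must share the same retention-time grid.
#'
#' @param dir directory of per-sample TSV files.
#' @param design_path path to the design TSV (default `dir/design.tsv`).
#' @param wavelengths wavelengths to load.
#' @return a `chromatogram_set` (ground truth reloaded when
#'   `ground_truth.json` is present).
#' @export
read_chromatogram_set <- function(dir, design_path = file.path(dir, "design.tsv"),
                                  wavelengths = c(280, 330)) {
  if (!file.exists(design_path)) stop("design table not found: ", design_path)
  design <- utils::read.table(design_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  class(design) <- c("design_table", "data.frame")

  expected <- as.vector(outer(design$sample_id, wavelengths,
                              function(s, w) sprintf("%s_%gnm.tsv", s, w)))
  present <- list.files(dir, pattern = "_[0-9]+nm\\.tsv$")
  extra <- setdiff(present, expected)
  if (length(extra) > 0) {
    warning("ignoring ", length(extra), " chromatogram file(s) not in the design")
  }

  chroms <- list()
  grid <- NULL
  for (i in seq_len(nrow(design))) {
    for (wl in wavelengths) {
      f <- file.path(dir, sprintf("%s_%gnm.tsv", design$sample_id[i], wl))
      if (!file.exists(f)) {
        stop("missing chromatogram file for sample ", design$sample_id[i],
             " at ", wl, " nm")
      }
      d <- utils::read.table(f, header = TRUE, sep = "\t")
      if (is.null(grid)) {
        grid <- d$rt_minutes
      } else if (length(d$rt_minutes) != length(grid) ||
                 max(abs(d$rt_minutes - grid)) > 1e-9) {
        stop("inconsistent retention-time grid in ", basename(f))
      }
      chroms[[sprintf("%s_%g", design$sample_id[i], wl)]] <- structure(
        list(rt = grid, intensity = d$intensity_AU, wavelength = wl,
             sample_id = design$sample_id[i],
             sample_mass = design$sample_mass[i]),
        class = "chromatogram")
    }
  }

  gt <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt$metabolites <- as.data.frame(gt$metabolites)
    gt$categories <- as.data.frame(gt$categories)
    gt$effects <- as.data.frame(gt$effects)
    if (!is.null(gt$phenotype_effects)) {
      gt$phenotype_effects <- as.data.frame(gt$phenotype_effects)
    }
    class(gt) <- "ground_truth"
  }

  structure(list(chromatograms = chroms, design = design, grid = grid,
                 wavelengths = wavelengths, ground_truth = gt),
            class = "chromatogram_set")
}

#' Write a metabolite table as TSV (design columns first)
#' @param table a `metabolite_table` with design attached.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_metabolite_table <- function(table, path) {
  stopifnot(inherits(table, "metabolite_table"))
  df <- cbind(as.data.frame(table$design),
              as.data.frame(table$values, check.names = FALSE))
  write_tsv(df, path)
}

#' Read a metabolite table TSV written by [write_metabolite_table()]
#' @param path TSV file.
#' @return a `metabolite_table`.
#' @export
read_metabolite_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  design_cols <- c("sample_id", "variety", "treatment", "condition",
                   "day", "replicate", "sample_mass")
  design_cols <- intersect(design_cols, names(df))
  design <- df[, design_cols, drop = FALSE]
  values <- as.matrix(df[, setdiff(names(df), design_cols), drop = FALSE])
  rownames(values) <- design$sample_id
  structure(list(values = values,
                 variables = data.frame(variable = colnames(values),
                                        stringsAsFactors = FALSE),
                 design = design),
            class = "metabolite_table")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key/value YAML naming the simulation and analysis parameters;
#' keys must be a subset of the [pipeline_config()] arguments. Values are
#' validated by `pipeline_config()`.
#'
#' @param path YAML file.
#' @return a validated `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
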