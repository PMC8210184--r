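#' Protein-by-sample MS2 intensity matrix with sample metadata
#'
#' The central container of the package: a numeric matrix of MS2 spectral
#' intensities (rows = proteins, columns = pull-down runs) together with a
#' per-sample metadata sheet describing the experimental design. "Not
#' detected" is encoded as `NA`, never as zero: downstream mock subtraction
#' and contaminant filtering are presence/absence operations and must
#' distinguish absence from low signal.
#'
#' @param values Numeric matrix, proteins x samples. Row names are protein
#'   identifiers (opaque strings, UniProt accessions in practice); column
#'   names are sample identifiers. All non-missing values must be >= 0.
#' @param sample_meta Data frame with one row per sample and columns
#'   `sample_id`, `cell_line`, `bait`, `condition`, `culture`, `tech_rep`,
#'   `is_mock` (0/1). `sample_id` must match `colnames(values)` exactly.
#'
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values` and `samples`.
#' @export
intensity_matrix <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("'values' must have unique protein row names", call. = FALSE)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("'values' must have unique sample column names", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("negative intensities are not allowed", call. = FALSE)
  required <- c("sample_id", "cell_line", "bait", "condition",
                "culture", "tech_rep", "is_mock")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols))
    stop(sprintf("sample metadata lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicated sample_id in metadata", call. = FALSE)
  unmatched <- setdiff(colnames(values), sample_meta$sample_id)
  if (length(unmatched))
    stop(sprintf("metadata missing sample(s): %s",
                 paste(unmatched, collapse = ", ")), call. = FALSE)
  extra <- setdiff(sample_meta$sample_id, colnames(values))
  if (length(extra))
    stop(sprintf("metadata lists unknown sample(s): %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  if (any(is.na(sample_meta[required])))
    stop("sample metadata contains missing entries", call. = FALSE)
  structure(list(values = values, samples = sample_meta),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d proteins x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  cell lines: %s\n",
              paste(unique(x$samples$cell_line), collapse = ", ")))
  cat(sprintf("  baits:      %s\n",
              paste(unique(x$samples$bait), collapse = ", ")))
  cat(sprintf("  detected:   %.1f%% of cells\n",
              100 * mean(!is.na(x$values))))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' Read an intensity table and its sample metadata sheet
#'
#' Reads the tab-separated protein x sample intensity table (first column =
#' protein ID, empty cell = not detected) and the sample metadata sheet, and
#' validates them into an [intensity_matrix()].
#'
#' @param path Path to the intensity TSV.
#' @param meta_path Path to the sample metadata TSV with columns `sample_id`,
#'   `cell_line`, `bait`, `condition`, `culture`, `tech_rep`, `is_mock`.
#' @return An [intensity_matrix()].
#' @export
read_intensity_table <- function(path, meta_path) {
  tab <- read_tsv_strict(path)
  if (ncol(tab) < 2)
    stop("intensity table needs a protein_id column plus >= 1 sample",
         call. = FALSE)
  ids <- as.character(tab[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicated protein ID(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  meta <- read_tsv_strict(meta_path)
  meta$sample_id <- as.character(meta$sample_id)
  intensity_matrix(values, meta)
}

#' Write an intensity matrix (and optional ground truth) as TSV fixtures
#'
#' Emits the intensity table (`intensity.tsv`, empty cell = not detected),
#' the sample metadata sheet (`sample_meta.tsv`) and, when supplied, the
#' ground-truth table (`ground_truth.tsv`) into `dir`, in the exact formats
#' [read_intensity_table()] and [read_ground_truth()] consume.
#'
#' @param x An [intensity_matrix()].
#' @param dir Output directory (created if absent).
#' @param truth Optional ground-truth data frame as produced by
#'   [simulate_interactome()].
#' @return Invisibly, a named character vector of the files written.
#' @export
write_fixture <- function(x, dir, truth = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create directory: %s", dir), call. = FALSE)
  }
  paths <- c(intensity = file.path(dir, "intensity.tsv"),
             sample_meta = file.path(dir, "sample_meta.tsv"))
  tab <- data.frame(protein_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(tab, paths[["intensity"]])
  write_tsv_strict(x$samples, paths[["sample_meta"]])
  if (!is.null(truth)) {
    paths <- c(paths, ground_truth = file.path(dir, "ground_truth.tsv"))
    write_tsv_strict(truth, paths[["ground_truth"]])
  }
  invisible(paths)
}

#' Read a ground-truth table written by [write_fixture()]
#'
#' @param path Path to a TSV with columns `protein_id`, `true_complex`
#'   (empty = no complex), `is_contaminant`, `is_modulation_coupled`.
#' @return A data frame with those columns.
#' @export
read_ground_truth <- function(path) {
  truth <- read_tsv_strict(path)
  required <- c("protein_id", "true_complex", "is_contaminant",
                "is_modulation_coupled")
  missing_cols <- setdiff(required, names(truth))
  if (length(missing_cols))
    stop(sprintf("ground-truth table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(truth$protein_id))
    stop("duplicated protein_id in ground truth", call. = FALSE)
  truth$true_complex <- as.character(truth$true_complex)
  truth$is_contaminant <- as.logical(truth$is_contaminant)
  truth$is_modulation_coupled <- as.logical(truth$is_modulation_coupled)
  truth
}
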