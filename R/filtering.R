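#' Contaminant-repository frequency table
#'
#' Holds, for each protein, the fraction of negative-control AP-MS runs in
#' which it was detected — the frequency-filter logic behind community
#' contaminant repositories. Proteins absent from the table are treated as
#' never seen in controls.
#'
#' @param table Data frame with columns `protein_id`, `frequency` (in
#'   \[0, 1\]) and optionally `n_runs`.
#' @return An object of class `contaminant_repository`.
#' @export
contaminant_repository <- function(table) {
  required <- c("protein_id", "frequency")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols))
    stop(sprintf("contaminant repository lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(table$protein_id))
    stop("duplicated protein_id in contaminant repository", call. = FALSE)
  if (any(is.na(table$frequency)) ||
      any(table$frequency < 0 | table$frequency > 1))
    stop("repository frequencies must be in [0, 1]", call. = FALSE)
  if (is.null(table$n_runs)) table$n_runs <- NA_integer_
  structure(list(table = table[, c("protein_id", "frequency", "n_runs")]),
            class = "contaminant_repository")
}

#' Read a contaminant repository TSV (columns protein_id, frequency, n_runs)
#' @param path Path to the TSV.
#' @return A [contaminant_repository()].
#' @export
read_contaminant_repository <- function(path) {
  contaminant_repository(read_tsv_strict(path))
}

#' Write a contaminant repository as TSV
#' @param repo A [contaminant_repository()].
#' @param path Output path.
#' @export
write_contaminant_repository <- function(repo, path) {
  stopifnot(inherits(repo, "contaminant_repository"))
  write_tsv_strict(repo$table, path)
  invisible(path)
}

#' Post-filter prey set for one (bait, cell line, condition) experiment
#'
#' Carries the proteins surviving the applied filters together with a
#' provenance record of each filter and the number of proteins it removed.
#'
#' @param proteins Character vector of protein IDs.
#' @param bait,cell_line,condition Labels of the experiment.
#' @param provenance Data frame with columns `filter`, `removed`; by default
#'   an empty record.
#' @return An object of class `interactor_set`.
#' @export
interactor_set <- function(proteins, bait, cell_line, condition = "control",
                           provenance = NULL) {
  if (anyDuplicated(proteins))
    stop("duplicated protein IDs in interactor set", call. = FALSE)
  if (is.null(provenance))
    provenance <- data.frame(filter = character(0), removed = integer(0),
                             stringsAsFactors = FALSE)
  structure(list(bait = bait, cell_line = cell_line, condition = condition,
                 proteins = as.character(proteins), provenance = provenance),
            class = "interactor_set")
}

#' @export
print.interactor_set <- function(x, ...) {
  cat(sprintf("<interactor_set> %s / %s / %s: %d proteins\n",
              x$bait, x$cell_line, x$condition, length(x$proteins)))
  if (nrow(x$provenance))
    for (i in seq_len(nrow(x$provenance)))
      cat(sprintf("  - %s: removed %d\n",
                  x$provenance$filter[i], x$provenance$removed[i]))
  invisible(x)
}

#' @export
length.interactor_set <- function(x) length(x$proteins)

#' Proteins detected in a given pull-down experiment
#'
#' A protein counts as detected for a (bait, cell line, condition) experiment
#' when it has a non-missing intensity in at least `min_runs` of the
#' replicate runs (cultures x technical replicates) of that experiment.
#'
#' @param x An [intensity_matrix()].
#' @param bait,cell_line,condition Which experiment to look at.
#' @param min_runs Minimum number of replicate runs with detection; default 2
#'   of the 4 runs in a 2-culture x 2-technical-replicate design. `min_runs
#'   = 1` gives the union over runs.
#' @return Character vector of detected protein IDs.
#' @export
detect_present <- function(x, bait, cell_line, condition = "control",
                           min_runs = 2L) {
  stopifnot(inherits(x, "intensity_matrix"))
  sel <- x$samples$bait == bait & x$samples$cell_line == cell_line &
    x$samples$condition == condition
  if (!any(sel))
    stop(sprintf("no samples match bait '%s', cell line '%s', condition '%s'",
                 bait, cell_line, condition), call. = FALSE)
  n_runs <- sum(sel)
  if (min_runs < 1 || min_runs > n_runs)
    stop(sprintf("min_runs must be in [1, %d] for this design", n_runs),
         call. = FALSE)
  counts <- rowSums(!is.na(x$values[, sel, drop = FALSE]))
  rownames(x$values)[counts >= min_runs]
}

#' Remove proteins detected in mock (no-antibody) pull-downs
#'
#' Strict presence-based background subtraction: any protein detected in the
#' mock set is removed from the pull-down set, regardless of intensity.
#'
#' @param ip_set An [interactor_set()] (or character vector, in which case
#'   bait/line labels must be supplied via `...` to [interactor_set()]).
#' @param mock_set Character vector of proteins detected in mock runs, or an
#'   [interactor_set()].
#' @return The filtered [interactor_set()] with updated provenance.
#' @export
subtract_mock <- function(ip_set, mock_set) {
  stopifnot(inherits(ip_set, "interactor_set"))
  mock <- if (inherits(mock_set, "interactor_set")) mock_set$proteins else mock_set
  kept <- setdiff(ip_set$proteins, mock)
  prov <- rbind(ip_set$provenance,
                data.frame(filter = "mock_subtraction",
                           removed = length(ip_set$proteins) - length(kept),
                           stringsAsFactors = FALSE))
  interactor_set(kept, ip_set$bait, ip_set$cell_line, ip_set$condition, prov)
}

#' Remove frequent contaminants by repository frequency
#'
#' Removes proteins whose control-run detection frequency in the repository
#' exceeds `max_freq`. Proteins absent from the repository are kept.
#'
#' @param ip_set An [interactor_set()].
#' @param repo A [contaminant_repository()].
#' @param max_freq Maximum tolerated control-run frequency, in \[0, 1\];
#'   default 0.10.
#' @return The filtered [interactor_set()] with updated provenance.
#' @export
filter_contaminants <- function(ip_set, repo, max_freq = 0.10) {
  stopifnot(inherits(ip_set, "interactor_set"),
            inherits(repo, "contaminant_repository"))
  if (max_freq < 0 || max_freq > 1)
    stop("max_freq must be in [0, 1]", call. = FALSE)
  freq <- repo$table$frequency[match(ip_set$proteins, repo$table$protein_id)]
  drop <- !is.na(freq) & freq > max_freq
  kept <- ip_set$proteins[!drop]
  prov <- rbind(ip_set$provenance,
                data.frame(filter = "contaminant_frequency",
                           removed = sum(drop), stringsAsFactors = FALSE))
  interactor_set(kept, ip_set$bait, ip_set$cell_line, ip_set$condition, prov)
}

#' Build the fully filtered interactor set for one experiment
#'
#' Convenience composition of [detect_present()], [subtract_mock()] (against
#' the matching mock pull-down) and [filter_contaminants()].
#'
#' @inheritParams detect_present
#' @param repo A [contaminant_repository()] or `NULL` to skip the frequency
#'   filter.
#' @param mock_bait Label of the mock pull-down in the metadata.
#' @param max_freq Repository frequency cutoff.
#' @return An [interactor_set()].
#' @export
filtered_interactors <- function(x, bait, cell_line, condition = "control",
                                 min_runs = 2L, repo = NULL,
                                 mock_bait = "mock", max_freq = 0.10) {
  present <- detect_present(x, bait, cell_line, condition, min_runs)
  mock <- detect_present(x, mock_bait, cell_line, condition, min_runs = 1L)
  s <- interactor_set(present, bait, cell_line, condition)
  s <- subtract_mock(s, mock)
  if (!is.null(repo)) s <- filter_contaminants(s, repo, max_freq)
  s
}

#' Write an interactor set as TSV plus a JSON provenance sidecar
#' @param s An [interactor_set()].
#' @param path Output TSV path; the sidecar is written at `<path>.json`.
#' @export
write_interactor_set <- function(s, path) {
  stopifnot(inherits(s, "interactor_set"))
  write_tsv_strict(data.frame(protein_id = s$proteins,
                              stringsAsFactors = FALSE), path)
  jsonlite::write_json(
    list(bait = s$bait, cell_line = s$cell_line, condition = s$condition,
         n_proteins = length(s$proteins),
         provenance = s$provenance),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
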