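#' Exhaustive Venn partition of k labelled sets
#'
#' Computes all `2^k - 1` mutually exclusive regions of the Venn diagram of
#' the supplied sets. Region names join the labels of the sets an element
#' belongs to with `"&"` (e.g. `"A&B"` holds elements in A and B but in no
#' other set). The regions are disjoint and cover the union exactly.
#'
#' @param sets Named list of character vectors (2 or more sets).
#' @return An object of class `venn_report`: list with `set_labels`,
#'   `regions` (named list of ID vectors) and `counts` (named integer).
#' @export
venn_report <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets)))
    stop("'sets' must be a uniquely named list", call. = FALSE)
  if (length(sets) < 1L) stop("need at least one set", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  labels <- names(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  key <- apply(membership, 1L, function(row)
    paste(labels[row], collapse = "&"))
  k <- length(sets)
  all_keys <- unlist(lapply(seq_len(k), function(size)
    utils::combn(labels, size, paste, collapse = "&")))
  regions <- lapply(all_keys, function(kk) universe[key == kk])
  names(regions) <- all_keys
  structure(list(set_labels = labels,
                 regions = regions,
                 counts = vapply(regions, length, 0L)),
            class = "venn_report")
}

#' @export
print.venn_report <- function(x, ...) {
  cat(sprintf("<venn_report> %d sets: %s\n", length(x$set_labels),
              paste(x$set_labels, collapse = ", ")))
  for (nm in names(x$counts))
    cat(sprintf("  %-30s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Members of a Venn region selected by inclusion (and optional exclusion)
#'
#' `region_members(v, "A")` returns the exclusive A-only region;
#' `region_members(v, c("A","B"))` the exclusive A-and-B-only region.
#' `region_members(v, "A", exact = FALSE)` returns everything in A
#' regardless of other memberships (the whole input set).
#'
#' @param v A [venn_report()].
#' @param labels Set labels the elements must belong to.
#' @param exact If `TRUE` (default) the exclusive region; if `FALSE`, the
#'   union of all regions containing `labels`.
#' @return Character vector of IDs.
#' @export
region_members <- function(v, labels, exact = TRUE) {
  stopifnot(inherits(v, "venn_report"))
  bad <- setdiff(labels, v$set_labels)
  if (length(bad))
    stop(sprintf("unknown set label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (exact) {
    key <- paste(v$set_labels[v$set_labels %in% labels], collapse = "&")
    return(v$regions[[key]])
  }
  in_region <- vapply(names(v$regions), function(kk)
    all(labels %in% strsplit(kk, "&", fixed = TRUE)[[1L]]), TRUE)
  unique(unlist(v$regions[in_region], use.names = FALSE))
}

#' Compare one bait's interactor sets across two cell lines
#'
#' Three-region report of the proteins found only in the first line, shared
#' between the two lines (the disease-specific candidates carried forward by
#' the pipeline), and only in the second line. Both sets must come from the
#' same bait.
#'
#' @param set_a,set_b [interactor_set()] objects for the same bait in two
#'   cell lines.
#' @return A [venn_report()] labelled by cell line.
#' @export
intersect_lines <- function(set_a, set_b) {
  stopifnot(inherits(set_a, "interactor_set"),
            inherits(set_b, "interactor_set"))
  if (!identical(set_a$bait, set_b$bait))
    stop(sprintf("bait mismatch: '%s' vs '%s'", set_a$bait, set_b$bait),
         call. = FALSE)
  if (identical(set_a$cell_line, set_b$cell_line))
    stop("the two sets must come from different cell lines", call. = FALSE)
  sets <- list(set_a$proteins, set_b$proteins)
  names(sets) <- c(set_a$cell_line, set_b$cell_line)
  venn_report(sets)
}

#' Compare the cross-line shared interactomes of two baits
#'
#' Partitions the hub bait's shared interactome against a discriminating
#' second bait: proteins seen only with the first bait (canonical-complex
#' candidates), with both baits (shared core) and only with the second bait.
#'
#' @param shared_bait1,shared_bait2 Character vectors: the cross-line shared
#'   sets of the two baits (see [intersect_lines()]).
#' @param labels Length-2 character: the two bait labels.
#' @return A [venn_report()] labelled by bait.
#' @export
compare_baits <- function(shared_bait1, shared_bait2,
                          labels = c("bait1", "bait2")) {
  stopifnot(length(labels) == 2L, !anyDuplicated(labels))
  sets <- list(unique(as.character(shared_bait1)),
               unique(as.character(shared_bait2)))
  names(sets) <- labels
  venn_report(sets)
}

membership_categories <- c("canonical_only", "shared_core",
                           "noncanonical_only", "chromatome_catalytic",
                           "chromatome_independent",
                           "bait_independent_unassigned")

#' Assign complex-membership categories from a two-bait proteome comparison
#'
#' Maps the disjoint regions of [compare_baits()] onto membership
#' categories: first-bait-only -> `canonical_only`, shared -> `shared_core`,
#' second-bait-only -> `noncanonical_only`; any other protein of `universe`
#' -> `bait_independent_unassigned`.
#'
#' @param baits_venn A two-set [venn_report()] from [compare_baits()], hub
#'   bait first.
#' @param universe Character vector of all proteins to categorize (default:
#'   the union of the two sets).
#' @return Data frame `protein_id`, `category`.
#' @export
assign_membership <- function(baits_venn, universe = NULL) {
  stopifnot(inherits(baits_venn, "venn_report"),
            length(baits_venn$set_labels) == 2L)
  l1 <- baits_venn$set_labels[1L]
  l2 <- baits_venn$set_labels[2L]
  cat_of <- c(canonical_only = l1, shared_core = paste(l1, l2, sep = "&"),
              noncanonical_only = l2)
  assigned <- data.frame(
    protein_id = unlist(baits_venn$regions[cat_of], use.names = FALSE),
    category = rep(names(cat_of), baits_venn$counts[cat_of]),
    stringsAsFactors = FALSE)
  if (!is.null(universe)) {
    rest <- setdiff(unique(as.character(universe)), assigned$protein_id)
    assigned <- rbind(assigned,
                      data.frame(protein_id = rest,
                                 category = rep("bait_independent_unassigned",
                                                length(rest)),
                                 stringsAsFactors = FALSE))
  }
  rownames(assigned) <- NULL
  assigned
}

#' Partition three chromatome datasets and assign chromatome categories
#'
#' Full seven-region Venn of the hub-bait chromatome against the
#' non-canonical-complex bait chromatome and the catalytic histone-mark
#' chromatome, plus a membership assignment: hub proteins co-occurring with
#' the mark are `chromatome_catalytic` (catalysis-associated); hub proteins
#' in neither other dataset are `chromatome_independent`
#' (catalytic-independent, hub-specific); everything else in the union is
#' `bait_independent_unassigned`.
#'
#' @param hub_chrom,partner_chrom,mark_chrom Character vectors of protein
#'   IDs over a common ID space.
#' @param labels Length-3 labels for the three datasets.
#' @return List with `venn` (a [venn_report()]) and `assignment` (data frame
#'   `protein_id`, `category`).
#' @export
chromatome_partition <- function(hub_chrom, partner_chrom, mark_chrom,
                                 labels = c("BMI1", "RYBP", "H2AK119ub")) {
  stopifnot(length(labels) == 3L, !anyDuplicated(labels))
  sets <- list(unique(as.character(hub_chrom)),
               unique(as.character(partner_chrom)),
               unique(as.character(mark_chrom)))
  names(sets) <- labels
  v <- venn_report(sets)
  hub <- sets[[1L]]
  catalytic <- intersect(hub, sets[[3L]])
  independent <- setdiff(hub, union(sets[[2L]], sets[[3L]]))
  rest <- setdiff(unique(unlist(sets, use.names = FALSE)),
                  c(catalytic, independent))
  assignment <- data.frame(
    protein_id = c(catalytic, independent, rest),
    category = c(rep("chromatome_catalytic", length(catalytic)),
                 rep("chromatome_independent", length(independent)),
                 rep("bait_independent_unassigned", length(rest))),
    stringsAsFactors = FALSE)
  list(venn = v, assignment = assignment)
}

#' Intersect a proteome-only set with a chromatome-only set
#'
#' @param proteome_only,chromatome_only Character vectors of protein IDs.
#' @return List with `shared` (the intersection) and `n` (its size).
#' @export
integrate_proteome_chromatome <- function(proteome_only, chromatome_only) {
  shared <- intersect(unique(as.character(proteome_only)),
                      unique(as.character(chromatome_only)))
  list(shared = shared, n = length(shared))
}

#' Precision and recall of a membership assignment against ground truth
#'
#' Compares assigned categories with the categories implied by the true
#' complex labels of the synthetic ground truth. `truth_map` states which
#' true complex corresponds to which category; proteins whose true complex
#' is unmapped (contaminants, background) are expected to be
#' `bait_independent_unassigned`. Only proteins present in both the
#' assignment and the truth table are scored.
#'
#' @param assignment Data frame `protein_id`, `category`.
#' @param truth Ground-truth data frame (see [simulate_interactome()]).
#' @param truth_map Named character: `complex_id -> category`.
#' @return Data frame `category`, `n_assigned`, `n_true`, `tp`, `precision`,
#'   `recall`; precision is `NA` (flagged, not 0) for empty categories.
#' @export
recovery_metrics <- function(assignment, truth, truth_map) {
  stopifnot(all(c("protein_id", "category") %in% names(assignment)))
  if (anyDuplicated(assignment$protein_id))
    stop("a protein may receive only one category", call. = FALSE)
  shared <- intersect(assignment$protein_id, truth$protein_id)
  a <- assignment[match(shared, assignment$protein_id), ]
  true_complex <- truth$true_complex[match(shared, truth$protein_id)]
  true_cat <- ifelse(is.na(true_complex) |
                       !(true_complex %in% names(truth_map)),
                     "bait_independent_unassigned",
                     unname(truth_map[true_complex]))
  cats <- union(unique(a$category), unique(true_cat))
  res <- lapply(cats, function(cc) {
    n_assigned <- sum(a$category == cc)
    n_true <- sum(true_cat == cc)
    tp <- sum(a$category == cc & true_cat == cc)
    data.frame(category = cc, n_assigned = n_assigned, n_true = n_true,
               tp = tp,
               precision = if (n_assigned > 0) tp / n_assigned else NA_real_,
               recall = if (n_true > 0) tp / n_true else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a Venn report as JSON (regions, counts, members)
#' @param v A [venn_report()].
#' @param path Output JSON path.
#' @export
write_venn_report <- function(v, path) {
  stopifnot(inherits(v, "venn_report"))
  jsonlite::write_json(
    list(set_labels = v$set_labels,
         counts = as.list(v$counts),
         members = v$regions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
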