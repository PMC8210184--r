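#' Upper-tail hypergeometric overlap test
#'
#' Tests whether the overlap between a query set and a reference set is
#' larger than expected for random draws from a finite universe. With
#' `N = |universe|`, `K = |reference|`, `n = |query|` and
#' `k = |query intersect reference|`, the p-value is the upper tail
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` — the observed overlap is
#' included, so `p` is always in `(0, 1]` and `k = 0` gives `p = 1`.
#'
#' @param query,reference Character vectors, both subsets of `universe`.
#' @param universe Character vector: the population sets are drawn from.
#' @return An object of class `overlap_test`: list with `k`, `K`, `n`, `N`,
#'   `p_value`.
#' @export
hypergeom_overlap <- function(query, reference, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(as.character(query))
  reference <- unique(as.character(reference))
  out_q <- setdiff(query, universe)
  if (length(out_q))
    stop(sprintf("query not contained in universe (e.g. %s)", out_q[[1L]]),
         call. = FALSE)
  out_r <- setdiff(reference, universe)
  if (length(out_r))
    stop(sprintf("reference not contained in universe (e.g. %s)", out_r[[1L]]),
         call. = FALSE)
  N <- length(universe); K <- length(reference); n <- length(query)
  k <- length(intersect(query, reference))
  p <- hyper_upper_tail(k, K, n, N)
  structure(list(k = k, K = K, n = n, N = N, p_value = p),
            class = "overlap_test")
}

# P(X >= k), X ~ Hypergeometric(N, K, n); stable in log space via phyper.
hyper_upper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("<overlap_test> k = %d of n = %d vs K = %d in N = %d; P(X >= k) = %.4g\n",
              x$k, x$n, x$K, x$N, x$p_value))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value under the minimum-likelihood rule: with margins
#' fixed, sum the hypergeometric probabilities of every table whose point
#' probability does not exceed that of the observed table. A table with a
#' zero margin has a single attainable configuration, so `p = 1`.
#'
#' @param table 2x2 matrix of non-negative integer counts (not all zero).
#' @return The two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L)))
    stop("need a 2x2 table", call. = FALSE)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(m) == 0L) stop("all-zero table", call. = FALSE)
  r1 <- sum(m[1L, ]); c1 <- sum(m[, 1L]); N <- sum(m)
  support <- max(0L, c1 - (N - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, N - r1, c1)
  p_obs <- probs[support == m[1L, 1L]]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Order-preserving FDR adjustment: `adj_(i) = min_{j >= i} min(1,
#' p_(j) * m / j)` over the sorted p-values. `NA` entries stay `NA` and do
#' not count toward `m`.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Collection of named gene/protein sets
#'
#' @param sets Named list of character vectors.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets)))
    stop("collections must be uniquely named", call. = FALSE)
  structure(list(sets = lapply(sets, function(s) unique(as.character(s)))),
            class = "gene_set_collection")
}

#' Read gene sets from GMT or one-ID-per-line text files
#'
#' GMT files (`.gmt`: name, description, members per tab-separated line)
#' yield one set per line; plain text files yield a single set named after
#' the file.
#'
#' @param path File path.
#' @return A [gene_set_collection()].
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[[`, "", 1L)
    gene_set_collection(sets)
  } else {
    nm <- sub("\\.[^.]*$", "", basename(path))
    out <- list(trimws(lines))
    names(out) <- nm
    gene_set_collection(out)
  }
}

#' Over-representation analysis of a query set against set collections
#'
#' Applies [hypergeom_overlap()] of the query against every collection
#' (collections are clipped to the universe first), then adjusts the
#' p-values across collections with [benjamini_hochberg()].
#'
#' @param query Character vector, subset of `universe`.
#' @param collections A [gene_set_collection()] or named list.
#' @param universe Character vector population.
#' @return Data frame `set`, `k`, `K`, `n`, `N`, `p_value`, `q_value`.
#' @export
ora_collections <- function(query, collections, universe) {
  if (inherits(collections, "gene_set_collection"))
    collections <- collections$sets
  universe <- unique(as.character(universe))
  rows <- lapply(names(collections), function(nm) {
    ref <- intersect(collections[[nm]], universe)
    ht <- hypergeom_overlap(query, ref, universe)
    data.frame(set = nm, k = ht$k, K = ht$K, n = ht$n, N = ht$N,
               p_value = ht$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- benjamini_hochberg(out$p_value)
  rownames(out) <- NULL
  out
}

#' Read a differential-exon-usage results table
#'
#' @param path TSV with columns `gene_id`, `exon_id`, `p_value` (raw
#'   per-exon p-values, as exported from an exon-usage analysis).
#' @return Data frame with those columns.
#' @export
read_deu_table <- function(path) {
  tab <- read_tsv_strict(path)
  validate_deu_table(tab)
}

validate_deu_table <- function(tab) {
  required <- c("gene_id", "exon_id", "p_value")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop(sprintf("DEU table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(tab) == 0L) stop("empty DEU table", call. = FALSE)
  if (anyDuplicated(tab[c("gene_id", "exon_id")]))
    stop("duplicated (gene_id, exon_id) rows", call. = FALSE)
  if (any(tab$p_value < 0 | tab$p_value > 1, na.rm = TRUE))
    stop("raw p-values must be in [0, 1]", call. = FALSE)
  tab
}

#' Overlap of differential-exon-usage genes with reference gene sets
#'
#' Adjusts the per-exon raw p-values with [benjamini_hochberg()] across all
#' exons, calls a gene a DEU gene when at least one of its exons has
#' adjusted p below `alpha` (each gene counted once), and tests the DEU gene
#' set for overlap against every reference set by [hypergeom_overlap()].
#' The default universe is all genes present in the table; reference sets
#' are clipped to the universe and the universe used is reported.
#'
#' @param table DEU results data frame (`gene_id`, `exon_id`, `p_value`).
#' @param reference A [gene_set_collection()] or named list of gene sets.
#' @param alpha Adjusted-p significance cutoff in (0, 1); default 0.05.
#' @param universe Optional character vector of genes; default all genes in
#'   `table`.
#' @return List with `deu_genes` (character), `results` (data frame `set`,
#'   `k`, `K`, `n`, `N`, `p_value`, `q_value`) and `universe`.
#' @export
deu_overlap_analysis <- function(table, reference, alpha = 0.05,
                                 universe = NULL) {
  table <- validate_deu_table(table)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  adj <- benjamini_hochberg(table$p_value)
  deu_genes <- unique(table$gene_id[!is.na(adj) & adj < alpha])
  if (is.null(universe)) universe <- unique(table$gene_id)
  universe <- unique(as.character(universe))
  deu_genes <- intersect(deu_genes, universe)
  results <- ora_collections(deu_genes, reference, universe)
  list(deu_genes = deu_genes, results = results, universe = universe)
}
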