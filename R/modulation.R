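#' Rescale samples so a per-sample statistic is equal across runs
#'
#' Multiplies each sample column by a scalar so the chosen statistic of its
#' non-missing intensities equals the across-sample mean of that statistic.
#' The missingness pattern is unchanged; `method = "none"` is the identity.
#'
#' @param x An [intensity_matrix()].
#' @param method One of `"none"`, `"total"` (equalize sums) or `"median"`
#'   (equalize medians of detected values).
#' @return A rescaled [intensity_matrix()].
#' @export
normalize_samples <- function(x, method = c("none", "total", "median")) {
  stopifnot(inherits(x, "intensity_matrix"))
  method <- match.arg(method)
  if (method == "none") return(x)
  stat <- switch(method,
                 total = colSums(x$values, na.rm = TRUE),
                 median = apply(x$values, 2L, stats::median, na.rm = TRUE))
  n_obs <- colSums(!is.na(x$values))
  if (any(n_obs == 0L))
    stop(sprintf("sample(s) with no detected values cannot be normalized: %s",
                 paste(colnames(x$values)[n_obs == 0L], collapse = ", ")),
         call. = FALSE)
  target <- mean(stat)
  scaled <- sweep(x$values, 2L, target / stat, `*`)
  intensity_matrix(scaled, x$samples)
}

#' Average replicate runs of one pull-down experiment
#'
#' Arithmetic mean of each protein's intensity over the replicate runs
#' (cultures x technical replicates) of one (bait, cell line, condition)
#' experiment. Missing values are handled per `policy`: `"impute-floor"`
#' replaces them with the detection floor `floor` before averaging (a
#' protein missing in all runs stays `NA`); `"ignore-missing"` averages the
#' detected runs only.
#'
#' @param x An [intensity_matrix()].
#' @param bait,cell_line,condition Which experiment to average.
#' @param policy `"impute-floor"` (default) or `"ignore-missing"`.
#' @param floor Imputation floor in intensity units (default 1).
#' @return Named numeric vector of mean intensities, one per protein.
#' @export
aggregate_replicates <- function(x, bait, cell_line, condition,
                                 policy = c("impute-floor", "ignore-missing"),
                                 floor = 1) {
  stopifnot(inherits(x, "intensity_matrix"))
  policy <- match.arg(policy)
  sel <- x$samples$bait == bait & x$samples$cell_line == cell_line &
    x$samples$condition == condition
  if (!any(sel))
    stop(sprintf("no samples match bait '%s', cell line '%s', condition '%s'",
                 bait, cell_line, condition), call. = FALSE)
  vals <- x$values[, sel, drop = FALSE]
  all_missing <- rowSums(!is.na(vals)) == 0L
  out <- if (policy == "impute-floor") {
    vals[is.na(vals)] <- floor
    rowMeans(vals)
  } else {
    rowMeans(vals, na.rm = TRUE)
  }
  out[all_missing] <- NA_real_
  out
}

#' Log2 fold-change of averaged intensities with a pseudocount
#'
#' `log2((mean_mod + pseudo) / (mean_ctrl + pseudo))`. The pseudocount keeps
#' fold-changes finite when one mean is zero; with intensities many orders of
#' magnitude above 1 the default distortion is negligible. Antisymmetric
#' under argument exchange and zero at equality. Missing means propagate to
#' `NA`.
#'
#' @param mean_mod,mean_ctrl Non-negative mean intensities (vectorized).
#' @param pseudo Pseudocount, >= 0 (default 1 intensity unit).
#' @return Numeric log2 fold-change(s).
#' @export
compute_log2fc <- function(mean_mod, mean_ctrl, pseudo = 1) {
  if (pseudo < 0) stop("pseudo must be >= 0", call. = FALSE)
  if (any(mean_mod < 0, na.rm = TRUE) || any(mean_ctrl < 0, na.rm = TRUE))
    stop("negative mean intensities are not allowed", call. = FALSE)
  log2((mean_mod + pseudo) / (mean_ctrl + pseudo))
}

# Replicate-level log2 intensities of one bait's non-mock runs, in the
# 2 x 2 (cell line x genotype condition) layout used by the ANOVA.
modulation_frame <- function(x, bait, pseudo = 1,
                             policy = c("impute-floor", "ignore-missing"),
                             floor = 1) {
  policy <- match.arg(policy)
  sel <- x$samples$bait == bait & x$samples$is_mock == 0L
  if (!any(sel)) stop(sprintf("no samples for bait '%s'", bait), call. = FALSE)
  meta <- x$samples[sel, , drop = FALSE]
  vals <- x$values[, sel, drop = FALSE]
  if (policy == "impute-floor") vals[is.na(vals)] <- floor
  list(meta = meta, log2_vals = log2(vals + pseudo))
}

#' Two-way ANOVA for a genotype (modulation) effect on one protein
#'
#' Fits a fixed-effects two-way ANOVA (cell line x genotype condition, with
#' interaction) to the replicate-level log2 intensities of one protein in
#' one bait's pull-downs across both cell lines and both genotype
#' conditions, and returns the p-value of the genotype main effect.
#'
#' With zero residual variance (e.g. noise-free data) the F statistic is
#' undefined; the function then returns `NA` with attribute
#' `degenerate = TRUE` rather than a silent 0 or 1.
#'
#' @param x An [intensity_matrix()].
#' @param protein Protein ID (row name).
#' @param bait Bait label whose non-mock runs are analysed.
#' @param pseudo Pseudocount added before the log2 transform.
#' @param policy,floor Missing-value policy, as [aggregate_replicates()].
#' @return The genotype main-effect p-value, or flagged `NA` when degenerate.
#' @export
test_modulation <- function(x, protein, bait, pseudo = 1,
                            policy = c("impute-floor", "ignore-missing"),
                            floor = 1) {
  stopifnot(inherits(x, "intensity_matrix"))
  if (!protein %in% rownames(x$values))
    stop(sprintf("unknown protein '%s'", protein), call. = FALSE)
  fr <- modulation_frame(x, bait, pseudo, policy, floor)
  anova_genotype_p(fr$log2_vals[protein, ], fr$meta$cell_line,
                   fr$meta$condition)
}

# Genotype main-effect p from y ~ line * condition (sequential ANOVA,
# identical to the balanced two-way decomposition for complete designs).
anova_genotype_p <- function(y, line, condition) {
  keep <- !is.na(y)
  y <- y[keep]; line <- line[keep]; condition <- condition[keep]
  if (length(unique(condition)) < 2L || length(unique(line)) < 2L)
    return(structure(NA_real_, degenerate = TRUE))
  fit <- stats::lm(y ~ factor(line) * factor(condition))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  if (fit$df.residual < 1L || rss <= max(tss, 1) * 1e-12)
    return(structure(NA_real_, degenerate = TRUE))
  tab <- stats::anova(fit)
  unname(tab["factor(condition)", "Pr(>F)"])
}

#' Classify prey response to bait modulation as concordant or discordant
#'
#' A prey is *concordant* with the bait when its abundance increases in the
#' overexpression line and decreases in the knockdown line:
#' `log2fc_up > fc_min` and `log2fc_down < -fc_min` (and, when `alpha` is
#' given, genotype-effect `p_value < alpha`). It is *discordant* when both
#' fold-changes exceed `fc_min` in magnitude with the same sign. Anything
#' else — including ties at exactly `fc_min` and missing fold-changes — is
#' *unchanged*.
#'
#' @param log2fc_up Log2 fold-change in the overexpression line (modulated
#'   vs control), vectorized.
#' @param log2fc_down Log2 fold-change in the knockdown line.
#' @param p_value Optional genotype-effect p-values (used only with `alpha`).
#' @param fc_min Minimum absolute log2 fold-change; default 0 (any
#'   sign-consistent change counts).
#' @param alpha Optional significance cutoff on `p_value`; default `NULL`
#'   (no p-value gating).
#' @return Character vector in `{"concordant", "discordant", "unchanged"}`.
#' @export
classify_concordance <- function(log2fc_up, log2fc_down, p_value = NULL,
                                 fc_min = 0, alpha = NULL) {
  if (fc_min < 0) stop("fc_min must be >= 0", call. = FALSE)
  n <- length(log2fc_up)
  stopifnot(length(log2fc_down) == n)
  out <- rep("unchanged", n)
  ok <- !is.na(log2fc_up) & !is.na(log2fc_down)
  conc <- ok & log2fc_up > fc_min & log2fc_down < -fc_min
  if (!is.null(alpha)) {
    if (is.null(p_value)) stop("alpha given but no p_value", call. = FALSE)
    conc <- conc & !is.na(p_value) & p_value < alpha
  }
  disc <- ok & ((log2fc_up > fc_min & log2fc_down > fc_min) |
                  (log2fc_up < -fc_min & log2fc_down < -fc_min))
  out[disc] <- "discordant"
  out[conc] <- "concordant"
  out
}

#' Quantify prey modulation for a set of proteins
#'
#' The full modulation stage for one bait: optional normalization, replicate
#' averaging per (line, condition), log2 fold-change of modulated over
#' control in the overexpression (`line_up`) and knockdown (`line_down`)
#' lines, a two-way ANOVA genotype-effect p-value per protein, and the
#' concordance class.
#'
#' @param x An [intensity_matrix()].
#' @param bait Bait label.
#' @param proteins Protein IDs to quantify (default: all rows).
#' @param line_up,line_down The overexpression and knockdown cell lines.
#' @param normalize Normalization method, see [normalize_samples()].
#' @param pseudo Pseudocount for fold-changes and the log transform.
#' @param policy,floor Missing-value policy, see [aggregate_replicates()].
#' @param fc_min,alpha Concordance thresholds, see [classify_concordance()].
#' @return Data frame with columns `protein_id`, `log2fc_up`, `log2fc_down`,
#'   `p_value`, `p_defined`, `concordance`.
#' @export
quantify_modulation <- function(x, bait, proteins = NULL,
                                line_up, line_down,
                                normalize = "none", pseudo = 1,
                                policy = "impute-floor", floor = 1,
                                fc_min = 0, alpha = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  x <- normalize_samples(x, normalize)
  if (is.null(proteins)) proteins <- rownames(x$values)
  missing_ids <- setdiff(proteins, rownames(x$values))
  if (length(missing_ids))
    stop(sprintf("unknown protein(s): %s",
                 paste(utils::head(missing_ids, 5L), collapse = ", ")),
         call. = FALSE)

  mean_of <- function(line, condition)
    aggregate_replicates(x, bait, line, condition, policy, floor)[proteins]
  fc_up <- compute_log2fc(mean_of(line_up, "modulated"),
                          mean_of(line_up, "control"), pseudo)
  fc_down <- compute_log2fc(mean_of(line_down, "modulated"),
                            mean_of(line_down, "control"), pseudo)

  fr <- modulation_frame(x, bait, pseudo, policy, floor)
  pvals <- vapply(proteins, function(p)
    as.numeric(anova_genotype_p(fr$log2_vals[p, ], fr$meta$cell_line,
                                fr$meta$condition)), 0)

  data.frame(protein_id = proteins,
             log2fc_up = unname(fc_up),
             log2fc_down = unname(fc_down),
             p_value = unname(pvals),
             p_defined = !is.na(pvals),
             concordance = classify_concordance(fc_up, fc_down, pvals,
                                                fc_min = fc_min, alpha = alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}
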