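# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the code paths they check.

# Upper-tail hypergeometric probability by direct combinatorial enumeration.
oracle_hyper_tail <- function(k, K, n, N) {
  j <- max(0L, k):min(n, K)
  if (k <= 0) return(1)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Two-sided Fisher p by enumerating all tables with the observed margins
# and summing point probabilities <= the observed one (minimum-likelihood).
oracle_fisher_two_sided <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); N <- sum(m)
  support <- max(0, c1 - (N - r1)):min(r1, c1)
  point <- function(a)
    choose(r1, a) * choose(N - r1, c1 - a) / choose(N, c1)
  probs <- vapply(support, point, 0)
  p_obs <- probs[support == m[1, 1]]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Literal step-up BH: adj_i = min over j with p_(j) >= p_(i) of
# min(1, p_(j) * m / rank(j)).  O(m^2), no cummin shortcut.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  rank_of <- integer(m)
  rank_of[ord] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    js <- which(p >= p[i])
    min(1, min(p[js] * m / rank_of[js]))
  }, 0)
}

# Per-element membership enumeration of Venn regions (counts only).
oracle_venn_counts <- function(sets) {
  labels <- names(sets)
  universe <- unique(unlist(sets))
  keys <- vapply(universe, function(el)
    paste(labels[vapply(sets, function(s) el %in% s, TRUE)], collapse = "&"),
    "")
  table(keys)
}

# Build k sets with exactly the requested exclusive-region sizes.
# `region_sizes` is named by "&"-joined label subsets, e.g.
# c(A = 5, `A&B` = 2, B = 3).
sets_from_regions <- function(labels, region_sizes) {
  ids <- sprintf("P%05d", seq_len(sum(region_sizes)))
  start <- cumsum(c(1, utils::head(region_sizes, -1)))
  sets <- stats::setNames(vector("list", length(labels)), labels)
  for (l in labels) sets[[l]] <- character(0)
  for (i in seq_along(region_sizes)) {
    members <- ids[seq(start[i], length.out = region_sizes[i])]
    for (l in strsplit(names(region_sizes)[i], "&", fixed = TRUE)[[1]])
      sets[[l]] <- c(sets[[l]], members)
  }
  sets
}

# Two sets with given sizes and intersection size.
two_sets <- function(n_a, n_b, n_shared, labels = c("A", "B")) {
  sets_from_regions(labels, stats::setNames(
    c(n_a - n_shared, n_shared, n_b - n_shared),
    c(labels[1], paste(labels, collapse = "&"), labels[2])))
}

# Small noise-free simulation used by several filtering tests.
noise_free_config <- function(seed = 11L, n_contaminants = 0L,
                              contaminant_detection_prob = 1,
                              background = 0) {
  canonical <- complex_model("cA", sprintf("A%02d", 1:8), "BMI1",
                             coupled_to_hub = TRUE)
  core <- complex_model("cB", sprintf("B%02d", 1:5), c("BMI1", "RYBP"))
  simulation_config(
    n_proteins = 13L + n_contaminants,
    complexes = list(canonical, core),
    n_contaminants = n_contaminants,
    contaminant_detection_prob = contaminant_detection_prob,
    log_noise_sd = 0, protein_baseline_sd = 0,
    dropout_threshold = 0,
    background_detection_prob = background,
    baits = c("BMI1", "RYBP", "mock"),
    seed = seed)
}

# Hand-built 2-sample x few-protein matrix for unit tests.
tiny_matrix <- function(values, baits, lines = NULL, conditions = NULL,
                        is_mock = NULL) {
  m <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- sprintf("s%d", seq_len(m))
  meta <- data.frame(
    sample_id = colnames(values),
    cell_line = lines %||% rep("L1", m),
    bait = baits,
    condition = conditions %||% rep("control", m),
    culture = rep(1L, m),
    tech_rep = seq_len(m),
    is_mock = is_mock %||% as.integer(baits == "mock"),
    stringsAsFactors = FALSE)
  intensity_matrix(values, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
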