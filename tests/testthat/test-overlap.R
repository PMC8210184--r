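test_that("set-level overlap test reproduces enumeration and the worked example", {
  u <- sprintf("g%02d", 1:10)
  res <- hypergeom_overlap(u[1:5], u[1:5], u)
  expect_identical(c(res$k, res$K, res$n, res$N), c(5L, 5L, 5L, 10L))
  expect_equal(res$p_value, 1 / 252)            # C(10,5) = 252 equally likely draws
  expect_equal(hypergeom_overlap(u[1:3], u[4:10], u)$p_value, 1)
  expect_error(hypergeom_overlap("x", u[1:2], u), "universe")
  expect_error(hypergeom_overlap(character(0), character(0), character(0)),
               "empty universe")
  set.seed(31)
  for (i in 1:100) {
    N <- sample(10:60, 1)
    universe <- sprintf("u%03d", 1:N)
    query <- sample(universe, sample(1:N, 1))
    reference <- sample(universe, sample(1:N, 1))
    res <- hypergeom_overlap(query, reference, universe)
    expect_equal(res$p_value,
                 oracle_hyper_tail(res$k, res$K, res$n, res$N),
                 tolerance = 1e-9)
    # agrees with one-sided Fisher on the equivalent 2x2 table
    tab <- matrix(c(res$k, res$n - res$k,
                    res$K - res$k, res$N - res$K - res$n + res$k), 2)
    expect_equal(res$p_value,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("two-sided Fisher worked example, degenerate margins, transposition", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2)), 34 / 70)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 7), 2)), 1)  # zero margin
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  set.seed(17)
  for (i in 1:100) {
    m <- matrix(rpois(4, 5), 2)
    if (sum(m) == 0) next
    expect_equal(fisher_exact_2x2(m), fisher_exact_2x2(t(m)))
    expect_equal(fisher_exact_2x2(m), stats::fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the brute-force step-up on 1000 random vectors", {
  expect_equal(benjamini_hochberg(0.03), 0.03)    # m = 1 unchanged
  expect_equal(benjamini_hochberg(rep(0.2, 7)), rep(0.2, 7))
  set.seed(23)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- round(runif(m), sample(c(1, 2, 6), 1))   # force ties sometimes
    adj <- benjamini_hochberg(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))   # order-preserving
  }
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "0, 1")
})

test_that("DEU overlap analysis dedups genes and mirrors the planted construction", {
  # all raw p = 1 -> no DEU genes
  null_tab <- data.frame(gene_id = rep(sprintf("g%02d", 1:10), each = 3),
                         exon_id = paste0("e", 1:30), p_value = 1)
  ref <- gene_set_collection(list(AS = sprintf("g%02d", 1:5)))
  out0 <- deu_overlap_analysis(null_tab, ref)
  expect_length(out0$deu_genes, 0)
  expect_equal(out0$results$p_value, 1)

  # planted construction mirroring the published counts: 362 DEU genes of
  # which 60 sit inside a 700-gene reference, universe of 12000 genes
  genes <- sprintf("G%05d", 1:12000)
  deu_genes <- c(genes[1:60], genes[701:1002])          # 60 in-ref + 302 out
  reference <- genes[1:700]
  tab <- data.frame(
    gene_id = c(rep(deu_genes, each = 2), genes[3001:8000]),
    exon_id = paste0("e", seq_len(2 * 362 + 5000)),
    p_value = c(rep(1e-8, 2 * 362), runif(5000, 0.5, 1)),
    stringsAsFactors = FALSE)
  out <- deu_overlap_analysis(tab, gene_set_collection(list(AS_GBM = reference)),
                              alpha = 0.05, universe = genes)
  expect_length(out$deu_genes, 362)                     # each gene counted once
  expect_identical(out$results$k, 60L)
  expect_identical(out$results$K, 700L)
  expect_identical(out$results$N, 12000L)
  expect_equal(out$results$p_value,
               apmsdecon:::hyper_upper_tail(60, 700, 362, 12000))
  # verified against enumeration at reduced scale (36 DEU genes, 6 of them
  # inside a 7-gene reference, universe of 120)
  su <- sprintf("s%03d", 1:120)
  small <- hypergeom_overlap(su[1:36], su[c(1:6, 40)], su)
  expect_equal(small$p_value,
               oracle_hyper_tail(small$k, small$K, small$n, small$N),
               tolerance = 1e-12)
  # a gene with two significant exons appears once
  expect_false(anyDuplicated(out$deu_genes) > 0)
  expect_error(deu_overlap_analysis(null_tab[0, ], ref), "empty")
})

test_that("over-representation across collections composes overlap + BH", {
  universe <- sprintf("g%03d", 1:200)
  query <- universe[1:20]
  colls <- gene_set_collection(list(self = query,
                                    disjoint = universe[101:150],
                                    partial = universe[11:60]))
  res <- ora_collections(query, colls, universe)
  expect_identical(res$set, c("self", "disjoint", "partial"))
  expect_equal(res$p_value[res$set == "disjoint"], 1)
  expect_lt(res$p_value[res$set == "self"],
            min(res$p_value[res$set != "self"]))
  manual_q <- benjamini_hochberg(vapply(colls$sets, function(s)
    hypergeom_overlap(query, s, universe)$p_value, 0))
  expect_equal(res$q_value, unname(manual_q))
})

test_that("gene sets load from GMT and plain one-ID-per-line files", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"), gmt)
  colls <- read_gene_sets(gmt)
  expect_setequal(names(colls$sets), c("setA", "setB"))
  expect_setequal(colls$sets$setA, c("g1", "g2", "g3"))
  txt <- file.path(dir, "prognostic.txt")
  writeLines(c("g1", "g9"), txt)
  single <- read_gene_sets(txt)
  expect_identical(names(single$sets), "prognostic")
  expect_setequal(single$sets$prognostic, c("g1", "g9"))
})
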