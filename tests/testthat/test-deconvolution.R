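test_that("venn regions are a disjoint partition matching brute-force enumeration", {
  set.seed(7)
  ids <- sprintf("G%03d", 1:25)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    sets <- stats::setNames(
      lapply(seq_len(k), function(j) sample(ids, sample(0:20, 1))),
      LETTERS[seq_len(k)])
    if (all(lengths(sets) == 0)) next
    v <- venn_report(sets)
    members <- unlist(v$regions, use.names = FALSE)
    expect_false(anyDuplicated(members) > 0)               # disjoint
    expect_setequal(members, unique(unlist(sets)))         # coverage
    expect_identical(sum(v$counts), length(unique(unlist(sets))))
    oracle <- oracle_venn_counts(sets)
    nonzero <- v$counts[v$counts > 0]
    expect_identical(sort(names(nonzero)), sort(names(oracle)))
    expect_identical(unname(nonzero[names(oracle)]),
                     unname(as.integer(oracle)))
  }
})

test_that("cross-line intersection reports only/shared/only regions", {
  sets <- two_sets(747, 409, 226, labels = c("LN428", "U87MG"))
  a <- interactor_set(sets$LN428, "BMI1", "LN428")
  b <- interactor_set(sets$U87MG, "BMI1", "U87MG")
  v <- intersect_lines(a, b)
  expect_identical(length(region_members(v, "LN428")), 521L)
  expect_identical(length(region_members(v, "U87MG")), 183L)
  expect_identical(length(region_members(v, c("LN428", "U87MG"))), 226L)
  # A = B collapses to the shared region
  same <- intersect_lines(interactor_set(letters, "BMI1", "l1"),
                          interactor_set(letters, "BMI1", "l2"))
  expect_identical(unname(same$counts[c("l1", "l2")]), c(0L, 0L))
  expect_setequal(region_members(same, c("l1", "l2")), letters)
  # disjoint sets share nothing
  disj <- intersect_lines(interactor_set(letters[1:5], "BMI1", "l1"),
                          interactor_set(letters[6:9], "BMI1", "l2"))
  expect_identical(unname(disj$counts[["l1&l2"]]), 0L)
  expect_error(intersect_lines(a, interactor_set("x", "RYBP", "U87MG")),
               "bait mismatch")
})

test_that("bait comparison isolates canonical candidates from the shared core", {
  sets <- two_sets(226, 109, 8, labels = c("BMI1", "RYBP"))
  v <- compare_baits(sets$BMI1, sets$RYBP, labels = c("BMI1", "RYBP"))
  expect_identical(length(region_members(v, "BMI1")), 218L)
  expect_identical(length(region_members(v, "RYBP")), 101L)
  expect_identical(length(region_members(v, c("BMI1", "RYBP"))), 8L)
  # empty second set -> everything is bait1-only
  v0 <- compare_baits(letters[1:5], character(0))
  expect_identical(length(region_members(v0, "bait1")), 5L)
})

test_that("three-way chromatome partition reproduces set arithmetic and is permutation-consistent", {
  regions <- c(BMI1 = 51, RYBP = 68, mark = 2,
               `BMI1&RYBP` = 6, `BMI1&mark` = 13, `RYBP&mark` = 1,
               `BMI1&RYBP&mark` = 1)
  sets <- sets_from_regions(c("BMI1", "RYBP", "mark"), regions)
  expect_length(sets$BMI1, 71)
  expect_length(sets$RYBP, 76)
  expect_length(sets$mark, 17)
  cp <- chromatome_partition(sets$BMI1, sets$RYBP, sets$mark,
                             labels = c("BMI1", "RYBP", "mark"))
  expect_identical(unname(cp$venn$counts["BMI1"]), 51L)
  catalytic <- cp$assignment$protein_id[cp$assignment$category ==
                                          "chromatome_catalytic"]
  independent <- cp$assignment$protein_id[cp$assignment$category ==
                                            "chromatome_independent"]
  expect_length(catalytic, 14)                       # BMI1 & mark
  expect_length(independent, 51)                     # BMI1 only
  expect_identical(length(setdiff(sets$BMI1, sets$mark)), 57L)
  expect_identical(length(setdiff(sets$BMI1, sets$RYBP)), 64L)
  # every protein categorized exactly once
  expect_identical(sort(cp$assignment$protein_id),
                   sort(unique(unlist(sets))))
  # permuting the input labels permutes the regions accordingly
  cp2 <- chromatome_partition(sets$RYBP, sets$BMI1, sets$mark,
                              labels = c("RYBP", "BMI1", "mark"))
  expect_identical(unname(cp2$venn$counts["RYBP"]),
                   unname(cp$venn$counts["RYBP"]))
  expect_identical(sort(region_members(cp2$venn, c("BMI1", "mark"))),
                   sort(region_members(cp$venn, c("BMI1", "mark"))))
  # three identical sets populate only the triple region
  same <- chromatome_partition(letters, letters, letters,
                               labels = c("x", "y", "z"))
  expect_identical(unname(same$venn$counts[["x&y&z"]]), 26L)
  expect_identical(sum(same$venn$counts), 26L)
})

test_that("proteome/chromatome integration is plain intersection", {
  listed <- c("1433E", "AP2A1", "AP2M1", "CAPR1", "EIFCL", "ELAV1", "PRP6",
              "RL10", "RL29", "SPTB2", "TBB5", "TCPZ", "U2AF1", "FUBP3",
              "FXR1", "RAB7A", "RRBP1")
  proteome <- c(listed, sprintf("EXTRA%02d", 1:40))
  out <- integrate_proteome_chromatome(proteome, listed)
  expect_identical(out$n, 17L)
  expect_setequal(out$shared, listed)
  expect_identical(integrate_proteome_chromatome(letters[1:3],
                                                 letters[10:12])$n, 0L)
  expect_true(all(out$shared %in% proteome) && all(out$shared %in% listed))
})

test_that("recovery metrics score assignments against ground truth", {
  truth <- data.frame(
    protein_id = sprintf("P%03d", 1:40),
    true_complex = rep(c("c1", "c2"), each = 20),
    is_contaminant = FALSE, is_modulation_coupled = FALSE,
    stringsAsFactors = FALSE)
  map <- c(c1 = "canonical_only", c2 = "shared_core")
  perfect <- data.frame(
    protein_id = truth$protein_id,
    category = rep(c("canonical_only", "shared_core"), each = 20),
    stringsAsFactors = FALSE)
  m <- recovery_metrics(perfect, truth, map)
  expect_true(all(m$precision == 1) && all(m$recall == 1))
  # random assignment over 2 equal categories -> precision ~ 0.5 at n = 1000
  truth2 <- data.frame(protein_id = sprintf("Q%04d", 1:1000),
                       true_complex = rep(c("c1", "c2"), each = 500),
                       is_contaminant = FALSE, is_modulation_coupled = FALSE,
                       stringsAsFactors = FALSE)
  set.seed(5)
  rand <- data.frame(protein_id = truth2$protein_id,
                     category = sample(c("canonical_only", "shared_core"),
                                       1000, replace = TRUE),
                     stringsAsFactors = FALSE)
  m2 <- recovery_metrics(rand, truth2, map)
  expect_true(all(abs(m2$precision - 0.5) < 0.06))
  # an empty assigned category yields flagged NA precision, not zero
  part <- data.frame(protein_id = truth$protein_id,
                     category = "canonical_only", stringsAsFactors = FALSE)
  m3 <- recovery_metrics(part, truth, map)
  expect_true(is.na(m3$precision[m3$category == "shared_core"]))
})
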