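# DE flagging, RSD filter, Fisher test, enrichment ratios, overlaps, TPM,
# bootstrap median CI.

test_that("DE flags use strict cutoffs on both log2FC and FDR", {
  expr <- expression_table(
    gene = c("up", "edge_lfc", "fdr_fail", "down"),
    log2fc = c(2.3, 1.0, -3, -2),
    fdr = c(1e-4, 1e-9, 0.02, 1e-3),
    condition = "heat")
  fl <- flag_de(expr)
  expect_equal(setNames(fl$direction, fl$gene),
               c(up = "up", edge_lfc = "none", fdr_fail = "none",
                 down = "down"))
  expect_equal(fl$is_de, fl$direction != "none")
})

test_that("relaxing either DE cutoff never removes a flag", {
  set.seed(4)
  expr <- expression_table(sprintf("g%03d", 1:200),
                           log2fc = rnorm(200, 0, 2),
                           fdr = runif(200), condition = "x")
  strict <- flag_de(expr, lfc_cut = 1, fdr_cut = 0.01)
  for (relax in list(c(0.5, 0.01), c(1, 0.05), c(0.2, 0.2))) {
    loose <- flag_de(expr, lfc_cut = relax[1], fdr_cut = relax[2])
    expect_true(all(loose$is_de[strict$is_de]))
  }
})

test_that("RSD filter keeps quiet genes and drops noisy or silent ones", {
  counts <- counts_matrix(
    matrix(c(10, 10, 10,
             0.1, 5, 20,
             0, 0, 0), nrow = 3, byrow = TRUE,
           dimnames = list(c("steady", "noisy", "silent"),
                           c("std_1", "std_2", "std_3"))),
    length_bp = c(1000, 1000, 1000))
  # (0.1, 5, 20): sd/mean = 1.218... > 1
  expect_gt(sd(c(0.1, 5, 20)) / mean(c(0.1, 5, 20)), 1)
  expect_equal(filter_rsd(counts, threshold = 1), "steady")
  one_rep <- counts_matrix(
    matrix(1:3, 3, dimnames = list(c("a", "b", "c"), "std_1")),
    length_bp = c(1, 1, 1))
  expect_error(filter_rsd(one_rep), "replicate", class = "agestrat_error")
})

test_that("two-sided Fisher p-values match degenerate and extreme enumerations", {
  # degenerate margin: only one table possible
  expect_equal(fisher_two_sided(0, 10, 0, 90), 1)
  # perfectly separated 10/10: the two extreme tables out of C(20,10)
  expect_equal(fisher_two_sided(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  # moderate table against the exhaustive hypergeometric oracle
  expect_equal(fisher_two_sided(4, 6, 6, 84),
               fisher_enumeration(4, 6, 6, 84), tolerance = 1e-12)
  expect_error(fisher_two_sided(-1, 2, 3, 4), class = "agestrat_error")
})

test_that("enrichment ratios follow the normalization formula", {
  # one group of 50 genes with 10 DE in a 1000-gene genome with 40 DE:
  # (10/50)/(40/1000) = 5
  ages <- data.frame(gene = sprintf("g%04d", 1:1000),
                     age_group = rep(c("young", "old"), c(50, 950)),
                     stringsAsFactors = FALSE)
  de_genes <- c(sprintf("g%04d", 1:10), sprintf("g%04d", 101:130))
  fl <- structure(
    data.frame(gene = ages$gene, is_de = ages$gene %in% de_genes,
               direction = ifelse(ages$gene %in% de_genes, "up", "none"),
               stringsAsFactors = FALSE),
    condition = "stress", class = c("de_flags", "data.frame"))
  et <- enrichment_table(ages, fl)
  expect_equal(et$ratio[et$age_group == "young"], 5.0)
  expect_equal(et$n_group, c(50L, 950L))
  expect_equal(et$de_group, c(10L, 30L))
  # group-size-weighted ratios average to exactly 1
  expect_equal(sum(et$n_group / sum(et$n_group) * et$ratio), 1)
})

test_that("the weighted-ratio identity holds on arbitrary inputs", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(50:400, 1)
    ages <- data.frame(gene = sprintf("g%04d", 1:n),
                       age_group = sample(LETTERS[1:4], n, TRUE),
                       stringsAsFactors = FALSE)
    de <- runif(n) < 0.2
    fl <- structure(
      data.frame(gene = ages$gene, is_de = de,
                 direction = ifelse(de, sample(c("up", "down"), n, TRUE),
                                    "none"),
                 stringsAsFactors = FALSE),
      condition = "c1", class = c("de_flags", "data.frame"))
    et <- enrichment_table(ages, fl)
    if (any(de)) {
      expect_equal(sum(et$n_group / sum(et$n_group) * et$ratio), 1)
    }
  }
})

test_that("a condition without DE genes yields rows with absent ratios", {
  ages <- data.frame(gene = c("a", "b"), age_group = c("I", "V"))
  fl <- structure(
    data.frame(gene = c("a", "b"), is_de = c(FALSE, FALSE),
               direction = c("none", "none"), stringsAsFactors = FALSE),
    condition = "calm", class = c("de_flags", "data.frame"))
  et <- enrichment_table(ages, fl)
  expect_equal(nrow(et), 2L)
  expect_true(all(is.na(et$ratio)))
})

test_that("up/down scopes count only the requested direction", {
  ages <- data.frame(gene = c("a", "b", "c", "d"),
                     age_group = c("I", "I", "V", "V"))
  fl <- structure(
    data.frame(gene = c("a", "b", "c", "d"),
               is_de = c(TRUE, TRUE, TRUE, FALSE),
               direction = c("up", "down", "up", "none"),
               stringsAsFactors = FALSE),
    condition = "x", class = c("de_flags", "data.frame"))
  up <- enrichment_table(ages, fl, scope = "up")
  expect_equal(sum(up$de_group), 2L)
  down <- enrichment_table(ages, fl, scope = "down")
  expect_equal(sum(down$de_group), 1L)
})

test_that("overlap counts enumerate every condition combination exactly", {
  mk <- function(up, cond) structure(
    data.frame(gene = up, is_de = TRUE, direction = "up",
               stringsAsFactors = FALSE),
    condition = cond, class = c("de_flags", "data.frame"))
  flags <- list(A = mk(c("g1", "g2"), "A"), B = mk("g1", "B"),
                C = mk(c("g1", "g3"), "C"))
  ov <- overlap_counts(flags, direction = "up")
  expect_equal(ov$count[ov$combination == "A&B&C"], 1L)  # g1
  expect_equal(ov$count[ov$combination == "A"], 1L)      # g2
  expect_equal(ov$count[ov$combination == "C"], 1L)      # g3
  expect_equal(sum(ov$count), 3L)                        # union size

  disjoint <- list(A = mk("g1", "A"), B = mk("g2", "B"))
  ov2 <- overlap_counts(disjoint, direction = "up")
  expect_equal(ov2$count[ov2$n_conditions == 2], 0L)
})

test_that("overlap counts match brute-force membership enumeration", {
  set.seed(12)
  genes <- sprintf("g%02d", 1:40)
  mk <- function(cond) {
    up <- sample(genes, sample(5:20, 1))
    structure(data.frame(gene = up, is_de = TRUE, direction = "up",
                         stringsAsFactors = FALSE),
              condition = cond, class = c("de_flags", "data.frame"))
  }
  flags <- list(A = mk("A"), B = mk("B"), C = mk("C"))
  ov <- overlap_counts(flags, direction = "up")
  sets <- lapply(flags, function(f) f$gene)
  union <- unique(unlist(sets))
  brute <- vapply(union, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  for (i in seq_len(nrow(ov))) {
    expect_equal(ov$count[i], sum(brute == ov$combination[i]),
                 info = ov$combination[i])
  }
  expect_equal(sum(ov$count), length(union))
})

test_that("TPM normalizes by length and depth with columns summing to 1e6", {
  cm <- counts_matrix(
    matrix(c(100, 200), 2, 1, dimnames = list(c("g1", "g2"), "std_1")),
    length_bp = c(1000, 2000))
  expect_equal(unname(tpm(cm)[, 1]), c(5e5, 5e5))

  # equal count/length rates force equal TPMs of 1e6/3
  cm3 <- counts_matrix(
    matrix(c(50, 100, 200), 3, 1,
           dimnames = list(c("a", "b", "c"), "std_1")),
    length_bp = c(500, 1000, 2000))
  expect_equal(unname(tpm(cm3)[, 1]), rep(1e6 / 3, 3))
  # rates (0.2, 0.2, 0.1) split as 40/40/20 percent
  cm4 <- counts_matrix(
    matrix(c(100, 200, 200), 3, 1,
           dimnames = list(c("a", "b", "c"), "std_1")),
    length_bp = c(500, 1000, 2000))
  expect_equal(unname(tpm(cm4)[, 1]), c(4e5, 4e5, 2e5))

  set.seed(3)
  cmr <- counts_matrix(
    matrix(rpois(40, 50), 10, 4,
           dimnames = list(sprintf("g%02d", 1:10),
                           c("a_1", "a_2", "b_1", "b_2"))),
    length_bp = sample(500:3000, 10))
  expect_equal(unname(colSums(tpm(cmr))), rep(1e6, 4), tolerance = 1e-6)

  zero <- counts_matrix(
    matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "std_1")),
    length_bp = c(100, 100))
  expect_error(tpm(zero), "zero total", class = "agestrat_error")
})

test_that("median CI collapses for constant or single inputs and is seeded", {
  expect_equal(median_ci(rep(3.5, 10)), c(median = 3.5, lo = 3.5, hi = 3.5))
  expect_equal(median_ci(42), c(median = 42, lo = 42, hi = 42))
  x <- rnorm(30)
  a <- median_ci(x, reps = 500, seed = 9)
  b <- median_ci(x, reps = 500, seed = 9)
  expect_identical(a, b)
  expect_true(a[["lo"]] <= a[["median"]] && a[["median"]] <= a[["hi"]])
  expect_error(median_ci(numeric(0)), class = "agestrat_error")
})
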