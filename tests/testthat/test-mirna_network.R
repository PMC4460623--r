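test_that("hypergeometric tail matches closed forms and enumeration", {
  # N = 10, K = 4, n = 5, k = 4 -> 6/252
  expect_equal(hypergeom_p(4, 4, 5, 10), 6 / 252, tolerance = 1e-12)
  # C(5,3)C(15,0)/C(20,3) = 10/1140
  expect_equal(hypergeom_p(3, 5, 3, 20), 10 / 1140, tolerance = 1e-12)
  expect_equal(hypergeom_p(0, 4, 5, 10), 1)

  # exhaustive combinatorial oracle for N <= 25
  set.seed(91)
  for (i in 1:20) {
    N <- sample(5:25, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    # enumerate over all C(N, n) draws by summing the pmf directly
    p_enum <- sum(vapply(k:min(K, n), function(j) {
      choose(K, j) * choose(N - K, n - j) / choose(N, n)
    }, numeric(1L)))
    expect_equal(hypergeom_p(k, K, n, N), p_enum, tolerance = 1e-10)
  }
})

mk_target_table <- function() {
  data.frame(
    regulator_id = rep(c("mir1", "mir2"), c(5, 3)),
    target_id = c(paste0("G", 1:5), paste0("G", 6:8)),
    kind = "mirna_to_mrna", source = "db", stringsAsFactors = FALSE)
}

test_that("miRNA->mRNA edges pass the worked hypergeometric example", {
  # universe of 10 genes, 4 DE, mir1 has 5 targets of which 4 DE
  tab <- data.frame(regulator_id = c(rep("mir1", 5), rep("mir2", 5)),
                    target_id = c(paste0("G", 1:5), paste0("G", 6:10)))
  de_genes <- paste0("G", c(1:4))
  out <- mirna_to_mrna_edges("mir1", tab, de_genes, paste0("G", 1:10))
  expect_equal(out$tests$p, 6 / 252, tolerance = 1e-12)
  expect_identical(nrow(out$edges), 4L)
  expect_setequal(out$edges$to, de_genes)

  # zero overlap -> p = 1, no edges
  none <- mirna_to_mrna_edges("mir2", tab, de_genes, paste0("G", 1:10))
  expect_equal(none$tests$p, 1)
  expect_identical(nrow(none$edges), 0L)

  # p_threshold = 1 admits every miRNA with >= 1 DE target
  all_in <- mirna_to_mrna_edges(c("mir1"), tab, de_genes,
                                paste0("G", 1:10), p_threshold = 1.0)
  expect_identical(nrow(all_in$edges), 4L)

  # miRNA without annotated targets is skipped with a log message
  expect_message(
    skip <- mirna_to_mrna_edges("mirX", tab, de_genes, paste0("G", 1:10)),
    "no annotated")
  expect_identical(nrow(skip$edges), 0L)
})

test_that("edge sets grow monotonically with the p threshold", {
  b <- test_bundle()
  de_genes <- b$truth$de_genes
  de_mirnas <- b$truth$de_mirnas
  tab <- b$tables$mirna_targets
  measured <- rownames(b$cohort$expr)
  lo <- suppressMessages(mirna_to_mrna_edges(de_mirnas, tab, de_genes,
                                             measured, 0.01))
  hi <- suppressMessages(mirna_to_mrna_edges(de_mirnas, tab, de_genes,
                                             measured, 0.2))
  expect_true(all(paste(lo$edges$from, lo$edges$to) %in%
                    paste(hi$edges$from, hi$edges$to)))
})

test_that("TF->miRNA edges admit only differential TFs", {
  tab <- data.frame(regulator_id = rep(c("TF1", "TF2"), each = 3),
                    target_id = paste0("mir", c(1, 2, 3, 1, 4, 5)))
  de_mirnas <- paste0("mir", 1:3)
  # universe 5 miRNAs, K = 3 DE, TF1 regulates 3, all DE ->
  # p = 1/C(5,3) = 0.1, above the default 0.05 cutoff
  out <- tf_to_mirna_edges(de_mirnas, tab, de_genes = "TF1")
  expect_equal(out$tests$p, hypergeom_p(3, 3, 3, 5), tolerance = 1e-12)
  expect_identical(nrow(out$edges), 0L)
  relaxed <- tf_to_mirna_edges(de_mirnas, tab, de_genes = "TF1",
                               p_threshold = 0.2)
  expect_identical(unique(relaxed$edges$from), "TF1")
  expect_setequal(relaxed$edges$to, de_mirnas)
  none <- tf_to_mirna_edges(de_mirnas, tab, de_genes = "TF9")
  expect_identical(nrow(none$edges), 0L)
})

test_that("merged network deduplicates and reports counts", {
  a <- data.frame(from = c("mir1", "mir1", "mir2"),
                  to = c("G1", "G2", "G1"),
                  provenance = "mirna_target", p = 0.01)
  b <- data.frame(from = c("G1", "G3"), to = c("mir1", "mir2"),
                  provenance = "tf_mirna", p = 0.01)
  net <- merge_mirna_networks(a, b)
  expect_identical(nrow(net$edges), 5L)
  expect_identical(net$report$n_total_mirnas, 2L)
  expect_identical(net$report$n_total_genes, 3L)
  expect_identical(net$report$n_genes_in_both, 1L)    # G1
  expect_identical(net$report$n_mirnas_in_both, 2L)
  expect_setequal(net$nodes$type[net$nodes$id %in% c("mir1", "mir2")],
                  "mirna")
  # a duplicated (from, to) pair collapses keeping both provenances
  dup <- merge_mirna_networks(
    data.frame(from = "mirX", to = "G9", provenance = "mirna_target",
               p = 0.01),
    data.frame(from = "mirX", to = "G9", provenance = "tf_mirna",
               p = 0.01))
  expect_identical(nrow(dup$edges), 1L)
  expect_identical(dup$edges$provenance, "mirna_target+tf_mirna")
})

test_that("synthetic truth tables yield edges only among differential features", {
  b <- test_bundle()
  mm <- suppressMessages(
    mirna_to_mrna_edges(b$truth$de_mirnas, b$tables$mirna_targets,
                        b$truth$de_genes, rownames(b$cohort$expr)))
  tm <- tf_to_mirna_edges(b$truth$de_mirnas, b$tables$tf_mirna,
                          b$truth$de_genes)
  net <- merge_mirna_networks(mm$edges, tm$edges)
  expect_gt(nrow(net$edges), 0L)
  ok_from <- net$edges$from %in% c(b$truth$de_mirnas, b$truth$de_genes)
  ok_to <- net$edges$to %in% c(b$truth$de_mirnas, b$truth$de_genes)
  expect_true(all(ok_from & ok_to))
})
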