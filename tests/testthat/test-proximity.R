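mk_sizes <- function() c(chr1 = 1000000L, chr2 = 1000000L)

test_that("find_proximal applies window, genotype filter and distances", {
  sizes <- c(chr1 = 2000000L)
  feats <- data.frame(chrom = "chr1",
                      start = c(740000L, 760001L),
                      end = c(740080L, 760081L),
                      id = c("mirA", "mirB"))
  vars <- data.frame(chrom = "chr1", pos = 500000L, ref = "G", alt = "T",
                     sample_id = "S1")
  cases <- find_proximal(feats, vars, 250000L, NULL, sizes)
  expect_identical(cases$feature_id, "mirA")     # 240,000 <= 250,000
  expect_identical(cases$distance, 240000L)      # mirB at 260,001 excluded

  # C-reference filter for the CpG analysis
  cpg <- data.frame(chrom = "chr1", start = 500100L, end = 500101L,
                    id = "cg1")
  v2 <- data.frame(chrom = "chr1", pos = c(500000L, 499900L),
                   ref = c("T", "C"), alt = c("A", "A"),
                   sample_id = "S1")
  cc <- find_proximal(cpg, v2, 3000L, list(ref = "C", alt = c("A", "G", "T")),
                      sizes)
  expect_identical(nrow(cc), 1L)
  expect_identical(cc$ref, "C")

  # variant inside the feature interval has distance 0
  inside <- find_proximal(feats,
                          data.frame(chrom = "chr1", pos = 740050L,
                                     ref = "A", alt = "C",
                                     sample_id = "S1"),
                          10L, NULL, sizes)
  expect_identical(inside$distance, 0L)
  expect_error(find_proximal(feats, data.frame(chrom = "chrX", pos = 1L,
                                               ref = "A", alt = "C",
                                               sample_id = "S1"),
                             10L, NULL, sizes), "absent")
})

test_that("find_proximal equals an all-pairs brute force", {
  set.seed(111)
  sizes <- mk_sizes()
  feats <- data.frame(chrom = sample(names(sizes), 80, replace = TRUE),
                      start = sample(1:999000, 80))
  feats$end <- feats$start + sample(1:200, 80)
  feats$id <- paste0("f", 1:80)
  vars <- data.frame(chrom = sample(names(sizes), 60, replace = TRUE),
                     pos = sample(0:999999, 60),
                     ref = sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                     alt = sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                     sample_id = "S1")
  vars <- vars[vars$ref != vars$alt, ]
  window <- 50000L
  out <- find_proximal(feats, vars, window, NULL, sizes)
  brute <- character()
  for (i in seq_len(nrow(vars))) {
    for (j in seq_len(nrow(feats))) {
      if (vars$chrom[i] != feats$chrom[j]) next
      d <- if (vars$pos[i] < feats$start[j]) feats$start[j] - vars$pos[i]
      else if (vars$pos[i] >= feats$end[j]) vars$pos[i] - (feats$end[j] - 1L)
      else 0L
      if (d <= window) {
        brute <- c(brute, paste0(vars$chrom[i], ":", vars$pos[i],
                                 vars$ref[i], ">", vars$alt[i], "|",
                                 feats$id[j], "|", d))
      }
    }
  }
  expect_setequal(paste0(out$variant_id, "|", out$feature_id, "|",
                         out$distance), brute)
})

test_that("permutation p hits the floor when all iterations are farther", {
  sizes <- c(chr1 = 10000000L)
  feats <- data.frame(chrom = "chr1", start = c(1000L, 2000L, 3000L),
                      end = c(1080L, 2080L, 3080L),
                      id = c("fa", "fb", "fc"))
  vars <- data.frame(chrom = "chr1", pos = c(1001L, 2001L, 3001L),
                     ref = "C", alt = "T", sample_id = "S1")
  cases <- find_proximal(feats, vars, 100L, NULL, sizes)
  res <- proximity_permutation_test(cases, feats, vars, sizes,
                                    n_perm = 1000L, seed = 1L)
  expect_equal(res$empirical_p, 1 / 1001, tolerance = 1e-12)
  expect_identical(res$b, 0L)
  expect_error(proximity_permutation_test(cases[0, ], feats, vars, sizes),
               "no observed")
})

test_that("planted-proximity fixture is significant at the fixed seed", {
  b <- test_bundle()
  pp <- b$truth$planted_proximal_pairs
  mir_ids <- unique(pp$feature_id[pp$kind == "mirna"])
  feats <- b$features$mirna[b$features$mirna$id %in% mir_ids, ]
  cases <- find_proximal(feats, b$cohort$variants, 250000L, NULL,
                         b$features$chrom_sizes)
  res <- proximity_permutation_test(cases, feats, b$cohort$variants,
                                    b$features$chrom_sizes,
                                    n_perm = 999L, seed = 5L)
  expect_lte(res$empirical_p, 0.01)
})

test_that("methylation-direction split conserves counts", {
  cases <- data.frame(variant_id = paste0("v", 1:6), chrom = "chr1",
                      pos = 1:6, ref = "C",
                      alt = c("A", "A", "G", "G", "T", "T"),
                      sample_id = "S1",
                      feature_id = paste0("cg", 1:6))
  cpg_gene <- data.frame(cpg_id = paste0("cg", 1:6),
                         gene_id = paste0("G", c(1, 1, 2, 2, 3, 4)))
  dm <- data.frame(feature = paste0("G", 1:4),
                   direction = c("up", "down", "up", "up"))
  out <- split_by_methylation_direction(cases, cpg_gene, dm)
  expect_identical(sum(out$counts), 6L)
  expect_equal(unname(colSums(out$counts)),
               as.vector(table(cases$alt)))
  # all-up case zeroes the down row
  dm_up <- transform(dm, direction = "up")
  up_only <- split_by_methylation_direction(cases, cpg_gene, dm_up)
  expect_true(all(up_only$counts["down_methylated", ] == 0L))
  # unmapped features are excluded and counted
  cpg_gene2 <- cpg_gene[1:5, ]
  expect_message(
    part <- split_by_methylation_direction(cases, cpg_gene2, dm),
    "unmapped")
  expect_identical(part$n_unmapped, 1L)
})

test_that("split recovers the planted 2:1 up:down methylation ratio", {
  b <- test_bundle()
  dm_truth <- data.frame(feature = names(b$truth$dm_direction),
                         direction = unname(b$truth$dm_direction))
  cpg_gene <- b$features$cpg_gene
  dm_cpg <- b$features$cpg[
    cpg_gene$gene_id[match(b$features$cpg$id, cpg_gene$cpg_id)] %in%
      dm_truth$feature, ]
  cases <- find_proximal(dm_cpg, b$cohort$variants, 3000L,
                         list(ref = "C", alt = c("A", "G", "T")),
                         b$features$chrom_sizes)
  out <- split_by_methylation_direction(cases, cpg_gene, dm_truth)
  n_up <- sum(out$counts["up_methylated", ])
  n_down <- sum(out$counts["down_methylated", ])
  # planted silenced genes are all up-methylated and the extra DM genes
  # are planted 2:1, so up cases must dominate
  expect_gt(n_up, n_down)
})

test_that("exclusivity flags variants with only dysregulated neighbors", {
  sizes <- c(chr1 = 1000000L)
  all_feats <- data.frame(chrom = "chr1",
                          start = c(1000L, 2000L, 50000L),
                          end = c(1080L, 2080L, 50080L),
                          id = c("dysA", "otherB", "dysC"))
  vars <- data.frame(chrom = "chr1", pos = c(1500L, 49000L),
                     ref = "C", alt = "T", sample_id = "S1")
  dys <- c("dysA", "dysC")
  cases <- find_proximal(all_feats[all_feats$id %in% dys, ], vars, 5000L,
                         NULL, sizes)
  out <- exclusivity_check(cases, all_feats, dys, 5000L)
  # variant at 1500 also near otherB -> not exclusive; 49000 only near dysC
  expect_identical(out$exclusive[out$variant_id == "chr1:1500C>T"], FALSE)
  expect_identical(out$exclusive[out$variant_id == "chr1:49000C>T"], TRUE)
  # empty non-dysregulated catalogue -> everything exclusive
  all_dys <- exclusivity_check(cases, all_feats[all_feats$id %in% dys, ],
                               dys, 5000L)
  expect_true(all(all_dys$exclusive))
})
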