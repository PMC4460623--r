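## Genomic proximity of somatic variants to dysregulated miRNA loci
## (window 250 kb, no genotype filter) and differentially methylated CpG
## sites (window 3 kb, C->A / C->G / C->T variants only), with
## significance from a chromosome-preserving position permutation.

# distance from a 0-based position to a 0-based half-open interval
interval_distance <- function(pos, start, end) {
  ifelse(pos < start, start - pos,
         ifelse(pos >= end, pos - (end - 1L), 0L))
}

#' Find variant-feature proximity cases
#'
#' For every variant passing the genotype filter, emits each
#' same-chromosome feature within `window_bp` (distance measured to the
#' feature's nearest base, 0 if inside). Results are sorted and
#' deduplicated.
#'
#' @param features Feature data frame (chrom, start, end, id).
#' @param variants Variant data frame (chrom, pos, ref, alt, sample_id).
#' @param window_bp Half-width of the window around each variant (250000
#'   for the miRNA analysis, 3000 for the CpG analysis).
#' @param genotype_filter `NULL` (no filter) or a list with `ref` and
#'   `alt` character vectors (e.g. `list(ref = "C", alt = c("A","G","T"))`).
#' @param chrom_sizes Named vector; all records must lie on known
#'   chromosomes.
#' @return `ProximityCase` data frame (variant_id, chrom, pos, ref, alt,
#'   sample_id, feature_id, distance).
#' @export
find_proximal <- function(features, variants, window_bp,
                          genotype_filter = NULL, chrom_sizes = NULL) {
  if (!is.null(chrom_sizes)) {
    missing <- setdiff(unique(c(features$chrom, variants$chrom)),
                       names(chrom_sizes))
    if (length(missing) > 0L) {
      stop("chromosome(s) absent from size table: ",
           paste(missing, collapse = ", "))
    }
  }
  v <- variants
  if (!is.null(genotype_filter)) {
    v <- v[v$ref %in% genotype_filter$ref &
             v$alt %in% genotype_filter$alt, , drop = FALSE]
  }
  rows <- list()
  for (chrom in unique(v$chrom)) {
    vi <- which(v$chrom == chrom)
    fi <- which(features$chrom == chrom)
    if (length(fi) == 0L) next
    for (i in vi) {
      d <- interval_distance(v$pos[i], features$start[fi], features$end[fi])
      hit <- which(d <= window_bp)
      if (length(hit) > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = paste0(chrom, ":", v$pos[i], v$ref[i], ">", v$alt[i]),
          chrom = chrom, pos = v$pos[i], ref = v$ref[i], alt = v$alt[i],
          sample_id = v$sample_id[i],
          feature_id = features$id[fi[hit]],
          distance = as.integer(d[hit]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), ref = character(),
                      alt = character(), sample_id = character(),
                      feature_id = character(), distance = integer()))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("variant_id", "feature_id")]), ,
             drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# per-feature distance to the nearest variant on its chromosome (Inf if
# that chromosome has no variant)
nearest_variant_distance <- function(features, var_chrom, var_pos) {
  vapply(seq_len(nrow(features)), function(i) {
    on_chrom <- var_pos[var_chrom == features$chrom[i]]
    if (length(on_chrom) == 0L) return(Inf)
    min(interval_distance(on_chrom, features$start[i], features$end[i]))
  }, numeric(1L))
}

#' Chromosome-preserving permutation test of proximity
#'
#' Each iteration redraws, per chromosome, the same number of variant
#' positions uniformly over that chromosome, and recomputes each
#' observed-case feature's distance to its nearest variant. All
#' `n_perm + 1` distance sets (observed + permuted) are pooled and jointly
#' ranked; each set's statistic is its rank-sum (a joint Wilcoxon-type
#' statistic, small = close), and
#' `empirical_p = (1 + b) / (1 + n_perm)` where `b` counts permuted sets
#' with statistic at most the observed one. This exceedance scheme is
#' exchangeable, hence uniformly distributed under the null. Per-iteration
#' two-sample Wilcoxon p-values (observed vs that iteration, alternative
#' "observed smaller") are also returned so alternative aggregations can
#' be computed.
#'
#' @param cases `ProximityCase` data frame from [find_proximal()].
#' @param features Full feature table (to locate the case features).
#' @param variants Observed variants (defines per-chromosome counts).
#' @param chrom_sizes Named chromosome-size vector.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return `PermutationResult` list: observed_statistic, perm_statistics,
#'   b, empirical_p, observed_distances, per_iteration_wilcoxon_p.
#' @export
proximity_permutation_test <- function(cases, features, variants,
                                       chrom_sizes, n_perm = 1000L,
                                       seed = 1L) {
  if (nrow(cases) == 0L) stop("no observed proximity cases")
  missing <- setdiff(unique(variants$chrom), names(chrom_sizes))
  if (length(missing) > 0L) {
    stop("chromosome(s) absent from size table: ",
         paste(missing, collapse = ", "))
  }
  case_feats <- features[match(unique(cases$feature_id), features$id), ,
                         drop = FALSE]
  observed <- nearest_variant_distance(case_feats, variants$chrom,
                                       variants$pos)
  chrom_counts <- table(variants$chrom)
  m <- nrow(case_feats)
  perm_dist <- matrix(NA_real_, nrow = n_perm, ncol = m)
  with_seed(seed, {
    for (b_i in seq_len(n_perm)) {
      pc <- rep(names(chrom_counts), chrom_counts)
      pp <- unlist(lapply(names(chrom_counts), function(ch) {
        sample.int(chrom_sizes[[ch]], chrom_counts[[ch]],
                   replace = TRUE) - 1L
      }))
      stopifnot(length(pp) == nrow(variants))
      perm_dist[b_i, ] <- nearest_variant_distance(case_feats, pc, pp)
    }
  })
  # joint ranking of all n_perm + 1 sets; statistic = per-set rank-sum
  pooled <- c(observed, as.vector(t(perm_dist)))
  ranks <- rank(pooled)
  obs_stat <- sum(ranks[seq_len(m)])
  perm_stats <- rowSums(matrix(ranks[-seq_len(m)], nrow = n_perm,
                               byrow = TRUE))
  b <- sum(perm_stats <= obs_stat)
  wilcox_p <- apply(perm_dist, 1L, function(pd) {
    suppressWarnings(stats::wilcox.test(observed, pd,
                                        alternative = "less")$p.value)
  })
  list(
    n_perm = n_perm,
    observed_statistic = obs_stat,
    perm_statistics = perm_stats,
    b = b,
    empirical_p = (1 + b) / (1 + n_perm),
    observed_distances = stats::setNames(observed, case_feats$id),
    per_iteration_wilcoxon_p = wilcox_p
  )
}

#' Tabulate CpG proximity cases by methylation direction and genotype
#'
#' @param cases `ProximityCase` data frame (CpG analysis).
#' @param cpg_gene Data frame (cpg_id, gene_id) from
#'   [filter_promoter_cpgs()] (columns `cpg_id`, `gene_id`).
#' @param dm_calls `DifferentialCall` data frame for methylation (feature
#'   = gene, direction up = hyper-methylated in tumor).
#' @return List: `counts` (direction x genotype contingency matrix),
#'   `fractions` (per-genotype direction fractions), `n_unmapped`.
#' @export
split_by_methylation_direction <- function(cases, cpg_gene, dm_calls) {
  gene <- cpg_gene$gene_id[match(cases$feature_id, cpg_gene$cpg_id)]
  dir <- dm_calls$direction[match(gene, dm_calls$feature)]
  unmapped <- is.na(dir)
  if (any(unmapped)) {
    message(sum(unmapped), " case(s) with unmapped feature excluded")
  }
  genotype <- paste0(cases$ref, ">", cases$alt)[!unmapped]
  dir <- dir[!unmapped]
  dir <- factor(ifelse(dir == "up", "up_methylated", "down_methylated"),
                levels = c("up_methylated", "down_methylated"))
  counts <- table(direction = dir, genotype = genotype)
  fractions <- prop.table(counts, margin = 2L)
  list(counts = counts, fractions = fractions,
       n_unmapped = sum(unmapped))
}

#' Variants proximal only to dysregulated features
#'
#' @param cases `ProximityCase` data frame (against dysregulated
#'   features).
#' @param all_features Full catalogue (dysregulated + non-dysregulated).
#' @param dysregulated_ids Ids of the dysregulated features.
#' @param window_bp Window used for the case detection.
#' @return Data frame (variant_id, exclusive, n_dysregulated,
#'   n_other) per case variant.
#' @export
exclusivity_check <- function(cases, all_features, dysregulated_ids,
                              window_bp) {
  other <- all_features[!all_features$id %in% dysregulated_ids, ,
                        drop = FALSE]
  vars <- cases[!duplicated(cases$variant_id), , drop = FALSE]
  rows <- lapply(seq_len(nrow(vars)), function(i) {
    fi <- which(other$chrom == vars$chrom[i])
    n_other <- if (length(fi) == 0L) 0L else {
      d <- interval_distance(vars$pos[i], other$start[fi], other$end[fi])
      sum(d <= window_bp)
    }
    data.frame(variant_id = vars$variant_id[i],
               exclusive = n_other == 0L,
               n_dysregulated = sum(cases$variant_id == vars$variant_id[i]),
               n_other = as.integer(n_other),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(variant_id = character(), exclusive = logical(),
                      n_dysregulated = integer(), n_other = integer())
  }
  out
}
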