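## Methylation-aware network pruning: regulatory edges into genes whose
## downregulation is better explained by promoter hyper-methylation
## (strong expression-methylation anti-correlation) are removed.

#' Per-gene expression / promoter-methylation correlation
#'
#' Pearson correlation across the matched-sample intersection, for genes
#' present in both matrices. Genes with a constant profile in either layer
#' are excluded with a warning.
#'
#' @param expr Gene expression matrix (genes x samples).
#' @param meth Gene-level promoter methylation matrix (genes x samples).
#' @return Data frame (gene, r, n_samples).
#' @export
expr_meth_correlation <- function(expr, meth) {
  samples <- intersect(colnames(expr), colnames(meth))
  if (length(samples) < 3L) stop("need >= 3 matched samples")
  genes <- intersect(rownames(expr), rownames(meth))
  e <- expr[genes, samples, drop = FALSE]
  m <- meth[genes, samples, drop = FALSE]
  const <- apply(e, 1L, stats::sd) == 0 | apply(m, 1L, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " gene(s) with constant profile excluded")
  }
  genes <- genes[!const]
  r <- vapply(genes, function(g) stats::cor(e[g, ], m[g, ]), numeric(1L))
  data.frame(gene = genes, r = unname(r), n_samples = length(samples),
             stringsAsFactors = FALSE)
}

#' Prune regulatory edges into methylation-silenced genes
#'
#' A gene is *silenced* iff it is in `down_genes` and its
#' expression-methylation correlation is strictly below `-threshold`.
#' Every directed edge whose target is silenced is removed; an undirected
#' edge is removed iff one endpoint is silenced and the other is a TF
#' (interpreting the link as a putative regulation of the silenced gene).
#'
#' @param network `RegulatoryNetwork` data frame (from, to, directed,
#'   provenance, confidence).
#' @param correlations Data frame from [expr_meth_correlation()].
#' @param down_genes Character vector of downregulated genes (vote calls).
#' @param threshold Anti-correlation magnitude threshold (default 0.65;
#'   `r = -0.65` exactly is kept, removal requires `r < -0.65`).
#' @param tf_flags Named logical vector of TF flags (used for undirected
#'   edges; unnamed genes count as non-TF).
#' @param prune_undirected Also prune undirected links (default TRUE).
#' @return List: `network` (pruned), `removed` (edge data frame with the
#'   target's r), `silenced` (gene vector).
#' @export
prune_network <- function(network, correlations, down_genes,
                          threshold = 0.65, tf_flags = NULL,
                          prune_undirected = TRUE) {
  r <- stats::setNames(correlations$r, correlations$gene)
  is_silenced <- function(g) {
    g %in% down_genes & !is.na(r[g]) & r[g] < -threshold
  }
  silenced <- correlations$gene[is_silenced(correlations$gene)]
  tf <- function(g) {
    if (is.null(tf_flags)) return(rep(FALSE, length(g)))
    out <- tf_flags[g]
    out[is.na(out)] <- FALSE
    unname(out)
  }
  drop_dir <- network$directed & network$to %in% silenced
  drop_und <- rep(FALSE, nrow(network))
  if (prune_undirected) {
    drop_und <- !network$directed &
      ((network$from %in% silenced & tf(network$to)) |
         (network$to %in% silenced & tf(network$from)))
  }
  drop <- drop_dir | drop_und
  removed <- network[drop, , drop = FALSE]
  removed$target_r <- ifelse(removed$directed, r[removed$to],
                             ifelse(removed$to %in% silenced,
                                    r[removed$to], r[removed$from]))
  kept <- network[!drop, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  message("pruned ", sum(drop), " edge(s) into ", length(silenced),
          " silenced gene(s)")
  list(network = kept, removed = removed, silenced = silenced)
}
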