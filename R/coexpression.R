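## Weighted co-expression network: soft-thresholded correlation adjacency,
## topological overlap (TOM), average-linkage module detection, and the
## tighter-threshold reduction used for modules too large for Bayesian
## structure learning.

#' Unsigned soft-threshold adjacency
#'
#' `a_ij = |cor(i, j)|^beta` with zero diagonal. Constant genes get zero
#' correlation to everything, with a warning.
#'
#' @param expr Expression matrix (genes x samples), >= 3 samples.
#' @param beta Soft-threshold power >= 1 (default 6, the common unsigned
#'   default).
#' @return Symmetric adjacency matrix in \[0, 1\], zero diagonal.
#' @export
adjacency_matrix <- function(expr, beta = 6) {
  stopifnot(ncol(expr) >= 3L, beta >= 1)
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s); their adjacencies set to 0")
  }
  cors <- suppressWarnings(stats::cor(t(expr)))
  cors[is.na(cors)] <- 0
  a <- abs(cors)^beta
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' `tom_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`,
#' where `l_ij = sum_u a_iu a_uj` and `k_i` is the connectivity; the
#' diagonal is 1 by convention.
#'
#' @param adj Adjacency matrix from [adjacency_matrix()].
#' @return TOM similarity matrix in \[0, 1\], unit diagonal.
#' @export
tom_similarity <- function(adj) {
  stopifnot(isSymmetric(unname(adj)), all(adj >= 0), all(adj <= 1))
  k <- rowSums(adj)
  l <- adj %*% adj
  min_k <- outer(k, k, pmin)
  tom <- (l + adj) / (min_k + 1 - adj)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect modules by average-linkage clustering of 1 - TOM
#'
#' Static tree cut at `cut_height`; clusters smaller than `min_size` are
#' assigned the unassigned label 0 ("grey"). Remaining modules are
#' relabelled 1, 2, ... by decreasing size.
#'
#' @param tom TOM similarity matrix.
#' @param min_size Minimum module size (default 25; smaller clusters go
#'   grey).
#' @param cut_height Static cut height on the 1 - TOM dendrogram
#'   (default 0.9).
#' @return Named integer vector: gene -> module label (0 = unassigned).
#' @export
detect_modules <- function(tom, min_size = 25L, cut_height = 0.9) {
  diss <- 1 - tom
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  labels <- stats::setNames(rep(0L, length(raw)), names(raw))
  if (length(keep) > 0L) {
    ord <- keep[order(-sizes[keep], as.integer(keep))]
    for (i in seq_along(ord)) labels[raw == as.integer(ord[i])] <- i
  } else {
    warning("no cluster reaches min_size; all genes unassigned")
  }
  labels
}

# cosmetic color names for reports, mirroring WGCNA-style palettes
module_colors <- function(labels) {
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan")
  cols <- ifelse(labels == 0L, "grey",
                 palette[(labels - 1L) %% length(palette) + 1L])
  stats::setNames(cols, names(labels))
}

#' Reduce an oversized module to its tightest co-expression links
#'
#' Retains within-module gene pairs whose TOM is at or above the given
#' within-module quantile (ties included), emitting an undirected edge
#' list. Used for modules exceeding the Bayesian-learning size cap.
#'
#' @param tom TOM similarity matrix over all network genes.
#' @param module_genes Character vector of the module's genes.
#' @param tom_quantile Quantile in \[0, 1\]; 0 keeps every pair.
#' @return Data frame (gene_a, gene_b, tom) of retained undirected edges.
#' @export
tighten_module <- function(tom, module_genes, tom_quantile = 0.9) {
  sub <- tom[module_genes, module_genes, drop = FALSE]
  idx <- which(upper.tri(sub), arr.ind = TRUE)
  vals <- sub[idx]
  cut <- stats::quantile(vals, tom_quantile, names = FALSE, type = 7)
  keep <- vals >= cut
  if (!any(keep)) warning("tighten_module produced an empty edge set")
  data.frame(gene_a = module_genes[idx[keep, 1L]],
             gene_b = module_genes[idx[keep, 2L]],
             tom = vals[keep], stringsAsFactors = FALSE)
}

#' Undirected co-expression edge list for a module
#'
#' All within-module pairs, weighted by TOM (no thresholding); the
#' Bayesian learner and prior overlay operate on this link set.
#'
#' @param tom TOM matrix.
#' @param module_genes Genes of one module.
#' @return Data frame (gene_a, gene_b, tom).
#' @export
module_edges <- function(tom, module_genes) {
  tighten_module(tom, module_genes, tom_quantile = 0)
}
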