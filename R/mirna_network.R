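## miRNA-mRNA network assembly: miRNA -> target-mRNA edges and
## TF -> miRNA edges among differential features, each regulator kept only
## if its differential-target overlap is hypergeometrically significant,
## then merged into one typed directed network.

#' miRNA -> mRNA edges with per-miRNA hypergeometric filtering
#'
#' The universe is the set of measured genes carrying at least one target
#' annotation. For each differential miRNA, its annotated targets within
#' the universe are tested for over-representation of differential genes;
#' if `p < p_threshold`, edges to the differential targets are emitted.
#'
#' @param de_mirnas Differential miRNA ids.
#' @param target_table Data frame (regulator_id = miRNA, target_id =
#'   gene).
#' @param de_genes Differential gene ids.
#' @param measured_genes All measured gene ids (defines the universe).
#' @param p_threshold Hypergeometric threshold (default 0.05; strict `<`).
#' @return List: `edges` (from = miRNA, to = gene, provenance =
#'   "mirna_target", p), `tests` (per-miRNA N, K, n, k, p).
#' @export
mirna_to_mrna_edges <- function(de_mirnas, target_table, de_genes,
                                measured_genes, p_threshold = 0.05) {
  universe <- intersect(measured_genes, unique(target_table$target_id))
  N <- length(universe)
  K <- length(intersect(de_genes, universe))
  edges <- list()
  tests <- list()
  for (m in de_mirnas) {
    targets <- intersect(
      unique(target_table$target_id[target_table$regulator_id == m]),
      universe)
    if (length(targets) == 0L) {
      message("miRNA ", m, " has no annotated measured targets; skipped")
      next
    }
    hits <- intersect(targets, de_genes)
    p <- hypergeom_p(length(hits), K, length(targets), N)
    tests[[length(tests) + 1L]] <-
      data.frame(regulator = m, N = N, K = K, n = length(targets),
                 k = length(hits), p = p, stringsAsFactors = FALSE)
    if (p < p_threshold && length(hits) > 0L) {
      edges[[length(edges) + 1L]] <-
        data.frame(from = m, to = hits, provenance = "mirna_target",
                   p = p, stringsAsFactors = FALSE)
    }
  }
  list(
    edges = if (length(edges) > 0L) do.call(rbind, edges)
    else data.frame(from = character(), to = character(),
                    provenance = character(), p = numeric()),
    tests = if (length(tests) > 0L) do.call(rbind, tests)
    else data.frame(regulator = character(), N = integer(), K = integer(),
                    n = integer(), k = integer(), p = numeric())
  )
}

#' TF -> miRNA edges with per-TF hypergeometric filtering
#'
#' Only TFs that are themselves differential genes enter the network. The
#' universe is the set of miRNAs appearing in the TF-miRNA table; each
#' TF's regulated miRNAs are tested for over-representation of
#' differential miRNAs.
#'
#' @param de_mirnas Differential miRNA ids.
#' @param tf_mirna_table Data frame (regulator_id = TF gene, target_id =
#'   miRNA).
#' @param de_genes Differential gene ids (TF admission filter).
#' @param p_threshold Hypergeometric threshold (default 0.05).
#' @return List as in [mirna_to_mrna_edges()], provenance "tf_mirna".
#' @export
tf_to_mirna_edges <- function(de_mirnas, tf_mirna_table, de_genes,
                              p_threshold = 0.05) {
  universe <- unique(tf_mirna_table$target_id)
  N <- length(universe)
  K <- length(intersect(de_mirnas, universe))
  tfs <- intersect(unique(tf_mirna_table$regulator_id), de_genes)
  edges <- list()
  tests <- list()
  for (t in tfs) {
    regulated <- intersect(
      unique(tf_mirna_table$target_id[tf_mirna_table$regulator_id == t]),
      universe)
    if (length(regulated) == 0L) next
    hits <- intersect(regulated, de_mirnas)
    p <- hypergeom_p(length(hits), K, length(regulated), N)
    tests[[length(tests) + 1L]] <-
      data.frame(regulator = t, N = N, K = K, n = length(regulated),
                 k = length(hits), p = p, stringsAsFactors = FALSE)
    if (p < p_threshold && length(hits) > 0L) {
      edges[[length(edges) + 1L]] <-
        data.frame(from = t, to = hits, provenance = "tf_mirna",
                   p = p, stringsAsFactors = FALSE)
    }
  }
  list(
    edges = if (length(edges) > 0L) do.call(rbind, edges)
    else data.frame(from = character(), to = character(),
                    provenance = character(), p = numeric()),
    tests = if (length(tests) > 0L) do.call(rbind, tests)
    else data.frame(regulator = character(), N = integer(), K = integer(),
                    n = integer(), k = integer(), p = numeric())
  )
}

#' Merge the miRNA -> mRNA and TF -> miRNA edge sets
#'
#' Duplicate (from, to) pairs are collapsed keeping both provenance tags.
#' Node types are inferred from edge roles (miRNA vs gene).
#'
#' @param mirna_mrna Edge data frame from [mirna_to_mrna_edges()].
#' @param tf_mirna Edge data frame from [tf_to_mirna_edges()].
#' @return List: `edges` (from, to, directed = TRUE, provenance,
#'   confidence = NA), `nodes` (id, type), `report` (counts mirroring the
#'   published summary: unique miRNAs/genes/links per edge type and the
#'   node overlap between the two).
#' @export
merge_mirna_networks <- function(mirna_mrna, tf_mirna) {
  a <- mirna_mrna
  b <- tf_mirna
  all_edges <- rbind(
    data.frame(from = a$from, to = a$to, provenance = a$provenance,
               stringsAsFactors = FALSE),
    data.frame(from = b$from, to = b$to, provenance = b$provenance,
               stringsAsFactors = FALSE))
  if (nrow(all_edges) > 0L) {
    key <- paste(all_edges$from, all_edges$to)
    prov <- vapply(split(all_edges$provenance, key), function(p) {
      paste(sort(unique(p)), collapse = "+")
    }, character(1L))
    uniq <- all_edges[!duplicated(key), , drop = FALSE]
    uniq$provenance <- unname(prov[paste(uniq$from, uniq$to)])
    all_edges <- uniq
  }
  mirnas <- unique(c(a$from, b$to))
  genes <- unique(c(a$to, b$from))
  nodes <- rbind(
    data.frame(id = mirnas, type = rep("mirna", length(mirnas)),
               stringsAsFactors = FALSE),
    data.frame(id = setdiff(genes, mirnas),
               type = rep("gene", length(setdiff(genes, mirnas))),
               stringsAsFactors = FALSE))
  report <- list(
    n_mirna_mrna_links = nrow(a),
    n_mirna_mrna_mirnas = length(unique(a$from)),
    n_mirna_mrna_genes = length(unique(a$to)),
    n_tf_mirna_links = nrow(b),
    n_tf_mirna_tfs = length(unique(b$from)),
    n_tf_mirna_mirnas = length(unique(b$to)),
    n_total_genes = length(genes),
    n_total_mirnas = length(mirnas),
    n_genes_in_both = length(intersect(a$to, b$from)),
    n_mirnas_in_both = length(intersect(a$from, b$to))
  )
  edges <- data.frame(from = all_edges$from, to = all_edges$to,
                      directed = TRUE, provenance = all_edges$provenance,
                      confidence = NA_real_, stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  list(edges = edges, nodes = nodes, report = report)
}
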