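## Over-representation analysis of driver sets against user-supplied term
## annotations, and druggability flagging against drug-target tables.

#' Hypergeometric over-representation analysis
#'
#' Per term: `k` = study-set genes annotated to the term. The term is
#' reported iff `k >= min_study_annotated` and the upper-tail
#' hypergeometric p is strictly below `p_threshold`. No multiple-testing
#' correction is applied by default (optional BH).
#'
#' @param study_set Character vector of study genes (must lie in the
#'   universe).
#' @param term_annotations Data frame (term_id, term_name, gene).
#' @param universe Character vector of background genes.
#' @param min_study_annotated Minimum study-set overlap (default 2).
#' @param p_threshold Raw-p cutoff (default 0.05).
#' @param adjust BH-adjust p-values and filter on the adjusted value
#'   (default FALSE).
#' @return Data frame (term_id, term_name, N, K, n, k, p \[, p_adj\])
#'   sorted by p.
#' @export
ora <- function(study_set, term_annotations, universe,
                min_study_annotated = 2L, p_threshold = 0.05,
                adjust = FALSE) {
  if (length(universe) == 0L) stop("empty universe")
  study_set <- unique(study_set)
  if (!all(study_set %in% universe)) {
    stop("study set contains genes outside the universe")
  }
  ann <- term_annotations[term_annotations$gene %in% universe, , drop = FALSE]
  terms <- split(ann, ann$term_id)
  rows <- lapply(terms, function(t) {
    term_genes <- unique(t$gene)
    k <- length(intersect(study_set, term_genes))
    data.frame(term_id = t$term_id[1L], term_name = t$term_name[1L],
               N = length(universe), K = length(term_genes),
               n = length(study_set), k = k,
               p = hypergeom_p(k, length(term_genes), length(study_set),
                               length(universe)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term_id = character(), term_name = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p = numeric()))
  }
  rownames(out) <- NULL
  if (adjust) {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out <- out[out$k >= min_study_annotated & out$p_adj < p_threshold, ,
               drop = FALSE]
  } else {
    out <- out[out$k >= min_study_annotated & out$p < p_threshold, ,
               drop = FALSE]
  }
  out[order(out$p, out$term_id), , drop = FALSE]
}

#' Flag driver genes present in drug-target tables
#'
#' A gene is druggable iff it appears in at least one supplied table;
#' per-source indicator columns are attached and the overall druggable
#' fraction reported.
#'
#' @param driver_genes Character vector.
#' @param drug_tables Named list of data frames (gene, drug, source).
#' @return List: `table` (gene, druggable, one indicator column per
#'   source, drugs = collapsed drug names), `fraction`.
#' @export
druggability <- function(driver_genes, drug_tables) {
  stopifnot(is.list(drug_tables))
  tab <- data.frame(gene = driver_genes, stringsAsFactors = FALSE)
  all_hits <- rep(FALSE, length(driver_genes))
  drugs <- rep("", length(driver_genes))
  for (src in names(drug_tables)) {
    dt <- drug_tables[[src]]
    hit <- driver_genes %in% dt$gene
    tab[[src]] <- as.integer(hit)
    all_hits <- all_hits | hit
    for (i in which(hit)) {
      d <- unique(dt$drug[dt$gene == driver_genes[i]])
      drugs[i] <- paste(unique(c(strsplit(drugs[i], ";")[[1L]], d)),
                        collapse = ";")
    }
  }
  tab$druggable <- all_hits
  tab$drugs <- sub("^;", "", drugs)
  fraction <- if (length(driver_genes) == 0L) 0 else mean(all_hits)
  list(table = tab, fraction = fraction)
}
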