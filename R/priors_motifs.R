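## Directed seed edges overlaid on the co-expression network: curated
## TF -> target regulations restricted to co-expression links, and a PWM
## promoter scan with exact score-distribution p-values computed by
## dynamic programming under the background model.

#' Flag transcription factors by table union
#'
#' A gene is a TF iff it is listed in at least one supplied TF table.
#'
#' @param network_genes Character vector of network genes.
#' @param tf_tables List of character vectors (or data frames whose first
#'   column holds gene ids).
#' @return Logical vector named by `network_genes`.
#' @export
mark_tfs <- function(network_genes, tf_tables) {
  stopifnot(length(tf_tables) >= 1L)
  ids <- unique(unlist(lapply(tf_tables, function(t) {
    if (is.data.frame(t)) as.character(t[[1L]]) else as.character(t)
  })))
  stats::setNames(network_genes %in% ids, network_genes)
}

#' Directed seed edges from curated priors
#'
#' For each undirected co-expression link (TF, g) with a known regulation
#' TF -> g in the prior tables, a directed seed edge is emitted; links
#' without a prior stay undirected. Priors whose endpoint pair is not a
#' co-expression link contribute nothing.
#'
#' @param coexpr_edges Data frame (gene_a, gene_b) of undirected links.
#' @param prior_table Data frame (tf, target, source).
#' @param tf_flags Logical vector from [mark_tfs()].
#' @return Data frame (from, to, provenance = "curated").
#' @export
curated_edges <- function(coexpr_edges, prior_table, tf_flags) {
  link_key <- c(paste(coexpr_edges$gene_a, coexpr_edges$gene_b),
                paste(coexpr_edges$gene_b, coexpr_edges$gene_a))
  pri <- unique(prior_table[, c("tf", "target")])
  ok <- tf_flags[pri$tf]
  ok[is.na(ok)] <- FALSE
  pri <- pri[ok & paste(pri$tf, pri$target) %in% link_key, , drop = FALSE]
  data.frame(from = pri$tf, to = pri$target, provenance = "curated",
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read JASPAR plain-text count matrices
#'
#' Parses the `>ID name` header followed by four `A [ ... ]` style rows.
#'
#' @param path JASPAR-format file (may hold several motifs).
#' @return Named list of 4 x L count matrices (rows A, C, G, T), names =
#'   motif ids.
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  stopifnot(length(starts) >= 1L)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[i]]), "\\s+")[[1L]]
    block <- lines[(starts[i] + 1L):ends[i]]
    rows <- lapply(c("A", "C", "G", "T"), function(b) {
      ln <- block[grepl(paste0("^", b, "\\b"), block)]
      if (length(ln) != 1L) stop("motif ", hdr[1L], ": missing row ", b)
      vals <- strsplit(gsub("[^0-9. -]", " ", sub("^.", "", ln)), "\\s+")[[1L]]
      as.numeric(vals[nzchar(vals)])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[hdr[1L]]] <- m
  }
  out
}

#' Build a log-odds PWM from a count matrix
#'
#' A pseudocount is added per cell before column normalization; scores are
#' log2 of the probability over the background frequency.
#'
#' @param counts 4 x L count matrix (rows A, C, G, T).
#' @param pseudocount Added to every cell (default 0.01).
#' @param background Background base frequencies (default uniform).
#' @return List with `score` (4 x L log2-odds matrix), `prob`,
#'   `background`, `length`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.01,
                            background = c(A = .25, C = .25, G = .25, T = .25)) {
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 1L,
            abs(sum(background) - 1) < 1e-9)
  p <- sweep(counts + pseudocount, 2L, colSums(counts + pseudocount), "/")
  score <- log2(p / background)
  rownames(score) <- rownames(p) <- c("A", "C", "G", "T")
  list(score = score, prob = p, background = background, length = ncol(p))
}

# Discretize per-column scores to integer bins (round-half-even is fine:
# only consistency between DP and scanning matters).
binned_scores <- function(pwm, bin = 0.05) {
  round(pwm$score / bin)
}

#' Exact null distribution of the PWM score under the background model
#'
#' Dynamic programming over positions on scores discretized to `bin`:
#' convolves the per-column score distributions induced by the background
#' base frequencies, yielding the exact distribution of the (binned)
#' window score.
#'
#' @param pwm PWM from [pwm_from_counts()].
#' @param bin Score discretization bin width (default 0.05).
#' @return List with integer vector `support` (binned scores) and `prob`.
#' @export
pwm_score_distribution <- function(pwm, bin = 0.05) {
  sb <- binned_scores(pwm, bin)
  bg <- pwm$background[rownames(sb)]
  dist <- c(`0` = 1)  # names are binned-score values
  for (j in seq_len(ncol(sb))) {
    new <- new.env(hash = TRUE)
    for (s in names(dist)) {
      for (b in 1:4) {
        key <- as.character(as.integer(s) + sb[b, j])
        prev <- if (is.null(new[[key]])) 0 else new[[key]]
        new[[key]] <- prev + dist[[s]] * bg[[b]]
      }
    }
    keys <- ls(new)
    dist <- stats::setNames(vapply(keys, function(k) new[[k]], numeric(1L)),
                            keys)
  }
  support <- as.integer(names(dist))
  ord <- order(support)
  list(support = support[ord], prob = unname(dist[ord]), bin = bin)
}

#' P-value of a PWM score: P(score >= s) under the background null
#'
#' @param pwm PWM from [pwm_from_counts()].
#' @param score Raw log2-odds score (binned internally).
#' @param bin Discretization bin, must match the scan's.
#' @return Exact upper-tail probability.
#' @export
pwm_score_pvalue <- function(pwm, score, bin = 0.05) {
  d <- pwm_score_distribution(pwm, bin)
  sum(d$prob[d$support >= round(score / bin)])
}

# smallest binned score whose upper tail probability is <= p_threshold
pwm_score_cutoff <- function(pwm, p_threshold, bin = 0.05) {
  d <- pwm_score_distribution(pwm, bin)
  tail_p <- rev(cumsum(rev(d$prob)))
  ok <- which(tail_p <= p_threshold)
  if (length(ok) == 0L) return(Inf)
  d$support[min(ok)]
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "")[[1L]]), collapse = "")
         }, character(1L), USE.NAMES = FALSE))
}

# Best (binned) window score of a PWM on one strand of one sequence;
# windows containing non-ACGT letters are skipped. Returns -Inf if no
# scorable window.
scan_strand <- function(code, sb) {
  L <- ncol(sb)
  n <- length(code)
  if (n < L) return(-Inf)
  nw <- n - L + 1L
  s <- rep(0L, nw)
  ok <- rep(TRUE, nw)
  for (j in seq_len(L)) {
    b <- code[seq_len(nw) + j - 1L]
    ok <- ok & !is.na(b)
    s <- s + ifelse(is.na(b), 0L, sb[cbind(b, j)])
  }
  if (!any(ok)) return(-Inf)
  max(s[ok])
}

#' Best binned PWM hit score on both strands of a sequence
#'
#' @param seq DNA string.
#' @param pwm PWM from [pwm_from_counts()].
#' @param bin Discretization bin.
#' @return Best binned score over both strands (integer, -Inf if the
#'   sequence is shorter than the motif).
#' @export
pwm_best_score <- function(seq, pwm, bin = 0.05) {
  sb <- binned_scores(pwm, bin)
  fwd <- DNA_CODE[strsplit(toupper(seq), "")[[1L]]]
  rev <- DNA_CODE[strsplit(toupper(revcomp(seq)), "")[[1L]]]
  max(scan_strand(fwd, sb), scan_strand(rev, sb))
}

#' Scan promoters with TF-mapped PWMs and emit directed motif edges
#'
#' A sliding-window log2-odds scan on both strands; a promoter is hit iff
#' some window's exact null p-value is at or below `p_threshold`. One edge
#' per (TF, gene) regardless of hit multiplicity. Sequences whose
#' non-ACGT fraction exceeds `max_n_fraction` are skipped with a warning.
#'
#' @param promoters Named character vector of promoter sequences (names =
#'   gene ids) or a FASTA path readable by [read_promoters_fasta()].
#' @param pwms Named list of PWMs ([pwm_from_counts()]); `names(pwms)` are
#'   motif ids.
#' @param pwm_tf Named character vector mapping motif id -> TF gene id.
#' @param p_threshold Exact-p hit threshold (default 1e-4).
#' @param bin Score discretization bin (default 0.05).
#' @param max_n_fraction Tolerated non-ACGT fraction per sequence.
#' @return Data frame (from = TF, to = gene, provenance = "motif",
#'   score = best binned score x bin).
#' @export
pwm_scan <- function(promoters, pwms, pwm_tf, p_threshold = 1e-4,
                     bin = 0.05, max_n_fraction = 0.1) {
  if (length(promoters) == 1L && file.exists(promoters[[1L]]) &&
      is.null(names(promoters))) {
    promoters <- read_promoters_fasta(promoters[[1L]])
  }
  frac_n <- vapply(promoters, function(s) {
    ch <- strsplit(toupper(s), "")[[1L]]
    mean(!ch %in% names(DNA_CODE))
  }, numeric(1L))
  if (any(frac_n > max_n_fraction)) {
    warning(sum(frac_n > max_n_fraction),
            " promoter(s) exceed the non-ACGT tolerance; skipped")
    promoters <- promoters[frac_n <= max_n_fraction]
  }
  rows <- list()
  for (mid in names(pwms)) {
    tf <- pwm_tf[[mid]]
    if (is.null(tf) || is.na(tf)) next
    cutoff <- pwm_score_cutoff(pwms[[mid]], p_threshold, bin)
    for (g in names(promoters)) {
      best <- pwm_best_score(promoters[[g]], pwms[[mid]], bin)
      if (is.finite(best) && best >= cutoff) {
        rows[[length(rows) + 1L]] <-
          data.frame(from = tf, to = g, provenance = "motif",
                     score = best * bin, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(from = character(), to = character(),
                      provenance = character(), score = numeric()))
  }
  out <- do.call(rbind, rows)
  # one edge per (TF, gene): keep the best-scoring record
  out <- out[order(out$from, out$to, -out$score), ]
  out[!duplicated(out[, c("from", "to")]), , drop = FALSE]
}

#' Read promoter sequences from FASTA (ids = gene ids)
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_promoters_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
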