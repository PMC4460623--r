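## Per-module directed structure learning: equal-frequency discretization,
## BDe family scores, mutual-information sparse candidates, greedy hill
## climbing with add / remove / reverse / swap-parent moves, three-run
## consensus, and assembly of the final mixed network.

#' Equal-frequency discretization of an expression matrix
#'
#' Per gene, samples are split into `r` near-equal bins in order of value;
#' ties are broken by (stable) value order so the assignment is
#' deterministic. A constant gene collapses to a single bin with a
#' warning.
#'
#' @param mat Genes x samples matrix.
#' @param r Target arity (default 3).
#' @return Integer matrix of labels in `0..r-1` with the input dimnames.
#' @export
discretize_expression <- function(mat, r = 3L) {
  stopifnot(r >= 2L)
  n <- ncol(mat)
  out <- matrix(0L, nrow(mat), n, dimnames = dimnames(mat))
  constant <- 0L
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    if (length(unique(x)) == 1L) {
      constant <- constant + 1L
      next
    }
    ord <- order(x)  # stable: ties keep column order
    lab <- integer(n)
    lab[ord] <- as.integer(floor(seq(0L, n - 1L) * r / n))
    out[i, ] <- lab
  }
  if (constant > 0L) warning(constant, " constant gene(s) placed in one bin")
  out
}

# parent-configuration index (1-based) for each sample given parent rows
parent_config_index <- function(data, parents, arity) {
  if (length(parents) == 0L) return(rep(1L, ncol(data)))
  idx <- rep(0L, ncol(data))
  mult <- 1L
  for (p in parents) {
    idx <- idx + data[p, ] * mult
    mult <- mult * arity[p]
  }
  idx + 1L
}

#' BDe family score (log marginal-likelihood contribution of one node)
#'
#' For node `i` with parent set `Pa`, arity `r_i` and `q_i` parent
#' configurations, with Dirichlet hyperparameters
#' `alpha_ijk = ess / (q_i r_i)`:
#' `sum_j [lgamma(a_ij) - lgamma(a_ij + N_ij) +
#'         sum_k (lgamma(a_ijk + N_ijk) - lgamma(a_ijk))]`.
#' Family scores add up to the DAG score (decomposability).
#'
#' @param node Node (row) name.
#' @param parents Character vector of parent node names.
#' @param data Discrete matrix from [discretize_expression()].
#' @param ess Equivalent sample size > 0.
#' @param arity Named vector of per-node arities; default max label + 1
#'   per row.
#' @return Log score (0 for zero data rows).
#' @export
bde_family_score <- function(node, parents, data, ess = 1,
                             arity = NULL) {
  stopifnot(ess > 0)
  if (is.null(arity)) {
    arity <- stats::setNames(apply(data, 1L, max) + 1L, rownames(data))
  }
  if (ncol(data) == 0L) return(0)
  r_i <- arity[[node]]
  q_i <- if (length(parents) == 0L) 1 else prod(arity[parents])
  a_ijk <- ess / (q_i * r_i)
  a_ij <- ess / q_i
  j_idx <- parent_config_index(data, parents, arity)
  k_idx <- data[node, ]
  # q_i x r_i count matrix via a single tabulate pass
  counts <- matrix(tabulate((k_idx * q_i) + j_idx, nbins = q_i * r_i),
                   nrow = q_i)
  observed <- which(rowSums(counts) > 0L)
  N_ij <- rowSums(counts)[observed]
  sum(lgamma(a_ij) - lgamma(a_ij + N_ij)) +
    sum(lgamma(a_ijk + counts[observed, , drop = FALSE]) - lgamma(a_ijk))
}

#' Total BDe score of a DAG
#'
#' @param dag Named list node -> character vector of parents.
#' @param data Discrete data matrix.
#' @param ess Equivalent sample size.
#' @return Sum of family scores.
#' @export
bde_dag_score <- function(dag, data, ess = 1) {
  arity <- stats::setNames(apply(data, 1L, max) + 1L, rownames(data))
  sum(vapply(names(dag), function(v) {
    bde_family_score(v, dag[[v]], data, ess, arity)
  }, numeric(1L)))
}

# empirical mutual information (nats) between two discrete rows
mutual_information <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Sparse-candidate parent sets by mutual information
#'
#' Each node's candidate parents are its top-`k` partners by empirical
#' mutual information on the discretized data, always augmented with its
#' seed-edge parents.
#'
#' @param data Discrete data matrix.
#' @param k Candidates per node (`k >= n - 1` means everyone).
#' @param seed_edges Optional data frame (from, to) whose parents are
#'   forced into the candidate sets.
#' @return Named list node -> character vector of candidate parents.
#' @export
sparse_candidates <- function(data, k = 5L, seed_edges = NULL) {
  stopifnot(k >= 1L)
  nodes <- rownames(data)
  n <- length(nodes)
  mi <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        mi[i, j] <- mi[j, i] <- mutual_information(data[i, ], data[j, ])
      }
    }
  }
  cand <- lapply(nodes, function(v) {
    others <- setdiff(nodes, v)
    picked <- others[order(-mi[v, others])][seq_len(min(k, length(others)))]
    if (!is.null(seed_edges)) {
      picked <- union(picked, seed_edges$from[seed_edges$to == v])
    }
    setdiff(picked, v)
  })
  stats::setNames(cand, nodes)
}

# does adding edge from -> to create a cycle? (path to -> ... -> from)
creates_cycle <- function(dag_children, from, to) {
  if (from == to) return(TRUE)
  seen <- character()
  stack <- to
  while (length(stack) > 0L) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (v == from) return(TRUE)
    if (v %in% seen) next
    seen <- c(seen, v)
    stack <- c(stack, dag_children[[v]])
  }
  FALSE
}

children_map <- function(dag) {
  ch <- stats::setNames(vector("list", length(dag)), names(dag))
  for (v in names(dag)) for (p in dag[[v]]) ch[[p]] <- c(ch[[p]], v)
  ch
}

dag_is_acyclic <- function(dag) {
  g <- igraph::graph_from_data_frame(
    dag_edges(dag), directed = TRUE,
    vertices = data.frame(name = names(dag)))
  igraph::is_dag(g)
}

dag_edges <- function(dag) {
  rows <- lapply(names(dag), function(v) {
    if (length(dag[[v]]) == 0L) return(NULL)
    data.frame(from = dag[[v]], to = v, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(from = character(), to = character()) else out
}

# drop seed edges that close a cycle (insertion order), with a message
break_seed_cycles <- function(seed_edges, nodes) {
  dag <- stats::setNames(replicate(length(nodes), character(0),
                                   simplify = FALSE), nodes)
  dropped <- 0L
  if (!is.null(seed_edges) && nrow(seed_edges) > 0L) {
    for (e in seq_len(nrow(seed_edges))) {
      from <- seed_edges$from[e]
      to <- seed_edges$to[e]
      if (!(from %in% nodes) || !(to %in% nodes) || from == to) next
      if (from %in% dag[[to]]) next
      ch <- children_map(dag)
      if (creates_cycle(ch, from, to)) {
        dropped <- dropped + 1L
        next
      }
      dag[[to]] <- c(dag[[to]], from)
    }
  }
  if (dropped > 0L) {
    message("dropped ", dropped, " seed edge(s) closing cycles")
  }
  dag
}

#' Greedy hill climbing under the BDe score
#'
#' Starts from the (acyclicity-repaired) seed graph and repeatedly applies
#' the best strictly score-improving move among: add edge, remove edge,
#' reverse edge, and swap parent node. Legality: candidate-set membership,
#' acyclicity, and the max-parents cap. The run seed only shuffles the
#' tie-order among equal-score moves.
#'
#' @param data Discrete data matrix (nodes x samples).
#' @param seed_edges Data frame (from, to) of directed seed edges.
#' @param candidates Candidate-parent sets from [sparse_candidates()].
#' @param run_seed Integer seed for move-order shuffling.
#' @param ess Equivalent sample size (default 1).
#' @param max_parents Parent cap per node (default 4).
#' @param max_iter Move budget (default 500); reaching it sets a warning
#'   flag on the result.
#' @return `LearnedDag` list: `parents` (node -> parent vector), `edges`
#'   (data frame), `score`, `run_seed`, `converged`.
#' @export
learn_structure <- function(data, seed_edges = NULL, candidates = NULL,
                            run_seed = 1L, ess = 1, max_parents = 4L,
                            max_iter = 500L) {
  nodes <- rownames(data)
  if (is.null(candidates)) candidates <- sparse_candidates(data, k = 5L,
                                                           seed_edges = seed_edges)
  arity <- stats::setNames(apply(data, 1L, max) + 1L, nodes)
  dag <- break_seed_cycles(seed_edges, nodes)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  fam <- function(v, pa) {
    key <- paste(v, paste(sort(pa), collapse = ","), sep = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- bde_family_score(v, pa, data, ess, arity)
    cache[[key]] <- val
    val
  }
  fam_scores <- vapply(nodes, function(v) fam(v, dag[[v]]), numeric(1L))
  converged <- FALSE
  with_seed(run_seed, {
    for (iter in seq_len(max_iter)) {
      ch <- children_map(dag)
      moves <- list()
      for (v in nodes) {
        pa <- dag[[v]]
        # add u -> v
        for (u in setdiff(candidates[[v]], pa)) {
          if (length(pa) >= max_parents) next
          if (creates_cycle(ch, u, v)) next
          delta <- fam(v, c(pa, u)) - fam_scores[[v]]
          moves[[length(moves) + 1L]] <-
            list(kind = "add", u = u, v = v, w = NA, delta = delta)
        }
        for (u in pa) {
          # remove u -> v
          delta <- fam(v, setdiff(pa, u)) - fam_scores[[v]]
          moves[[length(moves) + 1L]] <-
            list(kind = "remove", u = u, v = v, w = NA, delta = delta)
          # reverse u -> v (new edge v -> u needs candidacy + acyclicity)
          if (v %in% candidates[[u]] && length(dag[[u]]) < max_parents) {
            ch2 <- ch
            ch2[[u]] <- setdiff(ch2[[u]], v)
            if (!creates_cycle(ch2, v, u)) {
              delta <- (fam(v, setdiff(pa, u)) - fam_scores[[v]]) +
                (fam(u, c(dag[[u]], v)) - fam_scores[[u]])
              moves[[length(moves) + 1L]] <-
                list(kind = "reverse", u = u, v = v, w = NA, delta = delta)
            }
          }
          # swap parent u of v for non-parent w
          for (w in setdiff(candidates[[v]], c(pa, v))) {
            ch2 <- ch
            ch2[[u]] <- setdiff(ch2[[u]], v)
            if (creates_cycle(ch2, w, v)) next
            delta <- fam(v, c(setdiff(pa, u), w)) - fam_scores[[v]]
            moves[[length(moves) + 1L]] <-
              list(kind = "swap", u = u, v = v, w = w, delta = delta)
          }
        }
      }
      if (length(moves) == 0L) { converged <- TRUE; break }
      deltas <- vapply(moves, `[[`, numeric(1L), "delta")
      best <- max(deltas)
      if (best <= 1e-9) { converged <- TRUE; break }
      tied <- which(deltas >= best - 1e-9)
      mv <- moves[[tied[sample.int(length(tied), 1L)]]]
      if (mv$kind == "add") {
        dag[[mv$v]] <- c(dag[[mv$v]], mv$u)
      } else if (mv$kind == "remove") {
        dag[[mv$v]] <- setdiff(dag[[mv$v]], mv$u)
      } else if (mv$kind == "reverse") {
        dag[[mv$v]] <- setdiff(dag[[mv$v]], mv$u)
        dag[[mv$u]] <- c(dag[[mv$u]], mv$v)
        fam_scores[[mv$u]] <- fam(mv$u, dag[[mv$u]])
      } else {
        dag[[mv$v]] <- c(setdiff(dag[[mv$v]], mv$u), mv$w)
      }
      fam_scores[[mv$v]] <- fam(mv$v, dag[[mv$v]])
      stopifnot(dag_is_acyclic(dag))
    }
  })
  if (!converged) warning("hill climbing stopped at max_iter = ", max_iter)
  res <- list(parents = dag, edges = dag_edges(dag),
              score = sum(fam_scores), run_seed = run_seed,
              converged = converged)
  class(res) <- "LearnedDag"
  res
}

#' Consensus of repeated structure-learning runs
#'
#' A directed edge is retained iff it appears in at least `min_support` of
#' the runs; its confidence is support / number of runs.
#'
#' @param dags List of `LearnedDag` objects (typically 3).
#' @param min_support Minimum run count (default 2, i.e. confidence >=
#'   2/3).
#' @return Data frame (from, to, support, confidence).
#' @export
consensus_edges <- function(dags, min_support = 2L) {
  n_runs <- length(dags)
  keys <- unlist(lapply(dags, function(d) {
    if (nrow(d$edges) == 0L) character(0)
    else paste(d$edges$from, d$edges$to, sep = "\r")
  }))
  if (length(keys) == 0L) {
    return(data.frame(from = character(), to = character(),
                      support = integer(), confidence = numeric()))
  }
  tab <- table(keys)
  keep <- names(tab)[tab >= min_support]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(
    from = vapply(parts, `[[`, character(1L), 1L),
    to = vapply(parts, `[[`, character(1L), 2L),
    support = as.integer(tab[keep]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$confidence <- out$support / n_runs
  out[order(out$from, out$to), , drop = FALSE]
}

#' Learn one module's structure three times and take the consensus
#'
#' Runs differ only in their tie-breaking sub-seed (derived from `seed`).
#'
#' @param data Discrete data matrix.
#' @param seed_edges Directed seed edges.
#' @param seed Base seed; the three run seeds are derived from it.
#' @param n_runs Number of runs (default 3).
#' @param min_support Consensus support (default 2).
#' @param ... Passed to [learn_structure()].
#' @return List: `consensus` (edge data frame), `runs` (LearnedDag list).
#' @export
learn_consensus <- function(data, seed_edges = NULL, seed = 1L,
                            n_runs = 3L, min_support = 2L, ...) {
  runs <- lapply(seq_len(n_runs), function(i) {
    learn_structure(data, seed_edges = seed_edges,
                    run_seed = derive_seed(seed, i), ...)
  })
  list(consensus = consensus_edges(runs, min_support), runs = runs)
}

#' Assemble the mixed regulatory network for a module
#'
#' Directed edges are the seed edges plus those consensus edges whose
#' endpoint pair is also a co-expression link; co-expression links left
#' without a direction stay undirected. Provenance is recorded per edge.
#'
#' @param seed_edges Data frame (from, to, provenance) of curated/motif
#'   edges.
#' @param consensus Data frame from [consensus_edges()].
#' @param coexpr_edges Data frame (gene_a, gene_b) of undirected links.
#' @return `RegulatoryNetwork` data frame (from, to, directed, provenance,
#'   confidence).
#' @export
assemble_grn <- function(seed_edges, consensus, coexpr_edges) {
  link_key <- unique(c(paste(coexpr_edges$gene_a, coexpr_edges$gene_b),
                       paste(coexpr_edges$gene_b, coexpr_edges$gene_a)))
  rows <- list()
  if (!is.null(seed_edges) && nrow(seed_edges) > 0L) {
    rows[[1L]] <- data.frame(from = seed_edges$from, to = seed_edges$to,
                             directed = TRUE,
                             provenance = seed_edges$provenance,
                             confidence = 1.0, stringsAsFactors = FALSE)
  }
  if (nrow(consensus) > 0L) {
    conf <- consensus[paste(consensus$from, consensus$to) %in% link_key, ,
                      drop = FALSE]
    if (nrow(conf) > 0L) {
      rows[[length(rows) + 1L]] <-
        data.frame(from = conf$from, to = conf$to, directed = TRUE,
                   provenance = "bayesian", confidence = conf$confidence,
                   stringsAsFactors = FALSE)
    }
  }
  directed <- if (length(rows) > 0L) do.call(rbind, rows)
  else data.frame(from = character(), to = character(),
                  directed = logical(), provenance = character(),
                  confidence = numeric())
  directed <- directed[!duplicated(directed[, c("from", "to")]), ,
                       drop = FALSE]
  dir_key <- unique(c(paste(directed$from, directed$to),
                      paste(directed$to, directed$from)))
  und <- coexpr_edges[!(paste(coexpr_edges$gene_a, coexpr_edges$gene_b)
                        %in% dir_key), , drop = FALSE]
  undirected <- data.frame(from = und$gene_a, to = und$gene_b,
                           directed = logical(nrow(und)),
                           provenance = rep("coexpression", nrow(und)),
                           confidence = rep(NA_real_, nrow(und)),
                           stringsAsFactors = FALSE)
  out <- rbind(directed, undirected)
  rownames(out) <- NULL
  class(out) <- c("RegulatoryNetwork", class(out))
  out
}
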