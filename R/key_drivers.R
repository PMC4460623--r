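## Key drivers as an exact minimum dominating set (MDS). A node dominates
## itself and its out-neighbors; undirected edges dominate both ways. The
## exact solver is a combinatorial branch-and-bound over the equivalent
## set-cover formulation (choose closed out-neighborhoods covering every
## node) with a proved-optimal contract; a brute-force enumerator serves
## as the independent oracle on small instances, and a clearly labelled
## greedy approximation is available behind a flag.

# closed out-neighborhood list: node -> nodes it dominates
domination_sets <- function(nodes, edges) {
  covers <- stats::setNames(as.list(nodes), nodes)
  if (!is.null(edges) && nrow(edges) > 0L) {
    directed <- if ("directed" %in% colnames(edges)) edges$directed
    else rep(TRUE, nrow(edges))
    for (i in seq_len(nrow(edges))) {
      u <- edges$from[i]
      v <- edges$to[i]
      covers[[u]] <- c(covers[[u]], v)
      if (!directed[i]) covers[[v]] <- c(covers[[v]], u)
    }
  }
  lapply(covers, unique)
}

#' Check that a node set dominates a network
#'
#' @param nodes All network nodes.
#' @param edges Edge data frame (from, to \[, directed\]); edges lacking a
#'   `directed` column are taken as directed.
#' @param set Candidate dominating set.
#' @return TRUE iff every node is in `set` or is an out-neighbor of a
#'   member.
#' @export
is_dominating <- function(nodes, edges, set) {
  covers <- domination_sets(nodes, edges)
  covered <- unique(unlist(covers[intersect(set, nodes)]))
  all(nodes %in% covered)
}

# greedy cover: repeatedly pick the set covering most uncovered nodes
greedy_mds <- function(covers, nodes) {
  uncovered <- nodes
  chosen <- character()
  while (length(uncovered) > 0L) {
    gains <- vapply(covers, function(s) sum(uncovered %in% s), integer(1L))
    pick <- names(covers)[which.max(gains)]
    chosen <- c(chosen, pick)
    uncovered <- setdiff(uncovered, covers[[pick]])
  }
  chosen
}

# exact branch-and-bound set cover (integer indices for speed)
bnb_cover <- function(cover_idx, n_elem, best_size, node_budget = 5e6) {
  # cover_idx: list per set of covered element indices
  # covered_by: per element, the sets covering it
  covered_by <- vector("list", n_elem)
  for (s in seq_along(cover_idx)) {
    for (e in cover_idx[[s]]) covered_by[[e]] <- c(covered_by[[e]], s)
  }
  best <- NULL
  best_k <- best_size + 1L
  nodes_visited <- 0L
  recurse <- function(uncovered, chosen) {
    nodes_visited <<- nodes_visited + 1L
    if (nodes_visited > node_budget) {
      stop("branch-and-bound budget exceeded; instance too hard")
    }
    if (length(uncovered) == 0L) {
      if (length(chosen) < best_k) {
        best_k <<- length(chosen)
        best <<- chosen
      }
      return(invisible(NULL))
    }
    # lower bound: remaining sets can cover at most max-gain elements each
    max_gain <- max(vapply(cover_idx, function(s) {
      sum(s %in% uncovered)
    }, integer(1L)))
    if (max_gain == 0L) return(invisible(NULL))
    lb <- length(chosen) + ceiling(length(uncovered) / max_gain)
    if (lb >= best_k) return(invisible(NULL))
    # branch on the uncovered element with fewest covering sets
    n_opts <- vapply(uncovered, function(e) length(covered_by[[e]]),
                     integer(1L))
    e <- uncovered[which.min(n_opts)]
    opts <- covered_by[[e]]
    # try larger-gain sets first
    gains <- vapply(opts, function(s) sum(cover_idx[[s]] %in% uncovered),
                    integer(1L))
    for (s in opts[order(-gains)]) {
      recurse(setdiff(uncovered, cover_idx[[s]]), c(chosen, s))
    }
    invisible(NULL)
  }
  recurse(seq_len(n_elem), integer(0))
  list(sets = best, size = best_k)
}

#' Exact minimum dominating set
#'
#' Solves the set-cover formulation (`x_v + sum_{u in in(v)} x_u >= 1` for
#' every node `v`, minimize `sum x_v`) exactly by branch-and-bound with a
#' greedy incumbent; the returned set is proved optimal or an error is
#' raised. Isolated nodes are necessarily selected.
#'
#' @param nodes Character vector of network nodes.
#' @param edges Edge data frame (from, to \[, directed\]).
#' @param method `"exact"` (default) or `"greedy"` (ln-n approximation,
#'   clearly non-optimal; use only for instances the exact solver
#'   rejects).
#' @return List: `drivers` (node set), `size`, `optimal` (logical).
#' @export
mds_drivers <- function(nodes, edges, method = c("exact", "greedy")) {
  method <- match.arg(method)
  if (length(nodes) == 0L) stop("empty network")
  covers <- domination_sets(nodes, edges)
  greedy <- greedy_mds(covers, nodes)
  if (method == "greedy") {
    return(list(drivers = greedy, size = length(greedy), optimal = FALSE))
  }
  elem_id <- stats::setNames(seq_along(nodes), nodes)
  cover_idx <- lapply(covers, function(s) unname(elem_id[s]))
  res <- bnb_cover(cover_idx, length(nodes), length(greedy))
  drivers <- if (is.null(res$sets)) greedy else names(covers)[res$sets]
  if (!is_dominating(nodes, edges, drivers)) {
    stop("internal error: solver returned a non-dominating set")
  }
  list(drivers = sort(drivers), size = length(drivers), optimal = TRUE)
}

#' Brute-force minimum dominating set (oracle)
#'
#' Exhaustive search in increasing cardinality; returns the minimum size
#' and every optimal set. Limited to 20 nodes.
#'
#' @param nodes Node vector (length <= 20).
#' @param edges Edge data frame.
#' @return List: `size`, `sets` (list of character vectors).
#' @export
mds_bruteforce <- function(nodes, edges) {
  n <- length(nodes)
  if (n > 20L) stop("brute force capped at 20 nodes (got ", n, ")")
  covers <- domination_sets(nodes, edges)
  cover_mask <- vapply(nodes, function(v) {
    bits <- rep(FALSE, n)
    bits[match(covers[[v]], nodes)] <- TRUE
    bits
  }, logical(n))
  # cover_mask: n_elem x n_sets logical
  for (k in seq_len(n)) {
    hits <- list()
    combos <- utils::combn(n, k)
    for (c_i in seq_len(ncol(combos))) {
      sel <- combos[, c_i]
      covered <- if (k == 1L) cover_mask[, sel] else rowSums(
        cover_mask[, sel, drop = FALSE]) > 0
      if (all(covered)) hits[[length(hits) + 1L]] <- nodes[sel]
    }
    if (length(hits) > 0L) return(list(size = k, sets = hits))
  }
  list(size = n, sets = list(nodes))
}

#' Per-driver report rows
#'
#' @param nodes Network node vector.
#' @param edges Edge data frame.
#' @param drivers Driver node set (must be in the network).
#' @param node_type Optional named vector node -> type (gene/mirna).
#' @param module Optional named vector node -> module label.
#' @param druggable Optional named logical vector.
#' @return `DriverReport` data frame (node, type, module, out_degree,
#'   in_degree, druggable), grouped by module.
#' @export
drivers_report <- function(nodes, edges, drivers, node_type = NULL,
                           module = NULL, druggable = NULL) {
  if (!all(drivers %in% nodes)) {
    stop("driver(s) absent from network: ",
         paste(setdiff(drivers, nodes), collapse = ", "))
  }
  pull <- function(v, default) {
    if (is.null(v)) return(rep(default, length(drivers)))
    out <- v[drivers]
    out[is.na(out)] <- default
    unname(out)
  }
  out_deg <- vapply(drivers, function(d) sum(edges$from == d), integer(1L))
  in_deg <- vapply(drivers, function(d) sum(edges$to == d), integer(1L))
  out <- data.frame(
    node = drivers,
    type = pull(node_type, "gene"),
    module = pull(module, NA_integer_),
    out_degree = unname(out_deg),
    in_degree = unname(in_deg),
    druggable = pull(druggable, NA),
    stringsAsFactors = FALSE
  )
  out[order(out$module, out$node), , drop = FALSE]
}
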