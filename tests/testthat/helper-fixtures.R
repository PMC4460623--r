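# Shared fixtures and small independent oracles used across test files.
# The default synthetic bundle is generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

test_bundle <- function(seed = 42L) {
  key <- paste0("bundle_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_cohort(synth_config(), seed = seed)
  }
  .fixture_cache[[key]]
}

# small two-group matrices with known statistics
toy_groups <- function() {
  list(x_t = matrix(c(1, 2, 3), 1, dimnames = list("f1", NULL)),
       x_n = matrix(c(4, 5, 6), 1, dimnames = list("f1", NULL)))
}

# adjusted Rand index between two labelings (independent implementation)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# brute-force AUC by pair counting
auc_pairs <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# O(n^3) TOM oracle
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, ] * a[, j])
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# exhaustive PWM score distribution: enumerate all 4^L sequences
pwm_enum_distribution <- function(pwm, bin = 0.05) {
  sb <- round(pwm$score / bin)
  L <- ncol(sb)
  bg <- pwm$background[rownames(sb)]
  grid <- expand.grid(rep(list(1:4), L))
  scores <- apply(grid, 1L, function(idx) sum(sb[cbind(idx, seq_len(L))]))
  probs <- apply(grid, 1L, function(idx) prod(bg[idx]))
  agg <- tapply(probs, scores, sum)
  list(support = as.integer(names(agg)), prob = unname(as.vector(agg)))
}

# BDe marginal likelihood via the sequential Polya-urn predictive product
# (independent of the lgamma closed form)
bde_sequential_oracle <- function(dag, data, ess = 1) {
  arity <- apply(data, 1L, max) + 1L
  names(arity) <- rownames(data)
  logp <- 0
  for (v in names(dag)) {
    pa <- dag[[v]]
    q <- if (length(pa) == 0L) 1 else prod(arity[pa])
    r <- arity[[v]]
    counts <- matrix(0, q, r)
    for (s in seq_len(ncol(data))) {
      j <- 1L
      mult <- 1L
      for (p in pa) {
        j <- j + data[p, s] * mult
        mult <- mult * arity[[p]]
      }
      k <- data[v, s] + 1L
      a_ijk <- ess / (q * r)
      a_ij <- ess / q
      logp <- logp + log((a_ijk + counts[j, k]) / (a_ij + sum(counts[j, ])))
      counts[j, k] <- counts[j, k] + 1
    }
  }
  logp
}

# all DAGs over the given nodes (for tiny n), as parent lists
all_dags <- function(nodes) {
  pairs <- t(utils::combn(length(nodes), 2L))
  # each unordered pair can be absent, ->, or <-
  states <- expand.grid(rep(list(0:2), nrow(pairs)))
  out <- list()
  for (r in seq_len(nrow(states))) {
    dag <- stats::setNames(replicate(length(nodes), character(0),
                                     simplify = FALSE), nodes)
    ok <- TRUE
    edges <- list()
    for (p in seq_len(nrow(pairs))) {
      s <- states[r, p]
      if (s == 1) edges[[length(edges) + 1L]] <- pairs[p, c(1, 2)]
      if (s == 2) edges[[length(edges) + 1L]] <- pairs[p, c(2, 1)]
    }
    for (e in edges) dag[[nodes[e[2]]]] <- c(dag[[nodes[e[2]]]], nodes[e[1]])
    g <- igraph::make_graph(as.integer(unlist(edges)), n = length(nodes),
                            directed = TRUE)
    if (igraph::is_dag(g)) out[[length(out) + 1L]] <- dag
  }
  out
}

# fixed 8-node ground-truth DAG with strong discrete effects; returns the
# consensus skeleton F1 against the truth for one simulation seed
truth_dag8 <- data.frame(
  from = c("A", "A", "B", "C", "D", "E", "F"),
  to   = c("B", "C", "D", "E", "F", "G", "H"),
  stringsAsFactors = FALSE)

simulate_dag8 <- function(n, seed) {
  nodes <- LETTERS[1:8]
  set.seed(seed)
  d <- matrix(0L, 8, n, dimnames = list(nodes, NULL))
  d["A", ] <- sample(0:2, n, replace = TRUE)
  flip <- function(x) ifelse(stats::runif(n) < 0.85, x,
                             sample(0:2, n, replace = TRUE))
  for (i in seq_len(nrow(truth_dag8))) {
    d[truth_dag8$to[i], ] <- flip(d[truth_dag8$from[i], ])
  }
  d
}

skeleton_f1_for_seed <- function(seed, n = 500L) {
  d <- simulate_dag8(n, seed)
  res <- learn_consensus(d, seed = seed, candidates = k_to_candidates(d))
  cons <- res$consensus
  skel <- function(e) unique(vapply(seq_len(nrow(e)), function(i) {
    paste(sort(c(e$from[i], e$to[i])), collapse = "-")
  }, character(1L)))
  truth <- skel(truth_dag8)
  if (nrow(cons) == 0L) return(0)
  found <- skel(cons)
  tp <- length(intersect(found, truth))
  prec <- tp / length(found)
  rec <- tp / length(truth)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

k_to_candidates <- function(d) sparse_candidates(d, k = nrow(d) - 1L)

# random digraph edge list for MDS tests
random_digraph <- function(n, density) {
  nodes <- paste0("n", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < density
  list(nodes = nodes, edges = pairs[keep, , drop = FALSE])
}
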