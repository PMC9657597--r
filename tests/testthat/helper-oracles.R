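# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by the most naive route available (all-pairs BFS via
# igraph, direct counting over confusion matrices, dense matrix products) so
# they share no code with the package implementation.

# Random bipartite 0/1 matrix (not SBM - plain Bernoulli).
random_bipartite <- function(nm, nd, p, seed) {
  with_seed(seed, {
    Y <- matrix(rbinom(nm * nd, 1, p), nm, nd)
    assoc_matrix(Y, paste0("m", seq_len(nm)), paste0("d", seq_len(nd)))
  })
}

# seed helper mirroring the package-internal one (not exported)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Brute-force double-radius labels: igraph all-pairs shortest paths with the
# opposite center deleted, then the hash applied position by position.
bf_drnl <- function(adj, centers) {
  n <- nrow(adj)
  x <- centers[1]; y <- centers[2]
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  dist_without <- function(drop, from) {
    gg <- igraph::delete_vertices(g, drop)
    d <- rep(Inf, n)
    keep <- setdiff(seq_len(n), drop)
    from_pos <- match(from, keep)
    d[keep] <- as.numeric(igraph::distances(gg, v = from_pos))
    d
  }
  dx <- dist_without(y, x)
  dy <- dist_without(x, y)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (i == x || i == y) {
      out[i] <- 1L
    } else if (is.finite(dx[i]) && is.finite(dy[i])) {
      d <- dx[i] + dy[i]
      out[i] <- as.integer(1 + min(dx[i], dy[i]) +
                             (d %/% 2) * ((d %/% 2) + (d %% 2) - 1))
    } else {
      out[i] <- 0L
    }
  }
  out
}

# Brute-force confusion-matrix metrics by explicit counting loops.
bf_metrics <- function(scores, labels, threshold) {
  TP <- FP <- TN <- FN <- 0
  for (i in seq_along(scores)) {
    pred <- scores[i] >= threshold
    if (pred && labels[i] == 1) TP <- TP + 1
    if (pred && labels[i] == 0) FP <- FP + 1
    if (!pred && labels[i] == 1) FN <- FN + 1
    if (!pred && labels[i] == 0) TN <- TN + 1
  }
  den <- function(x) if (x == 0) NA_real_ else x
  mccd <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       acc = (TP + TN) / length(scores),
       precision = TP / den(TP + FP),
       recall = TP / den(TP + FN),
       fpr = FP / den(FP + TN),
       mcc = if (mccd == 0) NA_real_ else (TP * TN - FP * FN) / mccd)
}

# AUROC as the normalized Mann-Whitney U statistic (average-rank ties).
bf_auroc_mw <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# AUROC by direct pair counting (second independent route, O(n^2)).
bf_auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# k-hop closure by explicit BFS on an edge list (independent of the sparse
# matrix sweep in the package).
bf_khop <- function(am, row, col, h) {
  nm <- nrow(am$Y)
  Yd <- as.matrix(am$Y)
  nbrs <- function(v) {
    if (v <= nm) nm + which(Yd[v, ] != 0) else which(Yd[, v - nm] != 0)
  }
  frontier <- c(row, nm + col)
  seen <- frontier
  for (step in seq_len(h)) {
    frontier <- setdiff(unique(unlist(lapply(frontier, nbrs))), seen)
    seen <- c(seen, frontier)
    if (!length(frontier)) break
  }
  sort(seen)
}
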