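#' One-hot label encoding
#'
#' Double-radius labels are unbounded in principle, so the one-hot feature
#' width is fixed by capping: labels `1..cap` get their own slot, label 0
#' (disconnected from a center) gets a dedicated slot, and every label above
#' `cap` shares a single overflow slot. Feature width is therefore
#' `L = cap + 2`, identical across subgraphs.
#'
#' @param cap largest label with its own slot (default 50).
#' @return A list of class `label_encoding` with `cap` and `L`.
#' @export
label_encoding <- function(cap = 50) {
  cap <- as.integer(cap)
  if (cap < 1) stop("cap must be >= 1")
  structure(list(cap = cap, L = cap + 2L), class = "label_encoding")
}

# Feature slot of a label: 0 -> 1, 1..cap -> label + 1, > cap -> L.
label_slot <- function(labels, encoding) {
  ifelse(labels == 0L, 1L,
         ifelse(labels <= encoding$cap, labels + 1L, encoding$L))
}

#' Expand integer node labels into one-hot feature rows
#'
#' @param labels non-negative integer labels.
#' @param encoding a [label_encoding()].
#' @return A numeric matrix with one row per label and exactly one 1 per row.
#' @export
build_features <- function(labels, encoding) {
  if (any(labels < 0)) stop("labels must be non-negative")
  X <- matrix(0, nrow = length(labels), ncol = encoding$L)
  X[cbind(seq_along(labels), label_slot(as.integer(labels), encoding))] <- 1
  X
}

#' Nodes within h hops of a candidate pair
#'
#' Breadth-first closure on the full bipartite graph induced by `Y`: all
#' nodes at graph distance `<= h` from either center. Nodes are reported as
#' global indices in a single namespace, rows first: side-A node `i` is `i`,
#' side-B node `j` is `nm + j`. Both centers are always included.
#'
#' @param am an [assoc_matrix()].
#' @param center_row,center_col 1-based indices of the candidate pair.
#' @param h hop count (`>= 1`).
#' @return Sorted integer vector of global node indices.
#' @export
khop_node_set <- function(am, center_row, center_col, h) {
  nm <- nrow(am$Y); nd <- ncol(am$Y)
  if (h < 1) stop("h must be >= 1")
  if (center_row < 1 || center_row > nm || center_col < 1 || center_col > nd) {
    stop("center indices out of range")
  }
  rows <- logical(nm); cols <- logical(nd)
  rows[center_row] <- TRUE; cols[center_col] <- TRUE
  fr <- rows; fc <- cols
  for (step in seq_len(h)) {
    # one hop: frontier rows reach columns, frontier columns reach rows
    nc <- if (any(fr)) Matrix::colSums(am$Y[fr, , drop = FALSE]) > 0 else
      logical(nd)
    nr <- if (any(fc)) Matrix::rowSums(am$Y[, fc, drop = FALSE]) > 0 else
      logical(nm)
    fc <- nc & !cols
    fr <- nr & !rows
    cols <- cols | nc
    rows <- rows | nr
    if (!any(fr) && !any(fc)) break
  }
  unname(sort(c(which(rows), nm + which(cols))))
}

# Unweighted BFS distances over an adjacency list.
# nbrs: list of integer neighbor vectors; blocked nodes are never entered.
bfs_dist <- function(nbrs, n, start, blocked = integer(0)) {
  d <- rep(Inf, n)
  visited <- logical(n)
  visited[blocked] <- TRUE
  if (visited[start]) return(d)
  d[start] <- 0
  queue <- start
  visited[start] <- TRUE
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nxt <- nbrs[[v]]
    nxt <- nxt[!visited[nxt]]
    if (length(nxt)) {
      d[nxt] <- d[v] + 1
      visited[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
  }
  d
}

adj_to_nbrs <- function(adj) {
  lapply(seq_len(nrow(adj)), function(i) which(adj[i, ] != 0))
}

#' Double-radius node labels
#'
#' Structural labels for the nodes of an enclosing subgraph. With `dx` the
#' distance of node `i` to center `x` computed with center `y` removed from
#' the graph (and symmetrically for `dy`), and `d = dx + dy`, the label is
#'
#' `fl(i) = 1 + min(dx, dy) + (d %/% 2) * ((d %/% 2) + (d %% 2) - 1)`
#'
#' Both centers are labeled 1; a node disconnected from either center under
#' this masking is labeled 0. Labels depend only on the graph, not on node
#' order.
#'
#' @param adj symmetric 0/1 adjacency matrix of the subgraph (target edge
#'   already removed).
#' @param centers length-2 integer vector: local indices of centers x and y.
#' @return Integer label vector, one entry per node.
#' @export
drnl_label <- function(adj, centers) {
  n <- nrow(adj)
  x <- centers[1]; y <- centers[2]
  nbrs <- adj_to_nbrs(adj)
  dx <- bfs_dist(nbrs, n, x, blocked = y)
  dy <- bfs_dist(nbrs, n, y, blocked = x)
  labels <- drnl_from_distances(dx, dy)
  labels[c(x, y)] <- 1L
  labels
}

# The double-radius hash applied to precomputed distance vectors.
drnl_from_distances <- function(dx, dy) {
  n <- length(dx)
  labels <- integer(n)
  ok <- is.finite(dx) & is.finite(dy)
  d <- dx[ok] + dy[ok]
  labels[ok] <- as.integer(1 + pmin(dx[ok], dy[ok]) +
                             (d %/% 2) * ((d %/% 2) + (d %% 2) - 1))
  labels
}

#' Extract the labeled enclosing subgraph of one candidate pair
#'
#' The classification unit of the whole method: the induced subgraph on all
#' nodes within `h` hops of either center, with the pair's own edge removed
#' (always, so a positive sample's supervision label can never leak through
#' its subgraph), double-radius labels, and one-hot features. Local node
#' order is deterministic: center x, center y, then the remaining nodes
#' sorted by (label, side, global index).
#'
#' @param am an [assoc_matrix()] (already masked of held-out positives when
#'   extracting for training).
#' @param row,col 1-based indices of the candidate pair.
#' @param label 0/1 supervision label of the pair.
#' @param h hop count.
#' @param encoding a [label_encoding()].
#' @param distances `"subgraph"` (default) computes labeling distances on
#'   the extracted subgraph; `"full"` computes them on the whole graph
#'   before restriction.
#' @return An object of class `labeled_subgraph`: list with `adj` (dense
#'   symmetric 0/1 matrix), `side` (`"A"`/`"B"` per node), `global` (global
#'   node index per node), `centers` (always `c(1, 2)`), `labels`,
#'   `features`, `h`, `true_label`, `encoding`.
#' @export
extract_enclosing_subgraph <- function(am, row, col, label, h,
                                       encoding = label_encoding(),
                                       distances = c("subgraph", "full")) {
  distances <- match.arg(distances)
  nm <- nrow(am$Y)
  nodes <- khop_node_set(am, row, col, h)
  is_row <- nodes <= nm
  rsel <- nodes[is_row]
  csel <- nodes[!is_row] - nm
  B <- as.matrix(am$Y[rsel, csel, drop = FALSE])
  n <- length(nodes)
  adj <- matrix(0, n, n)
  adj[is_row, !is_row] <- B
  adj[!is_row, is_row] <- t(B)
  gx <- row; gy <- nm + col
  x <- match(gx, nodes); y <- match(gy, nodes)
  adj[x, y] <- 0; adj[y, x] <- 0  # never expose the target edge
  if (distances == "subgraph") {
    labels <- drnl_label(adj, c(x, y))
  } else {
    df <- full_bipartite_dists(am, gx, blocked = gy, drop_edge = c(row, col))
    dg <- full_bipartite_dists(am, gy, blocked = gx, drop_edge = c(row, col))
    labels <- drnl_from_distances(df[nodes], dg[nodes])
    labels[c(x, y)] <- 1L
  }
  # canonical local order: centers first, then (label, side, global index)
  rest <- setdiff(seq_len(n), c(x, y))
  side <- ifelse(is_row, "A", "B")
  ord <- c(x, y, rest[order(labels[rest], side[rest], nodes[rest])])
  structure(list(adj = adj[ord, ord, drop = FALSE],
                 side = side[ord],
                 global = nodes[ord],
                 centers = c(1L, 2L),
                 labels = labels[ord],
                 features = build_features(labels[ord], encoding),
                 h = as.integer(h),
                 true_label = as.integer(label),
                 encoding = encoding),
            class = "labeled_subgraph")
}

# BFS distances from one global node over the full bipartite graph, with one
# node excluded and (optionally) one association edge dropped.
full_bipartite_dists <- function(am, start, blocked, drop_edge = NULL) {
  nm <- nrow(am$Y); nd <- ncol(am$Y)
  Y <- am$Y
  if (!is.null(drop_edge)) Y[drop_edge[1], drop_edge[2]] <- 0
  n <- nm + nd
  d <- rep(Inf, n)
  visited <- logical(n)
  visited[blocked] <- TRUE
  if (visited[start]) return(d)
  d[start] <- 0
  visited[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nxt <- if (v <= nm) nm + which(Y[v, ] != 0) else which(Y[, v - nm] != 0)
    nxt <- nxt[!visited[nxt]]
    if (length(nxt)) {
      d[nxt] <- d[v] + 1
      visited[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
  }
  d
}

#' @exportS3Method base::print
print.labeled_subgraph <- function(x, ...) {
  cat(sprintf(
    "Labeled enclosing subgraph: %d nodes, %d edges, h = %d, label = %d\n",
    nrow(x$adj), sum(x$adj) / 2, x$h, x$true_label))
  invisible(x)
}

#' Extract enclosing subgraphs for a whole sample set
#'
#' @param am an [assoc_matrix()].
#' @param samples a [pair_samples()] data frame.
#' @param h hop count.
#' @param encoding a [label_encoding()].
#' @param distances see [extract_enclosing_subgraph()].
#' @return List of `labeled_subgraph` objects, one per sample row.
#' @export
batch_extract <- function(am, samples, h, encoding = label_encoding(),
                          distances = "subgraph") {
  lapply(seq_len(nrow(samples)), function(i) {
    extract_enclosing_subgraph(am, samples$row[i], samples$col[i],
                               samples$label[i], h, encoding, distances)
  })
}

#' Serialize / reload a subgraph dataset
#'
#' Writes a directory with a JSON `manifest.json` (hop count, encoding,
#' record count, seed) and a `records.jsonl` file holding one JSON record
#' per subgraph: local edges in coordinate form, node sides and global
#' indices, labels and the supervision label. Features are rebuilt from the
#' labels on load, so the round trip is exact.
#'
#' @param subgraphs list of `labeled_subgraph` objects.
#' @param dir output directory (created if missing).
#' @param seed seed recorded in the manifest (provenance only).
#' @return `read_subgraph_dataset` returns the list of subgraphs.
#' @export
write_subgraph_dataset <- function(subgraphs, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enc <- subgraphs[[1]]$encoding
  manifest <- list(format = "bilinkgnn-subgraphs-v1",
                   h = subgraphs[[1]]$h, cap = enc$cap, L = enc$L,
                   count = length(subgraphs), seed = seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  recs <- vapply(subgraphs, function(sg) {
    e <- which(upper.tri(sg$adj) & sg$adj != 0, arr.ind = TRUE)
    jsonlite::toJSON(list(n = nrow(sg$adj), ei = e[, 1], ej = e[, 2],
                          side = sg$side, global = sg$global,
                          labels = sg$labels, true_label = sg$true_label),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(recs, file.path(dir, "records.jsonl"))
  invisible(dir)
}

#' @rdname write_subgraph_dataset
#' @export
read_subgraph_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  enc <- label_encoding(manifest$cap)
  lines <- readLines(file.path(dir, "records.jsonl"))
  lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln)
    n <- r$n
    adj <- matrix(0, n, n)
    if (length(r$ei)) {
      adj[cbind(r$ei, r$ej)] <- 1
      adj[cbind(r$ej, r$ei)] <- 1
    }
    labels <- as.integer(r$labels)
    structure(list(adj = adj, side = r$side, global = as.integer(r$global),
                   centers = c(1L, 2L), labels = labels,
                   features = build_features(labels, enc),
                   h = as.integer(manifest$h),
                   true_label = as.integer(r$true_label),
                   encoding = enc),
              class = "labeled_subgraph")
  })
}
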