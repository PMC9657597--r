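#' Model configuration
#'
#' Architecture hyperparameters of the subgraph classifier. The graph
#' convolution aggregates up to four propagation operators per layer
#' (see [build_propagators()]); removing operators from `propagators` yields
#' the ablation variants: dropping `"A"` is variant a, `"A2"` variant b,
#' `"RW"` variant c, `"SYM"` variant d, and `propagators = "SYM"` alone is
#' the plain DGCNN-style baseline.
#'
#' @param propagators ordered subset of `c("A", "A2", "RW", "SYM")`.
#' @param conv_dims per-layer output widths; the last must be 1 because the
#'   final channel drives sort pooling's importance ranking.
#' @param pooling_k either an integer number of nodes kept by sort pooling,
#'   or a fraction in (0, 1) resolved at training time as that quantile of
#'   the training subgraph sizes (default 0.6).
#' @param conv1_channels,conv2_channels,conv2_kernel,dense_units,pool_size,
#'   pool_stride read-out head shape: first 1-D convolution (kernel and
#'   stride equal to the embedding width), max pooling, second 1-D
#'   convolution, dense layer.
#' @param activation graph-convolution activation, `"tanh"` (default) or
#'   `"relu"`; the read-out head always uses rectified linear units.
#' @param seed integer seed for weight initialization.
#' @return A list of class `model_config`.
#' @export
model_config <- function(propagators = c("A", "A2", "RW", "SYM"),
                         conv_dims = c(32, 32, 1),
                         pooling_k = 0.6,
                         conv1_channels = 16,
                         conv2_channels = 32,
                         conv2_kernel = 5,
                         dense_units = 128,
                         pool_size = 2,
                         pool_stride = 2,
                         activation = c("tanh", "relu"),
                         seed = 1) {
  if (!length(propagators)) stop("at least one propagator is required")
  propagators <- match.arg(propagators, c("A", "A2", "RW", "SYM"),
                           several.ok = TRUE)
  if (anyDuplicated(propagators)) stop("duplicated propagators")
  conv_dims <- as.integer(conv_dims)
  if (any(conv_dims < 1)) stop("conv_dims must be positive")
  if (conv_dims[length(conv_dims)] != 1L) {
    stop("the last graph-convolution layer must have width 1 (it ranks nodes for sort pooling)")
  }
  if (is.numeric(pooling_k) && pooling_k >= 1) pooling_k <- as.integer(pooling_k)
  if (pooling_k <= 0) stop("pooling_k must be positive")
  structure(list(propagators = propagators,
                 conv_dims = conv_dims,
                 pooling_k = pooling_k,
                 conv1_channels = as.integer(conv1_channels),
                 conv2_channels = as.integer(conv2_channels),
                 conv2_kernel = as.integer(conv2_kernel),
                 dense_units = as.integer(dense_units),
                 pool_size = as.integer(pool_size),
                 pool_stride = as.integer(pool_stride),
                 activation = match.arg(activation),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Read / write a model configuration as YAML
#'
#' @param config a [model_config()].
#' @param path file path.
#' @return `read_model_config` returns a [model_config()].
#' @export
write_model_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  do.call(model_config, yaml::read_yaml(path))
}

#' Build the propagation operators of one subgraph
#'
#' Four operators carry complementary topology: `A` is the raw adjacency
#' (heterogeneous neighbors); `A2 = A %*% A` reaches homogeneous nodes —
#' in a bipartite graph two hops land on the same side, so `A2` counts
#' common neighbors within a side and is identically zero across sides;
#' `RW` is the random-walk normalized adjacency `solve(D~) %*% A~` and `SYM`
#' the symmetric normalization `D~^-1/2 %*% A~ %*% D~^-1/2`, both built on
#' `A~ = A + I` (self-loops) as in standard graph convolution. Rows of any
#' inverse degree for isolated nodes are set to zero.
#'
#' @param adj symmetric 0/1 adjacency matrix.
#' @param which ordered subset of `c("A", "A2", "RW", "SYM")`.
#' @return Named list of dense n x n matrices, in the order of `which`.
#' @export
build_propagators <- function(adj, which = c("A", "A2", "RW", "SYM")) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  out <- list()
  if (any(c("RW", "SYM") %in% which)) {
    At <- adj + diag(n)
    deg <- rowSums(At)
    dinv <- ifelse(deg > 0, 1 / deg, 0)
    dhalf <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  }
  for (p in which) {
    out[[p]] <- switch(p,
      A = adj,
      A2 = adj %*% adj,
      RW = dinv * At,
      SYM = dhalf * sweep(At, 2, dhalf, `*`))
  }
  out
}

#' One multi-propagator graph-convolution layer
#'
#' Applies every propagator to the incoming node matrix, splices the
#' results column-wise, multiplies by the layer weight and applies the
#' activation: `Z_out = sigma(cbind(P1 Z, ..., Pm Z) %*% W)`.
#'
#' @param Z node matrix (n x d_in).
#' @param props list of propagator matrices from [build_propagators()].
#' @param W weight matrix of shape (m * d_in) x d_out.
#' @param activation activation function (default `tanh`).
#' @return Node matrix of shape n x d_out.
#' @export
graph_conv_layer <- function(Z, props, W, activation = tanh) {
  H <- do.call(cbind, lapply(props, function(P) P %*% Z))
  if (ncol(H) != nrow(W)) {
    stop(sprintf("weight shape mismatch: spliced width %d, W expects %d",
                 ncol(H), nrow(W)))
  }
  activation(H %*% W)
}

#' Run all graph-convolution layers and concatenate their outputs
#'
#' Feeds the one-hot features through `length(W_list)` layers and returns
#' the per-node concatenation `Z = cbind(Z1, ..., ZT)` whose width is the
#' sum of the layer dims; the final width-1 channel ranks nodes for sort
#' pooling.
#'
#' @param X one-hot feature matrix (n x L).
#' @param props propagator list.
#' @param W_list list of layer weight matrices.
#' @param activation activation function.
#' @return Matrix n x sum(conv_dims).
#' @export
stack_conv_layers <- function(X, props, W_list, activation = tanh) {
  Z <- X
  outs <- vector("list", length(W_list))
  for (t in seq_along(W_list)) {
    Z <- graph_conv_layer(Z, props, W_list[[t]], activation)
    outs[[t]] <- Z
  }
  do.call(cbind, outs)
}

#' Sort pooling: fixed-size node selection
#'
#' Rows are ordered descending lexicographically starting from the last
#' column and moving backwards on ties; the top `k` rows are kept and, when
#' the subgraph has fewer than `k` nodes, all-zero rows are appended so the
#' output is always `k x ncol(Z_cat)`. Full ties keep their original
#' relative order (stable sort), which is irrelevant to the output since
#' tied rows are identical.
#'
#' @param Z_cat concatenated node embeddings.
#' @param k number of rows to keep.
#' @return Matrix k x ncol(Z_cat).
#' @export
sort_pooling <- function(Z_cat, k) {
  if (k < 1) stop("k must be >= 1")
  n <- nrow(Z_cat); f <- ncol(Z_cat)
  keys <- lapply(rev(seq_len(f)), function(c) Z_cat[, c])
  ord <- do.call(order, c(keys, list(method = "radix",
                                     decreasing = rep(TRUE, f))))
  pooled <- matrix(0, k, f)
  take <- min(n, k)
  pooled[seq_len(take), ] <- Z_cat[ord[seq_len(take)], , drop = FALSE]
  pooled
}

relu <- function(x) pmax(x, 0)

#' 1-D convolutional read-out head
#'
#' The pooled `k x F` tensor is read row-by-row: the first 1-D convolution
#' has kernel and stride equal to `F`, i.e. one output position per node
#' slot; after 2/2 max pooling a second 1-D convolution (kernel
#' `conv2_kernel`, stride 1) runs along the node axis; a dense layer and a
#' 2-class log-softmax finish the classifier. Hidden activations are
#' rectified linear.
#'
#' @param pooled output of [sort_pooling()].
#' @param params parameter list (see [init_params()]).
#' @param config a [model_config()].
#' @return Numeric length-2 vector of class log-probabilities
#'   (no-association, association); `sum(exp(.)) == 1`.
#' @export
conv1d_head <- function(pooled, params, config) {
  k <- nrow(pooled)
  a1 <- sweep(pooled %*% t(params$K1), 2, params$b1, `+`)  # k x c1
  r1 <- relu(a1)
  Q <- (k - config$pool_size) %/% config$pool_stride + 1L
  if (Q < config$conv2_kernel) {
    stop(sprintf("pooling_k = %d too small for the head's receptive field (need >= %d)",
                 k, (config$conv2_kernel - 1L) * config$pool_stride +
                   config$pool_size))
  }
  m1 <- matrix(0, Q, ncol(r1))
  for (q in seq_len(Q)) {
    rows <- (q - 1L) * config$pool_stride + seq_len(config$pool_size)
    m1[q, ] <- apply(r1[rows, , drop = FALSE], 2, max)
  }
  O2 <- Q - config$conv2_kernel + 1L
  Mwin <- t(vapply(seq_len(O2), function(q) {
    as.vector(t(m1[q + seq_len(config$conv2_kernel) - 1L, , drop = FALSE]))
  }, numeric(config$conv2_kernel * ncol(m1))))
  a2 <- sweep(Mwin %*% t(params$K2), 2, params$b2, `+`)  # O2 x c2
  r2 <- relu(a2)
  flat <- as.vector(t(r2))
  hid <- relu(drop(params$Wd1 %*% flat) + params$bd1)
  logits <- drop(params$Wd2 %*% hid) + params$bd2
  logits - log(sum(exp(logits - max(logits)))) - max(logits)
}

#' Initialize model parameters
#'
#' Glorot-style uniform initialization scaled by layer fan, deterministic
#' given `seed`. The read-out shapes depend on the resolved pooling size
#' `k` and the feature width `L`, which is why both are fixed before
#' initialization.
#'
#' @param config a [model_config()].
#' @param L one-hot feature width.
#' @param k resolved sort-pooling size.
#' @param seed integer seed (default: `config$seed`).
#' @return Named list: `W` (list of graph-conv weights), `K1`, `b1`, `K2`,
#'   `b2`, `Wd1`, `bd1`, `Wd2`, `bd2`.
#' @export
init_params <- function(config, L, k, seed = config$seed) {
  m <- length(config$propagators)
  dims <- c(L, config$conv_dims)
  fdim <- sum(config$conv_dims)
  Q <- (k - config$pool_size) %/% config$pool_stride + 1L
  if (Q < config$conv2_kernel) {
    stop(sprintf("pooling_k = %d too small for the head's receptive field", k))
  }
  O2 <- Q - config$conv2_kernel + 1L
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  with_seed(seed, {
    W <- lapply(seq_along(config$conv_dims), function(t) {
      glorot(m * dims[t], dims[t + 1])
    })
    list(W = W,
         K1 = glorot(config$conv1_channels, fdim),
         b1 = numeric(config$conv1_channels),
         K2 = glorot(config$conv2_channels,
                     config$conv2_kernel * config$conv1_channels),
         b2 = numeric(config$conv2_channels),
         Wd1 = glorot(config$dense_units, O2 * config$conv2_channels),
         bd1 = numeric(config$dense_units),
         Wd2 = glorot(2L, config$dense_units),
         bd2 = numeric(2L))
  })
}

#' Resolve the sort-pooling size against a training set
#'
#' Fractional `pooling_k` becomes the given quantile of the subgraph sizes
#' (DGCNN convention); the result is clamped from below so the read-out
#' head's receptive field is valid.
#'
#' @param config a [model_config()].
#' @param sizes integer vector of training subgraph node counts.
#' @return Integer pooling size.
#' @export
resolve_pooling_k <- function(config, sizes) {
  k_min <- (config$conv2_kernel - 1L) * config$pool_stride + config$pool_size
  k <- if (is.integer(config$pooling_k)) config$pooling_k else
    as.integer(ceiling(stats::quantile(sizes, config$pooling_k, names = FALSE)))
  max(k, k_min)
}

#' Reference forward pass (pure R)
#'
#' Composes [build_propagators()], [stack_conv_layers()], [sort_pooling()]
#' and [conv1d_head()] on dense matrices. This is the readable reference
#' path; [predict_pairs()] and [train()] use the equivalent compiled engine
#' and the test suite holds the two to within 1e-6.
#'
#' @param subgraph a `labeled_subgraph`.
#' @param model a `trained_model` (see [train()]), or any list with
#'   `params`, `config`, `resolved_k`, `feature_width`.
#' @return Probability of association, in `[0, 1]`.
#' @export
forward <- function(subgraph, model) {
  if (ncol(subgraph$features) != model$feature_width) {
    stop(sprintf("feature width %d does not match model width %d",
                 ncol(subgraph$features), model$feature_width))
  }
  act <- if (model$config$activation == "tanh") tanh else relu
  props <- build_propagators(subgraph$adj, model$config$propagators)
  Zcat <- stack_conv_layers(subgraph$features, props, model$params$W, act)
  pooled <- sort_pooling(Zcat, model$resolved_k)
  logp <- conv1d_head(pooled, model$params, model$config)
  unname(exp(logp[2]))
}

#' Mean negative log-likelihood loss
#'
#' @param log_probs matrix with one row per sample and one column per class
#'   (log-probabilities), or a length-2 vector for a single sample.
#' @param labels 0/1 integer labels.
#' @return Mean of `-log_probs[i, labels[i] + 1]`; 0 for a perfect
#'   predictor, `log(2)` for the uniform predictor.
#' @export
nll_loss <- function(log_probs, labels) {
  if (is.null(dim(log_probs))) log_probs <- matrix(log_probs, nrow = 1)
  stopifnot(all(labels %in% c(0, 1)), nrow(log_probs) == length(labels))
  mean(-log_probs[cbind(seq_along(labels), labels + 1L)])
}
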