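#' Training specification
#'
#' Optimization settings for [train()]: adaptive-moment gradient descent
#' (Adam) over shuffled mini-batches of enclosing subgraphs.
#'
#' @param epochs number of passes over the training set (default 50).
#' @param batch_size mini-batch size (default 50).
#' @param learning_rate Adam step size (default 1e-4).
#' @param seed integer seed driving the epoch shuffles.
#' @return A list of class `train_spec`.
#' @export
train_spec <- function(epochs = 50, batch_size = 50, learning_rate = 1e-4,
                       seed = 1) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "train_spec")
}

# Convert labeled_subgraph objects into the flat records the compiled
# engine consumes (0-based indices).
pack_subgraphs <- function(subgraphs) {
  lapply(subgraphs, function(sg) {
    e <- which(upper.tri(sg$adj) & sg$adj != 0, arr.ind = TRUE)
    list(n = nrow(sg$adj),
         ei = as.integer(e[, 1]) - 1L,
         ej = as.integer(e[, 2]) - 1L,
         slots = label_slot(sg$labels, sg$encoding) - 1L,
         y = sg$true_label)
  })
}

# Flat config record for the compiled engine.
cpp_config <- function(config, L, k) {
  list(L = as.integer(L),
       props = match(config$propagators, c("A", "A2", "RW", "SYM")) - 1L,
       conv_dims = config$conv_dims,
       k = as.integer(k),
       conv1_channels = config$conv1_channels,
       conv2_channels = config$conv2_channels,
       conv2_kernel = config$conv2_kernel,
       dense_units = config$dense_units,
       pool_size = config$pool_size,
       pool_stride = config$pool_stride,
       activation = config$activation)
}

check_subgraph_set <- function(subgraphs) {
  if (!length(subgraphs)) stop("empty subgraph set")
  L <- unique(vapply(subgraphs, function(s) s$encoding$L, integer(1)))
  if (length(L) != 1) stop("subgraphs use inconsistent label encodings")
  L
}

#' Train the enclosing-subgraph classifier
#'
#' End-to-end supervised training: every labeled subgraph is one sample,
#' the loss is the mean negative log-likelihood of the true pair label, and
#' parameters are updated with Adam over shuffled mini-batches. The
#' sort-pooling size is resolved against the training subgraph-size
#' distribution before initialization. Deterministic given the config and
#' spec seeds (up to floating-point non-associativity of the BLAS).
#'
#' @param subgraphs list of `labeled_subgraph` objects; at least one
#'   positive and one negative are required.
#' @param config a [model_config()].
#' @param spec a [train_spec()].
#' @return An object of class `trained_model`: list with `config`,
#'   `params`, `resolved_k`, `feature_width`, `h`, `encoding` and
#'   `loss_history` (mean NLL per epoch).
#' @export
train <- function(subgraphs, config = model_config(), spec = train_spec()) {
  L <- check_subgraph_set(subgraphs)
  ys <- vapply(subgraphs, function(s) s$true_label, integer(1))
  if (!any(ys == 1L) || !any(ys == 0L)) {
    stop("training set needs at least one positive and one negative sample")
  }
  sizes <- vapply(subgraphs, function(s) nrow(s$adj), integer(1))
  k <- resolve_pooling_k(config, sizes)
  params0 <- init_params(config, L, k, seed = config$seed)
  n <- length(subgraphs)
  perms <- with_seed(spec$seed, {
    t(vapply(seq_len(spec$epochs), function(e) sample.int(n) - 1L,
             integer(n)))
  })
  fit <- cpp_train(pack_subgraphs(subgraphs), params0,
                   cpp_config(config, L, k),
                   spec$learning_rate, spec$batch_size, perms)
  structure(list(config = config, params = fit$params,
                 resolved_k = as.integer(k), feature_width = as.integer(L),
                 h = subgraphs[[1]]$h, encoding = subgraphs[[1]]$encoding,
                 loss_history = as.numeric(fit$epoch_loss)),
            class = "trained_model")
}

#' An initialized but untrained model
#'
#' Same resolution and initialization path as [train()], without any
#' gradient steps — the random-weight control whose ranking performance
#' should hover around chance.
#'
#' @inheritParams train
#' @return A `trained_model` with freshly initialized parameters.
#' @export
untrained_model <- function(subgraphs, config = model_config()) {
  L <- check_subgraph_set(subgraphs)
  sizes <- vapply(subgraphs, function(s) nrow(s$adj), integer(1))
  k <- resolve_pooling_k(config, sizes)
  structure(list(config = config,
                 params = init_params(config, L, k, seed = config$seed),
                 resolved_k = as.integer(k), feature_width = as.integer(L),
                 h = subgraphs[[1]]$h, encoding = subgraphs[[1]]$encoding,
                 loss_history = numeric(0)),
            class = "trained_model")
}

#' @exportS3Method base::print
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "Subgraph GNN (%s), conv dims [%s], k = %d, feature width %d, h = %d\n",
    paste(x$config$propagators, collapse = "+"),
    paste(x$config$conv_dims, collapse = ", "),
    x$resolved_k, x$feature_width, x$h))
  if (length(x$loss_history)) {
    cat(sprintf("  trained %d epochs, final NLL %.4f\n",
                length(x$loss_history), utils::tail(x$loss_history, 1)))
  } else {
    cat("  untrained (random weights)\n")
  }
  invisible(x)
}

#' Score already-extracted subgraphs
#'
#' @param model a `trained_model`.
#' @param subgraphs list of `labeled_subgraph` objects.
#' @return Numeric vector of association probabilities in `[0, 1]`.
#' @export
predict_subgraphs <- function(model, subgraphs) {
  if (!length(subgraphs)) return(numeric(0))
  L <- check_subgraph_set(subgraphs)
  if (L != model$feature_width) {
    stop(sprintf("feature width %d does not match model width %d",
                 L, model$feature_width))
  }
  logp <- cpp_forward_batch(pack_subgraphs(subgraphs), model$params,
                            cpp_config(model$config, L, model$resolved_k))
  exp(logp[, 2])
}

#' Score arbitrary candidate pairs
#'
#' Extracts each pair's enclosing subgraph from `am` — always with the
#' pair's own edge masked, so scoring a known association never sees the
#' edge it predicts — and runs the forward pass.
#'
#' @param model a `trained_model`.
#' @param am an [assoc_matrix()].
#' @param pairs data frame with integer columns `row` and `col`.
#' @param h hop count (default: the model's training hop count).
#' @return Numeric vector of association probabilities, one per pair.
#' @export
predict_pairs <- function(model, am, pairs, h = model$h) {
  if (!nrow(pairs)) return(numeric(0))
  labels <- as.integer(am$Y[cbind(pairs$row, pairs$col)] != 0)
  sgs <- batch_extract(am, pair_samples(pairs$row, pairs$col, labels), h,
                       model$encoding)
  predict_subgraphs(model, sgs)
}

#' Rank unobserved partners of one entity
#'
#' Scores every zero entry of the target's row/column and returns them in
#' descending score order (ties broken by identifier for determinism) —
#' the candidate-screening use case: "which miRNAs should be tested against
#' this disease next?".
#'
#' @param model a `trained_model`.
#' @param am an [assoc_matrix()].
#' @param target identifier of the target entity.
#' @param h hop count (default: the model's).
#' @param side `"B"` (default) if the target is a column entity (e.g. a
#'   disease), `"A"` if it is a row entity.
#' @return Data frame `rank`, `id`, `score`, descending by score.
#' @export
rank_candidates <- function(model, am, target, h = model$h,
                            side = c("B", "A")) {
  side <- match.arg(side)
  if (side == "B") {
    j <- match(target, am$col_ids)
    if (is.na(j)) stop("unknown target id: ", target)
    cand <- which(am$Y[, j] == 0)
    pairs <- data.frame(row = cand, col = rep(j, length(cand)))
    ids <- am$row_ids[cand]
  } else {
    i <- match(target, am$row_ids)
    if (is.na(i)) stop("unknown target id: ", target)
    cand <- which(am$Y[i, ] == 0)
    pairs <- data.frame(row = rep(i, length(cand)), col = cand)
    ids <- am$col_ids[cand]
  }
  if (!length(cand)) {
    return(data.frame(rank = integer(0), id = character(0),
                      score = numeric(0)))
  }
  score <- predict_pairs(model, am, pairs, h)
  ord <- order(-score, ids, method = "radix")
  data.frame(rank = seq_along(cand), id = ids[ord], score = score[ord])
}

#' Train/test holdout split of a balanced sample set
#'
#' Pools all positives with an equal number of sampled negatives, holds out
#' `test_fraction` of the positives plus the same number of negatives,
#' masks the held-out positive edges from `Y`, and extracts training and
#' test subgraphs from the masked matrix. This is the single-split protocol
#' used by the hop and ablation studies; [cross_validate()] is the k-fold
#' analogue.
#'
#' @param am an [assoc_matrix()].
#' @param h hop count.
#' @param seed integer seed (negative sampling and the split draw).
#' @param test_fraction fraction of positives held out (default 0.1).
#' @param encoding a [label_encoding()].
#' @return List with `train_subgraphs`, `test_subgraphs`, `test_labels`,
#'   `train_samples`, `test_samples` and the masked matrix `am_masked`.
#' @export
holdout_split <- function(am, h, seed, test_fraction = 0.1,
                          encoding = label_encoding()) {
  samples <- balanced_samples(am, seed)
  pos <- which(samples$label == 1L)
  neg <- which(samples$label == 0L)
  n_test <- max(1L, round(test_fraction * length(pos)))
  test_idx <- with_seed(seed + 1L, c(sample(pos, n_test),
                                     sample(neg, n_test)))
  test <- samples[test_idx, , drop = FALSE]
  trn <- samples[-test_idx, , drop = FALSE]
  am_masked <- mask_test_positives(am, test)
  list(train_subgraphs = batch_extract(am_masked, trn, h, encoding),
       test_subgraphs = batch_extract(am_masked, test, h, encoding),
       test_labels = test$label,
       train_samples = trn, test_samples = test, am_masked = am_masked)
}

#' Single-split holdout evaluation
#'
#' Convenience wrapper: [holdout_split()], [train()], score the held-out
#' subgraphs, [compute_metrics()].
#'
#' @inheritParams holdout_split
#' @param config a [model_config()].
#' @param spec a [train_spec()].
#' @param split optionally a precomputed [holdout_split()] (so several
#'   configs can share one extraction).
#' @return List with `metrics` (a `metrics_report`), `model` and `split`.
#' @export
evaluate_holdout <- function(am, h, config = model_config(),
                             spec = train_spec(), seed = 1,
                             test_fraction = 0.1,
                             encoding = label_encoding(), split = NULL) {
  if (is.null(split)) {
    split <- holdout_split(am, h, seed, test_fraction, encoding)
  }
  model <- train(split$train_subgraphs, config, spec)
  scores <- predict_subgraphs(model, split$test_subgraphs)
  list(metrics = compute_metrics(scores, split$test_labels),
       model = model, split = split)
}

#' Leakage-safe k-fold cross-validation
#'
#' Pools positives with an equal number of sampled negatives, partitions
#' them into folds, and per round: masks the test fold's positive edges
#' from `Y`, extracts training and test subgraphs from the masked matrix,
#' trains, and evaluates on the held-out fold.
#'
#' @param am an [assoc_matrix()].
#' @param h hop count.
#' @param config a [model_config()].
#' @param spec a [train_spec()].
#' @param n_folds number of folds (default 10).
#' @param seed integer seed (negative sampling + fold assignment).
#' @param encoding a [label_encoding()].
#' @param threshold decision threshold passed to [compute_metrics()].
#' @return List of class `cv_result`: `folds` (list of `metrics_report`),
#'   `mean` (named numeric vector), `plan` (the [make_cv_folds()] plan) and
#'   `samples`.
#' @export
cross_validate <- function(am, h, config = model_config(),
                           spec = train_spec(), n_folds = 10, seed = 1,
                           encoding = label_encoding(), threshold = 0.5) {
  samples <- balanced_samples(am, seed)
  plan <- make_cv_folds(samples, n_folds, seed + 1L)
  folds <- lapply(seq_len(n_folds), function(f) {
    test <- samples[plan$assignments == f, , drop = FALSE]
    trn <- samples[plan$assignments != f, , drop = FALSE]
    am_masked <- mask_test_positives(am, test)
    model <- train(batch_extract(am_masked, trn, h, encoding), config, spec)
    scores <- predict_subgraphs(model,
                                batch_extract(am_masked, test, h, encoding))
    compute_metrics(scores, test$label, threshold)
  })
  structure(list(folds = folds, mean = mean_metrics(folds), plan = plan,
                 samples = samples),
            class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (mean over folds):\n",
              x$plan$n_folds))
  print(round(x$mean, 5))
  invisible(x)
}

#' Loss and gradients at the current parameters
#'
#' Mean NLL over the given subgraphs and its analytic gradient with respect
#' to every parameter — the hook used by finite-difference gradient checks.
#'
#' @param model a `trained_model`.
#' @param subgraphs list of `labeled_subgraph` objects.
#' @return List with `loss` (scalar) and `grads` (same shapes as
#'   `model$params`).
#' @export
loss_gradients <- function(model, subgraphs) {
  L <- check_subgraph_set(subgraphs)
  cpp_loss_grad(pack_subgraphs(subgraphs), model$params,
                cpp_config(model$config, L, model$resolved_k))
}

#' Save / load a trained model checkpoint
#'
#' Single-file JSON archive: a version string, the config, the resolved
#' pooling size, the label encoding and all parameter tensors at full
#' precision.
#'
#' @param model a `trained_model`.
#' @param path file path.
#' @return `load_model` returns the `trained_model`.
#' @export
save_model <- function(model, path) {
  payload <- list(format = "bilinkgnn-model-v1",
                  config = unclass(model$config),
                  resolved_k = model$resolved_k,
                  feature_width = model$feature_width,
                  h = model$h, cap = model$encoding$cap,
                  loss_history = model$loss_history,
                  params = model$params)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
             path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::fromJSON(readLines(path), simplifyMatrix = TRUE)
  if (!identical(x$format, "bilinkgnn-model-v1")) {
    stop("unrecognized model checkpoint format")
  }
  cfg <- do.call(model_config, x$config)
  params <- list(W = lapply(x$params$W, function(w) matrix(unlist(w),
                                                           nrow = nrow(w))),
                 K1 = x$params$K1, b1 = as.numeric(x$params$b1),
                 K2 = x$params$K2, b2 = as.numeric(x$params$b2),
                 Wd1 = x$params$Wd1, bd1 = as.numeric(x$params$bd1),
                 Wd2 = x$params$Wd2, bd2 = as.numeric(x$params$bd2))
  structure(list(config = cfg, params = params,
                 resolved_k = as.integer(x$resolved_k),
                 feature_width = as.integer(x$feature_width),
                 h = as.integer(x$h), encoding = label_encoding(x$cap),
                 loss_history = as.numeric(x$loss_history)),
            class = "trained_model")
}
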