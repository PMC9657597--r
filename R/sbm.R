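#' Bipartite stochastic-block-model specification
#'
#' Describes the synthetic benchmark: `nm` side-A and `nd` side-B nodes are
#' assigned round-robin to `n_blocks` latent groups; a pair in the same
#' group is linked with probability `p_in`, otherwise `p_out`. Round-robin
#' (rather than random) assignment keeps expected block sizes exact, so
#' density checks in tests can be tight.
#'
#' @param nm,nd side sizes.
#' @param n_blocks number of latent blocks (`>= 1`).
#' @param p_in,p_out within/between-block edge probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param seed integer seed.
#' @return A list of class `sbm_spec`.
#' @export
sbm_spec <- function(nm = 150, nd = 120, n_blocks = 4,
                     p_in = 0.25, p_out = 0.02, seed = 1) {
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  if (nm < n_blocks || nd < n_blocks) stop("fewer nodes than blocks")
  structure(list(nm = as.integer(nm), nd = as.integer(nd),
                 n_blocks = as.integer(n_blocks),
                 p_in = p_in, p_out = p_out, seed = as.integer(seed)),
            class = "sbm_spec")
}

#' Generate a bipartite stochastic-block-model association matrix
#'
#' Plants a block structure that any topology-aware link predictor should
#' recover: same-block pairs are connected with `p_in`, cross-block pairs
#' with `p_out`. Deterministic given `spec$seed`.
#'
#' @param spec an [sbm_spec()].
#' @return An [assoc_matrix()] with ids `m1..m<nm>` / `d1..d<nd>`.
#' @examples
#' am <- generate_bipartite_sbm(sbm_spec(20, 16, 2, 0.9, 0.05, seed = 7))
#' Matrix::nnzero(am$Y)
#' @export
generate_bipartite_sbm <- function(spec) {
  stopifnot(inherits(spec, "sbm_spec"))
  bm <- sbm_blocks(spec$nm, spec$n_blocks)
  bd <- sbm_blocks(spec$nd, spec$n_blocks)
  same <- outer(bm, bd, `==`)
  p <- ifelse(same, spec$p_in, spec$p_out)
  draw <- with_seed(spec$seed,
                    matrix(stats::runif(spec$nm * spec$nd), spec$nm, spec$nd))
  Y <- (draw < p) * 1
  assoc_matrix(Y, paste0("m", seq_len(spec$nm)), paste0("d", seq_len(spec$nd)))
}

# Round-robin block assignment: node i -> block ((i - 1) mod n_blocks) + 1.
sbm_blocks <- function(n, n_blocks) {
  rep(seq_len(n_blocks), length.out = n)
}

#' Expected edge count of a bipartite SBM
#'
#' Closed form used by distributional tests: within-block pairs times `p_in`
#' plus cross-block pairs times `p_out`.
#'
#' @param spec an [sbm_spec()].
#' @return A list with `mean` and binomial `sd` of the edge count.
#' @export
sbm_expected_edges <- function(spec) {
  same <- outer(sbm_blocks(spec$nm, spec$n_blocks),
                sbm_blocks(spec$nd, spec$n_blocks), `==`)
  n_in <- sum(same)
  n_out <- spec$nm * spec$nd - n_in
  list(mean = n_in * spec$p_in + n_out * spec$p_out,
       sd = sqrt(n_in * spec$p_in * (1 - spec$p_in) +
                   n_out * spec$p_out * (1 - spec$p_out)))
}

#' Tiny hand-verified fixture graphs
#'
#' Small bipartite graphs whose k-hop neighborhoods, double-radius labels
#' and second-order adjacencies were worked out by hand; shared across the
#' test suite and handy for interactive exploration.
#'
#' * `two_by_two`: Y = \[\[1,1\],\[0,1\]\] — the worked example threaded through
#'   the loader/extractor documentation.
#' * `path`: m1-d1-m2-d2, a 4-node path.
#' * `star`: one disease hub d1 linked to miRNAs m1..m5.
#' * `blocks`: 6x6 two-block graph (p_in = 1, p_out = 0 pattern).
#'
#' @return Named list of [assoc_matrix()] objects.
#' @export
fixture_graphs <- function() {
  two_by_two <- assoc_matrix(rbind(c(1, 1), c(0, 1)),
                             c("m1", "m2"), c("d1", "d2"))
  path <- assoc_matrix(rbind(c(1, 0), c(1, 1)), c("m1", "m2"), c("d1", "d2"))
  star <- assoc_matrix(matrix(1, nrow = 5, ncol = 1),
                       paste0("m", 1:5), "d1")
  blocks <- assoc_matrix(kronecker(diag(2), matrix(1, 3, 3)),
                         paste0("m", 1:6), paste0("d", 1:6))
  list(two_by_two = two_by_two, path = path, star = star, blocks = blocks)
}
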