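#' Bipartite association matrices
#'
#' An `assoc_matrix` holds the 0/1 association matrix `Y` (rows = side-A
#' entities such as miRNAs, columns = side-B entities such as diseases)
#' together with the ordered identifier registries for both sides. `Y` is
#' stored as a sparse [Matrix::sparseMatrix()] so that genome-scale
#' association tables stay cheap.
#'
#' @param Y matrix-like object coercible to a sparse 0/1 matrix.
#' @param row_ids character vector of side-A identifiers (length `nrow(Y)`).
#' @param col_ids character vector of side-B identifiers (length `ncol(Y)`).
#'
#' @return An object of class `assoc_matrix`: a list with elements `Y`
#'   (sparse 0/1 `dgCMatrix`), `row_ids` and `col_ids`.
#' @examples
#' am <- assoc_matrix(rbind(c(1, 1), c(0, 1)), c("m1", "m2"), c("d1", "d2"))
#' dim(am$Y)
#' @export
assoc_matrix <- function(Y, row_ids = NULL, col_ids = NULL) {
  Y <- methods::as(methods::as(Matrix::Matrix(Y, sparse = TRUE), "dMatrix"),
                   "CsparseMatrix")
  Y <- Matrix::drop0(Y)
  if (length(Y@x) && !all(Y@x == 1)) {
    stop("Y must contain only 0/1 entries")
  }
  if (is.null(row_ids)) row_ids <- rownames(Y)
  if (is.null(col_ids)) col_ids <- colnames(Y)
  if (is.null(row_ids)) row_ids <- paste0("A", seq_len(nrow(Y)))
  if (is.null(col_ids)) col_ids <- paste0("B", seq_len(ncol(Y)))
  row_ids <- as.character(row_ids)
  col_ids <- as.character(col_ids)
  if (length(row_ids) != nrow(Y) || length(col_ids) != ncol(Y)) {
    stop("id registries must match the dimensions of Y")
  }
  if (anyDuplicated(row_ids)) stop("duplicated row_ids")
  if (anyDuplicated(col_ids)) stop("duplicated col_ids")
  dimnames(Y) <- list(row_ids, col_ids)
  structure(list(Y = Y, row_ids = row_ids, col_ids = col_ids),
            class = "assoc_matrix")
}

#' @exportS3Method base::print
print.assoc_matrix <- function(x, ...) {
  cat(sprintf("Bipartite association matrix: %d x %d, %d associations\n",
              nrow(x$Y), ncol(x$Y), as.integer(Matrix::nnzero(x$Y))))
  invisible(x)
}

#' @export
dim.assoc_matrix <- function(x) dim(x$Y)

#' Read a two-column association edge list
#'
#' Each non-empty line names one association: a side-A identifier and a
#' side-B identifier separated by `delimiter`. Duplicate lines collapse to a
#' single association (the matrix is 0/1, not a count matrix). Row and
#' column order follow first appearance in the file, so loading is fully
#' reproducible.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator, default tab.
#' @param header logical; if `TRUE` the first line is skipped.
#' @return An [assoc_matrix()].
#' @export
load_edge_list <- function(path, delimiter = "\t", header = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines)) lines <- lines[-1]
  keep <- nzchar(trimws(lines))
  line_no <- which(keep) + as.integer(header)
  lines <- lines[keep]
  if (!length(lines)) stop("empty edge list: ", path)
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(vapply(parts, function(p) length(p) < 2L ||
                        !nzchar(trimws(p[1])) || !nzchar(trimws(p[2])),
                      logical(1)))
  if (length(bad)) {
    stop(sprintf("malformed edge list line %d in %s: %s",
                 line_no[bad[1]], path, lines[bad[1]]))
  }
  a <- trimws(vapply(parts, `[`, character(1), 1L))
  b <- trimws(vapply(parts, `[`, character(1), 2L))
  row_ids <- unique(a)
  col_ids <- unique(b)
  i <- match(a, row_ids)
  j <- match(b, col_ids)
  Y <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(row_ids), length(col_ids)))
  Y@x[] <- 1  # collapse duplicate lines
  assoc_matrix(Y, row_ids, col_ids)
}

#' Write an association matrix as a two-column edge list
#'
#' Inverse of [load_edge_list()]: one line per 1-entry of `Y`, rows emitted
#' in row-major order so that reloading reproduces the same matrix and, for
#' matrices with no all-zero leading rows/columns, the same id order.
#'
#' @param am an [assoc_matrix()].
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @export
write_edge_list <- function(am, path, delimiter = "\t") {
  idx <- Matrix::which(am$Y != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  writeLines(paste(am$row_ids[idx[, 1]], am$col_ids[idx[, 2]],
                   sep = delimiter), path)
}

#' Read/write an association matrix in MatrixMarket format
#'
#' The sparse pattern goes to `<path>` in MatrixMarket coordinate format via
#' [Matrix::writeMM()]; the identifier registries go to two sidecar text
#' files `<path>.rows` and `<path>.cols`, one id per line.
#'
#' @param am an [assoc_matrix()].
#' @param path path of the `.mtx` file.
#' @return `load_assoc_mtx` returns an [assoc_matrix()].
#' @export
write_assoc_mtx <- function(am, path) {
  Matrix::writeMM(am$Y, path)
  writeLines(am$row_ids, paste0(path, ".rows"))
  writeLines(am$col_ids, paste0(path, ".cols"))
  invisible(path)
}

#' @rdname write_assoc_mtx
#' @export
load_assoc_mtx <- function(path) {
  Y <- Matrix::readMM(path)
  assoc_matrix(Y, readLines(paste0(path, ".rows")),
               readLines(paste0(path, ".cols")))
}

#' Candidate pair samples
#'
#' A `pair_samples` object is a data frame with integer columns `row` and
#' `col` (1-based indices into `Y`) and a 0/1 `label` column: label 1 marks a
#' known association, label 0 a sampled potential association.
#'
#' @param row,col integer indices.
#' @param label 0/1 labels.
#' @return A `data.frame` with class `pair_samples` prepended.
#' @export
pair_samples <- function(row, col, label) {
  stopifnot(length(row) == length(col), length(row) == length(label),
            all(label %in% c(0, 1)))
  structure(data.frame(row = as.integer(row), col = as.integer(col),
                       label = as.integer(label)),
            class = c("pair_samples", "data.frame"))
}

#' Positive samples of an association matrix
#'
#' All 1-entries of `Y` as labeled pairs, ordered row-major.
#'
#' @param am an [assoc_matrix()].
#' @return A [pair_samples()] data frame with `label = 1`.
#' @export
positive_pairs <- function(am) {
  idx <- Matrix::which(am$Y != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  pair_samples(idx[, 1], idx[, 2], rep(1L, nrow(idx)))
}

#' Sample negative (potential) association pairs
#'
#' Draws `n` distinct zero cells of `Y` uniformly without replacement. The
#' draw is a pure function of `seed`: the caller's RNG state is left
#' untouched.
#'
#' @param am an [assoc_matrix()].
#' @param n number of pairs to draw.
#' @param seed integer seed.
#' @return A [pair_samples()] data frame with `label = 0`.
#' @export
sample_negative_pairs <- function(am, n, seed) {
  nm <- nrow(am$Y); nd <- ncol(am$Y)
  ones <- Matrix::which(am$Y != 0)
  n_zero <- nm * nd - length(ones)
  if (n > n_zero) {
    stop(sprintf("requested %d negatives but only %d zero cells exist",
                 n, n_zero))
  }
  zeros <- setdiff(seq_len(nm * nd), ones)
  # sample.int avoids R's scalar-x surprise when only one zero cell remains
  pick <- with_seed(seed, zeros[sample.int(length(zeros), n)])
  pair_samples(row = ((pick - 1L) %% nm) + 1L,
               col = ((pick - 1L) %/% nm) + 1L,
               label = rep(0L, n))
}

#' Build a balanced positive/negative sample set
#'
#' Pools every known association with an equal number of uniformly sampled
#' potential associations — the standard balanced design for link-prediction
#' cross-validation.
#'
#' @param am an [assoc_matrix()].
#' @param seed integer seed for the negative draw.
#' @param n_negative optional count of negatives (default: one per positive).
#' @return A [pair_samples()] data frame, positives first.
#' @export
balanced_samples <- function(am, seed, n_negative = NULL) {
  pos <- positive_pairs(am)
  if (is.null(n_negative)) n_negative <- nrow(pos)
  neg <- sample_negative_pairs(am, n_negative, seed)
  out <- rbind(pos, neg)
  class(out) <- c("pair_samples", "data.frame")
  out
}

#' Assign samples to cross-validation folds
#'
#' Random balanced partition: fold sizes differ by at most one and every
#' sample lands in exactly one fold. Deterministic given `seed`.
#'
#' @param samples a [pair_samples()] data frame (or anything with rows).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return A list of class `cv_fold_plan` with `n_folds`, `assignments`
#'   (integer fold index per sample) and `seed`.
#' @export
make_cv_folds <- function(samples, n_folds = 10, seed = 1) {
  n <- nrow(samples)
  if (n_folds < 2) stop("n_folds must be at least 2")
  if (n_folds > n) stop("more folds than samples")
  perm <- with_seed(seed, sample.int(n))
  assignments <- integer(n)
  assignments[perm] <- rep(seq_len(n_folds), length.out = n)
  structure(list(n_folds = as.integer(n_folds), assignments = assignments,
                 seed = as.integer(seed)),
            class = "cv_fold_plan")
}

#' Remove held-out positive edges from the association matrix
#'
#' Cross-validation hygiene: before training, every positive sample of the
#' test fold is zeroed in `Y` so that neither subgraph adjacencies nor node
#' labels can see the edges the model is asked to predict. The input object
#' is left unmodified.
#'
#' @param am an [assoc_matrix()].
#' @param test_samples a [pair_samples()] data frame; rows with `label == 1`
#'   are masked.
#' @return A new [assoc_matrix()] with the test positives set to 0.
#' @export
mask_test_positives <- function(am, test_samples) {
  pos <- test_samples[test_samples$label == 1L, , drop = FALSE]
  if (!nrow(pos)) return(am)
  vals <- am$Y[cbind(pos$row, pos$col)]
  if (any(vals == 0)) {
    bad <- which(vals == 0)[1]
    stop(sprintf("test positive (%d, %d) is not present in Y: split bookkeeping bug",
                 pos$row[bad], pos$col[bad]))
  }
  Y <- am$Y
  Y[cbind(pos$row, pos$col)] <- 0
  assoc_matrix(Matrix::drop0(Y), am$row_ids, am$col_ids)
}

# Run an expression under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
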