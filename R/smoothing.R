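#' Smooth a counts matrix along a neighbor graph
#'
#' Computes `M = A %*% X` in sparse representation: each cell's smoothed
#' profile is the adjacency-weighted combination of its own counts and its
#' neighbors'. With a binary adjacency and `row_normalize = "sum"` (the
#' default) row i of M is the summed counts over cell i and its neighbors — a
#' per-cell mini-pseudobulk that raises abundances and breaks rank ties.
#' `row_normalize = "mean"` divides row i by the i-th row sum of A, which
#' preserves the scale of X for scale-sensitive scores (mean / median /
#' mean-z).
#'
#' @param A Adjacency operator (sparse n x n, from [binary_adjacency()],
#'   [gaussian_connectivities()], or [identity_adjacency()]).
#' @param X Counts for the same n cells (sparse or dense, n x genes).
#' @param row_normalize `"sum"` (plain A X) or `"mean"` (rows of A scaled to
#'   sum 1 first).
#' @return A sparse `dgCMatrix` M of the same shape as X, with attributes
#'   `"mode"` (inherited from A) and `"row_normalize"`.
#' @export
smooth_counts <- function(A, X, row_normalize = c("sum", "mean")) {
  row_normalize <- rlang::arg_match(row_normalize)
  if (nrow(A) != ncol(A)) abort("adjacency matrix must be square")
  if (nrow(A) != nrow(X)) {
    abort(sprintf("adjacency is %dx%d but counts have %d rows",
                  nrow(A), ncol(A), nrow(X)))
  }
  A <- methods::as(A, "CsparseMatrix")
  Xs <- methods::as(methods::as(methods::as(X, "dMatrix"), "generalMatrix"),
                    "CsparseMatrix")
  if (row_normalize == "mean") {
    rs <- Matrix::rowSums(A)
    rs[rs == 0] <- 1
    A <- Matrix::Diagonal(x = 1 / rs) %*% A
  }
  M <- methods::as(A %*% Xs, "CsparseMatrix")
  dimnames(M) <- dimnames(X)
  structure(M, mode = attr(A, "mode") %||% "custom",
            row_normalize = row_normalize)
}

#' Binomial downsampling (thinning) of integer counts
#'
#' Each count `c` is replaced by a draw from Binomial(`c`, `fraction`):
#' every sequenced unit is kept independently with probability `fraction`.
#' The expected total is `fraction` times the original total. Used to
#' emulate shallower sequencing when studying the robustness of scores.
#'
#' @param X Integer counts (sparse or dense cells x genes matrix).
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer; the draw is deterministic per seed.
#' @return A thinned sparse `dgCMatrix` of the same shape.
#' @export
downsample_counts <- function(X, fraction, seed = 0L) {
  stopifnot(fraction > 0, fraction <= 1)
  Xs <- methods::as(methods::as(methods::as(X, "dMatrix"), "generalMatrix"),
                    "CsparseMatrix")
  if (length(Xs@x) && any(Xs@x != round(Xs@x))) {
    abort("downsampling is defined on integer counts only")
  }
  if (fraction == 1) return(Xs)
  withr::with_seed(seed, {
    Xs@x <- as.numeric(rbinom(length(Xs@x), size = as.integer(round(Xs@x)),
                              prob = fraction))
  })
  Matrix::drop0(Xs)
}
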