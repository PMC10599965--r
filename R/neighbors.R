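#' Embed cells for neighbor search
#'
#' Standard preprocessing ahead of KNN graph construction: total-count
#' normalization to the median cell depth, `log1p`, per-gene centering and
#' unit-variance scaling (variance-zero genes dropped), then exact truncated
#' PCA. Distances between cells are computed in this PCA space.
#'
#' @param x An [expression_dataset()] or a cells x genes matrix.
#' @param n_components Number of principal components (default 50). Clipped
#'   with a warning when it reaches `min(n_cells, n_variable_genes)`.
#' @param seed Kept for interface stability; the decomposition is exact and
#'   deterministic, so the seed is not consumed.
#' @return A numeric matrix, cells x `n_components`, with attribute
#'   `"representation"` describing the embedding.
#' @export
embed_cells <- function(x, n_components = 50L, seed = 0L) {
  X <- if (inherits(x, "expr_dataset")) x$counts else x
  n <- nrow(X)
  if (n < 3) abort("embedding needs at least 3 cells")
  stopifnot(n_components >= 2)
  X <- as.matrix(X)

  depth <- rowSums(X)
  target <- median(depth[depth > 0])
  scale_f <- ifelse(depth > 0, target / depth, 0)
  Xn <- log1p(X * scale_f)

  v <- apply(Xn, 2, stats::var)
  keep <- which(v > 0)
  if (!length(keep)) abort("no variable genes: all genes have zero variance")
  Xs <- scale(Xn[, keep, drop = FALSE])

  k_max <- min(n, length(keep)) - 1L
  if (n_components > k_max) {
    warn(sprintf("n_components clipped from %d to %d (min dimension limit)",
                 n_components, k_max))
    n_components <- k_max
  }

  # Exact PCA via the smaller Gram matrix: cheap and deterministic at the
  # group sizes smoothing operates on.
  if (length(keep) <= n) {
    C <- crossprod(Xs) / (n - 1)
    eig <- eigen(C, symmetric = TRUE)
    emb <- Xs %*% eig$vectors[, seq_len(n_components), drop = FALSE]
  } else {
    G <- tcrossprod(Xs)
    eig <- eigen(G, symmetric = TRUE)
    lam <- pmax(eig$values[seq_len(n_components)], 0)
    emb <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
      diag(sqrt(lam), n_components)
  }
  dimnames(emb) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  attr(emb, "representation") <-
    sprintf("median-depth norm + log1p + scaled + PCA(%d)", n_components)
  emb
}

#' Build an exact K-nearest-neighbor graph
#'
#' Euclidean K nearest neighbors per cell, self excluded, computed by exact
#' blockwise search. Distance ties are broken toward the lower cell index, so
#' the neighbor lists are deterministic and nested in K: the first `K'`
#' neighbors for any `K' < K` are a prefix of the list.
#'
#' @param embedding Cells x dims coordinate matrix (see [embed_cells()]).
#' @param K Neighbors per cell, excluding self. Clipped to `n - 1` with a
#'   warning when it reaches the group size.
#' @param seed Kept for interface stability; the exact search does not
#'   consume randomness.
#' @return An object of class `neighbor_graph`: list with `n`, `K`,
#'   `idx` (n x K integer matrix), `dist` (n x K, non-decreasing along each
#'   row), and `representation`.
#' @export
build_knn <- function(embedding, K, seed = 0L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  stopifnot(K >= 0)
  if (n == 1L || K == 0L) {
    g <- list(n = n, K = 0L,
              idx = matrix(integer(), n, 0),
              dist = matrix(numeric(), n, 0),
              representation = attr(embedding, "representation") %||% "given")
    return(structure(g, class = "neighbor_graph"))
  }
  if (K >= n) {
    warn(sprintf("K clipped from %d to %d (group size %d)", K, n - 1L, n))
    K <- n - 1L
  }
  K <- as.integer(K)

  sq <- rowSums(embedding^2)
  idx <- matrix(0L, n, K)
  dst <- matrix(0, n, K)
  block <- max(1L, min(n, as.integer(2^24 / n)))
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, `+`) -
      2 * tcrossprod(embedding[rows, , drop = FALSE], embedding)
    d2[d2 < 0] <- 0
    for (r in seq_along(rows)) {
      i <- rows[r]
      di <- d2[r, ]
      di[i] <- Inf                       # self never a neighbor
      ord <- order(di)[seq_len(K)]       # stable: ties go to the lower index
      idx[i, ] <- ord
      dst[i, ] <- sqrt(di[ord])
    }
  }
  structure(list(n = n, K = K, idx = idx, dist = dst,
                 representation = attr(embedding, "representation") %||% "given"),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d cells, K=%d (%s)\n",
              x$n, x$K, x$representation))
  invisible(x)
}

edge_triplets <- function(g) {
  list(i = rep.int(seq_len(g$n), g$K),
       j = as.vector(g$idx),
       d = as.vector(g$dist))
}

#' Density-adjusted Gaussian connectivity weights
#'
#' Converts a neighbor graph into a weighted adjacency operator. Each cell
#' gets a local bandwidth equal to its distance to its K-th listed neighbor
#' (wide in sparse regions, narrow in dense ones), and each directed edge
#' gets weight `exp(-d_ij^2 / (sigma_i * sigma_j))`. The matrix is
#' symmetrized by taking the maximum over the two directions of every edge,
#' and the diagonal (each cell's own weight) is fixed at 1 so smoothing never
#' discards a cell's own measurements.
#'
#' Degenerate bandwidths are repaired: a zero bandwidth (K-th neighbor
#' coincident) is replaced by the smallest positive neighbor distance in the
#' group; if every distance is zero all weights are 1.
#'
#' @param g A [build_knn()] graph with at least one neighbor per cell.
#' @return A symmetric sparse `dgCMatrix` with unit diagonal and off-diagonal
#'   entries in (0, 1]; attribute `"mode"` is `"connectivity"`.
#' @export
gaussian_connectivities <- function(g) {
  stopifnot(inherits(g, "neighbor_graph"))
  if (g$K < 1) return(identity_adjacency(g$n))
  sigma <- g$dist[, g$K]
  if (any(sigma == 0)) {
    pos <- g$dist[g$dist > 0]
    if (length(pos)) {
      sigma[sigma == 0] <- min(pos)
    } else {
      sigma[] <- 1  # all points coincident: uniform weights
    }
  }
  tr <- edge_triplets(g)
  w <- exp(-tr$d^2 / (sigma[tr$i] * sigma[tr$j]))
  A <- symmetrize_max(tr$i, tr$j, w, g$n)
  Matrix::diag(A) <- 1
  structure(methods::as(A, "CsparseMatrix"), mode = "connectivity")
}

#' Binary adjacency from a neighbor graph
#'
#' `A[i, j] = 1` iff `j` is in `i`'s neighbor list or `i` is in `j`'s (union
#' symmetrization), plus a unit diagonal. With this operator smoothing sums
#' raw counts over each cell's neighborhood (a per-cell mini-pseudobulk).
#'
#' @param g A [build_knn()] graph.
#' @return A symmetric binary sparse `dgCMatrix` with unit diagonal;
#'   attribute `"mode"` is `"binary"`.
#' @export
binary_adjacency <- function(g) {
  stopifnot(inherits(g, "neighbor_graph"))
  if (g$K < 1) return(structure(identity_adjacency(g$n), mode = "binary"))
  tr <- edge_triplets(g)
  A <- Matrix::sparseMatrix(i = c(tr$i, tr$j, seq_len(g$n)),
                            j = c(tr$j, tr$i, seq_len(g$n)),
                            x = 1, dims = c(g$n, g$n))
  A <- methods::as(A, "CsparseMatrix")
  A@x[] <- 1  # collapse summed duplicates to presence
  structure(A, mode = "binary")
}

#' Identity adjacency (smoothing off)
#'
#' @param n Number of cells.
#' @return An n x n sparse identity matrix with attribute `"mode" = "off"`.
#' @export
identity_adjacency <- function(n) {
  A <- methods::as(methods::as(Matrix::Diagonal(n), "generalMatrix"),
                   "CsparseMatrix")
  structure(A, mode = "off")
}

# max-aggregated symmetric sparse matrix from directed edge triplets
symmetrize_max <- function(i, j, w, n) {
  ii <- c(i, j)
  jj <- c(j, i)
  ww <- c(w, w)
  key <- (ii - 1) * n + jj
  ord <- order(key, -ww)
  first <- !duplicated(key[ord])
  sel <- ord[first]
  Matrix::sparseMatrix(i = ii[sel], j = jj[sel], x = ww[sel], dims = c(n, n))
}
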