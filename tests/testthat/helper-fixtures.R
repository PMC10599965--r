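# Small programmatic fixtures shared across the suite.

random_sparse_counts <- function(n_cells, n_genes, density = 0.3,
                                 max_count = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nnz <- rbinom(1, n_cells * n_genes, density)
  i <- sample.int(n_cells * n_genes, nnz)
  x <- numeric(n_cells * n_genes)
  x[i] <- sample.int(max_count, nnz, replace = TRUE)
  Matrix::Matrix(matrix(x, n_cells, n_genes), sparse = TRUE)
}

toy_dataset <- function(n_cells = 12, n_genes = 8, seed = 42,
                        groups = rep(c("g1", "g2"), length.out = n_cells)) {
  X <- random_sparse_counts(n_cells, n_genes, seed = seed)
  gene_ids <- paste0("G", seq_len(n_genes))
  cell_ids <- paste0("C", seq_len(n_cells))
  expression_dataset(X, gene_ids, cell_ids,
                     tibble::tibble(cell_id = cell_ids, grp = groups))
}

write_gmt_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# All permutations of 1..n (n small), as a list of integer vectors.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# All non-empty proper subsets of 1..n, as a list of integer vectors.
all_proper_subsets <- function(n) {
  out <- list()
  for (m in seq_len(2^n - 2)) {
    out[[m]] <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
  }
  out
}
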