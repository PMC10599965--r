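#' Construct an expression dataset
#'
#' The core container: a sparse cells x genes matrix of non-negative counts
#' (raw or normalized), ordered gene and cell identifiers, and a cell
#' annotation table with one row per cell in matrix row order.
#'
#' @param counts A matrix or sparse Matrix, cells in rows, genes in columns.
#'   Entries must be non-negative; non-integer values are allowed (smoothed or
#'   renormalized counts are re-scored as-is).
#' @param gene_ids Character vector of unique gene identifiers, one per column.
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#' @param annotations A data frame with a `cell_id` column covering every cell
#'   id. Rows are reordered to match `cell_ids`. If `NULL`, a bare table with
#'   only `cell_id` is created.
#'
#' @return An object of class `expr_dataset`: a list with elements `counts`
#'   (`dgCMatrix`), `gene_ids`, `cell_ids`, and `annotations` (tibble).
#' @export
expression_dataset <- function(counts, gene_ids, cell_ids, annotations = NULL) {
  counts <- as(as(as(counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) != length(cell_ids)) {
    abort(sprintf("counts has %d rows but %d cell ids were given",
                  nrow(counts), length(cell_ids)))
  }
  if (ncol(counts) != length(gene_ids)) {
    abort(sprintf("counts has %d columns but %d gene ids were given",
                  ncol(counts), length(gene_ids)))
  }
  if (length(counts@x) && min(counts@x) < 0) {
    abort("counts must be non-negative")
  }
  if (anyDuplicated(gene_ids)) {
    abort(sprintf("duplicate gene ids (e.g. '%s')",
                  gene_ids[duplicated(gene_ids)][1]))
  }
  if (anyDuplicated(cell_ids)) {
    abort(sprintf("duplicate cell ids (e.g. '%s')",
                  cell_ids[duplicated(cell_ids)][1]))
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  dimnames(counts) <- list(cell_ids, gene_ids)

  if (is.null(annotations)) {
    annotations <- tibble(cell_id = cell_ids)
  } else {
    annotations <- as_tibble(annotations)
    if (!"cell_id" %in% names(annotations)) {
      abort("annotations must contain a 'cell_id' column")
    }
    annotations$cell_id <- as.character(annotations$cell_id)
    missing <- setdiff(cell_ids, annotations$cell_id)
    if (length(missing)) {
      abort(sprintf("annotations missing %d cell id(s), e.g. '%s'",
                    length(missing), missing[1]))
    }
    if (anyDuplicated(annotations$cell_id)) {
      abort("annotations must have exactly one row per cell_id")
    }
    annotations <- annotations[match(cell_ids, annotations$cell_id), , drop = FALSE]
  }

  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         annotations = annotations),
    class = "expr_dataset"
  )
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %d cells x %d genes (%.1f%% nonzero)\n",
              length(x$cell_ids), length(x$gene_ids),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  extra <- setdiff(names(x$annotations), "cell_id")
  if (length(extra)) {
    cat("annotations:", paste(extra, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$counts)

#' Load an expression dataset from MTX + ID files + annotation TSV
#'
#' Reads a Matrix Market counts file with matching gene/cell identifier files
#' (one id per line) and a TSV annotation table keyed by `cell_id`. The
#' orientation is decided by matching MTX dimensions against the two id file
#' lengths: a genes x cells matrix (the common 10x convention) is transposed
#' to cells x genes. A square matrix is ambiguous and requires an explicit
#' `orientation`.
#'
#' @param counts_path Path to the MTX file.
#' @param genes_path,cells_path Paths to one-id-per-line text files.
#' @param annotations_path Optional path to a TSV with header and a `cell_id`
#'   column covering all cells.
#' @param orientation `"auto"` (default), `"cells_by_genes"`, or
#'   `"genes_by_cells"`.
#' @return An [expression_dataset()].
#' @export
load_dataset <- function(counts_path, genes_path, cells_path,
                         annotations_path = NULL,
                         orientation = c("auto", "cells_by_genes", "genes_by_cells")) {
  orientation <- rlang::arg_match(orientation)
  for (p in c(counts_path, genes_path, cells_path, annotations_path)) {
    if (!file.exists(p)) abort(sprintf("file not found: %s", p))
  }
  m <- Matrix::readMM(counts_path)
  gene_ids <- read_id_file(genes_path)
  cell_ids <- read_id_file(cells_path)
  ng <- length(gene_ids)
  nc <- length(cell_ids)

  fits_cg <- nrow(m) == nc && ncol(m) == ng
  fits_gc <- nrow(m) == ng && ncol(m) == nc
  if (orientation == "auto") {
    if (fits_cg && fits_gc) {
      abort(paste0("counts matrix is square (", nrow(m), "x", ncol(m), "); ",
                   "orientation is ambiguous - pass orientation = ",
                   "'cells_by_genes' or 'genes_by_cells' explicitly"))
    } else if (fits_cg) {
      orientation <- "cells_by_genes"
    } else if (fits_gc) {
      orientation <- "genes_by_cells"
    } else {
      abort(sprintf(
        "dimension mismatch: %s is %dx%d but %s has %d ids and %s has %d ids",
        counts_path, nrow(m), ncol(m), genes_path, ng, cells_path, nc))
    }
  }
  if (orientation == "genes_by_cells") {
    if (!fits_gc) abort(sprintf(
      "dimension mismatch: %s is %dx%d, expected %d genes x %d cells",
      counts_path, nrow(m), ncol(m), ng, nc))
    m <- Matrix::t(m)
  } else if (!fits_cg) {
    abort(sprintf(
      "dimension mismatch: %s is %dx%d, expected %d cells x %d genes",
      counts_path, nrow(m), ncol(m), nc, ng))
  }

  ann <- NULL
  if (!is.null(annotations_path)) {
    ann <- readr::read_tsv(annotations_path, show_col_types = FALSE,
                           progress = FALSE)
  }
  expression_dataset(m, gene_ids, cell_ids, ann)
}

read_id_file <- function(path) {
  ids <- readLines(path)
  ids <- sub("\r$", "", ids)
  ids <- ids[nzchar(ids)]
  # 10x-style features files carry extra tab-separated columns; the first is
  # the identifier.
  vapply(strsplit(ids, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write an expression dataset as MTX + ID files + annotation TSV
#'
#' Inverse of [load_dataset()]: writes `matrix.mtx`, `genes.txt`, `cells.txt`
#' and `annotations.tsv` (cells x genes orientation) into `dir`.
#'
#' @param ds An [expression_dataset()].
#' @param dir Output directory, created if needed.
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "expr_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "matrix.mtx"),
             genes = file.path(dir, "genes.txt"),
             cells = file.path(dir, "cells.txt"),
             annotations = file.path(dir, "annotations.tsv"))
  Matrix::writeMM(ds$counts, paths[["counts"]])
  writeLines(ds$gene_ids, paths[["genes"]])
  writeLines(ds$cell_ids, paths[["cells"]])
  readr::write_tsv(ds$annotations, paths[["annotations"]], progress = FALSE)
  invisible(paths)
}
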