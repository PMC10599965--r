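#' Partition cells by annotation columns
#'
#' Cells are split by the observed combinations of the `groupby` annotation
#' columns. Graph construction and smoothing never mix cells across groups.
#' Missing values form their own `"(missing)"` group rather than being
#' dropped, so every cell belongs to exactly one group. An empty `groupby`
#' yields a single group holding all cells.
#'
#' @param ds An [expression_dataset()].
#' @param groupby Character vector of annotation column names (may be empty).
#' @return A tibble with one row per group: `group_key` (string, values
#'   joined by `"|"`), `n_cells`, and `idx` (list-column of integer cell
#'   indices into the dataset's row order).
#' @export
split_by_groupby <- function(ds, groupby = character()) {
  stopifnot(inherits(ds, "expr_dataset"))
  n <- length(ds$cell_ids)
  if (!length(groupby)) {
    return(tibble(group_key = "(all)", n_cells = n, idx = list(seq_len(n))))
  }
  unknown <- setdiff(groupby, names(ds$annotations))
  if (length(unknown)) {
    abort(sprintf("unknown groupby column '%s'; available columns: %s",
                  unknown[1],
                  paste(setdiff(names(ds$annotations), "cell_id"),
                        collapse = ", ")))
  }
  cols <- lapply(groupby, function(cn) {
    v <- as.character(ds$annotations[[cn]])
    v[is.na(v)] <- "(missing)"
    v
  })
  key <- do.call(paste, c(cols, sep = "|"))
  idx <- split(seq_len(n), key)
  tibble(group_key = names(idx),
         n_cells = lengths(idx),
         idx = unname(idx))
}

#' Apply a function independently per group and merge results
#'
#' `per_group_fn(idx, group_key, smooth_allowed)` is called once per group
#' with the group's cell indices and must return a numeric matrix with
#' `length(idx)` rows (cells, in `idx` order) and named score columns. Group
#' computations share no state, so they may legally run in any order or in
#' parallel; results are merged back into the original cell order. Groups
#' smaller than `min_group_size` are passed `smooth_allowed = FALSE` (scored
#' with smoothing forced off) and flagged in the log. A group whose function
#' throws gets missing values for all its cells; other groups are unaffected
#' and the failure is recorded.
#'
#' @param groups A group table from [split_by_groupby()].
#' @param per_group_fn Function of `(idx, group_key, smooth_allowed)`.
#' @param n_cells Total number of cells (defines output row count).
#' @param min_group_size Below this size smoothing is disabled (default 5).
#' @return A list: `scores` (numeric matrix, `n_cells` rows, original order)
#'   and `failures` (tibble of `group_key`, `message`).
#' @export
process_groups <- function(groups, per_group_fn, n_cells,
                           min_group_size = 5L) {
  out <- NULL
  failures <- list()
  for (g in seq_len(nrow(groups))) {
    idx <- groups$idx[[g]]
    key <- groups$group_key[g]
    smooth_allowed <- length(idx) >= min_group_size
    if (!smooth_allowed) {
      log_record("small_group", group = key, size = length(idx))
    }
    res <- tryCatch(
      per_group_fn(idx, key, smooth_allowed),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      log_record("group_failed", group = key, message = conditionMessage(res))
      failures[[length(failures) + 1L]] <-
        tibble(group_key = key, message = conditionMessage(res))
      next
    }
    res <- as.matrix(res)
    if (nrow(res) != length(idx)) {
      abort(sprintf("per_group_fn returned %d rows for group '%s' of size %d",
                    nrow(res), key, length(idx)))
    }
    if (is.null(out)) {
      out <- matrix(NA_real_, n_cells, ncol(res),
                    dimnames = list(NULL, colnames(res)))
    }
    out[idx, ] <- res
  }
  if (is.null(out)) out <- matrix(NA_real_, n_cells, 0L)
  list(scores = out,
       failures = if (length(failures)) dplyr::bind_rows(failures)
                  else tibble(group_key = character(), message = character()))
}
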