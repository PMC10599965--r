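#' Score every cell against gene sets on neighbor-smoothed counts
#'
#' The full pipeline, applied independently within each annotation group:
#' restrict gene sets to the measured universe, embed the group's cells
#' ([embed_cells()]), build the KNN graph ([build_knn()]), form the adjacency
#' operator (binary, density-adjusted Gaussian connectivities, or identity),
#' smooth the counts (`M = AX`, [smooth_counts()]), and score each cell with
#' the chosen single-sample statistic ([score_profile()] methods).
#'
#' Groups smaller than `min_group_size` are scored with smoothing forced off
#' and flagged; a group whose computation fails yields missing scores for its
#' cells without affecting other groups. Output rows are always in the
#' dataset's original cell order, independent of grouping.
#'
#' @param ds An [expression_dataset()].
#' @param genesets A [gene_set()] or list of them.
#' @param method Scoring function name; see [score_profile()].
#' @param groupby Character vector of annotation columns partitioning cells
#'   before graph construction (default none: one graph over all cells).
#' @param smooth_mode `"connectivity"` (default), `"binary"`, or `"off"`.
#' @param knn Neighbors per cell, excluding self (default 32; clipped to
#'   group size - 1).
#' @param n_components PCA dimensions for the embedding (default 50).
#' @param row_normalize `"auto"` (default: rows of A scaled to mean for the
#'   scale-sensitive methods `average_score`/`median_score`/`mean_z_score`,
#'   plain sums for the rank-based ones), `"sum"`, or `"mean"`.
#' @param min_group_size Below this group size smoothing is disabled
#'   (default 5).
#' @param seed Integer seed forwarded to the graph stages.
#' @inheritParams score_profile
#' @return A tibble of class `score_table`: `cell_id` plus one column per
#'   gene set named `"<set>__<method>"`, in the original cell order, with a
#'   `run_info` attribute (effective parameters, per-group sizes and K used,
#'   set coverages, failures).
#' @export
score_cells <- function(ds, genesets, method = "singscore",
                        groupby = character(),
                        smooth_mode = c("connectivity", "binary", "off"),
                        knn = 32L, n_components = 50L,
                        row_normalize = c("auto", "sum", "mean"),
                        alpha = 0.75, rbo_p = 0.9, rbo_depth = NULL,
                        threshold = 0, as_fraction = FALSE,
                        min_group_size = 5L, seed = 0L) {
  stopifnot(inherits(ds, "expr_dataset"))
  smooth_mode <- rlang::arg_match(smooth_mode)
  row_normalize <- rlang::arg_match(row_normalize)
  method <- rlang::arg_match(method, c("singscore", "ssgsea",
                                       "rank_biased_overlap", "mean_z_score",
                                       "average_score", "median_score",
                                       "summed_up", "geneset_overlap"))
  if (inherits(genesets, "gene_set")) genesets <- list(genesets)
  stopifnot(length(genesets) > 0)

  rn_eff <- if (row_normalize != "auto") row_normalize
            else if (method %in% c("average_score", "median_score",
                                   "mean_z_score")) "mean" else "sum"
  if (row_normalize == "auto") {
    log_record("row_normalize", effective = rn_eff, method = method)
  }

  restricted <- lapply(genesets, restrict_to_universe, universe = ds$gene_ids)
  set_names <- vapply(genesets, function(s) s$name, character(1))
  set_info <- tibble(
    set = set_names,
    coverage = vapply(restricted, `[[`, numeric(1), "coverage"),
    scorable = vapply(restricted, `[[`, logical(1), "scorable"))
  up_idx <- lapply(restricted, function(r) {
    if (r$scorable) which(ds$gene_ids %in% r$set$up) else integer()
  })
  down_idx <- lapply(restricted, function(r) {
    if (r$scorable) which(ds$gene_ids %in% r$set$down) else integer()
  })

  groups <- split_by_groupby(ds, groupby)
  n_cells <- length(ds$cell_ids)

  # Smooth each group once; failures are isolated and surface as missing
  # scores for that group's cells.
  cache <- vector("list", nrow(groups))
  fail_msg <- rep(NA_character_, nrow(groups))
  K_used <- integer(nrow(groups))
  for (g in seq_len(nrow(groups))) {
    idx <- groups$idx[[g]]
    allowed <- smooth_mode != "off" && length(idx) >= min_group_size
    res <- tryCatch(
      smooth_group(ds$counts[idx, , drop = FALSE], smooth_mode, knn,
                   n_components, rn_eff, allowed, seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      fail_msg[g] <- conditionMessage(res)
      log_record("group_failed", group = groups$group_key[g],
                 message = fail_msg[g])
    } else {
      cache[[g]] <- res$M
      K_used[g] <- res$K_used
      log_record("group", group = groups$group_key[g],
                 size = length(idx), K_used = res$K_used)
    }
  }

  gene_means <- gene_sds <- NULL
  if (method == "mean_z_score") {
    ok <- which(is.na(fail_msg))
    if (!length(ok)) abort("mean_z_score: smoothing failed for every group")
    Mall <- do.call(rbind, cache[ok])
    mu <- colMeans(Mall)
    sq <- colMeans(Mall^2)
    n_ok <- nrow(Mall)
    sdv <- sqrt(pmax(sq - mu^2, 0) * n_ok / max(n_ok - 1, 1))
    gene_means <- setNames(mu, ds$gene_ids)
    gene_sds <- setNames(sdv, ds$gene_ids)
  }

  per_group_fn <- function(idx, key, smooth_allowed) {
    g <- match(key, groups$group_key)
    if (!is.na(fail_msg[g])) abort(fail_msg[g])
    M <- cache[[g]]
    out <- matrix(NA_real_, length(idx), length(genesets),
                  dimnames = list(NULL, paste0(set_names, "__", method)))
    for (s in seq_along(genesets)) {
      if (!set_info$scorable[s]) next
      for (i in seq_len(nrow(M))) {
        out[i, s] <- score_idx(M[i, ], up_idx[[s]], down_idx[[s]], method,
                               alpha = alpha, rbo_p = rbo_p,
                               rbo_depth = rbo_depth, threshold = threshold,
                               as_fraction = as_fraction,
                               gene_means = gene_means, gene_sds = gene_sds,
                               gene_names = ds$gene_ids)
      }
    }
    out
  }

  merged <- process_groups(groups, per_group_fn, n_cells,
                           min_group_size = min_group_size)
  res <- dplyr::bind_cols(tibble(cell_id = ds$cell_ids),
                          as_tibble(merged$scores))
  n_unscorable <- sum(!set_info$scorable)
  if (n_unscorable) {
    warn(sprintf("%d gene set(s) had no measured genes and were not scored: %s",
                 n_unscorable,
                 paste(set_info$set[!set_info$scorable], collapse = ", ")))
  }
  attr(res, "run_info") <- list(
    method = method, smooth_mode = smooth_mode, row_normalize = rn_eff,
    knn = knn, n_components = n_components, seed = seed,
    alpha = alpha, rbo_p = rbo_p, threshold = threshold,
    min_group_size = min_group_size, groupby = groupby,
    groups = tibble(group_key = groups$group_key, n_cells = groups$n_cells,
                    K_used = K_used, failed = !is.na(fail_msg)),
    sets = set_info,
    failures = merged$failures)
  class(res) <- c("score_table", class(res))
  res
}

smooth_group <- function(Xg, smooth_mode, knn, n_components, row_normalize,
                         smooth_allowed, seed) {
  n <- nrow(Xg)
  if (!smooth_allowed || smooth_mode == "off" || knn < 1 || n == 1) {
    return(list(M = as.matrix(Xg), K_used = 0L))
  }
  K <- min(knn, n - 1L)
  if (n < 3) {
    emb <- as.matrix(Xg)  # too few cells to embed: all-pairs graph in raw space
  } else {
    emb <- tryCatch(
      embed_cells(Xg, n_components = min(n_components, n - 1L), seed = seed),
      error = function(e) NULL)
    if (is.null(emb)) {
      # nothing to embed (e.g. constant counts): no structure to smooth along
      log_record("smoothing_skipped", reason = "embedding degenerate", size = n)
      return(list(M = as.matrix(Xg), K_used = 0L))
    }
  }
  g <- build_knn(emb, K, seed = seed)
  A <- if (smooth_mode == "binary") binary_adjacency(g)
       else gaussian_connectivities(g)
  M <- smooth_counts(A, Xg, row_normalize)
  list(M = as.matrix(M), K_used = as.integer(K))
}

#' @export
print.score_table <- function(x, ...) {
  info <- attr(x, "run_info")
  cat(sprintf("<score_table> %d cells, method=%s, smooth_mode=%s, K=%d\n",
              nrow(x), info$method, info$smooth_mode, info$knn))
  NextMethod()
}
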