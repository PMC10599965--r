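#' Simulate two cell populations with a planted marker signature
#'
#' Negative-binomial scRNA-seq counts for two labeled populations, A and B.
#' Per-gene baseline means are drawn log-normally around `base_mean`,
#' per-cell size factors log-normally with spread `depth_variation`, and
#' counts follow `NB(mean = s_j * mu_gi, dispersion)` with
#' `variance = mu + mu^2 / dispersion`. A marker gene set — drawn from the
#' mid-expression stratum, so its genes are neither saturated nor absent and
#' smoothing has signal to recover — has its mean multiplied by
#' `fold_change` in population B only. `fold_change = 1` gives exchangeable
#' populations (the null). `dispersion = Inf` gives the Poisson limit.
#'
#' @param n_cells_a,n_cells_b Cells per population (defaults 1000 each).
#' @param n_genes Number of genes (default 1000).
#' @param marker_genes Number of marker genes (default 40).
#' @param fold_change Marker mean multiplier in population B (> 0;
#'   default 1.5).
#' @param base_mean Median per-gene baseline mean count (default 0.5).
#' @param dispersion NB dispersion (default 2; `Inf` = Poisson).
#' @param depth_variation sdlog of the per-cell size factors (default 0.35).
#' @param seed Integer; identical seeds give bit-identical fixtures.
#' @return A list: `dataset` (an [expression_dataset()] whose annotations
#'   carry `population` in {"A","B"}), `markers` (the planted [gene_set()]),
#'   and `params`.
#' @export
simulate_two_populations <- function(n_cells_a = 1000L, n_cells_b = 1000L,
                                     n_genes = 1000L, marker_genes = 40L,
                                     fold_change = 1.5, base_mean = 0.5,
                                     dispersion = 2, depth_variation = 0.35,
                                     seed = 1L) {
  if (fold_change <= 0) abort("fold_change must be > 0")
  stopifnot(n_cells_a >= 1, n_cells_b >= 1, n_genes >= marker_genes,
            marker_genes >= 1, base_mean > 0, dispersion > 0,
            depth_variation >= 0)
  n_cells <- n_cells_a + n_cells_b
  withr::with_seed(seed, {
    mu_g <- rlnorm(n_genes, meanlog = log(base_mean), sdlog = 1)
    # markers from the middle expression tertile
    ord <- order(mu_g)
    mid <- ord[seq.int(floor(n_genes / 3) + 1L, ceiling(2 * n_genes / 3))]
    marker_idx <- sort(sample(mid, marker_genes))
    s_j <- rlnorm(n_cells, meanlog = 0, sdlog = depth_variation)
    pop <- rep(c("A", "B"), c(n_cells_a, n_cells_b))

    mu_mat <- outer(s_j, mu_g)                        # cells x genes
    b_rows <- which(pop == "B")
    mu_mat[b_rows, marker_idx] <- mu_mat[b_rows, marker_idx] * fold_change
    counts <- if (is.infinite(dispersion)) {
      rpois(length(mu_mat), lambda = mu_mat)
    } else {
      rnbinom(length(mu_mat), size = dispersion, mu = mu_mat)
    }
    counts <- matrix(as.numeric(counts), n_cells, n_genes)
  })
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  ds <- expression_dataset(
    Matrix::Matrix(counts, sparse = TRUE), gene_ids, cell_ids,
    tibble(cell_id = cell_ids, population = pop))
  list(dataset = ds,
       markers = gene_set("markers", up = gene_ids[marker_idx]),
       params = list(n_cells_a = n_cells_a, n_cells_b = n_cells_b,
                     n_genes = n_genes, marker_genes = marker_genes,
                     fold_change = fold_change, base_mean = base_mean,
                     dispersion = dispersion,
                     depth_variation = depth_variation, seed = seed))
}

#' Score separation under count downsampling, across smoothing levels
#'
#' For every combination of keep-fraction and K: binomially thin the counts
#' ([downsample_counts()]), rebuild the embedding and KNN graph on the
#' thinned data, re-smooth, re-score, and measure the marker-set AUC between
#' the labeled populations ([auc_separation()]). `K = 0` means smoothing off.
#' A fully degenerate thinned matrix (all scores tied) gives AUC 0.5, not an
#' error.
#'
#' @param ds An [expression_dataset()] whose annotations contain `label_col`.
#' @param gs The marker [gene_set()] to score.
#' @param fractions Numeric keep-fractions in (0, 1].
#' @param k_values Integer K grid (0 = unsmoothed).
#' @param method Scoring function (default `"summed_up"`).
#' @param smooth_mode Adjacency mode for K > 0 (default `"connectivity"`).
#' @param label_col Annotation column with the two population labels.
#' @param positive Label value treated as positive (default: larger value).
#' @param seed Integer seed driving the thinning draws.
#' @param ... Further arguments passed to [score_cells()].
#' @return A tibble of class `robustness_curve` with columns `fraction`,
#'   `K`, and `auc`, one row per grid point.
#' @export
run_robustness_curve <- function(ds, gs, fractions = c(0.95, 0.5, 0.2, 0.1, 0.05),
                                 k_values = c(0L, 32L), method = "summed_up",
                                 smooth_mode = "connectivity",
                                 label_col = "population", positive = NULL,
                                 seed = 1L, ...) {
  stopifnot(inherits(ds, "expr_dataset"))
  if (!label_col %in% names(ds$annotations)) {
    abort(sprintf("label column '%s' not found in annotations", label_col))
  }
  labels <- ds$annotations[[label_col]]
  rows <- list()
  for (f in fractions) {
    thinned <- if (f == 1) ds else {
      expression_dataset(downsample_counts(ds$counts, f, seed = seed),
                         ds$gene_ids, ds$cell_ids, ds$annotations)
    }
    for (K in k_values) {
      st <- score_cells(thinned, gs, method = method,
                        smooth_mode = if (K == 0) "off" else smooth_mode,
                        knn = as.integer(K), seed = seed, ...)
      scores <- st[[paste0(gs$name, "__", method)]]
      rows[[length(rows) + 1L]] <- tibble(
        fraction = f, K = as.integer(K),
        auc = auc_separation(scores, labels, positive = positive))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("robustness_curve", class(out))
  out
}
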