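#' Rank a single expression profile
#'
#' Ascending ranks (rank 1 = lowest expression) with average-rank tie
#' handling, so the shared zeros of sparse profiles all receive one average
#' rank and scores are invariant to the input order of genes. The rank sum is
#' always exactly `N(N+1)/2`.
#'
#' @param values Named numeric vector: one cell's expression over the
#'   measured genes.
#' @return An object of class `ranked_profile`: list with `values`, `ranks`,
#'   and `gene_ids` ordered by decreasing expression (ties by input position).
#' @export
rank_profile <- function(values) {
  ranks <- rank(values, ties.method = "average")
  ord <- order(values, decreasing = TRUE)
  structure(list(values = values, ranks = ranks,
                 gene_ids = names(values)[ord]),
            class = "ranked_profile")
}

#' Score one expression profile against a gene set
#'
#' The per-cell primitive behind [score_cells()]: maps one (smoothed)
#' expression profile and a gene set to a single number. The set is first
#' restricted to the measured genes (`names(values)`); a set with no
#' measured genes yields `NA`, never zero.
#'
#' Methods, each direction-aware for two-part sets:
#' \describe{
#'   \item{`summed_up`}{Sum of the ranks of the up-genes minus the rank sum
#'     of the down-genes.}
#'   \item{`average_score`, `median_score`}{Mean / median expression over the
#'     up-genes minus the same statistic over the down-genes.}
#'   \item{`mean_z_score`}{Mean per-gene z-score (against population gene
#'     means/sds supplied via `gene_means`/`gene_sds`) over the up-genes,
#'     minus the down-gene mean z; sd-zero genes are excluded.}
#'   \item{`geneset_overlap`}{Number (or fraction, `as_fraction`) of measured
#'     set genes expressed above `threshold`.}
#'   \item{`singscore`}{Normalized mean rank in \[0, 1\] per direction
#'     (down-genes against the reversed ranking); two-part total is
#'     `up + down - 1` in \[-1, 1\], single-direction sets report
#'     `score - 0.5` in \[-0.5, 0.5\].}
#'   \item{`ssgsea`}{Integrated weighted running sum over the
#'     decreasing-expression ordering with exponent `alpha`; two-part sets
#'     score `up - down`.}
#'   \item{`rank_biased_overlap`}{Geometrically top-weighted overlap between
#'     the expression ranking and the set, truncated at `rbo_depth` (default
#'     the measured set size) and normalized so a perfect prefix scores 1;
#'     two-part sets score up minus down-on-reversed-ranking.}
#' }
#'
#' @param values Named numeric vector, one cell's profile.
#' @param gs A [gene_set()].
#' @param method One of `"singscore"`, `"ssgsea"`, `"rank_biased_overlap"`,
#'   `"mean_z_score"`, `"average_score"`, `"median_score"`, `"summed_up"`,
#'   `"geneset_overlap"`.
#' @param alpha ssGSEA rank-weight exponent (default 0.75).
#' @param rbo_p RBO persistence in (0, 1), default 0.9.
#' @param rbo_depth RBO evaluation depth; default `NULL` uses the measured
#'   set size per direction.
#' @param threshold,as_fraction `geneset_overlap` expression threshold
#'   (default 0) and count-vs-fraction switch.
#' @param gene_means,gene_sds Named per-gene statistics for `mean_z_score`,
#'   computed across the scored cell population.
#' @return A single numeric score, or `NA` when the set is unscorable.
#' @export
score_profile <- function(values, gs,
                          method = c("singscore", "ssgsea",
                                     "rank_biased_overlap", "mean_z_score",
                                     "average_score", "median_score",
                                     "summed_up", "geneset_overlap"),
                          alpha = 0.75, rbo_p = 0.9, rbo_depth = NULL,
                          threshold = 0, as_fraction = FALSE,
                          gene_means = NULL, gene_sds = NULL) {
  method <- rlang::arg_match(method)
  stopifnot(inherits(gs, "gene_set"), !is.null(names(values)))
  up <- which(names(values) %in% gs$up)
  down <- which(names(values) %in% gs$down)
  if (!length(up) && !length(down)) return(NA_real_)
  score_idx(values, up, down, method,
            alpha = alpha, rbo_p = rbo_p, rbo_depth = rbo_depth,
            threshold = threshold, as_fraction = as_fraction,
            gene_means = gene_means, gene_sds = gene_sds,
            gene_names = names(values))
}

score_idx <- function(values, up, down, method, alpha, rbo_p, rbo_depth,
                      threshold, as_fraction, gene_means, gene_sds,
                      gene_names) {
  switch(method,
    summed_up = {
      r <- rank(values, ties.method = "average")
      s <- if (length(up)) sum(r[up]) else 0
      if (length(down)) s <- s - sum(r[down])
      s
    },
    average_score = {
      s <- if (length(up)) mean(values[up]) else 0
      if (length(down)) s <- s - mean(values[down])
      s
    },
    median_score = {
      s <- if (length(up)) median(values[up]) else 0
      if (length(down)) s <- s - median(values[down])
      s
    },
    mean_z_score = {
      if (is.null(gene_means) || is.null(gene_sds)) {
        abort("mean_z_score needs gene_means and gene_sds")
      }
      mz <- function(idx) {
        g <- gene_names[idx]
        sd_g <- gene_sds[g]
        g <- g[!is.na(sd_g) & sd_g > 0]
        if (!length(g)) return(NA_real_)
        mean((values[g] - gene_means[g]) / gene_sds[g])
      }
      s_up <- if (length(up)) mz(up) else NA_real_
      s_dn <- if (length(down)) mz(down) else NA_real_
      if (is.na(s_up) && is.na(s_dn)) return(NA_real_)
      (if (is.na(s_up)) 0 else s_up) - (if (is.na(s_dn)) 0 else s_dn)
    },
    geneset_overlap = {
      u <- union(up, down)
      cnt <- sum(values[u] > threshold)
      if (as_fraction) cnt / length(u) else cnt
    },
    singscore = {
      N <- length(values)
      if (length(up) == N || length(down) == N) {
        warn("gene set spans the whole universe: singscore normalization degenerate, returning 0")
        return(0)
      }
      r <- rank(values, ties.method = "average")
      s_up <- if (length(up)) singscore_half(r[up], N) else NULL
      s_dn <- if (length(down)) singscore_half((N + 1 - r)[down], N) else NULL
      if (!is.null(s_up) && !is.null(s_dn)) s_up + s_dn - 1
      else if (!is.null(s_up)) s_up - 0.5
      else s_dn - 0.5
    },
    ssgsea = {
      s_up <- if (length(up)) ssgsea_half(values, up, alpha) else NULL
      s_dn <- if (length(down)) ssgsea_half(values, down, alpha) else NULL
      if (!is.null(s_up) && !is.null(s_dn)) s_up - s_dn
      else s_up %||% -s_dn
    },
    rank_biased_overlap = {
      s_up <- if (length(up)) {
        rbo_half(values, up, rbo_p, rbo_depth, reversed = FALSE)
      } else NULL
      s_dn <- if (length(down)) {
        rbo_half(values, down, rbo_p, rbo_depth, reversed = TRUE)
      } else NULL
      if (!is.null(s_up) && !is.null(s_dn)) s_up - s_dn
      else s_up %||% -s_dn
    }
  )
}

# Normalized mean rank: with n set genes among N, the mean rank ranges from
# (n+1)/2 (all at the bottom) to N-(n-1)/2 (all at the top); map to [0,1].
singscore_half <- function(set_ranks, N) {
  n <- length(set_ranks)
  if (n == N) {
    warn("gene set spans the whole universe: singscore normalization degenerate, returning 0")
    return(0)
  }
  minp <- (n + 1) / 2
  maxp <- N - (n - 1) / 2
  (mean(set_ranks) - minp) / (maxp - minp)
}

# Integrated running sum of Barbie et al.: walk the decreasing-expression
# ordering; in-set genes add their normalized rank weight |N - pos + 1|^alpha,
# out-of-set genes subtract 1/(N - n); the score integrates (sums) the
# running statistic over all N positions.
ssgsea_half <- function(values, set_idx, alpha) {
  N <- length(values)
  n <- length(set_idx)
  if (n == 0 || n == N) return(NA_real_)
  ord <- order(values, decreasing = TRUE)   # ties stable by input position
  in_set <- ord %in% set_idx
  w <- (N - seq_len(N) + 1)^alpha
  step <- ifelse(in_set, w / sum(w[in_set]), -1 / (N - n))
  sum(cumsum(step))
}

# Truncated, normalized rank-biased overlap: agreement A_d between the top-d
# of the ranking and the set, geometric weights p^(d-1), depth D defaulting
# to the measured set size, scaled so a perfect prefix scores exactly 1.
rbo_half <- function(values, set_idx, p, depth = NULL, reversed = FALSE) {
  N <- length(values)
  n <- length(set_idx)
  if (n == 0) return(NA_real_)
  D <- depth %||% n
  D <- min(D, N)
  ord <- order(values, decreasing = !reversed)
  hits <- cumsum(ord[seq_len(D)] %in% set_idx)
  A_d <- hits / seq_len(D)
  wts <- p^(seq_len(D) - 1)
  sum(wts * A_d) / sum(wts)
}

#' Separation of two labeled score distributions (Mann-Whitney AUC)
#'
#' The probability that a randomly chosen positive cell outscores a randomly
#' chosen negative one, computed as the Mann-Whitney U statistic
#' `U / (n1 * n0)` with average-rank tie correction. 1 means perfect
#' separation, 0.5 none.
#'
#' @param scores Numeric scores (NAs dropped with their labels).
#' @param labels Logical, or a two-valued vector with `positive` naming the
#'   positive class.
#' @param positive The label value treated as positive; defaults to `TRUE`
#'   for logical labels and to the larger value of a two-valued 0/1 vector.
#' @return AUC in \[0, 1\], or `NA` if either class is empty.
#' @export
auc_separation <- function(scores, labels, positive = NULL) {
  keep <- !is.na(scores)
  scores <- scores[keep]
  labels <- labels[keep]
  if (is.logical(labels)) {
    pos <- labels
  } else {
    vals <- sort(unique(labels))
    if (is.null(positive)) {
      if (length(vals) != 2) {
        abort("labels must be binary; pass `positive` for multi-valued labels")
      }
      positive <- vals[length(vals)]
    }
    pos <- labels == positive
  }
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
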