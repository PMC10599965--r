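# Brute-force oracles, coded independently of the package internals:
# explicit loops and literal definitions, no shared helpers.

# Average ranks by explicit position counting: rank of v_i = mean of the
# sorted positions occupied by values equal to v_i.
oracle_ranks <- function(v) {
  n <- length(v)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(v < v[i])
    eq <- sum(v == v[i])
    r[i] <- mean((less + 1):(less + eq))
  }
  r
}

oracle_summed_up <- function(v, up, down = integer()) {
  r <- oracle_ranks(v)
  s <- 0
  for (i in up) s <- s + r[i]
  for (i in down) s <- s - r[i]
  s
}

oracle_average <- function(v, up, down = integer()) {
  s <- if (length(up)) sum(v[up]) / length(up) else 0
  if (length(down)) s <- s - sum(v[down]) / length(down)
  s
}

oracle_median <- function(v, up, down = integer()) {
  med <- function(x) {
    x <- sort(x)
    n <- length(x)
    if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  }
  s <- if (length(up)) med(v[up]) else 0
  if (length(down)) s <- s - med(v[down])
  s
}

oracle_mean_z <- function(v, mu, sdv, up, down = integer()) {
  part <- function(idx) {
    idx <- idx[sdv[idx] > 0]
    if (!length(idx)) return(NA_real_)
    tot <- 0
    for (i in idx) tot <- tot + (v[i] - mu[i]) / sdv[i]
    tot / length(idx)
  }
  s_up <- if (length(up)) part(up) else NA_real_
  s_dn <- if (length(down)) part(down) else NA_real_
  if (is.na(s_up) && is.na(s_dn)) return(NA_real_)
  (if (is.na(s_up)) 0 else s_up) - (if (is.na(s_dn)) 0 else s_dn)
}

oracle_overlap <- function(v, set_idx, threshold = 0, as_fraction = FALSE) {
  cnt <- 0
  for (i in set_idx) if (v[i] > threshold) cnt <- cnt + 1
  if (as_fraction) cnt / length(set_idx) else cnt
}

oracle_singscore <- function(v, up, down = integer()) {
  N <- length(v)
  half <- function(idx, reversed) {
    r <- oracle_ranks(if (reversed) -v else v)
    n <- length(idx)
    if (n == N) return(0)
    mr <- mean(r[idx])
    lo <- (n + 1) / 2
    hi <- N - (n - 1) / 2
    (mr - lo) / (hi - lo)
  }
  if (length(up) && length(down)) half(up, FALSE) + half(down, TRUE) - 1
  else if (length(up)) half(up, FALSE) - 0.5
  else half(down, TRUE) - 0.5
}

# Literal walk down the decreasing-expression list (ties kept in input
# order), accumulating the weighted running sum and integrating it.
oracle_ssgsea_half <- function(v, set_idx, alpha) {
  N <- length(v)
  n <- length(set_idx)
  if (n == 0 || n == N) return(NA_real_)
  ord <- order(-v)  # stable: ties by input position
  wsum <- 0
  for (pos in seq_len(N)) {
    if (ord[pos] %in% set_idx) wsum <- wsum + abs(N - pos + 1)^alpha
  }
  running <- 0
  total <- 0
  for (pos in seq_len(N)) {
    if (ord[pos] %in% set_idx) {
      running <- running + abs(N - pos + 1)^alpha / wsum
    } else {
      running <- running - 1 / (N - n)
    }
    total <- total + running
  }
  total
}

oracle_ssgsea <- function(v, up, down = integer(), alpha = 0.75) {
  if (length(up) && length(down)) {
    oracle_ssgsea_half(v, up, alpha) - oracle_ssgsea_half(v, down, alpha)
  } else if (length(up)) {
    oracle_ssgsea_half(v, up, alpha)
  } else {
    -oracle_ssgsea_half(v, down, alpha)
  }
}

oracle_rbo_half <- function(v, set_idx, p, depth = NULL, reversed = FALSE) {
  N <- length(v)
  n <- length(set_idx)
  D <- if (is.null(depth)) n else min(depth, N)
  ord <- order(if (reversed) v else -v)
  num <- 0
  den <- 0
  for (d in seq_len(D)) {
    agree <- length(intersect(ord[seq_len(d)], set_idx)) / d
    num <- num + p^(d - 1) * agree
    den <- den + p^(d - 1)
  }
  num / den
}

oracle_rbo <- function(v, up, down = integer(), p = 0.9, depth = NULL) {
  if (length(up) && length(down)) {
    oracle_rbo_half(v, up, p, depth) - oracle_rbo_half(v, down, p, depth, TRUE)
  } else if (length(up)) {
    oracle_rbo_half(v, up, p, depth)
  } else {
    -oracle_rbo_half(v, down, p, depth, TRUE)
  }
}

# Exhaustive pairwise comparison AUC.
oracle_auc <- function(scores, pos) {
  sp <- scores[pos]
  sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# Exhaustive all-pairs KNN with ties broken toward the lower index.
oracle_knn <- function(emb, K) {
  n <- nrow(emb)
  D <- as.matrix(stats::dist(emb))
  idx <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(n))
    idx[i, ] <- ord[seq_len(K)]
  }
  idx
}

# Dispatch an implementation score by method name on an index-based profile,
# mirroring score_profile() through named vectors.
impl_score <- function(v, up, down, method, ...) {
  names(v) <- paste0("g", seq_along(v))
  gs <- gene_set("s", up = names(v)[up], down = names(v)[down])
  score_profile(v, gs, method = method, ...)
}
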