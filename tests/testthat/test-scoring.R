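test_that("rank_profile assigns ascending average ranks", {
  expect_equal(rank_profile(c(a = 5, b = 1, c = 3))$ranks,
               c(a = 3, b = 1, c = 2))
  expect_equal(rank_profile(c(a = 0, b = 0, c = 7))$ranks,
               c(a = 1.5, b = 1.5, c = 3))
  expect_equal(rank_profile(setNames(rep(2, 5), letters[1:5]))$ranks,
               setNames(rep(3, 5), letters[1:5]))
  # rank sum is always N(N+1)/2
  set.seed(1)
  for (i in 1:5) {
    v <- setNames(rpois(20, 2), paste0("g", 1:20))
    expect_equal(sum(rank_profile(v)$ranks), 20 * 21 / 2)
  }
})

test_that("summed_up sums signature ranks, down-genes subtracted", {
  v <- setNames(c(10, 1:9), paste0("g", 1:10))  # g1 is the top gene
  expect_equal(score_profile(v, gene_set("s", up = "g1"), "summed_up"), 10)
  expect_equal(score_profile(v, gene_set("s", up = "g1", down = "g2"),
                             "summed_up"), 10 - 1)
  # all set genes unmeasured -> missing, not zero
  expect_true(is.na(score_profile(v, gene_set("s", up = "zz"), "summed_up")))
})

test_that("average and median scores subtract the down-statistic", {
  v <- c(A = 2, B = 4, C = 9, D = 1)
  expect_equal(score_profile(v, gene_set("s", up = c("A", "B")),
                             "average_score"), 3)
  expect_equal(score_profile(v, gene_set("s", up = c("A", "B")),
                             "median_score"), 3)
  expect_equal(score_profile(v, gene_set("s", up = "C"), "average_score"), 9)
  expect_equal(score_profile(v, gene_set("s", up = c("A", "B"), down = "D"),
                             "average_score"), 3 - 1)
})

test_that("mean_z centers on the population statistics", {
  v <- c(A = 5, B = 3, C = 8)
  mu <- c(A = 5, B = 2, C = 9)
  sdv <- c(A = 2, B = 1, C = 1)
  expect_equal(score_profile(v, gene_set("s", up = "A"), "mean_z_score",
                             gene_means = mu, gene_sds = sdv), 0)
  # z-scores +1 and -1 cancel
  expect_equal(score_profile(v, gene_set("s", up = c("B", "C")),
                             "mean_z_score", gene_means = mu,
                             gene_sds = sdv), 0)
  # a cell sitting exactly at the population mean scores 0 on any set
  expect_equal(score_profile(mu, gene_set("s", up = c("A", "B", "C")),
                             "mean_z_score", gene_means = mu,
                             gene_sds = sdv), 0)
})

test_that("geneset_overlap counts genes above threshold", {
  v <- c(A = 1, B = 0, C = 2)
  gs <- gene_set("s", up = c("A", "B", "C"))
  expect_equal(score_profile(v, gs, "geneset_overlap"), 2)
  expect_equal(score_profile(v, gs, "geneset_overlap", as_fraction = TRUE),
               2 / 3)
  expect_equal(score_profile(v, gs, "geneset_overlap", threshold = 5), 0)
})

test_that("singscore is the normalized mean rank with direction handling", {
  v <- setNames(10:1, paste0("g", 1:10))  # g1 highest ... g10 lowest
  top3 <- gene_set("s", up = paste0("g", 1:3))
  bottom3 <- gene_set("s", up = paste0("g", 8:10))
  # up-only scores are reported centered: up-score - 0.5
  expect_equal(score_profile(v, top3, "singscore"), 0.5)    # up-score 1
  expect_equal(score_profile(v, bottom3, "singscore"), -0.5) # up-score 0
  # random profiles match the direct-formula oracle
  set.seed(4)
  for (i in 1:20) {
    vv <- setNames(sample(10), paste0("g", 1:10))
    up <- sample(10, 3)
    gs <- gene_set("s", up = paste0("g", up))
    expect_equal(score_profile(vv, gs, "singscore"),
                 oracle_singscore(vv, up))
  }
  # a set spanning the whole universe is degenerate
  expect_warning(
    s <- score_profile(v, gene_set("s", up = paste0("g", 1:10)), "singscore"),
    "degenerate")
  expect_equal(s, 0)
})

test_that("ssgsea integrates the weighted running sum", {
  # single set gene at the top of 4: running sum (1, 2/3, 1/3, 0) -> 2
  v <- c(A = 9, B = 3, C = 2, D = 1)
  expect_equal(score_profile(v, gene_set("s", up = "A"), "ssgsea"), 2)
  # the bottom placement is the unique minimum over all single-gene placements
  scores <- sapply(names(v), function(g) {
    score_profile(v, gene_set("s", up = g), "ssgsea")
  })
  expect_equal(names(which.min(scores)), "D")
  expect_equal(unname(which.min(scores)), 4L)
  # alpha = 0: uniform weights, matches the oracle with uniform increments
  set.seed(8)
  for (i in 1:10) {
    vv <- setNames(sample(8), paste0("g", 1:8))
    up <- sample(8, 3)
    expect_equal(score_profile(vv, gene_set("s", up = paste0("g", up)),
                               "ssgsea", alpha = 0),
                 oracle_ssgsea(vv, up, alpha = 0))
  }
  # n = N is unscorable
  expect_true(is.na(score_profile(v, gene_set("s", up = names(v)), "ssgsea")))
})

test_that("rank-biased overlap is top-weighted and anchored at 1", {
  v <- setNames(10:1, paste0("g", 1:10))
  expect_equal(score_profile(v, gene_set("s", up = paste0("g", 1:3)),
                             "rank_biased_overlap"), 1)
  expect_equal(score_profile(v, gene_set("s", up = paste0("g", 9:10)),
                             "rank_biased_overlap"), 0)
  # n=2, N=5, set genes at ranking positions 1 and 3, p = 0.9:
  # A_1 = 1, A_2 = 1/2 -> (1 + 0.9/2) / (1 + 0.9)
  v5 <- setNames(c(9, 1, 7, 2, 3), paste0("g", 1:5))  # order: g1, g3, g5, ...
  got <- score_profile(v5, gene_set("s", up = c("g1", "g5")),
                       "rank_biased_overlap", rbo_p = 0.9)
  expect_equal(got, (1 + 0.9 * 0.5) / 1.9)
})

test_that("swapping up and down halves negates the directional scores", {
  set.seed(13)
  for (i in 1:10) {
    v <- setNames(sample(12) + rpois(12, 1), paste0("g", 1:12))
    halves <- split(sample(paste0("g", 1:12), 6), rep(1:2, 3))
    a <- gene_set("s", up = halves[[1]], down = halves[[2]])
    b <- gene_set("s", up = halves[[2]], down = halves[[1]])
    for (m in c("singscore", "ssgsea", "summed_up")) {
      expect_equal(score_profile(v, a, m), -score_profile(v, b, m),
                   tolerance = 1e-12)
    }
    # RBO's halves are scored on opposite ranking directions, so swapping
    # them reverses which half is top-weighted rather than negating the
    # total; both orientations must still be bounded per direction.
    for (g in list(a, b)) {
      expect_lte(abs(score_profile(v, g, "rank_biased_overlap")), 1)
    }
  }
})

test_that("summed_up of a set and its complement add to N(N+1)/2", {
  set.seed(14)
  v <- setNames(rpois(15, 3), paste0("g", 1:15))
  idx <- sample(15, 6)
  s1 <- score_profile(v, gene_set("s", up = paste0("g", idx)), "summed_up")
  s2 <- score_profile(v, gene_set("s", up = paste0("g", setdiff(1:15, idx))),
                      "summed_up")
  expect_equal(s1 + s2, 15 * 16 / 2)
})

test_that("auc_separation matches the exhaustive pairwise oracle", {
  expect_equal(auc_separation(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_separation(rep(3, 8), rep(c(TRUE, FALSE), 4)), 0.5)
  set.seed(17)
  for (i in 1:10) {
    s <- rpois(40, 3)
    lab <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
    expect_equal(auc_separation(s, lab), oracle_auc(s, lab))
  }
  # labels given as strings with an explicit positive class
  expect_equal(auc_separation(c(1, 2, 3, 4), c("u", "u", "t", "t"),
                              positive = "t"), 1)
})

test_that("score_cells matches hand counting on a toy fixture, smoothing off", {
  X <- Matrix::Matrix(matrix(c(1, 0, 2,
                               0, 0, 3,
                               5, 0, 0), 3, 3, byrow = TRUE), sparse = TRUE)
  ds <- expression_dataset(X, c("A", "B", "C"), c("c1", "c2", "c3"))
  st <- score_cells(ds, gene_set("s", up = c("A", "B")),
                    method = "geneset_overlap", smooth_mode = "off")
  expect_equal(st$s__geneset_overlap, c(1, 0, 1))
  expect_equal(st$cell_id, c("c1", "c2", "c3"))
})

test_that("smooth off equals an identity adjacency for every method", {
  sim <- simulate_two_populations(n_cells_a = 15, n_cells_b = 15,
                                  n_genes = 30, marker_genes = 6, seed = 6)
  ds <- sim$dataset
  for (m in c("singscore", "ssgsea", "rank_biased_overlap", "mean_z_score",
              "average_score", "median_score", "summed_up",
              "geneset_overlap")) {
    off <- score_cells(ds, sim$markers, method = m, smooth_mode = "off")
    col <- paste0("markers__", m)
    # identity route: smooth_counts with identity A, scored per profile
    M <- as.matrix(smooth_counts(identity_adjacency(30), ds$counts))
    if (m == "mean_z_score") {
      mu <- setNames(colMeans(M), ds$gene_ids)
      sdv <- setNames(apply(M, 2, sd), ds$gene_ids)
    }
    direct <- sapply(seq_len(nrow(M)), function(i) {
      v <- setNames(M[i, ], ds$gene_ids)
      if (m == "mean_z_score") {
        score_profile(v, sim$markers, m, gene_means = mu, gene_sds = sdv)
      } else {
        score_profile(v, sim$markers, m)
      }
    })
    expect_equal(off[[col]], unname(direct), tolerance = 1e-12)
  }
})

test_that("unscorable sets yield missing columns and a warning summary", {
  ds <- toy_dataset(6, 5, seed = 2)
  sets <- list(gene_set("good", up = c("G1", "G2")),
               gene_set("ghost", up = c("zz1", "zz2")))
  w <- capture_warnings(
    st <- score_cells(ds, sets, method = "summed_up", smooth_mode = "off"))
  expect_true(any(grepl("not scored", w)))
  expect_true(all(is.na(st$ghost__summed_up)))
  expect_true(all(!is.na(st$good__summed_up)))
  info <- attr(st, "run_info")
  expect_false(info$sets$scorable[info$sets$set == "ghost"])
})

test_that("rank methods agree between matrix pipeline and profile calls", {
  sim <- simulate_two_populations(n_cells_a = 10, n_cells_b = 10,
                                  n_genes = 25, marker_genes = 5, seed = 9)
  st <- score_cells(sim$dataset, sim$markers, method = "ssgsea",
                    smooth_mode = "connectivity", knn = 4, n_components = 5)
  expect_equal(nrow(st), 20L)
  expect_true(all(is.finite(st$markers__ssgsea)))
})
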