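test_that("null communities preserve richness, totals and abundance ranks", {
  set.seed(55)
  tbl <- random_count_table(40, 5, lambda = 6)
  m <- tbl_matrix(tbl)
  draws <- null_communities(tbl, n_draws = 20, seed = 3)
  expect_length(draws, 20)
  q <- rowMeans(halocline:::close_columns(m))
  rho <- sapply(draws, function(d) {
    dm <- tbl_matrix(d)
    expect_equal(unname(colSums(dm > 0)), unname(colSums(m > 0)))
    expect_equal(unname(colSums(dm)), unname(colSums(m)))
    qd <- rowMeans(halocline:::close_columns(dm))
    cor(q, qd, method = "spearman")
  })
  expect_gte(median(rho), 0.8)
  d1 <- null_communities(tbl, n_draws = 3, seed = 9)
  d2 <- null_communities(tbl, n_draws = 3, seed = 9)
  expect_identical(d1, d2)
  expect_error(null_communities(tbl, 0), "integer")
})

test_that("largest-remainder apportionment is exact and proportional", {
  lr <- halocline:::largest_remainder
  expect_equal(sum(lr(c(0.5, 0.3, 0.2), 7)), 7)
  expect_equal(lr(c(1, 1), 4), c(2L, 2L))
  expect_equal(lr(c(5, 3, 2), 10), c(5L, 3L, 2L))
  expect_equal(lr(c(1, 0, 0), 3), c(3L, 0L, 0L))
  set.seed(2)
  for (i in 1:20) {
    w <- runif(8); tot <- sample(0:50, 1)
    out <- lr(w, tot)
    expect_equal(sum(out), max(tot, 0))
    expect_true(all(abs(out - tot * w / sum(w)) <= 1))
  }
})

test_that("stochasticity ratio hits its forced boundary values", {
  ids <- c("A", "B", "C")
  zero <- as.dist(matrix(0, 3, 3, dimnames = list(ids, ids)))
  half <- as.dist(matrix(0.5 * (1 - diag(3)), 3, dimnames = list(ids, ids)))
  # identical observed samples vs a dissimilar null: pure selection, NST 0
  st0 <- stochasticity_ratio(zero, list(half, half))
  expect_equal(st0$nst_pair, rep(0, 3))
  # observed equal to the null mean: no selection, NST 1
  st1 <- stochasticity_ratio(half, list(half, half))
  expect_equal(st1$nst_pair, rep(1, 3))
  # observed == null == zero boundary: treated as no deviation
  stz <- stochasticity_ratio(zero, list(zero))
  expect_equal(stz$nst_pair, rep(1, 3))
  expect_error(stochasticity_ratio(zero, list()), "at least one")
  bad <- as.dist(matrix(0.2 * (1 - diag(3)), 3,
                        dimnames = list(c("X", "Y", "Z"), c("X", "Y", "Z"))))
  expect_error(stochasticity_ratio(zero, list(bad)), "sample ids")
})

test_that("nst is deterministic under a seed and classifies by the 50% rule", {
  spec <- synthetic_spec(S = 120, n_samples = 4, depth = 5000, m = 0.2, seed = 17)
  tbl <- simulate_neutral(spec, n_samples = 8)
  md <- tibble::tibble(sample_id = names(tbl)[-1],
                       group = rep(c("g1", "g2"), each = 4))
  r1 <- nst(tbl, md, n_draws = 100, seed = 12)
  r2 <- nst(tbl, md, n_draws = 100, seed = 12)
  expect_identical(r1, r2)
  expect_equal(r1$classification, ifelse(r1$nst > 0.5, "stochastic-dominated",
                                         "deterministic-dominated"))
  expect_true(all(r1$nst >= 0 & r1$nst <= 1))
  expect_equal(r1$n_pairs, rep(6L, 2))
  md_small <- tibble::tibble(sample_id = names(tbl)[-1],
                             group = c(rep("big", 6), "tiny", "tiny"))
  expect_warning(out <- nst(tbl, md_small, n_draws = 50, seed = 1), "fewer than 3")
  expect_equal(out$group, "big")
})

test_that("nst self-calibrates above 0.5 on null-generated data and near 0 under hard filtering", {
  set.seed(23)
  tbl <- random_count_table(60, 6, lambda = 10)
  m <- tbl_matrix(tbl)
  hits <- sapply(1:10, function(i) {
    null_tbl <- null_communities(tbl, 1, seed = 400 + i)[[1]]
    md <- tibble::tibble(sample_id = names(null_tbl)[-1], group = "g")
    nst(null_tbl, md, n_draws = 120, seed = i)$nst
  })
  expect_gte(mean(hits > 0.5), 0.9)
  # identical within-group composition = pure determinism
  same <- m[, rep(1, 5)]
  colnames(same) <- sprintf("R%d", 1:5)
  md <- tibble::tibble(sample_id = colnames(same), group = "g")
  v <- nst(halocline:::as_count_tbl(same), md, n_draws = 100, seed = 2)$nst
  expect_lt(v, 0.1)
})

test_that("niche breadth matches Levins' formula, bounds and oracle", {
  uni <- tibble::tibble(taxon_id = "t", !!!setNames(as.list(rep(5, 6)), paste0("S", 1:6)))
  expect_equal(niche_breadth(uni)$b, 6)
  single <- tibble::tibble(taxon_id = "t", S1 = 9, S2 = 0)
  expect_equal(niche_breadth(single)$b, 1)
  two <- tibble::tibble(taxon_id = "t", S1 = 6, S2 = 4)
  expect_equal(niche_breadth(two)$b, 1 / 0.52, tolerance = 1e-12)
  set.seed(6)
  for (i in 1:50) {
    tbl <- random_count_table(12, 5, lambda = 3)
    m <- tbl_matrix(tbl)
    nb <- niche_breadth(tbl)
    for (k in seq_len(nrow(nb))) {
      expect_equal(nb$b[k], oracle_niche_breadth(m[nb$taxon_id[k], ]),
                   tolerance = 1e-10)
    }
    expect_true(all(nb$b >= 1 - 1e-12 & nb$b <= ncol(m) + 1e-12))
    even <- abs(nb$b - ncol(m)) < 1e-12
    for (k in which(even)) {
      expect_true(all(abs(m[nb$taxon_id[k], ] - mean(m[nb$taxon_id[k], ])) < 1e-12))
    }
  }
})

test_that("community niche breadth averages over present taxa", {
  tbl <- tibble::tibble(taxon_id = c("wide", "narrow"),
                        S1 = c(5, 10), S2 = c(5, 0))
  nb <- setNames(niche_breadth(tbl)$b, niche_breadth(tbl)$taxon_id)
  bc <- community_niche_breadth(tbl)
  expect_equal(bc$bcom[bc$sample_id == "S1"], mean(nb))
  expect_equal(bc$bcom[bc$sample_id == "S2"], nb[["wide"]])
  w <- community_niche_breadth(tbl, weighted = TRUE)
  expect_equal(w$bcom[w$sample_id == "S1"],
               (5 * nb[["wide"]] + 10 * nb[["narrow"]]) / 15)
})
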