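test_that("edge scores hit their self-similarity identities", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
             c = c(2, 4, 6, 8, 10) + 1, d = c(5, 4, 3, 2, 1))
  colnames(m) <- paste0("S", 1:5)
  tbl <- halocline:::as_count_tbl(m)
  es <- edge_scores(tbl)
  row_ab <- es[es$taxon_1 == "a" & es$taxon_2 == "b", ]
  expect_equal(row_ab$pearson, 1)
  expect_equal(row_ab$spearman, 1)
  expect_equal(row_ab$kl, 0, tolerance = 1e-12)
  # affine transform of a row keeps pearson at 1 (pre-closure values)
  raw_cor <- cor(m["a", ], m["c", ])
  expect_equal(raw_cor, 1)
  row_ad <- es[es$taxon_1 == "a" & es$taxon_2 == "d", ]
  expect_lt(row_ad$spearman, 0)
  # BC similarity between row profiles, by hand on a 2-sample table
  two <- tibble::tibble(taxon_id = c("x", "y"), S1 = c(1, 2), S2 = c(2, 1),
                        S3 = c(1, 2), S4 = c(2, 1))
  bc <- edge_scores(to_relative(two), methods = "bray_curtis")$bray_curtis
  expect_equal(bc, 1 - 1 / 3, tolerance = 1e-12)
  # constant taxon flags the pair
  # row k stays constant after column closure (equal sample totals)
  cm <- rbind(k = c(3, 3, 3, 3), l = c(1, 2, 3, 4), pad = c(6, 5, 4, 3))
  colnames(cm) <- paste0("S", 1:4)
  esc <- edge_scores(halocline:::as_count_tbl(cm))
  expect_true(any(esc$excluded))
  expect_error(edge_scores(two[, 1:3]), "4 samples")
})

test_that("permutation p-values are calibrated, powered and floor-bounded", {
  set.seed(88)
  n <- 24
  m <- matrix(rexp(40 * n), 40, n, dimnames = list(sprintf("t%02d", 1:40), sprintf("s%02d", 1:n)))
  tbl <- halocline:::as_count_tbl(m)
  ps <- sapply(1:60, function(i) {
    pair <- sprintf("t%02d", sample(40, 2))
    permutation_null(tbl, pair, "pearson", n_perm = 120, seed = i)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(ps >= 1 / 121))
  # planted strong correlation is detected
  z <- rnorm(n)
  m2 <- m
  m2[1, ] <- exp(z); m2[2, ] <- exp(0.95 * z + sqrt(1 - 0.95^2) * rnorm(n))
  tbl2 <- halocline:::as_count_tbl(m2)
  pp <- permutation_null(tbl2, c("t01", "t02"), "spearman", n_perm = 999, seed = 1)
  expect_lte(pp$p, 0.01)
  expect_error(permutation_null(tbl, c("t01", "t02"), "pearson", n_perm = 5), "at least 10")
  expect_warning(permutation_null(tbl, c("t01", "t02"), "pearson", n_perm = 50, seed = 1),
                 "coarse")
})

test_that("bootstrap restoration keeps stable signals and drops noise", {
  set.seed(91)
  n <- 30
  z <- rnorm(n)
  m <- rbind(a = exp(z), b = exp(0.97 * z + 0.2 * rnorm(n)),
             c = rexp(n), d = rexp(n), pad = rexp(n) + 1)
  colnames(m) <- sprintf("s%02d", seq_len(n))
  tbl <- halocline:::as_count_tbl(m)
  keep <- bootstrap_restore(tbl, c("a", "b"), "pearson", n_boot = 200, seed = 2,
                            null_mean = 0)
  expect_true(keep$keep)
  expect_gt(keep$lower, 0)
  r1 <- bootstrap_restore(tbl, c("a", "b"), "pearson", n_boot = 100, seed = 5)
  r2 <- bootstrap_restore(tbl, c("a", "b"), "pearson", n_boot = 100, seed = 5)
  expect_identical(r1, r2)
  drops <- sapply(1:40, function(i) {
    mm <- m
    mm["c", ] <- sample(mm["c", ]); mm["d", ] <- sample(mm["d", ])
    bootstrap_restore(halocline:::as_count_tbl(mm), c("c", "d"), "pearson",
                      n_boot = 100, seed = i, null_mean = 0)$keep
  })
  expect_gte(mean(!drops), 0.75)
})

test_that("brown_merge recovers its degenerate and independent limits", {
  set.seed(14)
  r <- 400
  u <- runif(r)
  # perfectly correlated methods: identical replicate p-values
  x3 <- rbind(u, u, u)
  p0 <- 0.02
  merged_dup <- brown_merge(rep(p0, 3), x3)
  expect_equal(merged_dup, p0, tolerance = 0.2)
  # independent methods: Brown ~ Fisher
  xi <- rbind(runif(r), runif(r), runif(r))
  pv <- c(0.03, 0.2, 0.5)
  expect_equal(brown_merge(pv, xi), oracle_fisher(pv), tolerance = 0.3)
  # no-signal case
  expect_gt(brown_merge(c(1, 1), rbind(runif(r), runif(r))), 0.9)
  expect_error(brown_merge(0.5, rbind(u)), "at least 2")
  expect_error(brown_merge(c(.1, .2), matrix(runif(20), 2)), "30 replicate")
})

test_that("bh_fdr reproduces the step-up procedure", {
  res <- bh_fdr(c(0.01, 0.02, 0.04, 0.8), q = 0.05)
  # step-up: largest k with p_(k) <= k q/m is k = 2 (0.04 > 3 * 0.05 / 4)
  expect_equal(res$accepted, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$q_value, p.adjust(c(0.01, 0.02, 0.04, 0.8), "BH"))
  all_small <- bh_fdr(rep(0.001, 10), q = 0.05)
  expect_true(all(all_small$accepted))
  sorted_q <- bh_fdr(sort(runif(50)))$q_value
  expect_true(all(diff(sorted_q) >= -1e-15))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  expect_error(bh_fdr(numeric(0)), "non-empty")
})

test_that("build_network recovers planted positive and negative edges with correct signs", {
  pe <- tibble::tibble(taxon_1 = c(1, 3, 5), taxon_2 = c(2, 4, 6),
                       rho = c(0.9, 0.9, -0.85))
  spec <- synthetic_spec(S = 40, depth = 20000, seed = 5, planted_edges = pe)
  tbl <- simulate_correlated(spec, n_samples = 30)
  net <- build_network(tbl, top_n = 40, n_perm = 400, n_boot = 100, seed = 8)
  expect_s3_class(net, "halo_network")
  got <- paste(net$edges$taxon_1, net$edges$taxon_2)
  planted <- paste(sprintf("OTU%04d", pe$taxon_1), sprintf("OTU%04d", pe$taxon_2))
  expect_gte(mean(planted %in% got), 2 / 3)
  hit <- net$edges[got %in% planted, ]
  want <- ifelse(pe$rho > 0, "positive", "negative")[match(got[got %in% planted], planted)]
  expect_equal(hit$sign, want)
  # determinism
  net2 <- build_network(tbl, top_n = 40, n_perm = 400, n_boot = 100, seed = 8)
  expect_identical(net$edges, net2$edges)
})

test_that("an empty edge set still yields a valid topology", {
  spec <- synthetic_spec(S = 12, depth = 4000, seed = 3, latent_sigma = 0.3)
  tbl <- simulate_correlated(spec, n_samples = 10)
  net <- build_network(tbl, top_n = 12, n_perm = 150, n_boot = 50, seed = 1, q = 1e-6)
  topo <- net$topology
  expect_equal(topo$density, nrow(net$edges) / (12 * 11))
  if (nrow(net$edges) == 0) {
    expect_equal(topo$n_edges, 0)
    expect_equal(topo$diameter, 0)
    expect_equal(topo$clustering_coefficient, 0)
  }
  expect_error(build_network(tbl[, 1:4], top_n = 12, n_perm = 150), "5 samples")
})

test_that("topology metrics match closed forms", {
  tri <- tibble::tibble(taxon_1 = c("a", "b", "c"), taxon_2 = c("b", "c", "a"),
                        sign = rep("positive", 3))
  topo <- topology(tri)
  expect_equal(topo$clustering_coefficient, 1)
  expect_equal(topo$diameter, 1)
  expect_equal(topo$mean_neighbors, 2)
  expect_equal(topo$density, 3 / (3 * 2))
  expect_equal(topo$positive_pct, 100)
  set.seed(10)
  g <- igraph::sample_gnm(50, 120)
  topo2 <- topology(g)
  expect_equal(topo2$mean_neighbors, 2 * 120 / 50)
  expect_equal(topo2$density, 120 / (50 * 49))
  # reference graph sizes: arithmetic identities of the topology conventions
  gA <- igraph::sample_gnm(93, 554)
  tA <- topology(gA)
  expect_equal(round(tA$mean_neighbors, 2), 11.91)
  expect_equal(round(tA$density, 3), 0.065)
  gD <- igraph::sample_gnm(96, 314)
  tD <- topology(gD)
  expect_equal(round(tD$mean_neighbors, 2), 6.54)
  expect_equal(round(tD$density, 3), 0.034)
})
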