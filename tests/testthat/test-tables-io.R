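test_that("count tables round-trip through TSV and reject malformed cells", {
  tbl <- example_counts()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tbl, tf)
  expect_equal(read_count_table(tf), tbl)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tS1\tS2", "OTU1\t3\t2", "OTU2\t-4\t1"), bad)
  expect_error(read_count_table(bad), "OTU2.*S1|negative")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tS1", "OTU1\t3", "OTU1\t2"), dup)
  expect_error(read_count_table(dup), "duplicated")

  alpha <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tS1", "OTU1\tfoo"), alpha)
  expect_error(read_count_table(alpha), "OTU1.*S1")

  frac <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tS1", "OTU1\t0.5"), frac)
  expect_error(read_count_table(frac), "relative")
  expect_equal(read_count_table(frac, relative = TRUE)$S1, 0.5)
})

test_that("transposed layout and BIOM JSON readers give the same table", {
  tbl <- example_counts()
  tf <- withr::local_tempfile(fileext = ".tsv")
  m <- tbl_matrix(tbl)
  readr::write_tsv(tibble::as_tibble(as.data.frame(t(m)), rownames = "sample_id"), tf)
  expect_equal(tbl_matrix(read_count_table(tf, transpose = TRUE)), m)

  bf <- withr::local_tempfile(fileext = ".biom")
  biom <- list(
    id = "x", format = "1.0.0", format_url = "http://biom-format.org",
    type = "OTU table", matrix_type = "sparse",
    shape = c(3, 2),
    rows = lapply(rownames(m), function(r) list(id = r, metadata = NULL)),
    columns = lapply(colnames(m), function(s) list(id = s, metadata = NULL)),
    data = {
      nz <- which(m != 0, arr.ind = TRUE)
      lapply(seq_len(nrow(nz)), function(k) {
        list(nz[k, 1] - 1L, nz[k, 2] - 1L, m[nz[k, 1], nz[k, 2]])
      })
    }
  )
  jsonlite::write_json(biom, bf, auto_unbox = TRUE, digits = NA)
  expect_equal(tbl_matrix(read_biom_table(bf)), m)
})

test_that("rarefaction hits the target depth exactly and is seed-deterministic", {
  set.seed(42)
  tbl <- random_count_table(30, 5, lambda = 60)
  depth <- 100
  r1 <- rarefy(tbl, depth, seed = 7)
  r2 <- rarefy(tbl, depth, seed = 7)
  r3 <- rarefy(tbl, depth, seed = 8)
  expect_identical(r1, r2)
  expect_equal(unname(colSums(tbl_matrix(r1))), rep(depth, 5))
  expect_equal(unname(colSums(tbl_matrix(r3))), rep(depth, 5))
  expect_false(identical(tbl_matrix(r1), tbl_matrix(r3)))

  # a sample already exactly at depth passes through untouched
  m <- tbl_matrix(tbl)
  m[, 1] <- 0; m[1:4, 1] <- 25
  exact <- rarefy(halocline:::as_count_tbl(m), depth, seed = 1)
  expect_equal(tbl_matrix(exact)[, 1], m[, 1])

  # under-depth samples are dropped with a message
  m[, 2] <- 0; m[1, 2] <- 10
  expect_message(out <- rarefy(halocline:::as_count_tbl(m), depth, seed = 1),
                 "dropping")
  expect_false("S02" %in% names(out))
  expect_error(rarefy(example_counts(), 10000), "fewer than")
  expect_error(rarefy(tbl, 0), "integer")
})

test_that("rarefaction preserves expected taxon proportions", {
  set.seed(11)
  counts <- c(400, 250, 150, 90, 50, 30, 15, 10, 3, 2)
  m <- matrix(counts, ncol = 1, dimnames = list(paste0("T", 1:10), "S1"))
  tbl <- halocline:::as_count_tbl(m)
  depth <- 200
  reps <- sapply(1:200, function(i) tbl_matrix(rarefy(tbl, depth, seed = i))[, 1])
  p_obs <- rowMeans(reps) / depth
  p_true <- counts / sum(counts)
  # hypergeometric SE of the mean proportion over 200 replicates
  fpc <- (sum(counts) - depth) / (sum(counts) - 1)
  se <- sqrt(p_true * (1 - p_true) / depth * fpc / 200)
  expect_true(all(abs(p_obs - p_true) <= 3 * pmax(se, 1e-6)))
})

test_that("relative abundance closes columns and inverts exactly on integers", {
  tbl <- example_counts()
  rel <- to_relative(tbl)
  mr <- tbl_matrix(rel)
  expect_true(all(abs(colSums(mr) - 1) <= 1e-9))
  expect_equal(mr[, 1], c(OTU1 = 0.6, OTU2 = 0.3, OTU3 = 0.1))
  m <- tbl_matrix(tbl)
  back <- sweep(mr, 2, colSums(m), "*")
  expect_equal(back, m)
  zero <- tibble::tibble(taxon_id = "OTU1", S1 = 0)
  expect_error(to_relative(zero), "S1")
})

test_that("taxonomy aggregation sums counts, pools unassigned, conserves totals", {
  tbl <- tibble::tibble(taxon_id = c("O1", "O2", "O3", "O4"),
                        A = c(3, 4, 5, 1), B = c(1, 0, 2, 2))
  tax <- tibble::tibble(taxon_id = c("O1", "O2", "O3", "O4"),
                        phylum = c("P1", "P1", "P2", "P2"),
                        genus = c("G1", "G1", "G2", NA))
  g <- aggregate_taxonomy(tbl, tax, "genus")
  m <- tbl_matrix(g)
  expect_equal(m["G1", ], c(A = 7, B = 1))
  expect_equal(m["norank_P2", ], c(A = 1, B = 2))
  expect_equal(sum(m), sum(tbl_matrix(tbl)))
  # aggregation at a rank where labels are unique keeps the row count
  tax2 <- tibble::tibble(taxon_id = tbl$taxon_id, genus = paste0("G", 1:4))
  expect_equal(nrow(aggregate_taxonomy(tbl, tax2, "genus")), 4)
  expect_error(aggregate_taxonomy(tbl, tax, "species"), "unknown rank")
  expect_error(aggregate_taxonomy(tbl, tax[1:3, ], "genus"), "missing")
})

test_that("top_n_taxa keeps the heaviest rows with lexicographic tie-break", {
  tbl <- tibble::tibble(taxon_id = c("B", "A", "C"), S1 = c(5, 5, 2), S2 = c(0, 0, 0))
  expect_equal(top_n_taxa(tbl, 5), tbl)
  expect_equal(top_n_taxa(tbl, 1)$taxon_id, "A")
  expect_equal(top_n_taxa(tbl, 2)$taxon_id, c("B", "A"))
  expect_error(top_n_taxa(tbl, 0), "integer")
})
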