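# Normalized stochasticity ratio: how far observed pairwise dissimilarity
# departs from a taxon-shuffling null that fixes each sample's richness and
# total while drawing taxon identities by regional occurrence frequency and
# abundances by regional mean relative abundance.

#' Null communities under the proportional-abundance fixed-richness model
#'
#' Each draw keeps every sample's observed richness and read total. Taxon
#' identities are sampled without replacement with probability proportional
#' to regional occurrence frequency; each drawn taxon is seeded with one
#' read and the remaining reads are distributed proportional to regional
#' mean relative abundance with largest-remainder rounding.
#'
#' @param tbl A count table tibble (>= 2 samples, integer counts).
#' @param n_draws Number of null tables to generate.
#' @param seed Optional integer seed.
#' @return A list of `n_draws` count table tibbles.
#' @export
null_communities <- function(tbl, n_draws, seed = NULL) {
  n_draws <- check_scalar_int(n_draws, "n_draws")
  m <- as_count_matrix(tbl)
  check_integerish(m)
  if (ncol(m) < 2) abort("need at least 2 samples.")
  draws <- with_seed_if(seed, null_draws_matrix(m, n_draws))
  lapply(draws, as_count_tbl)
}

# Matrix-level workhorse; assumes the RNG is already positioned.
null_draws_matrix <- function(m, n_draws) {
  s <- nrow(m)
  w <- rowMeans(m > 0)            # regional occurrence frequency
  q <- rowMeans(close_columns(m)) # regional mean relative abundance
  rich <- colSums(m > 0)
  tot <- colSums(m)
  if (any(rich == 0)) abort("sample(s) with zero richness cannot be randomized.")
  lapply(seq_len(n_draws), function(k) {
    out <- matrix(0L, s, ncol(m), dimnames = dimnames(m))
    for (j in seq_len(ncol(m))) {
      # weighted sampling without replacement via the exponential race
      idx <- order(rexp(s) / w)[seq_len(rich[j])]
      out[idx, j] <- 1L + largest_remainder(q[idx], tot[j] - rich[j])
    }
    out
  })
}

# Integer apportionment of `total` units proportional to `weights`.
largest_remainder <- function(weights, total) {
  if (total <= 0) return(integer(length(weights)))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Pairwise stochasticity ratio against a null ensemble
#'
#' For each sample pair, with observed dissimilarity \eqn{D}, similarity
#' \eqn{C = 1 - D} and null means \eqn{\bar D, \bar C}: the selection
#' strength is \eqn{(C - \bar C)/(1 - \bar C)} when \eqn{C \ge \bar C} and
#' \eqn{(D - \bar D)/(1 - \bar D)} otherwise; the pairwise stochasticity
#' ratio is one minus that strength, capped to \[0, 1\]. When the observed
#' and null-mean dissimilarities coincide at a boundary (both 0 or both 1)
#' the strength is taken as 0.
#'
#' @param dm_obs Observed `dist` over samples.
#' @param null_dms List of `dist` objects from null draws (same samples).
#' @return A tibble with one row per sample pair: `sample_1`, `sample_2`,
#'   `d_obs`, `d_null`, `st` (selection strength), `nst_pair`.
#' @export
stochasticity_ratio <- function(dm_obs, null_dms) {
  dm_obs <- as_distance(dm_obs)
  if (length(null_dms) == 0) abort("need at least one null distance matrix.")
  ids <- labels(dm_obs)
  nulls <- vapply(null_dms, function(d) {
    d <- as_distance(d)
    if (!identical(labels(d), ids)) abort("null distance matrices must share the observed sample ids.")
    as.numeric(d)
  }, numeric(length(dm_obs)))
  d_null <- if (is.matrix(nulls)) rowMeans(nulls) else nulls
  d_obs <- as.numeric(dm_obs)
  st <- pair_selection_strength(d_obs, d_null)
  pairs <- which(lower.tri(matrix(0, length(ids), length(ids))), arr.ind = TRUE)
  tibble::tibble(sample_1 = ids[pairs[, 2]], sample_2 = ids[pairs[, 1]],
                 d_obs = d_obs, d_null = d_null, st = st,
                 nst_pair = pmin(pmax(1 - st, 0), 1))
}

pair_selection_strength <- function(d_obs, d_null) {
  c_obs <- 1 - d_obs; c_null <- 1 - d_null
  ifelse(c_obs >= c_null,
         ifelse(d_null <= 0, 0, (c_obs - c_null) / d_null),
         ifelse(d_null >= 1, 0, (d_obs - d_null) / (1 - d_null)))
}

#' Normalized stochasticity ratio per group
#'
#' Runs the full pipeline per metadata group: null draws with
#' [null_communities()]'s model, a chosen dissimilarity, and
#' [stochasticity_ratio()]; the group NST is the mean pairwise ratio over
#' within-group pairs, read against the 50% rule (NST > 0.5: assembly
#' dominated by stochastic processes).
#'
#' @param tbl A count table tibble of integer counts.
#' @param metadata Tibble with `sample_id` and `group` for every sample.
#' @param metric `"bray"` (abundance-based, on relative abundances) or
#'   `"jaccard"` (presence/absence).
#' @param n_draws Null draws per group (>= 100 recommended).
#' @param seed Optional integer seed; per-group streams are derived from it.
#' @return A tibble with one row per group: `group`, `n_samples`, `n_pairs`,
#'   `nst`, `classification`, `metric`, `n_draws`. Groups with fewer than 3
#'   samples are skipped with a warning.
#' @export
nst <- function(tbl, metadata, metric = c("bray", "jaccard"), n_draws = 1000,
                seed = NULL) {
  metric <- match.arg(metric)
  n_draws <- check_scalar_int(n_draws, "n_draws")
  m <- as_count_matrix(tbl)
  check_integerish(m)
  miss <- setdiff(colnames(m), metadata$sample_id)
  if (length(miss)) abort(sprintf("samples missing from metadata: %s", paste(miss, collapse = ", ")))
  grp <- setNames(as.character(metadata$group), metadata$sample_id)[colnames(m)]
  purrr::map_dfr(unique(grp), function(g) {
    cols <- which(grp == g)
    if (length(cols) < 3) {
      warn(sprintf("group '%s' has fewer than 3 samples; skipped.", g))
      return(tibble::tibble())
    }
    sub <- m[, cols, drop = FALSE]
    sub <- sub[rowSums(sub) > 0, , drop = FALSE]
    gseed <- if (is.null(seed)) NULL else derive_seed(seed, paste0("nst::", g))
    d_obs <- dissimilarity_matrix(sub, metric)
    nulls <- with_seed_if(gseed, null_draws_matrix(sub, n_draws))
    null_d <- vapply(nulls, function(x) as.numeric(dissimilarity_matrix(x, metric)),
                     numeric(length(d_obs)))
    d_null <- rowMeans(null_d)
    st <- pair_selection_strength(as.numeric(d_obs), d_null)
    val <- mean(pmin(pmax(1 - st, 0), 1))
    tibble::tibble(group = g, n_samples = length(cols),
                   n_pairs = length(st), nst = val,
                   classification = if (val > 0.5) "stochastic-dominated" else "deterministic-dominated",
                   metric = metric, n_draws = n_draws)
  })
}

dissimilarity_matrix <- function(m, metric) {
  if (metric == "bray") {
    vegan::vegdist(t(close_columns(m)), method = "bray")
  } else {
    vegan::vegdist(t(m > 0), method = "jaccard")
  }
}

#' Levins niche breadth per taxon
#'
#' \eqn{B_j = 1 / \sum_i P_{ij}^2} where \eqn{P_{ij}} is the share of taxon
#' j's total abundance found in community i. \eqn{B_j = 1} for single-site
#' occupancy and \eqn{B_j = N} (the number of communities) for perfectly
#' even spread.
#'
#' @param tbl A count table tibble.
#' @return A tibble (`taxon_id`, `b`); taxa with zero total are excluded.
#' @export
niche_breadth <- function(tbl) {
  m <- as_count_matrix(tbl)
  tot <- rowSums(m)
  m <- m[tot > 0, , drop = FALSE]
  p <- m / rowSums(m)
  tibble::tibble(taxon_id = rownames(m), b = unname(1 / rowSums(p^2)))
}

#' Community-level niche breadth (Bcom)
#'
#' Per-sample average of taxon niche breadths over the taxa present in that
#' sample (unweighted by default; `weighted = TRUE` weights by the taxon's
#' relative abundance in the sample).
#'
#' @param tbl A count table tibble.
#' @param weighted Abundance-weight the average.
#' @return A tibble (`sample_id`, `bcom`).
#' @export
community_niche_breadth <- function(tbl, weighted = FALSE) {
  m <- as_count_matrix(tbl)
  nb <- niche_breadth(tbl)
  b <- setNames(nb$b, nb$taxon_id)
  purrr::map_dfr(colnames(m), function(s) {
    present <- rownames(m)[m[, s] > 0]
    if (length(present) == 0) return(tibble::tibble(sample_id = s, bcom = NA_real_))
    val <- if (weighted) {
      wgt <- m[present, s] / sum(m[present, s])
      sum(b[present] * wgt)
    } else {
      mean(b[present])
    }
    tibble::tibble(sample_id = s, bcom = val)
  })
}
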