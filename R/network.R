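# Ensemble co-occurrence network inference in the CoNet style: several
# association measures per taxon pair, an edge-wise permutation null with
# compositional renormalization, bootstrap "restoration" of unstable edges,
# Brown's correlated p-value merge across measures, and Benjamini-Hochberg
# control of the accepted edge set.

NETWORK_METHODS <- c("pearson", "spearman", "bray_curtis", "kl")

#' Pairwise association scores between taxa
#'
#' Scores every taxon pair with the requested measures on relative
#' abundances: Pearson and Spearman correlation across samples, Bray-Curtis
#' similarity (1 - dissimilarity) between taxon profiles, and symmetric
#' Kullback-Leibler divergence between row-normalized profiles (with a
#' per-taxon pseudocount of half the smallest nonzero relative abundance).
#' Pairs in which a taxon is constant get `NA` correlations and are flagged.
#'
#' @param tbl A count or relative-abundance table tibble (>= 4 samples).
#' @param methods Subset of `c("pearson", "spearman", "bray_curtis", "kl")`.
#' @return A tibble with `taxon_1`, `taxon_2`, one column per method, and
#'   `excluded` (TRUE when a correlation was undefined).
#' @export
edge_scores <- function(tbl, methods = NETWORK_METHODS) {
  methods <- match.arg(methods, NETWORK_METHODS, several.ok = TRUE)
  m <- as_count_matrix(tbl)
  if (ncol(m) < 4) abort("need at least 4 samples for association scores.")
  prop <- if (is_relative_matrix(m)) m else close_columns(m)
  mats <- lapply(setNames(methods, methods), function(mt) score_matrix(prop, mt))
  pair_table(rownames(m), mats)
}

# One taxa x taxa score matrix on a relative-abundance matrix.
score_matrix <- function(prop, method) {
  switch(method,
    pearson = suppressWarnings(stats::cor(t(prop))),
    spearman = suppressWarnings(stats::cor(apply(prop, 1, rank))),
    # a bootstrap resample can zero out a profile; vegdist then warns and
    # returns NaN for that row, which propagates as an NA score
    bray_curtis = 1 - as.matrix(suppressWarnings(vegan::vegdist(prop, method = "bray"))),
    kl = sym_kl_matrix(prop)
  )
}

sym_kl_matrix <- function(prop) {
  pc <- apply(prop, 1, function(x) {
    nz <- x[x > 0]
    if (length(nz) == 0) 1e-12 else min(nz) / 2
  })
  p <- prop + pc
  p <- p / rowSums(p)
  lp <- log(p)
  u <- rowSums(p * lp)
  cross <- p %*% t(lp)
  k <- outer(u, u, "+") - cross - t(cross)
  k[k < 0] <- 0
  diag(k) <- 0
  k
}

pair_table <- function(ids, mats) {
  n <- length(ids)
  ut <- which(upper.tri(matrix(0, n, n)))
  ij <- arrayInd(ut, c(n, n))
  out <- tibble::tibble(taxon_1 = ids[ij[, 1]], taxon_2 = ids[ij[, 2]])
  for (mt in names(mats)) out[[mt]] <- mats[[mt]][ut]
  corr <- intersect(c("pearson", "spearman"), names(mats))
  out$excluded <- if (length(corr)) {
    Reduce(`|`, lapply(corr, function(mt) is.na(out[[mt]])))
  } else {
    rep(FALSE, nrow(out))
  }
  out
}

#' Permutation null for one taxon pair
#'
#' Shuffles the two taxa's values across samples independently `n_perm`
#' times; with `renormalize = TRUE` (the ReBoot compositional correction)
#' the shuffled table's columns are re-closed to sum one before scoring, so
#' the null retains the spurious associations induced by closure. The
#' two-sided p-value is centred on the null mean with the add-one rule.
#'
#' @param tbl A count or relative-abundance table tibble.
#' @param pair Character vector of the two taxon ids.
#' @param method One association measure (see [edge_scores()]).
#' @param n_perm Number of permutations (>= 100 recommended; < 10 is an
#'   error).
#' @param seed Optional integer seed.
#' @param renormalize Re-close columns after shuffling.
#' @return A list: `observed`, `null` (length `n_perm`), `p`.
#' @export
permutation_null <- function(tbl, pair, method, n_perm = 1000, seed = NULL,
                             renormalize = TRUE) {
  method <- match.arg(method, NETWORK_METHODS)
  n_perm <- check_scalar_int(n_perm, "n_perm")
  if (n_perm < 10) abort("`n_perm` must be at least 10.")
  if (n_perm < 100) warn("fewer than 100 permutations gives a coarse p-value.")
  m <- as_count_matrix(tbl)
  prop <- if (is_relative_matrix(m)) m else close_columns(m)
  i <- match(pair[1], rownames(prop)); j <- match(pair[2], rownames(prop))
  if (anyNA(c(i, j))) abort("pair taxa not found in table.")
  obs <- pair_score(prop, i, j, method)
  nulls <- with_seed_if(seed, vapply(seq_len(n_perm), function(k) {
    ms <- prop
    ms[i, ] <- sample(ms[i, ])
    ms[j, ] <- sample(ms[j, ])
    if (renormalize) ms <- sweep(ms, 2, colSums(ms), "/")
    pair_score(ms, i, j, method)
  }, numeric(1)))
  mu <- mean(nulls, na.rm = TRUE)
  p <- (1 + sum(abs(nulls - mu) >= abs(obs - mu), na.rm = TRUE)) / (n_perm + 1)
  list(observed = obs, null = nulls, p = p)
}

pair_score <- function(prop, i, j, method) {
  x <- prop[i, ]; y <- prop[j, ]
  switch(method,
    pearson = suppressWarnings(stats::cor(x, y)),
    spearman = suppressWarnings(stats::cor(x, y, method = "spearman")),
    bray_curtis = 1 - sum(abs(x - y)) / sum(x + y),
    kl = {
      pcx <- min(x[x > 0]) / 2; pcy <- min(y[y > 0]) / 2
      px <- (x + pcx) / sum(x + pcx); py <- (y + pcy) / sum(y + pcy)
      sum((px - py) * (log(px) - log(py)))
    }
  )
}

#' Bootstrap restoration for one taxon pair
#'
#' Resamples samples with replacement, rescoring the pair, and builds the
#' 95% percentile interval of the score. The edge is "restored" (dropped)
#' when the null expectation lies inside the interval, i.e. the observed
#' association is not stable enough to exclude its null value.
#'
#' @inheritParams permutation_null
#' @param n_boot Number of bootstrap resamples.
#' @param null_mean Null expectation of the score (e.g. the permutation-null
#'   mean); 0 by default for correlation measures.
#' @return A list: `lower`, `upper`, `keep`, `n_skipped` (degenerate
#'   replicates where a correlation was undefined).
#' @export
bootstrap_restore <- function(tbl, pair, method, n_boot = 100, seed = NULL,
                              null_mean = 0) {
  method <- match.arg(method, NETWORK_METHODS)
  n_boot <- check_scalar_int(n_boot, "n_boot")
  m <- as_count_matrix(tbl)
  prop <- if (is_relative_matrix(m)) m else close_columns(m)
  i <- match(pair[1], rownames(prop)); j <- match(pair[2], rownames(prop))
  if (anyNA(c(i, j))) abort("pair taxa not found in table.")
  boots <- with_seed_if(seed, vapply(seq_len(n_boot), function(k) {
    cols <- sample.int(ncol(prop), replace = TRUE)
    pair_score(prop[, cols, drop = FALSE], i, j, method)
  }, numeric(1)))
  skipped <- sum(is.na(boots))
  qs <- quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(lower = qs[1], upper = qs[2],
       keep = null_mean < qs[1] || null_mean > qs[2],
       n_skipped = skipped)
}

#' Brown's p-value merge across correlated tests
#'
#' Fisher's statistic \eqn{-2\sum \ln p} referred to a scaled chi-square
#' whose scale and degrees of freedom come from the empirical covariance of
#' \eqn{-2 \ln p} across shared permutation replicates (Brown's
#' approximation for dependent tests).
#'
#' @param pvals One p-value per method (>= 2).
#' @param null_p_matrix Methods x replicates matrix of per-replicate
#'   pseudo p-values from a shared permutation null (>= 30 replicates).
#' @return The merged p-value.
#' @export
brown_merge <- function(pvals, null_p_matrix) {
  if (length(pvals) < 2) abort("Brown's method needs at least 2 p-values.")
  if (any(pvals <= 0 | pvals > 1)) abort("p-values must lie in (0, 1].")
  if (!is.matrix(null_p_matrix) || nrow(null_p_matrix) != length(pvals) ||
      ncol(null_p_matrix) < 30) {
    abort("`null_p_matrix` must have one row per p-value and >= 30 replicate columns.")
  }
  x <- -2 * log(pmax(null_p_matrix, 1e-300))
  v <- sum(stats::cov(t(x)))
  e <- 2 * length(pvals)
  stat <- -2 * sum(log(pvals))
  if (!is.finite(v) || v <= 0) { # degenerate: fall back to Fisher
    return(pchisq(stat, df = e, lower.tail = FALSE))
  }
  scale <- v / (2 * e)
  df <- 2 * e^2 / v
  pchisq(stat / scale, df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up control
#'
#' @param pvals Vector of p-values in (0, 1].
#' @param q Target false-discovery rate.
#' @return A tibble (`p`, `q_value`, `accepted`) in input order; `q_value`
#'   is the BH-adjusted p.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) abort("`pvals` must be non-empty.")
  if (any(is.na(pvals) | pvals <= 0 | pvals > 1)) abort("p-values must lie in (0, 1].")
  q <- check_fraction(q, "q")
  adj <- p.adjust(pvals, method = "BH")
  tibble::tibble(p = pvals, q_value = adj, accepted = adj <= q)
}

#' Build an ensemble co-occurrence network
#'
#' Full inference pipeline on the most abundant taxa: multi-measure scoring,
#' row-shuffling permutation null with compositional renormalization,
#' bootstrap restoration per measure, Brown merge of the surviving measures'
#' p-values, BH control at `q`, and sign assignment (mean of Pearson and
#' Spearman; edges whose two correlations disagree in sign are discarded).
#'
#' @param tbl A count table tibble; aggregated at `rank` first when
#'   `taxonomy` is supplied.
#' @param taxonomy Optional taxonomy tibble for aggregation and node
#'   annotation.
#' @param rank Rank at which to aggregate (default `"genus"`).
#' @param top_n Number of most abundant taxa to keep (default 100).
#' @param methods Association measures to combine.
#' @param n_perm Permutation replicates for the null.
#' @param n_boot Bootstrap replicates for restoration.
#' @param q BH false-discovery target.
#' @param seed Optional integer seed.
#' @param renormalize Apply the compositional renormalization in the null.
#' @return An object of class `halo_network`: `nodes`, `edges`,
#'   `candidates` (per-pair statistics), `topology` (see [topology()]) and
#'   `params`.
#' @export
build_network <- function(tbl, taxonomy = NULL, rank = "genus", top_n = 100,
                          methods = NETWORK_METHODS, n_perm = 1000,
                          n_boot = 100, q = 0.05, seed = NULL,
                          renormalize = TRUE) {
  methods <- match.arg(methods, NETWORK_METHODS, several.ok = TRUE)
  if (length(methods) < 2) abort("the ensemble needs at least 2 methods.")
  n_perm <- check_scalar_int(n_perm, "n_perm")
  n_boot <- check_scalar_int(n_boot, "n_boot")
  q <- check_fraction(q, "q")
  work <- tbl
  if (!is.null(taxonomy)) work <- aggregate_taxonomy(work, taxonomy, rank)
  work <- top_n_taxa(work, top_n)
  m <- as_count_matrix(work)
  if (ncol(m) < 5) abort("network inference needs at least 5 samples.")
  prop <- close_columns(m)
  n_taxa <- nrow(prop)
  ut <- which(upper.tri(matrix(0, n_taxa, n_taxa)))
  ij <- arrayInd(ut, c(n_taxa, n_taxa))

  obs <- lapply(setNames(methods, methods), function(mt) score_matrix(prop, mt)[ut])
  valid <- !Reduce(`|`, lapply(obs, is.na))

  seeds <- if (is.null(seed)) list(perm = NULL, boot = NULL) else
    list(perm = derive_seed(seed, "network::perm"), boot = derive_seed(seed, "network::boot"))

  # Permutation null: one row-shuffled, re-closed table per replicate scores
  # every pair at once.
  null_arr <- with_seed_if(seeds$perm, {
    lapply(seq_len(n_perm), function(k) {
      ms <- t(apply(prop, 1, sample))
      if (renormalize) ms <- sweep(ms, 2, colSums(ms), "/")
      lapply(setNames(methods, methods), function(mt) score_matrix(ms, mt)[ut])
    })
  })
  nulls <- lapply(setNames(methods, methods), function(mt) {
    do.call(cbind, lapply(null_arr, `[[`, mt)) # pairs x n_perm
  })
  rm(null_arr)

  null_mean <- lapply(nulls, function(x) rowMeans(x, na.rm = TRUE))
  p_obs <- lapply(setNames(methods, methods), function(mt) {
    dev <- abs(nulls[[mt]] - null_mean[[mt]])
    obs_dev <- abs(obs[[mt]] - null_mean[[mt]])
    (1 + rowSums(dev >= obs_dev, na.rm = TRUE)) / (n_perm + 1)
  })
  # Per-replicate pseudo p-values (rank of each replicate's deviation within
  # its own null) feed Brown's empirical covariance.
  xmat <- lapply(setNames(methods, methods), function(mt) {
    dev <- abs(nulls[[mt]] - null_mean[[mt]])
    pr <- t(apply(dev, 1, function(d) {
      (length(d) - rank(d, ties.method = "min", na.last = "keep") + 1) / length(d)
    }))
    -2 * log(pr) # pr >= 1/n_perm by construction
  })
  rm(nulls)

  boot_arr <- with_seed_if(seeds$boot, {
    lapply(seq_len(n_boot), function(k) {
      cols <- sample.int(ncol(prop), replace = TRUE)
      lapply(setNames(methods, methods), function(mt) score_matrix(prop[, cols, drop = FALSE], mt)[ut])
    })
  })
  survive <- vapply(setNames(methods, methods), function(mt) {
    bm <- do.call(cbind, lapply(boot_arr, `[[`, mt))
    lo <- apply(bm, 1, quantile, probs = 0.025, na.rm = TRUE)
    hi <- apply(bm, 1, quantile, probs = 0.975, na.rm = TRUE)
    null_mean[[mt]] < lo | null_mean[[mt]] > hi
  }, logical(length(ut)))
  rm(boot_arr)
  survive[is.na(survive)] <- FALSE
  n_survive <- rowSums(survive)

  merged <- brown_merge_vectorized(p_obs, xmat, survive, methods)
  cand_keep <- valid & n_survive >= 2 & !is.na(merged)

  candidates <- tibble::tibble(
    taxon_1 = rownames(prop)[ij[, 1]], taxon_2 = rownames(prop)[ij[, 2]],
    n_methods_surviving = n_survive, merged_p = merged
  )
  for (mt in methods) {
    candidates[[mt]] <- obs[[mt]]
    candidates[[paste0("p_", mt)]] <- p_obs[[mt]]
  }
  candidates <- assign_signs(candidates, null_mean, methods)

  edges <- candidates[cand_keep & !candidates$sign_conflict, , drop = FALSE]
  if (nrow(edges) > 0) {
    fdr <- bh_fdr(edges$merged_p, q)
    edges$q_value <- fdr$q_value
    edges <- edges[fdr$accepted, , drop = FALSE]
  } else {
    edges$q_value <- numeric(0)
  }

  nodes <- tibble::tibble(taxon_id = rownames(prop),
                          total_abundance = rowSums(m))
  if (!is.null(taxonomy) && "phylum" %in% names(taxonomy)) {
    ph <- taxonomy$phylum[match(nodes$taxon_id, taxonomy[[rank]])]
    nodes$phylum <- ph
  }
  net <- structure(list(nodes = nodes, edges = edges, candidates = candidates,
                        params = list(methods = methods, top_n = top_n,
                                      n_perm = n_perm, n_boot = n_boot, q = q,
                                      seed = seed, renormalize = renormalize)),
                   class = "halo_network")
  net$topology <- topology(net)
  net
}

brown_merge_vectorized <- function(p_obs, xmat, survive, methods) {
  n_pairs <- length(p_obs[[1]])
  n_rep <- ncol(xmat[[1]])
  means <- lapply(xmat, rowMeans)
  # empirical covariance of -2 ln p between each method pair, per taxon pair
  v <- numeric(n_pairs); e <- numeric(n_pairs); stat <- numeric(n_pairs)
  for (a in seq_along(methods)) {
    sa <- survive[, a]
    e <- e + 2 * sa
    stat <- stat - 2 * log(p_obs[[methods[a]]]) * sa
    for (b in seq_along(methods)) {
      sb <- survive[, b]
      cov_ab <- (rowSums(xmat[[methods[a]]] * xmat[[methods[b]]]) -
                   n_rep * means[[methods[a]]] * means[[methods[b]]]) / (n_rep - 1)
      v <- v + cov_ab * sa * sb
    }
  }
  out <- rep(NA_real_, n_pairs)
  ok <- e >= 4 # at least two surviving methods
  fisher <- ok & (v <= 0 | !is.finite(v))
  out[fisher] <- pchisq(stat[fisher], df = e[fisher], lower.tail = FALSE)
  br <- ok & !fisher
  out[br] <- pchisq(stat[br] * 2 * e[br] / v[br], df = 2 * e[br]^2 / v[br],
                    lower.tail = FALSE)
  out
}

# Sign per candidate pair: mean of the two rank/linear correlations when
# both are in play (conflicting signs are flagged for discard); otherwise
# the single correlation; otherwise similarity above/below its null mean.
assign_signs <- function(candidates, null_mean, methods) {
  corr <- intersect(c("pearson", "spearman"), methods)
  if (length(corr) == 2) {
    candidates$sign_conflict <- !is.na(candidates$pearson) & !is.na(candidates$spearman) &
      sign(candidates$pearson) * sign(candidates$spearman) < 0
    candidates$sign <- ifelse((candidates$pearson + candidates$spearman) / 2 >= 0,
                              "positive", "negative")
  } else if (length(corr) == 1) {
    candidates$sign_conflict <- FALSE
    candidates$sign <- ifelse(candidates[[corr]] >= 0, "positive", "negative")
  } else {
    candidates$sign_conflict <- FALSE
    ref <- if ("bray_curtis" %in% methods) "bray_curtis" else methods[1]
    candidates$sign <- ifelse(candidates[[ref]] >= null_mean[[ref]],
                              "positive", "negative")
  }
  candidates
}

#' Topology metrics of a co-occurrence network
#'
#' Node and edge counts, mean local clustering coefficient (nodes with fewer
#' than two neighbours contribute zero), average number of neighbours
#' \eqn{2E/N}, directed-convention density \eqn{E/(N(N-1))}, diameter of the
#' largest connected component, and the percentage of positive and negative
#' edges.
#'
#' @param net A `halo_network`, an `igraph` graph, or an edge tibble with
#'   `taxon_1`/`taxon_2` (plus optional `sign`) — in the latter case supply
#'   `n_nodes` for isolated vertices.
#' @param n_nodes Total node count when `net` is an edge tibble.
#' @return A one-row tibble of metrics.
#' @export
topology <- function(net, n_nodes = NULL) {
  if (inherits(net, "halo_network")) {
    g <- network_igraph(net)
    signs <- net$edges$sign
  } else if (inherits(net, "igraph")) {
    g <- net
    signs <- igraph::edge_attr(g, "sign")
  } else if (is.data.frame(net)) {
    verts <- unique(c(net$taxon_1, net$taxon_2))
    if (!is.null(n_nodes) && n_nodes > length(verts)) {
      verts <- c(verts, paste0(".isolated", seq_len(n_nodes - length(verts))))
    }
    g <- igraph::graph_from_data_frame(net[, c("taxon_1", "taxon_2")],
                                       directed = FALSE, vertices = verts)
    signs <- net$sign
  } else {
    abort("unsupported input to topology().")
  }
  if (igraph::any_multiple(g) || any(igraph::which_loop(g))) {
    abort("network must be a simple graph (no loops or multi-edges).")
  }
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  diam <- if (e == 0) 0 else {
    comp <- igraph::components(g)
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    igraph::diameter(sub, weights = NA)
  }
  pos <- if (!is.null(signs) && length(signs)) 100 * mean(signs == "positive") else NA_real_
  tibble::tibble(
    n_nodes = n, n_edges = e,
    clustering_coefficient = if (e == 0) 0 else
      igraph::transitivity(g, type = "localaverage", isolates = "zero"),
    mean_neighbors = if (n > 0) 2 * e / n else 0,
    density = if (n > 1) e / (n * (n - 1)) else 0,
    diameter = diam,
    positive_pct = pos,
    negative_pct = if (is.na(pos)) NA_real_ else 100 - pos
  )
}

network_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, intersect(c("taxon_1", "taxon_2", "sign"), names(net$edges)), drop = FALSE],
    directed = FALSE, vertices = net$nodes$taxon_id)
}

#' @export
print.halo_network <- function(x, ...) {
  cat(sprintf("Ensemble co-occurrence network: %d nodes, %d edges (q <= %g)\n",
              nrow(x$nodes), nrow(x$edges), x$params$q))
  print(x$topology)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.halo_network <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.halo_network <- function(x, ...) x$topology
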