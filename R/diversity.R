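# Alpha-diversity estimators. The vector-level estimators are deliberately
# explicit about their degenerate branches (no singletons, empty rare class,
# all-singleton rare class) because those drive the error contracts.

check_counts_vector <- function(x, arg = "counts") {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) abort(sprintf("`%s` must be a numeric vector without NA.", arg))
  if (any(x < 0)) abort(sprintf("`%s` has negative entries.", arg))
  if (sum(x) <= 0) abort(sprintf("`%s` is all zero; diversity is undefined.", arg))
  x[x > 0]
}

#' Shannon diversity of one sample
#'
#' \eqn{H = -\sum_i p_i \log_b p_i} over taxa with positive counts.
#'
#' @param counts Non-negative abundance vector for one sample.
#' @param base Logarithm base (> 1); natural log by default.
#' @return Shannon index (nats for the default base).
#' @examples shannon(c(5, 3, 2))
#' @export
shannon <- function(counts, base = exp(1)) {
  x <- check_counts_vector(counts)
  if (!is.numeric(base) || length(base) != 1 || base <= 1) abort("`base` must be a single number > 1.")
  p <- x / sum(x)
  -sum(p * log(p)) / log(base)
}

#' Simpson dominance of one sample
#'
#' The concentration form \eqn{D = \sum_i p_i^2}: 1 for a single-taxon
#' community, \eqn{1/S} for a perfectly even one. Larger values mean lower
#' diversity.
#'
#' @inheritParams shannon
#' @return Dominance in (0, 1].
#' @export
simpson_dominance <- function(counts) {
  x <- check_counts_vector(counts)
  p <- x / sum(x)
  sum(p^2)
}

#' Bias-corrected Chao1 richness
#'
#' \eqn{S_{obs} + F_1(F_1-1) / (2(F_2+1))} with \eqn{F_1, F_2} the singleton
#' and doubleton counts; the bias-corrected form stays defined when
#' \eqn{F_2 = 0}.
#'
#' @inheritParams shannon
#' @return Estimated richness (>= observed richness).
#' @export
chao1 <- function(counts) {
  x <- check_counts_vector(counts)
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' ACE richness estimator
#'
#' Classical abundance-based coverage estimator with rare class
#' `counts <= rare_cutoff`. When every rare-class read is a singleton the
#' sample coverage is zero and ACE is undefined; the function then falls back
#' to [chao1()] with a warning.
#'
#' @inheritParams shannon
#' @param rare_cutoff Count threshold separating rare from abundant taxa.
#' @return Estimated richness.
#' @export
ace <- function(counts, rare_cutoff = 10) {
  x <- check_counts_vector(counts)
  rare_cutoff <- check_scalar_int(rare_cutoff, "rare_cutoff")
  rare <- x[x <= rare_cutoff]
  s_abund <- sum(x > rare_cutoff)
  if (length(rare) == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) {
    warn("ACE undefined (all rare-class reads are singletons); returning Chao1 instead.")
    return(chao1(counts))
  }
  fk <- tabulate(rare, nbins = rare_cutoff)
  g2 <- max(length(rare) * sum(seq_len(rare_cutoff) * (seq_len(rare_cutoff) - 1) * fk) /
              (c_ace * n_rare * (n_rare - 1)) - 1, 0)
  s_abund + length(rare) / c_ace + f1 / c_ace * g2
}

#' Good's coverage of one sample
#'
#' \eqn{1 - F_1 / N}: the estimated fraction of the community's reads that
#' belong to taxa already observed.
#'
#' @inheritParams shannon
#' @return Coverage in \[0, 1\].
#' @export
goods_coverage <- function(counts) {
  x <- check_counts_vector(counts)
  1 - sum(x == 1) / sum(x)
}

#' Per-sample alpha-diversity table
#'
#' Computes observed richness, Shannon, Simpson dominance, Chao1, ACE and
#' Good's coverage for every sample of a count table.
#'
#' @param tbl A count table tibble.
#' @param base Shannon logarithm base.
#' @param rare_cutoff ACE rare-class cutoff.
#' @return A tibble with one row per sample.
#' @examples alpha_diversity(example_counts())
#' @export
alpha_diversity <- function(tbl, base = exp(1), rare_cutoff = 10) {
  m <- as_count_matrix(tbl)
  purrr::map_dfr(colnames(m), function(s) {
    x <- m[, s]
    tibble::tibble(
      sample_id = s,
      observed_richness = sum(x > 0),
      shannon = shannon(x, base = base),
      simpson = simpson_dominance(x),
      chao1 = chao1(x),
      ace = suppressWarnings(ace(x, rare_cutoff = rare_cutoff)),
      goods_coverage = goods_coverage(x)
    )
  })
}

#' Rarefaction curves
#'
#' Mean observed richness and Shannon index over repeated subsamples at each
#' requested depth, per sample. Depths exceeding a sample's total are skipped
#' for that sample with a message.
#'
#' @param tbl A count table tibble of integer counts.
#' @param depths Increasing vector of positive integer depths.
#' @param replicates Subsamples averaged per depth.
#' @param seed Optional integer seed.
#' @return A long tibble: `sample_id`, `depth`, `observed_richness`,
#'   `shannon`.
#' @export
rarefaction_curve <- function(tbl, depths, replicates = 10, seed = NULL) {
  if (length(depths) == 0) abort("`depths` must be a non-empty vector of positive integers.")
  depths <- vapply(depths, check_scalar_int, integer(1), arg = "depths")
  replicates <- check_scalar_int(replicates, "replicates")
  m <- as_count_matrix(tbl)
  check_integerish(m)
  tot <- colSums(m)
  with_seed_if(seed, {
    purrr::map_dfr(colnames(m), function(s) {
      ok <- depths <= tot[s]
      if (any(!ok)) {
        inform(sprintf("sample '%s': skipping %d depth(s) above its total %d.",
                       s, sum(!ok), tot[s]))
      }
      purrr::map_dfr(depths[ok], function(d) {
        reps <- vapply(seq_len(replicates), function(i) {
          sub <- if (d == tot[s]) m[, s] else draw_hypergeometric(m[, s], d)
          c(sum(sub > 0), shannon(sub))
        }, numeric(2))
        tibble::tibble(sample_id = s, depth = d,
                       observed_richness = mean(reps[1, ]),
                       shannon = mean(reps[2, ]))
      })
    })
  })
}
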