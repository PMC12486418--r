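# Seeded community generators mirroring a 4-pond salinity-gradient design:
# neutral assembly (drift + immigration from a shared metacommunity),
# Gaussian environmental filtering along salinity, latent-copula planted
# correlations, and a mixed gradient combining the first two.

#' Parameters of the synthetic community generators
#'
#' Defaults echo the emulated study design: 4 ponds at salinities
#' 31/39/47/55 psu, ~6 samples per pond, ~30,000 reads per sample, hundreds
#' of taxa with log-normal metacommunity abundances.
#'
#' @param S Number of taxa in the metacommunity.
#' @param n_samples Samples per group.
#' @param depth Reads per sample.
#' @param meta_sigma Log-normal shape of metacommunity abundances.
#' @param m Immigration (migration) rate in (0, 1].
#' @param filter_sigma Gaussian niche width along salinity (psu).
#' @param group_salinities Named group salinities (psu).
#' @param mix_max Maximum neutral/filtered mixing weight reached by the last
#'   group of the gradient design.
#' @param diversity_decline Shrink the filter width along the gradient so
#'   alpha diversity also declines (see [simulate_gradient_dataset()]).
#' @param planted_edges Tibble (`taxon_1`, `taxon_2`, `rho`) of latent
#'   correlations for [simulate_correlated()]; taxa given as integer indices
#'   or ids `OTU<index>`.
#' @param latent_sigma Log-scale dispersion of the latent abundance noise.
#' @param seed Integer seed; every generator is bit-reproducible given the
#'   spec.
#' @return An object of class `halo_spec`.
#' @export
synthetic_spec <- function(S = 500, n_samples = 6, depth = 30000,
                           meta_sigma = 2, m = 0.1, filter_sigma = 3,
                           group_salinities = c(A = 31, B = 39, C = 47, D = 55),
                           mix_max = 0.9, diversity_decline = TRUE,
                           planted_edges = NULL, latent_sigma = 1, seed = 1) {
  S <- check_scalar_int(S, "S"); n_samples <- check_scalar_int(n_samples, "n_samples")
  depth <- check_scalar_int(depth, "depth")
  if (m <= 0 || m > 1) abort("`m` must lie in (0, 1].")
  if (filter_sigma <= 0) abort("`filter_sigma` must be positive.")
  if (meta_sigma <= 0) abort("`meta_sigma` must be positive.")
  mix_max <- check_fraction(mix_max, "mix_max")
  seed <- check_scalar_int(seed, "seed", min = 0L)
  structure(list(S = S, n_samples = n_samples, depth = depth,
                 meta_sigma = meta_sigma, m = m, filter_sigma = filter_sigma,
                 group_salinities = group_salinities, mix_max = mix_max,
                 diversity_decline = diversity_decline,
                 planted_edges = planted_edges, latent_sigma = latent_sigma,
                 seed = seed),
            class = "halo_spec")
}

check_spec <- function(spec) {
  if (!inherits(spec, "halo_spec")) abort("`spec` must come from synthetic_spec().")
  spec
}

taxon_ids <- function(S) sprintf("OTU%04d", seq_len(S))
sample_ids <- function(n, prefix = "S") sprintf("%s%02d", prefix, seq_len(n))

meta_proportions <- function(spec) {
  p <- rlnorm(spec$S, meanlog = 0, sdlog = spec$meta_sigma)
  p / sum(p)
}

#' Simulate a neutral metacommunity sample set
#'
#' Metacommunity proportions `p` are drawn once from a log-normal; each
#' sample's composition is Dirichlet with concentration `depth * m * p` —
#' whose marginals are the Beta distributions of the Sloan neutral model —
#' and counts are multinomial at the requested depth.
#'
#' @param spec A [synthetic_spec()].
#' @param n_samples Total number of samples (defaults to samples-per-group
#'   times the number of groups, i.e. a whole study's worth).
#' @return A count table tibble.
#' @export
simulate_neutral <- function(spec, n_samples = NULL) {
  spec <- check_spec(spec)
  n <- n_samples %||% (spec$n_samples * length(spec$group_salinities))
  with_seed_if(spec$seed, {
    p <- meta_proportions(spec)
    counts <- vapply(seq_len(n), function(j) {
      g <- rgamma(spec$S, shape = spec$depth * spec$m * p)
      if (sum(g) <= 0) g <- p
      rmultinom(1, spec$depth, g / sum(g))[, 1]
    }, numeric(spec$S))
    dimnames(counts) <- list(taxon_ids(spec$S), sample_ids(n))
    as_count_tbl(counts)
  })
}

#' Simulate environmentally filtered communities
#'
#' Each taxon receives a salinity optimum uniform over the gradient range;
#' sample-level weights are the metacommunity proportions damped by a
#' Gaussian kernel \eqn{\exp(-(salinity - optimum)^2 / (2\sigma^2))} and
#' counts are multinomial. Small `filter_sigma` means strong filtering.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `counts` (count table tibble) and `metadata` (tibble with
#'   `sample_id`, `group`, `salinity`).
#' @export
simulate_filtered <- function(spec) {
  spec <- check_spec(spec)
  sal <- spec$group_salinities
  with_seed_if(spec$seed, {
    p <- meta_proportions(spec)
    opt <- runif(spec$S, min(sal), max(sal))
    res <- filtered_counts(spec, p, opt, rep(spec$filter_sigma, length(sal)))
    res
  })
}

# Shared machinery: multinomial draws from filtered weights per group.
filtered_counts <- function(spec, p, opt, sigma_by_group, mix = NULL, m_dirichlet = NULL) {
  sal <- spec$group_salinities
  groups <- names(sal) %||% LETTERS[seq_along(sal)]
  cols <- list(); meta <- list()
  for (g in seq_along(sal)) {
    w_filter <- p * exp(-(sal[g] - opt)^2 / (2 * sigma_by_group[g]^2))
    if (sum(w_filter) <= 0) w_filter <- p
    w_filter <- w_filter / sum(w_filter)
    for (j in seq_len(spec$n_samples)) {
      w <- if (is.null(mix)) {
        w_filter
      } else {
        gam <- rgamma(spec$S, shape = spec$depth * spec$m * p)
        neutral <- if (sum(gam) > 0) gam / sum(gam) else p
        (1 - mix[g]) * neutral + mix[g] * w_filter
      }
      cols[[length(cols) + 1]] <- rmultinom(1, spec$depth, w)[, 1]
      meta[[length(meta) + 1]] <- tibble::tibble(
        sample_id = sprintf("%s%02d", groups[g], j),
        group = groups[g], salinity = unname(sal[g]))
    }
  }
  counts <- do.call(cbind, cols)
  md <- dplyr::bind_rows(meta)
  dimnames(counts) <- list(taxon_ids(spec$S), md$sample_id)
  list(counts = as_count_tbl(counts), metadata = md)
}

#' Simulate communities with planted correlations
#'
#' A latent Gaussian copula carries the requested pairwise correlations;
#' latent values are pushed through a log-normal onto heterogeneous
#' baseline abundances, closed to proportions and sampled as multinomial
#' counts. Non-planted taxa are independent in the latent layer.
#'
#' @param spec A [synthetic_spec()] with `planted_edges` set (or not, for a
#'   signal-free table).
#' @param n_samples Number of samples (default 30).
#' @return A count table tibble.
#' @export
simulate_correlated <- function(spec, n_samples = 30) {
  spec <- check_spec(spec)
  S <- spec$S
  sigma <- diag(S)
  pe <- spec$planted_edges
  if (!is.null(pe) && nrow(pe)) {
    i1 <- planted_index(pe$taxon_1, S); i2 <- planted_index(pe$taxon_2, S)
    if (any(i1 == i2)) abort("planted edges must join distinct taxa.")
    for (k in seq_len(nrow(pe))) {
      sigma[i1[k], i2[k]] <- sigma[i2[k], i1[k]] <- pe$rho[k]
    }
  }
  ev <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) abort("requested correlation structure is not positive definite.")
  with_seed_if(spec$seed, {
    p <- meta_proportions(spec)
    z <- MASS::mvrnorm(n_samples, mu = rep(0, S), Sigma = sigma)
    counts <- vapply(seq_len(n_samples), function(j) {
      a <- p * exp(spec$latent_sigma * z[j, ])
      rmultinom(1, spec$depth, a / sum(a))[, 1]
    }, numeric(S))
    dimnames(counts) <- list(taxon_ids(S), sample_ids(n_samples))
    as_count_tbl(counts)
  })
}

planted_index <- function(x, S) {
  idx <- if (is.numeric(x)) as.integer(x) else match(as.character(x), taxon_ids(S))
  if (anyNA(idx) || any(idx < 1) || any(idx > S)) abort("planted edge taxa out of range.")
  idx
}

#' Simulate the 4-pond salinity-gradient study design
#'
#' Group g's samples mix a per-sample neutral Dirichlet draw with the
#' group's filtered weight profile; the mixing weight rises linearly from 0
#' (first group: purely neutral) to `mix_max` (last group: strongly
#' filtered). With `diversity_decline = TRUE` the filter width also shrinks
#' along the gradient, so richness and Shannon diversity fall with salinity.
#'
#' @param spec A [synthetic_spec()].
#' @return A list: `counts`, `metadata`, and `truth` (the generating
#'   parameters: mixing weights, per-group filter widths, `m`, seed).
#' @export
simulate_gradient_dataset <- function(spec) {
  spec <- check_spec(spec)
  sal <- spec$group_salinities
  G <- length(sal)
  mix <- seq(0, spec$mix_max, length.out = G)
  sigma_by_group <- if (isTRUE(spec$diversity_decline)) {
    spec$filter_sigma * rev(seq_len(G)) / G
  } else {
    rep(spec$filter_sigma, G)
  }
  res <- with_seed_if(spec$seed, {
    p <- meta_proportions(spec)
    opt <- runif(spec$S, min(sal), max(sal))
    filtered_counts(spec, p, opt, sigma_by_group, mix = mix)
  })
  res$truth <- list(mix = mix, filter_sigma = sigma_by_group, m = spec$m,
                    depth = spec$depth, S = spec$S, seed = spec$seed,
                    group_salinities = sal)
  res
}
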