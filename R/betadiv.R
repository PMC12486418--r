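# Beta diversity: Bray-Curtis distances, principal coordinates, PERMANOVA
# and average-linkage clustering. Distances are carried as base `dist`
# objects, the currency of the vegan/ape ecosystem.

#' Bray-Curtis distance between samples
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} over the taxa of
#' two samples; bounded in \[0, 1\].
#'
#' @param tbl A count or relative-abundance table tibble.
#' @return A `dist` object labelled with the sample ids.
#' @examples bray_curtis(example_counts())
#' @export
bray_curtis <- function(tbl) {
  m <- as_count_matrix(tbl)
  if (ncol(m) < 2) abort("need at least 2 samples for a distance matrix.")
  close_columns(m) # validates positive totals
  vegan::vegdist(t(m), method = "bray")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a sample distance matrix (eigendecomposition
#' of the double-centred Gower matrix). Negative eigenvalues are reported
#' raw; `proportion_explained` is computed over the positive eigenvalues.
#'
#' @param dm A `dist` object or symmetric square matrix with zero diagonal.
#' @return An object of class `halo_pcoa`: `coordinates` (tibble, one row per
#'   sample), `eigenvalues`, `proportion_explained`.
#' @export
pcoa <- function(dm) {
  dm <- as_distance(dm)
  n <- attr(dm, "Size")
  fit <- suppressWarnings(stats::cmdscale(dm, k = n - 1, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) == 0) { # fully degenerate: all samples coincide
    pts <- matrix(0, n, 1, dimnames = list(labels(dm), NULL))
  }
  colnames(pts) <- paste0("Axis.", seq_len(ncol(pts)))
  eig <- fit$eig
  pos <- pmax(eig, 0)
  structure(list(
    coordinates = tibble::as_tibble(as.data.frame(pts), rownames = "sample_id"),
    eigenvalues = eig,
    proportion_explained = if (sum(pos) > 0) pos / sum(pos) else rep(0, length(eig))
  ), class = "halo_pcoa")
}

as_distance <- function(dm) {
  if (inherits(dm, "dist")) {
    if (anyNA(dm)) abort("distance matrix contains NA/NaN.")
    return(dm)
  }
  m <- as.matrix(dm)
  if (anyNA(m)) abort("distance matrix contains NA/NaN.")
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-12) || any(abs(diag(m)) > 1e-12)) {
    abort("`dm` must be symmetric with a zero diagonal.")
  }
  as.dist(m)
}

#' @export
print.halo_pcoa <- function(x, ...) {
  pe <- x$proportion_explained
  cat(sprintf("PCoA of %d samples; first two axes explain %.2f%% of positive-eigenvalue variation\n",
              nrow(x$coordinates), 100 * sum(pe[seq_len(min(2, length(pe)))])))
  print(x$coordinates, n = 5)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.halo_pcoa <- function(x, ...) x$coordinates

#' @exportS3Method generics::glance
glance.halo_pcoa <- function(x, ...) {
  pe <- x$proportion_explained
  tibble::tibble(n_samples = nrow(x$coordinates),
                 n_positive_axes = sum(x$eigenvalues > 1e-12),
                 prop_axis1 = pe[1],
                 prop_axis2 = if (length(pe) > 1) pe[2] else NA_real_)
}

#' Permutational multivariate analysis of variance
#'
#' Anderson's PERMANOVA on a distance matrix, delegated to
#' [vegan::adonis2()] with raw label permutation and the add-one p-value
#' rule: \eqn{p = (1 + \#\{F^{perm} \ge F\}) / (n_{perm} + 1)}.
#'
#' @param dm A `dist` object (or symmetric matrix) over samples.
#' @param groups Group label per sample, aligned with `labels(dm)`.
#' @param n_perm Number of label permutations.
#' @param seed Optional integer seed for the permutation stream.
#' @return A one-row tibble: `pseudo_f`, `r2`, `p_value`, `n_perm`,
#'   `df_between`, `df_within`.
#' @export
permanova <- function(dm, groups, n_perm = 999, seed = NULL) {
  dm <- as_distance(dm)
  n_perm <- check_scalar_int(n_perm, "n_perm")
  g <- factor(groups)
  if (length(g) != attr(dm, "Size")) abort("`groups` must have one label per sample in `dm`.")
  if (nlevels(g) < 2) abort("PERMANOVA needs at least 2 groups.")
  if (any(table(g) < 2)) abort("every group needs at least 2 samples.")
  fit <- with_seed_if(seed, vegan::adonis2(dm ~ g, permutations = n_perm))
  tibble::tibble(
    pseudo_f = fit$F[1],
    r2 = fit$R2[1],
    p_value = fit$`Pr(>F)`[1],
    n_perm = n_perm,
    df_between = fit$Df[1],
    df_within = fit$Df[2]
  )
}

#' UPGMA clustering of samples
#'
#' Average-linkage agglomeration of a distance matrix into an ultrametric
#' tree. Samples are sorted lexicographically before clustering so ties
#' resolve deterministically.
#'
#' @param dm A `dist` object (or symmetric matrix) over samples.
#' @return An [ape] `phylo` tree with branch lengths; write it to newick with
#'   [ape::write.tree()].
#' @export
upgma <- function(dm) {
  dm <- as_distance(dm)
  m <- as.matrix(dm)
  if (nrow(m) < 2) abort("need at least 2 samples.")
  ord <- order(rownames(m))
  hc <- stats::hclust(as.dist(m[ord, ord]), method = "average")
  ape::as.phylo(hc)
}
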