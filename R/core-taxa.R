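# Core-microbiome detection: taxa that are both persistent (occurrence
# fraction) and abundant (mean relative abundance) within a sample set.

#' Identify core taxa
#'
#' A taxon is core when it occurs (count > 0) in at least
#' `occurrence_min` of the samples AND its unweighted mean per-sample
#' relative abundance is at least `mean_ra_min`. Both comparisons are
#' inclusive.
#'
#' @param tbl A count table tibble.
#' @param occurrence_min Minimum occurrence fraction (default 0.8).
#' @param mean_ra_min Minimum mean relative abundance (default 0.001, i.e.
#'   0.1%).
#' @return A tibble of core taxa (`taxon_id`, `occurrence`, `mean_ra`),
#'   sorted by decreasing mean relative abundance, with attributes
#'   `core_fraction_of_reads` (share of all reads in core taxa) and
#'   `n_samples`.
#' @examples find_core(example_counts(), occurrence_min = 0.5)
#' @export
find_core <- function(tbl, occurrence_min = 0.8, mean_ra_min = 0.001) {
  occurrence_min <- check_fraction(occurrence_min, "occurrence_min")
  mean_ra_min <- check_fraction(mean_ra_min, "mean_ra_min")
  m <- as_count_matrix(tbl)
  prop <- close_columns(m)
  occ <- rowMeans(m > 0)
  mra <- rowMeans(prop)
  keep <- occ >= occurrence_min & mra >= mean_ra_min
  out <- tibble::tibble(taxon_id = rownames(m)[keep],
                        occurrence = unname(occ[keep]),
                        mean_ra = unname(mra[keep]))
  out <- out[order(-out$mean_ra, out$taxon_id), , drop = FALSE]
  attr(out, "core_fraction_of_reads") <- sum(m[keep, , drop = FALSE]) / sum(m)
  attr(out, "n_samples") <- ncol(m)
  out
}

#' Per-group core sets
#'
#' Splits the samples by a metadata group label and runs [find_core()]
#' within each group.
#'
#' @inheritParams find_core
#' @param metadata Tibble with `sample_id` and `group` columns covering every
#'   sample of `tbl`.
#' @return A tibble of core taxa with a leading `group` column and a
#'   `core_fraction_of_reads` column per row's group.
#' @export
core_sets <- function(tbl, metadata, occurrence_min = 0.8, mean_ra_min = 0.001) {
  m <- as_count_matrix(tbl)
  miss <- setdiff(colnames(m), metadata$sample_id)
  if (length(miss)) abort(sprintf("samples missing from metadata: %s", paste(miss, collapse = ", ")))
  grp <- setNames(as.character(metadata$group), metadata$sample_id)[colnames(m)]
  purrr::map_dfr(unique(grp), function(g) {
    sub <- as_count_tbl(m[, grp == g, drop = FALSE])
    core <- find_core(sub, occurrence_min, mean_ra_min)
    if (nrow(core) == 0) {
      return(tibble::tibble(group = character(), taxon_id = character(),
                            occurrence = numeric(), mean_ra = numeric(),
                            core_fraction_of_reads = numeric()))
    }
    dplyr::mutate(core, group = g,
                  core_fraction_of_reads = attr(core, "core_fraction_of_reads"),
                  .before = 1)
  })
}

#' Shared core across groups
#'
#' Intersection of the core taxon ids of two or more core sets.
#'
#' @param coresets Either the tibble returned by [core_sets()] (intersected
#'   across its `group` values) or a list of core tibbles / character vectors
#'   of taxon ids.
#' @return A sorted character vector of shared taxon ids.
#' @export
shared_core <- function(coresets) {
  sets <- if (is.data.frame(coresets)) {
    if (!"group" %in% names(coresets)) abort("data-frame input needs a `group` column; use core_sets().")
    split(coresets$taxon_id, coresets$group)
  } else if (is.list(coresets)) {
    lapply(coresets, function(x) if (is.data.frame(x)) x$taxon_id else as.character(x))
  } else {
    abort("`coresets` must be a core_sets() tibble or a list of core sets.")
  }
  if (length(sets) < 2) abort("need at least 2 core sets to intersect.")
  sort(Reduce(intersect, sets))
}

#' Fraction of reads captured by a core set
#'
#' @param tbl A count table tibble.
#' @param core A core tibble (with `taxon_id`) or character vector of taxon
#'   ids, all present in `tbl`.
#' @return Sum of counts over core taxa divided by the grand total.
#' @export
core_fraction <- function(tbl, core) {
  m <- as_count_matrix(tbl)
  ids <- if (is.data.frame(core)) core$taxon_id else as.character(core)
  miss <- setdiff(ids, rownames(m))
  if (length(miss)) abort(sprintf("core taxa not in table: %s", paste(miss, collapse = ", ")))
  if (length(ids) == 0) return(0)
  sum(m[ids, , drop = FALSE]) / sum(m)
}
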