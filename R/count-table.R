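#' Read a taxon-by-sample count table
#'
#' Reads a tab-separated abundance table with taxa as rows and samples as
#' columns (header row = sample ids, first column = taxon ids). Every cell
#' must parse as a non-negative number; unless `relative = TRUE` cells must
#' additionally be whole counts.
#'
#' @param path Path to a tab-separated file.
#' @param transpose If `TRUE` the file stores samples as rows and taxa as
#'   columns and is transposed on read.
#' @param relative Accept fractional (relative-abundance) values instead of
#'   integer counts.
#' @return A tibble with a `taxon_id` column followed by one numeric column
#'   per sample, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_count_table(example_counts(), tf)
#' read_count_table(tf)
#' @export
read_count_table <- function(path, transpose = FALSE, relative = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("count table needs an id column plus at least one data column.")
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated row id(s) in %s: %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (anyDuplicated(names(raw)[-1])) abort(sprintf("duplicated column id(s) in %s.", path))
  num <- lapply(names(raw)[-1], function(s) {
    v <- suppressWarnings(as.numeric(raw[[s]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      abort(sprintf("cell for taxon '%s', sample '%s' does not parse as a number (value '%s').",
                    ids[i], s, raw[[s]][i]))
    }
    if (any(v < 0)) {
      i <- which(v < 0)[1]
      abort(sprintf("negative abundance for taxon '%s' in sample '%s'.", ids[i], s))
    }
    if (!relative && any(abs(v - round(v)) > 1e-8)) {
      i <- which(abs(v - round(v)) > 1e-8)[1]
      abort(sprintf("non-integer count for taxon '%s' in sample '%s'; use `relative = TRUE` for proportion tables.",
                    ids[i], s))
    }
    v
  })
  names(num) <- names(raw)[-1]
  tbl <- tibble::tibble(taxon_id = ids, !!!num)
  if (transpose) {
    m <- as_count_matrix(tbl)
    tbl <- as_count_tbl(t(m))
  }
  tbl
}

#' Write a count table to tab-separated text
#'
#' @param tbl A count table tibble (see [read_count_table()]).
#' @param path Output path.
#' @return `tbl`, invisibly.
#' @export
write_count_table <- function(tbl, path) {
  as_count_matrix(tbl) # validate
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(tbl)
}

#' Read sample metadata
#'
#' Expects tab-separated text with at least `sample_id` and `group` columns;
#' a `salinity` column and further covariates are read as numeric when
#' present.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  md <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(md))) {
    abort("metadata must have `sample_id` and `group` columns.")
  }
  if (anyDuplicated(md$sample_id)) abort("duplicated sample_id in metadata.")
  if (any(is.na(md$group) | !nzchar(as.character(md$group)))) {
    abort("empty group label(s) in metadata.")
  }
  md
}

#' Read a taxonomy table
#'
#' Tab-separated text mapping `taxon_id` to ranked lineage columns
#' (e.g. domain, phylum, class, order, family, genus).
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with `taxon_id` plus one character column per rank.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tax <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (names(tax)[1] != "taxon_id") names(tax)[1] <- "taxon_id"
  if (anyDuplicated(tax$taxon_id)) abort("duplicated taxon_id in taxonomy.")
  tax
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) down to `depth`. Samples whose total is already exactly
#' `depth` pass through unchanged; samples below `depth` are dropped with a
#' message.
#'
#' @param tbl A count table tibble of integer counts.
#' @param depth Target reads per sample (positive integer).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return A rarefied count table in which every retained sample sums to
#'   `depth`. Dropped sample ids are attached as attribute `"dropped"`.
#' @examples
#' rarefy(example_counts(), depth = 10, seed = 1)
#' @export
rarefy <- function(tbl, depth, seed = NULL) {
  depth <- check_scalar_int(depth, "depth")
  m <- as_count_matrix(tbl)
  check_integerish(m)
  tot <- colSums(m)
  keep <- tot >= depth
  if (!any(keep)) abort(sprintf("all samples have fewer than %d reads; nothing to rarefy.", depth))
  if (any(!keep)) {
    inform(sprintf("dropping %d sample(s) below depth %d: %s",
                   sum(!keep), depth, paste(colnames(m)[!keep], collapse = ", ")))
  }
  m <- m[, keep, drop = FALSE]
  tot <- tot[keep]
  out <- with_seed_if(seed, {
    vapply(seq_len(ncol(m)), function(j) {
      if (tot[j] == depth) return(m[, j])
      draw_hypergeometric(m[, j], depth)
    }, numeric(nrow(m)))
  })
  dimnames(out) <- dimnames(m)
  res <- as_count_tbl(out)
  attr(res, "dropped") <- colnames(as_count_matrix(tbl))[!keep]
  res
}

# Exact multivariate hypergeometric draw: choose `depth` of the sample's
# reads uniformly without replacement and map read indices back to taxa.
draw_hypergeometric <- function(counts, depth) {
  cs <- cumsum(counts)
  idx <- sample.int(cs[length(cs)], depth)
  tabulate(findInterval(idx, cs, left.open = TRUE) + 1L, nbins = length(counts))
}

#' Convert counts to relative abundances
#'
#' @param tbl A count table tibble; every sample total must be positive.
#' @return A tibble of the same shape whose sample columns each sum to 1.
#' @export
to_relative <- function(tbl) {
  m <- as_count_matrix(tbl)
  as_count_tbl(close_columns(m))
}

#' Aggregate a count table at a taxonomic rank
#'
#' Sums rows sharing the same label at `rank`. Lineages with no annotation at
#' that rank are pooled under a sentinel `norank_<nearest annotated parent>`
#' label.
#'
#' @param tbl A count table tibble.
#' @param taxonomy A taxonomy tibble (`taxon_id` + rank columns).
#' @param rank Name of a rank column of `taxonomy`.
#' @return A count table whose `taxon_id` column holds rank labels.
#' @export
aggregate_taxonomy <- function(tbl, taxonomy, rank) {
  m <- as_count_matrix(tbl)
  ranks <- setdiff(names(taxonomy), "taxon_id")
  if (!rank %in% ranks) {
    abort(sprintf("unknown rank '%s'; taxonomy has: %s", rank, paste(ranks, collapse = ", ")))
  }
  miss <- setdiff(rownames(m), taxonomy$taxon_id)
  if (length(miss)) {
    abort(sprintf("taxa missing from taxonomy: %s%s", paste(head(miss, 5), collapse = ", "),
                  if (length(miss) > 5) ", ..." else ""))
  }
  tax <- taxonomy[match(rownames(m), taxonomy$taxon_id), , drop = FALSE]
  upto <- ranks[seq_len(match(rank, ranks))]
  lab <- vapply(seq_len(nrow(tax)), function(i) {
    lin <- as.character(unlist(tax[i, upto]))
    lin[is.na(lin) | !nzchar(lin)] <- NA_character_
    if (!is.na(lin[length(lin)])) return(lin[length(lin)])
    parent <- rev(lin[!is.na(lin)])[1]
    paste0("norank_", if (is.na(parent) || is.null(parent)) "root" else parent)
  }, character(1))
  agg <- rowsum(m, group = lab)
  out <- as_count_tbl(agg)
  out[order(match(out$taxon_id, unique(lab))), , drop = FALSE]
}

#' Keep the n most abundant taxa
#'
#' Retains the rows with the `n` largest total counts, preserving their
#' original order; ties at the cutoff are broken by ascending taxon id.
#'
#' @param tbl A count table tibble.
#' @param n Number of taxa to keep (positive integer).
#' @return The filtered count table.
#' @export
top_n_taxa <- function(tbl, n) {
  n <- check_scalar_int(n, "n")
  m <- as_count_matrix(tbl)
  if (n >= nrow(m)) return(tbl)
  tot <- rowSums(m)
  ord <- order(-tot, rownames(m))
  keep <- rownames(m)[ord[seq_len(n)]]
  tbl[tbl[[1]] %in% keep, , drop = FALSE]
}

#' Read a BIOM (JSON dialect) table
#'
#' Minimal reader for the dense or sparse JSON BIOM encoding, returning the
#' same tibble layout as [read_count_table()].
#'
#' @param path Path to a BIOM 1.0 JSON file.
#' @return A count table tibble.
#' @export
read_biom_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  b <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- vapply(b$rows, function(r) r$id, character(1))
  cols <- vapply(b$columns, function(c) c$id, character(1))
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  if (identical(b$matrix_type, "dense")) {
    for (i in seq_along(b$data)) m[i, ] <- unlist(b$data[[i]])
  } else {
    for (trip in b$data) m[trip[[1]] + 1L, trip[[2]] + 1L] <- trip[[3]]
  }
  as_count_tbl(m)
}

#' Tiny worked-example count table
#'
#' Three taxa by two samples; used in documentation examples.
#' @return A count table tibble.
#' @export
example_counts <- function() {
  tibble::tibble(taxon_id = c("OTU1", "OTU2", "OTU3"),
                 S1 = c(12, 6, 2), S2 = c(8, 10, 4))
}
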