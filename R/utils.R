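# Internal helpers shared across modules.

# A "count table" throughout the package is a tibble whose first column
# (`taxon_id`, character) identifies taxa and whose remaining columns are one
# numeric vector of abundances per sample. These helpers move between that
# tidy representation and the taxa x samples matrix most algorithms want.

as_count_matrix <- function(tbl, arg = "tbl") {
  if (!is.data.frame(tbl) || ncol(tbl) < 2) {
    abort(sprintf("`%s` must be a data frame with a taxon id column plus at least one sample column.", arg))
  }
  ids <- as.character(tbl[[1]])
  if (anyNA(ids) || any(!nzchar(ids))) {
    abort(sprintf("`%s` has missing or empty taxon ids.", arg))
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated taxon id(s) in `%s`: %s", arg,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  num <- tbl[-1]
  bad <- names(num)[!vapply(num, is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("non-numeric sample column(s) in `%s`: %s", arg, paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(names(num))) {
    abort(sprintf("duplicated sample id(s) in `%s`.", arg))
  }
  m <- as.matrix(num)
  if (anyNA(m)) abort(sprintf("`%s` contains missing values.", arg))
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative abundance for taxon '%s' in sample '%s'.",
                  ids[idx[1]], colnames(m)[idx[2]]))
  }
  rownames(m) <- ids
  m
}

as_count_tbl <- function(m) {
  tibble::as_tibble(as.data.frame(m), rownames = "taxon_id")
}

# Require integer-valued counts (rarefaction, aggregation of raw tables).
check_integerish <- function(m, arg = "tbl") {
  if (any(abs(m - round(m)) > 1e-8)) {
    idx <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)[1, ]
    abort(sprintf("`%s` must hold integer counts; taxon '%s', sample '%s' is fractional.",
                  arg, rownames(m)[idx[1]], colnames(m)[idx[2]]))
  }
  invisible(m)
}

sample_totals <- function(m) colSums(m)

# Column-close a matrix to proportions; errors on empty samples.
close_columns <- function(m) {
  tot <- colSums(m)
  if (any(tot <= 0)) {
    abort(sprintf("sample(s) with zero total: %s",
                  paste(colnames(m)[tot <= 0], collapse = ", ")))
  }
  sweep(m, 2, tot, "/")
}

is_relative_matrix <- function(m, tol = 1e-6) {
  all(abs(colSums(m) - 1) <= tol)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; a NULL seed
# leaves the global stream untouched.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

check_scalar_int <- function(x, arg, min = 1L) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || abs(x - round(x)) > 0) {
    abort(sprintf("`%s` must be a single integer >= %d.", arg, min))
  }
  as.integer(x)
}

check_fraction <- function(x, arg) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single value in [0, 1].", arg))
  }
  as.numeric(x)
}

# Deterministic per-stage seed derived from one global seed; keeps every
# derived seed inside the 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}
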