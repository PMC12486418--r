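# Brute-force oracles: direct transcription of the defining formulas,
# independent of the package's implementation paths.

oracle_shannon <- function(x, base = exp(1)) {
  p <- x[x > 0] / sum(x)
  s <- 0
  for (pi in p) s <- s - pi * log(pi, base = base)
  s
}

oracle_simpson <- function(x) {
  p <- x[x > 0] / sum(x)
  sum(p * p)
}

oracle_chao1 <- function(x) {
  x <- x[x > 0]
  f1 <- sum(x == 1); f2 <- sum(x == 2)
  length(x) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_ace <- function(x, cutoff = 10) {
  x <- x[x > 0]
  rare <- x[x <= cutoff]; abund <- x[x > cutoff]
  if (!length(rare)) return(length(abund))
  n_rare <- sum(rare); f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) return(NA_real_)
  num <- 0
  for (k in seq_len(cutoff)) num <- num + k * (k - 1) * sum(rare == k)
  g2 <- max(length(rare) * num / (c_ace * n_rare * (n_rare - 1)) - 1, 0)
  length(abund) + length(rare) / c_ace + f1 / c_ace * g2
}

oracle_goods <- function(x) 1 - sum(x == 1) / sum(x)

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Levins niche breadth, element by element.
oracle_niche_breadth <- function(row) {
  p <- row / sum(row)
  1 / sum(p^2)
}

# Core detection by explicit double loop over taxa and samples.
oracle_core <- function(m, occ_min, ra_min) {
  prop <- sweep(m, 2, colSums(m), "/")
  hits <- character(0)
  for (i in seq_len(nrow(m))) {
    n_present <- 0
    for (j in seq_len(ncol(m))) if (m[i, j] > 0) n_present <- n_present + 1
    if (n_present / ncol(m) >= occ_min && mean(prop[i, ]) >= ra_min) {
      hits <- c(hits, rownames(m)[i])
    }
  }
  hits
}

# Sloan predicted frequency by numerical integration of the Beta density
# over (d, 1].
oracle_ncm_freq <- function(p, Nm, d) {
  stats::integrate(function(x) stats::dbeta(x, Nm * p, Nm * (1 - p)),
                   lower = d, upper = 1, rel.tol = 1e-10)$value
}

oracle_fisher <- function(pvals) {
  stats::pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals), lower.tail = FALSE)
}

random_count_table <- function(n_taxa, n_samples, lambda = 8) {
  m <- matrix(stats::rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("T%03d", seq_len(n_taxa)),
                              sprintf("S%02d", seq_len(n_samples))))
  # guarantee positive sample totals
  m[1, ] <- m[1, ] + 1
  halocline:::as_count_tbl(m)
}

tbl_matrix <- function(tbl) halocline:::as_count_matrix(tbl)
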