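# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's counting/CDF/enumeration code paths.

# tags with start <= p < end, by explicit comparison
brute_count <- function(positions, start, end) {
  sum(positions >= start & positions < end)
}

# per-tag assignment to consecutive bins given genomic bin start/ends
brute_bin_counts <- function(positions, lo, hi) {
  vapply(seq_along(lo), function(k) {
    sum(positions >= lo[k] & positions < hi[k])
  }, numeric(1))
}

# KS D as an explicit sup over pooled points
brute_ks_D <- function(x, y) {
  v <- c(x, y)
  max(vapply(v, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}

# Kolmogorov series, truncated at 100 terms, on the effective sample size
series_ks_p <- function(D, n1, n2) {
  lam <- sqrt(n1 * n2 / (n1 + n2)) * D
  if (lam <= 0) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))))
}

# Fisher two-sided p by direct enumeration over free cells of a 2 x c table
# (probability ordering, relative slack 1e-7)
brute_fisher_2xc <- function(tab) {
  stopifnot(nrow(tab) == 2)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  ptab <- function(m) {
    exp(sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1) -
          sum(lgamma(m + 1)))
  }
  cc <- ncol(tab)
  grids <- lapply(seq_len(cc - 1), function(j) 0:min(rs[1], cs[j]))
  combos <- expand.grid(grids)
  p_obs <- ptab(tab)
  total <- 0
  for (i in seq_len(nrow(combos))) {
    top <- as.numeric(combos[i, ])
    last <- rs[1] - sum(top)
    if (last < 0 || last > cs[cc]) next
    row1 <- c(top, last)
    row2 <- cs - row1
    if (any(row2 < 0)) next
    m <- rbind(row1, row2)
    p <- ptab(m)
    if (p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  total
}

# small deterministic single-exon gene
tiny_gene <- function(id = "g1", start = 100, end = 600, strand = "+",
                      chrom = "chr1") {
  gene_model(id, chrom, start, end, strand)
}

# coverage from explicit positions on one chrom/strand
tiny_cov <- function(positions, strand = "+", chrom = "chr1",
                     library_size = NULL, condition = "control",
                     replicate = 1L) {
  tags <- stats::setNames(list(positions),
                          paste0(chrom, ":", strand))
  if (length(positions) == 0L) tags <- list()
  stranded_coverage(condition, replicate, tags,
                    library_size = library_size)
}

# small, fast simulation configuration shared by several tests
small_sim_config <- function(depth = 1e6, ...) {
  sim_config(n_genes = 60L, depth = depth, seed = 11L, ...)
}
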