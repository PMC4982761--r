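test_result <- function(statistic, p_value, n1, n2, method) {
  structure(list(statistic = as.numeric(statistic),
                 p_value = min(1, max(0, as.numeric(p_value))),
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 method = method),
            class = "rt_test")
}

#' @export
print.rt_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.6g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the exact supremum of |ECDF_x - ECDF_y| over the pooled sample
#' points (ties handled by evaluating both ECDFs at the pooled unique
#' values). The p-value is asymptotic, from the Kolmogorov distribution
#' with effective sample size n1 n2 / (n1 + n2):
#' p = 2 sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2),
#' lambda = sqrt(n_eff) D.
#'
#' @param x,y Numeric sample vectors (non-empty).
#' @return An `rt_test` with `statistic` = D and the asymptotic p-value.
#' @export
ks_two_sample <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  if (anyNA(x) || anyNA(y)) stop("NA in sample")
  v <- sort(unique(c(x, y)))
  fx <- findInterval(v, sort(x)) / length(x)
  fy <- findInterval(v, sort(y)) / length(y)
  D <- max(abs(fx - fy))
  n_eff <- length(x) * length(y) / (length(x) + length(y))
  p <- kolmogorov_sf(sqrt(n_eff) * D)
  test_result(D, p, length(x), length(y),
              "two-sample Kolmogorov-Smirnov (asymptotic)")
}

# survival function of the Kolmogorov distribution, 100-term series
kolmogorov_sf <- function(lambda, terms = 100L) {
  if (lambda <= 0) return(1)
  k <- seq_len(terms)
  s <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, s))
}

#' Exact Fisher test on a small r x c contingency table
#'
#' Two-sided p-value under the probability-ordering definition: the sum of
#' the (multivariate hypergeometric) probabilities of all tables with the
#' observed margins whose probability does not exceed that of the observed
#' table (up to a relative slack of 1e-7). Tables are enumerated
#' exhaustively, so the table must be small (r*c <= 9, total <= 500, and
#' at most ~2e6 candidate tables).
#'
#' @param tab Matrix of non-negative integers.
#' @param max_tables Enumeration cap.
#' @return An `rt_test` with `statistic` = probability of the observed
#'   table.
#' @export
fisher_exact <- function(tab, max_tables = 2e6) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table must contain non-negative integers")
  }
  r <- nrow(tab); cc <- ncol(tab); n <- sum(tab)
  if (r * cc > 9 || n > 500) {
    stop("table too large for exact enumeration; ",
         "use an approximate method")
  }
  if (n == 0) stop("empty table")
  rs <- rowSums(tab); cs <- colSums(tab)
  log_denom <- lgamma(n + 1) - sum(lgamma(rs + 1)) - sum(lgamma(cs + 1))
  log_p_table <- function(m) -(log_denom + sum(lgamma(m + 1)))
  lp_obs <- log_p_table(tab)
  p_obs <- exp(lp_obs)
  thresh <- lp_obs + log1p(1e-7)
  total <- 0
  count <- 0L
  cells <- matrix(0L, r, cc)
  recurse <- function(i, j, row_left, col_left) {
    if (count > max_tables) stop("too many tables to enumerate; ",
                                 "use an approximate method")
    if (i == r) {
      # last row forced by column margins
      if (any(col_left < 0)) return()
      cells[r, ] <<- col_left
      count <<- count + 1L
      lp <- log_p_table(cells)
      if (lp <= thresh) total <<- total + exp(lp)
      return()
    }
    if (j == cc) {
      # last cell in row forced by row margin
      v <- row_left
      if (v < 0 || v > col_left[cc]) return()
      cells[i, cc] <<- v
      recurse(i + 1L, 1L, rs[i + 1L],
              col_left - cells[i, ])
      return()
    }
    for (v in 0:min(row_left, col_left[j])) {
      cells[i, j] <<- v
      recurse(i, j + 1L, row_left - v, col_left)
    }
  }
  recurse(1L, 1L, rs[1L], cs)
  test_result(p_obs, total, n1 = n, n2 = n,
              "Fisher exact (probability ordering)")
}

#' Pearson co-occupancy matrix with average-linkage leaf order
#'
#' Pairwise Pearson correlation of equal-length signal vectors (e.g.
#' genome-wide binned tag counts per factor), with the leaf order of
#' average-linkage hierarchical clustering on distance 1 - r for display.
#'
#' @param tracks Named list of equal-length numeric vectors (>= 2 tracks,
#'   length >= 3, each with nonzero variance), or a matrix with tracks in
#'   columns.
#' @return A `correlation_matrix`: list with `labels`, `r` (symmetric,
#'   unit diagonal), and `order` (labels in clustered leaf order).
#' @export
pearson_matrix <- function(tracks) {
  if (is.matrix(tracks)) {
    m <- tracks
  } else {
    lens <- lengths(tracks)
    if (length(unique(lens)) != 1L) stop("tracks differ in length")
    m <- do.call(cbind, tracks)
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  if (ncol(m) < 2L) stop("need at least 2 tracks")
  if (nrow(m) < 3L) stop("tracks must have length >= 3")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance track: ", colnames(m)[sds == 0][1L])
  }
  r <- stats::cor(m)
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  structure(list(labels = colnames(m), r = r,
                 order = colnames(m)[hc$order]),
            class = "correlation_matrix")
}

#' Genome-wide binned tag counts (both strands pooled)
#'
#' Utility for co-occupancy analysis: counts tags of a coverage object in
#' consecutive `bin_bp` bins along one chromosome.
#'
#' @param cov A [stranded_coverage()].
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length (bp).
#' @param bin_bp Bin width (bp), 200 by default.
#' @return Numeric vector of `ceiling(chrom_length / bin_bp)` counts.
#' @export
binned_genome_counts <- function(cov, chrom, chrom_length, bin_bp = 200) {
  edges <- c(seq(0, chrom_length, by = bin_bp))
  if (edges[length(edges)] < chrom_length) {
    edges <- c(edges, chrom_length)
  }
  out <- numeric(length(edges) - 1L)
  for (strand in c("+", "-")) {
    p <- get_tags(cov, chrom, strand)
    if (length(p)) out <- out + bin_counts(p, edges)
  }
  out
}

#' Two-tailed two-sample t-test
#'
#' Welch's unequal-variance statistic by default (pooled-variance
#' optional), two-sided p from the t distribution.
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @param pooled Use the pooled-variance (Student) form.
#' @return An `rt_test`.
#' @export
t_test_two_tailed <- function(x, y, pooled = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 values per sample")
  }
  ht <- stats::t.test(x, y, var.equal = pooled, alternative = "two.sided")
  test_result(unname(ht$statistic), ht$p.value, length(x), length(y),
              if (pooled) "two-tailed t-test (pooled)" else
                "two-tailed t-test (Welch)")
}
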