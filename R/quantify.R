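#' Count tags whose 5' end falls in a half-open interval
#'
#' Counts stored positions p with `interval$start <= p < interval$end` on
#' the matching chromosome and strand. Tags are sorted at load time, so
#' counting is a pair of binary searches.
#'
#' @param cov A [stranded_coverage()].
#' @param interval A [genomic_interval()].
#' @param strand Strand to count on; defaults to the interval's strand.
#' @return Integer tag count. An unknown chromosome yields 0 with a
#'   warning, not an error.
#' @export
count_tags <- function(cov, interval, strand = interval$strand) {
  key <- tag_key(interval$chrom, strand)
  p <- cov$tags[[key]]
  if (is.null(p)) {
    known <- unique(sub(":[+-]$", "", names(cov$tags)))
    if (!(interval$chrom %in% known)) {
      warning("chromosome not in coverage: ", interval$chrom)
    }
    return(0L)
  }
  # sorted p: number of p < end minus number of p < start
  findInterval(interval$end - 0.5, p) - findInterval(interval$start - 0.5, p)
}

#' Fragments per kilobase of exon per million mapped fragments
#'
#' @param count Fragment count (>= 0).
#' @param length_bp Feature length in bp (> 0).
#' @param library_size Mapped fragments in the library (> 0).
#' @return `count / (length_bp/1000) / (library_size/1e6)`.
#' @export
fpkm <- function(count, length_bp, library_size) {
  if (any(length_bp <= 0)) stop("length_bp must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  count / (length_bp / 1000) / (library_size / 1e6)
}

#' Quantify one gene in one library
#'
#' Body count is the strand-matched tag count over the exons; read-through
#' count is the tag count in the downstream window. Body FPKM uses the
#' exonic length, read-through FPKM the actual (possibly clipped) window
#' length, preserving the density interpretation at chromosome edges.
#'
#' @param gene A [gene_model()].
#' @param cov A [stranded_coverage()].
#' @param window_bp Downstream window (bp); 5000 by default, 3000 is the
#'   common alternative.
#' @param chrom_length Optional chromosome length for window clipping.
#' @return One-row data.frame with gene_id, condition, replicate,
#'   body_count, body_fpkm, rt_count, rt_fpkm, window_bp.
#' @export
quantify_gene <- function(gene, cov, window_bp = 5000,
                          chrom_length = NULL) {
  body_count <- sum(vapply(seq_len(nrow(gene$exons)), function(i) {
    count_tags(cov, genomic_interval(gene$chrom, gene$exons[i, 1L],
                                     gene$exons[i, 2L], gene$strand))
  }, integer(1)))
  w <- downstream_window(gene, window_bp, chrom_length)
  if (is.null(w)) {
    warning("gene ", gene$gene_id,
            ": downstream window clipped to empty; read-through set to 0")
    rt_count <- 0L; w_len <- NA_real_; rt_fpkm_v <- 0
  } else {
    rt_count <- count_tags(cov, w)
    w_len <- w$end - w$start
    rt_fpkm_v <- fpkm(rt_count, w_len, cov$library_size)
  }
  data.frame(gene_id = gene$gene_id, condition = cov$condition,
             replicate = cov$replicate,
             body_count = body_count,
             body_fpkm = fpkm(body_count, gene$body_length,
                              cov$library_size),
             rt_count = rt_count, rt_fpkm = rt_fpkm_v,
             window_bp = window_bp,
             stringsAsFactors = FALSE)
}

#' Quantify all genes across libraries
#'
#' @param models List of [gene_model()]s (unique gene_ids).
#' @param libraries List of [stranded_coverage()] objects.
#' @param window_bp Downstream window length (bp).
#' @param chrom_length Optional chromosome length.
#' @return data.frame with one row per gene x library, ordered by gene
#'   within library input order.
#' @export
quantify_all <- function(models, libraries, window_bp = 5000,
                         chrom_length = NULL) {
  stopifnot(length(libraries) >= 1L)
  ids <- vapply(models, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id: ", ids[duplicated(ids)][1L])
  }
  out <- lapply(libraries, function(cov) {
    do.call(rbind, lapply(models, quantify_gene, cov = cov,
                          window_bp = window_bp,
                          chrom_length = chrom_length))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Condition-mean view of a quantification table
#'
#' @param quants Output of [quantify_all()].
#' @return data.frame with one row per gene x condition: replicate-mean
#'   body_fpkm and rt_fpkm (columns `mean_body_fpkm`, `mean_rt_fpkm`,
#'   `n_replicates`).
#' @export
condition_means <- function(quants) {
  agg <- stats::aggregate(
    cbind(mean_body_fpkm = quants$body_fpkm,
          mean_rt_fpkm = quants$rt_fpkm) ~ gene_id + condition,
    data = quants, FUN = mean)
  n <- stats::aggregate(replicate ~ gene_id + condition, data = quants,
                        FUN = length)
  names(n)[3L] <- "n_replicates"
  merge(agg, n, by = c("gene_id", "condition"), sort = TRUE)
}

#' Estimate the read-through fraction from the density ratio
#'
#' Inverts the generator's placement geometry: with window density over
#' body density r = rt_fpkm / body_fpkm, window length W >= D, and
#' g = [expected_past_tts_fraction()], the read-through fraction solves
#' rho = r W / (g (L + r W)).
#'
#' @param rt_fpkm Read-through window FPKM.
#' @param body_fpkm Body FPKM (> 0).
#' @param body_length Exonic gene length L (bp).
#' @param window_bp Window length W used for rt_fpkm (bp).
#' @param d_max Maximum extension D (bp); must be <= window_bp for the
#'   inversion to be exact.
#' @return Estimated rho, clamped to [0, 1].
#' @export
estimate_rho <- function(rt_fpkm, body_fpkm, body_length,
                         window_bp = 5000, d_max = window_bp) {
  stopifnot(all(body_fpkm > 0), d_max <= window_bp)
  r <- rt_fpkm / body_fpkm
  g <- expected_past_tts_fraction(body_length, d_max)
  pmin(1, pmax(0, r * window_bp / (g * (body_length + r * window_bp))))
}
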