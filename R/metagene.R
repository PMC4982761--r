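#' Profile specification for binned signal
#'
#' Fixed-anchor mode lays out `upstream_bp/bin_bp` bins 5' of the anchor
#' (TSS or TTS) and `downstream_bp/bin_bp` bins 3' of it, in transcript
#' orientation. Scaled-body mode additionally stretches each gene body
#' into `body_bins` equal-width slices between 50-bp flanks.
#'
#' @param anchor `"TSS"`, `"TTS"`, or `"scaled-body"`.
#' @param upstream_bp,downstream_bp Flank extents (bp); must be multiples
#'   of `bin_bp`.
#' @param bin_bp Bin width (bp), 50 by default.
#' @param body_bins Number of body slices in scaled mode.
#' @return A `profile_spec` list.
#' @export
profile_spec <- function(anchor = c("TTS", "TSS", "scaled-body"),
                         upstream_bp = 1000, downstream_bp = 5000,
                         bin_bp = 50, body_bins = 60) {
  anchor <- match.arg(anchor)
  stopifnot(bin_bp > 0, upstream_bp >= 0, downstream_bp >= 0,
            upstream_bp %% bin_bp == 0, downstream_bp %% bin_bp == 0,
            body_bins > 0)
  structure(list(anchor = anchor, upstream_bp = upstream_bp,
                 downstream_bp = downstream_bp, bin_bp = bin_bp,
                 body_bins = as.integer(body_bins)),
            class = "profile_spec")
}

# tag counts in consecutive half-open genomic bins given by increasing
# edge positions; sorted tag vector p
bin_counts <- function(p, edges) {
  fi <- findInterval(edges - 0.5, p)
  diff(fi)
}

#' Per-gene binned signal around a fixed anchor
#'
#' Bins are laid out 5' to 3' in gene orientation; each bin value is the
#' tag count in its half-open genomic interval times 1e6 / library_size
#' (tags per million per bin). Bins extending beyond the chromosome are
#' `NA` (missing, not zero).
#'
#' @param gene A [gene_model()].
#' @param cov A [stranded_coverage()].
#' @param spec A fixed-anchor [profile_spec()].
#' @param chrom_length Optional chromosome length.
#' @return Numeric vector of length
#'   `(upstream_bp + downstream_bp) / bin_bp`.
#' @export
per_gene_bins <- function(gene, cov, spec, chrom_length = NULL) {
  stopifnot(inherits(spec, "profile_spec"),
            spec$anchor %in% c("TSS", "TTS"))
  a <- if (spec$anchor == "TSS") gene$tss else gene$tts
  offs <- seq(-spec$upstream_bp, spec$downstream_bp, by = spec$bin_bp)
  p <- get_tags(cov, gene$chrom, gene$strand)
  bin_starts <- offs[-length(offs)]    # transcript-offset of each bin start
  if (gene$strand == "+") {
    edges <- a + offs
    v <- bin_counts(p, edges)
    lo <- a + bin_starts
  } else {
    edges <- sort(a - offs)            # increasing genomic edges
    v <- rev(bin_counts(p, edges))     # back to 5'->3' transcript order
    lo <- a - bin_starts - spec$bin_bp # genomic start of each transcript bin
  }
  hi <- lo + spec$bin_bp
  out <- v * 1e6 / cov$library_size
  bad <- lo < 0
  if (!is.null(chrom_length)) bad <- bad | hi > chrom_length
  out[bad] <- NA_real_
  out
}

#' Average binned profile across genes
#'
#' Arithmetic mean per bin across genes; bins a gene cannot contribute
#' (beyond the chromosome) are missing for that gene and the mean divides
#' by the number of contributing genes.
#'
#' @param genes List of [gene_model()]s (>= 1).
#' @param cov A [stranded_coverage()].
#' @param spec A fixed-anchor [profile_spec()].
#' @param chrom_length Optional chromosome length.
#' @return A `binned_profile`: list with `spec`, `values` (per-bin means,
#'   tags per million per bin), `offsets` (bp of each bin start relative
#'   to the anchor), `n_genes`, `n_contributing` per bin.
#' @export
average_profile <- function(genes, cov, spec, chrom_length = NULL) {
  if (length(genes) == 0L) stop("empty gene list")
  m <- t(vapply(genes, per_gene_bins, cov = cov, spec = spec,
                chrom_length = chrom_length,
                FUN.VALUE = numeric((spec$upstream_bp + spec$downstream_bp) /
                                      spec$bin_bp)))
  if (length(genes) == 1L) m <- matrix(m, nrow = 1L)
  structure(list(
    spec = spec,
    values = colMeans(m, na.rm = TRUE),
    offsets = seq(-spec$upstream_bp,
                  spec$downstream_bp - spec$bin_bp, by = spec$bin_bp),
    n_genes = length(genes),
    n_contributing = colSums(!is.na(m))
  ), class = "binned_profile")
}

# transcript coordinate (0-based from the TSS) of genomic tag positions;
# NA for positions outside the exons
genomic_to_transcript <- function(gene, p) {
  ex <- gene$exons
  if (gene$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  lens <- ex[, 2L] - ex[, 1L]
  before <- c(0, cumsum(lens))[seq_len(nrow(ex))]
  t <- rep(NA_real_, length(p))
  for (i in seq_len(nrow(ex))) {
    inside <- p >= ex[i, 1L] & p < ex[i, 2L]
    if (gene$strand == "+") {
      t[inside] <- before[i] + (p[inside] - ex[i, 1L])
    } else {
      t[inside] <- before[i] + (ex[i, 2L] - 1 - p[inside])
    }
  }
  t
}

#' Body-scaled metagene profile with fixed flanks
#'
#' Flanks (5' of the TSS, 3' of the TTS) are binned at `bin_bp`; the gene
#' body is stretched into `body_bins` equal-width slices. Each tag is
#' treated as a unit interval in transcript coordinates and split
#' fractionally across slice boundaries; slice values are rescaled
#' densities (mass / slice width * bin_bp, tags per million per
#' bin-equivalent), so a uniformly covered gene shows equal flank and body
#' bins regardless of its length. Genes shorter than `body_bins` bases are
#' skipped with a warning.
#'
#' @param genes List of [gene_model()]s.
#' @param cov A [stranded_coverage()].
#' @param spec A [profile_spec()] with `anchor = "scaled-body"`.
#' @param chrom_length Optional chromosome length.
#' @return A `binned_profile` with
#'   `upstream/bin + body_bins + downstream/bin` values; attribute
#'   `n_skipped` counts too-short genes.
#' @export
scaled_metagene <- function(genes, cov, spec, chrom_length = NULL) {
  stopifnot(inherits(spec, "profile_spec"), spec$anchor == "scaled-body")
  keep <- vapply(genes, function(g) g$body_length >= spec$body_bins,
                 logical(1))
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) shorter than body_bins skipped")
  }
  genes <- genes[keep]
  if (length(genes) == 0L) stop("no gene long enough for scaled profile")
  B <- spec$body_bins
  n_up <- spec$upstream_bp / spec$bin_bp
  n_dn <- spec$downstream_bp / spec$bin_bp
  flank_up_spec <- profile_spec("TSS", upstream_bp = spec$upstream_bp,
                                downstream_bp = 0, bin_bp = spec$bin_bp)
  flank_dn_spec <- profile_spec("TTS", upstream_bp = 0,
                                downstream_bp = spec$downstream_bp,
                                bin_bp = spec$bin_bp)
  rows <- lapply(genes, function(g) {
    up <- if (n_up > 0) per_gene_bins(g, cov, flank_up_spec, chrom_length)
      else numeric(0)
    dn <- if (n_dn > 0) per_gene_bins(g, cov, flank_dn_spec, chrom_length)
      else numeric(0)
    p <- get_tags(cov, g$chrom, g$strand)
    i1 <- findInterval(g$start - 0.5, p)
    i2 <- findInterval(g$end - 0.5, p)
    p <- if (i2 > i1) p[(i1 + 1):i2] else numeric(0)
    t <- genomic_to_transcript(g, p)
    t <- t[!is.na(t)]
    wd <- g$body_length / B
    mass <- numeric(B)
    if (length(t)) {
      j1 <- pmin(floor(t / wd), B - 1)
      m1 <- pmin((j1 + 1) * wd, t + 1) - t
      mass <- mass + as.numeric(tapply(m1, factor(j1, levels = 0:(B - 1)),
                                       sum, default = 0))
      spill <- (t + 1) - (j1 + 1) * wd
      has2 <- spill > 1e-12 & (j1 + 1) <= (B - 1)
      if (any(has2)) {
        mass <- mass + as.numeric(
          tapply(spill[has2], factor(j1[has2] + 1, levels = 0:(B - 1)),
                 sum, default = 0))
      }
    }
    body <- mass * 1e6 / cov$library_size / wd * spec$bin_bp
    c(up, body, dn)
  })
  m <- do.call(rbind, rows)
  structure(list(
    spec = spec,
    values = colMeans(m, na.rm = TRUE),
    offsets = c(
      if (n_up > 0) seq(-spec$upstream_bp, -spec$bin_bp, by = spec$bin_bp),
      seq_len(B),   # body slice index, not bp
      if (n_dn > 0) seq(0, spec$downstream_bp - spec$bin_bp,
                        by = spec$bin_bp)),
    n_genes = length(genes),
    n_contributing = colSums(!is.na(m))
  ), class = c("scaled_profile", "binned_profile"))
  }

#' Per-gene heatmap matrix centred on an anchor
#'
#' One row per gene (normalized tags per bin, orientation-normalized),
#' rows ordered by descending condition-mean body FPKM; 8 kb at 50-bp bins
#' gives the canonical 160 columns.
#'
#' @param genes List of [gene_model()]s.
#' @param cov A [stranded_coverage()].
#' @param anchor `"TSS"` or `"TTS"`.
#' @param order_fpkm Numeric vector (parallel to `genes`) used for row
#'   ordering, typically condition-mean body FPKM.
#' @param halfspan Half-width of the window (bp); default 4000.
#' @param bin_bp Bin width (bp).
#' @param chrom_length Optional chromosome length.
#' @return List with `matrix` (rows ordered), `gene_ids`, `order_fpkm`,
#'   `offsets`, `spec`.
#' @export
heatmap_matrix <- function(genes, cov, anchor = c("TSS", "TTS"),
                           order_fpkm, halfspan = 4000, bin_bp = 50,
                           chrom_length = NULL) {
  anchor <- match.arg(anchor)
  stopifnot(length(order_fpkm) == length(genes))
  spec <- profile_spec(anchor, upstream_bp = halfspan,
                       downstream_bp = halfspan, bin_bp = bin_bp)
  m <- t(vapply(genes, per_gene_bins, cov = cov, spec = spec,
                chrom_length = chrom_length,
                FUN.VALUE = numeric(2 * halfspan / bin_bp)))
  if (length(genes) == 1L) m <- matrix(m, nrow = 1L)
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  ord <- order(-order_fpkm, ids)   # descending FPKM, id as tie-break
  list(matrix = m[ord, , drop = FALSE], gene_ids = ids[ord],
       order_fpkm = order_fpkm[ord],
       offsets = seq(-halfspan, halfspan - bin_bp, by = bin_bp),
       spec = spec)
}
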