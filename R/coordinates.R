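#' Genomic interval in 0-based, half-open coordinates
#'
#' All positions in this package are 0-based, half-open `[start, end)`,
#' matching BED/bedGraph. GTF input is converted on read.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (bp).
#' @param end 0-based exclusive end (bp); must exceed `start`.
#' @param strand `"+"` or `"-"`.
#' @return A `genomic_interval` object (named list).
#' @export
genomic_interval <- function(chrom, start, end, strand) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-', got: ", strand)
  }
  if (!(start >= 0 && start < end)) {
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' Gene model with strand-aware TSS/TTS
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param start,end Span of the gene, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of non-overlapping, sorted
#'   exon intervals inside the span. Defaults to a single exon covering the
#'   span.
#' @return A `gene_model` with `tss`, `tts` and `body_length` filled in:
#'   on `+` the TSS is the span start and the TTS the span end; on `-` the
#'   TSS is the span end and the TTS the span start.
#' @export
gene_model <- function(gene_id, chrom, start, end, strand,
                       exons = cbind(start, end)) {
  span <- genomic_interval(chrom, start, end, strand)
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("gene ", gene_id, ": no exons")
  ord <- order(exons[, 1L])
  exons <- exons[ord, , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) {
    stop("gene ", gene_id, ": exon with non-positive length")
  }
  if (any(exons[, 1L] < start) || any(exons[, 2L] > end)) {
    stop("gene ", gene_id, ": exon block extends past the gene span")
  }
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("gene ", gene_id, ": overlapping exons")
  }
  body_length <- sum(exons[, 2L] - exons[, 1L])
  structure(list(
    gene_id = as.character(gene_id),
    chrom = span$chrom, start = span$start, end = span$end,
    strand = span$strand,
    exons = exons,
    tss = if (strand == "+") span$start else span$end,
    tts = if (strand == "+") span$end else span$start,
    body_length = body_length
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) exons=%d body=%d bp\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons), x$body_length))
  invisible(x)
}

#' Downstream (read-through) window of a gene
#'
#' The window of `length_bp` bases immediately 3' of the annotated TTS, in
#' transcription direction: `[tts, tts + length_bp)` on `+`,
#' `[tts - length_bp, tts)` on `-`. Clipped at position 0 and, when a
#' chromosome length is supplied, at the chromosome end.
#'
#' @param gene A `gene_model`.
#' @param length_bp Window length in bp (> 0); the read-through
#'   quantification default is 5000, with 3000 as the common alternative.
#' @param chrom_length Optional chromosome length for right-clipping.
#' @return A `genomic_interval` on the gene's strand, or `NULL` if clipping
#'   empties the window.
#' @export
downstream_window <- function(gene, length_bp, chrom_length = NULL) {
  stopifnot(inherits(gene, "gene_model"), length_bp > 0)
  if (gene$strand == "+") {
    s <- gene$tts; e <- gene$tts + length_bp
  } else {
    s <- gene$tts - length_bp; e <- gene$tts
  }
  s <- max(0, s)
  if (!is.null(chrom_length)) e <- min(e, chrom_length)
  if (s >= e) return(NULL)
  genomic_interval(gene$chrom, s, e, gene$strand)
}

flip_strand <- function(strand) ifelse(strand == "+", "-", "+")

#' Mirror a gene model around a fixed genome length
#'
#' Maps position p to `genome_length - p` (interval-wise) and flips the
#' strand, so TSS maps to TSS and TTS to TTS. Used to verify orientation
#' invariance of every downstream computation.
#'
#' @param gene A `gene_model`.
#' @param genome_length Length of the (single-chromosome) genome.
#' @return The mirrored `gene_model`.
#' @export
mirror_gene_model <- function(gene, genome_length) {
  ex <- cbind(genome_length - gene$exons[, 2L],
              genome_length - gene$exons[, 1L])
  gene_model(gene$gene_id, gene$chrom,
             genome_length - gene$end, genome_length - gene$start,
             flip_strand(gene$strand),
             exons = ex[order(ex[, 1L]), , drop = FALSE])
}
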