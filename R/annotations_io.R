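tag_key <- function(chrom, strand) paste0(chrom, ":", strand)

#' Strand-specific tag coverage for one sequencing library
#'
#' Stores, per chromosome and strand, the sorted multiset of fragment
#' 5'-end positions ("tags"), plus the mapped-library size used for
#' per-million normalization. `library_size` may exceed the number of
#' stored tags when the stored tags are a slice of a larger library.
#'
#' @param condition Condition label (e.g. `"control"`).
#' @param replicate Replicate index (integer >= 1).
#' @param tags Named list, names `"<chrom>:<strand>"`, values integer
#'   vectors of 0-based tag positions (sorted internally).
#' @param library_size Total mapped fragments; defaults to the stored tag
#'   count.
#' @return A `stranded_coverage` object.
#' @export
stranded_coverage <- function(condition, replicate, tags,
                              library_size = NULL) {
  stopifnot(is.list(tags))
  tags <- lapply(tags, function(p) {
    p <- as.numeric(p)
    if (any(p < 0)) stop("negative tag position")
    sort(p)
  })
  n_stored <- sum(vapply(tags, length, integer(1)))
  if (is.null(library_size)) library_size <- n_stored
  if (library_size < n_stored) {
    stop("library_size (", library_size, ") < stored tag count (",
         n_stored, ")")
  }
  if (library_size <= 0) stop("library_size must be > 0")
  structure(list(condition = as.character(condition),
                 replicate = as.integer(replicate),
                 library_size = as.numeric(library_size),
                 tags = tags),
            class = "stranded_coverage")
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat(sprintf("<stranded_coverage> %s rep%d: %d stored tags, library %g\n",
              x$condition, x$replicate, n_stored_tags(x), x$library_size))
  invisible(x)
}

#' Number of tags stored in a coverage object
#' @param cov A `stranded_coverage`.
#' @export
n_stored_tags <- function(cov) {
  sum(vapply(cov$tags, length, integer(1)))
}

get_tags <- function(cov, chrom, strand) {
  v <- cov$tags[[tag_key(chrom, strand)]]
  if (is.null(v)) numeric(0) else v
}

#' Read gene models from BED12 or GTF
#'
#' BED12 coordinates are taken verbatim (0-based half-open); GTF is
#' converted from 1-based closed on read. For GTF with several transcripts
#' per gene, the transcript with the largest summed exon length defines the
#' model (`isoform = "longest"`), or the per-gene exon union
#' (`isoform = "union"`).
#'
#' @param path Annotation file.
#' @param dialect `"BED12"` or `"GTF"`.
#' @param isoform GTF multi-transcript handling, `"longest"` or `"union"`.
#' @return List of [gene_model()] objects in file order (GTF: by gene_id).
#' @export
read_gene_models <- function(path, dialect = c("BED12", "GTF"),
                             isoform = c("longest", "union")) {
  dialect <- match.arg(dialect)
  isoform <- match.arg(isoform)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "BED12") read_bed12(path) else read_gtf(path, isoform)
}

read_bed12 <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 12L) {
    stop("BED12 parse error in ", path, ": expected 12 columns, found ",
         ncol(dt))
  }
  models <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    row <- dt[i, ]
    sizes <- suppressWarnings(as.numeric(strsplit(as.character(row[[11L]]), ",")[[1]]))
    offs <- suppressWarnings(as.numeric(strsplit(as.character(row[[12L]]), ",")[[1]]))
    nb <- as.integer(row[[10L]])
    if (anyNA(sizes) || anyNA(offs) || length(sizes) != nb ||
        length(offs) != nb) {
      stop("BED12 parse error at line ", i, " of ", path,
           ": malformed block columns")
    }
    ex_start <- as.numeric(row[[2L]]) + offs
    models[[i]] <- gene_model(
      gene_id = as.character(row[[4L]]), chrom = as.character(row[[1L]]),
      start = as.numeric(row[[2L]]), end = as.numeric(row[[3L]]),
      strand = as.character(row[[6L]]),
      exons = cbind(ex_start, ex_start + sizes)
    )
  }
  models
}

read_gtf <- function(path, isoform) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("GTF input requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon records in GTF: ", path)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gr$gene_id,
    transcript_id = if (!is.null(gr$transcript_id)) gr$transcript_id else gr$gene_id,
    stringsAsFactors = FALSE
  )
  if (any(!df$strand %in% c("+", "-"))) {
    stop("GTF exon without +/- strand in ", path)
  }
  lapply(split(df, df$gene_id), function(g) {
    if (isoform == "longest") {
      len <- tapply(g$end - g$start, g$transcript_id, sum)
      g <- g[g$transcript_id == names(len)[which.max(len)], , drop = FALSE]
      ex <- cbind(g$start, g$end)[order(g$start), , drop = FALSE]
    } else {
      ir <- reduce_intervals(cbind(g$start, g$end))
      ex <- ir
    }
    gene_model(g$gene_id[1L], g$chrom[1L], min(ex[, 1L]), max(ex[, 2L]),
               g$strand[1L], exons = ex)
  })
}

# union of possibly-overlapping intervals (two-column matrix)
reduce_intervals <- function(m) {
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- m[1L, , drop = FALSE]
  if (nrow(m) > 1L) for (i in 2L:nrow(m)) {
    last <- nrow(out)
    if (m[i, 1L] <= out[last, 2L]) {
      out[last, 2L] <- max(out[last, 2L], m[i, 2L])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

#' Load stranded fragment tags from a BED6 file
#'
#' Each BED6 record contributes one tag at its strand-aware 5' end: `start`
#' for `+` records, `end - 1` for `-` records.
#'
#' @param path BED6 file (6 tab-separated columns, strand in column 6).
#' @param condition,replicate Library labels.
#' @param library_size Optional override of the mapped-library size;
#'   defaults to the record count.
#' @return A [stranded_coverage()].
#' @export
load_stranded_tags <- function(path, condition, replicate,
                               library_size = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0L) {
    return(stranded_coverage(condition, replicate, list(),
                             library_size = library_size))
  }
  if (ncol(dt) < 6L) {
    stop("BED6 parse error in ", path, ": expected 6 columns, found ",
         ncol(dt))
  }
  chrom <- as.character(dt[[1L]])
  start <- as.numeric(dt[[2L]]); end <- as.numeric(dt[[3L]])
  strand <- as.character(dt[[6L]])
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop("unstranded BED record at line ", bad[1L], " of ", path)
  }
  if (any(start < 0)) {
    stop("negative coordinate at line ", which(start < 0)[1L], " of ", path)
  }
  pos <- ifelse(strand == "+", start, end - 1)
  key <- tag_key(chrom, strand)
  tags <- split(pos, key)
  stranded_coverage(condition, replicate, tags, library_size = library_size)
}

#' Load per-strand bedGraph pair as tag coverage
#'
#' Per-base integer counts are expanded losslessly into tag positions.
#'
#' @param plus_path,minus_path bedGraph files for the two strands; either
#'   may be `NULL`.
#' @param condition,replicate Library labels.
#' @param library_size Optional mapped-library size override.
#' @return A [stranded_coverage()].
#' @export
load_bedgraph_pair <- function(plus_path = NULL, minus_path = NULL,
                               condition, replicate, library_size = NULL) {
  read_one <- function(path, strand) {
    if (is.null(path)) return(list())
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    if (nrow(dt) == 0L) return(list())
    if (ncol(dt) != 4L) {
      stop("bedGraph parse error in ", path, ": expected 4 columns")
    }
    chrom <- as.character(dt[[1L]])
    start <- as.numeric(dt[[2L]]); end <- as.numeric(dt[[3L]])
    count <- as.numeric(dt[[4L]])
    if (any(start < 0) || any(end <= start)) {
      stop("invalid interval in ", path)
    }
    if (any(count != round(count)) || any(count < 0)) {
      stop("bedGraph counts must be non-negative integers: ", path)
    }
    pos <- numeric(0); key <- character(0)
    per_chrom <- split(seq_len(nrow(dt)), chrom)
    out <- lapply(per_chrom, function(idx) {
      p <- unlist(lapply(idx, function(i) {
        if (count[i] == 0) return(numeric(0))
        rep(seq(start[i], end[i] - 1), each = count[i])
      }))
      p
    })
    names(out) <- tag_key(names(per_chrom), strand)
    out
  }
  tags <- c(read_one(plus_path, "+"), read_one(minus_path, "-"))
  stranded_coverage(condition, replicate, tags, library_size = library_size)
}

#' Write one strand of a coverage object as bedGraph
#'
#' Values are raw per-base tag counts; adjacent bases with equal counts are
#' run-length merged, rows sorted by chromosome then start. Round-trips
#' through [load_bedgraph_pair()].
#'
#' @param cov A [stranded_coverage()].
#' @param strand `"+"` or `"-"`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(cov, strand, path) {
  stopifnot(strand %in% c("+", "-"))
  keys <- names(cov$tags)
  keys <- keys[endsWith(keys, paste0(":", strand))]
  keys <- sort(keys)
  rows <- lapply(keys, function(k) {
    p <- cov$tags[[k]]
    if (length(p) == 0L) return(NULL)
    chrom <- sub(":[+-]$", "", k)
    tab <- table(p)
    pos <- as.numeric(names(tab)); cnt <- as.integer(tab)
    # merge runs of contiguous positions with identical counts
    brk <- c(TRUE, diff(pos) != 1 | diff(cnt) != 0)
    grp <- cumsum(brk)
    s <- tapply(pos, grp, min); e <- tapply(pos, grp, max) + 1
    v <- tapply(cnt, grp, function(x) x[1L])
    data.table::data.table(chrom = chrom, start = as.numeric(s),
                           end = as.numeric(e), count = as.integer(v))
  })
  rows <- data.table::rbindlist(rows)
  tryCatch({
    if (nrow(rows) == 0L) {
      writeLines(character(0), path)
    } else {
      data.table::fwrite(rows, path, sep = "\t", col.names = FALSE)
    }
  }, error = function(e) stop("failed writing bedGraph to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Mirror a coverage object around a fixed genome length
#'
#' Position p maps to `genome_length - 1 - p`; strands are swapped. The
#' companion of [mirror_gene_model()] for orientation-invariance checks.
#'
#' @param cov A [stranded_coverage()].
#' @param genome_length Genome length in bp.
#' @return The mirrored `stranded_coverage`.
#' @export
mirror_coverage <- function(cov, genome_length) {
  tags <- lapply(cov$tags, function(p) genome_length - 1 - p)
  names(tags) <- vapply(names(tags), function(k) {
    strand <- sub("^.*:", "", k)
    paste0(sub(":[+-]$", "", k), ":", flip_strand(strand))
  }, character(1))
  stranded_coverage(cov$condition, cov$replicate, tags,
                    library_size = cov$library_size)
}

#' Write tags as a BED6 file (one record per tag, width 1)
#' @param cov A [stranded_coverage()].
#' @param path Output file.
#' @export
write_tags_bed6 <- function(cov, path) {
  keys <- sort(names(cov$tags))
  rows <- lapply(keys, function(k) {
    p <- cov$tags[[k]]
    if (length(p) == 0L) return(NULL)
    strand <- sub("^.*:", "", k)
    chrom <- sub(":[+-]$", "", k)
    data.table::data.table(chrom = chrom, start = p, end = p + 1,
                           name = "tag", score = 0L, strand = strand)
  })
  rows <- data.table::rbindlist(rows)
  data.table::fwrite(rows, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
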