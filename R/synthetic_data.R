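#' Simulation configuration
#'
#' Describes a synthetic strand-specific poly(A)+ RNA-seq experiment: a
#' single-chromosome annotation of single-exon genes in four expression
#' tiers, two conditions with replicate libraries, and a perturbation in
#' which a subset of genes multiplies its read-through fraction rho (the
#' per-transcript probability of extending past the annotated TTS).
#'
#' Defaults emulate the study conditions this package targets: two
#' replicates per condition, 300 genes, baseline rho 0.15, a 3-fold rho
#' increase in 1/6 of genes, extensions up to 5 kb, and sequencing depth
#' such that a gene at FPKM 100 receives about one fragment start per
#' exonic base (the coverage of a 50-bp-read library at ~50x).
#'
#' @param n_genes Number of genes.
#' @param chrom Chromosome name of the synthetic genome.
#' @param chrom_length Chromosome length (bp); must accommodate the genes.
#' @param gene_length_range Uniform range of gene (single-exon) lengths.
#' @param gap_range Uniform range of intergenic gaps for ordinary
#'   junctions; the lower bound should exceed `d_max` so that ordinary
#'   neighbours stay out of the read-through window.
#' @param close_gap_range Uniform gap range for closely spaced junctions
#'   (inside the read-through window, to exercise the exclusion rule).
#' @param fraction_closely_spaced Proportion of gene junctions packed
#'   closely with matched strands.
#' @param tier_mix Named proportions over tiers High/Middle/Low/No; must
#'   sum to 1.
#' @param base_fpkm Named per-tier base FPKM.
#' @param fpkm_jitter_sdlog Lognormal sd of per-gene FPKM jitter around the
#'   tier base (0 disables).
#' @param rho0 Baseline read-through fraction per gene.
#' @param affected_fraction Proportion of genes whose rho is multiplied in
#'   the perturbed condition.
#' @param rho_fold Multiplier applied to rho in affected genes (> 1;
#'   1 gives a null experiment).
#' @param d_max Maximum read-through extension past the TTS (bp).
#' @param n_replicates Replicate libraries per condition.
#' @param depth Expected mapped fragments per library (nominal library
#'   size).
#' @param conditions Length-2 character vector, control first.
#' @param library_size_mode `"depth"` (library_size = depth; stored tags
#'   are the simulated genes' slice of a larger transcriptome, keeping
#'   realized FPKM on the nominal scale) or `"stored"` (library_size =
#'   stored tag count).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 300L,
                       chrom = "chrS",
                       chrom_length = NULL,
                       gene_length_range = c(1000, 4000),
                       gap_range = c(6000, 12000),
                       close_gap_range = c(200, 4000),
                       fraction_closely_spaced = 0.2,
                       tier_mix = c(High = 0.05, Middle = 0.15,
                                    Low = 0.50, No = 0.30),
                       base_fpkm = c(High = 800, Middle = 250,
                                     Low = 40, No = 3),
                       fpkm_jitter_sdlog = 0.35,
                       rho0 = 0.15,
                       affected_fraction = 1 / 6,
                       rho_fold = 3,
                       d_max = 5000,
                       n_replicates = 2L,
                       depth = 1e7,
                       conditions = c("control", "treated"),
                       library_size_mode = c("depth", "stored"),
                       seed = 1L) {
  library_size_mode <- match.arg(library_size_mode)
  tiers <- c("High", "Middle", "Low", "No")
  stopifnot(n_genes >= 0,
            all(tiers %in% names(tier_mix)),
            all(tiers %in% names(base_fpkm)),
            all(tier_mix >= 0), abs(sum(tier_mix) - 1) < 1e-9,
            all(base_fpkm > 0),
            rho0 >= 0, rho_fold > 0, min(1, rho0 * rho_fold) <= 1,
            rho0 * min(rho_fold, 1) >= 0,
            affected_fraction >= 0, affected_fraction <= 1,
            fraction_closely_spaced >= 0, fraction_closely_spaced <= 1,
            d_max > 0, depth > 0, n_replicates >= 1,
            length(conditions) == 2L)
  if (rho0 * rho_fold > 1) stop("rho0 * rho_fold must be <= 1")
  if (is.null(chrom_length)) {
    # generous auto-size: worst-case gene + gap per slot plus margins
    chrom_length <- ceiling(2 * d_max + 2000 +
      n_genes * (max(gene_length_range) + max(gap_range)))
  }
  cfg <- list(n_genes = as.integer(n_genes), chrom = chrom,
              chrom_length = as.numeric(chrom_length),
              gene_length_range = gene_length_range,
              gap_range = gap_range, close_gap_range = close_gap_range,
              fraction_closely_spaced = fraction_closely_spaced,
              tier_mix = tier_mix[tiers], base_fpkm = base_fpkm[tiers],
              fpkm_jitter_sdlog = fpkm_jitter_sdlog,
              rho0 = rho0, affected_fraction = affected_fraction,
              rho_fold = rho_fold, d_max = as.numeric(d_max),
              n_replicates = as.integer(n_replicates),
              depth = as.numeric(depth),
              conditions = as.character(conditions),
              library_size_mode = library_size_mode,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an annotation and truth table
#'
#' Tiles single-exon genes along one chromosome with sampled intergenic
#' gaps. A configured fraction of junctions is "closely spaced": the two
#' genes share a strand and the gap falls inside the read-through window,
#' so that one of them (the upstream one in transcription direction) has an
#' expressed neighbour inside its downstream window — the situation the
#' classifier's exclusion rule must catch. The per-gene flag
#' `close_packed` in the truth table is computed geometrically after
#' placement.
#'
#' @param config A [sim_config()].
#' @return `list(models, truth, config)`: gene models and a data.table with
#'   columns gene_id, tier, fpkm (nominal, both conditions),
#'   rho_control, rho_treated, affected, close_packed.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0L) {
    return(list(models = list(),
                truth = data.table::data.table(
                  gene_id = character(0), tier = character(0),
                  fpkm = numeric(0), rho_control = numeric(0),
                  rho_treated = numeric(0), affected = logical(0),
                  close_packed = logical(0)),
                config = config))
  }
  withr::with_seed(config$seed, {
    tiers <- sample(names(config$tier_mix), n, replace = TRUE,
                    prob = config$tier_mix)
    fpkm <- config$base_fpkm[tiers] *
      exp(stats::rnorm(n, 0, config$fpkm_jitter_sdlog))
    lens <- round(stats::runif(n, config$gene_length_range[1],
                               config$gene_length_range[2]))
    close_junction <- c(stats::runif(n - 1) < config$fraction_closely_spaced,
                        FALSE)
    gaps <- ifelse(close_junction,
                   round(stats::runif(n, config$close_gap_range[1],
                                      config$close_gap_range[2])),
                   round(stats::runif(n, config$gap_range[1],
                                      config$gap_range[2])))
    strands <- character(n)
    strands[1] <- sample(c("+", "-"), 1L)
    for (i in seq_len(n - 1L)) {
      strands[i + 1L] <- if (close_junction[i]) strands[i] else
        sample(c("+", "-"), 1L)
    }
    n_aff <- round(config$affected_fraction * n)
    affected <- logical(n)
    affected[sample.int(n, n_aff)] <- TRUE
  })
  margin <- config$d_max + 1000
  starts <- numeric(n); pos <- margin
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + lens[i] + gaps[i]
  }
  if (starts[n] + lens[n] + margin > config$chrom_length) {
    stop("genes do not fit on the chromosome; increase chrom_length ",
         "(need >= ", starts[n] + lens[n] + margin, ")")
  }
  ids <- sprintf("g%04d", seq_len(n))
  models <- lapply(seq_len(n), function(i) {
    gene_model(ids[i], config$chrom, starts[i], starts[i] + lens[i],
               strands[i])
  })
  truth <- data.table::data.table(
    gene_id = ids, tier = tiers, fpkm = as.numeric(fpkm),
    rho_control = config$rho0,
    rho_treated = ifelse(affected, pmin(1, config$rho_fold * config$rho0),
                         config$rho0),
    affected = affected,
    close_packed = close_packed_flags(models, config$d_max))
  list(models = models, truth = truth, config = config)
}

# geometric ground truth for the exclusion rule: does any same-strand gene
# span intersect this gene's downstream window?
close_packed_flags <- function(models, window_bp) {
  vapply(models, function(g) {
    w <- downstream_window(g, window_bp)
    if (is.null(w)) return(FALSE)
    any(vapply(models, function(h) {
      h$gene_id != g$gene_id && h$strand == g$strand &&
        h$chrom == g$chrom && h$start < w$end && h$end > w$start
    }, logical(1)))
  }, logical(1))
}

# map integer transcript offsets (0-based from the TSS) to genomic tag
# positions through the exon structure
transcript_to_genomic <- function(gene, t) {
  ex <- gene$exons
  if (gene$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  lens <- ex[, 2L] - ex[, 1L]
  cum <- cumsum(lens)
  idx <- findInterval(t, cum) + 1L
  off <- t - c(0, cum)[idx]
  if (gene$strand == "+") ex[idx, 1L] + off else ex[idx, 2L] - 1 - off
}

#' Expected fraction of read-through fragments landing past the TTS
#'
#' Under the generator's placement rule a read-through transcript of a gene
#' of exonic length L extends by E ~ Uniform(0, D] and its fragment start
#' is uniform on the L + E transcribed bases, so the probability of landing
#' past the TTS is E[E / (L + E)] = 1 - (L/D) log((L + D)/L). This closed
#' form anchors both the simulator's Monte-Carlo checks and the
#' density-ratio estimator of rho.
#'
#' @param body_length Exonic gene length L (bp).
#' @param d_max Maximum extension D (bp).
#' @return Expected fraction in (0, 1).
#' @export
expected_past_tts_fraction <- function(body_length, d_max) {
  stopifnot(all(body_length > 0), d_max > 0)
  1 - (body_length / d_max) * log((body_length + d_max) / body_length)
}

#' Simulate one strand-specific RNA-seq library
#'
#' Per gene, the fragment count is Poisson with mean
#' `fpkm * (L/1000) * (depth/1e6)`. Each fragment is a read-through
#' fragment with probability rho (condition-specific); body fragments fall
#' uniformly on the exons, read-through fragments uniformly on the exons
#' plus an extension of length E ~ Uniform(0, d_max]. Tags are the
#' fragments' 5' ends on the gene's strand. Deterministic given
#' (config seed, condition, replicate).
#'
#' @param models List of [gene_model()]s.
#' @param truth Truth table from [simulate_annotation()].
#' @param condition One of `config$conditions`.
#' @param replicate Replicate index.
#' @param config The [sim_config()].
#' @return A [stranded_coverage()].
#' @export
simulate_library <- function(models, truth, condition, replicate, config) {
  stopifnot(inherits(config, "sim_config"))
  cond_idx <- match(condition, config$conditions)
  if (is.na(cond_idx)) stop("unknown condition: ", condition)
  rho_col <- if (cond_idx == 1L) truth$rho_control else truth$rho_treated
  lib_seed <- (config$seed %% 1000000L) + 7919L * cond_idx +
    104729L * as.integer(replicate)
  per_gene <- vector("list", length(models))
  withr::with_seed(lib_seed, {
    for (i in seq_along(models)) {
      g <- models[[i]]
      lambda <- truth$fpkm[i] * (g$body_length / 1000) *
        (config$depth / 1e6)
      n_frag <- stats::rpois(1L, lambda)
      if (n_frag == 0L) { per_gene[[i]] <- numeric(0); next }
      n_rt <- stats::rbinom(1L, n_frag, rho_col[i])
      n_body <- n_frag - n_rt
      pos_body <- if (n_body > 0) {
        transcript_to_genomic(g, floor(stats::runif(n_body) * g$body_length))
      } else numeric(0)
      pos_rt <- if (n_rt > 0) {
        ext <- stats::runif(n_rt, 0, config$d_max)
        t_cont <- stats::runif(n_rt) * (g$body_length + ext)
        in_body <- t_cont < g$body_length
        p <- numeric(n_rt)
        if (any(in_body)) {
          p[in_body] <- transcript_to_genomic(g, floor(t_cont[in_body]))
        }
        if (any(!in_body)) {
          over <- floor(t_cont[!in_body] - g$body_length)
          p[!in_body] <- if (g$strand == "+") g$tts + over else
            g$tts - 1 - over
        }
        p
      } else numeric(0)
      per_gene[[i]] <- c(pos_body, pos_rt)
    }
  })
  strands <- vapply(models, `[[`, character(1), "strand")
  chroms <- vapply(models, `[[`, character(1), "chrom")
  keys <- tag_key(chroms, strands)
  tags <- lapply(split(seq_along(models), keys),
                 function(idx) unlist(per_gene[idx], use.names = FALSE))
  n_stored <- sum(lengths(per_gene))
  lib_size <- if (config$library_size_mode == "depth") {
    max(config$depth, n_stored)
  } else n_stored
  stranded_coverage(condition, replicate, tags, library_size = lib_size)
}

#' Simulate a ChIP-like anchored tag track
#'
#' Expected tag density is a flat background plus Gaussian kernels at the
#' TSS and/or TTS of the supplied genes; tags are Poisson-sampled from that
#' density (kernel mass `height * width * sqrt(2*pi)` per anchor, positions
#' normal around the anchor). The track is unstranded and stored on `+`.
#'
#' @param models Genes providing anchors (pass the expressed subset to
#'   emulate expression-dependent occupancy).
#' @param enrichment_spec List with `background` (tags per bp) and
#'   `kernels`, a list of `list(anchor = "TSS"|"TTS", height, width)`.
#' @param seed Integer seed.
#' @param chrom_length Chromosome length for clamping and background.
#' @return A [stranded_coverage()] with condition `"chip"`.
#' @export
simulate_chip_track <- function(models, enrichment_spec, seed,
                                chrom_length) {
  bg <- enrichment_spec$background %||% 0
  kernels <- enrichment_spec$kernels %||% list()
  for (k in kernels) {
    if (k$height < 0) stop("negative kernel height")
    stopifnot(k$anchor %in% c("TSS", "TTS"), k$width > 0)
  }
  stopifnot(bg >= 0, chrom_length > 0)
  chroms <- unique(vapply(models, `[[`, character(1), "chrom"))
  if (length(models) > 0 && length(chroms) != 1L) {
    stop("simulate_chip_track expects a single-chromosome model set")
  }
  chrom <- if (length(models)) chroms else "chrS"
  withr::with_seed(as.integer(seed), {
    pos <- numeric(0)
    n_bg <- stats::rpois(1L, bg * chrom_length)
    if (n_bg > 0) pos <- c(pos, floor(stats::runif(n_bg) * chrom_length))
    for (k in kernels) {
      anchors <- vapply(models, function(g) {
        if (k$anchor == "TSS") g$tss else g$tts
      }, numeric(1))
      mass <- k$height * k$width * sqrt(2 * pi)
      for (a in anchors) {
        m <- stats::rpois(1L, mass)
        if (m > 0) pos <- c(pos, round(stats::rnorm(m, a, k$width)))
      }
    }
  })
  pos <- pos[pos >= 0 & pos < chrom_length]
  tags <- stats::setNames(list(pos), tag_key(chrom, "+"))
  if (length(pos) == 0L) tags <- list()
  stranded_coverage("chip", 1L, tags,
                    library_size = max(1, length(pos)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full two-condition experiment
#'
#' @param config A [sim_config()].
#' @return `list(models, truth, libraries, config)`; `libraries` is a list
#'   of [stranded_coverage()] objects, one per condition x replicate, named
#'   `"<condition>_<replicate>"`.
#' @export
simulate_experiment <- function(config) {
  ann <- simulate_annotation(config)
  libs <- list()
  for (cond in config$conditions) {
    for (rep_i in seq_len(config$n_replicates)) {
      libs[[paste0(cond, "_", rep_i)]] <-
        simulate_library(ann$models, ann$truth, cond, rep_i, config)
    }
  }
  list(models = ann$models, truth = ann$truth, libraries = libs,
       config = config)
}

#' Write a simulated experiment to a directory
#'
#' Writes `genes.bed12`, one `<condition>_<replicate>.bed6` tag file per
#' library, `truth.tsv`, and the resolved configuration as
#' `sim_config.yaml`.
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bed12(sim$models, file.path(dir, "genes.bed12"))
  for (nm in names(sim$libraries)) {
    write_tags_bed6(sim$libraries[[nm]], file.path(dir, paste0(nm, ".bed6")))
  }
  data.table::fwrite(sim$truth, file.path(dir, "truth.tsv"), sep = "\t")
  cfg <- sim$config; class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Write gene models as BED12
#' @param models List of [gene_model()]s.
#' @param path Output file.
#' @export
write_bed12 <- function(models, path) {
  rows <- lapply(models, function(g) {
    sizes <- g$exons[, 2L] - g$exons[, 1L]
    offs <- g$exons[, 1L] - g$start
    data.table::data.table(
      chrom = g$chrom, start = g$start, end = g$end, name = g$gene_id,
      score = 0L, strand = g$strand, thickStart = g$start,
      thickEnd = g$end, rgb = 0L, blockCount = nrow(g$exons),
      blockSizes = paste0(paste(sizes, collapse = ","), ","),
      blockStarts = paste0(paste(offs, collapse = ","), ","))
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}
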