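#' Classifier configuration
#'
#' Holds the thresholds of the read-through calling procedure: the
#' expression filter on read-through FPKM (0.5), the fold-change cutoffs
#' for up (1.4) and down (0.5) calls, the ln-fold-change cutoff (0.2) of
#' the differential-expression gene filter, the expression-tier bounds
#' (10/100/500 FPKM), and the pseudocount used in fold ratios.
#'
#' @param min_rt_fpkm Read-through expression floor (FPKM).
#' @param fc_up Up-call fold threshold (> 1).
#' @param fc_down Down-call fold threshold (< 1).
#' @param ln_fc ln-fold-change cutoff of the DE filter.
#' @param tier_bounds Ascending tier bounds (No/Low, Low-Middle,
#'   Middle/High).
#' @param epsilon Pseudocount (FPKM) stabilizing fold ratios.
#' @param window_bp Downstream window the quantification used.
#' @param min_neighbor_fpkm Body-FPKM floor above which a downstream
#'   neighbour triggers exclusion.
#' @param both_strands If `TRUE`, the exclusion rule ignores strand
#'   (emulating an unstranded reanalysis); default is same-strand only,
#'   because the library is strand-specific.
#' @param exclude_inside_readthrough If `TRUE`, additionally exclude genes
#'   lying inside another gene's downstream window (the alternative
#'   reading of the removal rule).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(min_rt_fpkm = 0.5, fc_up = 1.4,
                              fc_down = 0.5, ln_fc = 0.2,
                              tier_bounds = c(10, 100, 500),
                              epsilon = 0.1, window_bp = 5000,
                              min_neighbor_fpkm = 1.0,
                              both_strands = FALSE,
                              exclude_inside_readthrough = FALSE) {
  stopifnot(fc_down < 1, fc_up > 1, epsilon > 0, ln_fc >= 0,
            length(tier_bounds) == 3L, all(diff(tier_bounds) > 0),
            min_rt_fpkm >= 0, window_bp > 0)
  structure(list(min_rt_fpkm = min_rt_fpkm, fc_up = fc_up,
                 fc_down = fc_down, ln_fc = ln_fc,
                 tier_bounds = tier_bounds, epsilon = epsilon,
                 window_bp = window_bp,
                 min_neighbor_fpkm = min_neighbor_fpkm,
                 both_strands = both_strands,
                 exclude_inside_readthrough = exclude_inside_readthrough),
            class = "classifier_config")
}

#' Assign an expression tier from body FPKM
#'
#' Tiers follow the convention High: FPKM > 500; Middle: 100 < FPKM <= 500;
#' Low: 10 <= FPKM <= 100; No: FPKM < 10. The shared endpoints of the
#' printed ranges are resolved so that High keeps its strict `>` and 100
#' belongs to Low.
#'
#' @param body_fpkm Numeric vector of body FPKM (>= 0).
#' @param bounds Ascending bounds `c(no_low, low_middle, middle_high)`.
#' @return Character vector over `{"High","Middle","Low","No"}`.
#' @export
assign_tier <- function(body_fpkm, bounds = c(10, 100, 500)) {
  stopifnot(all(body_fpkm >= 0))
  ifelse(body_fpkm > bounds[3L], "High",
         ifelse(body_fpkm > bounds[2L], "Middle",
                ifelse(body_fpkm >= bounds[1L], "Low", "No")))
}

#' Differential-expression filter on ln fold change
#'
#' A gene is called up when `ln((trt + eps)/(ctrl + eps)) > ln_fc`, down
#' when below `-ln_fc`, else stable. This gene-list filter is kept
#' separate from read-through calling and can be composed with it.
#'
#' @param ctrl_fpkm,trt_fpkm Condition-mean body FPKM (>= 0).
#' @param ln_fc ln-fold-change cutoff.
#' @param epsilon Pseudocount (FPKM).
#' @return Character vector over `{"up","down","stable"}`.
#' @export
diff_expression_filter <- function(ctrl_fpkm, trt_fpkm, ln_fc = 0.2,
                                   epsilon = 0.1) {
  stopifnot(all(ctrl_fpkm >= 0), all(trt_fpkm >= 0))
  l <- log((trt_fpkm + epsilon) / (ctrl_fpkm + epsilon))
  ifelse(l > ln_fc, "up", ifelse(l < -ln_fc, "down", "stable"))
}

#' Does a gene have an expressed downstream neighbour in its window?
#'
#' True when any other gene on the same strand (or either strand with
#' `both_strands`) intersects the gene's downstream window and has
#' condition-mean body FPKM at or above `min_neighbor_fpkm` in at least
#' one condition. Such genes are removed from read-through analysis
#' because their window signal is confounded by the neighbour's own
#' transcription.
#'
#' @param gene A [gene_model()].
#' @param models All gene models.
#' @param cond_means Output of [condition_means()].
#' @param window_bp Window length (bp).
#' @param min_neighbor_fpkm Neighbour expression floor (FPKM).
#' @param both_strands Ignore strand when matching neighbours.
#' @param chrom_length Optional chromosome length.
#' @return Logical.
#' @export
has_expressed_downstream_neighbor <- function(gene, models, cond_means,
                                              window_bp = 5000,
                                              min_neighbor_fpkm = 1.0,
                                              both_strands = FALSE,
                                              chrom_length = NULL) {
  w <- downstream_window(gene, window_bp, chrom_length)
  if (is.null(w)) return(FALSE)
  peak <- tapply(cond_means$mean_body_fpkm, cond_means$gene_id, max)
  for (h in models) {
    if (h$gene_id == gene$gene_id) next
    if (h$chrom != gene$chrom) next
    if (!both_strands && h$strand != gene$strand) next
    if (h$start < w$end && h$end > w$start) {
      f <- peak[h$gene_id]
      if (!is.na(f) && f >= min_neighbor_fpkm) return(TRUE)
    }
  }
  FALSE
}

#' Call read-through change for one gene
#'
#' The gene is `excluded_low` when the larger of the two condition means
#' of read-through FPKM is at or below the expression floor (so a gene
#' silent in control but expressed after perturbation stays callable).
#' Otherwise the fold change is the mean over replicate pairs of
#' `(trt_i + eps)/(ctrl_i + eps)` (unequal replicate counts fall back to
#' treated replicates over the control mean): `up` above `fc_up`, `down`
#' below `fc_down`, else `unchanged`.
#'
#' @param ctrl_rt Per-replicate control read-through FPKM (>= 1 value).
#' @param trt_rt Per-replicate treated read-through FPKM (>= 1 value).
#' @param config A [classifier_config()].
#' @return `list(call, fold_change, ctrl_mean, trt_mean)`; `fold_change`
#'   is `NA` for excluded genes.
#' @export
call_readthrough <- function(ctrl_rt, trt_rt, config = classifier_config()) {
  if (length(ctrl_rt) == 0L || length(trt_rt) == 0L) {
    stop("empty replicate vector")
  }
  ctrl_mean <- mean(ctrl_rt); trt_mean <- mean(trt_rt)
  if (max(ctrl_mean, trt_mean) <= config$min_rt_fpkm) {
    return(list(call = "excluded_low", fold_change = NA_real_,
                ctrl_mean = ctrl_mean, trt_mean = trt_mean))
  }
  eps <- config$epsilon
  fold <- if (length(ctrl_rt) == length(trt_rt)) {
    mean((trt_rt + eps) / (ctrl_rt + eps))
  } else {
    mean((trt_rt + eps) / (ctrl_mean + eps))
  }
  call <- if (fold > config$fc_up) "up" else
    if (fold < config$fc_down) "down" else "unchanged"
  list(call = call, fold_change = fold, ctrl_mean = ctrl_mean,
       trt_mean = trt_mean)
}

#' Classify all genes between two conditions
#'
#' Applies, in order: the neighbour-overlap exclusion (and optionally the
#' inside-a-read-through exclusion), the read-through expression floor,
#' and the fold-change calls. Also reports the expression tier from the
#' control-mean body FPKM and the DE-filter direction.
#'
#' @param models List of [gene_model()]s.
#' @param quants Output of [quantify_all()].
#' @param control,treatment Condition labels present in `quants`.
#' @param config A [classifier_config()].
#' @param chrom_length Optional chromosome length.
#' @param verbose Log summary counts with `message()`.
#' @return data.frame with one row per gene: gene_id, tier, de_direction,
#'   ctrl_rt_fpkm, trt_rt_fpkm, fold_change, call.
#' @export
classify_all <- function(models, quants, control, treatment,
                         config = classifier_config(),
                         chrom_length = NULL, verbose = FALSE) {
  conds <- unique(quants$condition)
  for (cn in c(control, treatment)) {
    if (!(cn %in% conds)) stop("condition label not found: ", cn)
  }
  cm <- condition_means(quants)
  rows <- vector("list", length(models))
  inside_flags <- if (config$exclude_inside_readthrough) {
    genes_inside_readthrough(models, config$window_bp, chrom_length)
  } else rep(FALSE, length(models))
  for (i in seq_along(models)) {
    g <- models[[i]]
    ctrl_body <- cm$mean_body_fpkm[cm$gene_id == g$gene_id &
                                     cm$condition == control]
    trt_body <- cm$mean_body_fpkm[cm$gene_id == g$gene_id &
                                    cm$condition == treatment]
    ctrl_rt <- quants$rt_fpkm[quants$gene_id == g$gene_id &
                                quants$condition == control]
    trt_rt <- quants$rt_fpkm[quants$gene_id == g$gene_id &
                               quants$condition == treatment]
    tier <- assign_tier(ctrl_body, config$tier_bounds)
    de <- diff_expression_filter(ctrl_body, trt_body, config$ln_fc,
                                 config$epsilon)
    excluded <- inside_flags[i] ||
      has_expressed_downstream_neighbor(
        g, models, cm, config$window_bp, config$min_neighbor_fpkm,
        config$both_strands, chrom_length)
    if (excluded) {
      res <- list(call = "excluded_overlap", fold_change = NA_real_,
                  ctrl_mean = mean(ctrl_rt), trt_mean = mean(trt_rt))
    } else {
      res <- call_readthrough(ctrl_rt, trt_rt, config)
    }
    rows[[i]] <- data.frame(
      gene_id = g$gene_id, tier = tier, de_direction = de,
      ctrl_rt_fpkm = res$ctrl_mean, trt_rt_fpkm = res$trt_mean,
      fold_change = res$fold_change, call = res$call,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (verbose) {
    tab <- table(factor(out$call, levels = c("up", "down", "unchanged",
                                             "excluded_overlap",
                                             "excluded_low")))
    message("read-through calls: ",
            paste(names(tab), tab, sep = "=", collapse = ", "))
  }
  out
}

# genes lying (partly) inside another same-strand gene's downstream window
genes_inside_readthrough <- function(models, window_bp, chrom_length) {
  vapply(models, function(g) {
    any(vapply(models, function(h) {
      if (h$gene_id == g$gene_id || h$chrom != g$chrom ||
          h$strand != g$strand) return(FALSE)
      w <- downstream_window(h, window_bp, chrom_length)
      !is.null(w) && g$start < w$end && g$end > w$start
    }, logical(1)))
  }, logical(1))
}
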