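#!/usr/bin/env Rscript

# Stage 4: averaged signal profiles.
#
# Builds, for each condition (replicate-averaged, tags per million per
# 50-bp bin): a TTS-anchored profile (1 kb upstream to 5 kb downstream)
# over the analyzed (non-excluded) genes, and a body-scaled metagene
# (3-kb flanks, 60 body slices). Also writes an 8-kb TTS-centred per-gene
# matrix for the control condition, rows ordered by body FPKM.

suppressPackageStartupMessages(library(readthru))

cfg <- yaml::read_yaml("scratch/sim/sim_config.yaml")
models <- read_gene_models("scratch/sim/genes.bed12", "BED12")
quants <- as.data.frame(data.table::fread("results/quant.tsv"))
calls <- data.table::fread("results/calls.tsv")

lib_files <- list.files("scratch/sim", pattern = "\\.bed6$",
                        full.names = TRUE)
libraries <- lapply(lib_files, function(f) {
  nm <- sub("\\.bed6$", "", basename(f))
  load_stranded_tags(f, sub("_[0-9]+$", "", nm),
                     as.integer(sub("^.*_", "", nm)),
                     library_size = cfg$depth)
})

analyzed <- calls$gene_id[calls$call %in% c("up", "down", "unchanged")]
prof_genes <- models[vapply(models, `[[`, character(1),
                            "gene_id") %in% analyzed]
tts_spec <- profile_spec("TTS", upstream_bp = 1000, downstream_bp = 5000)
sc_spec <- profile_spec("scaled-body", upstream_bp = 3000,
                        downstream_bp = 3000, body_bins = 60)

for (cond in c("control", "treated")) {
  libs <- Filter(function(l) l$condition == cond, libraries)
  for (nm in c("tts", "scaled")) {
    spec <- if (nm == "tts") tts_spec else sc_spec
    per_rep <- lapply(libs, function(l) {
      if (nm == "tts") average_profile(prof_genes, l, spec,
                                       cfg$chrom_length)
      else suppressWarnings(scaled_metagene(prof_genes, l, spec,
                                            cfg$chrom_length))
    })
    vals <- rowMeans(vapply(per_rep, `[[`, numeric(
      length(per_rep[[1]]$values)), "values"))
    data.table::fwrite(
      data.table::data.table(bin = seq_along(vals),
                             offset = per_rep[[1]]$offsets,
                             mean = vals,
                             n_genes = per_rep[[1]]$n_genes),
      sprintf("results/profile_%s_%s.tsv", nm, cond), sep = "\t")
  }
}

cm <- condition_means(quants)
ctrl <- cm[cm$condition == "control", ]
ctrl <- ctrl[match(vapply(prof_genes, `[[`, character(1), "gene_id"),
                   ctrl$gene_id), ]
hm <- heatmap_matrix(prof_genes, libraries[[1]], anchor = "TTS",
                     order_fpkm = ctrl$mean_body_fpkm,
                     chrom_length = cfg$chrom_length)
data.table::fwrite(data.table::as.data.table(hm$matrix),
                   "results/heatmap_tts_control1.tsv", sep = "\t")

p_ctrl <- data.table::fread("results/profile_tts_control.tsv")
p_trt <- data.table::fread("results/profile_tts_treated.tsv")
dn <- p_ctrl$offset >= 0
cat(sprintf("profiled %d analyzed genes\n", length(prof_genes)))
cat(sprintf("mean downstream-of-TTS signal: control %.3f, treated %.3f\n",
            mean(p_ctrl$mean[dn]), mean(p_trt$mean[dn])))
cat("profiles in results/profile_{tts,scaled}_{control,treated}.tsv;\n")
cat("per-gene matrix in results/heatmap_tts_control1.tsv\n")
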