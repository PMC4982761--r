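#!/usr/bin/env Rscript

# Stage 5: statistical comparisons.
#
# (a) Two-sample KS test between the conditions' downstream-of-TTS
#     profile bins, and between per-gene read-through FPKM vectors.
# (b) Welch t-test on per-gene read-through FPKM of affected genes.
# (c) Fisher's exact test on the (affected x up-call) contingency table.
# (d) Pearson co-occupancy of two simulated TSS-anchored ChIP-like
#     tracks, clustered with average linkage.

suppressPackageStartupMessages(library(readthru))

cfg <- yaml::read_yaml("scratch/sim/sim_config.yaml")
models <- read_gene_models("scratch/sim/genes.bed12", "BED12")
quants <- as.data.frame(data.table::fread("results/quant.tsv"))
calls <- data.table::fread("results/calls.tsv")
truth <- data.table::fread("results/truth.tsv")

out <- list()

p_ctrl <- data.table::fread("results/profile_tts_control.tsv")
p_trt <- data.table::fread("results/profile_tts_treated.tsv")
dn <- p_ctrl$offset >= 0
ks_prof <- ks_two_sample(p_ctrl$mean[dn], p_trt$mean[dn])
out$ks_profile <- list(D = ks_prof$statistic, p = ks_prof$p_value)

cm <- condition_means(quants)
analyzed <- calls$gene_id[calls$call %in% c("up", "down", "unchanged")]
cma <- cm[cm$gene_id %in% analyzed, ]
ks_gene <- ks_two_sample(cma$mean_rt_fpkm[cma$condition == "control"],
                         cma$mean_rt_fpkm[cma$condition == "treated"])
out$ks_per_gene <- list(D = ks_gene$statistic, p = ks_gene$p_value)

aff <- truth$gene_id[truth$affected & truth$fpkm >= 10]
tt <- t_test_two_tailed(
  cma$mean_rt_fpkm[cma$condition == "control" & cma$gene_id %in% aff],
  cma$mean_rt_fpkm[cma$condition == "treated" & cma$gene_id %in% aff])
out$t_test_affected <- list(statistic = tt$statistic, p = tt$p_value)

scored <- calls$call %in% c("up", "down", "unchanged")
tab <- table(affected = truth$affected[scored],
             up_call = calls$call[scored] == "up")
fe <- fisher_exact(as.matrix(tab))
out$fisher_affected_vs_up <- list(p = fe$p_value,
                                  table = as.vector(tab))

expressed <- models[truth$fpkm >= 10]
chip_spec <- list(background = 5e-5,
                  kernels = list(list(anchor = "TSS", height = 0.8,
                                      width = 150)))
t1 <- simulate_chip_track(expressed, chip_spec, seed = 101L,
                          cfg$chrom_length)
t2 <- simulate_chip_track(expressed, chip_spec, seed = 202L,
                          cfg$chrom_length)
cmx <- pearson_matrix(list(
  factorA = binned_genome_counts(t1, cfg$chrom, cfg$chrom_length, 200),
  factorB = binned_genome_counts(t2, cfg$chrom, cfg$chrom_length, 200)))
out$cooccupancy_r <- cmx$r["factorA", "factorB"]

jsonlite::write_json(out, "results/stats_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("KS on condition profiles: D = %.3f, p = %.3g\n",
            ks_prof$statistic, ks_prof$p_value))
cat(sprintf("KS on per-gene read-through FPKM: D = %.3f, p = %.3g\n",
            ks_gene$statistic, ks_gene$p_value))
cat(sprintf("Welch t on affected genes: t = %.2f, p = %.3g\n",
            tt$statistic, tt$p_value))
cat(sprintf("Fisher on affected x up-call: p = %.3g\n", fe$p_value))
cat(sprintf("co-occupancy of replicate ChIP-like tracks: r = %.3f\n",
            out$cooccupancy_r))
cat("summary in results/stats_summary.json\n")
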