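#!/usr/bin/env Rscript

# Stage 3: expression tiers and read-through change calls.
#
# Applies, in order: exclusion of genes with an expressed same-strand
# neighbour inside their 5-kb downstream window; the 0.5-FPKM
# read-through expression floor; and the fold-change calls (up > 1.4,
# down < 0.5, replicate-pair mean with a 0.1-FPKM pseudocount). Tiers
# come from control body FPKM (High > 500, Middle 100-500, Low 10-100).
# Calls are compared against the simulation truth.

suppressPackageStartupMessages(library(readthru))

cfg <- yaml::read_yaml("scratch/sim/sim_config.yaml")
models <- read_gene_models("scratch/sim/genes.bed12", "BED12")
quants <- as.data.frame(data.table::fread("results/quant.tsv"))
truth <- data.table::fread("results/truth.tsv")

calls <- classify_all(models, quants, "control", "treated",
                      classifier_config(), cfg$chrom_length,
                      verbose = TRUE)
data.table::fwrite(calls, "results/calls.tsv", sep = "\t")

tier_tab <- table(calls$tier)[c("High", "Middle", "Low", "No")]
data.table::fwrite(data.table::data.table(tier = names(tier_tab),
                                          n_genes = as.integer(tier_tab)),
                   "results/tier_summary.tsv", sep = "\t")

eligible <- truth$affected & truth$fpkm >= 10 &
  calls$call != "excluded_overlap"
ups <- calls$call == "up"
cat(sprintf("tiers (control): %s\n",
            paste(names(tier_tab), tier_tab, sep = "=", collapse = ", ")))
cat(sprintf("up-call sensitivity on eligible affected genes: %.3f (n=%d)\n",
            mean(calls$call[eligible] == "up"), sum(eligible)))
cat(sprintf("false-discovery proportion among up calls: %.3f (n=%d)\n",
            if (any(ups)) mean(!truth$affected[ups]) else 0, sum(ups)))
cat("tables in results/calls.tsv and results/tier_summary.tsv\n")
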