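#!/usr/bin/env Rscript
# Stage 1: generate the synthetic methylome under the default "ccryptica"
# profile — a 5-Mbp mosaic genome with 5000 genes and two conditions drawn
# from one shared truth — and print the closed-form expectations the
# downstream stages should recover.

suppressPackageStartupMessages(library(methylscape))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 101L

profile <- sim_profile(seed = seed)
es <- expected_summaries(profile)
cat("Closed-form expectations of the default profile:\n")
cat(sprintf("  global CG level:            %.1f%%\n", 100 * es$global_cg_level))
cat(sprintf("  repeatome:                  %.1f%%\n", 100 * es$repeat_fraction))
cat(sprintf("  methylated genes:           %.1f%%\n",
            100 * es$p_methylated_gene))
cat(sprintf("  class mean methylation:     %.0f%% / %.0f%%\n",
            100 * es$class_mean_methylated, 100 * es$class_mean_unmethylated))
cat(sprintf("  class mean FPKM:            %.0f / %.0f\n",
            es$mean_fpkm_methylated, es$mean_fpkm_unmethylated))
cat(sprintf("  P(methylated | FPKM <= 10): %.1f%%\n",
            100 * es$p_methylated_given_low_fpkm))

manifest <- simulate_methylome(profile, "results/sim")
cat(sprintf("\nSimulated %d bp over %d contigs: %d genes (%d methylated),\n",
            manifest$realized$genome_length, manifest$realized$n_contigs,
            manifest$realized$n_genes, manifest$realized$n_methylated_true))
cat(sprintf("realized hyperdomain fraction %.3f, repeat fraction %.3f.\n",
            manifest$realized$hyper_fraction,
            manifest$realized$repeat_fraction))
cat("Outputs under results/sim/ (see manifest.json).\n")
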