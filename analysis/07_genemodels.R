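#!/usr/bin/env Rscript
# Stage 7: consensus high-confidence gene-model selection (predictor-B
# overlap + expression support) and genome statistics for the full and
# high-confidence model sets.

suppressPackageStartupMessages({
  library(methylscape)
  library(data.table)
})

manifest <- jsonlite::read_json("results/sim/manifest.json")
dir.create("results/models", showWarnings = FALSE, recursive = TRUE)

a <- read_gff3_genes(manifest$paths$genes_predictor_a)
b <- read_gff3_genes(manifest$paths$genes_predictor_b)
fpkm <- read_fpkm_table(manifest$paths$fpkm_tsv)

hc <- high_confidence_models(a, b, fpkm)
fwrite(hc$table, "results/models/selection.tsv", sep = "\t")
cat(sprintf("predictor A: %d models; %d removed for lacking B overlap, %d for zero FPKM; %d high confidence\n",
            length(a), hc$n_removed_overlap, hc$n_removed_fpkm,
            sum(hc$table$selected)))

stats <- rbind(
  cbind(set = "predictorA_all", genome_stats(a, manifest$paths$genome_fasta)),
  cbind(set = "high_confidence",
        genome_stats(hc$selected, manifest$paths$genome_fasta)))
fwrite(stats, "results/models/genome_stats.tsv", sep = "\t")
print(stats)
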