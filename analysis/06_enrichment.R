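#!/usr/bin/env Rscript
# Stage 6: methylation enrichment by taxonomic origin of genes, with a
# label-permutation significance assessment.

suppressPackageStartupMessages({
  library(methylscape)
  library(data.table)
})

manifest <- jsonlite::read_json("results/sim/manifest.json")
dir.create("results/enrichment", showWarnings = FALSE, recursive = TRUE)

status <- fread("results/status/gene_status_condition1.tsv")
taxonomy <- read_taxonomy_table(manifest$paths$taxonomy_tsv)

enr <- taxon_enrichment(status, taxonomy, n_permutations = 10000L,
                        seed = manifest$seed)
fwrite(enr, "results/enrichment/taxon_enrichment.tsv", sep = "\t")
print(enr)
cat(sprintf("count-weighted mean enrichment: %.2e (identically zero)\n",
            enr[, sum(n_genes * enrichment)]))
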