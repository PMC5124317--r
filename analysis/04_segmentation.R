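#!/usr/bin/env Rscript
# Stage 4: partition the genome into hyper- and hypomethylated domains and
# quantify their alignment with repeats and genes.

suppressPackageStartupMessages({
  library(methylscape)
  library(data.table)
  library(GenomicRanges)
})

manifest <- jsonlite::read_json("results/sim/manifest.json")
dir.create("results/segmentation", showWarnings = FALSE, recursive = TRUE)

track <- methylation_track(
  read_cytosine_report(manifest$paths$cx_reports[[1]]), min_coverage = 5L)
genome <- Biostrings::readDNAStringSet(manifest$paths$genome_fasta)
models <- read_gff3_genes(manifest$paths$genes_predictor_a)
repeats <- read_repeat_bed(manifest$paths$repeats_bed)

seg <- segment_domains(track, window = 1000L,
                       seqlengths = setNames(width(genome), names(genome)))
seg <- annotate_segments(seg, repeats, models)
write_segments_bed(seg, "results/segmentation/segments.bed")
dt <- as.data.table(seg)
fwrite(dt, "results/segmentation/segments.tsv", sep = "\t")

by_label <- dt[, .(n = .N, mean_length = mean(width),
                   max_length = max(width),
                   mean_fraction = mean(mean_fraction),
                   repeat_overlap = mean(repeat_overlap_fraction),
                   genes = sum(n_genes_contained)), by = label]
print(by_label)
cat(sprintf("hypermethylated domains span up to %.0f kb and are %.0f%% repeat;\n",
            by_label[label == "hyper", max_length] / 1000,
            100 * by_label[label == "hyper", repeat_overlap]))
cat(sprintf("hypomethylated domains hold %d of %d gene midpoints.\n",
            by_label[label == "hypo", genes], dt[, sum(n_genes_contained)]))
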