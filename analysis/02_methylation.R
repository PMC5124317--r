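#!/usr/bin/env Rscript
# Stage 2: per-context global methylation levels, the per-site level
# histogram (bimodality), per-gene-region methylation and the metagene
# profile, for each simulated condition.

suppressPackageStartupMessages({
  library(methylscape)
  library(data.table)
})

manifest <- jsonlite::read_json("results/sim/manifest.json")
dir.create("results/methylation", showWarnings = FALSE, recursive = TRUE)

models <- read_gff3_genes(manifest$paths$genes_predictor_a)
fpkm <- read_fpkm_table(manifest$paths$fpkm_tsv)
models <- subset_models(models, fpkm[sum_fpkm > 0, gene_id])

for (k in seq_along(manifest$paths$cx_reports)) {
  track <- methylation_track(
    read_cytosine_report(manifest$paths$cx_reports[[k]]), min_coverage = 5L)

  gl <- global_level(track)
  fwrite(gl, sprintf("results/methylation/global_levels_condition%d.tsv", k),
         sep = "\t")
  cat(sprintf("condition %d: CG %.1f%%, CHG %.1f%%, CHH %.1f%% (mean of fractions)\n",
              k, 100 * gl[context == "CG", mean_of_fractions],
              100 * gl[context == "CHG", mean_of_fractions],
              100 * gl[context == "CHH", mean_of_fractions]))

  hist <- site_level_histogram(track, n_bins = 20L)
  fwrite(hist, sprintf("results/methylation/site_histogram_condition%d.tsv", k),
         sep = "\t")
  extremes <- hist[c(1, .N), sum(count)] / hist[, sum(count)]
  cat(sprintf("  bimodality: %.0f%% of covered CpGs in the two extreme bins\n",
              100 * extremes))

  regions <- gene_region_methylation(track, models)
  fwrite(regions,
         sprintf("results/methylation/gene_regions_condition%d.tsv", k),
         sep = "\t")
  per_kind <- regions[!is.na(fraction),
                      .(mean = mean(fraction), median = median(fraction)),
                      by = region_kind]
  print(per_kind)

  prof <- metagene_profile(track, models)
  fwrite(prof, sprintf("results/methylation/metagene_condition%d.tsv", k),
         sep = "\t")

  write_fraction_bedgraph(
    track, sprintf("results/methylation/cg_fractions_condition%d.bedGraph", k))
}
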