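suppressPackageStartupMessages({
  library(data.table)
  library(GenomicRanges)
})

# canonical trinucleotide for each context (H bases chosen arbitrarily)
tri_for <- c(CG = "CGA", CHG = "CAG", CHH = "CAT")

toy_records <- function(pos, meth, unmeth, strand = "+", context = "CG",
                        contig = "c1") {
  n <- length(pos)
  data.table(
    contig = rep_len(contig, n), pos = as.integer(pos),
    strand = rep_len(strand, n),
    count_meth = as.integer(meth), count_unmeth = as.integer(unmeth),
    context = rep_len(context, n),
    trinucleotide = unname(tri_for[rep_len(context, n)])
  )
}

empty_records <- function() toy_records(integer(0), integer(0), integer(0))

# track from per-site fractions at fixed coverage
toy_track <- function(pos, fraction, coverage = 10L, strand = "+",
                      context = "CG", contig = "c1", min_coverage = 1L) {
  meth <- as.integer(round(fraction * coverage))
  methylation_track(
    toy_records(pos, meth, coverage - meth, strand = strand,
                context = context, contig = contig),
    min_coverage = min_coverage
  )
}

# minimal gene model builder
toy_models <- function(df, exons = NULL, source = "predictorA") {
  g <- GRanges(df$contig, IRanges(df$start, df$end), strand = df$strand)
  mcols(g)$gene_id <- df$gene_id
  exl <- NULL
  if (!is.null(exons)) {
    ex <- GRanges(exons$contig, IRanges(exons$start, exons$end),
                  strand = exons$strand)
    exl <- methods::as(
      S4Vectors::split(ex, factor(exons$gene_id, levels = df$gene_id)),
      "CompressedGRangesList")
  }
  gene_model_set(g, exons = exl, source = source)
}

# ---------------------------------------------------------------------------
# Shared large-scale simulation used by the acceptance suite: the default
# profile (5 Mbp, 5000 genes, two conditions) at a fixed seed, built once per
# session and cached.
.acc_env <- new.env(parent = emptyenv())

acceptance_fixture <- function() {
  if (!is.null(.acc_env$fix)) return(.acc_env$fix)
  profile <- sim_profile(seed = 101L)
  sim_dir <- file.path(tempdir(), "methylscape-acceptance-sim")
  manifest_path <- file.path(sim_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path) else
    simulate_methylome(profile, sim_dir)
  paths <- manifest$paths
  tracks <- lapply(unlist(paths$cx_reports), function(f)
    methylation_track(read_cytosine_report(f), min_coverage = 5L))
  models_a <- read_gff3_genes(paths$genes_predictor_a)
  fpkm <- read_fpkm_table(paths$fpkm_tsv)
  supported <- fpkm[sum_fpkm > 0, gene_id]
  models <- subset_models(models_a, intersect(
    mcols(models_a$genes)$gene_id, supported))
  status <- lapply(tracks, classify_genes, models = models, fpkm = fpkm)
  .acc_env$fix <- list(
    profile = profile, manifest = manifest, paths = paths,
    tracks = tracks, models = models, fpkm = fpkm, status = status,
    expected = expected_summaries(profile)
  )
  .acc_env$fix
}
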