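#' Select high-confidence consensus gene models
#'
#' A predictor-A model is high confidence when (a) some predictor-B model
#' overlaps its genomic span by at least `min_overlap_bp` on the same
#' strand, and (b) its FPKM summed across samples is strictly positive
#' (models with sum FPKM exactly 0 are presumed misscalls). This leverages
#' one predictor's boundary accuracy and the other's expression support.
#' Selection is monotone: adding B models never shrinks the selection, and
#' zeroing FPKM never grows it.
#'
#' @param models_a [gene_model_set()] from predictor A (the set selected
#'   from).
#' @param models_b [gene_model_set()] from predictor B.
#' @param fpkm FPKM table from [read_fpkm_table()]. A-models missing from it
#'   are treated as sum FPKM 0, with a warning.
#' @param overlap `"span"` (default) compares genomic spans; `"cds"`
#'   compares CDS intervals.
#' @param min_overlap_bp minimum overlap in bp (default 1).
#' @return list with `selected` (a `gene_model_set` subset of A), `table`
#'   (per A gene: `gene_id`, `overlaps_b`, `sum_fpkm`, `selected`),
#'   `n_removed_overlap`, `n_removed_fpkm`.
#' @export
high_confidence_models <- function(models_a, models_b, fpkm,
                                   overlap = c("span", "cds"),
                                   min_overlap_bp = 1L) {
  stopifnot(is(models_a, "gene_model_set"), is(models_b, "gene_model_set"))
  overlap <- match.arg(overlap)
  ids <- mcols(models_a$genes)$gene_id
  if (overlap == "span") {
    a_gr <- granges(models_a$genes)
    b_gr <- granges(models_b$genes)
    overlaps_b <- countOverlaps(a_gr, b_gr, minoverlap = min_overlap_bp,
                                ignore.strand = FALSE) > 0L
  } else {
    hits <- findOverlaps(models_a$cds, unlist(models_b$cds),
                         minoverlap = min_overlap_bp, ignore.strand = FALSE)
    overlaps_b <- seq_along(ids) %in% queryHits(hits)
  }
  fpkm <- as.data.table(fpkm)
  sum_fpkm <- fpkm$sum_fpkm[match(ids, fpkm$gene_id)]
  if (anyNA(sum_fpkm)) {
    warning(sum(is.na(sum_fpkm)),
            " predictor-A model(s) missing from the FPKM table; ",
            "treated as sum FPKM 0")
    sum_fpkm[is.na(sum_fpkm)] <- 0
  }
  expressed <- sum_fpkm > 0
  selected <- overlaps_b & expressed
  tab <- data.table(gene_id = ids, overlaps_b = overlaps_b,
                    sum_fpkm = sum_fpkm, selected = selected)
  sel_models <- if (any(selected)) subset_models(models_a, ids[selected])
    else NULL
  list(selected = sel_models, table = tab[],
       n_removed_overlap = sum(!overlaps_b),
       n_removed_fpkm = sum(overlaps_b & !expressed))
}

#' Genome-wide gene model statistics
#'
#' Assembly-level descriptive statistics of a gene model set: model count,
#' percent coding DNA (unique CDS bases — counted once even under
#' overlapping genes, since this is a genome fraction — over assembly
#' length), gene density per Mbp, mean model/exon/intron lengths and counts,
#' and assembly GC content.
#'
#' @param models a [gene_model_set()] (may be empty or `NULL`).
#' @param genome a `DNAStringSet` of the assembly (or a FASTA path).
#' @param coding `"cds"` (default) or `"exon"`: which intervals count as
#'   coding bases.
#' @return a one-row data.table with `n_models`, `percent_coding_dna`,
#'   `gene_density_per_mbp`, `mean_model_length`, `mean_exons_per_gene`,
#'   `mean_exon_length`, `mean_introns_per_gene`, `mean_intron_length`,
#'   `gc_content`. With zero genes, means are `NA` and counts 0.
#' @export
genome_stats <- function(models, genome, coding = c("cds", "exon")) {
  coding <- match.arg(coding)
  if (is.character(genome)) genome <- readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  asm_len <- sum(as.numeric(width(genome)))
  gc <- sum(letterFrequency(genome, "GC")) /
    max(1, sum(letterFrequency(genome, "ACGT")))

  if (is.null(models) || length(models) == 0L)
    return(data.table(n_models = 0L, percent_coding_dna = 0,
                      gene_density_per_mbp = 0, mean_model_length = NA_real_,
                      mean_exons_per_gene = NA_real_,
                      mean_exon_length = NA_real_,
                      mean_introns_per_gene = NA_real_,
                      mean_intron_length = NA_real_, gc_content = gc))
  g <- models$genes
  bad <- which(!(as.character(seqnames(g)) %in% names(genome)) |
                 end(g) > width(genome)[match(as.character(seqnames(g)),
                                              names(genome))])
  if (length(bad))
    stop("gene beyond contig end: ", mcols(g)$gene_id[bad[1L]])
  coding_ranges <- if (coding == "cds") models$cds else models$exons
  coding_bases <- sum(as.numeric(width(
    reduce(unlist(coding_ranges, use.names = FALSE), ignore.strand = TRUE))))
  ii <- introns(models)
  intron_w <- width(unlist(ii, use.names = FALSE))
  exon_w <- width(unlist(models$exons, use.names = FALSE))
  data.table(
    n_models = length(g),
    percent_coding_dna = 100 * coding_bases / asm_len,
    gene_density_per_mbp = length(g) / (asm_len / 1e6),
    mean_model_length = mean(width(g)),
    mean_exons_per_gene = mean(lengths(models$exons)),
    mean_exon_length = if (length(exon_w)) mean(exon_w) else NA_real_,
    mean_introns_per_gene = mean(lengths(ii)),
    mean_intron_length = if (length(intron_w)) mean(intron_w) else NA_real_,
    gc_content = gc
  )
}
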