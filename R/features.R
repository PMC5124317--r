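#' Methylation level of genomic features
#'
#' For each feature (a set of one or more intervals sharing a `feature_id`),
#' computes the unweighted mean — and median — of per-site methylation
#' fractions over the covered sites of the requested context falling inside
#' the feature's intervals. Site inclusion is strand-agnostic: a feature on
#' either strand collects cytosines of both strands within its span. A
#' feature with zero covered sites gets an undefined (`NA`) fraction, not an
#' error.
#'
#' @param track a [methylation_track()].
#' @param features a `GRanges` with a `feature_id` metadata column (or
#'   names); multiple ranges may share a `feature_id` and are aggregated.
#'   An optional `region_kind` column is carried through.
#' @param context methylation context (default `"CG"`).
#' @return data.table with one row per feature: `feature_id`,
#'   (`region_kind`,) `n_sites_covered`, `fraction` (mean of site
#'   fractions), `median_fraction`, `weighted_fraction` (summed methylated
#'   reads over summed reads) and `total_reads`.
#' @export
feature_methylation <- function(track, features, context = "CG") {
  stopifnot(is(features, "GRanges"))
  ids <- mcols(features)$feature_id %||% names(features)
  if (is.null(ids)) stop("'features' needs a feature_id column or names")
  ids <- as.character(ids)
  kinds <- mcols(features)$region_kind
  uniq <- unique(ids)
  out <- data.table(feature_id = uniq)
  if (!is.null(kinds))
    out[, region_kind := as.character(kinds)[match(uniq, ids)]]

  sites <- covered_sites(track, context = context)
  if (nrow(sites) && length(features)) {
    hits <- findOverlaps(.sites_gr(sites), unname(granges(features)),
                         ignore.strand = TRUE)
    # a site counts once per feature even if two of the feature's intervals
    # overlap it
    stat <- unique(data.table(feature_id = ids[subjectHits(hits)],
                              site = queryHits(hits)))
    stat[, fraction := sites$fraction[site]]
    stat[, cm := sites$count_meth[site]]
    stat[, cov := sites$coverage[site]]
    agg <- stat[, .(n_sites_covered = .N, fraction = mean(fraction),
                    median_fraction = median(fraction),
                    weighted_fraction = sum(cm) / sum(cov),
                    total_reads = sum(cov)), by = feature_id]
    out <- agg[out, on = "feature_id"]
    setcolorder(out, c("feature_id",
                       intersect("region_kind", names(out))))
  } else {
    out[, n_sites_covered := 0L]
    out[, fraction := NA_real_]
    out[, median_fraction := NA_real_]
    out[, weighted_fraction := NA_real_]
    out[, total_reads := 0L]
  }
  out[is.na(n_sites_covered), n_sites_covered := 0L]
  out[]
}

#' Per-gene methylation by gene region
#'
#' Computes, per gene, the mean methylation fraction of the gene body, its
#' exons, its introns, and the 500 bp (configurable) upstream and downstream
#' flanks taken on the gene's strand. Flanks extending past a contig edge
#' are truncated.
#'
#' @param track a [methylation_track()].
#' @param models a [gene_model_set()].
#' @param flank_bp flank width in bp (default 500).
#' @param context methylation context (default `"CG"`).
#' @return data.table with one row per gene and region kind: `gene_id`,
#'   `region_kind` (one of `gene_body`, `exon`, `intron`, `upstream`,
#'   `downstream`), `n_sites_covered`, `fraction`, `median_fraction`.
#' @export
gene_region_methylation <- function(track, models, flank_bp = 500L,
                                    context = "CG") {
  stopifnot(is(models, "gene_model_set"))
  g <- models$genes
  ids <- mcols(g)$gene_id
  minus <- as.character(strand(g)) == "-"

  up_start <- ifelse(minus, end(g) + 1L, pmax(1L, start(g) - flank_bp))
  up_end <- ifelse(minus, end(g) + flank_bp, start(g) - 1L)
  dn_start <- ifelse(minus, pmax(1L, start(g) - flank_bp), end(g) + 1L)
  dn_end <- ifelse(minus, start(g) - 1L, end(g) + flank_bp)
  flank_gr <- function(s, e) {
    keep <- which(e >= s)
    GRanges(seqnames(g)[keep], IRanges(s[keep], e[keep]),
            feature_id = ids[keep])
  }

  pieces <- list(
    gene_body = {
      gb <- granges(g); mcols(gb)$feature_id <- ids; gb
    },
    exon = {
      fl <- unlist(models$exons, use.names = FALSE)
      mcols(fl)$feature_id <- rep(ids, lengths(models$exons)); fl
    },
    intron = {
      ii <- introns(models)
      fl <- unlist(ii, use.names = FALSE)
      mcols(fl)$feature_id <- rep(ids, lengths(ii)); fl
    },
    upstream = flank_gr(up_start, up_end),
    downstream = flank_gr(dn_start, dn_end)
  )
  out <- rbindlist(lapply(names(pieces), function(kind) {
    fm <- feature_methylation(track, pieces[[kind]], context = context)
    fm[, region_kind := kind]
    fm
  }), fill = TRUE)
  setnames(out, "feature_id", "gene_id")
  setcolorder(out, c("gene_id", "region_kind"))
  out[]
}

#' Metagene methylation profile
#'
#' Averages methylation over genes after scaling each gene body to a fixed
#' number of bins and adding fixed-width flank bins. Minus-strand genes are
#' reversed so that bin 1 is always the 5' end. Each bin's value is the mean
#' over genes of the per-gene bin means; genes with no covered site in a bin
#' are skipped for that bin. Flanks extending past a contig edge are
#' truncated, not an error.
#'
#' @param track a [methylation_track()].
#' @param models a [gene_model_set()].
#' @param n_body_bins number of gene-body bins (>= 1).
#' @param flank_bp flank width in bp on each side.
#' @param flank_bin_bp width of each flank bin in bp.
#' @param context methylation context.
#' @return data.table with `bin` (1-based, 5' to 3'), `region` (`upstream`,
#'   `gene_body`, `downstream`), `mean_fraction`, `n_genes`.
#' @export
metagene_profile <- function(track, models, n_body_bins = 20L,
                             flank_bp = 500L, flank_bin_bp = 100L,
                             context = "CG") {
  if (n_body_bins < 1L) stop("n_body_bins must be >= 1")
  stopifnot(is(models, "gene_model_set"))
  n_flank_bins <- if (flank_bp > 0L) ceiling(flank_bp / flank_bin_bp) else 0L
  g <- models$genes
  ids <- mcols(g)$gene_id

  sites <- covered_sites(track, context = context)
  total_bins <- n_body_bins + 2L * n_flank_bins
  template <- data.table(
    bin = seq_len(total_bins),
    region = rep(c("upstream", "gene_body", "downstream"),
                 c(n_flank_bins, n_body_bins, n_flank_bins))
  )
  if (!nrow(sites) || !length(g)) {
    template[, `:=`(mean_fraction = NA_real_, n_genes = 0L)]
    return(template[])
  }

  win <- GRanges(seqnames(g),
                 IRanges(pmax(1L, start(g) - flank_bp), end(g) + flank_bp))
  hits <- findOverlaps(.sites_gr(sites), win, ignore.strand = TRUE)
  if (!length(hits)) {
    template[, `:=`(mean_fraction = NA_real_, n_genes = 0L)]
    return(template[])
  }
  gi <- subjectHits(hits)
  pos <- sites$pos[queryHits(hits)]
  frac <- sites$fraction[queryHits(hits)]
  gs <- start(g)[gi]; ge <- end(g)[gi]
  minus <- (as.character(strand(g)) == "-")[gi]

  # signed distance from the 5' gene start, in gene orientation
  upstream <- ifelse(minus, pos > ge, pos < gs)
  downstream <- ifelse(minus, pos < gs, pos > ge)
  body <- !upstream & !downstream
  bin <- integer(length(pos))
  # body: relative position in [0, 1), scaled to n_body_bins
  rel <- ifelse(minus, (ge - pos), (pos - gs)) / pmax(1L, ge - gs + 1L)
  bin[body] <- n_flank_bins + 1L +
    pmin(n_body_bins - 1L, floor(rel[body] * n_body_bins))
  dist_up <- ifelse(minus, pos - ge, gs - pos)     # >= 1 when upstream
  bin[upstream] <- n_flank_bins -
    pmin(n_flank_bins - 1L, (dist_up[upstream] - 1L) %/% flank_bin_bp)
  dist_dn <- ifelse(minus, gs - pos, pos - ge)
  bin[downstream] <- n_flank_bins + n_body_bins +
    pmin(n_flank_bins, 1L + (dist_dn[downstream] - 1L) %/% flank_bin_bp)

  per_gene <- data.table(gene = gi, bin = bin, fraction = frac)[
    , .(m = mean(fraction)), by = .(gene, bin)]
  prof <- per_gene[, .(mean_fraction = mean(m), n_genes = .N), by = bin]
  out <- prof[template, on = "bin"]
  out[is.na(n_genes), n_genes := 0L]
  setcolorder(out, c("bin", "region", "mean_fraction", "n_genes"))
  setorder(out, bin)
  out[]
}
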