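#' Classify genes as methylated or unmethylated
#'
#' Computes each gene's body CG methylation fraction (mean of per-site
#' fractions over covered sites in the gene span) and calls a status:
#' `methylated` when the fraction is at or above `threshold` (a tie at the
#' threshold goes to methylated), `unmethylated` below it, and
#' `undetermined` when fewer than `min_sites` covered sites support the
#' gene. On a well-separated bimodal methylome any mid-range threshold gives
#' the same calls; both knobs are exposed.
#'
#' @param track a [methylation_track()].
#' @param models a [gene_model_set()].
#' @param min_sites minimum covered sites for a determined status
#'   (default 5).
#' @param threshold fraction at/above which a gene is methylated
#'   (default 0.5).
#' @param fpkm optional FPKM table from [read_fpkm_table()]; appends
#'   `sum_fpkm`/`mean_fpkm` (NA for genes missing from the table).
#' @param context methylation context (default `"CG"`).
#' @return data.table with `gene_id`, `fraction`, `n_sites`, `status`,
#'   and (when `fpkm` is given) `sum_fpkm`, `mean_fpkm`.
#' @export
classify_genes <- function(track, models, min_sites = 5L, threshold = 0.5,
                           fpkm = NULL, context = "CG") {
  stopifnot(is(models, "gene_model_set"))
  gb <- granges(models$genes)
  mcols(gb)$feature_id <- mcols(models$genes)$gene_id
  fm <- feature_methylation(track, gb, context = context)
  out <- data.table(gene_id = fm$feature_id, fraction = fm$fraction,
                    n_sites = fm$n_sites_covered)
  out[, status := classify_status(fraction, n_sites, min_sites, threshold)]
  if (!is.null(fpkm)) {
    fpkm <- as.data.table(fpkm)
    out <- fpkm[, .(gene_id, sum_fpkm, mean_fpkm)][out, on = "gene_id"]
    setcolorder(out, c("gene_id", "fraction", "n_sites", "status"))
  }
  out[]
}

#' Vectorised status rule
#'
#' @param fraction gene-body methylation fraction.
#' @param n_sites covered sites supporting it.
#' @param min_sites,threshold see [classify_genes()].
#' @return character vector: `"methylated"`, `"unmethylated"` or
#'   `"undetermined"`.
#' @export
classify_status <- function(fraction, n_sites, min_sites = 5L,
                            threshold = 0.5) {
  ifelse(n_sites < min_sites | is.na(fraction), "undetermined",
         ifelse(fraction >= threshold, "methylated", "unmethylated"))
}

#' Summarise methylation classes
#'
#' Per-class counts, proportions (over determined genes only), mean
#' methylation fraction and mean FPKM. A run with two conditions is
#' summarised by calling this once per condition and averaging the
#' proportions.
#'
#' @param status_table output of [classify_genes()] (with FPKM columns if
#'   FPKM summaries are wanted).
#' @return data.table with one row per class (`methylated`,
#'   `unmethylated`): `n`, `proportion`, `mean_fraction`, and when
#'   available `mean_fpkm`, `median_fpkm`.
#' @export
class_summary <- function(status_table) {
  dt <- as.data.table(status_table)
  det <- dt[status %in% c("methylated", "unmethylated")]
  if (!nrow(det)) stop("no determined genes to summarise")
  out <- det[, {
    res <- list(n = .N, proportion = .N / nrow(det),
                mean_fraction = mean(fraction))
    if ("mean_fpkm" %in% names(det)) {
      res$mean_fpkm <- mean(mean_fpkm, na.rm = TRUE)
      res$median_fpkm <- median(mean_fpkm, na.rm = TRUE)
    }
    res
  }, by = status]
  # both classes always present in the output
  for (s in setdiff(c("methylated", "unmethylated"), out$status))
    out <- rbind(out, data.table(status = s, n = 0L, proportion = 0),
                 fill = TRUE)
  setorder(out, -status)[]
}

#' Correlation of methylation between two conditions
#'
#' Pearson correlation of per-unit mean methylation fractions between two
#' tracks from the same genome, at gene or fixed-window resolution. Units
#' with an undefined fraction in either condition are excluded and counted.
#'
#' @param track_a,track_b two [methylation_track()]s.
#' @param models a [gene_model_set()]; required when `unit = "gene"`.
#' @param unit `"gene"` or `"window"`.
#' @param window window size in bp for `unit = "window"` (default 1000).
#' @param context methylation context (default `"CG"`).
#' @param min_sites minimum covered sites per unit and condition
#'   (default 1).
#' @return list with `r` (Pearson), `n_units`, `n_excluded`, and the paired
#'   `table` (`unit`, `fraction_a`, `fraction_b`).
#' @export
condition_correlation <- function(track_a, track_b, models = NULL,
                                  unit = c("gene", "window"), window = 1000L,
                                  context = "CG", min_sites = 1L) {
  unit <- match.arg(unit)
  if (unit == "gene") {
    if (is.null(models)) stop("unit = 'gene' needs gene models")
    per_unit <- function(track) {
      cg <- classify_genes(track, models, min_sites = min_sites,
                           context = context)
      cg[n_sites >= min_sites, .(unit = gene_id, fraction)]
    }
  } else {
    per_unit <- function(track) {
      sites <- covered_sites(track, context = context)
      sites[, win := paste0(contig, ":", (pos - 1L) %/% window)]
      agg <- sites[, .(fraction = mean(fraction), n = .N), by = win]
      agg[n >= min_sites, .(unit = win, fraction)]
    }
  }
  a <- per_unit(track_a)
  b <- per_unit(track_b)
  merged <- merge(a, b, by = "unit", suffixes = c("_a", "_b"))
  merged <- merged[!is.na(fraction_a) & !is.na(fraction_b)]
  n_excl <- length(union(a$unit, b$unit)) - nrow(merged)
  if (nrow(merged) < 3L)
    stop("fewer than 3 units with defined fractions in both conditions")
  list(r = cor(merged$fraction_a, merged$fraction_b),
       n_units = nrow(merged), n_excluded = n_excl, table = merged[])
}

#' Cross-species shared methylation status of ortholog pairs
#'
#' Given per-gene status tables for two species and an ortholog pair table,
#' counts pairs where both genes are methylated, exactly one is, or
#' neither, over pairs with a determined status on both sides. Pairs
#' referencing genes missing from either table are excluded with a warning.
#'
#' @param status_a,status_b status tables from [classify_genes()] for
#'   species A and B.
#' @param pairs data.table with columns `gene_a`, `gene_b` (see
#'   [read_ortholog_pairs()]).
#' @return list with `counts` (named: `both_methylated`, `either_only`,
#'   `neither`), `n_pairs_used`, `n_dangling`, `n_undetermined`.
#' @export
shared_ortholog_status <- function(status_a, status_b, pairs) {
  pairs <- as.data.table(pairs)
  sa <- as.data.table(status_a)[, .(gene_a = gene_id, status_a = status)]
  sb <- as.data.table(status_b)[, .(gene_b = gene_id, status_b = status)]
  n0 <- nrow(pairs)
  m <- sb[sa[pairs, on = "gene_a"], on = "gene_b"]
  dangling <- is.na(m$status_a) | is.na(m$status_b)
  if (any(dangling))
    warning(sum(dangling), " ortholog pair(s) reference genes missing from ",
            "a status table; excluded")
  m <- m[!dangling]
  det <- m$status_a != "undetermined" & m$status_b != "undetermined"
  mm <- m[det]
  counts <- c(
    both_methylated = mm[, sum(status_a == "methylated" &
                                 status_b == "methylated")],
    either_only = mm[, sum((status_a == "methylated") !=
                             (status_b == "methylated"))],
    neither = mm[, sum(status_a == "unmethylated" &
                         status_b == "unmethylated")]
  )
  list(counts = counts, n_pairs_used = nrow(mm),
       n_dangling = sum(dangling), n_undetermined = sum(!det))
}
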