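#' Partition determined genes into expression-methylation populations
#'
#' Reproduces the three-population structure of methylation-versus-FPKM
#' scatter plots in heavily methylated genomes:
#' population `i` — genes with very low expression (mean FPKM in
#' `[0, low_fpkm_max]`), which in such genomes are almost all methylated;
#' population `iii` — methylated genes that are nonetheless moderately to
#' highly expressed (mean FPKM at or above `high_fpkm_min`);
#' population `ii` — expressed, unmethylated genes (mean FPKM above
#' `low_fpkm_max`); everything else is `other`. Population `i` takes
#' precedence over `iii` when both match, because `i` is defined by
#' expression alone. Gene FPKM is the mean across samples; the sum is kept
#' alongside.
#'
#' @param status_table output of [classify_genes()] including `mean_fpkm`.
#' @param low_fpkm_max upper FPKM bound of population `i` (default 10).
#' @param high_fpkm_min lower FPKM bound of population `iii` (default 100).
#' @return list with `assignments` (gene_id, fraction, mean_fpkm, status,
#'   population), `summary` (per population: n, mean_fpkm,
#'   percent_methylated), and `n_excluded` (determined genes lacking FPKM,
#'   excluded with a warning).
#' @export
partition_populations <- function(status_table, low_fpkm_max = 10,
                                  high_fpkm_min = 100) {
  dt <- as.data.table(status_table)
  if (!"mean_fpkm" %in% names(dt))
    stop("status table lacks FPKM columns; classify with an FPKM table")
  det <- dt[status %in% c("methylated", "unmethylated")]
  n_excl <- det[, sum(is.na(mean_fpkm))]
  if (n_excl > 0)
    warning(n_excl, " determined gene(s) missing from the FPKM table; ",
            "excluded from the partition")
  det <- det[!is.na(mean_fpkm)]
  det[, population := ifelse(
    mean_fpkm <= low_fpkm_max, "i_low_fpkm",
    ifelse(status == "methylated" & mean_fpkm >= high_fpkm_min,
           "iii_expressed_methylated",
           ifelse(status == "unmethylated", "ii_expressed_unmethylated",
                  "other")))]
  summary <- det[, .(
    n = .N,
    mean_fpkm = mean(mean_fpkm),
    percent_methylated = 100 * mean(status == "methylated")
  ), by = population]
  setorder(summary, population)
  list(assignments = det[, .(gene_id, fraction, mean_fpkm, status,
                             population)],
       summary = summary[], n_excluded = n_excl)
}

#' Methylation-versus-expression scatter table and correlations
#'
#' Emits the per-gene (fraction methylation, mean FPKM) table underlying a
#' methylation-expression scatter plot, with Pearson and Spearman
#' coefficients. In bimodal methylomes both are expected to be weak — the
#' structure is population-like, not linear. With a constant column the
#' correlation is undefined and reported as `NA`.
#'
#' @param status_table output of [classify_genes()] including `mean_fpkm`.
#' @return list with `table` (gene_id, fraction, mean_fpkm), `pearson`,
#'   `spearman`.
#' @export
methylation_expression_scatter <- function(status_table) {
  dt <- as.data.table(status_table)
  if (!"mean_fpkm" %in% names(dt))
    stop("status table lacks FPKM columns; classify with an FPKM table")
  tab <- dt[!is.na(fraction) & !is.na(mean_fpkm),
            .(gene_id, fraction, mean_fpkm)]
  safe_cor <- function(method) {
    if (nrow(tab) < 3L || sd(tab$fraction) == 0 || sd(tab$mean_fpkm) == 0)
      return(NA_real_)
    cor(tab$fraction, tab$mean_fpkm, method = method)
  }
  list(table = tab[], pearson = safe_cor("pearson"),
       spearman = safe_cor("spearman"))
}
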