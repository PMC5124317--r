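#' Taxonomic methylation enrichment with a permutation test
#'
#' For each taxonomic group, the enrichment is the proportion of methylated
#' genes within the group minus the proportion of methylated genes across
#' all determined genes; groups below 0 have proportionally fewer methylated
#' genes than the genome at large. Undetermined genes are excluded from both
#' numerator and denominator. Significance is assessed by permuting status
#' labels over genes (`n_permutations` shuffles) with a two-sided empirical
#' p-value `(1 + #{|perm| >= |obs|}) / (1 + n_permutations)` — the
#' permutation test is an addition beyond the descriptive statistic, kept in
#' its own column.
#'
#' The gene-count-weighted mean of enrichments over all groups is zero by
#' construction (each group's deviation is taken from the common genome-wide
#' proportion).
#'
#' @param status_table output of [classify_genes()].
#' @param taxonomy table with `gene_id`, `group` (see
#'   [read_taxonomy_table()]); must assign each determined gene exactly one
#'   group. Determined genes missing a group are dropped with a warning.
#' @param n_permutations permutation count (default 10000).
#' @param seed optional seed for the permutation stream.
#' @return data.table with `group`, `n_genes`, `p_group`, `p_genome`,
#'   `enrichment`, `p_perm`.
#' @export
taxon_enrichment <- function(status_table, taxonomy, n_permutations = 10000L,
                             seed = NULL) {
  dt <- as.data.table(status_table)[
    status %in% c("methylated", "unmethylated")]
  tax <- as.data.table(taxonomy)
  m <- tax[, .(gene_id, group)][dt[, .(gene_id, status)], on = "gene_id"]
  if (anyNA(m$group)) {
    warning(sum(is.na(m$group)),
            " determined gene(s) without a taxonomy group; excluded")
    m <- m[!is.na(group)]
  }
  if (!nrow(m)) stop("no determined genes with taxonomy groups")
  meth <- m$status == "methylated"
  grp <- factor(m$group)
  p_genome <- mean(meth)
  n_by <- tabulate(grp)
  obs_p <- as.numeric(tapply(meth, grp, mean))
  obs <- obs_p - p_genome

  if (!is.null(seed)) set.seed(seed)
  B <- as.integer(n_permutations)
  exceed <- integer(nlevels(grp))
  gi <- as.integer(grp)
  for (b in seq_len(B)) {
    perm <- meth[sample.int(length(meth))]
    perm_p <- rowsum(as.numeric(perm), gi)[, 1L] / n_by
    exceed <- exceed + (abs(perm_p - p_genome) >= abs(obs) - 1e-12)
  }
  data.table(group = levels(grp), n_genes = n_by,
             p_group = obs_p, p_genome = p_genome,
             enrichment = obs,
             p_perm = (1 + exceed) / (1 + B))[order(-enrichment)]
}
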