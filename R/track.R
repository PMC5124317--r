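#' Build a methylation track from cytosine records
#'
#' A methylation track indexes one condition's cytosine records and carries
#' the coverage threshold below which a site is treated as uncovered. Records
#' are kept per strand: CG sites are not pooled across the two strands of a
#' CpG unless an operation explicitly says so, because pooling changes the
#' coverage of the merged site.
#'
#' @param records data.table of cytosine records (see
#'   [read_cytosine_report()]), at most one per (contig, pos, strand).
#' @param min_coverage minimum reads (methylated + unmethylated) for a site
#'   to count as covered. Default 5, a standard WGBS choice.
#' @return an object of class `methylation_track`.
#' @export
methylation_track <- function(records, min_coverage = 5L) {
  dt <- as.data.table(records)
  if (!all(.cx_cols %in% names(dt)))
    stop("records must have columns: ", paste(.cx_cols, collapse = ", "))
  if (anyDuplicated(dt, by = c("contig", "pos", "strand")))
    stop("duplicate (contig, pos, strand) record in track")
  dt <- dt[, .SD, .SDcols = .cx_cols]
  setkey(dt, contig, pos, strand)
  structure(list(sites = dt, min_coverage = as.integer(min_coverage)),
            class = "methylation_track")
}

#' @export
print.methylation_track <- function(x, ...) {
  cov <- x$sites$count_meth + x$sites$count_unmeth
  cat("methylation_track:", nrow(x$sites), "sites on",
      length(unique(x$sites$contig)), "contigs;",
      sum(cov >= x$min_coverage), "covered at min_coverage",
      x$min_coverage, "\n")
  invisible(x)
}

#' Per-site methylation fraction
#'
#' The fraction of methylated reads at a cytosine:
#' `count_meth / (count_meth + count_unmeth)`. Undefined (NA) at zero
#' coverage — an uncovered site is a missing value, not an error.
#'
#' @param count_meth,count_unmeth non-negative read counts (vectorised).
#' @return numeric vector in `[0, 1]`, `NA` where coverage is zero.
#' @export
site_fraction <- function(count_meth, count_unmeth) {
  total <- count_meth + count_unmeth
  ifelse(total > 0, count_meth / total, NA_real_)
}

#' Covered sites of a track, with fractions
#'
#' @param track a [methylation_track()].
#' @param context optional context filter (`"CG"`, `"CHG"`, `"CHH"` or
#'   `NULL` for all).
#' @param min_coverage override of the track's threshold.
#' @return data.table of covered sites with columns `coverage` and
#'   `fraction` appended.
#' @export
covered_sites <- function(track, context = NULL, min_coverage = NULL) {
  stopifnot(is(track, "methylation_track"))
  mc <- min_coverage %||% track$min_coverage
  keep_ctx <- context
  dt <- track$sites
  if (!is.null(keep_ctx)) dt <- dt[dt$context %in% keep_ctx]
  dt <- dt[count_meth + count_unmeth >= mc]
  dt <- copy(dt)
  dt[, coverage := count_meth + count_unmeth]
  dt[, fraction := count_meth / coverage]
  dt[]
}

#' Global methylation level per context
#'
#' Two estimators over the covered sites of each context:
#' `mean_of_fractions` — the unweighted average of per-site methylation
#' fractions (the per-cytosine average) — and `weighted` — summed methylated
#' reads over summed total reads. The two agree exactly when every site has
#' the same coverage. Levels are reported per requested context and pooled
#' over all requested contexts (`"all"`).
#'
#' @param track a [methylation_track()].
#' @param contexts contexts to report (default all three).
#' @return data.table with columns `context`, `n_sites`,
#'   `mean_of_fractions`, `weighted`. Contexts with no covered site get `NA`
#'   levels with a warning.
#' @export
global_level <- function(track, contexts = c("CG", "CHG", "CHH")) {
  sites <- covered_sites(track, context = contexts)
  one <- function(dt, label) {
    if (!nrow(dt)) {
      warning("no covered sites for context ", label)
      return(data.table(context = label, n_sites = 0L,
                        mean_of_fractions = NA_real_, weighted = NA_real_))
    }
    data.table(context = label, n_sites = nrow(dt),
               mean_of_fractions = mean(dt$fraction),
               weighted = sum(dt$count_meth) / sum(dt$coverage))
  }
  out <- rbindlist(lapply(contexts, function(cx) one(sites[context == cx], cx)))
  if (length(contexts) > 1L) out <- rbind(out, one(sites, "all"))
  out[]
}

#' Histogram of per-site methylation fractions
#'
#' Bin counts of the methylation fraction over covered sites; with bimodal
#' methylomes the mass concentrates in the extreme bins.
#'
#' @param track a [methylation_track()].
#' @param context context to histogram (default `"CG"`).
#' @param n_bins number of equal-width bins over `[0, 1]` (>= 2).
#' @return data.table with `bin_low`, `bin_high`, `count`; counts sum to the
#'   number of covered sites.
#' @export
site_level_histogram <- function(track, context = "CG", n_bins = 20L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  sites <- covered_sites(track, context = context)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  counts <- if (nrow(sites))
    tabulate(findInterval(sites$fraction, breaks, rightmost.closed = TRUE),
             nbins = n_bins)
  else integer(n_bins)
  data.table(bin_low = head(breaks, -1L), bin_high = breaks[-1L],
             count = counts)
}

# covered sites of a context as GRanges (strand-agnostic width-1 ranges)
.sites_gr <- function(sites) {
  GRanges(sites$contig, IRanges(sites$pos, sites$pos))
}
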