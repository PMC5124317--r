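#' Segment contigs into hyper- and hypomethylated domains
#'
#' A two-state thresholded-window segmentation: each contig is tiled by
#' non-overlapping windows; a window is labelled `hyper` when its mean of
#' per-site methylation fractions is at or above `t_hyper`, `hypo` below,
#' and carries the previous window's label when it has fewer than
#' `min_sites_per_window` covered sites (data-sparse windows never open or
#' close a domain on their own evidence). Runs of equal labels merge into
#' segments; leading and trailing sparse windows of a contig are dropped, so
#' segments tile the covered territory of each contig exactly, with
#' adjacent segments always differing in label. The mosaic methylomes this
#' targets are near-binary, so a thresholded two-state method with exact
#' oracles is preferred over an HMM; an HMM remains a natural extension
#' point.
#'
#' @param track a [methylation_track()].
#' @param window window (and step) size in bp; windows tile each contig.
#' @param t_hyper threshold on the window mean (default 0.5).
#' @param min_sites_per_window minimum covered sites for a window to carry
#'   its own label (default 3).
#' @param context methylation context (default `"CG"`).
#' @param seqlengths optional named contig lengths; the final window of a
#'   contig is truncated there (short end windows are kept).
#' @return a sorted `GRanges` with metadata `label` (`hyper`/`hypo`),
#'   `mean_fraction` (mean of site fractions within the segment) and
#'   `n_sites`. Empty track gives an empty segmentation.
#' @export
segment_domains <- function(track, window = 1000L, t_hyper = 0.5,
                            min_sites_per_window = 3L, context = "CG",
                            seqlengths = NULL) {
  if (window <= 0) stop("window must be > 0")
  sites <- covered_sites(track, context = context)
  if (!nrow(sites)) return(GRanges())
  out <- vector("list", 0L)
  for (ctg in sort(unique(sites$contig))) {
    s <- sites[contig == ctg]
    clen <- if (!is.null(seqlengths) && ctg %in% names(seqlengths))
      as.integer(seqlengths[[ctg]]) else NA_integer_
    n_win <- if (is.na(clen)) (max(s$pos) - 1L) %/% window + 1L
      else (clen - 1L) %/% window + 1L
    widx <- (s$pos - 1L) %/% window + 1L
    agg <- s[, .(m = mean(fraction), n = .N), by = .(w = widx)]
    mean_w <- rep(NA_real_, n_win); n_w <- integer(n_win)
    mean_w[agg$w] <- agg$m; n_w[agg$w] <- agg$n
    lab <- ifelse(n_w < min_sites_per_window, NA_character_,
                  ifelse(mean_w >= t_hyper, "hyper", "hypo"))
    informative <- which(!is.na(lab))
    if (!length(informative)) next
    first <- informative[1L]; last <- informative[length(informative)]
    lab <- lab[first:last]
    # interior sparse windows carry the previous label
    for (i in which(is.na(lab))) lab[i] <- lab[i - 1L]
    r <- rle(lab)
    seg_end_w <- cumsum(r$lengths)
    seg_start_w <- c(1L, head(seg_end_w, -1L) + 1L)
    g_start <- (first - 1L + seg_start_w - 1L) * window + 1L
    g_end <- (first - 1L + seg_end_w) * window
    if (!is.na(clen)) g_end <- pmin(g_end, clen)
    seg <- GRanges(ctg, IRanges(g_start, g_end), label = r$values)
    seg_of_site <- findInterval(s$pos, g_start)
    inside <- seg_of_site >= 1L & s$pos <= g_end[pmax(1L, seg_of_site)]
    stat <- data.table(seg = seg_of_site[inside],
                       fraction = s$fraction[inside])[
      , .(m = mean(fraction), n = .N), by = seg]
    mcols(seg)$mean_fraction <- NA_real_
    mcols(seg)$n_sites <- 0L
    mcols(seg)$mean_fraction[stat$seg] <- stat$m
    mcols(seg)$n_sites[stat$seg] <- stat$n
    out[[length(out) + 1L]] <- seg
  }
  if (!length(out)) return(GRanges())
  res <- suppressWarnings(do.call(c, out))
  sort(res, ignore.strand = TRUE)
}

#' Annotate segments with repeat overlap and gene content
#'
#' Adds to each segment the fraction of its bases covered by repeat
#' annotation and the number of genes whose midpoint falls inside it.
#'
#' @param segments `GRanges` from [segment_domains()].
#' @param repeats `GRanges` of repeat intervals (see [read_repeat_bed()]).
#' @param models optional [gene_model_set()] for gene counts.
#' @return `segments` with `repeat_overlap_fraction` and (when `models`
#'   given) `n_genes_contained` metadata columns appended.
#' @export
annotate_segments <- function(segments, repeats, models = NULL) {
  stopifnot(is(segments, "GRanges"))
  if (length(segments) == 0L) return(segments)
  red <- reduce(granges(repeats), ignore.strand = TRUE)
  cov_bases <- numeric(length(segments))
  if (length(red)) {
    hits <- findOverlaps(segments, red, ignore.strand = TRUE)
    if (length(hits)) {
      ov <- pintersect(segments[queryHits(hits)], red[subjectHits(hits)],
                       ignore.strand = TRUE)
      per <- tapply(width(ov), queryHits(hits), sum)
      cov_bases[as.integer(names(per))] <- per
    }
  }
  mcols(segments)$repeat_overlap_fraction <- cov_bases / width(segments)
  if (!is.null(models)) {
    g <- models$genes
    mid <- GRanges(seqnames(g),
                   IRanges(floor((start(g) + end(g)) / 2),
                           floor((start(g) + end(g)) / 2)))
    mcols(segments)$n_genes_contained <-
      countOverlaps(segments, mid, ignore.strand = TRUE)
  }
  segments
}
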