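#' Classify a cytosine trinucleotide into its methylation context
#'
#' The context of a cytosine is determined by the two bases that follow it on
#' the same strand: `CG` when the next base is G, `CHG` when the base after
#' next is G (and the next is not), and `CHH` otherwise, with H meaning A, C
#' or T. Trinucleotides that do not start with C, are not 3 bases long, or
#' contain characters outside A/C/G/T yield `NA`.
#'
#' @param trinucleotide character vector of 3-mers read 5' to 3' on the
#'   cytosine's strand.
#' @return character vector with values `"CG"`, `"CHG"`, `"CHH"` or `NA`.
#' @export
#' @examples
#' classify_context(c("CGA", "CAG", "CTA", "AGG"))
classify_context <- function(trinucleotide) {
  tri <- toupper(as.character(trinucleotide))
  out <- rep(NA_character_, length(tri))
  ok <- !is.na(tri) & nchar(tri) == 3L & !grepl("[^ACGT]", tri) &
    substr(tri, 1L, 1L) == "C"
  b2 <- substr(tri, 2L, 2L)
  b3 <- substr(tri, 3L, 3L)
  out[ok & b2 == "G"] <- "CG"
  out[ok & b2 != "G" & b3 == "G"] <- "CHG"
  out[ok & b2 != "G" & b3 != "G"] <- "CHH"
  out
}

.cx_cols <- c("contig", "pos", "strand", "count_meth", "count_unmeth",
              "context", "trinucleotide")

#' Read a per-cytosine bisulfite report
#'
#' Reads a Bismark-style cytosine ("CX") report: a headerless tab-delimited
#' file with one row per cytosine and seven columns — contig, 1-based
#' position, strand (`+`/`-`), methylated read count, unmethylated read
#' count, context (`CG`/`CHG`/`CHH`) and trinucleotide. Rows with zero
#' coverage are retained; coverage filtering happens downstream (see
#' [methylation_track()]).
#'
#' @param path path to the report.
#' @return a `data.table` with columns `contig`, `pos`, `strand`,
#'   `count_meth`, `count_unmeth`, `context`, `trinucleotide`, in file order.
#' @seealso [write_cytosine_report()], [methylation_track()]
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop("cytosine report not found: ", path)
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t",
          colClasses = list(character = c(1L, 3L, 6L, 7L),
                            integer = c(2L, 4L, 5L))),
    error = function(e) stop("failed to parse cytosine report '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (ncol(dt) != 7L)
    stop("cytosine report '", path, "': expected 7 tab-delimited columns, got ",
         ncol(dt))
  setnames(dt, .cx_cols)
  .validate_cytosine_records(dt, path)
  dt[]
}

.validate_cytosine_records <- function(dt, what = "cytosine records") {
  bad <- function(idx, msg) {
    if (length(idx))
      stop(what, ", line ", idx[1L], ": ", msg, call. = FALSE)
  }
  bad(which(!dt$strand %in% c("+", "-")), "strand must be '+' or '-'")
  bad(which(is.na(dt$pos) | dt$pos < 1L), "position must be a 1-based integer")
  bad(which(is.na(dt$count_meth) | dt$count_meth < 0L |
            is.na(dt$count_unmeth) | dt$count_unmeth < 0L),
      "read counts must be non-negative integers")
  bad(which(!dt$context %in% c("CG", "CHG", "CHH")),
      "unknown context token (expected CG, CHG or CHH)")
  expected <- classify_context(dt$trinucleotide)
  bad(which(is.na(expected) | expected != dt$context),
      "context is inconsistent with trinucleotide")
  invisible(dt)
}

#' Write a per-cytosine bisulfite report
#'
#' Inverse of [read_cytosine_report()]: writes the seven-column headerless
#' tab-delimited cytosine report.
#'
#' @param records data.table of cytosine records (as returned by
#'   [read_cytosine_report()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  records <- as.data.table(records)[, .SD, .SDcols = .cx_cols]
  .validate_cytosine_records(records)
  fwrite(records, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene expression table (FPKM)
#'
#' Tab-delimited with a header: first column `gene_id`, remaining columns one
#' per sample, values non-negative FPKM.
#'
#' @param path path to the TSV.
#' @return a `data.table` with `gene_id`, the per-sample columns, plus derived
#'   `sum_fpkm` and `mean_fpkm` across samples.
#' @export
read_fpkm_table <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  setnames(dt, 1L, "gene_id")
  dt[, gene_id := as.character(gene_id)]
  if (anyDuplicated(dt$gene_id))
    stop("duplicate gene ids in FPKM table: ",
         paste(head(unique(dt$gene_id[duplicated(dt$gene_id)]), 3L),
               collapse = ", "))
  samples <- setdiff(names(dt), "gene_id")
  if (!length(samples)) stop("FPKM table has no sample columns")
  vals <- as.matrix(dt[, samples, with = FALSE])
  if (!is.numeric(vals) || anyNA(vals) || any(vals < 0))
    stop("FPKM values must be non-negative numbers")
  dt[, sum_fpkm := rowSums(vals)]
  dt[, mean_fpkm := rowMeans(vals)]
  dt[]
}

#' Read a gene-to-taxonomic-group assignment table
#'
#' Tab-delimited with a header and columns `gene_id` and `group` (further
#' columns are kept but unused), one row per gene, in the style of a
#' DarkHorse-derived top-hit taxonomy summary.
#'
#' @param path path to the TSV.
#' @return `data.table` with character columns `gene_id` and `group`.
#' @export
read_taxonomy_table <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  if (!all(c("gene_id", "group") %in% names(dt)))
    stop("taxonomy table must have columns 'gene_id' and 'group'")
  dt[, gene_id := as.character(gene_id)]
  dt[, group := as.character(group)]
  if (anyDuplicated(dt$gene_id))
    stop("taxonomy table assigns some gene more than one group")
  dt[]
}

#' Read an ortholog pair table
#'
#' Tab-delimited with a header and columns `gene_a` and `gene_b`, one ortholog
#' pair per row (species A gene, species B gene).
#'
#' @param path path to the TSV.
#' @return `data.table` with character columns `gene_a`, `gene_b`.
#' @export
read_ortholog_pairs <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  if (!all(c("gene_a", "gene_b") %in% names(dt)))
    stop("ortholog pair table must have columns 'gene_a' and 'gene_b'")
  dt[, gene_a := as.character(gene_a)]
  dt[, gene_b := as.character(gene_b)]
  dt[]
}

#' Read repeat annotations from a BED file
#'
#' Thin wrapper over [rtracklayer::import.bed()]; BED's 0-based half-open
#' coordinates are converted to the 1-based closed convention of `GRanges`.
#'
#' @param path path to the BED file (>= 3 columns).
#' @return a `GRanges` of repeat intervals.
#' @export
read_repeat_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!length(gr)) return(gr)
  unname(gr)
}

#' Write genomic segments to BED
#'
#' Writes a `GRanges` to BED via [rtracklayer::export.bed()]. If a `label`
#' metadata column is present it becomes the BED name field; a
#' `mean_fraction` column becomes the score (scaled to 0-1000).
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(gr, path) {
  out <- granges(gr)
  if (!is.null(mcols(gr)$label)) names(out) <- as.character(mcols(gr)$label)
  if (!is.null(mcols(gr)$mean_fraction))
    mcols(out)$score <- round(pmin(pmax(mcols(gr)$mean_fraction, 0), 1) * 1000)
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Write per-site methylation fractions as bedGraph
#'
#' Emits one bedGraph interval per covered cytosine with its methylation
#' fraction as the value.
#'
#' @param track a [methylation_track()].
#' @param path output path.
#' @param context context to export (default `"CG"`).
#' @return `path`, invisibly.
#' @export
write_fraction_bedgraph <- function(track, path, context = "CG") {
  sites <- covered_sites(track, context = context)
  gr <- GRanges(sites$contig, IRanges(sites$pos, sites$pos),
                score = sites$fraction)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
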