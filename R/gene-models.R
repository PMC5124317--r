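#' Construct a set of gene models
#'
#' A `gene_model_set` bundles gene spans with their exon and CDS structure.
#' Genes are held as a `GRanges` (one range per gene, with `gene_id` and
#' `source` metadata); exons and CDS are `GRangesList`s named by `gene_id`.
#' Multi-transcript genes are represented by the union of their exons (and
#' union of CDS), since all statistics here are per gene, not per isoform.
#' Introns are derived as the gaps between consecutive exons.
#'
#' @param genes `GRanges` with one range per gene and a `gene_id` metadata
#'   column (or names).
#' @param exons `GRangesList` named by `gene_id`; each element sorted,
#'   non-overlapping, within the gene span, on the gene's contig and strand.
#'   If `NULL`, each gene becomes a single-exon gene over its whole span.
#' @param cds `GRangesList` of coding intervals, same conventions; defaults
#'   to `exons`.
#' @param source predictor label for the set (recycled to one per set).
#' @return an object of class `gene_model_set`.
#' @export
gene_model_set <- function(genes, exons = NULL, cds = NULL,
                           source = "predictorA") {
  if (!is(genes, "GRanges")) stop("'genes' must be a GRanges")
  ids <- mcols(genes)$gene_id %||% names(genes)
  if (is.null(ids)) stop("'genes' needs a gene_id column or names")
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("duplicate gene_id: ", ids[duplicated(ids)][1L])
  mcols(genes)$gene_id <- ids
  names(genes) <- ids
  if (is.null(exons)) {
    exons <- methods::as(granges(genes), "GRangesList")
    names(exons) <- ids
  }
  if (is.null(cds)) cds <- exons
  exons <- .align_parts(exons, ids, "exons")
  cds <- .align_parts(cds, ids, "cds")
  .check_parts(genes, exons, "exon")
  .check_parts(genes, cds, "CDS")
  structure(list(genes = genes, exons = exons, cds = cds,
                 source = as.character(source)[1L]),
            class = "gene_model_set")
}

.align_parts <- function(parts, ids, what) {
  if (!is(parts, "GRangesList")) stop("'", what, "' must be a GRangesList")
  if (is.null(names(parts))) stop("'", what, "' must be named by gene_id")
  missing <- setdiff(ids, names(parts))
  if (length(missing)) {
    filler <- methods::as(GRangesList(lapply(missing, function(x) GRanges())),
                          "CompressedGRangesList")
    names(filler) <- missing
    parts <- c(parts, filler)
  }
  parts[ids]
}

.check_parts <- function(genes, parts, what) {
  n <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  owner <- rep(seq_along(genes), n)
  if (!length(flat)) return(invisible())
  bad <- which(as.character(seqnames(flat)) !=
                 as.character(seqnames(genes))[owner] |
               start(flat) < start(genes)[owner] |
               end(flat) > end(genes)[owner])
  if (length(bad))
    stop(what, " outside its gene span for gene ",
         mcols(genes)$gene_id[owner[bad[1L]]])
  # within-gene overlap check, vectorised over the flattened ranges:
  # consecutive ranges of the same gene must be sorted and non-overlapping
  ord <- order(owner, start(flat), end(flat))
  same <- owner[ord][-1L] == owner[ord][-length(ord)]
  clash <- which(same & start(flat)[ord][-1L] <= end(flat)[ord][-length(ord)])
  if (length(clash))
    stop("overlapping ", what, "s within gene ",
         mcols(genes)$gene_id[owner[ord][clash[1L] + 1L]])
  invisible()
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", length(x$genes), "genes from", x$source,
      "| mean exons/gene:",
      round(mean(lengths(x$exons)), 2), "\n")
  invisible(x)
}

#' @export
length.gene_model_set <- function(x) length(x$genes)

#' Subset a gene model set by gene id
#'
#' @param models a [gene_model_set()].
#' @param gene_ids character vector of ids to keep (order preserved).
#' @return a new `gene_model_set`.
#' @export
subset_models <- function(models, gene_ids) {
  stopifnot(is(models, "gene_model_set"))
  gene_ids <- as.character(gene_ids)
  missing <- setdiff(gene_ids, mcols(models$genes)$gene_id)
  if (length(missing)) stop("unknown gene_id: ", missing[1L])
  gene_model_set(models$genes[gene_ids], models$exons[gene_ids],
                 models$cds[gene_ids], source = models$source)
}

#' Derive introns for each gene
#'
#' Introns are the gaps between consecutive exons within each gene's exon
#' span; a gene with k exons has k - 1 introns.
#'
#' @param models a [gene_model_set()].
#' @return a `GRangesList` of introns, named by gene_id.
#' @export
introns <- function(models) {
  stopifnot(is(models, "gene_model_set"))
  spans <- unlist(range(models$exons), use.names = FALSE)
  out <- psetdiff(spans, models$exons)
  names(out) <- names(models$exons)
  out
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features linked by ID/Parent attributes into a
#' [gene_model_set()]. Exons of all transcripts of a gene are collapsed to
#' their union (likewise CDS). GFF3's 1-based inclusive coordinates carry
#' straight into the `GRanges` convention. A feature whose `Parent` cannot be
#' resolved to a gene is an error naming the orphan.
#'
#' @param path path to the GFF3 file.
#' @param source predictor label to attach; defaults to the file's source
#'   column when uniform, else the file name.
#' @return a [gene_model_set()].
#' @export
read_gff3_genes <- function(path, source = NULL) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(mcols(gff)$type)
  ids <- as.character(mcols(gff)$ID)
  genes <- gff[type == "gene"]
  gene_ids <- as.character(mcols(genes)$ID)
  if (!length(genes)) stop("no gene features in ", path)
  if (anyNA(gene_ids)) stop("gene feature without ID in ", path)

  first_parent <- function(gr) {
    p <- mcols(gr)$Parent
    vapply(as.list(p), function(x) if (length(x)) x[[1L]] else NA_character_,
           character(1L))
  }
  tx <- gff[type %in% c("mRNA", "transcript")]
  tx_ids <- as.character(mcols(tx)$ID)
  tx_parent <- first_parent(tx)
  orphan_tx <- which(is.na(tx_parent) | !tx_parent %in% gene_ids)
  if (length(orphan_tx))
    stop("orphan feature '", tx_ids[orphan_tx[1L]],
         "': Parent not found among genes")
  tx2gene <- setNames(tx_parent, tx_ids)

  resolve_gene <- function(parts, what) {
    parent <- first_parent(parts)
    gene <- ifelse(parent %in% names(tx2gene), tx2gene[parent],
                   ifelse(parent %in% gene_ids, parent, NA_character_))
    orphan <- which(is.na(gene))
    if (length(orphan)) {
      id <- as.character(mcols(parts)$ID)[orphan[1L]]
      stop("orphan ", what, " feature '",
           if (is.na(id)) paste0("at ", seqnames(parts)[orphan[1L]], ":",
                                 start(parts)[orphan[1L]]) else id,
           "': Parent '", parent[orphan[1L]], "' not found")
    }
    unname(gene)
  }

  collate <- function(parts, what) {
    if (!length(parts))
      return(setNames(methods::as(GRangesList(), "CompressedGRangesList"),
                      character()))
    gene <- resolve_gene(parts, what)
    gl <- methods::as(
      S4Vectors::split(granges(parts), factor(gene, levels = unique(gene))),
      "CompressedGRangesList")
    reduce(sort(gl))
  }

  exons <- collate(gff[type == "exon"], "exon")
  cds <- collate(gff[type == "CDS"], "CDS")
  if (is.null(source)) {
    src <- unique(as.character(mcols(genes)$source))
    source <- if (length(src) == 1L && !is.na(src)) src else basename(path)
  }
  out_genes <- granges(genes)
  mcols(out_genes)$gene_id <- gene_ids
  have_exons <- gene_ids %in% names(exons)
  if (!all(have_exons)) {
    # genes annotated without exon rows become single-exon genes
    solo <- methods::as(granges(out_genes[!have_exons]), "GRangesList")
    names(solo) <- gene_ids[!have_exons]
    exons <- c(exons, methods::as(solo, "CompressedGRangesList"))
  }
  cds_missing <- setdiff(gene_ids, names(cds))
  if (length(cds_missing)) cds <- c(cds, exons[cds_missing])
  gene_model_set(out_genes, exons[gene_ids], cds[gene_ids], source = source)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3_genes()]: emits gene, mRNA (one per gene), exon and
#' CDS features with ID/Parent linkage.
#'
#' @param models a [gene_model_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(models, path) {
  stopifnot(is(models, "gene_model_set"))
  g <- models$genes
  ids <- mcols(g)$gene_id
  tx_ids <- paste0(ids, ".t1")

  row <- function(gr, type, id, parent) {
    gr <- granges(gr)
    mcols(gr)$source <- models$source
    mcols(gr)$type <- type
    mcols(gr)$ID <- id
    mcols(gr)$Parent <- CharacterList(lapply(parent, function(p)
      if (is.na(p)) character(0) else p))
    gr
  }
  ex_flat <- unlist(models$exons, use.names = FALSE)
  ex_parent <- rep(tx_ids, lengths(models$exons))
  cds_flat <- unlist(models$cds, use.names = FALSE)
  cds_parent <- rep(tx_ids, lengths(models$cds))
  out <- c(
    row(g, "gene", ids, rep(NA_character_, length(ids))),
    row(g, "mRNA", tx_ids, ids),
    row(ex_flat, "exon", rep(NA_character_, length(ex_flat)), ex_parent),
    row(cds_flat, "CDS", rep(NA_character_, length(cds_flat)), cds_parent)
  )
  out <- out[order(as.character(seqnames(out)), start(out),
                   match(mcols(out)$type, c("gene", "mRNA", "exon", "CDS")))]
  suppressWarnings(rtracklayer::export(out, path, format = "gff3"))
  invisible(path)
}
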