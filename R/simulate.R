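#' Simulate a complete synthetic methylome dataset
#'
#' Generates, under a seeded [sim_profile()], every input the analysis
#' pipeline consumes: a genome FASTA, alternating hyper-/hypomethylated
#' domain truth (BED), repeat annotations placed inside hyperdomains (BED),
#' two predictor gene sets (GFF3), per-cytosine bisulfite reports for each
#' condition (Bismark-style CX dialect), a per-sample FPKM table, a taxonomy
#' table, and a gene truth table, plus a JSON manifest tying them together.
#'
#' The generative model: each contig is tiled by alternating hyper/hypo
#' domains with clamped-exponential lengths; each hyperdomain carries one
#' repeat block covering a fixed fraction of its bases; unmethylated genes
#' are placed non-overlapping inside hypodomains (covering
#' `genic_fraction_within_hypo` of their bases) and methylated genes inside
#' hyperdomains. Cytosine contexts are read off the generated sequence, so
#' context proportions follow the GC content. Each CpG dinucleotide gets one
#' true level (Beta around its territory's class mean) shared by both strands
#' and by all conditions; CHG/CHH sites get independent low levels. Read
#' counts are binomial at Poisson coverage, drawn independently per
#' condition from the shared truth. Identical profiles (including seed)
#' produce byte-identical output files.
#'
#' @param profile a [sim_profile()].
#' @param out_dir output directory (created if needed).
#' @param write_site_truth if `TRUE`, also write `site_truth.tsv` with the
#'   latent per-site methylation level (large; intended for tests).
#' @return the manifest, invisibly: a list with `seed`, `paths`, `profile`
#'   and `realized` (realized repeat/hyperdomain fractions, gene counts,
#'   genome length).
#' @seealso [expected_summaries()] for the closed-form expectations the
#'   realized data converge to.
#' @export
simulate_methylome <- function(profile, out_dir, write_site_truth = FALSE) {
  validate_profile(profile)
  p <- profile
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(p$seed)

  contigs <- sprintf("ctg%02d", seq_len(p$n_contigs))
  clen <- rep(as.integer(p$contig_length), p$n_contigs)
  names(clen) <- contigs

  domains <- .sim_domains(p, contigs, clen)
  repeats <- .sim_repeats(p, domains)
  genes <- .sim_genes(p, domains, clen)
  structure_dt <- .sim_gene_structure(p, genes)
  decoys <- .sim_decoys(p, genes, contigs, clen)
  models_a <- .assemble_models(rbind(genes[, .(gene_id, contig, start, end,
                                               strand)],
                                     decoys),
                               structure_dt, source = "predictorA")
  models_b <- .sim_predictor_b(p, models_a, clen)
  fpkm <- .sim_fpkm(p, genes, decoys)
  taxonomy <- .sim_taxonomy(p, genes, decoys)

  reports <- vector("list", p$n_conditions)
  truth_rows <- vector("list", p$n_contigs)
  seqs <- character(p$n_contigs)
  for (ci in seq_len(p$n_contigs)) {
    ctg <- contigs[ci]
    sim <- .sim_contig_sites(p, ctg, clen[ci], domains[contig == ctg],
                             genes[contig == ctg])
    seqs[ci] <- sim$seq
    for (k in seq_len(p$n_conditions))
      reports[[k]][[ci]] <- sim$conditions[[k]]
    if (write_site_truth) truth_rows[[ci]] <- sim$truth
  }
  names(seqs) <- contigs

  paths <- list(
    genome_fasta = file.path(out_dir, "genome.fa"),
    cx_reports = file.path(out_dir,
                           sprintf("methylome_condition%d.cx.txt",
                                   seq_len(p$n_conditions))),
    genes_predictor_a = file.path(out_dir, "genes_predictorA.gff3"),
    genes_predictor_b = file.path(out_dir, "genes_predictorB.gff3"),
    repeats_bed = file.path(out_dir, "repeats.bed"),
    domains_bed = file.path(out_dir, "domains_truth.bed"),
    fpkm_tsv = file.path(out_dir, "fpkm.tsv"),
    taxonomy_tsv = file.path(out_dir, "taxonomy.tsv"),
    gene_truth_tsv = file.path(out_dir, "gene_truth.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )

  writeXStringSet(DNAStringSet(seqs), paths$genome_fasta)
  for (k in seq_len(p$n_conditions))
    write_cytosine_report(rbindlist(reports[[k]]), paths$cx_reports[k])
  write_gff3_genes(models_a, paths$genes_predictor_a)
  write_gff3_genes(models_b, paths$genes_predictor_b)
  .write_bed(repeats, paths$repeats_bed, clen)
  .write_bed(domains, paths$domains_bed, clen, name_col = "label")
  fwrite(fpkm, paths$fpkm_tsv, sep = "\t")
  fwrite(taxonomy, paths$taxonomy_tsv, sep = "\t")
  fwrite(genes[, .(gene_id, contig, start, end, strand,
                   status = ifelse(methylated, "methylated", "unmethylated"))],
         paths$gene_truth_tsv, sep = "\t")
  if (write_site_truth) {
    paths$site_truth_tsv <- file.path(out_dir, "site_truth.tsv")
    fwrite(rbindlist(truth_rows), paths$site_truth_tsv, sep = "\t")
  }

  genome_bp <- sum(as.numeric(clen))
  manifest <- list(
    seed = p$seed,
    paths = lapply(paths, normalizePath, mustWork = FALSE),
    profile = .profile_as_list(p),
    realized = list(
      genome_length = genome_bp,
      n_contigs = p$n_contigs,
      hyper_fraction = domains[label == "hyper",
                               sum(as.numeric(end - start + 1))] / genome_bp,
      repeat_fraction = repeats[, sum(as.numeric(end - start + 1))] / genome_bp,
      n_genes = nrow(genes),
      n_methylated_true = genes[, sum(methylated)],
      n_decoys = nrow(decoys),
      n_predictor_b = length(models_b)
    )
  )
  write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
             pretty = TRUE)
  invisible(manifest)
}

.profile_as_list <- function(p) {
  out <- unclass(p)
  out$taxonomy_groups <- as.data.frame(out$taxonomy_groups)
  out
}

# integer allocation of n among weights, largest-remainder method
.largest_remainder <- function(n, weights) {
  if (n == 0L || !length(weights)) return(integer(length(weights)))
  raw <- n * weights / sum(weights)
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    idx <- order(raw - k, decreasing = TRUE)[seq_len(left)]
    k[idx] <- k[idx] + 1
  }
  as.integer(k)
}

.rclamped_exp <- function(n, mean, lo, hi) {
  pmin(pmax(stats::rexp(n, 1 / mean), lo), hi)
}

# Alternating hyper/hypo domains. Lengths are drawn from the profile's
# clamped-exponential family and then rescaled per class within each contig
# so the realized hyper base fraction equals hyper_domain_fraction exactly
# (up to 1-bp rounding): the domain process is conditioned on its own target
# so Monte-Carlo summaries stay centred on the closed-form expectations at
# any genome size.
.sim_domains <- function(p, contigs, clen) {
  h <- p$hyper_domain_fraction
  out <- vector("list", length(contigs))
  for (ci in seq_along(contigs)) {
    L <- clen[ci]
    if (h <= 0 || h >= 1) {
      out[[ci]] <- data.table(contig = contigs[ci], start = 1L, end = L,
                              label = if (h >= 1) "hyper" else "hypo")
      next
    }
    m_hypo <- .hypo_length_mean(p)
    labels <- character(0); lens <- numeric(0)
    is_hyper <- runif(1) < h
    while (sum(lens) < L || length(unique(labels)) < 2L) {
      m <- if (is_hyper) p$domain_length_mean else m_hypo
      lens <- c(lens, .rclamped_exp(1, m, p$domain_length_min,
                                    p$domain_length_max))
      labels <- c(labels, if (is_hyper) "hyper" else "hypo")
      is_hyper <- !is_hyper
    }
    hy <- labels == "hyper"
    target_h <- round(h * L)
    lens[hy] <- lens[hy] * target_h / sum(lens[hy])
    lens[!hy] <- lens[!hy] * (L - target_h) / sum(lens[!hy])
    bounds <- round(cumsum(lens))
    bounds[length(bounds)] <- L
    bounds <- cummax(pmax(bounds, seq_along(bounds)))   # monotone, >= 1 bp
    starts <- c(1L, head(bounds, -1L) + 1L)
    keep <- bounds >= starts
    out[[ci]] <- data.table(contig = contigs[ci],
                            start = as.integer(starts[keep]),
                            end = as.integer(bounds[keep]),
                            label = labels[keep])
  }
  rbindlist(out)
}

.sim_repeats <- function(p, domains) {
  hyper <- domains[label == "hyper"]
  rc <- p$repeat_coverage_within_hyper
  if (!nrow(hyper) || rc <= 0)
    return(data.table(contig = character(), start = integer(),
                      end = integer()))
  len <- hyper$end - hyper$start + 1L
  rep_len <- pmin(len, pmax(1L, as.integer(round(rc * len))))
  offset <- floor(runif(nrow(hyper)) * (len - rep_len + 1L))
  data.table(contig = hyper$contig,
             start = as.integer(hyper$start + offset),
             end = as.integer(hyper$start + offset + rep_len - 1L))
}

# place n genes of mean length mean_len non-overlapping inside the given
# domains, count per domain by largest remainder on domain length
.place_in_domains <- function(doms, n, mean_len) {
  empty <- data.table(contig = character(), start = integer(),
                      end = integer())
  if (n <= 0L || !nrow(doms)) return(empty)
  dlen <- doms$end - doms$start + 1L
  quota <- .largest_remainder(n, as.numeric(dlen))
  rows <- vector("list", nrow(doms))
  for (d in which(quota > 0L)) {
    k <- quota[d]
    D <- dlen[d]
    lens <- pmax(60L, as.integer(round(runif(k, 0.7, 1.3) * mean_len)))
    if (sum(lens) > 0.95 * D)
      lens <- pmax(60L, as.integer(floor(lens * 0.95 * D / sum(lens))))
    while (k > 0L && sum(lens) > D) {
      k <- k - 1L
      lens <- lens[seq_len(k)]
    }
    if (k == 0L) next
    free <- D - sum(lens)
    gaps <- stats::rexp(k + 1L)
    gaps <- floor(free * cumsum(gaps) / sum(gaps))
    starts <- doms$start[d] + gaps[seq_len(k)] + cumsum(c(0L, lens))[seq_len(k)]
    rows[[d]] <- data.table(contig = doms$contig[d],
                            start = as.integer(starts),
                            end = as.integer(starts + lens - 1L))
  }
  out <- rbindlist(rows)
  if (!nrow(out)) empty else out
}

.sim_genes <- function(p, domains, clen) {
  n <- as.integer(p$n_genes)
  empty <- data.table(gene_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), methylated = logical())
  if (n == 0L) return(empty)
  h <- p$hyper_domain_fraction
  methylated <- if (h <= 0) rep(FALSE, n) else
    runif(n) < p$p_methylated_gene
  hypo <- domains[label == "hypo"]
  hyper <- domains[label == "hyper"]
  hypo_bases <- if (nrow(hypo)) sum(as.numeric(hypo$end - hypo$start + 1L)) else 0
  n_unmeth <- sum(!methylated)
  mean_len <- if (hypo_bases > 0 && n_unmeth > 0)
    p$genic_fraction_within_hypo * hypo_bases / n_unmeth else 300
  mean_len <- max(80, mean_len)

  placed_u <- .place_in_domains(hypo, n_unmeth, mean_len)
  placed_m <- .place_in_domains(hyper, sum(methylated), mean_len)
  placed_u[, methylated := FALSE]
  placed_m[, methylated := TRUE]
  genes <- rbind(placed_u, placed_m)
  if (!nrow(genes)) return(empty)
  setorder(genes, contig, start)
  genes[, gene_id := sprintf("g%05d", .I)]
  genes[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  genes[, .(gene_id, contig, start, end, strand, methylated)]
}

# exon/CDS structure: 1-3 exons per gene separated by short introns
.sim_gene_structure <- function(p, genes) {
  if (!nrow(genes))
    return(data.table(gene_id = character(), exon_start = integer(),
                      exon_end = integer()))
  intron_len <- 30L
  min_exon <- 30L
  rows <- vector("list", nrow(genes))
  n_ex_all <- sample(1:3, nrow(genes), replace = TRUE,
                     prob = c(0.3, 0.4, 0.3))
  for (i in seq_len(nrow(genes))) {
    L <- genes$end[i] - genes$start[i] + 1L
    n_ex <- n_ex_all[i]
    while (n_ex > 1L && L < n_ex * min_exon + (n_ex - 1L) * intron_len)
      n_ex <- n_ex - 1L
    coding <- L - (n_ex - 1L) * intron_len
    w <- stats::rexp(n_ex) + 0.25
    ex_len <- pmax(min_exon, floor(coding * w / sum(w)))
    ex_len[n_ex] <- coding - sum(ex_len[-n_ex])
    if (ex_len[n_ex] < min_exon) {          # rebalance into the last exon
      need <- min_exon - ex_len[n_ex]
      ex_len[which.max(ex_len)] <- ex_len[which.max(ex_len)] - need
      ex_len[n_ex] <- min_exon
    }
    st <- genes$start[i] + cumsum(c(0L, head(ex_len, -1L) + intron_len))
    rows[[i]] <- data.table(gene_id = genes$gene_id[i],
                            exon_start = as.integer(st),
                            exon_end = as.integer(st + ex_len - 1L))
  }
  rbindlist(rows)
}

.sim_decoys <- function(p, genes, contigs, clen) {
  zf <- p$zero_fpkm_fraction
  n_dec <- if (zf > 0 && zf < 1) as.integer(round(nrow(genes) * zf / (1 - zf)))
    else 0L
  if (n_dec == 0L)
    return(data.table(gene_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  len <- pmax(60L, as.integer(round(runif(n_dec, 0.3, 0.7) * 300)))
  ctg_i <- sample(seq_along(contigs), n_dec, replace = TRUE,
                  prob = as.numeric(clen))
  start <- as.integer(floor(runif(n_dec) * (clen[ctg_i] - len)) + 1L)
  data.table(gene_id = sprintf("decoy%04d", seq_len(n_dec)),
             contig = contigs[ctg_i], start = start,
             end = as.integer(start + len - 1L),
             strand = sample(c("+", "-"), n_dec, replace = TRUE))
}

.assemble_models <- function(span_dt, structure_dt, source) {
  gr <- GRanges(span_dt$contig,
                IRanges(span_dt$start, span_dt$end),
                strand = span_dt$strand)
  mcols(gr)$gene_id <- span_dt$gene_id
  ex <- structure_dt[gene_id %in% span_dt$gene_id]
  if (nrow(ex)) {
    strand_of <- setNames(span_dt$strand, span_dt$gene_id)
    ctg_of <- setNames(span_dt$contig, span_dt$gene_id)
    ex_gr <- GRanges(ctg_of[ex$gene_id],
                     IRanges(ex$exon_start, ex$exon_end),
                     strand = strand_of[ex$gene_id])
    exl <- methods::as(S4Vectors::split(
      ex_gr, factor(ex$gene_id, levels = span_dt$gene_id)),
      "CompressedGRangesList")
  } else exl <- NULL
  gene_model_set(gr, exons = exl, source = source)
}

.sim_predictor_b <- function(p, models_a, clen) {
  g <- models_a$genes
  keep <- which(runif(length(g)) >= p$predictor_b_dropout)
  g <- g[keep]
  j <- as.integer(p$boundary_jitter_bp)
  ids <- mcols(g)$gene_id
  if (length(g) && j > 0) {
    ds <- sample(seq(-j, j), length(g), replace = TRUE)
    de <- sample(seq(-j, j), length(g), replace = TRUE)
    ns <- pmax(1L, start(g) + ds)
    ne <- pmin(clen[as.character(seqnames(g))], end(g) + de)
    ne <- pmax(ne, ns + 29L)
    g <- GRanges(seqnames(g), IRanges(ns, ne), strand = strand(g))
  } else g <- granges(g)
  mcols(g)$gene_id <- paste0("B_", ids)
  gene_model_set(g, source = "predictorB")
}

.sim_fpkm <- function(p, genes, decoys) {
  n <- nrow(genes)
  base <- numeric(n)
  if (n) {
    meth <- genes$methylated
    fm <- p$fpkm_meth
    comp <- sample(seq_along(fm$weights), sum(meth), replace = TRUE,
                   prob = fm$weights)
    base[meth] <- stats::rlnorm(sum(meth), fm$meanlog[comp], fm$sdlog[comp])
    base[!meth] <- stats::rlnorm(sum(!meth), p$fpkm_unmeth$meanlog,
                                 p$fpkm_unmeth$sdlog)
  }
  ns <- as.integer(p$n_samples)
  sdl <- p$sample_noise_sdlog
  noise <- matrix(exp(rnorm(n * ns, -sdl^2 / 2, sdl)), nrow = n)
  vals <- base * noise
  out <- data.table(gene_id = c(genes$gene_id, decoys$gene_id))
  for (s in seq_len(ns))
    out[, (sprintf("sample%d", s)) := c(vals[, s], rep(0, nrow(decoys)))]
  out
}

.sim_taxonomy <- function(p, genes, decoys) {
  tg <- p$taxonomy_groups
  assign_cond <- function(n, weights) {
    if (n == 0L) return(character(0))
    sample(tg$group, n, replace = TRUE, prob = weights / sum(weights))
  }
  meth <- genes$methylated
  grp <- character(nrow(genes))
  grp[meth] <- assign_cond(sum(meth), tg$weight * tg$propensity)
  grp[!meth] <- assign_cond(sum(!meth), tg$weight * (1 - tg$propensity))
  data.table(gene_id = c(genes$gene_id, decoys$gene_id),
             group = c(grp, assign_cond(nrow(decoys), tg$weight)))
}

.write_bed <- function(dt, path, clen, name_col = NULL) {
  if (!nrow(dt)) {
    gr <- GRanges()
  } else {
    gr <- GRanges(dt$contig, IRanges(dt$start, dt$end))
    if (!is.null(name_col)) names(gr) <- dt[[name_col]]
  }
  seqlevels(gr) <- names(clen)
  seqlengths(gr) <- clen
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# one contig's sequence, cytosine sites, shared truth, and per-condition
# count draws
.sim_contig_sites <- function(p, ctg, len, doms, genes_ctg) {
  base_prob <- c(A = (1 - p$gc_content) / 2, C = p$gc_content / 2,
                 G = p$gc_content / 2, T = (1 - p$gc_content) / 2)
  x <- sample(names(base_prob), len, replace = TRUE, prob = base_prob)

  # territory class per position: 1 hyper bg, 2 hypo intergenic,
  # 3 methylated gene body, 4 unmethylated gene body
  cls <- integer(len)
  for (d in seq_len(nrow(doms)))
    cls[doms$start[d]:doms$end[d]] <- if (doms$label[d] == "hyper") 1L else 2L
  if (nrow(genes_ctg))
    for (i in seq_len(nrow(genes_ctg)))
      cls[genes_ctg$start[i]:genes_ctg$end[i]] <-
        if (genes_ctg$methylated[i]) 3L else 4L
  mu_by_class <- c(p$mu_hyper, p$mu_hypo_intergenic, p$mu_meth_gene,
                   p$mu_unmeth_gene)

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ip <- which(x == "C")
  ip <- ip[ip <= len - 2L]
  b2p <- x[ip + 1L]; b3p <- x[ip + 2L]
  ctx_p <- ifelse(b2p == "G", "CG", ifelse(b3p == "G", "CHG", "CHH"))
  tri_p <- paste0("C", b2p, b3p)

  im <- which(x == "G")
  im <- im[im >= 3L]
  b2m <- comp[x[im - 1L]]; b3m <- comp[x[im - 2L]]
  ctx_m <- ifelse(b2m == "G", "CG", ifelse(b3m == "G", "CHG", "CHH"))
  tri_m <- paste0("C", b2m, b3m)

  sites <- data.table(
    pos = c(ip, im),
    strand = rep(c("+", "-"), c(length(ip), length(im))),
    context = c(ctx_p, ctx_m),
    trinucleotide = c(tri_p, tri_m)
  )
  # CpG dinucleotide key: the position of the C on the plus strand; shared
  # level for the two strands of one CpG
  sites[, cpg_key := ifelse(context == "CG",
                            ifelse(strand == "+", pos, pos - 1L), NA_integer_)]
  setorder(sites, pos, strand)

  conc <- p$beta_concentration
  level <- numeric(nrow(sites))
  is_cg <- sites$context == "CG"
  if (any(is_cg)) {
    keys <- sort(unique(sites$cpg_key[is_cg]))
    mu <- mu_by_class[cls[keys]]
    lvl <- rbeta(length(keys), mu * conc, (1 - mu) * conc)
    level[is_cg] <- lvl[match(sites$cpg_key[is_cg], keys)]
  }
  for (cx in c("CHG", "CHH")) {
    idx <- which(sites$context == cx)
    mu <- if (cx == "CHG") p$chg_level else p$chh_level
    if (length(idx)) level[idx] <- rbeta(length(idx), mu * conc,
                                         (1 - mu) * conc)
  }

  conditions <- vector("list", p$n_conditions)
  for (k in seq_len(p$n_conditions)) {
    cov <- rpois(nrow(sites), p$coverage_mean)
    meth <- rbinom(nrow(sites), cov, level)
    conditions[[k]] <- data.table(
      contig = ctg, pos = sites$pos, strand = sites$strand,
      count_meth = meth, count_unmeth = cov - meth,
      context = sites$context, trinucleotide = sites$trinucleotide
    )
  }
  list(
    seq = paste(x, collapse = ""),
    conditions = conditions,
    truth = data.table(contig = ctg, pos = sites$pos, strand = sites$strand,
                       context = sites$context, level = level,
                       class = cls[sites$pos])
  )
}
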