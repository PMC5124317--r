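#' Build a run configuration
#'
#' Collects input paths and per-stage parameters with defaults matching each
#' stage's documented defaults. All randomness in a run (only the
#' permutation test draws any) flows from the single `seed`.
#'
#' @param cx_reports character vector of cytosine report paths, one per
#'   condition (1 or 2 conditions supported downstream).
#' @param genes_a,genes_b GFF3 paths for the two predictors.
#' @param repeats BED path of repeat annotations.
#' @param fpkm FPKM TSV path.
#' @param taxonomy taxonomy TSV path.
#' @param genome genome FASTA path.
#' @param out_dir output directory for stage tables and the JSON summary.
#' @param min_coverage,min_sites,threshold classification parameters (see
#'   [methylation_track()], [classify_genes()]).
#' @param window,t_hyper,min_sites_per_window segmentation parameters (see
#'   [segment_domains()]).
#' @param low_fpkm_max,high_fpkm_min population bounds (see
#'   [partition_populations()]).
#' @param n_permutations permutations for [taxon_enrichment()].
#' @param flank_bp flank width for per-gene region methylation.
#' @param seed root seed.
#' @return a validated `run_config` list.
#' @export
run_config <- function(cx_reports, genes_a, genes_b, repeats, fpkm, taxonomy,
                       genome, out_dir,
                       min_coverage = 5L, min_sites = 5L, threshold = 0.5,
                       window = 1000L, t_hyper = 0.5,
                       min_sites_per_window = 3L,
                       low_fpkm_max = 10, high_fpkm_min = 100,
                       n_permutations = 1000L, flank_bp = 500L, seed = 1L) {
  cfg <- structure(as.list(environment()), class = "run_config")
  inputs <- c(cfg$cx_reports, cfg$genes_a, cfg$genes_b, cfg$repeats,
              cfg$fpkm, cfg$taxonomy, cfg$genome)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("config: missing input file(s): ", paste(missing, collapse = ", "))
  cfg
}

#' Configure a run directly from a simulation manifest
#'
#' @param manifest manifest list returned by [simulate_methylome()] or a
#'   path to its `manifest.json`.
#' @param out_dir output directory.
#' @param ... parameter overrides passed to [run_config()].
#' @return a `run_config`.
#' @export
run_config_from_manifest <- function(manifest, out_dir, ...) {
  if (is.character(manifest)) manifest <- read_json(manifest)
  p <- manifest$paths
  run_config(cx_reports = unlist(p$cx_reports),
             genes_a = p$genes_predictor_a, genes_b = p$genes_predictor_b,
             repeats = p$repeats_bed, fpkm = p$fpkm_tsv,
             taxonomy = p$taxonomy_tsv, genome = p$genome_fasta,
             out_dir = out_dir, ...)
}

#' Run the full methylome analysis
#'
#' Executes every stage against the configured inputs: consensus gene-model
#' selection and genome statistics; per-context global methylation levels
#' per condition; per-gene classification (on the expression-supported
#' predictor-A models, i.e. sum FPKM > 0) with class summaries averaged
#' over conditions; gene-unit and window-unit condition correlation (when
#' two conditions are given); domain segmentation with repeat annotation;
#' expression-population partition; and taxonomic methylation enrichment.
#' Stage tables are written as TSV/BED under `out_dir` and every headline
#' statistic lands in one JSON summary. A rerun with the same inputs and
#' seed is idempotent.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly (also written to
#'   `out_dir/summary.json`).
#' @export
run_methylome_analysis <- function(config) {
  stopifnot(is(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  log_stage <- function(...) message("[methylscape] ", ...)
  tsv <- function(x, name) fwrite(x, file.path(cfg$out_dir, name), sep = "\t")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## --- gene models ---------------------------------------------------
  models_a <- stage("models", read_gff3_genes(cfg$genes_a))
  models_b <- stage("models", read_gff3_genes(cfg$genes_b))
  fpkm <- stage("models", read_fpkm_table(cfg$fpkm))
  hc <- stage("models", high_confidence_models(models_a, models_b, fpkm))
  stats_all <- stage("models", genome_stats(models_a, cfg$genome))
  stats_hc <- stage("models", genome_stats(hc$selected, cfg$genome))
  tsv(hc$table, "high_confidence_selection.tsv")
  tsv(rbind(cbind(set = "predictorA_all", stats_all),
            cbind(set = "high_confidence", stats_hc)), "genome_stats.tsv")
  log_stage("models: ", length(models_a), " predictor-A models, ",
            sum(hc$table$selected), " high confidence")

  # analysis gene set: expression-supported predictor-A models
  supported_ids <- hc$table[sum_fpkm > 0, gene_id]
  models <- subset_models(models_a, supported_ids)
  log_stage("models: ", length(models), " expression-supported models ",
            "enter the methylation analyses")

  ## --- methylation ----------------------------------------------------
  n_cond <- length(cfg$cx_reports)
  tracks <- lapply(cfg$cx_reports, function(path)
    stage("methylation",
          methylation_track(read_cytosine_report(path),
                            min_coverage = cfg$min_coverage)))
  globals <- lapply(seq_len(n_cond), function(k) {
    gl <- stage("methylation", global_level(tracks[[k]]))
    gl[, condition := k]
    gl
  })
  global_tab <- rbindlist(globals)
  tsv(global_tab, "global_levels.tsv")
  cg_levels <- global_tab[context == "CG", mean_of_fractions]
  log_stage("methylation: mean CG level over conditions ",
            round(100 * mean(cg_levels), 1), "%")

  ## --- classify -------------------------------------------------------
  status <- lapply(seq_len(n_cond), function(k)
    stage("classify",
          classify_genes(tracks[[k]], models, min_sites = cfg$min_sites,
                         threshold = cfg$threshold, fpkm = fpkm)))
  summaries <- lapply(status, function(s) stage("classify", class_summary(s)))
  for (k in seq_len(n_cond)) {
    tsv(status[[k]], sprintf("gene_status_condition%d.tsv", k))
    tsv(summaries[[k]], sprintf("class_summary_condition%d.tsv", k))
  }
  prop_meth <- vapply(summaries, function(s)
    s[status == "methylated", proportion], numeric(1))
  log_stage("classify: ", round(100 * mean(prop_meth), 1),
            "% of determined genes methylated (condition mean)")

  ## --- compare conditions ---------------------------------------------
  corr <- NULL
  if (n_cond >= 2L) {
    corr <- stage("compare-conditions", list(
      gene = condition_correlation(tracks[[1L]], tracks[[2L]], models,
                                   unit = "gene",
                                   min_sites = cfg$min_sites),
      window = condition_correlation(tracks[[1L]], tracks[[2L]],
                                     unit = "window", window = cfg$window,
                                     min_sites = cfg$min_sites_per_window)))
    log_stage("compare-conditions: gene-unit r = ",
              round(corr$gene$r, 4))
  }

  ## --- segment --------------------------------------------------------
  genome_seq <- readDNAStringSet(cfg$genome)
  names(genome_seq) <- sub("\\s.*", "", names(genome_seq))
  seqlens <- setNames(width(genome_seq), names(genome_seq))
  repeats <- stage("segment", read_repeat_bed(cfg$repeats))
  segments <- stage("segment",
                    annotate_segments(
                      segment_domains(tracks[[1L]], window = cfg$window,
                                      t_hyper = cfg$t_hyper,
                                      min_sites_per_window =
                                        cfg$min_sites_per_window,
                                      seqlengths = seqlens),
                      repeats, models))
  write_segments_bed(segments, file.path(cfg$out_dir, "segments.bed"))
  seg_dt <- as.data.table(segments)
  tsv(seg_dt, "segments.tsv")
  log_stage("segment: ", length(segments), " segments")

  ## --- integrate expression -------------------------------------------
  pops <- lapply(status, function(s)
    stage("integrate-expression",
          partition_populations(s, low_fpkm_max = cfg$low_fpkm_max,
                                high_fpkm_min = cfg$high_fpkm_min)))
  scatter <- stage("integrate-expression",
                   methylation_expression_scatter(status[[1L]]))
  tsv(pops[[1L]]$summary, "populations_condition1.tsv")
  tsv(scatter$table, "methylation_fpkm_scatter.tsv")

  ## --- enrich ---------------------------------------------------------
  taxonomy <- stage("enrich", read_taxonomy_table(cfg$taxonomy))
  enrich <- stage("enrich",
                  taxon_enrichment(status[[1L]], taxonomy,
                                   n_permutations = cfg$n_permutations,
                                   seed = cfg$seed))
  tsv(enrich, "taxon_enrichment.tsv")

  ## --- summary --------------------------------------------------------
  seg_rep <- function(lab) {
    v <- seg_dt[label == lab, repeat_overlap_fraction]
    if (length(v)) mean(v) else NA_real_
  }
  pop_i <- pops[[1L]]$summary[population == "i_low_fpkm"]
  summary <- list(
    seed = cfg$seed,
    n_conditions = n_cond,
    global_levels = as.data.frame(global_tab),
    global_cg_mean_of_fractions =
      stats::setNames(as.list(cg_levels), paste0("condition", seq_len(n_cond))),
    global_cg_mean_over_conditions = mean(cg_levels),
    percent_genes_methylated_by_condition = 100 * prop_meth,
    percent_genes_methylated = 100 * mean(prop_meth),
    class_means = lapply(summaries, as.data.frame),
    condition_correlation_gene = if (!is.null(corr)) corr$gene$r else NULL,
    condition_correlation_window = if (!is.null(corr)) corr$window$r else NULL,
    n_segments = length(segments),
    repeat_overlap_hyper = seg_rep("hyper"),
    repeat_overlap_hypo = seg_rep("hypo"),
    populations = as.data.frame(pops[[1L]]$summary),
    percent_methylated_low_fpkm =
      if (nrow(pop_i)) pop_i$percent_methylated else NA_real_,
    scatter_pearson = scatter$pearson,
    scatter_spearman = scatter$spearman,
    enrichment = as.data.frame(enrich),
    n_models_predictor_a = length(models_a),
    n_models_high_confidence = sum(hc$table$selected),
    genome_stats_all = as.data.frame(stats_all),
    genome_stats_high_confidence = as.data.frame(stats_hc)
  )
  write_json(summary, file.path(cfg$out_dir, "summary.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(summary)
}
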