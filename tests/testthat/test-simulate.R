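# small profile for unit-scale checks; the full-size default profile is
# exercised by the acceptance suite
small_profile <- function(seed = 5L, ...) {
  sim_profile(seed = seed, n_contigs = 2L, contig_length = 60000L,
              n_genes = 60L, ...)
}

test_that("identical seeds give byte-identical outputs", {
  p <- small_profile()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_methylome(p, d1)
  m2 <- simulate_methylome(p, d2)
  for (f in c("genome.fa", "methylome_condition1.cx.txt",
              "methylome_condition2.cx.txt", "genes_predictorA.gff3",
              "repeats.bed", "fpkm.tsv", "gene_truth.tsv"))
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
})

test_that("an invalid profile fails before any file is written", {
  p <- small_profile()
  p$gc_content <- 2
  d <- file.path(withr::local_tempdir(), "never")
  expect_error(simulate_methylome(p, d), "invalid profile")
  expect_false(dir.exists(d))
})

test_that("domain truth tiles each contig exactly and alternates labels", {
  p <- small_profile(seed = 9L)
  d <- withr::local_tempdir()
  simulate_methylome(p, d)
  bed <- fread(file.path(d, "domains_truth.bed"))[, 1:4]
  setnames(bed, c("contig", "start0", "end", "label"))
  for (ctg in unique(bed$contig)) {
    b <- bed[contig == ctg][order(start0)]
    expect_equal(b$start0[1], 0L)
    expect_equal(b$end[nrow(b)], p$contig_length)
    if (nrow(b) > 1L) {
      expect_equal(b$start0[-1L], b$end[-nrow(b)])            # no gaps
      expect_true(all(b$label[-1L] != b$label[-nrow(b)]))      # alternation
    }
  }
})

test_that("repeats sit inside hyperdomains at the profile's coverage", {
  p <- small_profile(seed = 9L)
  d <- withr::local_tempdir()
  simulate_methylome(p, d)
  bed <- fread(file.path(d, "domains_truth.bed"))[, 1:4]
  setnames(bed, c("contig", "start0", "end", "label"))
  reps <- fread(file.path(d, "repeats.bed"))[, 1:3]
  setnames(reps, c("contig", "start0", "end"))
  hyper <- bed[label == "hyper"]
  for (i in seq_len(nrow(reps))) {
    host <- hyper[contig == reps$contig[i] & start0 <= reps$start0[i] &
                    end >= reps$end[i]]
    expect_equal(nrow(host), 1L)
    expect_equal(reps[i, end - start0] / host[, end - start0], 0.8,
                 tolerance = 0.01)
  }
})

test_that("the two conditions share sites and their latent truth", {
  p <- small_profile(seed = 3L)
  d <- withr::local_tempdir()
  simulate_methylome(p, d, write_site_truth = TRUE)
  r1 <- read_cytosine_report(file.path(d, "methylome_condition1.cx.txt"))
  r2 <- read_cytosine_report(file.path(d, "methylome_condition2.cx.txt"))
  key <- c("contig", "pos", "strand", "context", "trinucleotide")
  expect_equal(as.data.frame(r1[, ..key]), as.data.frame(r2[, ..key]))

  truth <- fread(file.path(d, "site_truth.tsv"))
  m <- merge(r1, truth, by = c("contig", "pos", "strand"))
  m <- m[count_meth + count_unmeth >= 5]
  m[, frac := count_meth / (count_meth + count_unmeth)]
  # observed fractions concentrate on the shared latent level
  expect_lt(m[, mean(abs(frac - level))], 0.08)
  # CpG symmetry: the two strands of one CpG share one level
  cg <- truth[context == "CG"]
  cg[, key := ifelse(strand == "+", pos, pos - 1L)]
  spread <- cg[, .(d = diff(range(level)), n = .N), by = .(contig, key)]
  expect_true(all(spread[n == 2L, d] == 0))
})

test_that("reported trinucleotides match the emitted genome sequence", {
  p <- small_profile(seed = 4L)
  d <- withr::local_tempdir()
  simulate_methylome(p, d)
  genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  r1 <- read_cytosine_report(file.path(d, "methylome_condition1.cx.txt"))
  plus <- r1[strand == "+"][sample(.N, 50)]
  seqs <- as.character(Biostrings::subseq(
    genome[plus$contig], start = plus$pos, end = plus$pos + 2L))
  expect_equal(unname(seqs), plus$trinucleotide)
  expect_equal(classify_context(plus$trinucleotide), plus$context)
})

test_that("a hyperdomain-free genome has no methylated genes and a low level", {
  p <- sim_profile(seed = 2L, n_contigs = 1L, contig_length = 150000L,
                   n_genes = 100L, hyper_domain_fraction = 0)
  d <- withr::local_tempdir()
  simulate_methylome(p, d)
  truth <- fread(file.path(d, "gene_truth.tsv"))
  expect_true(all(truth$status == "unmethylated"))
  bed <- fread(file.path(d, "domains_truth.bed"))[, 1:4]
  expect_true(all(bed$V4 == "hypo"))
  tk <- methylation_track(
    read_cytosine_report(file.path(d, "methylome_condition1.cx.txt")))
  lvl <- global_level(tk, contexts = "CG")
  expect_equal(lvl$mean_of_fractions,
               expected_summaries(p)$global_cg_level, tolerance = 0.25)
  expect_lt(lvl$mean_of_fractions, 0.08)
})

test_that("decoy models carry zero FPKM at the configured share", {
  p <- small_profile(seed = 6L)
  d <- withr::local_tempdir()
  simulate_methylome(p, d)
  fpkm <- read_fpkm_table(file.path(d, "fpkm.tsv"))
  truth <- fread(file.path(d, "gene_truth.tsv"))
  expect_true(all(fpkm[!gene_id %in% truth$gene_id, sum_fpkm] == 0))
  expect_true(all(fpkm[gene_id %in% truth$gene_id, sum_fpkm] > 0))
  # decoy count makes the zero-FPKM share of predictor-A models ~10%
  expect_equal(sum(fpkm$sum_fpkm == 0), round(60 * 0.1 / 0.9))
  expect_equal(mean(fpkm$sum_fpkm == 0), 0.1, tolerance = 0.1)
  # every truth gene is a predictor-A model
  models <- read_gff3_genes(file.path(d, "genes_predictorA.gff3"))
  expect_true(all(truth$gene_id %in% mcols(models$genes)$gene_id))
})
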