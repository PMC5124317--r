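mk_fpkm <- function(ids, sums) {
  data.table::data.table(gene_id = ids, s1 = sums, sum_fpkm = sums,
                         mean_fpkm = sums)
}

test_that("consensus selection needs both B overlap and expression", {
  a <- toy_models(data.frame(
    gene_id = c("m1", "m2", "m3"), contig = "c1",
    start = c(100, 1000, 2000), end = c(500, 1500, 2500), strand = "+"))
  b <- toy_models(data.frame(
    gene_id = c("b1", "b2"), contig = "c1",
    start = c(90, 1100), end = c(450, 1400), strand = "+"),
    source = "predictorB")
  fpkm <- mk_fpkm(c("m1", "m2", "m3"), c(5, 0, 8))
  res <- high_confidence_models(a, b, fpkm)
  expect_equal(res$table$selected, c(TRUE, FALSE, FALSE))
  expect_equal(mcols(res$selected$genes)$gene_id, "m1")
  expect_equal(res$n_removed_overlap, 1L)   # m3
  expect_equal(res$n_removed_fpkm, 1L)      # m2

  # overlap must be same-strand
  b_rev <- toy_models(data.frame(gene_id = "br", contig = "c1",
                                 start = 90, end = 450, strand = "-"),
                      source = "predictorB")
  res_rev <- high_confidence_models(a, b_rev, fpkm)
  expect_false(any(res_rev$table$selected))
})

test_that("degenerate consensus cases: empty B, identical B", {
  a <- toy_models(data.frame(gene_id = c("m1", "m2"), contig = "c1",
                             start = c(1, 1000), end = c(500, 1500),
                             strand = "+"))
  fpkm <- mk_fpkm(c("m1", "m2"), c(3, 4))
  b_empty <- gene_model_set(GRanges(gene_id = character(0)),
                            source = "predictorB")
  none <- high_confidence_models(a, b_empty, fpkm)
  expect_false(any(none$table$selected))
  expect_null(none$selected)

  all_in <- high_confidence_models(a, a, fpkm)
  expect_true(all(all_in$table$selected))
})

test_that("models missing from the FPKM table count as unexpressed", {
  a <- toy_models(data.frame(gene_id = c("m1", "m2"), contig = "c1",
                             start = c(1, 1000), end = c(500, 1500),
                             strand = "+"))
  expect_warning(res <- high_confidence_models(a, a, mk_fpkm("m1", 3)),
                 "missing from the FPKM")
  expect_equal(res$table$selected, c(TRUE, FALSE))
})

test_that("selection is monotone in B models and FPKM support", {
  set.seed(21)
  for (rep in 1:8) {
    n <- 12L
    starts <- sort(sample(seq(1, 50000, by = 100), n))
    a <- toy_models(data.frame(
      gene_id = sprintf("a%02d", 1:n), contig = "c1", start = starts,
      end = starts + 80, strand = sample(c("+", "-"), n, TRUE)))
    bdf <- data.frame(gene_id = sprintf("b%02d", 1:n), contig = "c1",
                      start = starts + sample(-40:40, n, TRUE),
                      end = starts + 80 + sample(-40:40, n, TRUE),
                      strand = as.character(strand(a$genes)))
    keep1 <- sort(sample(n, 5))
    keep2 <- sort(union(keep1, sample(n, 4)))     # superset of keep1
    fpkm <- mk_fpkm(sprintf("a%02d", 1:n), round(runif(n, 0, 5), 2))
    sel <- function(keep, fp) {
      b <- toy_models(bdf[keep, ], source = "predictorB")
      high_confidence_models(a, b, fp)$table[selected == TRUE, gene_id]
    }
    s1 <- sel(keep1, fpkm)
    s2 <- sel(keep2, fpkm)
    expect_true(all(s1 %in% s2))                 # adding B never shrinks
    fp0 <- data.table::copy(fpkm)
    zero <- sample(n, 3)
    fp0[zero, c("s1", "sum_fpkm", "mean_fpkm") := 0]
    s0 <- sel(keep2, fp0)
    expect_true(all(s0 %in% s2))                 # zeroing never grows
  }
})

test_that("genome statistics follow forced arithmetic on a toy assembly", {
  genome <- Biostrings::DNAStringSet(c(
    c1 = paste(rep("ACGT", 250), collapse = "")))   # 1000 bp, GC 0.5
  one <- toy_models(data.frame(gene_id = "g1", contig = "c1",
                               start = 101, end = 700, strand = "+"))
  gs <- genome_stats(one, genome)
  expect_equal(gs$n_models, 1L)
  expect_equal(gs$percent_coding_dna, 60)
  expect_equal(gs$gene_density_per_mbp, 1000)
  expect_equal(gs$mean_model_length, 600)
  expect_equal(gs$mean_exons_per_gene, 1)
  expect_equal(gs$mean_introns_per_gene, 0)
  expect_equal(gs$gc_content, 0.5)
})

test_that("overlapping coding bases are counted once", {
  genome <- Biostrings::DNAStringSet(c(
    c1 = paste(rep("ACGT", 250), collapse = "")))
  two <- toy_models(data.frame(gene_id = c("g1", "g2"), contig = "c1",
                               start = c(1, 51), end = c(100, 150),
                               strand = "+"))
  gs <- genome_stats(two, genome)
  expect_equal(gs$percent_coding_dna, 15)   # union [1,150] = 150 of 1000
})

test_that("empty model sets and out-of-bounds genes are handled", {
  genome <- Biostrings::DNAStringSet(c(c1 = paste(rep("A", 1000),
                                                  collapse = "")))
  gs <- genome_stats(NULL, genome)
  expect_equal(gs$n_models, 0L)
  expect_equal(gs$percent_coding_dna, 0)
  expect_true(is.na(gs$mean_model_length))

  beyond <- toy_models(data.frame(gene_id = "gX", contig = "c1",
                                  start = 900, end = 1200, strand = "+"))
  expect_error(genome_stats(beyond, genome), "gX")
})

test_that("intron counts equal exon counts minus one per gene", {
  models <- toy_models(
    data.frame(gene_id = c("g1", "g2"), contig = "c1",
               start = c(1, 1000), end = c(300, 1500), strand = "+"),
    exons = data.frame(
      gene_id = c("g1", "g1", "g1", "g2"), contig = "c1",
      start = c(1, 101, 201, 1000), end = c(50, 150, 300, 1500),
      strand = "+"))
  expect_equal(unname(lengths(introns(models))),
               unname(lengths(models$exons)) - 1L)
})
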