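test_that("exon, intron and body levels follow hand arithmetic", {
  models <- toy_models(
    data.frame(gene_id = "g1", contig = "c1", start = 1, end = 30,
               strand = "+"),
    exons = data.frame(gene_id = c("g1", "g1"), contig = "c1",
                       start = c(1, 21), end = c(10, 30), strand = "+"))
  # exon sites at fractions {1.0, 1.0}, intron site at {0.0}
  tk <- toy_track(c(5L, 8L, 15L), c(1, 1, 0))
  out <- gene_region_methylation(tk, models)
  val <- function(kind) out[out$region_kind == kind, ]$fraction
  expect_equal(val("exon"), 1)
  expect_equal(val("intron"), 0)
  expect_equal(val("gene_body"), 2 / 3)
})

test_that("features with no covered sites are undefined, not errors", {
  tk <- toy_track(5L, 1)
  fm <- feature_methylation(
    tk, GRanges("c1", IRanges(100, 200), feature_id = "far"))
  expect_equal(fm$n_sites_covered, 0L)
  expect_true(is.na(fm$fraction))
  # interval on an absent contig behaves the same
  fm2 <- feature_methylation(
    tk, GRanges("cX", IRanges(1, 10), feature_id = "off"))
  expect_true(is.na(fm2$fraction))
})

test_that("a uniform track yields that level for any gene", {
  pos <- seq(10L, 990L, by = 10L)
  tk <- toy_track(pos, rep(0.9, length(pos)))
  models <- toy_models(data.frame(gene_id = "g1", contig = "c1",
                                  start = 1, end = 1000, strand = "+"))
  fm <- feature_methylation(tk, setNames(granges(models$genes), "g1"))
  expect_equal(fm$fraction, 0.9)
})

test_that("flanks are taken on the gene's strand and truncated at edges", {
  # minus-strand gene: upstream is to the right of the span
  models <- toy_models(data.frame(gene_id = "gm", contig = "c1",
                                  start = 1000, end = 1500, strand = "-"))
  tk <- toy_track(c(1600L, 700L), c(1, 0))   # right flank 1.0, left flank 0.0
  out <- gene_region_methylation(tk, models, flank_bp = 500L)
  expect_equal(out[out$region_kind == "upstream", ]$fraction, 1)
  expect_equal(out[out$region_kind == "downstream", ]$fraction, 0)

  # flank reaching past the contig start is truncated silently
  near_edge <- toy_models(data.frame(gene_id = "ge", contig = "c1",
                                     start = 100, end = 300, strand = "+"))
  expect_silent(gene_region_methylation(tk, near_edge, flank_bp = 500L))
})

test_that("metagene profile is flat on uniform tracks", {
  pos <- seq(5L, 6000L, by = 7L)
  tk <- toy_track(pos, rep(0.5, length(pos)))
  models <- toy_models(data.frame(
    gene_id = c("g1", "g2"), contig = "c1", start = c(1000, 3500),
    end = c(2000, 4500), strand = c("+", "-")))
  prof <- metagene_profile(tk, models, n_body_bins = 10L, flank_bp = 300L,
                           flank_bin_bp = 100L)
  expect_equal(nrow(prof), 10L + 2L * 3L)
  got <- prof$mean_fraction[prof$n_genes > 0]
  expect_true(all(abs(got - 0.5) < 1e-12))
})

test_that("metagene body bins preserve a monotone 5'-3' gradient", {
  pos <- seq(110L, 990L, by = 20L)
  frac <- seq(0.05, 0.95, length.out = length(pos))   # rises toward 3'
  tk <- toy_track(pos, frac, coverage = 100L)
  models <- toy_models(data.frame(gene_id = "g1", contig = "c1",
                                  start = 100, end = 1000, strand = "+"))
  prof <- metagene_profile(tk, models, n_body_bins = 5L, flank_bp = 0L)
  body <- prof[prof$region == "gene_body" & prof$n_genes > 0, ]
  expect_true(all(diff(body$mean_fraction) >= 0))
})

test_that("a mirrored minus-strand gene reproduces its plus twin's profile", {
  d <- seq(0L, 890L, by = 10L)
  frac <- round(seq(0.1, 0.9, length.out = length(d)), 3)
  # plus gene at [1000, 1899]: site at 1000 + d has fraction frac[d]
  # minus gene at [5000, 5899]: site at 5899 - d mirrors it
  rec <- rbind(
    toy_records(1000L + d, round(frac * 100), 100L - round(frac * 100)),
    toy_records(5899L - d, round(frac * 100), 100L - round(frac * 100)))
  tk <- methylation_track(rec, min_coverage = 1L)
  plus <- toy_models(data.frame(gene_id = "gp", contig = "c1",
                                start = 1000, end = 1899, strand = "+"))
  minus <- toy_models(data.frame(gene_id = "gm", contig = "c1",
                                 start = 5000, end = 5899, strand = "-"))
  pp <- metagene_profile(tk, plus, n_body_bins = 9L, flank_bp = 0L)
  pm <- metagene_profile(tk, minus, n_body_bins = 9L, flank_bp = 0L)
  expect_equal(pp$mean_fraction, pm$mean_fraction, tolerance = 1e-12)
})
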