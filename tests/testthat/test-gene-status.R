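test_that("the status rule applies threshold, tie-break and site minimum", {
  expect_equal(classify_status(0.9, 10), "methylated")
  expect_equal(classify_status(0.9, 3), "undetermined")     # too few sites
  expect_equal(classify_status(0.5, 10), "methylated")      # tie goes up
  expect_equal(classify_status(0.49, 10), "unmethylated")
  expect_equal(classify_status(NA_real_, 0), "undetermined")
})

test_that("classify_genes ties fractions, counts and FPKM together", {
  models <- toy_models(data.frame(
    gene_id = c("g1", "g2"), contig = "c1",
    start = c(1, 1001), end = c(500, 1500), strand = "+"))
  # g1: 6 sites at 0.9; g2: only 3 covered sites
  tk <- toy_track(c(seq(10L, 60L, by = 10L), c(1100L, 1200L, 1300L)),
                  c(rep(0.9, 6), rep(0.2, 3)))
  fpkm <- data.table::data.table(gene_id = c("g1", "g2"),
                                 sum_fpkm = c(12, 0), mean_fpkm = c(6, 0))
  st <- classify_genes(tk, models, min_sites = 5L, fpkm = fpkm)
  expect_equal(st[st$gene_id == "g1", ]$status, "methylated")
  expect_equal(st[st$gene_id == "g1", ]$n_sites, 6L)
  expect_equal(st[st$gene_id == "g1", ]$sum_fpkm, 12)
  expect_equal(st[st$gene_id == "g2", ]$status, "undetermined")
  # counts always partition the gene set
  expect_equal(sum(table(st$status)), nrow(st))
})

test_that("class summary reproduces hand-computed class statistics", {
  st <- data.table::data.table(
    gene_id = paste0("g", 1:5),
    fraction = c(0.8, 1.0, 0.0, 0.1, 0.6),
    n_sites = c(10L, 10L, 10L, 10L, 2L),
    status = c("methylated", "methylated", "unmethylated", "unmethylated",
               "undetermined"))
  cs <- class_summary(st)
  meth <- cs[cs$status == "methylated", ]
  unmeth <- cs[cs$status == "unmethylated", ]
  expect_equal(meth$n, 2L)
  expect_equal(meth$proportion, 0.5)
  expect_equal(meth$mean_fraction, 0.9)
  expect_equal(unmeth$proportion, 0.5)
  expect_equal(unmeth$mean_fraction, 0.05)

  expect_error(class_summary(st[status == "undetermined"]), "no determined")
})

test_that("condition correlation is 1 for identical and -1 for inverted tracks", {
  models <- toy_models(data.frame(
    gene_id = paste0("g", 1:4), contig = "c1",
    start = c(1, 101, 201, 301), end = c(100, 200, 300, 400), strand = "+"))
  fr <- c(0.9, 0.1, 0.6, 0.3)
  pos <- c(50L, 150L, 250L, 350L)
  tka <- toy_track(pos, fr, coverage = 10L)
  tkb <- toy_track(pos, 1 - fr, coverage = 10L)
  same <- condition_correlation(tka, tka, models, unit = "gene")
  expect_equal(same$r, 1)
  expect_equal(same$n_units, 4L)
  flip <- condition_correlation(tka, tkb, models, unit = "gene")
  expect_equal(flip$r, -1)
  # symmetric in its arguments
  expect_equal(condition_correlation(tkb, tka, models, unit = "gene")$r,
               flip$r)
  # window unit works without models
  win <- condition_correlation(tka, tkb, unit = "window", window = 100L,
                               min_sites = 1L)
  expect_equal(win$r, -1)
})

test_that("correlation requires at least three shared units", {
  models <- toy_models(data.frame(gene_id = c("g1", "g2"), contig = "c1",
                                  start = c(1, 101), end = c(100, 200),
                                  strand = "+"))
  tk <- toy_track(c(50L, 150L), c(0.2, 0.9))
  expect_error(condition_correlation(tk, tk, models, unit = "gene"),
               "fewer than 3")
})

test_that("shared ortholog status counts pairs by joint status", {
  sa <- data.table::data.table(gene_id = c("a", "b"),
                               status = c("methylated", "methylated"))
  sb <- data.table::data.table(gene_id = c("x", "y"),
                               status = c("methylated", "unmethylated"))
  pairs <- data.table::data.table(gene_a = c("a", "b"), gene_b = c("x", "y"))
  res <- shared_ortholog_status(sa, sb, pairs)
  expect_equal(res$counts[["both_methylated"]], 1L)
  expect_equal(res$counts[["either_only"]], 1L)
  expect_equal(res$counts[["neither"]], 0L)

  empty <- shared_ortholog_status(
    sa, sb, data.table::data.table(gene_a = character(),
                                   gene_b = character()))
  expect_true(all(empty$counts == 0L))

  # identity pairing recovers the methylated gene count
  st <- data.table::data.table(
    gene_id = paste0("g", 1:6),
    status = c(rep("methylated", 2), rep("unmethylated", 3), "undetermined"))
  idp <- data.table::data.table(gene_a = st$gene_id, gene_b = st$gene_id)
  res2 <- shared_ortholog_status(st, st, idp)
  expect_equal(res2$counts[["both_methylated"]], 2L)
  expect_equal(res2$n_undetermined, 1L)

  # dangling ids warn and are excluded
  expect_warning(
    res3 <- shared_ortholog_status(
      sa, sb, data.table::data.table(gene_a = c("a", "zz"),
                                     gene_b = c("x", "x"))),
    "missing")
  expect_equal(res3$n_dangling, 1L)
  expect_equal(res3$counts[["both_methylated"]], 1L)
})
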