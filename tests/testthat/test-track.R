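test_that("site fractions follow counts, with zero coverage undefined", {
  expect_equal(site_fraction(5, 5), 0.5)
  expect_equal(site_fraction(0, 10), 0)
  expect_true(is.na(site_fraction(0, 0)))
  expect_equal(site_fraction(c(1, 0), c(1, 0)), c(0.5, NA))
})

test_that("tracks reject duplicate sites and respect the coverage filter", {
  rec <- toy_records(c(10L, 10L), c(1L, 2L), c(1L, 2L))
  expect_error(methylation_track(rec), "duplicate")
  tk <- methylation_track(toy_records(c(5L, 9L), c(2L, 9L), c(2L, 1L)),
                          min_coverage = 5L)
  expect_equal(nrow(covered_sites(tk)), 1L)            # (2,2) is below 5x
  expect_equal(nrow(covered_sites(tk, min_coverage = 1L)), 2L)
})

test_that("global level estimators agree and differ as coverage dictates", {
  # three equal-coverage sites at 1.0, 0.0, 0.5
  tk <- toy_track(c(1L, 5L, 9L), c(1, 0, 0.5), coverage = 10L)
  gl <- global_level(tk, contexts = "CG")
  expect_equal(gl$mean_of_fractions, 0.5)
  expect_equal(gl$weighted, 0.5)

  # (9,1) and (1,9): symmetric, both estimators 0.5
  tk2 <- methylation_track(toy_records(c(1L, 5L), c(9L, 1L), c(1L, 9L)),
                           min_coverage = 1L)
  gl2 <- global_level(tk2, contexts = "CG")
  expect_equal(gl2$mean_of_fractions, 0.5)
  expect_equal(gl2$weighted, 0.5)

  # (90,10) and (1,9): weighted 91/110, mean still 0.5
  tk3 <- methylation_track(toy_records(c(1L, 5L), c(90L, 1L), c(10L, 9L)),
                           min_coverage = 1L)
  gl3 <- global_level(tk3, contexts = "CG")
  expect_equal(gl3$weighted, 91 / 110)
  expect_equal(gl3$mean_of_fractions, 0.5)
})

test_that("estimators coincide exactly whenever coverage is uniform", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    cov <- sample(c(5L, 10L, 30L), 1)
    meth <- rbinom(n, cov, runif(1))
    tk <- methylation_track(
      toy_records(seq_len(n) * 3L, meth, cov - meth), min_coverage = 1L)
    gl <- global_level(tk, contexts = "CG")
    expect_equal(gl$mean_of_fractions, gl$weighted, tolerance = 1e-12)
  }
})

test_that("contexts are kept apart and empty contexts warn", {
  rec <- rbind(toy_records(1L, 9L, 1L, context = "CG"),
               toy_records(4L, 0L, 10L, context = "CHH"))
  tk <- methylation_track(rec, min_coverage = 1L)
  gl <- global_level(tk)
  expect_equal(gl[gl$context == "CG", ]$mean_of_fractions, 0.9)
  expect_equal(gl[gl$context == "CHH", ]$mean_of_fractions, 0)
  expect_equal(gl[gl$context == "all", ]$mean_of_fractions, 0.45)
  expect_warning(res <- global_level(tk, contexts = "CHG"), "no covered")
  expect_true(is.na(res$mean_of_fractions[1]))
})

test_that("coverage-weighted feature levels reconstitute the global level", {
  set.seed(7)
  pos <- sort(sample(1:3000, 200))
  cov <- rpois(200, 20) + 1L
  meth <- rbinom(200, cov, runif(200))
  tk <- methylation_track(toy_records(pos, meth, cov - meth),
                          min_coverage = 1L)
  parts <- GRanges("c1", IRanges(c(1, 1001, 2001), c(1000, 2000, 3000)),
                   feature_id = c("p1", "p2", "p3"))
  fm <- feature_methylation(tk, parts)
  combined <- sum(fm$weighted_fraction * fm$total_reads) / sum(fm$total_reads)
  expect_equal(combined, global_level(tk, contexts = "CG")$weighted,
               tolerance = 1e-12)
  expect_equal(sum(fm$n_sites_covered), 200L)
})

test_that("site-level histograms count covered sites into bins", {
  tk <- toy_track(c(1L, 4L, 7L, 10L), c(0, 0, 1, 1))
  h <- site_level_histogram(tk, n_bins = 2L)
  expect_equal(h$count, c(2L, 2L))
  expect_equal(sum(h$count), nrow(covered_sites(tk, context = "CG")))
  h2 <- site_level_histogram(methylation_track(empty_records()), n_bins = 4L)
  expect_equal(h2$count, rep(0L, 4L))
  expect_error(site_level_histogram(tk, n_bins = 1L), ">= 2")
})
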