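#' Default taxonomy group composition for the simulator
#'
#' Group weights (share of genes) and methylation propensities used by
#' [sim_profile()], loosely shaped like a DarkHorse top-hit breakdown of a
#' centric diatom genome: a diatom-derived majority that is depleted for
#' methylation, a large "unknown" set enriched for it, and minor foreign
#' groups. Weights sum to 1; the weighted propensity is close to the overall
#' methylated-gene probability so that the conditional assignment stays
#' well-behaved.
#'
#' @return data.frame with columns `group`, `weight`, `propensity`.
#' @export
default_taxonomy_groups <- function() {
  data.frame(
    group = c("diatom", "unknown", "opisthokont", "bacteria",
              "sar_other", "archaeplastida", "viral"),
    weight = c(0.60, 0.20, 0.05, 0.05, 0.06, 0.03, 0.01),
    propensity = c(0.15, 0.45, 0.40, 0.30, 0.30, 0.30, 0.35),
    stringsAsFactors = FALSE
  )
}

#' Parameter profile for the synthetic methylome generator
#'
#' Describes every knob of [simulate_methylome()]. The defaults form the
#' `"ccryptica"` profile: a mosaic genome in which two thirds of the bases
#' lie in hypermethylated, repeat-rich domains and one third in
#' hypomethylated, gene-rich domains, calibrated so that the closed-form
#' expectations of [expected_summaries()] reproduce the headline summaries of
#' a heavily methylated centric diatom methylome: a global CG level near 61%,
#' a repeatome near 53%, 23% methylated genes with class mean methylation
#' near 88% (vs 7% for unmethylated genes), and status-conditional FPKM
#' mixtures with means near 500 and 4500.
#'
#' Per-site true methylation levels are Beta-distributed around the class
#' mean (shared between the two simulated conditions); read counts are
#' binomial at Poisson coverage. Methylated genes live inside hypermethylated
#' domains, unmethylated genes inside hypomethylated domains.
#'
#' @param seed integer seed; the whole simulation is a deterministic function
#'   of the profile including the seed.
#' @param n_contigs,contig_length number and length (bp) of contigs.
#' @param gc_content genomic GC fraction.
#' @param hyper_domain_fraction expected fraction of bases in hypermethylated
#'   domains.
#' @param domain_length_mean,domain_length_min,domain_length_max parameters
#'   (bp) of the hyperdomain length distribution: exponential with the given
#'   mean, clamped to `[min, max]`. Hypomethylated domain lengths use the
#'   same clamped-exponential family with a mean solved numerically so the
#'   expected hyperdomain base fraction equals `hyper_domain_fraction`.
#' @param repeat_coverage_within_hyper fraction of each hyperdomain's bases
#'   covered by a repeat annotation.
#' @param genic_fraction_within_hypo fraction of hypodomain bases covered by
#'   (unmethylated) gene bodies.
#' @param n_genes total true genes across the genome.
#' @param p_methylated_gene probability a gene is methylated (and hence
#'   placed in a hyperdomain).
#' @param mu_hyper,mu_meth_gene,mu_unmeth_gene,mu_hypo_intergenic class mean
#'   CG methylation levels for hyperdomain background, methylated gene
#'   bodies, unmethylated gene bodies and hypodomain intergenic bases.
#' @param beta_concentration concentration of the per-site Beta draw around
#'   the class mean.
#' @param chg_level,chh_level mean methylation level of CHG/CHH sites
#'   (classless; non-CG methylation is uniformly low).
#' @param coverage_mean mean sequencing coverage per site and condition
#'   (Poisson).
#' @param n_conditions number of conditions; each gets its own cytosine
#'   report drawn from the shared truth.
#' @param fpkm_meth lognormal mixture for methylated genes: list with
#'   `weights`, `meanlog`, `sdlog` vectors.
#' @param fpkm_unmeth lognormal for unmethylated genes: list with `meanlog`,
#'   `sdlog`.
#' @param n_samples number of expression samples; per-sample FPKM is the
#'   gene's base value under mean-centred multiplicative lognormal noise.
#' @param sample_noise_sdlog sdlog of that per-sample noise.
#' @param taxonomy_groups data.frame of `group`, `weight`, `propensity`; see
#'   [default_taxonomy_groups()].
#' @param predictor_b_dropout fraction of predictor-A models absent from
#'   predictor B.
#' @param zero_fpkm_fraction fraction of predictor-A models that are
#'   unexpressed decoys (sum FPKM exactly 0), appended beyond `n_genes`.
#' @param boundary_jitter_bp max absolute jitter applied to predictor-B model
#'   boundaries.
#' @return an object of class `sim_profile` (a validated list).
#' @seealso [expected_summaries()], [simulate_methylome()]
#' @export
sim_profile <- function(seed = 1L,
                        n_contigs = 10L,
                        contig_length = 500000L,
                        gc_content = 0.43,
                        hyper_domain_fraction = 0.66,
                        domain_length_mean = 15000,
                        domain_length_min = 3000,
                        domain_length_max = 30000,
                        repeat_coverage_within_hyper = 0.80,
                        genic_fraction_within_hypo = 0.50,
                        n_genes = 5000L,
                        p_methylated_gene = 0.23,
                        mu_hyper = 0.90,
                        mu_meth_gene = 0.88,
                        mu_unmeth_gene = 0.07,
                        mu_hypo_intergenic = 0.03,
                        beta_concentration = 50,
                        chg_level = 0.03,
                        chh_level = 0.03,
                        coverage_mean = 30,
                        n_conditions = 2L,
                        fpkm_meth = list(weights = c(0.8, 0.2),
                                         meanlog = c(0.5, 7.3),
                                         sdlog = c(1.5, 1.0)),
                        fpkm_unmeth = list(meanlog = 6.6, sdlog = 1.9),
                        n_samples = 4L,
                        sample_noise_sdlog = 0.2,
                        taxonomy_groups = default_taxonomy_groups(),
                        predictor_b_dropout = 0.2,
                        zero_fpkm_fraction = 0.1,
                        boundary_jitter_bp = 20L) {
  profile <- structure(as.list(environment()), class = "sim_profile")
  validate_profile(profile)
  profile
}

#' Validate a simulation profile
#'
#' Errors on the first violated invariant; called by [sim_profile()] and at
#' the top of [simulate_methylome()] before any file is written.
#'
#' @param profile a `sim_profile`.
#' @return `profile`, invisibly.
#' @export
validate_profile <- function(profile) {
  p <- profile
  chk <- function(cond, msg) if (!isTRUE(cond)) stop("invalid profile: ", msg)
  frac_fields <- c("gc_content", "hyper_domain_fraction",
                   "repeat_coverage_within_hyper", "genic_fraction_within_hypo",
                   "p_methylated_gene", "chg_level", "chh_level",
                   "predictor_b_dropout", "zero_fpkm_fraction")
  for (f in frac_fields)
    chk(is.numeric(p[[f]]) && length(p[[f]]) == 1L &&
          p[[f]] >= 0 && p[[f]] <= 1, paste(f, "must be in [0, 1]"))
  for (f in c("mu_hyper", "mu_meth_gene", "mu_unmeth_gene",
              "mu_hypo_intergenic"))
    chk(p[[f]] > 0 && p[[f]] < 1, paste(f, "must be in (0, 1)"))
  chk(p$coverage_mean > 0, "coverage_mean must be > 0")
  chk(p$beta_concentration > 0, "beta_concentration must be > 0")
  chk(p$n_contigs >= 1 && p$contig_length >= 1000,
      "need >= 1 contig of >= 1000 bp")
  chk(p$n_genes >= 0, "n_genes must be >= 0")
  chk(p$n_conditions >= 1, "n_conditions must be >= 1")
  chk(p$domain_length_min > 0 &&
        p$domain_length_min <= p$domain_length_mean &&
        p$domain_length_mean <= p$domain_length_max,
      "domain lengths must satisfy min <= mean <= max")
  chk(isTRUE(all.equal(sum(p$taxonomy_groups$weight), 1)),
      "taxonomy group weights must sum to 1")
  chk(all(p$taxonomy_groups$propensity >= 0 &
            p$taxonomy_groups$propensity <= 1),
      "taxonomy propensities must be in [0, 1]")
  with(p$fpkm_meth, {
    chk(isTRUE(all.equal(sum(weights), 1)),
        "fpkm_meth mixture weights must sum to 1")
    chk(length(meanlog) == length(weights) && length(sdlog) == length(weights),
        "fpkm_meth component vectors must have equal length")
  })
  invisible(profile)
}

# mean of an Exp(mean = m) variable clamped to [a, b]
.clamped_exp_mean <- function(m, a, b) {
  a + m * (exp(-a / m) - exp(-b / m))
}

# hypodomain mean-length parameter giving the target hyper base fraction
.hypo_length_mean <- function(profile) {
  p <- profile
  h <- p$hyper_domain_fraction
  if (h <= 0 || h >= 1) return(NA_real_)
  hyper_bar <- .clamped_exp_mean(p$domain_length_mean, p$domain_length_min,
                                 p$domain_length_max)
  target <- hyper_bar * (1 - h) / h
  lo <- p$domain_length_min
  hi <- p$domain_length_max
  if (target <= lo) return(lo)
  if (target >= .clamped_exp_mean(1e9, lo, hi)) return(1e9)
  uniroot(function(m) .clamped_exp_mean(m, lo, hi) - target,
          interval = c(lo / 10, 1e9), tol = 1e-6)$root
}

# expected fraction of hyperdomain bases covered by methylated gene bodies:
# methylated and unmethylated genes share the same length distribution, so
# the ratio follows from gene counts and territory sizes.
.meth_gene_fraction_of_hyper <- function(profile) {
  p <- profile
  h <- p$hyper_domain_fraction
  if (h <= 0 || p$p_methylated_gene <= 0) return(0)
  if (p$p_methylated_gene >= 1) return(p$genic_fraction_within_hypo)
  p$p_methylated_gene / (1 - p$p_methylated_gene) *
    p$genic_fraction_within_hypo * (1 - h) / h
}

#' Closed-form expected summaries of a simulation profile
#'
#' Pure arithmetic on the profile: the expectations that a large simulated
#' genome converges to, used both to calibrate the default profile against
#' published headline values and as the oracle in parameter-recovery tests.
#'
#' The expected global CG level is the class-mean mixture over genomic
#' territory: with hyperdomain base fraction h, genic fraction g of
#' hypodomain bases, and methylated-gene base fraction f of hyperdomain
#' bases,
#' \deqn{E = h ((1-f) \mu_{hyper} + f \mu_{meth}) +
#'        (1-h)(g \mu_{unmeth} + (1-g) \mu_{intergenic}).}
#' When `hyper_domain_fraction` is 0 there is nowhere to place methylated
#' genes, so the realized methylated-gene probability is 0 and the level is
#' the hypodomain mixture alone. Lognormal means use
#' \eqn{\exp(\mu + \sigma^2/2)}; the low-expression conditional
#' \eqn{P(methylated \mid FPKM \le c)} comes from the two status-conditional
#' FPKM distributions by Bayes' rule.
#'
#' @param profile a [sim_profile()].
#' @param low_fpkm_max cutoff used for the low-expression conditional
#'   probability (default 10 FPKM).
#' @return named list: `global_cg_level`, `repeat_fraction`,
#'   `p_methylated_gene`, `class_mean_methylated`, `class_mean_unmethylated`,
#'   `mean_fpkm_methylated`, `mean_fpkm_unmethylated`,
#'   `p_methylated_given_low_fpkm`, plus the intermediate
#'   `meth_gene_fraction_of_hyper`.
#' @export
expected_summaries <- function(profile, low_fpkm_max = 10) {
  validate_profile(profile)
  p <- profile
  h <- p$hyper_domain_fraction
  g <- p$genic_fraction_within_hypo
  f <- .meth_gene_fraction_of_hyper(p)
  p_meth <- if (h <= 0) 0 else p$p_methylated_gene
  hypo_mix <- g * p$mu_unmeth_gene + (1 - g) * p$mu_hypo_intergenic
  global_cg <- h * ((1 - f) * p$mu_hyper + f * p$mu_meth_gene) +
    (1 - h) * hypo_mix

  lnorm_mean <- function(meanlog, sdlog) exp(meanlog + sdlog^2 / 2)
  fm <- p$fpkm_meth
  mean_fpkm_meth <- sum(fm$weights * lnorm_mean(fm$meanlog, fm$sdlog))
  fu <- p$fpkm_unmeth
  mean_fpkm_unmeth <- lnorm_mean(fu$meanlog, fu$sdlog)

  p_low_meth <- sum(fm$weights *
                      plnorm(low_fpkm_max, fm$meanlog, fm$sdlog))
  p_low_unmeth <- plnorm(low_fpkm_max, fu$meanlog, fu$sdlog)
  denom <- p_meth * p_low_meth + (1 - p_meth) * p_low_unmeth
  p_meth_low <- if (denom > 0) p_meth * p_low_meth / denom else NA_real_

  list(
    global_cg_level = global_cg,
    repeat_fraction = h * p$repeat_coverage_within_hyper,
    p_methylated_gene = p_meth,
    class_mean_methylated = p$mu_meth_gene,
    class_mean_unmethylated = p$mu_unmeth_gene,
    mean_fpkm_methylated = mean_fpkm_meth,
    mean_fpkm_unmethylated = mean_fpkm_unmeth,
    p_methylated_given_low_fpkm = p_meth_low,
    meth_gene_fraction_of_hyper = f
  )
}
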