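---
title: "Methods: mosaic methylome analysis and its synthetic calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mosaic methylome analysis and its synthetic calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

methylscape analyses whole-genome bisulfite methylomes whose methylation is
organised as a coarse binary mosaic — hypermethylated, repeat-dense blocks
up to tens of kilobases alternating with hypomethylated, gene-dense blocks
— the architecture reported for heavily methylated centric diatoms. This
vignette documents the statistical models, the parameters that matter, the
synthetic-data generator used for calibration and testing, and the design
choices made where the problem left the design open.

## Site-level model and estimators

Bisulfite sequencing reports, per cytosine and strand, a methylated count
$m_i$ and unmethylated count $u_i$. A site is *covered* when
$m_i + u_i \ge c$; the default $c = 5$ reads is standard WGBS practice and
is exposed everywhere (`min_coverage`). The per-site methylation fraction
is $f_i = m_i / (m_i + u_i)$, undefined (NA, not an error) at zero
coverage.

Two global estimators are always reported side by side:

* mean of fractions $\bar f = n^{-1} \sum_i f_i$ — the per-cytosine
  average, our default because the headline level this package recovers is
  defined per cytosine;
* weighted level $\sum_i m_i / \sum_i (m_i + u_i)$ — coverage-weighted;
  equal to $\bar f$ exactly when coverage is uniform (a tested invariant).

Records are kept per strand. CpG dinucleotides are biologically symmetric,
but merging the two strand records changes the coverage of the merged site,
so strand pooling is never implicit; all CG statistics here are per-strand
site statistics.

Context (CG/CHG/CHH, H ∈ {A, C, T}) is validated against the reported
trinucleotide at parse time; the generator reads contexts directly off its
emitted sequence, which keeps the parsers honest against real Bismark-style
CX reports.

## Gene-level statistics

A gene's body fraction is the unweighted mean of $f_i$ over covered CG
sites in its genomic span (strand-agnostic site inclusion); exon, intron,
and 500-bp strand-aware flank fractions are computed the same way. The
status rule is

* methylated if body fraction ≥ 0.5 (a tie at the threshold goes up —
  documented, tested),
* unmethylated below,
* undetermined with fewer than 5 covered sites.

Both knobs (`threshold`, `min_sites`) are configuration. On a
well-separated bimodal methylome (class means near 0.88 and 0.07) any
mid-range threshold yields identical calls, which is why a fixed 0.5 is a
safe default. Class proportions are computed over determined genes only;
two-condition studies are summarised by averaging the per-condition
proportions, matching how such results are usually quoted.

The metagene profile scales each gene body to a fixed number of bins plus
fixed-width flank bins, reverses minus-strand genes so bin 1 is 5', takes
per-gene bin means and then the mean over genes, skipping genes with no
covered site in a bin. Exact oracles (uniform tracks, monotone gradients,
strand mirroring) pin the binning arithmetic down in the tests.

## Segmentation

Domains are called by a two-state thresholded-window scan: non-overlapping
1-kb windows, labelled hyper when the window's mean of fractions is
≥ 0.5, hypo otherwise, with windows holding fewer than 3 covered sites
carrying the running label (sparse windows never open or close a domain on
their own evidence); leading/trailing sparse windows are dropped, and runs
of equal labels merge. The mosaic methylomes this targets are near-binary,
so the simplest method with exact oracle tests is preferred over an HMM;
an HMM is a natural extension point, not a default. Windows at contig ends
may be short and are kept. Only non-overlapping windows are supported
(`step = window`); sliding smoothing is out of scope.

Segments are annotated with the fraction of bases covered by (reduced)
repeat annotation and the number of gene midpoints they contain. Boundary
accuracy is tested as recovery: on the default simulation ≥ 95% of true
domain edges must lie within one window of a recovered segment boundary.

## Expression integration and enrichment

Gene expression enters as per-sample FPKM; a gene's FPKM is the mean across
samples (the sum is kept alongside, because the consensus-model filter is
defined on sums). The methylation–expression plane is partitioned into:
population i, mean FPKM in [0, 10]; population iii, methylated genes with
mean FPKM ≥ 100; population ii, unmethylated genes above 10 FPKM; the rest
"other". Population i takes precedence over iii because it is defined by
expression alone; both bounds are configuration (the upper bound of
population iii's source description is a range of averages, not a cut).

Taxonomic enrichment of methylation is the within-group proportion of
methylated genes minus the genome-wide proportion, over determined genes
only (undetermined genes leave both numerator and denominator). The
gene-count-weighted mean of enrichments is identically zero — an algebraic
identity used as the prime invariant test. Significance was not part of the
original descriptive statistic, so the label-permutation test (two-sided
empirical p-value with the +1 correction) is reported in its own column.
Permutation p-values of this form are exact but conservative under heavy
discreteness; the calibration test therefore uses 400 genes in two
200-gene groups, where the attained size of an exact test sits near the
nominal level (measured 0.040 at $\alpha = 0.05$ over 500 null
replicates).

## Consensus gene models and genome statistics

A predictor-A model is high confidence when some predictor-B model overlaps
its span by ≥ 1 bp on the same strand and its summed FPKM is strictly
positive ("non-zero" means exactly > 0 — no epsilon, since unsupported
models are reported with a sum of 0.00). Span overlap is the default
because "overlapping" is otherwise underdefined; CDS-level overlap and a
minimum-overlap flag are provided. Selection is monotone in both inputs
(tested as a property). Percent coding DNA counts unique CDS bases —
coding bases under overlapping genes count once, because the statistic is a
genome fraction, not a transcript sum; an exon-counting mode is a flag.

## The synthetic methylome generator

`sim_profile()` fixes the study conditions; `simulate_methylome()` emits a
complete dataset (FASTA, truth BEDs, two predictor GFF3s, two-condition CX
reports, FPKM, taxonomy, gene truth, JSON manifest) as a deterministic
function of the profile, byte-identical under one seed.

The generative model, per contig:

1. **Domains.** Alternating hyper/hypo blocks. Hyperdomain lengths are
   exponential with mean 15 kb, clamped to [3, 30] kb — "up to ~30 kb"
   matches the described block scale, and the 3-kb floor keeps every true
   domain resolvable at the 1-kb analysis window. The hypodomain mean is
   solved numerically so the expected hyper base fraction equals the
   profile's 0.66. The drawn lengths are then rescaled per class within
   each contig so the realized hyper fraction equals its target exactly:
   the unconditioned renewal process leaves ~1.4 points of standard
   deviation in the realized fraction at 5 Mbp, which would dominate every
   ±2-point recovery check; conditioning the simulator on its own stated
   design fraction removes that nuisance variance without touching any
   parameter.
2. **Repeats.** One repeat block per hyperdomain covering exactly 80% of
   its bases at a random offset, so the repeatome is 0.66 × 0.80 ≈ 53% by
   construction.
3. **Genes.** Each of the 5000 genes is methylated with probability 0.23.
   Methylated genes are placed inside hyperdomains; unmethylated genes
   inside hypodomains, covering half of the hypodomain bases
   (`genic_fraction_within_hypo = 0.5`), non-overlapping, with 1–3 exons
   separated by short introns. Mean gene length follows from the coverage
   constraint (~220 bp on the default genome — a toy scale; what matters
   for the statistics is CpG count per gene, ~15–20, comfortably above the
   5-site determination threshold at 30× coverage).
4. **Methylation truth.** Every CpG dinucleotide receives one true level,
   Beta-distributed around its territory's class mean (0.90 hyperdomain
   background, 0.88 methylated gene body, 0.07 unmethylated gene body,
   0.03 hypo intergenic; concentration 50) — CG levels are symmetric
   across the two strands of a CpG, CHG/CHH sites get independent low
   levels (mean 0.03) per strand, matching canonical bisulfite biology.
   The Beta-plus-binomial construction (counts Binomial at Poisson-30
   coverage) is what produces the strongly bimodal per-site fraction
   histogram. Both conditions draw their counts independently from the
   *same* truth, which is what makes the between-condition correlation a
   recovery target rather than an assumption.
5. **Expression.** Methylated genes draw FPKM from
   0.8·LogNormal(0.5, 1.5) + 0.2·LogNormal(7.3, 1.0) (mean ≈ 492);
   unmethylated genes from LogNormal(6.6, 1.9) (mean ≈ 4470,
   P(FPKM ≤ 10) ≈ 0.012). Four samples per gene with mean-centred
   multiplicative lognormal noise (sdlog 0.2) keep the per-gene mean
   unbiased.
6. **Predictors and decoys.** Predictor A is the truth genes plus
   unexpressed decoy models (all-zero FPKM) sized so 10% of A models lack
   expression; predictor B drops a random 20% of A and jitters boundaries
   by ≤ 20 bp. These two fractions exist only to make the consensus filter
   non-trivial. The methylation/expression analyses run on
   expression-supported models (sum FPKM > 0), which excludes the decoys
   exactly — the same move as removing transcript-unsupported predictions
   before analysis.
7. **Taxonomy.** Groups are assigned conditionally on true status by Bayes
   from group weights and per-group methylation propensities, shaped like a
   lateral-transfer screen of a diatom genome (a methylation-depleted
   diatom majority, a methylation-enriched "unknown" minority, small
   foreign groups).

`expected_summaries()` gives the closed forms all of this converges to.
With hyper fraction $h$, genic fraction $g$ of hypodomain bases, and
methylated-gene base fraction $f$ of hyperdomain bases (which equals
$\frac{p}{1-p}\, g\, \frac{1-h}{h}$ when both gene classes share one length
distribution),

$$E[\text{CG level}] = h\,[(1-f)\mu_{hyper} + f \mu_{meth}]
  + (1-h)\,[g\,\mu_{unmeth} + (1-g)\,\mu_{intergenic}] = 0.610$$

at the defaults; lognormal class means are $e^{\mu + \sigma^2/2}$; and
P(methylated | FPKM ≤ 10) ≈ 0.947 by Bayes' rule from the two conditional
FPKM laws. With `hyper_domain_fraction = 0` there is nowhere to place a
methylated gene, so the realized methylated-gene probability is zero and
the expectation reduces to the hypodomain mixture — the documented reading
of that degenerate profile.

### What the generator does and does not emulate

It reproduces: the bimodal per-site fraction histogram, the binary domain
mosaic with repeat-dense hyperdomains, the status split and class means,
the status-conditional FPKM structure, and near-perfect between-condition
agreement. It does *not* emulate: read-level artefacts (bisulfite
conversion errors, mapping bias), replicate variance, the mild 3'-ward
within-gene methylation gradient, the small exon-intron methylation
difference, or any within-gene positional FPKM structure — so passing
recovery tests demonstrates estimator correctness under the stated
generative model, not robustness to those real-data features. The metagene
and flank operations are therefore verified with exact oracles rather than
recovery.

## Numerical and scale choices

Default problem sizes: the calibration/acceptance runs use the full default
profile (10 × 500 kb, 5000 genes, two conditions, ~2.2 M cytosine records
per condition); unit tests use 1–2 contigs of 60–200 kb with 60–200 genes,
which keeps the whole suite within a few minutes while the closed-form
oracles stay exact at any size. Tie-breaks and degenerate inputs are fixed
and tested: fraction ties classify as methylated; zero-coverage sites are
NA; empty tracks segment to nothing; an all-undetermined status table is an
error for class summaries; correlation requires ≥ 3 shared units; constant
columns give NA correlations, reported as such.

Internally all intervals are Bioconductor `GRanges` (1-based, closed), the
native convention of the interval stack used for every overlap operation;
0-based half-open coordinates exist only in BED files and are converted at
the rtracklayer boundary, while GFF3 and the cytosine report are 1-based on
disk and in memory. Round-trip tests pin both conventions.

## Known limitations

Segmentation is threshold-based and inherits a one-window boundary
resolution; no HMM or changepoint refinement. No differential-methylation
testing between conditions beyond global correlation (the underlying study
design reports none). Ortholog status comparison consumes a precomputed
pair table; no orthology inference. The generator's gene scale is toy-sized
relative to real gene lengths; statistics that depend only on per-gene site
counts are unaffected, but length-sensitive analyses (e.g. metagene flank
shapes) should not be read quantitatively from simulations.
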