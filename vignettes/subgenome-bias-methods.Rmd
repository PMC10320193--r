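---
title: "Methods: detecting subgenome expression bias in allopolyploid RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting subgenome expression bias in allopolyploid RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subbias)
```

## Background and data model

`subbias` analyses bulk RNA-seq from species in which some populations are
allotriploid: every cell carries a primary diploid (2n) genome plus an
acquired haploid (1n) subgenome obtained through interspecific
hybridization. The motivating system is the yeast *Brettanomyces
bruxellensis*, where three hybrid populations (here labelled Teq/EtOH,
Beer and Wine 1) each carry a different acquired subgenome, alongside an
autotriploid population (Wine 2) and two diploid populations (Wine 3,
Kombucha). Because the acquired subgenomes are highly divergent from the
primary genome (> 2.5%), reads can be assigned to their subgenome of
origin by competitive mapping against a concatenated reference, yielding
three count objects per allotriploid sample: a 2n compartment, a 1n
compartment (indexed by the acquired-subgenome gene IDs), and their sum.
Loss-of-heterozygosity (LOH) has deleted part of each acquired subgenome,
so only a subset of primary genes has a 1n ortholog, recorded in a
per-population ortholog map.

All package inputs are plain TSV: count matrices, a sample table
(`sample_id`, `population`, `ploidy_class`, `subgenome_ref`), ortholog
maps, gene annotation (lengths in bp and GO terms), and BLAST tabular hit
files for building ortholog maps from alignment output.

## Ortholog transfer

`filter_ortholog_hits()` turns BLAST hits of primary gene models against
an acquired assembly into an injective ortholog map. A hit survives when
percent identity is **at least 85** (inclusive) and the alignment length
is **strictly above 95%** of the query length; the strict/inclusive
asymmetry follows the wording of the corresponding laboratory protocols
("at least … at 85%", "above 95%"). Each query then keeps its single
highest-bit-score hit, and target conflicts are resolved in favour of the
higher-scoring query. Both tie-breaks fall back to lexicographic IDs: the
choice is arbitrary, but determinism matters more than the choice, since
ties are essentially absent in real bit scores. Note that the two
selection stages mean the *output pairs* are not formally monotone in the
thresholds (removing a query's best hit can promote a different target),
even though the surviving-hit set is.

## Normalization

Within an allopolyploid library, only a fraction of reads maps to each
subgenome, so compartment comparisons require compartment-restricted
library sizes:

* `cpm_by_subgenome()` divides each sample by its compartment total
  (counts per million). The 1e6 scale is cosmetic; every downstream
  ordination is invariant to it.
* `shared_core_normalize()` restricts to the ortholog core shared by all
  acquired subgenomes before normalizing — the only fair library size when
  comparing 1n expression *across* populations whose subgenomes retain
  different gene sets.
* `collapse_counts()` sums 2n and 1n counts for mapped genes (2n alone
  otherwise), producing whole-genome totals over the primary gene universe
  so allotriploid samples are comparable with samples mapped only to the
  primary reference.
* `size_factors()` is the median-of-ratios estimator (per sample, the
  median over all-positive genes of the count divided by the gene's
  geometric mean). We take the median of the raw ratios; estimators that
  take it on the log scale differ only microscopically at even gene
  counts.
* `tpm()` and `log_transform()` (log2 with pseudocount 1, so zero counts
  map to zero) complete the set.

## The subgenome-bias model

The central question is which genes do not follow their sample's overall
2n-vs-1n relationship. `subgenome_bias()` fits, per allotriploid sample,
ordinary least squares of transformed 1n counts on transformed 2n counts
over the sample's ortholog pairs, then flags pairs outside the standard
simple-regression prediction interval for a new observation,
$\hat y \pm t_{1-\alpha/2,\,n-2}\, s_e \sqrt{1 + 1/n + (x-\bar x)^2/S_{xx}}$.

Design choices, and why:

* **Log2 scale with pseudocount 1.** On raw counts, OLS is dominated by
  the handful of most highly expressed genes and the residual variance is
  wildly heteroskedastic. The log scale makes the per-copy-ratio
  interpretation additive (under equal per-copy expression the line has
  slope 1 and intercept $\log_2 1/2$, since the 1n copy should show half
  the 2n count). Raw-scale regression remains available via
  `log2_scale = FALSE`.
* **Prediction level 0.95.** The deviation calls are screening calls whose
  error control comes from the downstream consistency requirement, not
  from the per-call level; 0.95 is the conventional default and is
  exposed as a parameter.
* **Genes absent in a sample** (zero in both compartments) are excluded
  from that sample's fit and do not count as evaluable for that gene.
* **Direction-specific consistency.** A gene is consistently biased in a
  population only if it deviates the *same way* in at least 25/30, 7/9 or
  5/6 samples (populations of size 30, 9, 6), or `ceiling(25/30 · n)`
  otherwise. Mixed above/below deviations never produce a call, since the
  target notion is consistent over- or under-expression of one subgenome.
* **Paired tests.** For visualizing and ranking consistent genes, each
  compartment is corrected by its library size over the population's
  ortholog pairs, and per gene a *standard paired t-test* compares
  corrected 1n vs 2n across samples, Holm-adjusted within population. A
  "paired test with unequal variances" is not a coherent object — a paired
  test has a single variance of differences — so the standard paired t is
  used. Zero-variance differences leave the p-value undefined and are
  reported as missing rather than forced to a value.
* **Haploid fraction.** The global statistic is the sample's share of
  paired-ortholog reads assigned to the 1n compartment; the package tests
  excess over 1/3 with a one-sided one-sample z-test across the
  population's per-sample fractions. A pooled-read binomial test would
  treat reads as independent within samples and vastly overstate
  precision; the across-sample form respects biological replication.

The fit is an S3 object with `print`, `summary`, `coef`, `predict`
(prediction bounds for new 2n counts), `residuals`, `fitted` and `plot`
(per-sample scatter with the prediction band) methods.

## Differential expression and signatures

`nb_wald_de()` contrasts one focal population against all other samples
pooled, the design that makes population-specific patterns visible without
enumerating pairwise contrasts. It is a deliberately minimal
negative-binomial Wald engine: median-of-ratios size factors; per-gene
method-of-moments dispersion $\hat\alpha = (s^2 - \bar x)/\bar x^2$
pooled across the two groups with weights $n_g - 1$ and floored at 1e-8;
a two-group NB GLM with log link and log size factors as offset; Wald
$z = \hat\beta/\mathrm{se}$ with a two-sided normal p; BH adjustment
across genes, excluding genes whose fit is undefined (all-zero counts)
from the denominator. There is no dispersion shrinkage toward a trend, no
fold-change shrinkage and no independent filtering: the package's
contribution is the contrast design and the thresholds applied downstream,
and the minimal engine keeps every step inspectable. The cost is mild
miscalibration — without shrinkage, moment dispersion estimates are noisy,
and the attained null rejection rate at p < 0.05 sits within about ±2.5
percentage points of nominal in the simulation checks rather than exactly
at 5%.

Thresholds: DE means adjusted p < 0.05 **and** |log2FC| > 1 (at least
2-fold). A *transcriptomic signature* additionally requires |log2FC| > 1.6
(at least 3-fold, since $2^{1.6} \approx 3.03$) and an adjusted p strictly
below the median adjusted p of same-direction DE genes. Two ambiguities
were settled as follows: the top-half rule uses the *adjusted* p (for
internal consistency with the DE filter, which is phrased on adjusted p),
and ties at the median are excluded (strict inequality), which also gives
the sensible boundary behaviour that a direction with a single DE gene has
no signature.

`welch_t_test()` provides the unequal-variance group comparison used when
contrasting expression between sets of populations.

## Enrichment and ordination

`enrich()` tests each GO term's overlap with a DE set by the upper-tail
hypergeometric distribution over the annotation universe, run separately
per category (BP/MF/CC) with BH adjustment within category, and reports
the enrichment score — the DE-set proportion carrying the term divided by
the universe proportion. Terms are flagged significant at adjusted
p < 0.1. Gene-length bias weighting (as in read-count-aware enrichment
tools) is deliberately not applied: the synthetic data carries no length
bias, and the score itself is independent of that correction. The
significance direction is "below 0.1"; a protocol that declared terms
significant *above* 0.1 would keep the least enriched terms, which cannot
be intended.

`pca_samples()` centers genes and decomposes samples, fixing each
component's sign so its largest-magnitude loading is positive (PCA is
sign-ambiguous; without the convention, scores are irreproducible across
BLAS implementations). `spearman_matrix()` is the rank correlation between
samples with average-rank ties.

## The synthetic-data generator

`simulate_counts()` produces datasets with known truth that emulate the
study design the package targets:

* **Populations and sizes** (defaults): Teq/EtOH 9, Beer 30, Wine 1 6
  (allotriploid); Wine 2 9 (autotriploid); Wine 3 26, Kombucha 7
  (diploid) — 87 samples.
* **Ortholog retention**: each primary gene is retained in an acquired
  subgenome independently with probability 0.88 / 0.70 / 0.75
  (Teq/EtOH / Beer / Wine 1), emulating LOH-driven gene loss. At the full
  genome scale of 5,206 genes this yields ≈ 4,580 / 3,640 / 3,900
  retained orthologs. Because retention is independent per gene, the
  expected three-way shared core is $5206 \cdot 0.88 \cdot 0.70 \cdot
  0.75 \approx 2400$; real LOH events are large and spatially correlated
  across populations, which inflates the observed core in real genomes
  relative to this independence baseline. The generator makes no attempt
  to model LOH breakpoint structure.
* **Expression**: per-gene relative expression is log-normal (default
  meanlog 0, sdlog 1.5, a typical bulk RNA-seq spread); expected counts
  are the relative expression times the library size (default 2e5 at the
  reduced test scale, 2e6 at `full_scale = TRUE`); totals are negative
  binomial with dispersion α (default 0.05, typical for isogenic yeast
  cultures; variance $\mu + \alpha\mu^2$), Poisson at α = 0.
* **Compartment split**: for allotriploid samples the total is thinned
  binomially into the 1n compartment with the gene's true allocation
  $p_g$ (default 1/3; 0 where the gene lacks a 1n ortholog), the 2n
  compartment taking the remainder. Thinning after drawing the total
  mirrors read assignment under competitive mapping and keeps
  2n + 1n = total exactly.
* **Truth sets**: `n_bias_genes` genes drawn from the shared core get
  allocation `bias_allocation` (default 0.6); `n_de_genes` genes get a
  $2^{\pm\text{log2fc}}$ expression scaling in a focal population
  (populations round-robin, directions alternating). The truth table
  records allocation, bias direction, DE population/effect and per-
  population 1n presence for every gene.
* **Autotriploids** are simulated like diploids up to an optional global
  scale (default 1): the package makes no 3n-specific transcriptional
  claim, and the default keeps the autotriploid population a pure
  negative control.
* Per-gene dispersion and library sizes are generator choices, not
  estimates from any particular dataset: real data do not report them at
  this granularity.

What the generator does **not** emulate — and what passing simulation
tests therefore cannot show about real data: sequence-level mapping error
and multi-mapping between diverged subgenomes, correlated LOH block
structure, GC/length biases, batch effects, and correlated expression
between genes. Calibration and recovery results below are statements
about the method under its own model.

Under `noise_model = "expected"` the generator returns rounded expected
counts (deterministic), which the exactness tests use. All outputs are
byte-deterministic given config + seed; seeded functions restore the
caller's RNG state.

## Numerical choices and degenerate inputs

* Regression requires ≥ 3 evaluable pairs and nonzero 2n variance;
  zero residual variance is legal (all points exactly on the line ⇒
  interval collapses to the line).
* The fraction z-test requires ≥ 2 samples and nonzero spread.
* `size_factors()` errors when no gene is all-positive (suggesting a
  pseudo-reference fallback) rather than silently switching estimators.
* All-zero genes propagate missing statistics; BH and Holm run over the
  tested set only.
* Pipeline configs are validated before any stage runs (seed mandatory in
  simulate mode; missing input fields named); a failing stage removes the
  partial outputs it wrote.

## Problem sizes in the test suite

The simulation tests run at a reduced scale chosen to keep the full suite
fast while leaving Monte-Carlo error well inside the asserted tolerances:
300–1,000 genes, libraries of 6e4–1e6 reads, the study's 87-sample layout
(or a single 20-sample allotriploid population for calibration checks),
and 100-instance oracle sweeps for the exact-equivalence checks.
Full-genome-scale runs (5,206 genes) are exercised for ortholog retention,
where they are cheap. Calibration assertions use a ±2.5-percentage-point
band around the nominal 5% (see the DE section for why exact nominal
calibration is not expected); the null haploid-fraction median is asserted
within ±1.5 percentage points of 33.3%.

## Known limitations

* Prediction intervals assume roughly normal residuals on the log2 scale;
  for very low counts the discreteness makes the attained outlier rate
  deviate from 1 − level (the simulations put it near 6% at level 0.95).
* The minimal NB engine is not a replacement for shrinkage-based DE tools
  on small designs; with fewer than ~5 samples per group its dispersion
  estimates are unstable.
* One-vs-rest contrasts respond to effects in *any* population (an effect
  in population A shifts the "rest" mean of every other contrast); calls
  should be interpreted per contrast, not as population-exclusive.
* The consistency thresholds are tuned to the study's population sizes;
  for other designs the `min_fraction` default (25/30) is a reasonable
  but arbitrary carry-over.
* cis/trans decomposition and within-diploid allele-specific expression
  are out of scope.
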