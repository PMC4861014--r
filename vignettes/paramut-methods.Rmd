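---
title: "Methods: locating a paramutated locus from methylome, siRNA and expression summaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locating a paramutated locus from methylome, siRNA and expression summaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paramut)
```

## The problem

Paramutation is the heritable transfer of a silent epigenetic state from
one allele to its active homologue. In tomato, the *sulfurea* (*sulf*)
epiallele silences the *SULFUREA* locus in *trans*, producing chlorotic
leaf sectors; homozygous paramutated tissue (*sulf*), heterozygous green
tissue (*sulf*/+), and wild type (wt) form a three-level genotype series.
Locating the silenced gene requires triangulating three genome-wide data
types around a positional prior (the locus must lie on chromosome 2,
upstream of the euchromatic *S* locus):

* **bisulfite methylomes** (two wt and two *sulf* replicates at roughly
  5x depth) to find differentially methylated regions (DMRs) in each
  cytosine context (CG, CHG, CHH — plant methylation is maintained by
  different pathways per context and must be analysed separately);
* **small RNA libraries** over the genotype series, because RNA-directed
  DNA methylation (RdDM) leaves a 23–24-nt siRNA signature at loci it
  silences;
* **mRNA expression**, because the paramutated gene should be repressed
  in *sulf*, partially in *sulf*/+.

`paramut` implements this analysis as a reusable pipeline plus a
synthetic-data generator with planted ground truth, so every stage can be
validated by parameter recovery without any external download.

## DMR calling: binning and the dual chi-square rule

Methylated and unmethylated calls from both strands are pooled into
contiguous 200-bp bins, separately per context; a cytosine at 1-based
position $p$ belongs to bin $\lfloor (p-1)/200 \rfloor$. Symmetric CG
positions are *not* collapsed into dinucleotide units; counts stay per
cytosine and strand pooling happens at the bin level. Bins are the unit
of testing.

**Count filter.** A bin enters the analysis only if it has at least 10
calls. The filter scope is ambiguous when four samples are compared; the
default (`filter_mode = "each"`) requires every sample to reach 10 calls,
which guarantees that both replicate 2×2 tables are populated. A
`"pooled"` mode (threshold on the summed total) is available for users
who prefer the laxer reading.

**Test.** For each retained bin the two replicate pairs are tested
independently: wt1 vs *sulf*1 and wt2 vs *sulf*2, each as a 2×2 table of
(methylated, unmethylated) counts with the Pearson chi-square statistic
on 1 df, *no* continuity correction (the common default for methylation
tables; Yates' correction would be conservative at these counts). A
table with an empty margin is uninformative and is assigned $p = 1$.
The bin is a DMR when

$$\max(p_1, p_2) < \alpha, \qquad \alpha = 0.01 .$$

Requiring both replicates to pass is a conjunction of two independent
null tests, so the null DMR rate is $\alpha^2 = 10^{-4}$ — a property the
acceptance suite verifies empirically on a genotype-identical simulation
with over $10^5$ retained bins. No multiple-testing correction is
applied on top of the raw threshold (the replicate-consistency rule *is*
the error control); the BED score field carries
$-10\log_{10}(\max p)$ so users can post-filter.

**Direction and effect.** The reported difference is the mean over
replicate pairs of (wt level − *sulf* level) in percentage points, so
negative values mean hypermethylation in *sulf*. A significant bin is
only labelled `hyper_in_sulf`/`hypo_in_sulf` when both replicate pairs
agree in sign; discordant significant bins are reported but tallied
separately, since a two-way hyper/hypo split is only coherent for
concordant calls.

**Region statistics.** The weighted methylation level of a region is
$100 \cdot \sum \text{meth} / \sum \text{total}$ over the cytosines of
one context — a coverage-weighted estimator that is robust at low depth.
Zero coverage yields `NA`, never 0. Browser-style profiles use 200-bp
windows sliding by 100 bp from coordinate 0. Region-level confirmation
uses a binomial (logistic) regression of the aggregated counts on
genotype, one binomial observation per sample, tested by likelihood
ratio against the intercept-only model; the two replicates enter as
independent observations (no replicate covariate, since with two
replicates per genotype a replicate term would saturate the fit).

## Small RNA stage: TMM normalization and Poisson regression

Locus counts are normalized with trimmed-mean-of-M-values (TMM) scaling
factors, implemented in-package: the factor subset is the loci detected
in *every* library with at least 10 total counts; the reference library
is the one whose 75th percentile count rate is closest to the mean; each
library's factor is the precision-weighted mean of log2 rate ratios
after a two-sided 30% trim on M-values and 5% trim on A-values, and
factors are rescaled to geometric mean 1 (the canonical TMM defaults).
The implementation is cross-checked against the reference
implementation in edgeR to $10^{-6}$ in the test suite — the package
computes its own factors and uses the library only as an oracle.

Counts are then rescaled to the mean effective library size, and each
locus is tested by Poisson regression of counts on the unordered
three-level genotype factor (wt reference), with a likelihood-ratio test
on 2 df against the intercept-only model — an omnibus test yielding one
p-value per locus. The default `"literal"` mode rounds the normalized
counts to integers and models them directly. Fitting *normalized*
counts with a Poisson likelihood slightly mis-states the sampling
variance when factors differ from 1; an `"offset"` mode (raw counts with
log effective sizes as offsets) is exposed as the statistically
preferred alternative, but `"literal"` remains the default because it is
the documented analysis this package reproduces. With equal library
sizes the two coincide. Null calibration (Kolmogorov–Smirnov distance of
p-values from uniform below 0.05 at baseline mean 20) and power (≥ 90%
at a 4-fold dose effect with two libraries per genotype) are verified on
simulation.

## Expression stage: four classes and the positional filter

Expression values are counts-per-million, $\log_2(x+1)$, per-gene
median-centered. Differentially expressed genes are clustered by
average-linkage hierarchical clustering with distance
$1 - r$ (Pearson, across samples), cutting the tree where the merge
correlation drops below 0.7. The upstream clustering tool this emulates
does not document its exact tree construction, so average linkage and
Pearson correlation — the conventional choices — are used and exposed as
parameters; equivalence with any particular historical partition is not
claimed, only recovery of planted structure (Rand index ≥ 0.95 at noise
SD 0.2). Zero-variance genes have no defined correlation and become
singleton "flat" clusters. Gene order cannot affect the result: rows
are processed in lexicographic id order.

Each cluster is categorized from the sign pattern of its genotype mean
differences (*sulf* − wt) and (*sulf*/+ − wt), with differences under
0.5 log2 counted as unchanged: down in both → I, down in *sulf* only →
II, up in both → III, up in *sulf* only → IV, anything else → "other".

The positional filter intersects three criteria: adjusted $p < 0.05$,
$\log_2(\text{wt}/\text{sulf}) > 0$ (down-regulated in *sulf*), and
location on chromosome 2 with gene end at or before the S-locus
boundary coordinate ("upstream" is the pericentromeric side; the
boundary is inclusive, a convention that must be fixed somewhere and is
asserted in the tests). Candidates are ranked by descending fold-change
— the most repressed gene is the top candidate.

## Assays

**McrBC-qPCR.** McrBC digests methylated DNA, so amplification after
digestion reflects the unmethylated fraction. With per-cycle efficiency
$E$ (default 2, perfect doubling; no efficiency correction is applied by
default), the surviving fraction is $R = E^{\,Cq_u - Cq_d}$ and the
methylation proportion is $100(1 - \min(R, 1))$. "No amplification" is
encoded as infinite Cq, making the proportion 100% when the digested
aliquot fails to amplify; a failed *undigested* aliquot is an assay
failure and returns `NA`.

**Relative expression.** Technical replicates are averaged on the Cq
scale; abundance $E^{-Cq}$ is normalized by the geometric mean of two
housekeeping genes. Fold changes between genotype groups are ratios of
arithmetic means, tested with a two-tailed Welch t-test on log2
abundances (log is the standard scale for qPCR ratios; the raw-scale
p-value is also reported for comparison).

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with planted truth for recovery tests:

* **Methylome.** Cytosine sites are a homogeneous Bernoulli process per
  context and strand. Default densities (CG 0.06, CHG 0.05, CHH 0.23
  cytosines/bp summed over strands) follow from a genome of roughly 34%
  GC with CpG depletion, as in tomato. Coverage is Poisson per site
  (default mean 5, the study's depth); methylated calls are
  beta-binomial parameterized by mean level and dispersion $\rho$, with
  $\rho = 0$ (plain binomial) as default since replicate-to-replicate
  biological variance was not quantified in the source design — $\rho$
  is exposed as a knob. Planted regions override the background level
  (CG 30%, CHG 10%, CHH 5%) per genotype. The default pipeline methylome
  plants a 727-bp region hypermethylated in *sulf* (wt CG 24%, CHG 4%,
  CHH 0.7%; *sulf* CG 73%, CHG 62%, CHH 4%) and an adjacent 400-bp
  repeat-like region hypomethylated in *sulf* (CHG 93% → 78%, CHH 27% →
  4%) — the published promoter-DMR geometry and levels.
* **Small RNA.** Poisson counts with mean library size × baseline ×
  per-genotype fold; defaults: 500 loci, baseline 20, six libraries (two
  per genotype), ten planted dose-responsive gains (1, 2, 4) and ten
  losses (1, 0.5, 0.25).
* **Expression.** The generator emits the already-normalized log2
  matrix plus DE table and annotation, not raw reads, because upstream
  DE calling is out of scope. Class patterns: I (0, −1.5, −1.5), II (0,
  0, −2), III (0, 1.5, 1.5), IV (0, 0, 2) over (wt, *sulf*/+, *sulf*),
  noise SD 0.2, sample design 2 wt + 3 *sulf*/+ + 3 *sulf*; class
  proportions follow the observed four-class split. DE p-values are
  honest Welch t-tests on the simulated matrix, BH-adjusted. Genes are
  placed uniformly over three 50-Mb chromosomes with down-regulated
  classes enriched on chromosome 2.
* **qPCR.** Cq values shift by $-\log_2(\text{fold})$ around a wild-type
  baseline, housekeepers stay flat, technical noise is Gaussian on the
  Cq scale (SD 0.1 cycles); the default target fold series is (1, 0.5,
  1/26), the published repression scale.

What the generator does **not** emulate: sequence-dependent site
spacing and CpG islands, bisulfite conversion failure, mapping bias and
copy-number artifacts, correlated biological replicate effects (unless
$\rho > 0$), and compositional (secondary) expression changes. Passing
recovery tests therefore demonstrates correctness of the statistics and
plumbing under the stated sampling models, not robustness to alignment
artifacts.

## Numerical and design choices

* Coordinates are 0-based half-open internally and in BED output;
  cytosine reports are 1-based (the common per-cytosine report
  convention). Conversion happens only at parse/write boundaries.
* Degenerate chi-square margins → $p=1$; zero-coverage regions → `NA`;
  all-zero sRNA loci → $p=1$ with an `all_zero` flag; bins missing from
  any sample are skipped with a logged count.
* Sub-seeds for pipeline stages derive linearly from the master seed and
  stay inside the 32-bit integer range; identical seeds give
  byte-identical stage outputs (the run log records seed and parameters
  and contains no timestamps).
* Validation problem sizes: the null-calibration simulation uses a
  24-Mb CG-only chromosome (≈ 120,000 retained bins); recovery,
  calibration and power checks use 200-kb chromosomes, 2,000-locus
  count matrices and 200-gene expression sets. These sizes give the
  acceptance properties comfortable Monte-Carlo margins while keeping
  the full suite under a minute of compute.

## Limitations

The DMR caller is the binned, threshold-based design it reproduces: no
smoothing, no HMM segmentation, no dispersion shrinkage across bins, and
raw-p thresholding rather than FDR control — by design, since the point
is a faithful, tested implementation of that analysis. The literal
Poisson mode inherits the variance mis-statement discussed above. The
four-class categorization depends on the 0.5-log2 effect floor; clusters
with weaker but consistent patterns fall into "other".
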