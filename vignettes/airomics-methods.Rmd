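---
title: "Methods: from somatic mutations to multi-omic subtypes"
author: "airomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from somatic mutations to multi-omic subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airomics)
```

# Scope

`airomics` implements the computational stages used to characterize
air-pollution-associated lung adenocarcinoma cohorts: trinucleotide
mutation spectra and mutational-signature inference, enrichment testing of
missense mutations at protein-protein interaction (PPI) interfaces,
single-sample gene-set and kinase-activity scoring, multi-omic consensus
subtyping, and evaluation of a linear radiomic signature. Every stage can
be exercised on synthetic data with known ground truth; no external
downloads are required. Upstream processing (alignment, variant calling,
CNV analysis, mass-spectrometry search, CT feature extraction) and
downstream services (pathway enrichment portals, actionability annotation,
docking/molecular dynamics) are out of scope.

# Mutation catalogs and the 96-channel spectrum

Somatic variants arrive as MAF-like tab-separated tables with 1-based
inclusive coordinates. Internally every interval intersection is performed
in 0-based half-open space; the conversion happens once, at the boundary
(`coord_1based_to_0h()`), so a single base at 1-based position $p$
occupies $[p-1, p)$.

Each single-nucleotide variant is assigned to one of 96 channels defined
by the substitution and its 5′/3′ flanking bases. Storage is always
pyrimidine-centered: a purine-reference SNV is reverse-complemented
(alleles and flanks) before labeling, so `G>T` in a `GGG` context becomes
`C[C>A]C`. Channels follow the fixed catalog display order (C>A, C>G,
C>T, T>A, T>C, T>G; flanks lexicographic within each class), matching
reference signature catalogs. When displaying purine-strand hotspots —
for example the guanine-adduct G>T transversions typical of
benzo[a]pyrene (BaP), whose tallest peak occurs at GpGpG —
`context_distribution()` also reports the purine-strand triplet next to
the stored pyrimidine-strand flank pair.

Records with `N` or unresolvable context are excluded from the spectrum
and counted in a QC report rather than failing the run. Duplicate records
on (sample, chromosome, position, alternate allele) are collapsed to one
occurrence, since multi-allelic and re-reported rows otherwise inflate
per-sample counts. Row sums of the spectrum equal each sample's
assignable SNV count by construction, and this conservation is enforced
in the test suite.

# Signature extraction and attribution

Per-sample spectra are normalized to frequencies and factorized by
non-negative matrix factorization (NMF) with Frobenius loss and
multiplicative updates. Initialization is non-negative double SVD; further
restarts perturb that initialization with random multiplicative noise, and
the restart with the lowest residual sum of squares (RSS) wins. Defaults:
5 restarts, at most 5000 iterations, relative RSS tolerance $10^{-6}$.
The engine is written in the package because the factorization is part of
the method surface; it is deterministic for a fixed seed, and the restart
stream never perturbs the caller's RNG state.

Signature profiles are reported L1-normalized (each row a probability
distribution over the 96 channels) with the scale absorbed into the
exposures. Extraction operates on frequencies; *re-fitting* exposures onto
fixed signatures (`attribute_exposures()`) operates on raw counts via
non-negative least squares, mirroring common signature-tool behavior, so
attributed exposures are interpretable as mutation counts.

The number of signatures is chosen from the RSS and explained-variance
curves. The visual "reflection point" rule needs a computable surrogate:
we use the $k$ maximizing the second difference (discrete curvature) of
the RSS curve, ties broken toward smaller $k$. A curve with no meaningful
curvature concentration — operationally, when the largest second
difference is below 20% of the total RSS drop across the grid, the
behavior of noise-only spectra whose RSS declines near-linearly in $k$ —
returns the smallest $k$ flagged low-confidence.

Extracted signatures are matched to reference catalogs by cosine
similarity, which for non-negative profiles lies in $[0, 1]$; exact ties
break to the first reference index and are flagged. The package ships no
third-party catalog: reference-shaped matrices used in examples and tests
are synthetic stand-ins generated in code. No normalization by genome
trinucleotide abundance is applied; spectra are modeled on the observed
channel frequencies directly.

# Interface-mutation enrichment (oncoPPIs)

For a gene $g$ participating in a structure-resolved PPI, let $M$ be the
interface length and $N$ the protein product length (same units), and let
$n$ be the total missense mutations observed in $g$ across the cohort.
Under the null that the interface is not recurrently mutated, the number
$k$ of those mutations falling in the interface is
$\mathrm{binomial}(n, M/N)$, and the enrichment p-value is the exact
upper tail

$$P(X \ge k) \;=\; 1 - \sum_{x=0}^{k-1} \binom{n}{x} p^x (1-p)^{n-x},
\qquad p = M/N,$$

computed through the stable binomial tail (`pbinom`) rather than naive
summation. (The prose definition "more than $k$" sometimes attached to
this test conflicts with the summation bound, which gives $P(X \ge k)$;
the summation form is implemented.) Benjamini–Hochberg adjustment runs
across **all** tested (pair, partner) hypotheses with $n \ge 1$, and a
pair is an oncoPPI when either partner passes FDR < 0.01. Recurrent
mutations at one position count once per cohort occurrence, because the
test is defined across individuals; only missense SNVs are counted.

Interval merging and mutation-interval intersection use the
`IRanges`/`GenomicRanges` machinery in-process; $M$ and $N$ are taken in
the units of the supplied interface table (coding bases for genomic
interval tables, residues if residue-unit columns are provided), keeping
$p = M/N$ dimensionally consistent.

# Single-sample scoring

`ssgsea_score()` implements the rank-based running-sum single-sample
enrichment score: genes are ranked by value (midranks for ties; ties are
walked in gene-name order so input order never matters), and the score
accumulates the difference between the weighted in-set empirical CDF
(weights $|r_i|^\alpha$, default $\alpha = 0.25$) and the unweighted
out-of-set CDF. At $\alpha = 0$ the score reduces to the unweighted
Kolmogorov-style running sum and is invariant to strictly monotone
transformations of the profile. Set members missing from the profile are
ignored; a set with zero coverage yields `NA` with a warning, never a
silent drop. Cross-sample min-max normalization exists behind a flag and
is off by default.

`ksea()` adopts the published KSEA App convention for kinase-activity
z-scores from phosphosite log2 fold-changes:

$$z = \frac{(\bar{s} - \bar{p})\sqrt{m}}{\delta},$$

where $\bar{s}$ is the mean log2 fold-change of the kinase's annotated
substrate sites, $\bar{p}$ and $\delta$ the mean and SD of all measured
sites, and $m$ the substrate count. Kinase-substrate links require a
NetworKIN prediction score of at least 5 and kinases at least 5 measured
substrates, the stated operating point of that tool; two-sided normal
p-values with $p < 0.05$ mark the significant view. Group-level analyses
are expected to supply per-group mean log2 ratios (e.g. tumor subtype
versus normal adjacent tissue).

# Multi-omic consensus subtyping

Each omics level (RNA, protein, phosphoprotein) is reduced to its most
variable features by raw median absolute deviation — the 1.4826
consistency constant is omitted since only the ranking matters — with
deterministic ties by feature id, 2000 features per level by default.
Features are z-scored per level and concatenated, so levels with
different dynamic ranges contribute comparably.

Consensus clustering follows the resampling recipe: for each $k$ in
$2..\mathrm{max}_k$ (default 6) and each of `reps` resamples (default
1000; 80% of samples, 80% of features), average-linkage hierarchical
clustering on $1 - $ Pearson correlation distance; the consensus matrix
records the fraction of co-sampled runs in which two samples co-cluster.
Final labels come from average-linkage clustering of $1 - $ consensus at
the chosen $k$.

$k$ is selected from the consensus CDF and delta-area curves. The area
under the empirical CDF of consensus values is computed per $k$ (trapezoid
rule on a 101-point grid) and the delta-area curve is the relative
increase from $k-1$ to $k$. The qualitative rule — stop where the CDF
approaches its maximum and the delta-area shows no appreciable increase —
is operationalized as: **the chosen $k$ is the last one before the
plateau**, i.e. one less than the smallest $k \ge 3$ whose relative
delta-area increase falls below 0.1 (configurable). When every delta is
essentially zero the smallest $k$ is returned flagged low-confidence; with
no plateau at all, $\mathrm{max}_k$ is returned flagged. We chose the
"one less" reading because a vanishing delta-area at $k$ certifies that
$k-1$ already captured the block structure: on a consensus sequence that
is perfectly block-diagonal at the true $k$ and only splits blocks softly
afterwards, this rule returns the true $k$, whereas reading the rule as
"the first small-delta $k$" systematically overshoots by one.

Cluster markers are isolated one-vs-rest per feature per cluster with a
Wilcoxon rank-sum test on log-scale values and BH adjustment within each
omics level; a marker requires FDR < 0.05 **and** fold change strictly
greater than 1.2, computed as the ratio of group means on the natural
scale. The rank-sum test stands in for a negative-binomial GLM
differential test; for the continuous, roughly log-normal intensity
matrices this stage consumes, it is the appropriate nonparametric choice,
and its null calibration is verified in the test suite. Cluster-clinical
association uses the exact two-sided Fisher test on (in-cluster vs
out-of-cluster) × (category vs not) tables; zero-margin tables return
p = 1 with a degenerate flag.

# Radiomic signature evaluation

A radiomic signature is an intercept plus named linear coefficients over
pyradiomics-style feature names. The shipped `builtin:mc2` signature
discriminates the proliferative, air-pollution-associated subtype from
the rest using five features (first-order maximum, root-mean-squared
intensity, GLCM maximum probability, GLRLM gray-level non-uniformity
normalized, NGTDM busyness); one published coefficient is typeset as
`+−0.0004598256`, which we interpret as a negative coefficient — the
`+−` is an artifact of concatenating signed terms. Evaluation is exact
arithmetic on raw feature values; no scaling is applied. Training of the
signature (LASSO selection, cross-validation, the imaging cohort split)
is not reproduced — only evaluation and generic ROC/confusion machinery,
with AUC computed by the rank (Mann–Whitney) formulation under midrank
ties.

# Synthetic data: what it emulates, and what it does not

Each generator draws from the statistical model its consuming stage
assumes, returns the ground truth alongside the data, is byte-reproducible
given a seed, and restores the caller's RNG state:

* `simulate_catalog()`: multinomial draws from signature mixtures, with
  contexts consistent with the drawn channels. Defaults in the test suite
  use 100 samples at 300–400 mutations each — loads at which
  three-signature recovery is expected to succeed.
* `simulate_interface_cohort()`: uniform-within-gene mutation placement,
  with within-interface probability multiplied by the enrichment factor
  (renormalized) in planted pairs. Interface fraction 0.1 and 30 mutations
  per gene mirror a desk-scale version of cohort interface testing.
* `simulate_omics()`: balanced clusters separated by `effect_size`
  noise-SD units on a random 10% of features per level, Gaussian noise;
  an optional log-normal (`positive`) scale for fold-change analyses.
* `simulate_phospho()`: N(0,1) background log2 ratios, planted mean
  shifts on selected kinases' substrates, NetworKIN scores at or above
  the filter threshold.
* `simulate_radiomic_table()`: the five signature features at plausible
  pyradiomics magnitudes (intensity maxima ~$10^3$, probabilities
  ~$10^{-1}$) so scores land in a realistic range, with the positive
  class shifted along the coefficient directions.

These generators emulate the *first-order statistical structure* of each
stage's inputs, not real data: no genome context composition, no
correlated gene modules beyond the planted cluster means, no
batch/purity/depth artifacts, no missingness. Passing tests therefore
certify the algorithms' correctness and calibration under their stated
models — they do not certify performance on real cohorts.

# Numerical choices and degenerate inputs

* NMF: convergence when the relative RSS change over a 10-iteration block
  falls below $10^{-6}$, or the fit is essentially exact
  (RSS $\le 10^{-6} \sum V^2$); non-convergence warns with the final
  residual rather than failing.
* Binomial tail, BH, Fisher, Wilcoxon: delegated to R's `stats`
  primitives (`pbinom`, `p.adjust`, `fisher.test`, `wilcox.test`).
* Degenerate cases fail loudly and early: empty spectra, zero-variance
  frequency vectors, zero vectors in cosine similarity, constant
  phosphosite ratios, single-class ROC labels. Cases that occur routinely
  in real data (ambiguous contexts, unmatched gene-set members, clusters
  below minimal size, zero-margin contingency tables) degrade gracefully
  with warnings or flags instead.
* Tie rules are deterministic everywhere: smaller $k$ for rank-selection
  curvature ties, first reference index for cosine ties, feature id for
  MAD ties, gene name for ssGSEA rank ties, midranks in all rank
  statistics.

# Problem sizes in the shipped checks

The test suite runs entirely on synthetic data at sizes chosen to make the
statistical assertions sharp yet quick to verify: 2000 interface
hypotheses for null calibration, 100 gene pairs with 20 planted for
power, 100 samples × 96 channels over ranks 2–6 for signature recovery,
60 samples × 700 concatenated features at 100 resamples per $k$ for
subtyping, 500 resampled kinase draws for KSEA null calibration. The
consensus-clustering default of 1000 resamples is retained for analysis
use; the cluster-recovery checks use 100, at which the consensus matrix
of a separated design is already stable.

# Known limitations

* NMF multiplicative updates find local optima; restarts mitigate but do
  not guarantee the global optimum, and signature recovery degrades for
  highly collinear signature profiles.
* The delta-area rule, like any operationalization of a visual criterion,
  can be off by one on weakly separated data; the low-confidence flag
  marks exactly the regimes where the curves carry little signal.
* Interface enrichment treats every base of a gene as equally mutable;
  sequence-context mutability is not modeled, which real cohorts violate.
* KSEA assumes substrate sites are exchangeable with the background under
  the null and independent across sites.
* ssGSEA scores are comparable across samples only for a fixed gene
  universe; missing-gene patterns that differ per sample bias scores.
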