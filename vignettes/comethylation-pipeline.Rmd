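---
title: "Co-methylation modules, cell-type enrichment and refined polygenic risk: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-methylation modules, cell-type enrichment and refined polygenic risk: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`comethnet` implements a desk-scale analysis chain for brain DNA
methylation in Parkinson's disease: unsigned weighted co-methylation
networks per brain region, module eigengene association with
neuropsychiatric traits, expression-weighted cell-type enrichment of a
trait-associated module's gene set against single-nucleus references, and
clumping+thresholding polygenic risk scores refined to genomic windows
around the module's CpG sites, with time-dependent Cox and Kaplan-Meier
modelling of conversion to depression. Because cohort methylomes and
genotypes of this kind are access-restricted, a first-class synthetic-data
module generates every input with planted ground truth; the test suite and
the acceptance script run entirely on those generators.

# The network model

For probes $i, j$ with Pearson correlation $r_{ij}$ across samples
(computed on covariate-residualized beta values), the unsigned adjacency
is $a_{ij} = |r_{ij}|^\beta$. The soft power $\beta$ is scanned over
1--20; for each power the scale-free fit $R^2$ regresses
$\log_{10} p(k)$ on $\log_{10} k$ over at least ten equal-occupancy
connectivity bins, where $p(k)$ is the empirical density (bin count over
bin width). Because the published choice was made by eye, the package's
rule is explicit: the smallest power with $R^2 \ge 0.8$, otherwise the
argmax, with a user override.

Topological overlap is
$\mathrm{TOM}_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij})$
with $\ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}$, and $1-\mathrm{TOM}$
is the average-linkage clustering dissimilarity.

## Simplified dynamic tree cut

The original block-wise procedure delegates the tree cut to a dynamic
algorithm whose exact settings are not reported, so the package uses a
reproducible surrogate with three parts:

1. **Best static cut.** Candidate cut heights (midpoints between up to 64
   distinct merge heights) are scanned; the cut maximizing the number of
   clusters of size $\ge$ `min_size` is kept, with ties broken by the
   number of probes those clusters cover and then by the higher cut, so
   complete modules are preferred. Clusters larger than
   $3 \times$ `min_size` are re-cut recursively by the same rule.
2. **Cluster-validity guard.** A candidate cluster of $p_c$ probes over
   $n$ samples is kept only if its first-PC variance share exceeds twice
   the Marchenko-Pastur white-noise edge $(1+\sqrt{p_c/n})^2/p_c$
   (capped at 0.9 so tiny or duplicated clusters pass). Without this
   guard, recursively re-cutting an unstructured branch can manufacture
   clusters above `min_size` out of pure noise.
3. **Membership pruning and eigengene merge.** Members with
   $|\mathrm{cor}(\text{probe}, \mathrm{ME})| <$ `kme_min` (default 0.3,
   the conventional stay-threshold) are returned to grey — this is what
   prevents weakly attached noise probes from inflating a module — and
   modules whose eigengenes correlate above $1 -$ `merge_cut` in absolute
   value (default cut 0.15) are merged. Absolute correlation is used
   because the network is unsigned and eigengene orientation is
   conventional.

For inputs larger than `max_block` (default 10000), probes are
pre-partitioned by k-means on the absolute top-8 singular-vector loadings
of the standardized probe matrix, balanced to the block size; absolute
loadings matter because members load on their module factor with either
sign, and signed loadings would split every module into its positively
and negatively loaded halves. Split module halves landing in different
blocks are reunited by the eigengene merge.

Module eigengenes are first-PC sample scores (unit variance), oriented so
the eigengene correlates non-negatively with the module's mean
methylation profile; `variance_explained` is the first eigenvalue share.

# Preprocessing

Probes are filtered per region by median absolute deviation: keep
probes with MAD strictly above the median probe MAD of that region, then
intersect the keep-sets across regions. The ambiguous phrasing of whether
the median is pooled across regions is resolved per-region, matching the
per-region filtering the text describes. Covariates (age, sex, technical
batch, neuronal proportion, PMI; factors treatment-coded) are removed per
probe by OLS, returning intercept plus residuals so values stay on the
beta scale (they may leave $[0,1]$, which downstream code accepts). The
visual PC inspection is operationalized as an advisory $|z| > 3$ flag on
the first four PC scores.

# Trait association

Binary traits use Spearman correlation on midranks — exact permutation
p-values by complete enumeration for $n \le 9$, a t approximation
otherwise; continuous traits use Pearson with t-based p. Modules with any
confound association at $p < 0.05$ (default screen: Braak Lewy-body and
neurofibrillary-tangle stages; configurable) are excluded before testing,
and the Bonferroni threshold is $0.05$ divided by the number of surviving
modules per region. Thresholds print with two significant figures below
0.005 and three decimals above, reproducing the conventional mixed
precision (27, 18 and 8 modules print as 0.0019, 0.0028, 0.006).
Sensitivity analyses use pairwise two-sided Wilcoxon rank-sum tests with
BH correction, optionally on an eigengene residualized for disease-stage
covariates.

# Cell-type enrichment

Specificity is built per annotation level by dropping unexpressed genes,
keeping genes differentially expressed across cell types (vectorized
one-way F test on log1p counts, BH $q < 10^{-5}$ — a deliberate
plain-ANOVA surrogate for the original moderated linear model), and
normalizing per-type mean expression to row sums of one. The bootstrap
test compares the target set's mean specificity per type against
`reps` random same-sized gene sets; $p = (1 + \#\{null \ge obs\}) /
(reps + 1)$ (the add-one rule keeps p usable for BH), and q-values are BH
across the types of the level tested.

The conditional test matches each null gene to a target gene on the
controlled type's specificity. Fixed decile bins — and uniform sampling
inside value windows — both leave a residual standardized deviation of
0.5--3 when the specificity distribution is sharply bimodal at
desk-scale universe sizes, because a bin or window straddling the
marker/non-marker jump is heterogeneous; the spec of the statistic
divides by the (small) matched-null SD, so even small matching bias
survives granularity tuning. The package therefore samples candidates
within one bin width (range divided by `n_bins`) of the matched gene's
value using linear importance weights calibrated so each window's
weighted mean equals the matched gene's specificity exactly: per-gene
unbiased matching. Controlling the tested type then collapses
$|SD\text{-from-mean}|$ to about 0--0.3, while orthogonal signal is
retained and fully collinear types are silenced, the three behaviours
that define the test.

Term (GO-style) enrichment corrects array coverage bias by resampling
probe sets of the target's probe count and mapping them to genes, so
heavily probed genes are proportionally likelier under the null; with one
probe per gene this reduces to the hypergeometric tail, which is the
oracle the tests check against.

# Polygenic scores and survival

Summary statistics drop variants with INFO $< 0.9$ and strand-ambiguous
(A/T, C/G) pairs, and are allele-aligned to the panel with sign flips.
Clumping is greedy: best remaining p (ties by position then id), removing
neighbours within 1000 kb at dosage $r^2 > 0.1$ (the conventional default
pairing for that window). Module windows extend each CpG by 1 Mb, clamped
at the chromosome start, and merge per chromosome (`GenomicRanges`).
Scores average effect-weighted dosages per counted allele
($\Sigma d\hat\beta / 2m$); per-variant mean imputation covers missing
dosages; thresholds with no variants yield missing scores. Incremental
$R^2$ comes from a linear model of the binary depression state on sex,
three dosage-derived genetic PCs (SVD without LD pruning — a desk-scale
simplification; real cohorts would prune first) and the score, with BH
FDR jointly across the 2 score sets × 9 thresholds = 18 tests.

Conversion to depression requires at least three longitudinal records and
GDS $\ge 5$ at two or more visits; the event time is the first qualifying
visit (a flag switches to the second, since the published definition is
ambiguous between them). Samples already qualifying at baseline are
prevalent, not converters, and are excluded from the time-to-event table
while still contributing to the cross-sectional binary outcome — counting
process intervals need positive length. Cox models use the counting
process formulation with Efron ties via the `survival` package (the same
engine the original analysis used), sex fixed, age and UPDRS-III carried
per visit interval, and predictors standardized so hazard ratios are per
SD of score. Kaplan-Meier strata default to the 0-5, 5-50, 50-95 and
95-100 percentiles with 5-50 as reference; the exact published cuts are
not printed, and these expose the extreme-tail contrast the figures show.

# Synthetic-data generators

The generators define the package's study conditions; their defaults are
fixed, not tuned per analysis.

* **Methylation** (80 donors/region, 2000 probes, three modules of 200):
  member probes are a logistic squash of
  $\text{intercept} + \lambda L_m + \text{covariates} + \varepsilon$,
  which guarantees $(0,1)$ support; marginal beta bimodality of real
  arrays is deliberately not modelled. Loading magnitudes are
  $|N(\lambda, 0.1\lambda)|$ with random sign. One module's latent
  correlates with the binary trait's liability at `trait_module_r`
  (default 0.6, chosen so that a failed detection at $n = 80$ indicates a
  method defect rather than sampling noise; the implied
  eigengene-binary-trait Spearman is about 0.48). The liability, not the
  thresholded trait, carries the planted correlation — a continuous score
  and a binary indicator cannot share it. Covariate effects (age, sex,
  batch, neuronal proportion, PMI) act through per-probe random
  susceptibilities so residualization has real work to do.
* **Expression** (6 subtypes × 100 nuclei, negative binomial, dispersion
  2): disjoint 50-gene marker sets, `marker_fold` = 5 in the own type,
  40 of the planted subtype's markers drawn from the trait module's gene
  pool; two annotation granularities.
* **Genetics** (1000 variants in LD blocks of 10, AR(1) $\rho = 0.8$
  latent thresholded at allele frequency; 400 target samples; discovery
  $n = 10^5$): causal variants (50, fixed standardized magnitude giving
  discovery $|z| \approx 4$, random sign) are placed inside ±1 Mb module
  windows at rate `causal_in_window_frac`; summary statistics add
  sampling noise and an INFO column, with ~5% strand-ambiguous pairs and
  ~10% allele-swapped rows to exercise harmonization. Target liability is
  the standardized genetic score scaled to $h^2 = 0.3$ plus environment;
  GDS trajectories bin a liability-driven AR(1) latent to integers 0-15,
  with visit-level UPDRS-III and 15% random dropout.

One master seed drives everything; the three generators use fixed seed
offsets, and every stochastic entry point restores the caller's RNG
state, so identical configs give byte-identical outputs (bundle manifests
store relative paths for the same reason).

What passing tests show — and do not show — about real data: the
generators produce the *statistical shapes* the methods assume (factor
modules, marker fold-changes, blocked LD, monotone GDS-liability
coupling). They do not reproduce beta-value bimodality, realistic
haplotype panels, multi-ancestry structure, batch-confounded module
structure or informative dropout, so green tests validate the machinery
and its calibration, not cohort-level effect sizes.

# Problem sizes and runtime choices

The tests and the acceptance script run the methylation recovery at
$n = 80 \times 2000$ probes, enrichment at 10000 bootstrap replicates
(the headline analysis used 100000; the default of `ewce_bootstrap`
remains 100000), PRS refinement at 1000 variants × 400 samples, and Cox
recovery at $n = 500$ with ~40% events — sizes chosen so each property
is measured with comfortable statistical margin on a single CPU.

# Known limitations

* The simplified tree cut is a surrogate, not a bit-level reproduction of
  the original dynamic algorithm; agreement is at the level of recovered
  partitions (ARI), which is what the tests assert.
* The degree-distribution fit can be unstable below ~30 probes; the scan
  refuses smaller inputs.
* The F-test specificity filter is harsher than a moderated model at very
  small per-type cell counts; universes shrink accordingly.
* Bootstrap p-values are bounded below at $1/(reps+1)$ by construction.
* With `min_size = 1` the cut scan degenerates to singletons and module
  structure is recovered purely by the eigengene merge; supported for the
  degenerate exact-duplicate case, not recommended in practice.
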