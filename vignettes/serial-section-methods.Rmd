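---
title: "Methods: clonal deconvolution and coexpression profiling of serial tumor sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal deconvolution and coexpression profiling of serial tumor sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The design this package models

Cutting a tumor specimen into a series of thin adjacent sections and profiling
every section produces a natural experiment: each section is a slightly
different mixture of malignant clones and nonmalignant cells, so any quantity
measured across the series — a variant allele frequency (VAF), a transcript,
a methylation probe — varies with the cellular composition. Features that
co-vary across sections belong together: mutations with proportional VAF
profiles arose in the same clone, and genes whose expression tracks a clone's
abundance are expressed by that clone. `clonesect` implements this logic end
to end, with a synthetic-data generator that supplies known ground truth for
every stage.

# Genetic model

## Clone trees and allele states

A tumor is described by a rooted clone phylogeny (`clone_tree()`): the root is
the truncal clone, every other clone adds mutations to its parent's genotype,
and the conceptual parent of the root is the nonmalignant compartment. For
every (mutation, clone) pair the model stores an allele state `(m, t)` — `m`
mutant copies out of `t` total at that locus in cells of that clone. SNVs
start heterozygous diploid `(1, 2)`; copy-number events rewrite states in the
clades below them: a gain raises `t` to 3 (duplicating the mutant or reference
allele), copy-neutral LOH (cn-LOH) duplicates the mutant allele to `(2, 2)`,
and a hemizygous loss drops to `t = 1` and may delete the mutant allele
(`(0, 1)`), which removes an upstream mutation from one clade — the mechanism
behind a truncal driver appearing subclonal at the VAF level.

## Expected VAF and cellular prevalence

With per-section exact-genotype fractions `f_c` (each cell counted once,
under the most derived clone matching its genotype), the expected VAF is the
copy-number-weighted mixture

```
VAF = sum_c f_c * m_c / sum_c f_c * t_c ,
```

the sum including the diploid wildtype nonmalignant remainder. Two special
cases carry diagnostic weight: a truncal heterozygous diploid mutation has
VAF = purity/2, and a truncal mutation under cn-LOH has VAF = purity, so the
two loci together read out purity and allelic configuration. For an event
with known allele context `(m, t)` in carriers and background copy number
`t_bg`, the model inverts in closed form to the cellular prevalence

```
phi = VAF * t_bg / (m - VAF * (t - t_bg)) ,
```

clipped to [0, 1] (`cellular_prevalence()`), with binomial read-count
uncertainty propagated through the (monotone) inversion. `expected_vaf()` and
`cellular_prevalence()` are exact mutual inverses, which the test suite
asserts over a grid of allele states.

## Clonal reconstruction

The reconstruction stage replaces a Bayesian Dirichlet-process clustering
plus integer-programming tree search with a transparent, fully testable
pipeline of the same shape:

1. **Prevalence clustering.** Events are clustered by their prevalence
   profiles across sections with Ward linkage. Cellular prevalence carries a
   meaningful absolute level — a subclone's prevalence can track its parent's
   in shape while sitting strictly below it — so this step uses Euclidean
   distance, not the correlation distance used for VAF-profile clustering
   (where only profile shape matters). Cluster prevalences are
   precision-weighted means of their members.
2. **Cluster count.** `consensus_cluster_count()` combines an elbow and a
   silhouette criterion. The elbow is the maximum second difference of
   `log W(k)` (total within-cluster dissimilarity): W typically falls by
   orders of magnitude until the true k and flattens after, so the kink is
   only visible on the log scale — on the raw scale the drop from W(1)
   dominates every fixture and the rule would always elect k = 2. When the
   two criteria agree within 1 the finer k wins: the mean silhouette is
   biased coarse on nested clusters, because merging an adjacent
   parent/child pair raises the average width (measured on simulated tumors:
   silhouette under-clusters ~15% of runs and never over-clusters, while the
   log-scree elbow is almost always exact). Larger disagreement signals
   instability and falls back to the smaller k, logged.
3. **Tree search.** All rooted trees over the clusters are enumerated
   (Cayley's `k^(k-2)`, guarded at k <= 7), with the maximal-mean-prevalence
   cluster as root. For each topology, per-section exact-genotype fractions
   solve `min || phi_obs - A f ||^2` subject to `f >= 0` and column sum <= 1,
   where `A` is the subtree-sum indicator — so the subclone-sum constraint
   (a parent's cumulative abundance covers its children's) holds by
   construction. The solver enumerates KKT active sets exactly (at most
   `2^(k+1)` equality-constrained solves, shared across sections), which is
   globally optimal for this convex program; the tests check it against a
   dense grid search.
4. **Selection.** The minimum-objective tree is returned. Near-ties (within
   1% relative objective, a documented choice — the original analysis broke
   such ties manually on biological grounds) are reported as a ranked
   candidate list with a flag.

Purity is the truncal cluster's cumulative frequency per section.

# Transcriptional model

## Coexpression modules

Bulk coexpression uses the biweight midcorrelation (bicor), an
outlier-robust correlation with weights `(1 - u^2)^2` for
`u = (x - med) / (9 MAD)`; zero-MAD genes fall back to Pearson. Genes are
clustered with complete linkage on `1 - bicor` and the dendrogram is cut at a
*static height* corresponding to a stated top fraction of the correlation
matrix; the mapping is formalized as `height = 1 - q`, with `q` the matching
off-diagonal quantile. Clusters below the minimum size stay unassigned.
Modules are summarized by their eigengene (first right singular vector of the
standardized member genes, sign-aligned to the members) and merged
iteratively while any eigengene pair correlates above the merge threshold
(0.80 for bulk, 0.85 for pseudobulk and differential coexpression). Module
membership is then expanded genome-wide by kME (Pearson correlation to the
eigengene) at BH FDR 0.05, each significant gene joining its best module.
Finally, eigengenes are correlated with each clone's *cumulative* abundance
(clone plus descendants; purity for the truncal clone) to assign modules to
clones.

One equivalence worth knowing: for the truncal clone, the nonmalignant
compartment is the exact complement of purity, so a module of nonmalignant
markers can tie the truncal module in absolute correlation (equal |r|,
opposite sign). Both describe the same axis of variation.

## Differential coexpression

Tumor-specific coexpression subtracts normal-brain structure: correlation
matrices are affinely scaled to [0, 1] (`(1 + r) / 2`), each normal matrix is
subtracted from the tumor matrix, and the consensus is the elementwise
minimum over normals — a gene pair scores high only if it co-varies more in
tumor than in *every* normal series. Modules are detected on the consensus
with the same static-cut machinery (the cut height is capped below distance
1, since nonpositive consensus values mean no tumor-specific excess);
eigengenes and kME are computed back on the tumor expression matrix.

The cut fraction must exceed the mass of truly tumor-specific gene pairs: at
desk scale the planted programs occupy ~1-2% of all pairs, so the
acceptance test cuts at the top 5% (the module default stays at the stated
2%, appropriate when specific coexpression is sparse relative to the
matrix).

## Lasso stability selection

Each gene's expression is regressed on the standardized cumulative
clone-abundance vectors along an L1 path (100 log-spaced penalties,
strongest first). The selection rule — the first path point at which exactly
one penalized predictor survives — formalizes "only models with one
surviving clonal frequency vector". In group mode the truncal clone is its
own unpenalized group (implemented as a zero penalty factor): the purity
vector is the dominant axis of variation and absorbs inflated correlations,
and leaving it unpenalized stops it from competing with subclonal signal. A
true two-group L2 penalty would give all-or-nothing survival within the
non-truncal group and could never yield exactly one survivor, so the
penalty-factor formalization is the faithful reading of the rule.

Stability is the number of bootstrap resamples (sections resampled with
replacement, n = 100) in which the modal surviving predictor is the sole
survivor. An empirical null repeats this after permuting each gene's
profile, and the significance threshold is the smallest stability value
above which at most 5% of surviving models are permuted — a plain
permutation FDR, checked against a brute-force scan in the tests. Strongly
collinear clone vectors can make a different clone enter the path first on
individual fits (the partial signal after the unpenalized truncal column
decides); the bootstrap exists precisely to expose that instability as a low
stability count.

## Pseudobulk and single-nucleus validation

The pseudobulk argument is an algebraic identity plus a simulation: for any
gene, correlating expression with a 0/1 malignancy vector reproduces the
pooled-variance two-sample t-test p-value exactly (point-biserial identity,
asserted to 1e-10), so correlation-to-abundance in aggregates is a
continuous generalization of differential expression. On simulated
two-population single-cell data, pseudobulk samples (sums over random 10%
subsets of cells, malignant fraction tracked) yield a module whose eigengene
correlates with the true malignant fraction at r >= 0.95 and whose
genome-wide kME reproduces single-cell DE t-values at r >= 0.8.

Single-nucleus genotyping calls each truncal locus mutant / wildtype /
indeterminate from amplicon reads (defaults: 10 reads minimum, variant
fraction 0.1 — the original calls came from a variant caller whose
thresholds are not printed), then sorts nuclei into three exhaustive
categories: *called* (two or more concordant calls, at most one
indeterminate; malignant if the agreement is mutant — allele dropout
explains a lone wildtype), *discrepant* (exactly two wildtype plus one
mutant), *insufficient* (two or more indeterminate, or an unresolvable
mixed pattern such as one call of each kind). Expression-based CNV-caller
outputs are evaluated against these genotypes by confusion-matrix
sensitivity, specificity and accuracy, excluding unknown-truth nuclei.

## Cross-case integration

Per-gene purity correlations from independent tumors are combined by
Fisher's z with weights `n - 3`; the combined estimate is the inverse
transform of the weighted mean and the test statistic divides it by the
joint standard error. Consistent genes must clear the per-case |r| threshold
with the same sign in every case (sign discordance excludes a gene) and a
BH q below 0.05 on the combined p. The sectioning-design power calculator
uses the Fisher-z approximation with the small-sample bias term
`r / (2(n-1))` and the exact-t critical correlation; it agrees with Monte
Carlo simulation to under 0.005 at the design points used here (n = 69 and
n = 90 at r = 0.3).

# The synthetic world

## What the generator emulates

`simulate_serial_tumor()` draws a random phylogeny (uniform attachment),
spatial clone-mixing profiles, amplicon read counts (Poisson depth, binomial
allele sampling), bulk expression for the tumor and four matched normal
series, and single-nucleus reads with allele dropout. Defaults follow the
study design the package models: 69 usable tumor sections, ~17,000x mean
amplicon coverage, three genotyped truncal loci, four normal series of 94
sections, 809 nuclei with a median of ~200 reads per locus, purity spanning
roughly 0.35-0.85.

Clone mixing is built hierarchically in cumulative space: purity follows a
smooth profile, and each child clone occupies a smoothly varying *share* of
its parent's clade, sweeping up to 90% of it at bump peaks and receding to
near zero elsewhere — clonal succession along the section axis, the pattern
the estimated fractions of real serially sectioned tumors show. Profiles are
redrawn (rejection sampling, ~0.6 redraws per tumor) until the tumor is
*clonally identifiable*: every wrong topology must violate the
exact-genotype constraints by at least 0.03 prevalence units (well above
binomial noise at 10,000x depth) and clone profiles must be pairwise
separated. Without this screen ~5-9% of random draws admit several
topologies that fit the noiseless prevalence matrix exactly; such tumors are
genuinely ambiguous — no method can pick the true tree from their sections —
and the reconstruction correctly flags them as ties. The screen makes
"recoverable tumor" part of the stated world rather than a property left to
chance.

Expression is an abundance-weighted mixture of population signatures
(markers of a clone are expressed throughout its clade, so they track
cumulative abundance) with CNV dosage multipliers (gain x1.5, hemizygous
loss x0.5, cn-LOH neutral — linear dosage on a two-copy baseline), Gaussian
noise, and a per-population latent *program factor*: lightly smoothed noise,
residualized against all abundance profiles and scaled to the population's
own abundance-driven signal. The factor models coordinated regulatory
variation beyond cell composition; statistically it tightens within-module
correlations and dilutes between-module correlations, exactly as real
coexpression data behave. Residualization matters: at ~70 sections even
independent smooth draws correlate incidentally (|r| up to ~0.4) with the
equally smooth abundance profiles and would contaminate eigengene-clone
correlations. The default noise SD (0.05) is half the typical
abundance-driven signal SD (~0.1), the intended reading of the "noise at
most half the signal" recovery regime.

`planted_clone_world()` fixes a representative branching phylogeny and
*designed* niche geometry (flat-top windows; truncal peak between two
lineage territories, each with one deeper subclone) with moderate pairwise
profile correlations, wide identifiability margins and per-clone abundance
SDs above 0.05. The transcriptional acceptance tests run on this world: a
clone whose abundance barely varies, or whose profile parallels another's,
is transcriptionally invisible no matter how good the method — the original
study saw exactly this for its low-frequency clone, which yielded no module.

## What a green test does and does not establish

The simulations stay well below real-data scale (1,000 genes vs ~20,000;
Gaussian noise on a linear scale rather than platform-specific error;
no batch effects, doublets or segmentation error; CNV segments are inputs,
not calls). A green suite establishes that every algorithm does what its
contract says on data generated by its own stated model, at stated noise —
not that the pipeline is robust to the full messiness of real multiomic
data. The genotype-category fractions, for example, depend strongly on
amplicon depth: at the simulated ~200 reads per locus nearly every nucleus
is called, whereas real data with variable capture produce a substantial
insufficient-data fraction.

# Numerical choices and edge cases

- Coordinates are 0-based half-open internally; VCF (1-based) and BED
  (0-based) convert at the I/O boundary. Zero-depth VAFs are explicit `NA`
  and excluded pairwise from correlations.
- Read downsampling is hypergeometric (without replacement) — reads are
  finite; entries whose observed depth falls below the target stay at full
  coverage and are logged.
- The constrained least-squares solver treats active-set candidates whose
  KKT system is singular as skipped; the all-zero solution is always
  feasible, so the search space is never empty.
- Eigengene signs follow the mean correlation with member genes; constant
  genes are dropped with a warning.
- `fisher_enrichment()` reports the cross-product odds ratio and the
  one-sided hypergeometric p; q-values are BH across all tested pairs.
- Degenerate dissimilarities (all points identical) short-circuit to k = 1.
- All stochastic functions take an explicit seed and restore the caller's
  RNG state; identical seeds reproduce every artifact byte-for-byte.

# Known limitations

- Tree enumeration is exact only to k = 7 clusters; larger trees need a
  heuristic search that this package deliberately does not provide.
- The prevalence model is linear in allele counts; extreme copy numbers or
  subclonal CNV interactions within one locus are out of scope.
- Mutations whose allele state differs *within* a clade (e.g. a CNV
  affecting only part of the carriers) have no single (m, t) context for
  prevalence inversion; the reconstruction pipeline assumes a shared
  context per mutation.
- The consensus cluster-count rule, the 1% tree tie tolerance, and the
  per-locus genotype thresholds are documented package choices where the
  original methods left the value unstated.
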