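---
title: "Methylation inheritance in hybrids from msGBS counts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation inheritance in hybrids from msGBS counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epihybrid)
```

## What the data are

Methylation-sensitive genotyping-by-sequencing (msGBS) digests genomic DNA
with a methylation-sensitive enzyme such as *Hpa*II before library
construction. Methylation at a recognition site blocks the cut, so the
read count observed at a cut-site locus is a *decreasing* function of the
methylation level of that site in that sample. The unit of analysis is
therefore a locus × sample matrix of non-negative integer counts, with a
per-sample library size; nothing in the downstream analysis requires the
underlying methylation fraction itself, only relative count differences.

The motivating design is a natural hybrid zone: two divergent parental
species (one outcrossing, one predominantly self-fertilizing) sampled in
sympatry, plus a small number of F1 hybrids. The package encodes this as
groups `parent1`, `parent2` and `hybrid`, with defaults of 22, 17 and 5
individuals in the simulator.

## Normalization and the occupancy filter

Counts are normalized as counts per million,
$\mathrm{CPM}_{ij} = c_{ij}\,10^6 / L_j$, with $L_j$ the *total* library
size of sample $j$ taken from the sample sheet. Column sums of the count
matrix are deliberately not used as $L_j$: the sequenced library includes
reads at loci later filtered out, and using total library size keeps the
transform exactly invertible. A fallback to column sums exists for sheets
without library sizes.

For a two-group comparison, a locus is tested only if its CPM exceeds the
threshold (default 1, *strict* inequality — "more than one count per
million") in at least $n$ individuals of *each* group, where $n$ defaults
to the size of the smaller group. The filter is applied per comparison,
not globally, because each comparison involves different groups and hence
a different $n$; a joint all-group filter is available for the pooled
ordination. No trimmed-mean scaling is applied: normalization is by
library size only, with everything else absorbed by the test's
conditioning.

## The exact conditional NB test

Let the two groups have $n_A$ and $n_B$ samples with counts scaled to a
common effective library (the mean library size of the compared samples),
and let $z_A$, $z_B$ be the rounded group totals at one locus with
$z = z_A + z_B$. Under negative-binomial sampling with common mean and
dispersion $\varphi$, the distribution of $z_A$ conditional on $z$ is

$$\Pr(z_A = a \mid z) \propto
  f_{NB}(a;\, n_A/\varphi,\, n_A \mu)\,
  f_{NB}(z - a;\, n_B/\varphi,\, n_B \mu), \qquad \mu = z/(n_A+n_B),$$

which removes the unknown locus mean. The two-sided p-value sums the
probabilities of all splits whose probability does not exceed that of the
observed split (minimum-likelihood rule, ties included, with a relative
tolerance of $10^{-7}$ for floating-point ties). At $\varphi = 0$ the
conditional distribution is exactly $\mathrm{Binomial}(z, n_A/(n_A+n_B))$,
which the test suite exploits as a closed-form oracle on an enumerated
grid of totals.

The dispersion is estimated by maximizing the conditional log-likelihood
(conditioning on each group's locus total) pooled over loci and groups —
the classic conditional-likelihood construction for small-sample NB
data — with continuous library-size-equalized counts plugged into the
gamma-function form. Per-locus maxima are shrunk toward the common value
by a fixed-weight convex combination, weight 0.8 on the common value by
default: with only five hybrids per group, per-locus estimates alone are
far too noisy. Cross-checks in the test suite show the estimator and the
resulting p-values track edgeR's independent implementation closely
(log-p correlation > 0.99) while remaining fully self-contained.

log₂ fold changes are computed on group mean CPMs with a pseudo-count of
0.5 CPM to avoid infinities at zero means. With the hybrids as the focal
group, positive logFC means more reads — more cutting, hence *less*
methylation — in hybrids ("hypomethylated in hybrids"); direction is
assigned by sign. DMCs are loci with Benjamini–Hochberg q-value below the
threshold (default 0.01); a threshold of exactly 1 is treated as
inclusive so "keep everything" configurations behave as expected.

## Inheritance classification

At each DMC the three group mean CPMs are compared. The hybrid mean inside
the *closed* parental interval is additive; strictly above the larger
parental mean, overdominant; strictly below the smaller, underdominant.
Boundary equality is assigned to additive because transgression is defined
strictly ("higher or lower" than the parents), and with continuous CPMs
exact ties have measure zero anyway. Group means (not medians) are used,
matching the logFC machinery. The three modes always partition the loci,
and the classification is symmetric in the parental labels.

Two DMC sets matter in practice and are both produced by the pipeline:
the parental DMC set (species vs species) for the overall additivity
fraction, and the common set (significant against *both* parents) for the
transgressive bookkeeping. Percentages are reported to one decimal.

## Genomic context

A locus is a promoter hit if it lies within the promoter window (default
2000 bp) *upstream* of a gene's strand-aware start — upstream of `start`
for `+` genes and of `end` for `-` genes, excluding the gene body itself.
Otherwise it is a gene-body hit if contained in a gene, intergenic if on
an annotated scaffold but in neither, and unannotated if its scaffold
carries no annotation at all. Precedence promoter > gene body >
intergenic makes the four categories mutually exclusive and exhaustive,
so the counts always sum to the number of input loci — the property that
makes the percentage bookkeeping exact. When several genes compete, the
nearest strand-aware start wins, then lexicographic gene id. "Unannotated
= scaffold without genes" is one defensible operationalization of
unplaced/unannotated regions; both the scaffold set and the window are
arguments.

## Distances, ordination, and the pairwise mixed model

Ordination uses classical MDS (principal coordinates): double-centred
Gram-matrix eigendecomposition via `stats::cmdscale`, with two
determinism refinements — each axis's sign is fixed so its
largest-magnitude coordinate is positive, and axes whose eigenvalues are
numerically zero (relative tolerance $10^{-8}$) are zeroed and flagged
rather than carrying noise. On genuinely Euclidean input the embedding
reproduces the distances to machine precision, which the tests assert at
$10^{-9}$.

Bray–Curtis dissimilarity is used for both SNP-dosage and methylation
profiles, $d(u,v) = \sum_i |u_i - v_i| / \sum_i (u_i + v_i)$, with
pairwise deletion of markers missing in either member of a pair (never
imputation) and $d = 0$ defined for pairs with no shared non-zero mass.

The Mantel test correlates the lower triangles of two distance matrices
(Pearson) and permutes sample labels of the second matrix jointly on rows
and columns; $p = (1 + \#\{r_\pi \ge r_{obs}\})/(1 + B)$, one-tailed for
positive association since the scientific hypothesis is a positive
genome–methylome relationship. The permutation stream is seeded, so runs
are reproducible.

Because pairwise distances are not independent observations, the
epigenetic-distance regression uses an MLPE-style Gaussian mixed model:
each unordered pair contributes one row, with genetic distance, the two
sampling sites and the two species as fixed effects and crossed random
intercepts for the identity of each pair member. The two "slots" of a
pair are filled in the fixed sample order of the distance matrices
(the convention the pair-slot covariates require, stated here because it
is otherwise ambiguous). Both the mixed and the fixed-effects-only models
are fitted by maximum likelihood, not REML, so AIC and likelihood-ratio
comparisons between them are valid. Single-level factors (e.g. one
sampling site) are dropped from the fixed part automatically; constant
genetic distances are a hard error rather than a silent zero slope.

## The simulator and what it does (not) emulate

`simulate_experiment()` generates data *on the expected-count scale*:
a methylation fraction $m$ at an accessible site maps to expected CPM
$\propto (1 - m)$, and since the analysis only ever sees counts, the
simulator parameterizes expected CPM directly. Per-locus baselines are
log-normal (meanlog $\log 10$, sdlog 1 — a long-tailed abundance
distribution whose median CPM ≈ 10 gives realistic per-locus coverage at
a $10^6$-read library); library sizes are log-normal with mean $10^6$ and
CV 0.3; counts are negative-binomial with dispersion 0.2, a typical
value for reduced-representation count data. A fraction (default 0.2) of
loci are species-divergent, split symmetrically by `effect_log2fc`
(default 3, an 8-fold difference) on the log₂ scale. Hybrid means at
divergent loci follow the inheritance mix (default 0.9/0.06/0.04
additive/over/under): additive hybrids sit at the log-scale midpoint of
the parents, matching the classifier's closed-interval geometry to first
order, and transgressive hybrids sit `transgressive_log2fc` (default 1,
i.e. 2-fold) beyond the nearer parent.

SNP dosages mix fixed species-diagnostic markers (0 in parent1, 2 in
parent2, heterozygous 1 in F1s) with shared polymorphic markers. The
shared fraction matters: a panel of *only* diagnostic markers makes the
Bray–Curtis distance between a hybrid (all 1s) and the dosage-0 parent
equal to 1 — farther than the parents are from each other — whereas real
panels contain segregating variation that places hybrids between the
parental clusters, which is the geometry the ordination analyses rely on.

Gene models tile three quarters of the scaffolds (5 kb genes every 25 kb,
alternating strand) so that all four context categories are populated;
the remaining scaffolds are unannotated. One global seed drives
independent sub-streams for locus geometry/counts, library sizes and
genotypes, so changing the marker panel does not perturb the simulated
counts.

The simulator does **not** emulate read-level artifacts (PCR duplicates,
mapping error, allele-specific cutting), spatial correlation of
methylation along the genome, backcross genotypes, or environment-driven
methylation differences between sampling sites. Passing tests on this
generator therefore demonstrate correctness of the statistical machinery
under the stated model, not robustness to those real-data complications.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle where
one exists and against simulation truth otherwise: binomial tail sums for
the zero-dispersion exact test (totals up to 50, agreement to $10^{-12}$);
edgeR as an independent NB implementation; dispersion recovery from
Poisson and NB(0.4) draws; null calibration of the DMC pipeline over 20
replicates of 2,000 loci (10 vs 10 samples, dispersion 0.3); recovery of
a 0.9 additive fraction among common DMCs at 5,000 loci; exact MDS
geometry on known 3-D point sets; Mantel type-I error over 200 replicates
of 8 samples with 999 permutations; MLPE slope recovery at 30
individuals; and byte-identical pipeline determinism on a 500-locus
dataset. These sizes keep the full suite around two minutes while leaving
each stochastic check enough resolution to be meaningful.

## Known limitations

* The exact test conditions on rounded library-size-equalized totals;
  with wildly unequal library sizes the rounding is a coarser
  approximation than edgeR's quantile adjustment, though the two agree
  closely at realistic CV.
* The per-locus dispersion shrinkage weight is fixed, not empirical-Bayes
  adaptive; with the default 0.8 the test behaves essentially like a
  common-dispersion test, which is the sane regime for five hybrids.
* The occupancy filter's $n$ follows the "smallest compared group" rule;
  published analyses sometimes report other values of $n$ for specific
  comparisons, so `filter_loci()` and `call_dmcs()` accept an explicit
  override.
* Context annotation is point-based (cut sites), with no exon/intron or
  CpG-island resolution, and GO enrichment is out of scope.
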