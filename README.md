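# epihybrid

DNA-methylation inheritance analysis for methylation-sensitive
genotyping-by-sequencing (msGBS) data from natural hybrids and their
parental species.

## The problem

msGBS libraries digest genomic DNA with a methylation-sensitive restriction
enzyme (e.g. *Hpa*II): methylation at a cut site blocks digestion, so the
number of sequenced reads at a cut-site locus *decreases* with methylation.
A locus × sample read-count matrix therefore carries a quantitative
methylation signal, and two-group differences in normalized counts identify
differentially methylated cytosines (DMCs).

For a hybrid system with two parental species (e.g. an outcrossing and a
self-fertilizing mangrove killifish living in sympatry) the questions are:

1. Which cut-site loci are differentially methylated between the species,
   and between the F1 hybrids and each species?
2. At DMCs, is hybrid methylation **additive** (intermediate between the
   parental means), **overdominant** (above both) or **underdominant**
   (below both)?
3. Where do DMCs fall in the genome (promoter, gene body, intergenic)?
4. How strongly do genome-wide genetic distances predict methylome
   distances (Mantel test; pairwise mixed model with crossed individual
   random effects)?

`epihybrid` implements this whole path, plus a negative-binomial simulator
with known truth labels so every stage can be validated without any
external data.

## Methods in brief

* **Normalization and filtering.** CPMᵢⱼ = countᵢⱼ · 10⁶ / library_sizeⱼ.
  A locus is kept in a comparison if CPM > 1 in at least *n* individuals of
  each group, with *n* the size of the smallest group.
* **DMC test.** Counts are scaled to equal effective library sizes and an
  exact conditional test is applied to each locus's split of reads between
  the groups: under NB(μ, φ) sampling, the group-A total conditional on the
  locus total follows a known discrete distribution; the two-sided p-value
  sums the probabilities of all splits no more likely than the observed one.
  At φ = 0 this is exactly the conditional binomial test. The common
  dispersion φ is estimated by pooled conditional maximum likelihood and
  per-locus estimates are shrunk toward it. q-values are Benjamini–Hochberg;
  DMCs are q < 0.01 by default. log₂FC uses group mean CPM with a 0.5-CPM
  pseudo-count; with hybrids focal, positive log₂FC = more reads = *hypo*-
  methylation in hybrids.
* **Inheritance.** At each DMC, hybrid mean CPM inside the closed parental
  interval ⇒ additive; strictly above/below ⇒ over-/under-dominant.
* **Context.** A locus within 2 kb upstream of a strand-aware gene start is
  a putative promoter; inside a gene, gene body; otherwise intergenic;
  loci on scaffolds without annotation are unannotated. Precedence
  promoter > gene body > intergenic makes the categories a partition.
* **Distances.** Euclidean distances + classical MDS (principal
  coordinates) for ordination; Bray–Curtis distances on SNP dosages
  (pairwise deletion of missing genotypes) and on DMC CPM profiles; Mantel
  test (Pearson r, one-tailed permutation p); and a Gaussian mixed model of
  pairwise epigenetic distance with genetic distance, sites and species as
  fixed effects and crossed random intercepts for the two pair members
  (MLPE), fitted by maximum likelihood for AIC comparison.

## Worked example

```r
library(epihybrid)

sim <- simulate_experiment(simulation_params(n_loci = 1000, seed = 7))
sim$counts
#> msGBS count matrix: 1000 loci x 44 samples
#>   groups: hybrid=5, parent1=22, parent2=17
#>   library sizes: 5.15e+05 - 1.84e+06

hvp1 <- call_dmcs(sim$counts, "hybrid", "parent1")
hvp1
#> DMC comparison hybrid vs parent1 (focal: hybrid)
#>   801 / 1000 loci tested after occupancy filter (n = 5)
#>   124 DMCs at FDR < 0.01 (63 hypo, 61 hyper in focal group)

hvp2 <- call_dmcs(sim$counts, "hybrid", "parent2")
common <- intersect_dmcs(hvp1, hvp2)   # 74 loci significant vs both parents

summarize_inheritance(classify_inheritance(sim$counts, common))
#> inheritance of 74 DMCs:
#>   additive          67 (90.5%)
#>   overdominant       7 (9.5%)
#>   underdominant      0 (0.0%)

epi <- bray_curtis_distances(t(cpm_normalize(sim$counts)[common, ]))
gen <- bray_curtis_distances(t(sim$genotypes$genotypes))
mantel_test(epi, gen, seed = 7)
#> Mantel test: r = 0.882, p = 0.001 (999 permutations, seed 7)
```

The 44 samples mirror a 22 + 17 + 5 parent/parent/hybrid design; 20% of
loci are simulated species-divergent with a 90/6/4 additive/over/under
inheritance mix, and the analysis recovers a predominantly additive
partition (90.5% here) together with a strong genome–methylome distance
correlation, as expected when methylation differences track genetic
divergence. `run_pipeline()` chains all stages (three comparisons, common
DMCs, inheritance, context, MDS/clustering, Mantel, mixed model) and writes
TSV outputs plus a JSON-lines manifest.

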