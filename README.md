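# AMGsurveyor

Marine bacteriophages reprogram host metabolism during infection with
**auxiliary metabolic genes (AMGs)** — host-derived metabolic genes carried
on virus genomes. Estimating how common AMGs are across ocean virus
communities, and which metabolic pathways they target, requires a long chain
of careful bookkeeping on assembled metagenomes: deciding which contigs are
viral, collapsing them into species-rank populations, separating genuine
virus-encoded metabolic genes from cellular contamination, and correcting
for the fact that fragmented assemblies hide AMGs that complete genomes
would reveal. `AMGsurveyor` implements that chain as a tested, reusable R
package for microbial ecologists and viromics researchers.

## What the package computes

- **Screening and vOTU clustering.** Contigs ≥ 5 kb with a virus score
  ≥ 0.75 and a "dsDNA phage"-maximal classifier are greedily clustered into
  virus populations at ≥ 95% average nucleotide identity (ANI) over ≥ 80%
  aligned fraction of the shorter sequence, longest first
  (`screenContigs()`, `clusterPopulations()`). A built-in k-mer-anchored
  ANI estimator (`estimateSimilarity()`) serves desk-scale data; external
  aligner tables are accepted too.
- **AMG curation.** A *permissive* catalog (bit score ≥ 60, metabolic
  module and/or known AMG, auxiliary score ≤ 3; `callPermissive()`) is
  refined into a *conservative* catalog by three rules
  (`applyConservativeRules()`): containment in a viral region or a
  confident (≥ 0.95) virus score; containment within prophage boundaries
  inferred from tRNAs and exact inverted/direct repeats
  (`detectPhageEnds()`); and a contig-wide mobile-element blacklist
  (transposases, integrases, endonucleases, plasmid-stability genes,
  lipopolysaccharide-island genes). Every decision is recorded in a
  per-gene trail.
- **Gene clusters and novelty.** Longest-first greedy clustering with
  alignment identity/coverage thresholds (`greedyCluster()`), and novelty
  assessment by co-clustering catalog proteins with published reference AMG
  proteins at 30% identity / 60% coverage (`assessNovelty()`).
- **Fragmentation correction.** Complete genomes are tiled into fragments
  whose lengths follow the survey distribution truncated to its 10th–90th
  percentiles, resampled with replacement to mimic the survey
  (`fragmentGenomes()`, `resampleFragments()`), yielding a conversion
  factor `f_true / f_obs` that corrects observed AMG-carrying fractions
  (`estimateConversionFactor()`, `applyConversion()`).
- **Pathway context.** A KEGG-style module-definition parser and stepwise
  completeness evaluator (`parseModuleDefinition()`,
  `stepwiseCompleteness()`) classify pathways as microbially present,
  complete (≥ 0.75), AMG-targeted, and AMG "hot-spots"
  (`classifyPathways()`).
- **Abundance and enrichment.** Read filters (≥ 95% identity, ≥ 75% read
  coverage), a 5%-both-tails trimmed-mean depth with a 70% breadth gate
  normalized per giga-read, paired-sample summation, and KO-level
  virus-versus-microbe fold ratios (`trimmedMeanAbundance()`,
  `populationAbundance()`, `koEnrichment()`).
- **Synthetic data.** A seeded generator (`amgSimParams()`,
  `generateSurveyContigs()`, `generateReferenceGenomes()`,
  `generateDepthProfiles()`) emulates the survey's statistical structure —
  sporadic AMG placement, prophages with tRNA/repeat-marked cellular
  flanks, blacklist contamination, lognormal contig lengths — with
  ground-truth sidecars, so the full pipeline runs and is tested without
  any downloads.

## Worked example

```r
library(AMGsurveyor)

report <- runPipeline(amgRunConfig(sim = amgSimParams(seed = 1L), seed = 1L))
report$n_populations
#> [1] 172
report$n_amgs_conservative
#> [1] 87
round(report$mean_amgs_per_carrier, 2)
#> [1] 2.12
round(report$conversion_factor, 2)
#> [1] 1.12
round(100 * report$corrected_fraction_conservative, 1)
#> [1] 26.7
```

Here 227 simulated contigs collapse into 172 populations; 87 conservative
AMGs survive curation (2.12 per carrier population); the mock-community
simulation estimates that fragmentation hides AMG carriers by a factor of
1.12 at this synthetic scale, lifting the observed 23.8% carrying fraction
to an estimated 26.7%.

The survey bookkeeping itself is one call:

```r
bk <- bookkeepingChain(86913, 51666, 579904, factor = 2.1,
                       n_previous = 488130)
round(100 * bk$observed_fraction)    # 9   — observed carrier percentage
round(100 * bk$corrected_fraction)   # 19  — fragmentation-corrected
round(bk$mean_per_carrier, 1)        # 1.7 — AMGs per carrier population
```

A thin command-line wrapper is included at
`inst/scripts/amg-surveyor` (`simulate` and `run` subcommands over a YAML
configuration).

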