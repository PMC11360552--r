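---
title: "Methods: cataloging auxiliary metabolic genes in ocean virus metagenomes"
author: "AMGsurveyor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cataloging auxiliary metabolic genes in ocean virus metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bacteriophages carry host-derived metabolic genes — auxiliary metabolic
genes (AMGs) — that can reprogram host metabolism during infection.
Quantifying how widespread AMGs are across an ocean virus community from
assembled metagenomes is a bookkeeping problem with several failure modes:
cellular metabolic genes masquerade as AMGs on prophage flanks and mobile
elements, assembled fragments hide AMGs that the complete genome carries,
and gene-level read mapping cannot tell a viral AMG from its cellular
homolog. `AMGsurveyor` implements the full analysis chain with explicit,
auditable decisions at each of these points.

## Screening and population clustering

Contigs are screened on three gates: length at least `min_len` (default
5,000 bp), virus-identification score at least `min_score` (default 0.75),
and a classifier profile maximized by the "dsDNA phage" group. A tie
between "dsDNA phage" and another group is treated as dsDNA-maximal: the
screen is deliberately permissive because the conservative curation rules
follow downstream. The upstream two-pass identification protocol is
modeled as a single decision on the final score fields.

Surviving contigs are clustered into species-rank populations (vOTUs) at
ANI ≥ 95% over aligned fraction ≥ 0.80. Two choices here were genuinely
open and are fixed as follows:

* **Aligned fraction is measured on the shorter sequence**, following
  common vOTU practice; it is configurable.
* **Clustering is greedy, longest-first, first-fit**: contigs sorted by
  length descending (ties by lexicographically smallest id) join the first
  existing representative that meets both thresholds, else found a new
  population. This mirrors the behavior of the commonly used
  cluster-genomes style tools, which do not specify tie-breaking; the
  sort makes the partition independent of input order.

Similarity can come from any external whole-genome aligner as a TSV. The
built-in estimator anchors exact 15-mers, merges anchors per diagonal into
gap-free blocks, chains blocks colinearly maximizing matched columns, and
computes identity position-wise over the chained blocks. It is intended
for synthetic and desk-scale data, not as a replacement for a production
aligner: diagonal-level block merging assumes mutations are roughly
uniform, which holds for the generator but not for biological mosaicism.

## AMG curation

The **permissive catalog** admits a gene iff annotation bit score ≥ 60, it
is assigned to a metabolic module and/or matches a previously described
AMG, and its auxiliary score (confidence that the gene is virus-encoded;
1 = flanked by viral genes on both sides) is ≤ 3.

The **conservative catalog** applies three ordered rules, each recorded
per gene in a decision trail:

* **R1 (viral region):** keep iff the gene interval lies fully inside a
  called viral region, or the contig's virus score is ≥ 0.95. "Fully
  inside" is the conservative reading — partial overlap does not count.
  The two conditions are combined with OR.
* **R2 (prophage ends):** tRNA features and maximal exact inverted/direct
  repeat pairs near the boundaries of the interval under test are
  collected; a bracketing repeat pair (or flanking tRNAs) defines an
  inferred phage interval, and candidates must lie fully inside it. The
  original end-handling scenarios are not fully recoverable from the
  upstream description, so containment in the bracketed interval is the
  documented stand-in, and the rule can be switched off
  (`use_phage_ends = FALSE`).
* **R3 (blacklist):** every candidate on a contig carrying at least one
  transposase, integrase, endonuclease, plasmid-stability,
  glycosyltransferase, nucleotidyl-transferase, carbohydrate-kinase, or
  nucleotide-sugar-epimerase gene is dropped, regardless of the
  candidate's own position — these contigs may be hypervariable islands
  whose metabolic genes are cellular.

Repeat detection uses exact matches with a minimum arm of 20 bp within
1,000 bp of the interval boundaries; a mismatch-tolerant mode is not the
default because exact arms are what the generator plants and what an
EMBOSS-style detector with standard settings reports most robustly.
Maximal extension of an exact repeat can absorb a few coincidentally
matching flanking bases, so inferred boundaries may differ from planted
ones by a base or two — the containment rule is insensitive to this. The
auxiliary score itself is consumed as an input column, never recomputed.

## Gene clusters and novelty

Conservative AMG nucleotide sequences are clustered longest-first,
first-fit with alignment identity ≥ 0.90 and member coverage ≥ 0.90;
protein novelty co-clusters catalog and published reference AMG proteins
at identity ≥ 0.30 and coverage ≥ 0.60, and a catalog cluster is novel iff
its co-cluster contains no reference. The nucleotide identity threshold is
an interpretation: the upstream tool invocation pins coverage (0.9) but
leaves identity unset, so 0.90 — the species-like rank used elsewhere in
the pipeline — is the default and is configurable.

Pairwise identity is matches over alignment columns from a local
alignment with match +1, mismatch −1, gap −2; coverage is the aligned
span of the member over its length. Equal-length ties in the greedy order
break lexicographically. A shared-k-mer prefilter (11-mers, ≥ 3 hits)
skips hopeless nucleotide alignments; it is bypassed below 50% identity
thresholds (e.g. the 0.30 novelty run) where exact k-mer sharing is no
longer a reliable witness.

## The fragmentation conversion factor

Assemblies rarely recover complete genomes, so a population whose
fragment lacks an AMG may still carry one. The mock-community simulator
quantifies this: complete genomes are tiled left-to-right with fragment
lengths drawn from the empirical survey length distribution truncated to
its 10th–90th percentiles (linear interpolation). Drawing from the
empirical distribution — rather than uniformly within the bounds — makes
the tiling itself mimic survey assembly. A terminal remainder shorter
than the lower bound excludes the whole population (mirroring the
drop of out-of-bounds mock populations); a merge-into-last-fragment mode
exists but is off by default. An AMG counts in a fragment iff its gene
interval is fully contained, so boundary-straddling AMGs are invisible —
fragmentation can only hide AMGs, never invent them, which is the
mechanism the correction captures.

Fragments are resampled with replacement (default n = 4,000) with weights
proportional to target-bin mass over source-bin mass in 1-kb bins. The
conversion factor is `f_true / f_obs` with `f_true` the fraction of kept
populations carrying ≥ 1 AMG on the complete genome and `f_obs`, by
default, the fraction of resampled fragments with ≥ 1 contained AMG. The
printed survey arithmetic is ambiguous between a per-fragment and a
per-population observed rate, so both modes are exposed
(`f_obs_mode = "fragment"` / `"population"`) and neither is asserted as
the original; the default is per-fragment. A bootstrap over the resample
gives a confidence interval, and corrected fractions are capped at 1.

## Pathway completeness and hot-spots

Module definitions follow the KEGG convention: top-level space-separated
tokens are steps; within a step `,` is OR, `+` (or a space inside
parentheses) is AND, `-`-prefixed components are optional, and `--` is a
gap step. Optional components never count toward or against satisfaction
(an AND whose evaluable children are all optional is vacuously satisfied;
an OR with none left is not); `--` counts in the denominator and is never
satisfied. Completeness is satisfied steps over total steps, with
"complete" at ≥ 0.75.

A module is *AMG-targeted* when it is microbially present (≥ 1 step
satisfied by microbial KOs) and ≥ 1 step is satisfied by the pooled viral
AMG KOs; an alternative mode counts any AMG KO occurring anywhere in the
definition, since the survey's targeting count does not pin the minimum.
*Hot-spots* are targeted modules whose viral completeness reaches the
threshold; the viral KO set is pooled across all virus populations, so a
hot-spot is a community-aggregate signal, not a claim about any single
virus.

## Abundance and enrichment

Reads are retained at ≥ 95% identity and ≥ 75% read coverage; retained
intervals stack into per-position depth vectors. A contig's abundance in
a sample is zero if breadth (fraction of covered positions) is below
0.70; otherwise it is the mean depth after discarding the top and bottom
`floor(0.05 · L)` positions by depth, normalized by the sample's total
reads and scaled per 10⁹ reads. The per-giga-read scale is a readability
choice (typical synthetic abundances land near the planted depths); only
"normalized by total reads" is inherited. Floor-counting the trim means
vectors shorter than 20 positions are not trimmed at all. Population
abundances sum the representative contig's normalized abundances over the
two paired fractions (virus- and prokaryote-enriched) of a station.

KO-level enrichment compares, per KO: the arithmetic mean over
AMG-carrying populations of their abundance summed across paired samples
(viral side), against the summed microbial KO abundance. Whether the
survey's per-KO viral mean is over per-sample values or sample-summed
totals is unstated; sample-summed is the default, with the per-sample
mode available for exploration. Division by a zero microbial abundance is
reported as the status `"microbe-absent"`, never as an infinite fold.

## What the generator emulates — and what it does not

The synthetic generator is the package's study-condition stand-in. Its
defaults encode the modeled survey: 81 mock reference populations with
86% AMG-carrying and zero-truncated Poisson AMG counts fitted to mean
11.1 truncated at 25 (the truncation-fitted rate is solved numerically);
survey contigs with lognormal lengths around a 12,608 bp median. Prophage
contigs (5%) get an internal viral region whose boundaries carry a
planted exact repeat pair (25 bp arms, direct or inverted) and an
upstream tRNA, AMGs planted both inside the region and on the cellular
flanks; blacklist contigs (8%) carry flagged mobile-element genes;
off-target contigs (10%) fail screening by construction; 15% of clean
contigs spawn a 2%-diverged 80% prefix duplicate that must co-cluster
with its parent. The prophage/blacklist rates approximate the survey's
curation removal rates (roughly 2% and 7% of virus contigs) while keeping
each kind represented at a 200-contig desk scale. Depth profiles draw
block-wise Poisson depths around a target mean and mask a contiguous
segment to hit the requested breadth exactly to rounding.

The generator does **not** emulate codon structure or phylogenetic
sequence evolution (composition is uniform ACGT — no scored computation
uses sequence content beyond exact matching), read-level errors,
chimeric misassembly, or biological repeat families. Passing tests
therefore demonstrate that the *decision logic* is correct under the
stated statistical structure, not that the heuristics (k-mer ANI, exact
repeat arms, alignment prefilter) are robust to every property of real
survey data.

## Numerical choices and degenerate inputs

* All coordinates are 1-based and inclusive on both ends; strand is
  "+"/"−"; missing values are written as `"."` in every TSV; LF line
  endings; fixed seeds give byte-identical generator output.
* Greedy tie-breaks are always (length descending, id ascending);
  cluster and population ids are founding-order ordinals.
* Percentiles use linear interpolation (R quantile type 7).
* Contradictory duplicate similarity rows are an error; an absent pair is
  simply below threshold.
* Empty inputs: zero genomes give an empty community; an empty reference
  panel makes every cluster novel with a warning; an empty depth vector
  and identity outside [0, 1] are errors; curation rejections are
  recorded in the trail, never raised.
* Bootstrap CIs use quantiles over resampled factor estimates; a
  resample with no observed AMG is an error (the factor is undefined).

## Problem sizes

The shipped tests and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which every contig kind, rule, and
statistical property is exercised: 40–200 contigs, 15–81 mock genomes,
1,500–4,000 resampled fragments with 200 bootstrap replicates, 20 seeded
runs for the coverage property, and brute-force oracles (full
dynamic-programming alignment, quadratic repeat scans, truth-table
enumeration) on inputs of at most 20 sequences, 2.5 kb contigs, or 6-KO
modules. The full synthetic end-to-end run completes in roughly two
minutes on one CPU.

## Known limitations

* The built-in ANI estimator underestimates aligned fraction across
  highly rearranged genome pairs (colinear chaining); supply an external
  similarity table for such data.
* The exact-repeat detector reports planted/biological exact arms only;
  the mismatch-tolerant mode trades speed for sensitivity and is not used
  by default.
* The conversion factor assumes AMG coordinates on complete genomes are
  trustworthy and that fragment observability is the only loss mechanism;
  annotation false negatives on real fragments would compound it.
* Enrichment folds are descriptive ratios; no significance testing is
  attached, by design.
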