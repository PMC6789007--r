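---
title: "Models and methods behind retrotools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retrotools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrotools)
```

retrotools analyses retrotransposition (RT) in paired-end exome cohorts:
mobile element insertions (MEIs: Alu, L1, SVA) and processed pseudogenes
(PPGs, intron-less gene copies created by the L1 machinery). This vignette
explains the models, the tunable parameters, what the synthetic fixtures do
and do not emulate, and the numerical choices made where the design was
genuinely open.

## Processed pseudogene calling

A PPG cross-hybridises with the exome baits of its donor gene, so the
daughter copy leaves a distinctive footprint on the donor: read pairs whose
mates map in *different exons* of the same transcript with an apparent
insert size far beyond the fragment-length distribution (the intervening
introns are absent from the sequenced molecule), and split reads spanning
exon–exon junctions.

Calling proceeds in two steps:

1. **Discovery (per individual).** For every gene with a defined pLI score,
   discordant read pairs (DRPs) linking two different exons of one
   transcript are counted, requiring an insert size strictly above the
   sample's 99.5th-percentile (nearest-rank) insert threshold. A gene with
   **more than 4** such pairs is flagged (`flag_retroduplicated_genes()`,
   configurable via `min_drp`).
2. **Genotyping (cohort-wide).** Junction evidence from all discovery-
   positive individuals is pooled into a per-gene model and every sample is
   typed: positive iff DRP + SRP ≥ 5 with at least one split read pair
   (SRP) *and* one DRP (`genotype_ppg()`).

Choices worth knowing:

* The insert-size percentile is computed over *properly paired, non-split
  primary* fragments — the aligner's proper-pair insert distribution. At
  desk scale (hundreds of background fragments) including the discordant
  pairs themselves would place the 99.5% nearest rank inside the signal and
  make the threshold self-defeating; estimating the null from proper pairs
  is also what aligners themselves do when they set the proper-pair flag.
* Exon assignment uses any overlap (≥ 1 bp) between a mate's aligned span
  and an exon; no overlap fraction is imposed.
* Duplicate fragments (identical mate coordinates) are counted once.
* The discovery threshold "more than four" is interpreted strictly (> 4);
  the step-2 wording ("at least five") suggests ≥ 5 was intended
  throughout, and the two agree under this reading.
* Insertion-site localisation is *not* attempted: exome evidence
  concentrates on the donor gene and two independent PPGs of the same
  donor cannot be distinguished.

## MEI call-set filtering and annotation

Records arrive as a MELT-style VCF (per-site ASSESS score, split-read
support, FILTER column, per-sample genotypes). Retention requires, with
removals attributed to the *first* failing criterion in a fixed order (lc,
call rate, split reads, ASSESS, FILTER) so ledgers are reproducible:

* no low-complexity flag: the reference window ± 50 bp around the insertion
  must not contain a run of ≥ 15 bp composed of ≤ 2 distinct nucleotides
  (`low_complexity_flag()`; `N` breaks runs). Only the reference flank is
  scanned, not the inserted ME sequence itself — exposed as the `flank` /
  `min_run` arguments;
* call rate ≥ 25% of the cohort (missing genotypes count against the
  record);
* split reads ≥ 3 (i.e. "≤ 2 split reads" removes);
* ASSESS ≥ 3;
* FILTER ⊆ {PASS, rSD}.

Consequence annotation retains exactly one label per variant with priority
enhancer > exonic > intronic > intergenic; genic hits carry the containing
transcript and its pLI. Allele frequencies are recomputed on the analysis
subset as alt alleles over `2 ×` non-missing diploid samples.

## Trio de novo events and parental mosaicism

A candidate de novo is heterozygous in exactly one proband, homozygous
reference in both its parents, and — because confirmed events are
proband-unique — carried by no other cohort member (cohort-uniqueness is a
package addition and can be disabled). Three statistics assess whether an
apparently false-negative parent is in fact mosaic:

* the **allelic proportion** alt / (alt + ref) of insertion-supporting
  reads; a low non-zero parental value suggests mosaicism;
* a **one-sample z-test** of a locus' mean homozygous-reference allelic
  proportion against the cohort distribution of per-locus means (elevated
  values indicate locus-specific error, not mosaicism). The published
  description does not fully specify the test; the one-sample-vs-cohort
  reading is implemented and documented here;
* a **two-sample Kolmogorov–Smirnov test** on read-start positions within
  ± 250 bp of the insertion, parent vs proband, with the asymptotic
  p-value (read-start samples number in the hundreds).

Long-read phasing tallies the four read configurations (MEI±, SNV±) and
assigns parental origin when ≥ 90% of MEI-supporting reads carry an SNV
allele unique to one parent. The 90% consistency threshold is a package
choice; published results report only phased/unphased outcomes.

## Mutation rate, extrapolation, and burden simulation

Per ME class, the Watterson estimator gives the population mutation
parameter per accessible site,

$$\Theta = \frac{S}{a_{2n-1}\,L}, \qquad a_k = \sum_{i=1}^{k} \frac1i,$$

with $S$ segregating sites, $L$ accessible bp and $2n$ haplotypes from $n$
individuals. The per-generation rate uses $Ne = 10{,}000$ and an additional
diploid-site factor of 2:

$$\mu = \frac{\Theta}{4\,Ne \cdot 2} = \frac{\Theta}{8\,Ne}.$$

The factor is kept as the named constant `DIPLOID_THETA_FACTOR` because
only this normalisation reproduces *both* published estimates from their
printed inputs — 8554/2047/329 sites on 1113.0/959.9 Mbp masks for 2504
individuals giving a combined 1.39 × 10⁻¹¹ (prints as 1.4 × 10⁻¹¹), and
653/107/30 sites on 74.2 Mbp for 17,032 parents giving 1.21 × 10⁻¹¹ (prints
as 1.2 × 10⁻¹¹). The SVA class shares the Alu mask. The 1KGP-style
computation defaults to 2504 individuals, which reproduces the printed
value.

Extrapolation: the expected genome-wide de novo count is
$\mu \times 2 \times G \times \text{births}$ with $G$ = `HAPLOID_GENOME_LENGTH`
(2.8973 Gbp, the ungapped GRCh37 primary assembly — the value consistent
with the published 677-event extrapolation; configurable). When
reconstructing the published pipeline the combined rate is first rounded to
its reported precision (two significant figures, 1.2 × 10⁻¹¹), which
reproduces 677 exactly; the unrounded rate gives 682.

`simulate_denovo_placements()` drops the expected number of events
uniformly over the genome, annotates each placement with the
single-consequence rule, and averages per-compartment counts over
replicates (default 100) to obtain a Poisson λ. The 95% interval is the
normal approximation λ ± 1.96√λ — which reproduces the published
(5.4–19.2) interval at λ = 12.3 — with a percentile-of-replicates
alternative (`ci = "percentile"`). Uniform placement deliberately ignores
local sequence preference (e.g. L1 endonuclease motifs); that is the null
being tested. Enrichment uses the upper Poisson tail
`P(X ≥ obs) = 1 − F(obs − 1)` and, for gene-set questions, the exact upper
binomial tail.

## Constraint metrics and QC statistics

Two standard constraint measures are computed with Wald (normal) intervals,
matching the population-proportion intervals used in the published figure:
the proportion of singletons (variants carried by exactly one individual)
and the proportion of variants in LoF-intolerant genes (pLI > 0.9,
exclusive). Donor-gene enrichment uses the two-sided Fisher exact test;
orientation bias uses a 1-df chi-squared test against 50:50.

SNV genotype QC mirrors standard missingness scoring: a genotype is missing
when GQ < 20, DP < 8, or the two-sided exact binomial allelic-balance
p-value (alt reads vs 0.5) is below 0.001; variants with > 50% missing
genotypes are dropped, after site-level prefilters (VQSLOD ≥ −2). The
allelic-balance test is applied to heterozygous calls only; homozygous
calls are judged on GQ/DP — a simplification of the cited convention,
documented here. The median-expression filter retains genes with row
median ≥ 1 (RPKM), the threshold used for fetal-brain expression.

`downsample_zscore()` draws subsets of the cohort repeatedly, counts sites
still segregating, and expresses an external reference count as a z-score
of that distribution.

## Methylation episignature

`build_signature()` samples 15 cases and 15 controls, tests each CpG with a
two-sample Welch t-test (the referenced protocol does not name its test;
Welch is the package's documented, swappable choice), adjusts by
Benjamini–Hochberg, and keeps CpGs with |Δβ| ≥ 0.20 and adjusted p ≤ 0.01.
Effect size is the absolute difference of group mean betas.
`classify_by_correlation()` computes the Pearson correlation of a query
profile against the mean-case and mean-control profiles restricted to
signature CpGs (training samples are excluded from evaluation; queries must
cover ≥ 90% of the signature); the label is the argmax, with exact ties
reported as `"uncertain"`.

## What the synthetic data emulate — and what they do not

The generators provide every input with the statistical structure the
pipeline assumes, at desk scale:

* `gen_toy_genome()` — non-overlapping multi-exon gene models with pLI
  scores, intergenic enhancers, exact exon/intron/enhancer/intergenic
  partition of the territory; deterministic per seed.
* `gen_ppg_readset()` — concordant background fragments
  (insert ~ N(300, 30²)), exon-linking DRPs, junction-spanning split reads.
* `gen_mei_cohort()` — sites drawn from a neutral 1/i site-frequency
  spectrum (default; a uniform spectrum is available for filter tests),
  allele counts placed on founder haplotypes without replacement, Mendelian
  trio inheritance, planted proband-only de novos, and mosaic parents with
  a known read-level allele fraction. Per-founder means default to the
  per-parent means of large exome call sets (Alu 23.6, L1 2.8, SVA 0.2);
  sites are drawn until the summed carrier probability reaches the target,
  so the realised cohort mean tracks the requested one.
* `gen_beta_matrix()` — baseline betas ~ U(0.2, 0.8), planted shifts of
  exactly the requested effect (direction chosen to stay inside [0, 1]),
  Gaussian noise (default SD 0.05), clipping to [0, 1].

Known limitations, hence what passing tests do and do not show:

* The neutral spectrum carries substantial common-variant mass, so
  per-individual site counts are **Poisson-binomial and underdispersed
  relative to Poisson** (variance/mean ≈ 0.35 at fixture scale; SDs below
  the published ± 4.2 at mean 23.6). Real exome MEI call sets are far more
  rare-skewed and do approximate Poisson. The goodness-of-fit machinery is
  therefore validated on genuinely Poisson counts, and the generator's
  counts on their Poisson-binomial truth; passing tests certify the
  statistics, not that the neutral fixture reproduces the empirical count
  dispersion.
* Reads carry no bases, qualities, sequencing error, or GC bias; PPG
  evidence rules use coordinates and flags only, so none of these affect
  the calling logic under test.
* Classifier results on planted beta matrices (exchangeable controls,
  i.i.d. noise) do not speak to array normalisation, batch effects, or
  probe cross-reactivity in real methylation data.

## Numerical choices and degenerate inputs

* Nearest-rank percentile for the insert threshold (`sorted[ceil(q·n)]`);
  pairs qualify strictly above it. An empty insert-size vector is an error;
  a sample with no proper pairs genotypes negative rather than erroring.
* Harmonic numbers by direct summation (exact to double precision at the
  sizes used).
* Tail probabilities via `ppois` / `pbinom` / `fisher.test`; test suites
  compare against brute-force enumeration oracles.
* Zero-depth allelic proportions, empty variant sets, zero-variance null
  distributions, degenerate 2×2 margins, and off-chromosome positions all
  raise (or warn with `NA`) rather than silently propagating.
* Coordinates are 0-based half-open in memory; VCF and SAM are 1-based on
  disk, BED is 0-based. Round-trips preserve coordinates exactly.
* All randomness flows through explicit integer seeds; identical seeds give
  byte-identical outputs.

## Problem sizes used by the test suite

The suite runs cohorts of 25–1000 individuals over 0.2–1 Mbp toy genomes,
read sets of ~500 fragments, 100-replicate placement simulations of 677
events, 100-cohort rate-recovery loops, and 10⁴-CpG beta matrices — sizes
chosen so the full suite completes in well under a minute per file on a
single CPU while keeping Monte-Carlo error small against the tested
tolerances.
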