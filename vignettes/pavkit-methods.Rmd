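---
title: "Methods: PAV population genetics with pavkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAV population genetics with pavkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavkit)
```

pavkit analyses presence/absence variation (PAV) — genomic segments
present in some accessions of a species and absent in others — in highly
selfing plants. This vignette documents the statistical machinery, the
modelling assumptions behind each stage, the defaults and why they were
chosen, and what the synthetic-data generator does and does not emulate.

## Data model and conventions

All intervals are 0-based half-open, so `length = end - start` with no
±1 bookkeeping; VCF and GFF3 coordinates (1-based, closed) are converted
at the I/O boundary and nowhere else. A catalog stores one presence
genotype per sample per record: 0 (reference allele), 1 (non-reference;
for a DEL-type PAV, the sequence is absent) or missing.

**Heterozygous calls are treated as missing.** In a predominantly selfing
species nearly all individuals are expected to be homozygous at SVs;
residual heterozygous genotype calls are far more often artifacts of
read mis-mapping around breakpoints than true heterozygotes, and no
defensible rule converts them to a presence state. Dropping them to
missing is conservative and affects a small minority of calls.

PAVs are records of type `DEL` relative to the reference. Analyses cap
SV length at 10 kb (`filter_catalog(max_len = 10000)`); short-read
callers degrade rapidly beyond that, and the floor is 1 bp so that small
indels stay in the analysis set. The 50 bp lower bound conventional in
long-read benchmarking applies only when comparing against long-read
call sets, not to the analysis catalog.

## Reciprocal-overlap benchmarking

`simulate_svs()` places `n_per_type` deletions, tandem duplications and
inversions uniformly at random without overlap, lengths uniform on
`[min_len, max_len]`, then adds i.i.d. point substitutions at per-base
rate `snp_rate` outside the SV intervals before editing the sequence.
The default substitution rate is 0.001/bp — a background-divergence knob;
values approaching 0.1/bp would make the reference unalignable and are
not what any read-based benchmark would use.

`match_reciprocal(calls, truth, min_ro, type_strict)` declares a pair
compatible when the overlap covers at least `min_ro` of the length of
*each* interval (default 0.5) and, by default, the SV types agree.
Assignment is one-to-one — a single oversized call cannot absorb many
truth events — greedy by descending overlap bases, ties broken by
(chrom, start, end) of the call then the truth record, which makes the
report deterministic. Greedy matching can in principle fall below the
maximum matching (never below half of it); on realistic sparse
instances, where events are far apart relative to their lengths, the
test suite shows it equals a brute-force maximum-cardinality matching.
Breakpoint uncertainty is expressed entirely through the reciprocal
fraction; there is no additional fixed ±bp slack. Zero denominators in
precision or sensitivity yield `NA`, never an error.

## Genic/intergenic partition and the base-count test

Any base covered by at least one annotated gene is genic; overlapping
genes are merged before summing, and the intergenic set is the exact
complement, so the two spans always add to the genome size. PAV coverage
per partition is a base *union* — two PAVs covering the same bases count
once — and a PAV spanning a partition boundary contributes its
overlapping bases (and its record count) to both sides, which is why
per-partition record counts may sum to slightly more than the catalog
size.

`enrichment_chisq()` tests the 2×2 table {genic, intergenic} ×
{PAV-covered, uncovered} measured in *bases*, with Pearson's χ² without
continuity correction (checked against Σ(O−E)²/E in the tests). Base
counts, not record counts, are the right unit here because the
hypothesis is about how much sequence tolerates loss; with genome-scale
inputs the statistic is of order 10⁷ and the p-value underflows double
precision, so the print method displays `P < 1E-16` below that point
while the numeric value is retained. The fold change is the intergenic
covered proportion over the genic one.

## Polarization and the unfolded SFS

The ancestral state at each locus is the majority allele among a small
panel of deeply diverged accessions (relict lineages standing in for an
outgroup). The state is `NA` when more than one panel member is missing
or when the panel allele frequency is exactly 0.5; the 0.5 rule is
evaluated over the *informative* (non-missing) panel calls — the natural
reading when one call may be absent — and this choice is confined to
`polarize()` should a user want the stricter variant.

`unfolded_sfs()` counts, per site and population, the samples carrying
the non-ancestral allele among non-missing calls, and bins sites by raw
derived count k = 1..n−1. Sites with an `NA` ancestral state, sites
monomorphic within the population, and sites with a within-population
call rate below 80% are dropped and tallied. The 80% threshold balances
site retention against frequency-estimation noise at the default
population size (n = 24, so at most 4 missing calls per used site) and
is configurable. Counts are *not* projected to a common sample size;
populations are compared on proportions, which is what a plot of
singleton/doubleton/... fractions shows anyway.

## Tajima's D with missing data

For sites × samples presence matrices, the pairwise-diversity estimator
is

θ̂π = Σ_sites 2 p̂ (1 − p̂) · m/(m − 1),

with p̂ the site allele frequency and m the site's non-missing count;
the m/(m−1) factor makes each site's term the unbiased mean pairwise
difference among its informative calls (for complete data this equals
the classical average over all C(n,2) pairs, which is how the tests
verify it). S counts sites polymorphic among informative calls, and the
normalization constants a₁…e₂ are evaluated at the *median* informative
count across sites, rounded to the nearest integer — a single effective
sample size is required by the constants, and the median is robust to a
few badly called sites. D is `NA` (never an error) when S = 0 or the
effective n is below 4.

`matched_resampling_test()` addresses the question "is the focal class's
D larger than expected for an equally sized set of background sites?"
Each replicate draws |focal| sites uniformly *without replacement* from
the background and recomputes D from precomputed per-site summaries.
The empirical p uses the add-one estimator (1 + #{D_null ≥ D_obs}) /
(1 + reps), so p is never exactly zero and the estimator is properly
calibrated (verified against its nominal size in the tests). The test is
one-sided upper-tail by default because the scientific hypothesis —
intermediate-frequency excess — is directional; `alternative =
"two.sided"` is available. Sites, not genes, are the resampling unit;
PAVs clustered within one gene are therefore treated as exchangeable
with scattered ones under the null, a caveat for strongly clustered
focal classes (the permutation enrichment test below is the
clustering-aware counterpart).

`tail_enrichment()` consumes any per-SNP score table (for instance
haplotype-based balancing-selection scores computed elsewhere), takes
the top `tail_fraction` (default 5%) of SNPs by score, maps them into
genes and runs a one-tailed Fisher exact test for focal-gene
over-representation among tail genes. Computing the scores themselves is
out of scope by design.

## Gene-set enrichment

`fisher_enrichment()` is the standard one-tailed hypergeometric test per
term with an enrichment score (k/n)/(K/N) and Benjamini–Hochberg
adjustment across terms (`benjamini_adjust()` delegates to the stock
step-up implementation; the tests pin it to a hand computation).

`permutation_enrichment()` is the conservative companion for genomes
where interesting genes are long or clustered: the statistic per term is
the number of *distinct* genes carrying the term hit by the candidate
variants (a long gene hit by twenty co-located PAVs counts once), and
the null resamples |candidate| variants from the full variant universe,
so terms whose genes soak up many variants by geometry alone are not
called enriched. Gene-level counting was chosen over variant-level
counting as the more conservative of the two readings. The suite
includes a constructed clustered-long-gene fixture on which the
permutation p exceeds the Fisher p by orders of magnitude — the intended
ordering — while on unclustered equal-length genes both tests rank terms
identically.

## Trees and LD tagging

`pav_distance()` uses the allele-sharing mismatch proportion with
pairwise deletion — the standard distance for binary presence data; no
explicit metric is canonical for PAVs, so the choice is documented and
the matrix is exposed for users who want another. `neighbor_joining()`
implements the classical Q-criterion agglomeration with deterministic
lexicographic tie-breaking (by the smallest leaf label in each clade) so
identical inputs always give identical trees; it returns an
ape-compatible `phylo`, and the tests require exact recovery of random
additive trees and topological agreement with the reference
implementation on noisy distances. Negative branch lengths, a known NJ
artifact, are clamped to zero by default with the raw values kept in an
attribute.

`best_tag_snp()` reports, per focal PAV, the maximum squared Pearson
correlation over SNPs within `window_bp` (default 10,000) of the PAV
*midpoint* — the window anchor had to be fixed somewhere, and the
midpoint treats both breakpoints symmetrically. Pairs with fewer than
two complete observations or zero variance give `NA` and are excluded
from the mean/SD summary with their count reported.

## The synthetic-data generator

`generate()` emulates the structure of a multi-population PAV study on a
deliberately compact scale: two 400 kb chromosomes; 220 genes (log-normal
lengths, median 1.5 kb) laid out in five-gene tandem clusters so that
~47% of the genome is genic; 20% of genes designated "defense" as whole
clusters, so the defense class is spatially clustered the way R-gene
families are; two populations of 24 accessions plus five divergent
polarizer accessions; 800 PAVs with log-normal lengths (median ~80 bp,
capped at 10 kb).

The planted signals, and the knobs that control them:

* **Genic deficit.** PAV bases are allocated so the intergenic/genic
  per-base coverage ratio hits `density_ratio` (default 3.5); placement
  is non-overlapping via exact free-gap sampling, so realized coverage
  matches the allocation closely (within 10% across seeds, enforced in
  the tests).
* **Defense PAV excess.** Within the genic share, defense genes receive
  `defense_pav_boost` (default 3×) the per-base PAV rate of other genic
  sequence, so defense-term enrichment is recoverable by both Fisher and
  permutation tests.
* **Balancing-selection signature.** Neutral-class derived counts follow
  the 1/k neutral spectrum; defense-class derived frequencies are drawn
  from Beta(κ/2, κ/2) with κ = `balanced_kappa` (default 20), i.e.
  concentrated near 0.5, then binomially sampled. As κ → ∞ all defense
  frequencies pin to 0.5 exactly (a tested limit).
* **Polarizability.** Polarizers carry the derived allele with
  probability 0.05 and each call is missing with probability 0.05, so a
  small, realistic fraction of loci polarize to `NA`.
* **SNP tagging.** 100 focal PAVs receive 5 nearby SNPs each; one SNP
  per focal PAV copies the PAV genotypes with a per-sample flip rate
  calibrated so that the population correlation equals √`target_r2`
  (default target r² = 0.75). The flip rate must shrink as the PAV
  frequency leaves 0.5 — a constant rate would systematically undershoot
  the target at skewed frequencies.

Everything is deterministic given the seed, and all outputs are plain
text re-readable by the package's own readers (tested byte-for-byte).

**What the generator does not emulate:** linkage disequilibrium beyond
the single tag-SNP knob (sites are independent given their class), any
demographic history (no bottlenecks, growth or migration — the two
populations are independent draws), gene conversion and recurrent
mutation, genotype-quality structure in the missingness (missingness is
uniform, not breakpoint- or repeat-associated), and sequencing of the
genome itself (the FASTA is random sequence). Passing the end-to-end
tests therefore demonstrates that the *machinery* recovers planted
signals of realistic effect size; it does not validate caller accuracy
on real reads or the demographic robustness of the D statistic —
bottlenecked populations genuinely shift genome-wide D, which is exactly
why the matched-resampling test compares the focal class against its own
genomic background rather than against zero.

## Problem sizes and numerical choices

The shipped test and acceptance runs use desk-scale sizes chosen so the
whole suite completes in minutes while keeping every estimator in its
calibrated regime: 1,000 resampling replicates (the add-one floor is
then ~0.001, well below the 0.05 and 0.01 decision points), 200-trial
null-calibration experiments with 99% binomial acceptance bounds, 500
permutations for gene-set tests, and 50-tree recovery sweeps. Production
analyses on real data would raise the replicate counts (the resampling
cost is linear and the per-site summaries are precomputed, so 10⁵
replicates on ~10³ genic sites is a few seconds).

Other numerical conventions: χ² without continuity correction
(two-sided underflow displayed as `< 1E-16`); NJ tie-breaks and greedy
matching tie-breaks are lexicographic and therefore deterministic;
`filter_catalog` bounds are inclusive; empty/degenerate inputs (no
polymorphic site, no SNP in a window, zero-margin tables, empty truth
sets) return `NA` with a warning or message rather than erroring, so
population-scale loops don't fall over on a degenerate class.

## Known limitations

* The distance, window-anchor and heterozygote conventions are sensible
  defaults, not discoveries; all are configurable and results should be
  checked for sensitivity where they matter.
* The permutation enrichment test conditions on the observed variant
  universe; if that universe itself is ascertained (e.g. callable
  regions differ by gene class) the null inherits the ascertainment.
* The matched-resampling test resamples sites, not genes; for focal
  classes dominated by a few genes, an additional gene-level block
  resample is a prudent follow-up.
* Unfolded spectra are only as good as the polarizer panel; with five
  panel members a single shared derived allele can mispolarize a locus,
  which inflates the high-frequency bins symmetrically.
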