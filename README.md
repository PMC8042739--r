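# pavkit

Population-genetic analysis of structural variants (SVs) — deletions /
presence-absence variants (PAVs), tandem duplications and inversions — in
highly selfing plants such as *Arabidopsis thaliana*. The package is aimed
at researchers who have SV genotype call sets (VCF with `SVTYPE`/`END` and
per-sample `GT`) for many accessions and want to ask evolutionary
questions of them: where in the genome PAVs are tolerated, whether
particular gene classes show the intermediate-frequency excess expected
under balancing selection, and how well SNPs tag PAVs.

## What it computes

* **Catalog I/O and filtering** — `read_sv_vcf()` / `write_sv_vcf()` parse
  and emit SV VCFs into an `sv_catalog` (0-based half-open intervals,
  diploid genotypes collapsed to presence states; heterozygous calls are
  treated as missing, the standard reading for a selfer).
  `filter_catalog()` restricts to an analysis set (type, length ≤ 10 kb,
  polymorphic).
* **Caller benchmarking** — `simulate_svs()` plants non-overlapping
  DEL/DUP/INV events plus background substitutions into a reference;
  `match_reciprocal()` scores a call set against a truth set requiring
  reciprocal overlap ≥ r of *both* intervals (default r = 0.5), assigns
  matches one-to-one greedily by overlap, and reports
  precision = TP/(TP+FP) and sensitivity = TP/(TP+FN).
* **Genome partition accounting** — `build_partition()` merges gene
  intervals into a genic/intergenic partition; `summarize_partition()`
  counts PAV-covered bases per partition (a union, never a sum);
  `enrichment_chisq()` runs Pearson's χ² (df = 1, no continuity
  correction) on the 2×2 base-count table and reports the
  intergenic/genic fold ratio.
* **Polarization and unfolded SFS** — `polarize()` takes the majority
  allele among a small panel of divergent accessions as ancestral (NA when
  more than one panel call is missing or the panel frequency is exactly
  0.5); `unfolded_sfs()` tabulates derived-allele counts k = 1..n−1 per
  population and genomic class.
* **Tajima's D and the matched-resampling test** — `tajimas_d()` computes
  D = (θ̂π − θ̂W) / √(e₁S + e₂S(S−1)) on presence/absence matrices with
  per-site missing-data handling; `matched_resampling_test()` draws
  size-matched site sets from the genic background to build an empirical
  null for the focal (e.g. defense-gene) class, with the add-one estimator
  p = (1 + #{D_null ≥ D_obs}) / (1 + reps).
* **Gene-set enrichment** — `fisher_enrichment()` (one-tailed
  hypergeometric + Benjamini–Hochberg) and `permutation_enrichment()`, a
  clustering- and gene-length-aware permutation test that counts distinct
  genes per term and resamples variants.
* **Trees and LD tagging** — `pav_distance()` (allele-sharing mismatch,
  pairwise deletion), `neighbor_joining()` (implemented from the standard
  Q-criterion definition; returns an ape-compatible `phylo`), and
  `best_tag_snp()` (best r² SNP within a window of each focal PAV).
* **Synthetic data** — `generate()` emits a complete, deterministic
  mini-study (genome FASTA, GFF3 with clustered defense genes, term table,
  PAV + SNP VCFs, population map, truth ledger) with a neutral 1/k
  spectrum everywhere except defense genes, whose derived frequencies are
  Beta-distributed around 0.5.

## Worked example

```r
library(pavkit)

dir <- tempfile()
sim <- generate(sim_config(), dir = dir, seed = 1)

genome  <- read_genome(sim$paths[["fai"]])
catalog <- read_sv_vcf(sim$paths[["pav_vcf"]], genome)
catalog
#> sv_catalog: 800 records, 53 samples, 2 chromosome(s)
#>   DEL: 800  DUP: 0  INV: 0
#>   missing genotype rate: 0.050

genes <- read_annotation(sim$paths[["gff"]])
part  <- build_partition(genes, genome)
s     <- summarize_partition(part, catalog)
print(s, digits = 4)
#>      partition   span n_pavs mean_length median_length pav_bases proportion
#> 1 whole_genome 800000    800       169.5            79    135638    0.16955
#> 2   intergenic 437649    649       168.9            77    109615    0.25046
#> 3        genic 362351    151       172.3            90     26023    0.07182
enrichment_chisq(s)
#> chi-square enrichment: chi2 = 44931.056, df = 1, P < 1E-16
#>   intergenic/genic fold = 3.488
```

PAVs cover 25.0% of intergenic but only 7.2% of genic bases — a 3.5-fold
deficit inside genes (the generator's planted purifying-selection signal),
overwhelmingly significant on the base-count χ² test.

```r
terms  <- read_terms(sim$paths[["terms"]])
popmap <- read_popmap(sim$paths[["popmap"]])
cls    <- assign_classes(catalog, genes, terms = terms,
                         defense_term = "GO:0006952")
pop1   <- popmap$pops[["pop1"]]
matched_resampling_test(catalog$geno[cls$genic, pop1],
                        catalog$geno[cls$defense, pop1],
                        n_reps = 1000, seed = 2)
#> matched resampling: observed D = 2.938, 1000 reps, empirical P = 0.000999 (greater)
```

Defense-gene PAVs sit at intermediate frequencies, so their Tajima's D
(2.94) exceeds every one of 1,000 size-matched genic resamples: the
empirical p is at its add-one floor of 1/1001.

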