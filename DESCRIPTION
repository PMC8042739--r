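Package: pavkit
Title: Population Genetics of Presence/Absence Variants from Structural
    Variant Call Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genetic analysis of structural variants
    (SVs), with a focus on presence/absence variants (PAVs) in selfing
    plants. Reads SV call sets from VCF, benchmarks call sets against
    simulated truth sets by reciprocal overlap, partitions the genome into
    genic and intergenic regions with base-level PAV accounting and a
    chi-square enrichment test, polarizes variants to ancestral/derived
    states using a consensus of divergent outgroup-proxy accessions,
    computes unfolded site-frequency spectra per population and genomic
    class, tests gene classes for intermediate-frequency excess with
    Tajima's D and a matched-resampling empirical null, performs Fisher and
    clustering-aware permutation gene-set enrichment, builds
    neighbor-joining trees from PAV allele-sharing distances, and
    summarizes how well SNPs tag PAVs via windowed r-squared. A synthetic
    data generator emits complete multi-population fixtures (genome,
    annotation, genotypes, population map) so every stage can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
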