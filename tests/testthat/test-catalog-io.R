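test_that("VCF coordinates convert to 0-based half-open intervals", {
  dir <- withr::local_tempdir()
  paths <- make_worked_fixtures(dir)
  genome <- read_genome(paths[["fai"]])
  cat <- read_sv_vcf(paths[["vcf"]], genome)
  expect_equal(nrow(cat$records), 3)
  del <- cat$records[cat$records$id == "del1", ]
  expect_equal(del$start, 100)
  expect_equal(del$end, 200)
  expect_equal(del$end - del$start, 100)
})

test_that("diploid genotypes collapse to presence states; hets are missing", {
  dir <- withr::local_tempdir()
  paths <- make_worked_fixtures(dir)
  cat <- read_sv_vcf(paths[["vcf"]], read_genome(paths[["fai"]]))
  expect_identical(unname(cat$geno[1, ]), c(0L, 1L, NA))
  # dup1 carries a 0/1 call for s3: heterozygotes are treated as missing
  expect_identical(unname(cat$geno[2, "s3"]), NA_integer_)
})

test_that("write/read round trip preserves the catalog field by field", {
  set.seed(101)
  cat1 <- make_random_catalog(n = 50)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(cat1, path)
  cat2 <- read_sv_vcf(path, cat1$genome)
  expect_equal(cat2$records$chrom, cat1$records$chrom)
  expect_equal(cat2$records$start, cat1$records$start)
  expect_equal(cat2$records$end, cat1$records$end)
  expect_equal(cat2$records$svtype, cat1$records$svtype)
  expect_equal(cat2$records$id, cat1$records$id)
  expect_identical(unname(cat2$geno), unname(cat1$geno))
  expect_equal(cat2$samples, cat1$samples)
  expect_equal(cat2$support$SU, cat1$support$SU)
  expect_equal(cat2$support$PE, cat1$support$PE)
  # re-writing the re-read catalog is byte-identical
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(cat2, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("record validation rejects out-of-bounds and degenerate intervals", {
  rec <- data.frame(chrom = "chr1", start = 100, end = 100, svtype = "DEL")
  g <- matrix(0L, 1, 1, dimnames = list(NULL, "s1"))
  expect_error(sv_catalog(rec, g, c(chr1 = 1000)), "end > start")
  rec$end <- 2000
  expect_error(sv_catalog(rec, g, c(chr1 = 1000)), "beyond chromosome")
  rec$end <- 200
  rec$chrom <- "chrX"
  expect_error(sv_catalog(rec, g, c(chr1 = 1000)), "not in genome")
})

test_that("filter_catalog matches a brute-force enumeration and is idempotent", {
  set.seed(7)
  cat <- make_random_catalog(n = 80)
  f <- filter_catalog(cat, svtypes = "DEL", min_len = 100, max_len = 2000,
                      polymorphic_only = TRUE)
  # brute-force oracle over the raw pieces
  len <- cat$records$end - cat$records$start
  poly <- vapply(seq_len(nrow(cat$records)), function(i) {
    g <- cat$geno[i, ]
    any(g == 0L, na.rm = TRUE) && any(g == 1L, na.rm = TRUE)
  }, logical(1))
  keep <- cat$records$svtype == "DEL" & len >= 100 & len <= 2000 & poly
  expect_equal(nrow(f$records), sum(keep))
  expect_equal(f$records$id, cat$records$id[keep])
  # idempotence
  f2 <- filter_catalog(f, svtypes = "DEL", min_len = 100, max_len = 2000,
                       polymorphic_only = TRUE)
  expect_identical(f2$records, f$records)
  expect_identical(f2$geno, f$geno)
  expect_error(filter_catalog(cat, min_len = 10, max_len = 1), "min_len")
})

test_that("length bounds are inclusive and fixed records are dropped", {
  rec <- data.frame(chrom = "chr1",
                    start = c(0, 100, 20000, 40000),
                    end = c(10000, 10101, 30001, 40001),
                    svtype = "DEL")
  g <- matrix(c(0L, 1L,
                0L, 1L,
                0L, 1L,
                1L, 1L), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  cat <- sv_catalog(rec, g, c(chr1 = 1e6))
  f <- filter_catalog(cat, max_len = 10000)
  expect_equal(nrow(f$records), 2)  # both 10,001 bp records are out
  f2 <- filter_catalog(cat, polymorphic_only = TRUE)
  expect_equal(nrow(f2$records), 3)  # the all-presence record is out
})

test_that("type counts are conserved after reading", {
  set.seed(11)
  cat1 <- make_random_catalog(n = 60)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(cat1, path)
  cat2 <- read_sv_vcf(path, cat1$genome)
  tab <- table(factor(cat2$records$svtype, c("DEL", "DUP", "INV")))
  expect_equal(sum(tab), nrow(cat2$records))
  expect_equal(as.vector(tab),
               as.vector(table(factor(cat1$records$svtype,
                                      c("DEL", "DUP", "INV")))))
})

test_that("annotation, term and popmap readers parse the generated formats", {
  dir <- withr::local_tempdir()
  sim <- generate(sim_config(n_pavs = 60, n_genes = 40,
                             n_background_snps = 20, n_tag_pavs = 5,
                             n_null_variants = 50),
                  dir = dir, seed = 3)
  genes <- read_annotation(sim$paths[["gff"]])
  expect_equal(genes$gene_id, sim$genes$gene_id)
  expect_equal(genes$start, as.integer(sim$genes$start))
  expect_equal(genes$end, as.integer(sim$genes$end))
  terms <- read_terms(sim$paths[["terms"]], annotation = genes)
  expect_setequal(unique(terms$gene_id), genes$gene_id)
  pm <- read_popmap(sim$paths[["popmap"]])
  expect_s3_class(pm, "pop_map")
  expect_equal(sort(names(pm$pops)), sort(unique(pm$sample2pop)))
  expect_equal(pm$pops[["pop1"]], sim$popmap$pops[["pop1"]])
  snps <- read_snp_vcf(sim$paths[["snp_vcf"]])
  expect_identical(unname(snps$geno), unname(sim$snps$geno))
  # a term table naming an unknown gene warns but keeps the row
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("geneX\tGO:1", paste0(genes$gene_id[1], "\tGO:2")), tf)
  expect_warning(tt <- read_terms(tf, annotation = genes), "absent")
  expect_equal(nrow(tt), 2)
})

test_that("duplicate sample assignment in a popmap is rejected", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tpopA", "s1\tpopB"), tf)
  expect_error(read_popmap(tf), "more than one population")
})
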