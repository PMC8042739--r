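random_reference <- function(len = 50000, seed = 1) {
  set.seed(seed)
  Biostrings::DNAStringSet(c(chrA = paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")))
}

test_that("simulation with no events and no substitutions is the identity", {
  ref <- random_reference(20000)
  ts <- simulate_svs(ref, n_per_type = 0, snp_rate = 0, seed = 5)
  expect_equal(as.character(ts$mutated), as.character(ref))
  expect_equal(nrow(ts$truth), 0)
})

test_that("a single deletion shortens the chromosome by its length", {
  ref <- random_reference(20000)
  ts <- simulate_svs(ref, n_per_type = 1, min_len = 500, max_len = 500,
                     snp_rate = 0, seed = 9, types = "DEL")
  expect_equal(Biostrings::width(ts$mutated)[1], 20000 - 500)
  # DUP lengthens, INV preserves
  td <- simulate_svs(ref, 1, 500, 500, 0, seed = 9, types = "DUP")
  expect_equal(Biostrings::width(td$mutated)[1], 20000 + 500)
  ti <- simulate_svs(ref, 1, 500, 500, 0, seed = 9, types = "INV")
  expect_equal(Biostrings::width(ti$mutated)[1], 20000)
})

test_that("re-simulation under a fixed seed is bit-identical", {
  ref <- random_reference(200000)
  a <- simulate_svs(ref, n_per_type = 20, min_len = 50, max_len = 2000,
                    snp_rate = 0.001, seed = 42)
  b <- simulate_svs(ref, n_per_type = 20, min_len = 50, max_len = 2000,
                    snp_rate = 0.001, seed = 42)
  expect_identical(as.character(a$mutated), as.character(b$mutated))
  expect_identical(a$truth, b$truth)
  expect_equal(as.vector(table(a$truth$svtype)), rep(20L, 3))
  # truth intervals never overlap
  gr <- GenomicRanges::GRanges(a$truth$chrom,
                               IRanges::IRanges(a$truth$start + 1,
                                                a$truth$end))
  expect_true(all(GenomicRanges::countOverlaps(gr, gr) == 1))
  # FASTA + truth files round-trip
  dir <- withr::local_tempdir()
  write_truth_set(a, fasta = file.path(dir, "mut.fa"),
                  vcf = file.path(dir, "truth.vcf"),
                  bed = file.path(dir, "truth.bed"))
  back <- read_sv_vcf(file.path(dir, "truth.vcf"), a$genome)
  expect_equal(back$records$start, a$truth$start)
  expect_equal(back$records$end, a$truth$end)
  expect_equal(back$records$svtype, a$truth$svtype)
})

test_that("self-comparison gives perfect precision and sensitivity", {
  set.seed(3)
  cat <- make_random_catalog(n = 40)
  for (ro in c(0.3, 0.5, 1)) {
    rep <- match_reciprocal(cat, cat, min_ro = ro)
    expect_equal(rep$precision, 1)
    expect_equal(rep$sensitivity, 1)
    expect_equal(rep$TP, 40)
  }
})

test_that("the reciprocal rule rejects one-sided overlap", {
  calls <- data.frame(chrom = "c", start = 100, end = 200, svtype = "DEL")
  truth <- data.frame(chrom = "c", start = 150, end = 350, svtype = "DEL")
  # overlap 50: 50/100 >= 0.5 but 50/200 < 0.5
  rep <- match_reciprocal(calls, truth, min_ro = 0.5)
  expect_equal(rep$TP, 0)
  expect_equal(rep$FP, 1)
  expect_equal(rep$FN, 1)
  # both sides pass at min_ro = 0.25
  rep2 <- match_reciprocal(calls, truth, min_ro = 0.25)
  expect_equal(rep2$TP, 1)
})

test_that("type-strict matching separates DEL from DUP calls", {
  calls <- data.frame(chrom = "c", start = 0, end = 100, svtype = "DUP")
  truth <- data.frame(chrom = "c", start = 0, end = 100, svtype = "DEL")
  expect_equal(match_reciprocal(calls, truth)$TP, 0)
  expect_equal(match_reciprocal(calls, truth, type_strict = FALSE)$TP, 1)
})

test_that("greedy assignment equals maximum matching on sparse instances", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (trial in 1:50) {
    # well-separated truth events with jittered calls
    n <- 30
    start <- cumsum(sample(2000:4000, n, replace = TRUE))
    len <- sample(100:900, n, replace = TRUE)
    truth <- data.frame(chrom = "c", start = start, end = start + len,
                        svtype = sample(c("DEL", "DUP", "INV"), n, TRUE))
    jit <- sample(-80:80, n, replace = TRUE)
    drop <- sample(n, 3)  # a few misses and a few spurious calls
    calls <- truth[-drop, ]
    calls$start <- calls$start + jit[-drop]
    calls$end <- calls$end + sample(-80:80, n - 3, replace = TRUE)
    calls <- calls[calls$end > calls$start, ]
    spur <- data.frame(chrom = "c",
                       start = max(truth$end) + c(1000, 5000),
                       end = max(truth$end) + c(1400, 5800),
                       svtype = "DEL")
    calls <- rbind(calls, spur)
    rep <- match_reciprocal(calls, truth, min_ro = 0.5)
    expect_equal(rep$TP, oracle_max_matching(calls, truth, 0.5))
    expect_equal(rep$TP + rep$FP, nrow(calls))
    expect_equal(rep$TP + rep$FN, nrow(truth))
  }
})

test_that("raising min_ro never increases the true-positive count", {
  set.seed(33)
  truth <- make_random_catalog(n = 40, seed = 1)$records
  calls <- truth
  calls$start <- pmax(0, calls$start + sample(-300:300, 40, TRUE))
  calls$end <- calls$start +
    pmax(1, (truth$end - truth$start) + sample(-300:300, 40, TRUE))
  tps <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1),
                function(r) match_reciprocal(calls, truth, r)$TP, numeric(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("precision and sensitivity follow the count formulas, NA on empty", {
  expect_equal(
    precision_sensitivity(list(TP = 95, FP = 5, FN = 5)),
    c(precision = 0.95, sensitivity = 0.95))
  expect_identical(
    precision_sensitivity(list(TP = 0, FP = 0, FN = 3)),
    c(precision = NA_real_, sensitivity = 0))
  set.seed(12)
  for (i in 1:20) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    ps <- precision_sensitivity(list(TP = tp, FP = fp, FN = fn))
    expect_equal(ps[["precision"]],
                 if (tp + fp > 0) tp / (tp + fp) else NA_real_)
    expect_equal(ps[["sensitivity"]],
                 if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }
  # empty truth: sensitivity undefined, all calls are false positives
  rep <- match_reciprocal(
    data.frame(chrom = "c", start = 0, end = 10, svtype = "DEL"),
    data.frame(chrom = character(0), start = numeric(0),
               end = numeric(0), svtype = character(0)))
  expect_true(is.na(rep$sensitivity))
  expect_equal(rep$precision, 0)
})
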