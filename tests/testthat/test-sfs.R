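make_pol_catalog <- function(pol_rows, pop_geno = NULL) {
  # pol_rows: matrix of polarizer genotypes (records x 5)
  np <- nrow(pol_rows)
  pop_geno <- if (is.null(pop_geno)) {
    matrix(0L, np, 4, dimnames = list(NULL, paste0("p", 1:4)))
  } else pop_geno
  geno <- cbind(pop_geno, pol_rows)
  colnames(geno) <- c(colnames(pop_geno), paste0("rel", 1:ncol(pol_rows)))
  rec <- data.frame(chrom = "c", start = seq_len(np) * 100,
                    end = seq_len(np) * 100 + 50, svtype = "DEL")
  sv_catalog(rec, geno, c(c = 1e6))
}

test_that("the polarizer consensus follows the majority / NA rules", {
  pol <- rbind(
    c(0L, 0L, 0L, 0L, 1L),   # majority reference
    c(0L, 0L, 1L, 1L, NA),   # 0.5 among informative -> NA
    c(0L, NA, NA, 1L, 1L),   # two missing -> NA
    c(1L, 1L, 1L, 0L, 0L),   # majority alternate
    c(NA, 1L, 1L, 1L, 1L))   # one missing, clear majority
  cat <- make_pol_catalog(pol)
  pc <- polarize(cat, paste0("rel", 1:5))
  expect_identical(pc$ancestral, c(0L, NA, NA, 1L, 1L))
  expect_error(polarize(cat, c("rel1", "nope")), "not in catalog")
})

test_that("derived counts flip when the alternate allele is ancestral", {
  n <- 10
  pop <- matrix(0L, 2, n, dimnames = list(NULL, paste0("p", 1:n)))
  pop[1, 1:3] <- 1L  # 3 alt carriers
  pop[2, 1:3] <- 1L
  pol <- rbind(c(0L, 0L, 0L, 0L, 0L),  # ancestral = reference
               c(1L, 1L, 1L, 1L, 1L))  # ancestral = alternate
  cat <- make_pol_catalog(pol, pop)
  pc <- polarize(cat, paste0("rel", 1:5))
  pm <- pop_map(setNames(rep("A", n), paste0("p", 1:n)))
  sfs <- unfolded_sfs(pc, pm, "A")
  # site 1: derived = alt carriers = 3; site 2: derived = 10 - 3 = 7
  expect_equal(sfs$count[sfs$k == 3], 1)
  expect_equal(sfs$count[sfs$k == 7], 1)
  expect_equal(sum(sfs$count), 2)
  expect_equal(sum(sfs$proportion), 1)
})

test_that("singleton-only data puts all spectrum mass at k = 1", {
  n <- 10
  pop <- t(vapply(1:5, function(i) {
    g <- integer(n); g[i] <- 1L; g
  }, integer(n)))
  colnames(pop) <- paste0("p", 1:n)
  pol <- matrix(0L, 5, 5)
  cat <- make_pol_catalog(pol, pop)
  pc <- polarize(cat, paste0("rel", 1:5))
  pm <- pop_map(setNames(rep("A", n), paste0("p", 1:n)))
  sfs <- unfolded_sfs(pc, pm, "A")
  expect_equal(sfs$proportion[sfs$k == 1], 1)
  expect_equal(sum(sfs$count), 5)
})

test_that("the SFS equals a brute-force per-site tabulation", {
  set.seed(17)
  n <- 12
  np <- 50
  pop <- matrix(sample(c(0L, 1L, NA), np * n, TRUE, prob = c(.5, .4, .1)),
                np, n, dimnames = list(NULL, paste0("p", 1:n)))
  pol <- matrix(sample(c(0L, 1L, NA), np * 5, TRUE, prob = c(.75, .2, .05)),
                np, 5)
  cat <- make_pol_catalog(pol, pop)
  pc <- polarize(cat, paste0("rel", 1:5))
  pm <- pop_map(setNames(rep("A", n), paste0("p", 1:n)))
  sfs <- unfolded_sfs(pc, pm, "A", min_call_rate = 0.8)
  # oracle: per-site loop with explicit rules
  counts <- integer(n - 1)
  for (i in seq_len(np)) {
    anc <- pc$ancestral[i]
    if (is.na(anc)) next
    g <- pop[i, ]
    m <- sum(!is.na(g))
    if (m / n < 0.8) next
    k <- sum(g == (1L - anc), na.rm = TRUE)
    if (k > 0 && k < m) counts[k] <- counts[k] + 1L
  }
  expect_equal(sfs$count, counts)
  expect_equal(attr(sfs, "sites_used")[["whole_genome"]], sum(counts))
})

test_that("flipping all genotypes and ancestral states leaves the SFS fixed", {
  set.seed(23)
  n <- 10
  np <- 60
  pop <- matrix(sample(c(0L, 1L, NA), np * n, TRUE, prob = c(.5, .4, .1)),
                np, n, dimnames = list(NULL, paste0("p", 1:n)))
  pol0 <- matrix(0L, np, 5)
  pol1 <- matrix(1L, np, 5)
  pm <- pop_map(setNames(rep("A", n), paste0("p", 1:n)))
  sfs_a <- unfolded_sfs(polarize(make_pol_catalog(pol0, pop),
                                 paste0("rel", 1:5)), pm, "A")
  flipped <- 1L - pop
  sfs_b <- unfolded_sfs(polarize(make_pol_catalog(pol1, flipped),
                                 paste0("rel", 1:5)), pm, "A")
  expect_equal(sfs_a$count, sfs_b$count)
})

test_that("adding monomorphic sites does not change the spectrum", {
  set.seed(29)
  n <- 8
  pop <- geno_from_counts(draw_neutral_counts(40, n), n)
  colnames(pop) <- paste0("p", 1:n)
  pm <- pop_map(setNames(rep("A", n), colnames(pop)))
  base <- unfolded_sfs(polarize(make_pol_catalog(matrix(0L, 40, 5), pop),
                                paste0("rel", 1:5)), pm, "A")
  mono <- matrix(0L, 10, n, dimnames = list(NULL, colnames(pop)))
  aug <- rbind(pop, mono)
  with_mono <- unfolded_sfs(polarize(
    make_pol_catalog(matrix(0L, 50, 5), aug), paste0("rel", 1:5)), pm, "A")
  expect_equal(with_mono$count, base$count)
})

test_that("neutral 1/k data yields a decreasing spectrum on average", {
  set.seed(31)
  n <- 16
  rho <- replicate(20, {
    g <- geno_from_counts(draw_neutral_counts(300, n), n)
    colnames(g) <- paste0("p", 1:n)
    pm <- pop_map(setNames(rep("A", n), colnames(g)))
    sfs <- unfolded_sfs(polarize(make_pol_catalog(matrix(0L, 300, 5), g),
                                 paste0("rel", 1:5)), pm, "A")
    suppressWarnings(cor(sfs$k, sfs$proportion, method = "spearman"))
  })
  expect_lt(mean(rho), 0)
  expect_gt(mean(rho < 0), 0.9)
})

test_that("class assignment respects gene and defense-term overlap", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c",
                      start = c(1000, 5000), end = c(2000, 6000))
  terms <- data.frame(gene_id = "g2", term_id = "DEF")
  rec <- data.frame(chrom = "c", start = c(1500, 5500, 8000),
                    end = c(1600, 5600, 8100), svtype = "DEL")
  g <- matrix(0L, 3, 1, dimnames = list(NULL, "s1"))
  cat <- sv_catalog(rec, g, c(c = 10000))
  cls <- assign_classes(cat, genes, terms = terms, defense_term = "DEF")
  expect_equal(cls$genic, c(1L, 2L))
  expect_equal(cls$defense, 2L)
  expect_equal(cls$intergenic, 3L)
  expect_equal(cls$whole_genome, 1:3)
})
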