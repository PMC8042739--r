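# Shared fixtures and independent oracles.

# small catalog with known composition
make_micro_catalog <- function() {
  rec <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100, 1000, 5000, 200),
    end = c(200, 1500, 6000, 250),
    svtype = c("DEL", "DUP", "INV", "DEL"),
    id = c("del1", "dup1", "inv1", "del2"),
    stringsAsFactors = FALSE
  )
  geno <- matrix(c(0L, 1L, NA,
                   1L, 0L, NA,
                   0L, 0L, 1L,
                   1L, 1L, 1L),
                 nrow = 4, byrow = TRUE,
                 dimnames = list(NULL, c("s1", "s2", "s3")))
  sv_catalog(rec, geno, genome = c(chr1 = 100000, chr2 = 50000))
}

# random catalog for property tests
make_random_catalog <- function(n = 50, n_samples = 6,
                                genome = c(chr1 = 1e5, chr2 = 8e4),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- sample(names(genome), n, replace = TRUE)
  len <- sample(1:5000, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(genome[[chrom[i]]] - len[i], 1L) - 1L
  }, numeric(1))
  rec <- data.frame(chrom = chrom, start = start, end = start + len,
                    svtype = sample(c("DEL", "DUP", "INV"), n, TRUE),
                    id = paste0("v", seq_len(n)), stringsAsFactors = FALSE)
  geno <- matrix(sample(c(0L, 1L, NA), n * n_samples, TRUE,
                        prob = c(0.45, 0.45, 0.1)),
                 nrow = n, dimnames = list(NULL, paste0("s", seq_len(n_samples))))
  support <- data.frame(SU = sample(1:40, n, TRUE),
                        PE = sample(0:20, n, TRUE),
                        SR = sample(0:20, n, TRUE))
  sv_catalog(rec, geno, genome, support = support)
}

# random 0/1/NA genotype matrix (sites x samples)
make_geno <- function(n_sites, n_samples, miss = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(c(0L, 1L, NA), n_sites * n_samples, TRUE,
                prob = c((1 - miss) / 2, (1 - miss) / 2, miss)),
         nrow = n_sites,
         dimnames = list(NULL, paste0("s", seq_len(n_samples))))
}

# genotype matrix with given per-site derived counts, no missing data
geno_from_counts <- function(counts, n) {
  t(vapply(counts, function(k) {
    g <- integer(n)
    if (k > 0) g[sample.int(n, k)] <- 1L
    g
  }, integer(n)))
}

# neutral 1/k site-count draw
draw_neutral_counts <- function(n_sites, n) {
  k <- seq_len(n - 1)
  sample(k, n_sites, replace = TRUE, prob = (1 / k) / sum(1 / k))
}

# clustered-long-gene fixture for the permutation-vs-Fisher ordering:
# two very long clustered genes carry term "CLUST", many short genes carry
# "SHORT", and the candidate variants all sit inside the long genes.
perm_fixture <- function() {
  genes <- rbind(
    data.frame(gene_id = c("L1", "L2"), chrom = "c",
               start = c(0, 21000), end = c(20000, 41000)),
    data.frame(gene_id = paste0("s", 1:48), chrom = "c",
               start = 50000 + (0:47) * 1000,
               end = 50000 + (0:47) * 1000 + 400))
  terms <- rbind(data.frame(gene_id = c("L1", "L2"), term_id = "CLUST"),
                 data.frame(gene_id = paste0("s", 1:48), term_id = "SHORT"))
  set.seed(83)
  inside <- data.frame(chrom = "c", start = sort(sample(0:40900, 120)))
  inside$end <- inside$start + 50
  outside <- data.frame(chrom = "c", start = sort(sample(50000:98000, 80)))
  outside$end <- outside$start + 50
  all_v <- rbind(inside, outside)
  cand_idx <- c(utils::head(which(all_v$end <= 20000), 6),
                utils::head(which(all_v$start >= 21000 & all_v$end <= 41000),
                            6))
  list(genes = genes, terms = terms, all = all_v, cand = cand_idx)
}

## ---- oracles ----------------------------------------------------------

# Tajima's D from first principles on a complete 0/1 matrix: pairwise
# mismatch enumeration and directly coded constants.
oracle_tajima <- function(geno) {
  n <- ncol(geno)
  pairs <- utils::combn(n, 2)
  diffs <- apply(pairs, 2, function(p) sum(geno[, p[1]] != geno[, p[2]]))
  theta_pi <- mean(diffs)
  d <- rowSums(geno)
  S <- sum(d > 0 & d < n)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  theta_w <- S / a1
  D <- (theta_pi - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
  list(theta_pi = theta_pi, theta_w = theta_w, S = S, D = D)
}

# textbook chi-square on a 2x2 table
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# upper-tail hypergeometric by direct enumeration
oracle_hyper_upper <- function(k, K, N, n) {
  sum(stats::dhyper(seq(k, min(K, n)), K, N - K, n))
}

# Benjamini-Hochberg by hand (step-up with monotone enforcement)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# maximum-cardinality matching size on the reciprocal-overlap
# compatibility graph (igraph bipartite matching)
oracle_max_matching <- function(calls, truth, min_ro, type_strict = TRUE) {
  nc <- nrow(calls); nt <- nrow(truth)
  edges <- integer(0)
  for (i in seq_len(nc)) {
    for (j in seq_len(nt)) {
      if (calls$chrom[i] != truth$chrom[j]) next
      ov <- min(calls$end[i], truth$end[j]) -
        max(calls$start[i], truth$start[j])
      if (ov <= 0) next
      lc <- calls$end[i] - calls$start[i]
      lt <- truth$end[j] - truth$start[j]
      if (ov / lc < min_ro || ov / lt < min_ro) next
      if (type_strict && calls$svtype[i] != truth$svtype[j]) next
      edges <- c(edges, i, nc + j)
    }
  }
  if (!length(edges)) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, nc), rep(TRUE, nt)), edges = edges)
  igraph::max_bipartite_match(g)$matching_size
}

# brute-force per-pair allele-sharing distance
oracle_pav_distance <- function(geno) {
  ns <- ncol(geno)
  d <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      ok <- !is.na(geno[, i]) & !is.na(geno[, j])
      d[i, j] <- if (sum(ok)) mean(geno[ok, i] != geno[ok, j]) else NA
    }
  }
  d
}
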