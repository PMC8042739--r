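# Tajima's D on presence/absence genotype matrices, and the
# matched-resampling empirical test for intermediate-frequency excess.

# Normalization constants of the D statistic for sample size n.
# Cached: the resampling loop evaluates them for a handful of n values only.
.taj_cache <- new.env(parent = emptyenv())

#' Tajima constants for a sample size
#'
#' The classical normalization constants `a1, a2, b1, b2, c1, c2, e1, e2`
#' used in the variance of the difference between the pairwise-diversity and
#' segregating-sites estimators of theta.
#'
#' @param n number of sequences (>= 4).
#' @return Named numeric vector of the eight constants.
#' @export
tajima_constants <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 4L)
  key <- as.character(n)
  if (!is.null(.taj_cache[[key]])) return(.taj_cache[[key]])
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  out <- c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
           e1 = e1, e2 = e2)
  .taj_cache[[key]] <- out
  out
}

# Per-site summaries reused by tajimas_d and the resampling loop.
# geno: sites x samples matrix of 0/1/NA.
.site_stats <- function(geno) {
  geno <- as.matrix(geno)
  m <- rowSums(!is.na(geno))
  d <- rowSums(geno == 1L, na.rm = TRUE)
  p <- ifelse(m > 0, d / m, NA_real_)
  poly <- m >= 2L & d > 0L & d < m
  # unbiased per-site heterozygosity: 2 p (1-p) m/(m-1)
  pi_site <- ifelse(m >= 2L, 2 * p * (1 - p) * m / (m - 1), 0)
  pi_site[!poly] <- 0
  list(m = m, poly = poly, pi_site = pi_site)
}

.tajima_from_stats <- function(m, poly, pi_site) {
  S <- sum(poly)
  n <- as.integer(round(stats::median(m)))
  theta_pi <- sum(pi_site)
  if (S == 0L || n < 4L) {
    return(structure(list(n = n, S = S, theta_pi = theta_pi,
                          theta_w = NA_real_, D = NA_real_),
                     class = "tajima_result"))
  }
  k <- tajima_constants(n)
  theta_w <- S / k[["a1"]]
  denom <- sqrt(k[["e1"]] * S + k[["e2"]] * S * (S - 1))
  D <- if (denom > 0) (theta_pi - theta_w) / denom else NA_real_
  structure(list(n = n, S = S, theta_pi = theta_pi, theta_w = theta_w,
                 D = D),
            class = "tajima_result")
}

#' Tajima's D from a presence/absence genotype matrix
#'
#' Sites are rows, samples are columns, entries 0/1/NA. Per site, allele
#' frequencies are computed over non-missing calls; the pairwise-diversity
#' estimator uses the unbiased per-site factor `2 p (1 - p) m / (m - 1)`
#' with `m` the non-missing count. The sample size used for the
#' normalization constants is the median non-missing count across sites
#' (rounded to the nearest integer). `S` is the number of sites polymorphic
#' among non-missing calls. Returns an NA statistic (no error) when `S = 0`
#' or the effective sample size is below 4.
#'
#' @param geno sites x samples matrix of 0/1/NA.
#' @return An object of class `tajima_result` with `n`, `S`, `theta_pi`,
#'   `theta_w`, `D`.
#' @export
tajimas_d <- function(geno) {
  st <- .site_stats(geno)
  .tajima_from_stats(st$m, st$poly, st$pi_site)
}

#' @export
print.tajima_result <- function(x, ...) {
  cat(sprintf(
    "Tajima's D: n = %d, S = %d, theta_pi = %.4f, theta_w = %s, D = %s\n",
    x$n, x$S, x$theta_pi, format(x$theta_w, digits = 4),
    format(x$D, digits = 4)))
  invisible(x)
}

#' Matched-resampling test for a Tajima's D shift
#'
#' Tests whether the focal class of variants (e.g. PAVs overlapping defense
#' genes) has a more positive Tajima's D than expected for an equally sized
#' set of variants from the background universe (e.g. all genic PAVs). Each
#' replicate draws `nrow(focal_sites)` sites uniformly without replacement
#' from the background and recomputes D; the empirical p-value is
#' `(1 + #[null D >= observed D]) / (1 + n_reps)` (add-one, so p is never
#' exactly 0). The alternative is one-sided upper-tail by default, matching
#' a directional intermediate-frequency-excess hypothesis.
#'
#' @param genic_sites background genotype matrix (sites x samples).
#' @param focal_sites focal genotype matrix over the same samples; must not
#'   have more rows than the background.
#' @param n_reps number of resampling replicates.
#' @param seed optional integer seed.
#' @param alternative `"greater"` (upper tail) or `"two.sided"`.
#' @return An object of class `resampling_result` with `observed_D`,
#'   `null_Ds`, `n_reps`, `empirical_p`, `seed`.
#' @export
matched_resampling_test <- function(genic_sites, focal_sites,
                                    n_reps = 1000, seed = NULL,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  genic_sites <- as.matrix(genic_sites)
  focal_sites <- as.matrix(focal_sites)
  if (nrow(focal_sites) > nrow(genic_sites)) {
    stop("focal set larger than the background universe")
  }
  if (n_reps < 100) {
    warning("n_reps < 100: empirical p-value will be unstable")
  }
  if (!is.null(seed)) set.seed(seed)
  observed <- tajimas_d(focal_sites)
  st <- .site_stats(genic_sites)
  nf <- nrow(focal_sites)
  ng <- nrow(genic_sites)
  null_Ds <- vapply(seq_len(n_reps), function(b) {
    idx <- sample.int(ng, nf)
    .tajima_from_stats(st$m[idx], st$poly[idx], st$pi_site[idx])$D
  }, numeric(1))
  obs <- observed$D
  valid <- !is.na(null_Ds)
  p <- if (is.na(obs)) {
    NA_real_
  } else if (alternative == "greater") {
    (1 + sum(null_Ds[valid] >= obs)) / (1 + n_reps)
  } else {
    up <- (1 + sum(null_Ds[valid] >= obs)) / (1 + n_reps)
    lo <- (1 + sum(null_Ds[valid] <= obs)) / (1 + n_reps)
    min(1, 2 * min(up, lo))
  }
  structure(list(observed = observed, observed_D = obs, null_Ds = null_Ds,
                 n_reps = n_reps, empirical_p = p, seed = seed,
                 alternative = alternative),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(
    "matched resampling: observed D = %s, %d reps, empirical P = %s (%s)\n",
    format(x$observed_D, digits = 4), x$n_reps,
    format(x$empirical_p, digits = 4), x$alternative))
  invisible(x)
}

#' Score-tail enrichment of a gene class
#'
#' Takes a table of per-SNP scores (e.g. haplotype-based balancing-selection
#' scores), extracts the top `tail_fraction` of SNPs by score, maps them to
#' the genes they fall in, and tests whether focal genes are
#' over-represented among tail genes with a one-tailed Fisher exact test on
#' the gene-level 2x2 table (tail vs non-tail, focal vs other).
#'
#' @param scores data frame with columns `chrom`, `pos` (1-based SNP
#'   position), `score`.
#' @param gene_intervals gene data frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param focal_genes character vector of focal gene ids.
#' @param tail_fraction fraction of SNPs in the extreme upper tail.
#' @return List with the 2x2 `table`, `odds_ratio`, one-sided `p`,
#'   `tail_genes`, and the score `threshold`.
#' @export
tail_enrichment <- function(scores, gene_intervals, focal_genes,
                            tail_fraction = 0.05) {
  stopifnot(tail_fraction > 0, tail_fraction < 1)
  scores <- as.data.frame(scores)
  n_tail <- max(1L, ceiling(tail_fraction * nrow(scores)))
  ord <- order(-scores$score)
  tail_snps <- scores[ord[seq_len(n_tail)], , drop = FALSE]
  threshold <- min(tail_snps$score)
  snp_iv <- data.frame(chrom = tail_snps$chrom, start = tail_snps$pos - 1,
                       end = tail_snps$pos)
  hit_idx <- .overlapping_idx(gene_intervals, snp_iv)
  tail_genes <- unique(gene_intervals$gene_id[hit_idx])
  universe <- unique(gene_intervals$gene_id)
  in_tail <- universe %in% tail_genes
  in_focal <- universe %in% focal_genes
  tab <- table(tail = factor(in_tail, levels = c(TRUE, FALSE)),
               focal = factor(in_focal, levels = c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value,
       tail_genes = tail_genes, threshold = threshold)
}
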