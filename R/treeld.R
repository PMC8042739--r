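#' Allele-sharing distance between samples from PAV genotypes
#'
#' `d(i, j)` is the proportion of mismatching presence states over the
#' informative sites (those where both samples are non-missing; pairwise
#' deletion). A pair with no informative site gets `NA`.
#'
#' @param catalog an [sv_catalog()] or a sites x samples 0/1/NA matrix.
#' @param samples optional subset of sample names (catalog input only).
#' @return An object of class `pav_dist`: list with the symmetric distance
#'   matrix `d`, the informative-site count matrix `n_informative`, and
#'   `samples`.
#' @export
pav_distance <- function(catalog, samples = NULL) {
  geno <- if (inherits(catalog, "sv_catalog")) catalog$geno else
    as.matrix(catalog)
  if (!is.null(samples)) geno <- geno[, samples, drop = FALSE]
  ns <- ncol(geno)
  nm <- colnames(geno)
  if (is.null(nm)) nm <- paste0("s", seq_len(ns))
  obs <- !is.na(geno)
  gz <- geno
  gz[!obs] <- 0L
  # informative pairs and mismatches via cross-products
  n_inf <- crossprod(obs)
  # mismatches = #(1,0) + #(0,1) among informative sites
  ones <- (gz == 1L) & obs
  zeros <- (gz == 0L) & obs
  mism <- crossprod(ones, zeros) + crossprod(zeros, ones)
  d <- ifelse(n_inf > 0, mism / n_inf, NA_real_)
  diag(d) <- 0
  dimnames(d) <- list(nm, nm)
  dimnames(n_inf) <- list(nm, nm)
  structure(list(d = d, n_informative = n_inf, samples = nm),
            class = "pav_dist")
}

#' @export
as.matrix.pav_dist <- function(x, ...) x$d

#' @export
print.pav_dist <- function(x, ...) {
  cat("pav_dist:", length(x$samples), "samples; mean distance",
      format(mean(x$d[upper.tri(x$d)]), digits = 4), "\n")
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Agglomerative neighbor joining from its standard definition: at each step
#' the pair minimizing `Q(i, j) = (r - 2) d(i, j) - R(i) - R(j)` (with `r`
#' active nodes and `R` the row sums) is joined; branch lengths follow the
#' usual three-point formulas and the reduced distances are
#' `d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2`. Ties in `Q` are broken
#' deterministically by the lexicographic order of the smallest leaf label
#' in each clade. Negative branch lengths are clamped to zero by default
#' (raw values kept in the `raw_edge_length` attribute).
#'
#' @param d a [pav_distance()] result, a `dist`, or a symmetric matrix with
#'   dimnames.
#' @param clamp_negative replace negative branch lengths with 0.
#' @return An unrooted tree of class `phylo` (compatible with the ape
#'   package, e.g. for plotting or Newick export).
#' @export
neighbor_joining <- function(d, clamp_negative = TRUE) {
  if (inherits(d, "pav_dist")) d <- d$d
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 3, isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (anyNA(d)) stop("distance matrix contains NA")
  # active nodes as newick fragments; rep = smallest leaf label for ties
  newick <- labels
  rep_lab <- labels
  D <- d
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- paste(pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]]),
                 pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]]))
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]
    j <- pick[[2L]]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- D[i, j] - bi
    new_nwk <- sprintf("(%s:%s,%s:%s)", newick[i], fmt(bi),
                       newick[j], fmt(bj))
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    newick <- c(newick[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(i, j)]))
    D <- D2
  }
  # final three-way join
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", newick[1], fmt(b1),
                 newick[2], fmt(b2), newick[3], fmt(b3))
  tree <- ape::read.tree(text = txt)
  if (clamp_negative) {
    attr(tree, "raw_edge_length") <- tree$edge.length
    tree$edge.length <- pmax(0, tree$edge.length)
  }
  tree
}

#' Best tag SNP per focal PAV
#'
#' For each focal PAV, computes the squared Pearson correlation (`r^2`)
#' between the PAV presence vector and every SNP within `window_bp` of the
#' PAV midpoint (pairwise-complete samples), and reports the best SNP. PAVs
#' with no SNP in the window (or no computable correlation) get `NA` and
#' are excluded from the mean/SD summary, with their count reported.
#'
#' @param pav_geno focal-PAV genotype matrix (PAVs x samples, 0/1/NA).
#' @param snp_geno SNP genotype matrix (SNPs x samples) over the same
#'   sample columns.
#' @param pav_pos data frame for the focal PAVs with `chrom`, `start`,
#'   `end` (0-based half-open) or `chrom`, `mid`.
#' @param snp_pos data frame with `chrom`, `pos` (1-based) and optionally
#'   `id`.
#' @param window_bp maximum distance from the PAV midpoint.
#' @return An object of class `tag_report`: per-PAV data frame `report`
#'   (`best_snp`, `best_r2`, `n_snps`), `mean_r2`, `sd_r2`, `n_na`.
#' @export
best_tag_snp <- function(pav_geno, snp_geno, pav_pos, snp_pos,
                         window_bp = 10000) {
  pav_geno <- as.matrix(pav_geno)
  snp_geno <- as.matrix(snp_geno)
  stopifnot(ncol(pav_geno) == ncol(snp_geno))
  pav_pos <- as.data.frame(pav_pos)
  snp_pos <- as.data.frame(snp_pos)
  mid <- if ("mid" %in% names(pav_pos)) pav_pos$mid else
    (pav_pos$start + pav_pos$end) / 2
  snp_id <- if ("id" %in% names(snp_pos)) snp_pos$id else
    paste0("snp", seq_len(nrow(snp_pos)))
  np <- nrow(pav_geno)
  best_snp <- rep(NA_character_, np)
  best_r2 <- rep(NA_real_, np)
  n_snps <- integer(np)
  for (i in seq_len(np)) {
    inwin <- which(snp_pos$chrom == pav_pos$chrom[i] &
                     abs(snp_pos$pos - mid[i]) <= window_bp)
    n_snps[i] <- length(inwin)
    if (!length(inwin)) next
    r2 <- vapply(inwin, function(s) {
      suppressWarnings(
        stats::cor(pav_geno[i, ], snp_geno[s, ],
                   use = "pairwise.complete.obs"))^2
    }, numeric(1))
    if (all(is.na(r2))) next
    b <- which.max(r2)
    best_snp[i] <- snp_id[inwin[b]]
    best_r2[i] <- r2[b]
  }
  rep_df <- data.frame(pav = seq_len(np), best_snp = best_snp,
                       best_r2 = best_r2, n_snps = n_snps,
                       stringsAsFactors = FALSE)
  ok <- !is.na(best_r2)
  structure(list(report = rep_df,
                 mean_r2 = if (any(ok)) mean(best_r2[ok]) else NA_real_,
                 sd_r2 = if (sum(ok) > 1) stats::sd(best_r2[ok]) else NA_real_,
                 n_na = sum(!ok), window_bp = window_bp),
            class = "tag_report")
}

#' @export
print.tag_report <- function(x, ...) {
  cat(sprintf(
    "tag_report: %d focal PAVs, window %d bp; best-r2 mean = %s, SD = %s (%d without a tag)\n",
    nrow(x$report), as.integer(x$window_bp), format(x$mean_r2, digits = 3),
    format(x$sd_r2, digits = 3), x$n_na))
  invisible(x)
}
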