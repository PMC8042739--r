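#' Fisher (hypergeometric) term enrichment
#'
#' One-tailed upper-tail test per term: with `N` universe genes, `K` of them
#' carrying the term, and a study set of `n` genes of which `k` carry the
#' term, the p-value is `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. The
#' enrichment score is the study proportion over the universe proportion,
#' `(k/n) / (K/N)`. P-values are Benjamini-Hochberg adjusted across terms.
#'
#' @param study_genes character vector of study gene ids.
#' @param universe character vector of all gene ids considered.
#' @param terms gene-to-term table (`gene_id`, `term_id`), e.g. from
#'   [read_terms()]; assignments outside the universe are ignored.
#' @return A data frame of class `term_results` with columns `term`, `k`,
#'   `n`, `K`, `N`, `enrichment_score`, `p`, `p_adjusted`, ordered by `p`.
#' @export
fisher_enrichment <- function(study_genes, universe, terms) {
  universe <- unique(universe)
  study_genes <- intersect(unique(study_genes), universe)
  terms <- terms[terms$gene_id %in% universe, , drop = FALSE]
  N <- length(universe)
  n <- length(study_genes)
  by_term <- split(terms$gene_id, terms$term_id)
  rows <- lapply(names(by_term), function(tm) {
    tg <- unique(by_term[[tm]])
    K <- length(tg)
    k <- length(intersect(tg, study_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    score <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               enrichment_score = score, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- benjamini_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("term_results", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement; the
#' order of the input vector is preserved.
#'
#' @param pvals numeric vector of p-values.
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_adjust <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Permutation-based term enrichment (clustering- and length-aware)
#'
#' The observed statistic per term is the number of distinct genes carrying
#' the term that are overlapped by at least one candidate variant. Each
#' permutation draws `|candidate|` variants uniformly without replacement
#' from the full variant set and recomputes the statistic, so terms whose
#' genes are long or clustered (hit by many co-located variants) are
#' penalized relative to a naive gene-level Fisher test. Empirical p-values
#' use the add-one estimator and are Benjamini-Hochberg adjusted across
#' terms.
#'
#' @param candidate_variants indices into `all_variants`, or a data frame of
#'   intervals forming a subset of it.
#' @param all_variants data frame of variant intervals (`chrom`, `start`,
#'   `end`).
#' @param gene_intervals gene data frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param terms gene-to-term table (`gene_id`, `term_id`). Terms with no
#'   gene in the annotation are skipped with a note.
#' @param n_perms number of permutations.
#' @param seed optional integer seed.
#' @return A data frame of class `term_results` with columns `term`,
#'   `obs_genes`, `K`, `p`, `p_adjusted`.
#' @export
permutation_enrichment <- function(candidate_variants, all_variants,
                                   gene_intervals, terms, n_perms = 1000,
                                   seed = NULL) {
  all_variants <- as.data.frame(all_variants)
  if (is.numeric(candidate_variants)) {
    cand_idx <- as.integer(candidate_variants)
    if (any(cand_idx < 1L | cand_idx > nrow(all_variants))) {
      stop("candidate indices out of range")
    }
  } else {
    cv <- as.data.frame(candidate_variants)
    key_all <- paste(all_variants$chrom, all_variants$start,
                     all_variants$end)
    key_c <- paste(cv$chrom, cv$start, cv$end)
    cand_idx <- match(key_c, key_all)
    if (anyNA(cand_idx)) {
      stop("candidate variants must be a subset of all_variants")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  genes <- as.data.frame(gene_intervals)
  gene_ids <- genes$gene_id
  # variant -> gene index incidence
  hits <- GenomicRanges::findOverlaps(.as_granges(all_variants),
                                      .as_granges(genes))
  var2gene <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  # term membership matrix over annotated genes
  terms_in <- terms[terms$gene_id %in% gene_ids, , drop = FALSE]
  skipped <- setdiff(unique(terms$term_id), unique(terms_in$term_id))
  if (length(skipped)) {
    message("permutation_enrichment: skipped ", length(skipped),
            " term(s) with no annotated gene")
  }
  term_ids <- sort(unique(terms_in$term_id))
  memb <- matrix(FALSE, nrow = length(gene_ids), ncol = length(term_ids),
                 dimnames = list(gene_ids, term_ids))
  memb[cbind(match(terms_in$gene_id, gene_ids),
             match(terms_in$term_id, term_ids))] <- TRUE
  count_terms <- function(idx) {
    g <- unique(unlist(var2gene[as.character(idx)], use.names = FALSE))
    if (!length(g)) return(integer(length(term_ids)))
    colSums(memb[g, , drop = FALSE])
  }
  obs <- count_terms(cand_idx)
  nc <- length(cand_idx)
  nv <- nrow(all_variants)
  exceed <- integer(length(term_ids))
  for (b in seq_len(n_perms)) {
    perm <- count_terms(sample.int(nv, nc))
    exceed <- exceed + (perm >= obs)
  }
  p <- (1 + exceed) / (1 + n_perms)
  out <- data.frame(term = term_ids, obs_genes = as.integer(obs),
                    K = as.integer(colSums(memb)), p = p,
                    stringsAsFactors = FALSE)
  out$p_adjusted <- benjamini_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("term_results", "data.frame")
  out
}

#' Genes overlapped by catalog records, and PAV-free genes
#'
#' Convenience accessors for building enrichment study sets: the genes hit
#' by at least one record of the catalog, and the complement (genes never
#' overlapped by any record in any sample).
#'
#' @param catalog an [sv_catalog()] or interval data frame.
#' @param genes gene data frame (`gene_id`, `chrom`, `start`, `end`).
#' @return Character vector of gene ids.
#' @export
pav_bearing_genes <- function(catalog, genes) {
  rec <- if (inherits(catalog, "sv_catalog")) catalog$records else
    as.data.frame(catalog)
  idx <- .overlapping_idx(genes, rec)
  unique(genes$gene_id[idx])
}

#' @rdname pav_bearing_genes
#' @export
pav_free_genes <- function(catalog, genes) {
  setdiff(unique(genes$gene_id), pav_bearing_genes(catalog, genes))
}
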