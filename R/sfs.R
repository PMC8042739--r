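#' Polarize a catalog to ancestral/derived states
#'
#' The ancestral allele at each locus is the majority allele among a small
#' set of divergent "polarizer" accessions (outgroup proxies, e.g. relict
#' lineages). The state is set to `NA` when more than one polarizer call is
#' missing, or when the allele frequency among the informative polarizers is
#' exactly 0.5.
#'
#' @param catalog an [sv_catalog()].
#' @param polarizer_samples sample names used as the ancestral-consensus
#'   panel; must be present in the catalog.
#' @return An object of class `polarized_catalog`: the catalog plus an
#'   `ancestral` vector (0 = reference allele ancestral, 1 = alternate
#'   allele ancestral, `NA` = unassigned) and per-record polarizer call
#'   counts.
#' @export
polarize <- function(catalog, polarizer_samples) {
  stopifnot(inherits(catalog, "sv_catalog"))
  missing_pol <- setdiff(polarizer_samples, catalog$samples)
  if (length(missing_pol)) {
    stop("polarizer sample(s) not in catalog: ",
         paste(missing_pol, collapse = ", "))
  }
  pg <- catalog$geno[, polarizer_samples, drop = FALSE]
  n_missing <- rowSums(is.na(pg))
  n_alt <- rowSums(pg == 1L, na.rm = TRUE)
  n_inf <- ncol(pg) - n_missing
  freq_alt <- ifelse(n_inf > 0, n_alt / n_inf, NA_real_)
  ancestral <- ifelse(freq_alt > 0.5, 1L, 0L)
  ancestral[n_missing > 1L | is.na(freq_alt) | freq_alt == 0.5] <- NA_integer_
  structure(
    list(catalog = catalog, ancestral = as.integer(ancestral),
         polarizers = polarizer_samples,
         polarizer_calls = data.frame(n_informative = n_inf,
                                      n_missing = n_missing,
                                      n_alt = n_alt)),
    class = "polarized_catalog"
  )
}

#' @export
print.polarized_catalog <- function(x, ...) {
  n <- length(x$ancestral)
  cat("polarized_catalog:", n, "records,",
      sum(is.na(x$ancestral)), "with NA ancestral state (",
      length(x$polarizers), "polarizer samples )\n")
  invisible(x)
}

#' Assign catalog records to genomic classes
#'
#' A record is `genic` when it overlaps at least one gene by one base or
#' more, `defense` when it overlaps at least one gene carrying the defense
#' term, and `intergenic` when it overlaps the intergenic partition. The
#' classes are not exclusive: a boundary-spanning record can be both genic
#' and intergenic, and defense records are a subset of genic records.
#'
#' @param catalog an [sv_catalog()].
#' @param genes gene-interval data frame (from [read_annotation()]).
#' @param genome named chromosome-length vector (defaults to the catalog's).
#' @param terms optional gene-to-term table (from [read_terms()]).
#' @param defense_term term id defining the defense class.
#' @param defense_genes alternatively, an explicit vector of defense gene
#'   ids (overrides `terms`).
#' @return Named list of record index vectors: `whole_genome`, `genic`,
#'   `intergenic`, and (when a defense set is given) `defense`.
#' @export
assign_classes <- function(catalog, genes, genome = catalog$genome,
                           terms = NULL, defense_term = NULL,
                           defense_genes = NULL) {
  stopifnot(inherits(catalog, "sv_catalog"))
  part <- build_partition(genes, genome)
  rec <- catalog$records
  out <- list(
    whole_genome = seq_len(nrow(rec)),
    genic = .overlapping_idx(rec, part$genic),
    intergenic = .overlapping_idx(rec, part$intergenic)
  )
  if (is.null(defense_genes) && !is.null(terms) && !is.null(defense_term)) {
    defense_genes <- unique(terms$gene_id[terms$term_id == defense_term])
  }
  if (!is.null(defense_genes)) {
    dg <- genes[genes$gene_id %in% defense_genes, , drop = FALSE]
    out$defense <- .overlapping_idx(rec, dg)
  }
  out
}

#' Unfolded site-frequency spectrum for one population
#'
#' For each polarized, sufficiently called site, the derived-allele count is
#' the number of population samples carrying the non-ancestral allele among
#' non-missing calls. Counts are binned by raw derived count `k = 1 ..
#' n - 1`; sites that are monomorphic within the population (derived count 0
#' or equal to the number of informative calls), sites with an `NA`
#' ancestral state, and sites below the call-rate threshold are dropped and
#' tallied.
#'
#' @param polarized a [polarize()] result.
#' @param popmap a [pop_map()].
#' @param population population label to tabulate.
#' @param classes optional named list of record index vectors (see
#'   [assign_classes()]); default is a single `whole_genome` class.
#' @param min_call_rate minimum fraction of non-missing calls within the
#'   population for a site to be used.
#' @return A data frame of class `spectrum_table` with columns `population`,
#'   `class`, `k`, `count`, `proportion`; attributes `n` (population size),
#'   `sites_used`, `sites_dropped` (named per class).
#' @export
unfolded_sfs <- function(polarized, popmap, population, classes = NULL,
                         min_call_rate = 0.8) {
  stopifnot(inherits(polarized, "polarized_catalog"),
            inherits(popmap, "pop_map"))
  if (!population %in% names(popmap$pops)) {
    stop("population not in popmap: ", population)
  }
  samples <- intersect(popmap$pops[[population]],
                       polarized$catalog$samples)
  if (!length(samples)) stop("no catalog samples in population ", population)
  n <- length(samples)
  geno <- polarized$catalog$geno[, samples, drop = FALSE]
  anc <- polarized$ancestral
  if (is.null(classes)) {
    classes <- list(whole_genome = seq_len(nrow(geno)))
  }
  m <- rowSums(!is.na(geno))
  n_alt <- rowSums(geno == 1L, na.rm = TRUE)
  # derived count: carriers of the non-ancestral allele
  k_derived <- ifelse(anc == 0L, n_alt, m - n_alt)
  usable <- !is.na(anc) & (m / n) >= min_call_rate &
    k_derived > 0 & k_derived < m
  rows <- lapply(names(classes), function(cl) {
    idx <- classes[[cl]]
    ok <- idx[usable[idx]]
    counts <- tabulate(k_derived[ok], nbins = n - 1L)
    data.frame(population = population, class = cl, k = seq_len(n - 1L),
               count = counts,
               proportion = if (sum(counts) > 0) counts / sum(counts) else
                 rep(NA_real_, n - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("spectrum_table", "data.frame")
  attr(out, "n") <- n
  attr(out, "sites_used") <- vapply(classes, function(idx)
    sum(usable[idx]), integer(1))
  attr(out, "sites_dropped") <- vapply(classes, function(idx)
    sum(!usable[idx]), integer(1))
  out
}

#' Plot a spectrum table
#'
#' Barplot of SFS proportions, one panel per class.
#'
#' @param x a [unfolded_sfs()] result.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.spectrum_table <- function(x, ...) {
  classes <- unique(x$class)
  op <- graphics::par(mfrow = c(1, length(classes)))
  on.exit(graphics::par(op))
  for (cl in classes) {
    sub <- x[x$class == cl, ]
    graphics::barplot(sub$proportion, names.arg = sub$k,
                      main = paste(sub$population[1], cl),
                      xlab = "derived-allele count",
                      ylab = "proportion of sites", ...)
  }
  invisible(x)
}
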