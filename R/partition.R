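#' Partition a genome into genic and intergenic regions
#'
#' Any base covered by at least one annotated gene is genic; the rest of the
#' genome is intergenic. Overlapping genes are merged before lengths are
#' summed, so `genic_bases` is the size of the union of gene intervals and
#' `genic_bases + intergenic_bases` equals the genome size.
#'
#' @param genes data frame of gene intervals (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. from [read_annotation()].
#' @param genome named numeric vector of chromosome lengths.
#' @return An object of class `genome_partition` with merged `genic` and
#'   complementary `intergenic` interval sets and their base totals.
#' @export
build_partition <- function(genes, genome) {
  genes <- as.data.frame(genes)
  if (nrow(genes)) {
    bad <- !(genes$chrom %in% names(genome)) |
      genes$start < 0 | genes$end > genome[genes$chrom]
    if (any(bad)) stop(sum(bad), " gene interval(s) outside genome bounds")
  }
  genic <- .merge_intervals(genes[, c("chrom", "start", "end")])
  intergenic <- .complement_intervals(genic, genome)
  gb <- if (nrow(genic)) sum(genic$end - genic$start) else 0
  ib <- if (nrow(intergenic)) sum(intergenic$end - intergenic$start) else 0
  stopifnot(isTRUE(all.equal(gb + ib, sum(genome))))
  structure(
    list(genic = genic, intergenic = intergenic,
         genic_bases = gb, intergenic_bases = ib, genome = genome),
    class = "genome_partition"
  )
}

#' @export
print.genome_partition <- function(x, ...) {
  cat("genome_partition:", format(sum(x$genome), big.mark = ","), "bases;",
      format(x$genic_bases, big.mark = ","), "genic /",
      format(x$intergenic_bases, big.mark = ","), "intergenic\n")
  invisible(x)
}

#' Summarize PAV coverage per genomic partition
#'
#' For each partition (whole genome, intergenic, genic) reports the span in
#' bases, the number of PAV records overlapping it by at least one base (a
#' boundary-spanning PAV counts in both partitions), the mean and median full
#' record length of those PAVs, the number of partition bases covered by at
#' least one PAV (a union, not a sum of lengths), and the covered proportion.
#'
#' @param partition a [build_partition()] result.
#' @param catalog an [sv_catalog()] or a data frame of intervals (`chrom`,
#'   `start`, `end`).
#' @return A data frame of class `partition_summary` with rows
#'   `whole_genome`, `intergenic`, `genic`.
#' @export
summarize_partition <- function(partition, catalog) {
  stopifnot(inherits(partition, "genome_partition"))
  pav <- if (inherits(catalog, "sv_catalog")) catalog$records else
    as.data.frame(catalog)
  pav_len <- pav$end - pav$start
  whole <- data.frame(chrom = names(partition$genome), start = 0,
                      end = as.numeric(partition$genome),
                      stringsAsFactors = FALSE)
  parts <- list(whole_genome = whole, intergenic = partition$intergenic,
                genic = partition$genic)
  spans <- c(sum(partition$genome), partition$intergenic_bases,
             partition$genic_bases)
  rows <- lapply(seq_along(parts), function(i) {
    idx <- .overlapping_idx(pav, parts[[i]])
    covered <- .intersect_bases(pav, parts[[i]])
    data.frame(
      partition = names(parts)[i],
      span = spans[i],
      n_pavs = length(idx),
      mean_length = if (length(idx)) mean(pav_len[idx]) else NA_real_,
      median_length = if (length(idx)) stats::median(pav_len[idx]) else NA_real_,
      pav_bases = covered,
      proportion = if (spans[i] > 0) covered / spans[i] else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("partition_summary", "data.frame")
  out
}

#' Chi-square test of PAV enrichment between partitions
#'
#' Builds the 2x2 base-count table {genic, intergenic} x {PAV-covered, not
#' covered} from a [summarize_partition()] result and applies Pearson's
#' chi-square test without continuity correction. The fold change is the
#' intergenic covered proportion divided by the genic covered proportion.
#' The test is on base counts, not record counts: the observed/expected
#' quantities are totals of bases, which is why the statistic can reach the
#' order of the genome size.
#'
#' @param summary a [summarize_partition()] result (or any data frame with
#'   `partition`, `span`, `pav_bases` rows named `genic` and `intergenic`).
#' @return An object of class `enrichment_test`: the 2x2 `table`, `chi2`,
#'   `df` (= 1), upper-tail `p`, and `fold`.
#' @export
enrichment_chisq <- function(summary) {
  s <- as.data.frame(summary)
  gi <- match(c("genic", "intergenic"), s$partition)
  if (any(is.na(gi))) stop("summary must contain genic and intergenic rows")
  covered <- s$pav_bases[gi]
  uncovered <- s$span[gi] - covered
  tab <- matrix(c(covered[1], uncovered[1], covered[2], uncovered[2]),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("genic", "intergenic"),
                                c("covered", "uncovered")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in the 2x2 table; statistic undefined")
    chi2 <- NA_real_
    p <- NA_real_
  } else {
    ct <- stats::chisq.test(tab, correct = FALSE)
    chi2 <- unname(ct$statistic)
    p <- unname(ct$p.value)
  }
  prop <- covered / s$span[gi]
  fold <- prop[2] / prop[1]
  structure(list(table = tab, chi2 = chi2, df = 1L, p = p, fold = fold),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  pdisp <- if (is.na(x$p)) "NA" else if (x$p < 1e-16) "< 1E-16" else
    format(x$p, digits = 3)
  cat(sprintf("chi-square enrichment: chi2 = %s, df = %d, P %s\n",
              format(x$chi2, digits = 8), x$df,
              if (grepl("^<", pdisp)) pdisp else paste("=", pdisp)))
  cat(sprintf("  intergenic/genic fold = %.3f\n", x$fold))
  invisible(x)
}

#' Per-window PAV density track
#'
#' Simple fixed-width window counts of PAV-covered bases, intended for
#' plotting chromosome-scale density profiles.
#'
#' @param catalog an [sv_catalog()] or interval data frame.
#' @param genome named chromosome-length vector.
#' @param window window width in bases.
#' @return Data frame with `chrom`, `start`, `end`, `covered_bases`,
#'   `density`.
#' @export
pav_density_track <- function(catalog, genome, window = 100000) {
  pav <- if (inherits(catalog, "sv_catalog")) catalog$records else
    as.data.frame(catalog)
  out <- lapply(names(genome), function(chr) {
    len <- genome[[chr]]
    starts <- seq(0, max(0, len - 1), by = window)
    wins <- data.frame(chrom = chr, start = starts,
                       end = pmin(starts + window, len))
    sub <- pav[pav$chrom == chr, , drop = FALSE]
    wins$covered_bases <- vapply(seq_len(nrow(wins)), function(i) {
      .intersect_bases(sub, wins[i, , drop = FALSE])
    }, numeric(1))
    wins$density <- wins$covered_bases / (wins$end - wins$start)
    wins
  })
  do.call(rbind, out)
}
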