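#' Simulate structural variants into a reference sequence
#'
#' Places `n_per_type` non-overlapping deletions, tandem duplications and
#' inversions uniformly at random on the reference, with lengths uniform on
#' `[min_len, max_len]`, then applies point substitutions at per-base
#' probability `snp_rate` outside the SV intervals and edits the sequence
#' (DEL removes the segment, DUP inserts a tandem copy, INV
#' reverse-complements in place). Truth coordinates refer to the original
#' reference. Deterministic for a fixed `seed`.
#'
#' @param reference a [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param n_per_type events to place per SV type.
#' @param min_len,max_len event length bounds in bases.
#' @param snp_rate per-base substitution probability outside SV intervals.
#' @param seed optional integer seed.
#' @param types SV types to simulate.
#' @return An object of class `truth_set`: `mutated` (DNAStringSet), `truth`
#'   (data frame `chrom`, `start`, `end`, `svtype`, `id`), `n_snps`.
#' @export
simulate_svs <- function(reference, n_per_type, min_len = 50,
                         max_len = 10000, snp_rate = 0.001, seed = NULL,
                         types = c("DEL", "DUP", "INV")) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  stopifnot(min_len >= 1, max_len >= min_len, n_per_type >= 0)
  if (!is.null(seed)) set.seed(seed)
  chrlen <- stats::setNames(Biostrings::width(reference), names(reference))
  n_total <- n_per_type * length(types)
  placed <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), svtype = character(0),
                       stringsAsFactors = FALSE)
  occupied <- lapply(chrlen, function(...) IRanges::IRanges())
  tries <- 0L
  max_tries <- max(1000L, 200L * n_total)
  want <- rep(types, each = n_per_type)
  i <- 1L
  while (i <= n_total) {
    if (tries >= max_tries) {
      stop("could not place all events without overlap; placed ",
           i - 1L, " of ", n_total)
    }
    tries <- tries + 1L
    chr <- sample(names(chrlen), 1L, prob = chrlen)
    len <- min_len + sample.int(max_len - min_len + 1L, 1L) - 1L
    if (len >= chrlen[[chr]]) next
    start <- sample.int(chrlen[[chr]] - len, 1L) - 1L
    cand <- IRanges::IRanges(start + 1L, start + len)
    if (length(occupied[[chr]]) &&
        sum(IRanges::countOverlaps(cand, occupied[[chr]]))) next
    occupied[[chr]] <- c(occupied[[chr]], cand)
    placed <- rbind(placed, data.frame(chrom = chr, start = start,
                                       end = start + len,
                                       svtype = want[i],
                                       stringsAsFactors = FALSE))
    i <- i + 1L
  }
  if (nrow(placed)) {
    placed <- placed[order(placed$chrom, placed$start, placed$end), ]
    placed$id <- paste0("truth", seq_len(nrow(placed)))
    rownames(placed) <- NULL
  } else {
    placed$id <- character(0)
  }

  n_snps <- 0L
  mutated_chr <- character(length(chrlen))
  names(mutated_chr) <- names(chrlen)
  for (chr in names(chrlen)) {
    ch <- strsplit(as.character(reference[[chr]]), "", fixed = TRUE)[[1]]
    L <- length(ch)
    sub <- placed[placed$chrom == chr, , drop = FALSE]
    # substitutions first (original coordinates), outside SV intervals
    if (snp_rate > 0) {
      mask <- rep(TRUE, L)
      for (j in seq_len(nrow(sub))) {
        mask[(sub$start[j] + 1L):sub$end[j]] <- FALSE
      }
      hit <- which(mask & stats::runif(L) < snp_rate)
      if (length(hit)) {
        bases <- c("A", "C", "G", "T")
        # shift by 1..3 within the base alphabet: always a different base
        cur_idx <- match(toupper(ch[hit]), bases)
        cur_idx[is.na(cur_idx)] <- 1L
        shift <- sample.int(3L, length(hit), replace = TRUE)
        ch[hit] <- bases[((cur_idx - 1L + shift) %% 4L) + 1L]
        n_snps <- n_snps + length(hit)
      }
    }
    # SV edits from rightmost to leftmost so coordinates stay valid
    if (nrow(sub)) {
      sub <- sub[order(-sub$start), , drop = FALSE]
      for (j in seq_len(nrow(sub))) {
        s <- sub$start[j] + 1L
        e <- sub$end[j]
        seg <- ch[s:e]
        ch <- switch(
          sub$svtype[j],
          DEL = ch[-(s:e)],
          DUP = append(ch, seg, after = e),
          INV = { comp <- c(A = "T", C = "G", G = "C", T = "A")
                  rc <- unname(comp[toupper(rev(seg))])
                  rc[is.na(rc)] <- "N"
                  ch[s:e] <- rc
                  ch }
        )
      }
    }
    mutated_chr[chr] <- paste(ch, collapse = "")
  }
  mutated <- Biostrings::DNAStringSet(mutated_chr)
  structure(list(mutated = mutated, truth = placed, n_snps = n_snps,
                 genome = chrlen),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$truth), "events (",
    paste(names(table(x$truth$svtype)), table(x$truth$svtype),
          sep = "=", collapse = ", "),
    "),", x$n_snps, "substitutions\n")
  invisible(x)
}

#' Write a truth set to BED and VCF
#'
#' @param truth_set a [simulate_svs()] result.
#' @param fasta,vcf,bed output paths; `NULL` skips that output.
#' @return Invisibly, the truth data frame.
#' @export
write_truth_set <- function(truth_set, fasta = NULL, vcf = NULL, bed = NULL) {
  stopifnot(inherits(truth_set, "truth_set"))
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(truth_set$mutated, fasta)
  }
  if (!is.null(bed)) {
    tr <- truth_set$truth
    writeLines(paste(tr$chrom, as.integer(tr$start), as.integer(tr$end),
                     paste(tr$id, tr$svtype, sep = "_"), sep = "\t"), bed)
  }
  if (!is.null(vcf)) {
    cat_ <- sv_catalog(truth_set$truth,
                       matrix(integer(0), nrow = nrow(truth_set$truth),
                              ncol = 0, dimnames = list(NULL, character(0))),
                       genome = truth_set$genome, samples = character(0))
    write_sv_vcf(cat_, vcf)
  }
  invisible(truth_set$truth)
}

.records_df <- function(x) {
  df <- if (inherits(x, "sv_catalog")) x$records else
    if (inherits(x, "truth_set")) x$truth else as.data.frame(x)
  stopifnot(all(c("chrom", "start", "end", "svtype") %in% names(df)))
  df
}

#' Match a call set against a truth set by reciprocal overlap
#'
#' A call `c` and a truth event `t` are compatible when (if `type_strict`)
#' they share an SV type and the overlap covers at least `min_ro` of the
#' length of *each*. Compatible pairs are assigned one-to-one, greedily by
#' descending overlap bases with ties broken by (chrom, start, end) order of
#' the call then the truth record. Unassigned calls are false positives;
#' unassigned truths are false negatives.
#'
#' @param calls,truth [sv_catalog()]s, [simulate_svs()] results, or interval
#'   data frames with `chrom`, `start`, `end`, `svtype`.
#' @param min_ro minimum reciprocal overlap fraction in (0, 1].
#' @param type_strict require equal SV type.
#' @return An object of class `match_report` with the `assignment` data
#'   frame, `TP`, `FP`, `FN`, `precision`, `sensitivity` and a per-type
#'   breakdown `by_type`.
#' @export
match_reciprocal <- function(calls, truth, min_ro = 0.5, type_strict = TRUE) {
  stopifnot(min_ro > 0, min_ro <= 1)
  calls <- .records_df(calls)
  truth <- .records_df(truth)
  nc <- nrow(calls)
  nt <- nrow(truth)
  pairs <- data.frame(call = integer(0), truth = integer(0),
                      overlap = numeric(0))
  if (nc && nt) {
    hits <- GenomicRanges::findOverlaps(.as_granges(calls),
                                        .as_granges(truth))
    ci <- S4Vectors::queryHits(hits)
    ti <- S4Vectors::subjectHits(hits)
    ov <- pmin(calls$end[ci], truth$end[ti]) -
      pmax(calls$start[ci], truth$start[ti])
    lc <- calls$end[ci] - calls$start[ci]
    lt <- truth$end[ti] - truth$start[ti]
    ok <- ov / lc >= min_ro & ov / lt >= min_ro
    if (type_strict) ok <- ok & calls$svtype[ci] == truth$svtype[ti]
    pairs <- data.frame(call = ci[ok], truth = ti[ok], overlap = ov[ok])
  }
  # greedy: largest overlap first; ties by call then truth coordinate order
  if (nrow(pairs)) {
    ord <- order(-pairs$overlap,
                 calls$chrom[pairs$call], calls$start[pairs$call],
                 calls$end[pairs$call],
                 truth$chrom[pairs$truth], truth$start[pairs$truth],
                 truth$end[pairs$truth])
    pairs <- pairs[ord, , drop = FALSE]
    used_c <- logical(nc)
    used_t <- logical(nt)
    take <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      if (!used_c[pairs$call[k]] && !used_t[pairs$truth[k]]) {
        take[k] <- TRUE
        used_c[pairs$call[k]] <- TRUE
        used_t[pairs$truth[k]] <- TRUE
      }
    }
    pairs <- pairs[take, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  TP <- nrow(pairs)
  FP <- nc - TP
  FN <- nt - TP
  types <- sort(unique(c(calls$svtype, truth$svtype)))
  by_type <- do.call(rbind, lapply(types, function(tp) {
    tpn <- sum(truth$svtype[pairs$truth] == tp)
    data.frame(svtype = tp, TP = tpn,
               FP = sum(calls$svtype == tp) - sum(calls$svtype[pairs$call] == tp),
               FN = sum(truth$svtype == tp) - tpn,
               stringsAsFactors = FALSE)
  }))
  res <- structure(list(assignment = pairs, TP = TP, FP = FP, FN = FN,
                        n_calls = nc, n_truth = nt, by_type = by_type,
                        min_ro = min_ro, type_strict = type_strict),
                   class = "match_report")
  ps <- precision_sensitivity(res)
  res$precision <- ps[["precision"]]
  res$sensitivity <- ps[["sensitivity"]]
  res
}

#' Precision and sensitivity of a match report
#'
#' `precision = TP / (TP + FP)`, `sensitivity = TP / (TP + FN)`. A zero
#' denominator yields `NA`, never an error.
#'
#' @param report a [match_reciprocal()] result (or any list with `TP`, `FP`,
#'   `FN`).
#' @return Named numeric vector `c(precision, sensitivity)`.
#' @export
precision_sensitivity <- function(report) {
  tp <- report$TP
  fp <- report$FP
  fn <- report$FN
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "match_report (min_ro = %.2f%s): TP = %d, FP = %d, FN = %d\n",
    x$min_ro, if (x$type_strict) ", type-strict" else "", x$TP, x$FP, x$FN))
  cat(sprintf("  precision = %s, sensitivity = %s\n",
              format(x$precision, digits = 4),
              format(x$sensitivity, digits = 4)))
  invisible(x)
}
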