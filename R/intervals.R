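# Internal interval helpers.
#
# All pavkit coordinates are 0-based half-open [start, end); GRanges/IRanges
# are 1-based closed. Conversions live here and nowhere else.

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
.as_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.from_granges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Merged (non-overlapping, sorted) union of intervals.
.merge_intervals <- function(df) {
  .from_granges(GenomicRanges::reduce(.as_granges(df)))
}

# Total bases in the union of intervals.
.union_bases <- function(df) {
  if (nrow(df) == 0L) return(0)
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(.as_granges(df)))))
}

# Complement of intervals within [0, genome[chrom]) per chromosome.
.complement_intervals <- function(df, genome) {
  out <- lapply(names(genome), function(chr) {
    len <- genome[[chr]]
    sub <- df[df$chrom == chr, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(data.frame(chrom = chr, start = 0, end = len,
                        stringsAsFactors = FALSE))
    }
    ir <- IRanges::reduce(IRanges::IRanges(sub$start + 1L, sub$end))
    gaps <- IRanges::gaps(ir, start = 1L, end = as.integer(len))
    data.frame(chrom = chr, start = IRanges::start(gaps) - 1L,
               end = IRanges::end(gaps), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[out$end > out$start, , drop = FALSE]
}

# Bases of `a` covered by the union of `b` (both 0-based data frames).
.intersect_bases <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  ga <- GenomicRanges::reduce(.as_granges(a))
  gb <- GenomicRanges::reduce(.as_granges(b))
  # disjoint seqlevel sets are expected (e.g. single-chromosome subsets)
  suppressWarnings(
    sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(ga, gb)))))
}

# Indices of rows of `a` overlapping the union of `b` by >= 1 base.
.overlapping_idx <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(integer(0))
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(.as_granges(a), .as_granges(b)))
  which(hits > 0L)
}
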