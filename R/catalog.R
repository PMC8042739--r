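#' Construct an SV catalog
#'
#' An `sv_catalog` bundles a set of structural-variant loci (deletions /
#' presence-absence variants, tandem duplications, inversions), a per-sample
#' presence genotype matrix, optional read-support metadata, and the
#' chromosome-length map of the genome the loci live on. Coordinates are
#' 0-based half-open, so `length = end - start`.
#'
#' @param records data frame with columns `chrom`, `start`, `end`, `svtype`
#'   (one of `"DEL"`, `"DUP"`, `"INV"`) and optionally `id`.
#' @param geno integer matrix, one row per record and one column per sample;
#'   entries are `0` (reference allele / sequence present), `1`
#'   (non-reference / sequence absent for a DEL-type PAV) or `NA` (missing).
#' @param genome named numeric vector of chromosome lengths in bases.
#' @param samples character vector of sample names; defaults to
#'   `colnames(geno)`.
#' @param support optional data frame of per-record evidence with columns
#'   among `SU` (total supporting reads), `PE` (discordant pairs), `SR`
#'   (split reads).
#' @return An object of class `sv_catalog`.
#' @examples
#' rec <- data.frame(chrom = "chr1", start = 100, end = 200, svtype = "DEL")
#' g <- matrix(c(0L, 1L), nrow = 1, dimnames = list(NULL, c("s1", "s2")))
#' sv_catalog(rec, g, genome = c(chr1 = 1000))
#' @export
sv_catalog <- function(records, geno, genome, samples = colnames(geno),
                       support = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "svtype")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(records$id)) {
    records$id <- if (nrow(records)) paste0("sv", seq_len(nrow(records))) else character(0)
  }
  records$chrom <- as.character(records$chrom)
  records$svtype <- as.character(records$svtype)
  if (!all(records$svtype %in% c("DEL", "DUP", "INV"))) {
    stop("svtype must be one of DEL, DUP, INV")
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(records)) {
    stop("geno must have one row per record")
  }
  if (is.null(samples)) {
    if (ncol(geno) == 0L) samples <- character(0) else
      stop("sample names are required")
  }
  colnames(geno) <- samples
  bad <- !(records$chrom %in% names(genome))
  if (any(bad)) {
    stop("record chromosome(s) not in genome: ",
         paste(unique(records$chrom[bad]), collapse = ", "))
  }
  if (any(records$end <= records$start)) {
    stop("all records must satisfy end > start")
  }
  oob <- records$start < 0 | records$end > genome[records$chrom]
  if (any(oob)) {
    stop(sum(oob), " record(s) extend beyond chromosome bounds")
  }
  if (!is.null(support)) {
    support <- as.data.frame(support)
    if (nrow(support) != nrow(records)) {
      stop("support must have one row per record")
    }
  }
  structure(
    list(records = records, geno = geno, genome = genome,
         samples = samples, support = support),
    class = "sv_catalog"
  )
}

#' @export
print.sv_catalog <- function(x, ...) {
  tab <- table(factor(x$records$svtype, levels = c("DEL", "DUP", "INV")))
  cat("sv_catalog:", nrow(x$records), "records,",
      length(x$samples), "samples,",
      length(x$genome), "chromosome(s)\n")
  cat("  DEL:", tab[["DEL"]], " DUP:", tab[["DUP"]], " INV:", tab[["INV"]], "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotype rate: %.3f\n", if (length(x$geno)) miss else 0))
  invisible(x)
}

#' @export
summary.sv_catalog <- function(object, ...) {
  len <- object$records$end - object$records$start
  out <- data.frame(
    svtype = c("DEL", "DUP", "INV"),
    n = as.integer(table(factor(object$records$svtype,
                                levels = c("DEL", "DUP", "INV")))),
    stringsAsFactors = FALSE
  )
  out$mean_length <- vapply(out$svtype, function(t) {
    if (out$n[out$svtype == t] == 0) NA_real_ else mean(len[object$records$svtype == t])
  }, numeric(1))
  out
}

#' Read a chromosome-length table
#'
#' Accepts an FAI-style file: whitespace-separated, chromosome name in column
#' 1 and length in column 2 (extra columns ignored).
#'
#' @param path file path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("genome file needs >= 2 columns (name, length)")
  stats::setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
}

# Collapse a diploid GT string to a presence state.
# 0/0 -> 0; 1/1 -> 1; ./., half-missing and heterozygous calls -> NA.
# Heterozygotes are treated as missing: in a highly selfing species they are
# most often calling artifacts.
.collapse_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0")] <- 0L
  out[gt %in% c("1/1", "1")] <- 1L
  out
}

#' Read a structural-variant VCF into a catalog
#'
#' Parses a VCF 4.2 file carrying `SVTYPE` and `END` (or `SVLEN`) INFO fields
#' and per-sample `GT` calls. 1-based `POS`/`END` are converted to 0-based
#' half-open intervals (`start = POS - 1`, `end = END`). Diploid genotypes
#' are collapsed to presence states (`0/0` -> 0, `1/1` -> 1, anything else ->
#' missing). Records with an SVTYPE outside DEL/DUP/INV are skipped with a
#' message.
#'
#' @param path VCF file path.
#' @param genome named numeric vector of chromosome lengths (see
#'   [read_genome()]).
#' @param support_keys INFO keys to harvest as read-support evidence, in the
#'   order total / discordant-pair / split-read.
#' @return An [sv_catalog()].
#' @export
read_sv_vcf <- function(path, genome, support_keys = c("SU", "PE", "SR")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) {
    return(sv_catalog(data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0), svtype = character(0)),
                      matrix(integer(0), nrow = 0, ncol = 0,
                             dimnames = list(NULL, character(0))),
                      genome, samples = character(0)))
  }
  svtype <- vcfR::extract.info(vcf, "SVTYPE")
  endf <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "END")))
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "SVLEN")))
  pos <- as.numeric(fix[, "POS"])
  keep <- !is.na(svtype) & svtype %in% c("DEL", "DUP", "INV")
  if (any(!keep)) {
    message("read_sv_vcf: skipped ", sum(!keep),
            " record(s) with unknown or missing SVTYPE")
  }
  end <- ifelse(!is.na(endf), endf, pos - 1 + abs(svlen))
  if (any(keep & is.na(end))) {
    stop("record(s) without END or SVLEN at line(s): ",
         paste(utils::head(which(keep & is.na(end)), 5), collapse = ", "))
  }
  records <- data.frame(
    chrom = as.character(fix[keep, "CHROM"]),
    start = pos[keep] - 1,
    end = end[keep],
    svtype = svtype[keep],
    id = as.character(fix[keep, "ID"]),
    stringsAsFactors = FALSE
  )
  noid <- is.na(records$id) | records$id == "."
  records$id[noid] <- paste0("sv", which(noid))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) {
    geno <- matrix(integer(0), nrow = nrow(records), ncol = 0,
                   dimnames = list(NULL, character(0)))
  } else {
    geno <- matrix(.collapse_gt(gt[keep, , drop = FALSE]),
                   nrow = sum(keep), dimnames = list(NULL, colnames(gt)))
  }
  support <- NULL
  if (length(support_keys)) {
    sup <- lapply(support_keys, function(k) {
      suppressWarnings(as.numeric(vcfR::extract.info(vcf, k))[keep])
    })
    names(sup) <- support_keys
    if (any(vapply(sup, function(v) any(!is.na(v)), logical(1)))) {
      support <- as.data.frame(sup)
      pe <- support[[2L]]
      sr <- support[[3L]]
      support$ev_pair <- !is.na(pe) & pe > 0
      support$ev_split <- !is.na(sr) & sr > 0
    }
  }
  sv_catalog(records, geno, genome, samples = colnames(geno), support = support)
}

#' Write a catalog as a structural-variant VCF
#'
#' Emits VCF 4.2 with symbolic ALT alleles, `SVTYPE`/`END`/`SVLEN` (and
#' support) INFO fields and collapsed `GT` calls (`0/0`, `1/1`, `./.`).
#' Round-trips through [read_sv_vcf()].
#'
#' @param catalog an [sv_catalog()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_sv_vcf <- function(catalog, path) {
  stopifnot(inherits(catalog, "sv_catalog"))
  rec <- catalog$records
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(catalog$genome),
            as.integer(catalog$genome)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the variant\">",
    "##INFO=<ID=SU,Number=1,Type=Integer,Description=\"Number of supporting reads\">",
    "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"Number of discordant read pairs\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Number of split reads\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", catalog$samples), collapse = "\t")
  )
  len <- as.integer(rec$end - rec$start)
  svlen <- ifelse(rec$svtype == "DEL", -len, len)
  info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", rec$svtype,
                  as.integer(rec$end), svlen)
  if (!is.null(catalog$support)) {
    sup <- catalog$support
    for (k in intersect(c("SU", "PE", "SR"), names(sup))) {
      v <- sup[[k]]
      add <- ifelse(is.na(v), "", sprintf(";%s=%d", k, as.integer(v)))
      info <- paste0(info, add)
    }
  }
  gt <- matrix("./.", nrow = nrow(rec), ncol = length(catalog$samples))
  gt[which(catalog$geno == 0L)] <- "0/0"
  gt[which(catalog$geno == 1L)] <- "1/1"
  body <- paste(rec$chrom, as.integer(rec$start + 1), rec$id, "N",
                paste0("<", rec$svtype, ">"), ".", ".", info, "GT",
                sep = "\t")
  if (length(catalog$samples)) {
    body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter a catalog to an analysis set
#'
#' Retains records whose type is in `svtypes`, whose length lies in
#' `[min_len, max_len]`, and (optionally) that are polymorphic: at least one
#' presence and one absence call among non-missing genotypes.
#'
#' @param catalog an [sv_catalog()].
#' @param svtypes character vector of types to keep; `NULL` keeps all.
#' @param min_len,max_len inclusive length bounds in bases.
#' @param polymorphic_only drop records fixed (all-0 or all-1) among
#'   non-missing calls.
#' @return A filtered [sv_catalog()].
#' @export
filter_catalog <- function(catalog, svtypes = NULL, min_len = 1,
                           max_len = Inf, polymorphic_only = FALSE) {
  stopifnot(inherits(catalog, "sv_catalog"))
  if (min_len > max_len) stop("min_len must be <= max_len")
  len <- catalog$records$end - catalog$records$start
  keep <- len >= min_len & len <= max_len
  if (!is.null(svtypes)) keep <- keep & catalog$records$svtype %in% svtypes
  if (polymorphic_only && length(catalog$samples)) {
    n1 <- rowSums(catalog$geno == 1L, na.rm = TRUE)
    n0 <- rowSums(catalog$geno == 0L, na.rm = TRUE)
    keep <- keep & n1 > 0 & n0 > 0
  }
  sv_catalog(catalog$records[keep, , drop = FALSE],
             catalog$geno[keep, , drop = FALSE],
             catalog$genome, samples = catalog$samples,
             support = if (is.null(catalog$support)) NULL else
               catalog$support[keep, , drop = FALSE])
}

#' Read gene intervals from a GFF3 annotation
#'
#' Keeps features of type `gene` and converts them to 0-based half-open
#' intervals.
#'
#' @param path GFF3 file path.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Read a gene-to-term assignment table
#'
#' Two tab-separated columns: gene id, term id; one row per assignment.
#'
#' @param path file path.
#' @param annotation optional annotation data frame (from
#'   [read_annotation()]); genes in the table but absent from the annotation
#'   trigger a warning and are retained (they still belong in enrichment
#'   universes).
#' @return Data frame with columns `gene_id`, `term_id`.
#' @export
read_terms <- function(path, annotation = NULL) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("gene_id", "term_id"))
  if (!is.null(annotation)) {
    missing <- setdiff(tab$gene_id, annotation$gene_id)
    if (length(missing)) {
      warning(length(missing),
              " gene(s) in the term table are absent from the annotation")
    }
  }
  tab
}

#' Read a sample-to-population map
#'
#' Two tab-separated columns: sample name, population label.
#'
#' @param path file path.
#' @return An object of class `pop_map`: a list with `sample2pop` (named
#'   character vector) and `pops` (named list of ordered sample vectors).
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  if (anyDuplicated(tab$sample)) {
    stop("sample(s) assigned to more than one population: ",
         paste(unique(tab$sample[duplicated(tab$sample)]), collapse = ", "))
  }
  pop_map(stats::setNames(tab$population, tab$sample))
}

#' Build a population map from a named vector
#'
#' @param sample2pop named character vector mapping sample name to
#'   population label.
#' @return A `pop_map` object.
#' @export
pop_map <- function(sample2pop) {
  stopifnot(!is.null(names(sample2pop)))
  pops <- split(names(sample2pop), sample2pop)
  structure(list(sample2pop = sample2pop, pops = pops), class = "pop_map")
}

#' @export
print.pop_map <- function(x, ...) {
  cat("pop_map:", length(x$sample2pop), "samples in",
      length(x$pops), "population(s)\n")
  for (p in names(x$pops)) cat("  ", p, ": ", length(x$pops[[p]]),
                               " samples\n", sep = "")
  invisible(x)
}

#' Read a SNP genotype VCF as a presence matrix
#'
#' Minimal biallelic-SNP reader for the LD-tagging workflow: returns SNP
#' positions and the collapsed genotype matrix (same 0/1/NA convention as
#' the SV reader).
#'
#' @param path VCF file path.
#' @return List with `pos` (data frame: `chrom`, `pos` 1-based, `id`) and
#'   `geno` (sites x samples integer matrix).
#' @export
read_snp_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  geno <- matrix(.collapse_gt(gt), nrow = nrow(fix),
                 dimnames = list(NULL, colnames(gt)))
  list(
    pos = data.frame(chrom = as.character(fix[, "CHROM"]),
                     pos = as.numeric(fix[, "POS"]),
                     id = as.character(fix[, "ID"]),
                     stringsAsFactors = FALSE),
    geno = geno
  )
}
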