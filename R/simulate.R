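#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: a compact two-
#' chromosome genome, a gene annotation with clustered defense genes, two
#' selfing populations plus a small panel of divergent polarizer accessions,
#' and PAV genotypes whose site-frequency spectra differ by gene class
#' (neutral `1/k` spectra everywhere except defense genes, whose derived
#' frequencies are Beta-distributed around 0.5).
#'
#' @param chrom_lengths named vector of chromosome lengths (bases).
#' @param n_genes number of genes.
#' @param gene_len_meanlog,gene_len_sdlog log-normal gene-length parameters.
#' @param genes_per_cluster,cluster_spacing genes are placed in tandem
#'   clusters with this many genes and this many bases between neighbours.
#' @param defense_fraction fraction of genes carrying the defense term;
#'   whole clusters are designated defense, so defense genes are clustered.
#' @param defense_term term id assigned to defense genes.
#' @param n_terms,terms_per_gene generic term pool size and assignments per
#'   gene.
#' @param populations named vector of population sample sizes (each >= 4).
#' @param n_polarizers number of divergent polarizer accessions.
#' @param n_pavs total PAV count.
#' @param pav_len_meanlog,pav_len_sdlog,pav_min_len,pav_max_len log-normal
#'   PAV length model, truncated to `[pav_min_len, pav_max_len]`.
#' @param density_ratio target intergenic/genic per-base PAV coverage ratio.
#' @param defense_pav_boost per-base PAV rate in defense genes relative to
#'   other genic sequence.
#' @param balanced_kappa Beta concentration of defense-class derived
#'   frequencies: `q ~ Beta(kappa/2, kappa/2)`; large kappa pins q at 0.5.
#' @param anc_alt_fraction fraction of loci where the ancestral allele is
#'   the alternate (absence) allele.
#' @param missing_rate per-call missing probability.
#' @param polarizer_derived_rate probability a polarizer carries the derived
#'   allele.
#' @param n_background_snps unlinked SNPs scattered over the genome.
#' @param n_tag_pavs,snps_per_pav,target_r2 focal PAVs that receive nearby
#'   SNPs, one of which is generated at squared correlation ~ `target_r2`
#'   with the PAV.
#' @param n_null_variants extra uniformly placed intervals forming, with the
#'   PAVs, the permutation universe for clustering-aware enrichment tests.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 400000, chr2 = 400000),
                       n_genes = 220,
                       gene_len_meanlog = log(1500),
                       gene_len_sdlog = 0.5,
                       genes_per_cluster = 5,
                       cluster_spacing = 400,
                       defense_fraction = 0.2,
                       defense_term = "GO:0006952",
                       n_terms = 20,
                       terms_per_gene = 2,
                       populations = c(pop1 = 24, pop2 = 24),
                       n_polarizers = 5,
                       n_pavs = 800,
                       pav_len_meanlog = log(80),
                       pav_len_sdlog = 1.2,
                       pav_min_len = 1,
                       pav_max_len = 10000,
                       density_ratio = 3.5,
                       defense_pav_boost = 3,
                       balanced_kappa = 20,
                       anc_alt_fraction = 0.1,
                       missing_rate = 0.05,
                       polarizer_derived_rate = 0.05,
                       n_background_snps = 200,
                       n_tag_pavs = 100,
                       snps_per_pav = 5,
                       target_r2 = 0.75,
                       n_null_variants = 4000) {
  cfg <- as.list(environment())
  probs <- c(defense_fraction, anc_alt_fraction, missing_rate,
             polarizer_derived_rate, target_r2)
  stopifnot(all(probs >= 0 & probs <= 1), all(populations >= 4),
            density_ratio > 0, balanced_kappa > 0,
            n_tag_pavs <= n_pavs, pav_min_len >= 1,
            pav_max_len >= pav_min_len)
  structure(cfg, class = "sim_config")
}

# truncated log-normal lengths
.rlen <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- round(stats::rlnorm(n, meanlog, sdlog))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# Place `lengths` as non-overlapping intervals inside `regions` (data frame
# chrom/start/end). Maintains the list of free gaps explicitly: each event
# picks a gap that fits (weighted by the number of admissible start
# offsets), then splits it. Errors only when no gap can hold an event.
.place_in_regions <- function(lengths, regions) {
  g_chrom <- as.character(regions$chrom)
  g_start <- as.numeric(regions$start)
  g_end <- as.numeric(regions$end)
  ord <- order(-lengths)  # large events first: they are the hardest to fit
  out_chrom <- character(length(lengths))
  out_start <- numeric(length(lengths))
  for (i in ord) {
    len <- lengths[i]
    w <- g_end - g_start
    fit <- which(w >= len)
    if (!length(fit)) {
      stop("infeasible density: no free gap can hold an interval of ",
           len, " bases")
    }
    slots <- w[fit] - len + 1
    gi <- if (length(fit) == 1L) fit else
      fit[sample.int(length(fit), 1L, prob = slots)]
    off <- floor(stats::runif(1) * (w[gi] - len + 1))
    s <- g_start[gi] + off
    out_chrom[i] <- g_chrom[gi]
    out_start[i] <- s
    # split the gap around [s, s + len)
    left_end <- s
    right_start <- s + len
    old_end <- g_end[gi]
    if (left_end > g_start[gi]) {
      g_end[gi] <- left_end
    } else {
      g_end[gi] <- g_start[gi]  # empty
    }
    if (right_start < old_end) {
      g_chrom <- c(g_chrom, g_chrom[gi])
      g_start <- c(g_start, right_start)
      g_end <- c(g_end, old_end)
    }
  }
  data.frame(chrom = out_chrom, start = out_start,
             end = out_start + lengths, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic data set
#'
#' Emits a genome (FASTA + length table), a gene annotation (GFF3) with
#' clustered defense genes, a gene-to-term table, a PAV VCF with genotypes
#' for all population samples and polarizer accessions, a SNP VCF, a
#' population map, and a truth ledger recording each variant's class and
#' generating model. All outputs are plain text, deterministic for a fixed
#' seed, and re-readable by the package's readers.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed); `NULL` skips writing.
#' @param seed integer seed.
#' @return An object of class `sim_output`: `paths` (named file paths, when
#'   written), `catalog` (the PAV [sv_catalog()]), `genes`, `terms`,
#'   `popmap`, `truth` (ledger data frame), `snps` (list `pos`, `geno`),
#'   `null_variants`, `focal_pavs` (indices of tag-SNP focal PAVs),
#'   `polarizers`, `config`, `seed`.
#' @export
generate <- function(config = sim_config(), dir = NULL, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  genome <- config$chrom_lengths
  ## ---- genes in tandem clusters --------------------------------------
  n_genes <- config$n_genes
  gpc <- config$genes_per_cluster
  n_clust <- ceiling(n_genes / gpc)
  sizes <- rep(gpc, n_clust)
  sizes[n_clust] <- n_genes - gpc * (n_clust - 1L)
  n_def_genes <- round(config$defense_fraction * n_genes)
  n_def_clust <- ceiling(n_def_genes / gpc)
  def_clusters <- sample.int(n_clust, n_def_clust)
  gene_rows <- list()
  occupied <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0))
  gi <- 0L
  for (cl in seq_len(n_clust)) {
    lens <- .rlen(sizes[cl], config$gene_len_meanlog, config$gene_len_sdlog,
                  200, 20000)
    span <- sum(lens) + config$cluster_spacing * (sizes[cl] - 1L)
    placed <- FALSE
    for (t in 1:500) {
      chr <- sample(names(genome), 1L, prob = genome)
      if (genome[[chr]] <= span) next
      s <- sample.int(genome[[chr]] - span, 1L) - 1L
      cand <- data.frame(chrom = chr, start = s, end = s + span)
      if (nrow(occupied) && length(.overlapping_idx(cand, occupied))) next
      occupied <- rbind(occupied, cand)
      at <- s
      for (g in seq_len(sizes[cl])) {
        gi <- gi + 1L
        gene_rows[[gi]] <- data.frame(
          gene_id = sprintf("gene%04d", gi), chrom = chr, start = at,
          end = at + lens[g], cluster = cl,
          defense = cl %in% def_clusters, stringsAsFactors = FALSE)
        at <- at + lens[g] + config$cluster_spacing
      }
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place gene cluster ", cl)
  }
  genes <- do.call(rbind, gene_rows)
  genes <- genes[order(genes$chrom, genes$start), ]
  rownames(genes) <- NULL
  defense_genes <- genes$gene_id[genes$defense]

  ## ---- term table -----------------------------------------------------
  pool <- sprintf("GO:%07d", seq_len(config$n_terms))
  term_rows <- lapply(seq_len(nrow(genes)), function(i) {
    tms <- sample(pool, config$terms_per_gene)
    if (genes$defense[i]) tms <- c(config$defense_term, tms)
    data.frame(gene_id = genes$gene_id[i], term_id = tms,
               stringsAsFactors = FALSE)
  })
  terms <- do.call(rbind, term_rows)

  ## ---- PAV placement --------------------------------------------------
  part <- build_partition(genes[, c("chrom", "start", "end")], genome)
  def_iv <- .merge_intervals(genes[genes$defense, c("chrom", "start", "end")])
  other_genic <- as.data.frame(.from_granges(GenomicRanges::setdiff(
    .as_granges(part$genic), .as_granges(def_iv))))
  span_g <- part$genic_bases
  span_i <- part$intergenic_bases
  span_d <- sum(def_iv$end - def_iv$start)
  span_o <- span_g - span_d
  lens <- .rlen(config$n_pavs, config$pav_len_meanlog, config$pav_len_sdlog,
                config$pav_min_len, config$pav_max_len)
  lens <- sample(lens)  # random order for unbiased greedy allocation
  B_total <- sum(lens)
  B_g <- B_total / (1 + config$density_ratio * span_i / span_g)
  B_d <- B_g / (1 + span_o / (config$defense_pav_boost * span_d))
  B_o <- B_g - B_d
  targets <- c(defense = B_d, other = B_o, intergenic = B_total - B_g)
  cum <- c(defense = 0, other = 0, intergenic = 0)
  where <- character(length(lens))
  for (i in seq_along(lens)) {
    deficit <- targets - cum
    w <- names(which.max(deficit))
    where[i] <- w
    cum[w] <- cum[w] + lens[i]
  }
  # shrink events too long for their destination regions
  cap_for <- function(regions) max(regions$end - regions$start)
  caps <- c(defense = cap_for(def_iv), other = cap_for(other_genic),
            intergenic = cap_for(part$intergenic))
  lens <- pmin(lens, caps[where])
  reg_sets <- list(defense = def_iv, other = other_genic,
                   intergenic = part$intergenic)
  pav_list <- lapply(c("defense", "other", "intergenic"), function(w) {
    idx <- which(where == w)
    if (!length(idx)) return(NULL)
    df <- .place_in_regions(lens[idx], reg_sets[[w]])
    df$placement <- w
    df
  })
  pavs <- do.call(rbind, pav_list)
  pavs <- pavs[order(pavs$chrom, pavs$start, pavs$end), ]
  rownames(pavs) <- NULL
  pavs$id <- sprintf("pav%04d", seq_len(nrow(pavs)))
  pavs$svtype <- "DEL"
  pavs$model <- ifelse(pavs$placement == "defense", "balanced", "neutral")

  ## ---- genotypes -------------------------------------------------------
  pops <- config$populations
  pop_samples <- unlist(lapply(names(pops), function(p) {
    sprintf("%s_%02d", p, seq_len(pops[[p]]))
  }))
  pol_samples <- sprintf("rel%d", seq_len(config$n_polarizers))
  samples <- c(pop_samples, pol_samples)
  sample_pop <- rep(names(pops), times = pops)
  np <- nrow(pavs)
  geno <- matrix(NA_integer_, nrow = np, ncol = length(samples),
                 dimnames = list(NULL, samples))
  anc_alt <- stats::runif(np) < config$anc_alt_fraction
  half <- config$balanced_kappa / 2
  kfreq <- lapply(pops, function(n) (1 / seq_len(n - 1)) /
                    sum(1 / seq_len(n - 1)))
  truth_k <- matrix(0L, nrow = np, ncol = length(pops),
                    dimnames = list(NULL, names(pops)))
  for (pi in seq_along(pops)) {
    n <- pops[[pi]]
    cols <- which(sample_pop == names(pops)[pi])
    for (v in seq_len(np)) {
      if (pavs$model[v] == "balanced") {
        repeat {
          q <- stats::rbeta(1, half, half)
          k <- stats::rbinom(1, n, q)
          if (k > 0 && k < n) break
        }
      } else {
        k <- sample.int(n - 1L, 1L, prob = kfreq[[pi]])
      }
      truth_k[v, pi] <- k
      derived <- integer(n)
      derived[sample.int(n, k)] <- 1L
      geno[v, cols] <- if (anc_alt[v]) 1L - derived else derived
    }
  }
  pol_derived <- matrix(
    as.integer(stats::runif(np * length(pol_samples)) <
                 config$polarizer_derived_rate),
    nrow = np)
  geno[, pol_samples] <- ifelse(matrix(anc_alt, np, length(pol_samples)),
                                1L - pol_derived, pol_derived)
  miss <- matrix(stats::runif(length(geno)) < config$missing_rate,
                 nrow = np)
  geno[miss] <- NA_integer_

  catalog <- sv_catalog(pavs[, c("chrom", "start", "end", "svtype", "id")],
                        geno, genome, samples = samples)
  popmap <- pop_map(stats::setNames(
    c(sample_pop, rep("relict", length(pol_samples))), samples))

  ## ---- SNPs ------------------------------------------------------------
  focal <- sort(sample.int(np, config$n_tag_pavs))
  # Flip rate achieving cor(PAV, tag SNP) = sqrt(target_r2) at PAV
  # frequency p. A constant rate only hits the target at p = 0.5: with a
  # symmetric per-sample flip at rate e, cov = p(1-p)(1-2e) while the SNP
  # variance grows as its frequency is pulled toward 0.5, so the rate must
  # shrink as p leaves 0.5.
  eps_for <- function(p, r) {
    if (is.na(p) || p <= 0 || p >= 1) return(0)
    f <- function(e) {
      ey <- p + e * (1 - 2 * p)
      p * (1 - p) * (1 - 2 * e) / sqrt(p * (1 - p) * ey * (1 - ey)) - r
    }
    if (f(0.5 - 1e-9) > 0) return(0.5 - 1e-9)
    stats::uniroot(f, c(0, 0.5 - 1e-9), tol = 1e-9)$root
  }
  snp_rows <- list()
  snp_geno <- list()
  si <- 0L
  add_snp <- function(chrom, pos, g) {
    si <<- si + 1L
    snp_rows[[si]] <<- data.frame(chrom = chrom, pos = pos,
                                  id = sprintf("snp%05d", si),
                                  stringsAsFactors = FALSE)
    snp_geno[[si]] <<- g
  }
  neutral_snp_geno <- function() {
    g <- integer(length(samples))
    for (pi in seq_along(pops)) {
      n <- pops[[pi]]
      cols <- which(sample_pop == names(pops)[pi])
      k <- sample.int(n - 1L, 1L, prob = kfreq[[pi]])
      gg <- integer(n)
      gg[sample.int(n, k)] <- 1L
      g[cols] <- gg
    }
    g
  }
  for (b in seq_len(config$n_background_snps)) {
    chr <- sample(names(genome), 1L, prob = genome)
    add_snp(chr, sample.int(genome[[chr]], 1L), neutral_snp_geno())
  }
  for (f in focal) {
    mid <- (pavs$start[f] + pavs$end[f]) / 2
    chr <- pavs$chrom[f]
    offs <- sample.int(10000L, config$snps_per_pav) - 5000L
    pos <- pmax(1, pmin(genome[[chr]], round(mid + offs)))
    pav_g <- geno[f, ]
    p_f <- mean(pav_g == 1L, na.rm = TRUE)
    eps <- eps_for(p_f, sqrt(config$target_r2))
    tag <- ifelse(is.na(pav_g), 0L,
                  as.integer(xor(pav_g == 1L,
                                 stats::runif(length(pav_g)) < eps)))
    add_snp(chr, pos[1L], tag)
    for (j in seq_len(config$snps_per_pav - 1L)) {
      add_snp(chr, pos[j + 1L], neutral_snp_geno())
    }
  }
  snp_pos <- do.call(rbind, snp_rows)
  snp_mat <- do.call(rbind, snp_geno)
  colnames(snp_mat) <- samples
  ord <- order(snp_pos$chrom, snp_pos$pos)
  snp_pos <- snp_pos[ord, , drop = FALSE]
  snp_mat <- snp_mat[ord, , drop = FALSE]
  rownames(snp_pos) <- NULL

  ## ---- null variants for permutation universes ------------------------
  nv <- config$n_null_variants
  null_lens <- .rlen(nv, config$pav_len_meanlog, config$pav_len_sdlog,
                     config$pav_min_len, config$pav_max_len)
  null_chr <- sample(names(genome), nv, replace = TRUE, prob = genome)
  null_start <- vapply(seq_len(nv), function(i) {
    L <- genome[[null_chr[i]]]
    len <- min(null_lens[i], L - 1)
    sample.int(L - len, 1L) - 1L
  }, numeric(1))
  null_variants <- data.frame(chrom = null_chr, start = null_start,
                              end = null_start + pmin(null_lens,
                                genome[null_chr] - null_start - 1),
                              stringsAsFactors = FALSE)

  ## ---- truth ledger ----------------------------------------------------
  truth <- data.frame(
    id = pavs$id, chrom = pavs$chrom, start = pavs$start, end = pavs$end,
    placement = pavs$placement,
    defense = pavs$placement == "defense",
    genic = pavs$placement %in% c("defense", "other"),
    model = pavs$model,
    anc_alt = anc_alt,
    stringsAsFactors = FALSE)
  for (p in names(pops)) truth[[paste0("k_", p)]] <- truth_k[, p]

  out <- structure(
    list(catalog = catalog, genes = genes, terms = terms, popmap = popmap,
         truth = truth, snps = list(pos = snp_pos, geno = snp_mat),
         null_variants = null_variants, focal_pavs = focal,
         polarizers = pol_samples, defense_genes = defense_genes,
         config = config, seed = seed, paths = NULL),
    class = "sim_output")

  ## ---- files -----------------------------------------------------------
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(fasta = file.path(dir, "genome.fa"),
               fai = file.path(dir, "genome.tsv"),
               gff = file.path(dir, "genes.gff3"),
               terms = file.path(dir, "terms.tsv"),
               pav_vcf = file.path(dir, "pavs.vcf"),
               snp_vcf = file.path(dir, "snps.vcf"),
               popmap = file.path(dir, "popmap.tsv"),
               truth = file.path(dir, "truth.tsv"))
    dna <- Biostrings::DNAStringSet(vapply(names(genome), function(chr) {
      paste(sample(c("A", "C", "G", "T"), genome[[chr]], replace = TRUE),
            collapse = "")
    }, character(1)))
    Biostrings::writeXStringSet(dna, paths[["fasta"]])
    writeLines(paste(names(genome), as.integer(genome), sep = "\t"),
               paths[["fai"]])
    gff <- c("##gff-version 3",
             sprintf("%s\tpavkit\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                     genes$chrom, as.integer(genes$start + 1),
                     as.integer(genes$end), genes$gene_id))
    writeLines(gff, paths[["gff"]])
    utils::write.table(terms, paths[["terms"]], sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    write_sv_vcf(catalog, paths[["pav_vcf"]])
    .write_snp_vcf(snp_pos, snp_mat, genome, paths[["snp_vcf"]])
    utils::write.table(
      data.frame(sample = samples,
                 population = c(sample_pop,
                                rep("relict", length(pol_samples)))),
      paths[["popmap"]], sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

.write_snp_vcf <- function(pos, geno, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome),
                   as.integer(genome)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(geno)), collapse = "\t"))
  gt <- matrix("./.", nrow = nrow(geno), ncol = ncol(geno))
  gt[which(geno == 0L)] <- "0/0"
  gt[which(geno == 1L)] <- "1/1"
  body <- paste(pos$chrom, as.integer(pos$pos), pos$id, "A", "T", ".", ".",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
}

#' @export
print.sim_output <- function(x, ...) {
  cat("sim_output (seed", x$seed, "):", nrow(x$catalog$records), "PAVs,",
      nrow(x$genes), "genes (", length(x$defense_genes), "defense ),",
      nrow(x$snps$pos), "SNPs,", length(x$catalog$samples), "samples\n")
  invisible(x)
}

#' Write the hand-checkable micro-fixtures
#'
#' Emits the small worked examples used across the documentation and tests:
#' a 3-record SV VCF with its chromosome-length table, a 4-taxon additive
#' distance matrix, and a 2x2 enrichment table.
#'
#' @param dir output directory.
#' @return Named vector of file paths, invisibly.
#' @export
make_worked_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf <- file.path(dir, "mini_svs.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t101\tdel1\tN\t<DEL>\t.\t.\tSVTYPE=DEL;END=200;SVLEN=-100\tGT\t0/0\t1/1\t./.",
    "chr1\t1001\tdup1\tN\t<DUP>\t.\t.\tSVTYPE=DUP;END=1500;SVLEN=500\tGT\t1/1\t0/0\t0/1",
    "chr1\t5001\tinv1\tN\t<INV>\t.\t.\tSVTYPE=INV;END=6000;SVLEN=1000\tGT\t0/0\t0/0\t1/1"),
    vcf)
  fai <- file.path(dir, "mini_genome.tsv")
  writeLines("chr1\t100000", fai)
  dist <- file.path(dir, "quartet_distances.tsv")
  # additive distances on the tree ((A:1,B:2):1,(C:3,D:1))
  dm <- matrix(c(0, 3, 5, 3,
                 3, 0, 6, 4,
                 5, 6, 0, 4,
                 3, 4, 4, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), NULL))
  utils::write.table(dm, dist, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  tab <- file.path(dir, "enrichment_2x2.tsv")
  writeLines(c("k\tn\tK\tN", "8\t10\t10\t100"), tab)
  invisible(c(vcf = vcf, fai = fai, dist = dist, table = tab))
}
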