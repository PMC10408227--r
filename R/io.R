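#' Read a VCF into a GenotypeMatrix
#'
#' Parses GT fields with 2 or 4 alleles per sample into alternate-allele
#' dosages. Non-biallelic records are skipped and their count reported via
#' a message and the `"n_skipped"` attribute. An `AA` INFO tag, when
#' present, sets the per-site ancestral polarization.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @return a [genotype_matrix()] with attribute `n_skipped`.
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  alt_list <- VariantAnnotation::alt(vcf)
  biallelic <- S4Vectors::elementNROWS(alt_list) == 1L
  n_skipped <- sum(!biallelic)
  if (n_skipped > 0)
    message("read_vcf: skipped ", n_skipped, " non-biallelic record(s)")
  vcf <- vcf[biallelic, ]
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  rr <- SummarizedExperiment::rowRanges(vcf)

  parse_col <- function(g) {
    toks <- strsplit(g, "[/|]")
    pl <- lengths(toks)
    miss <- vapply(toks, function(t) any(t == "."), logical(1)) |
      g %in% c(".", "./.", ".|.")
    dos <- vapply(toks, function(t) sum(t == "1"), integer(1))
    dos[miss] <- NA_integer_
    pl[g %in% c(".", "")] <- NA_integer_
    list(dosage = dos, ploidy = pl)
  }
  cols <- apply(gt, 2, parse_col, simplify = FALSE)
  dosage <- do.call(cbind, lapply(cols, `[[`, "dosage"))
  colnames(dosage) <- colnames(gt)
  ploidy <- vapply(cols, function(cc) {
    u <- unique(cc$ploidy[!is.na(cc$ploidy)])
    if (length(u) > 1L)
      stop("mixed ploidy within one sample across sites")
    if (length(u) == 0L) 2L else u
  }, integer(1))

  aa <- NULL
  if ("AA" %in% names(VariantAnnotation::info(vcf)))
    aa <- as.character(VariantAnnotation::info(vcf)$AA)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- vapply(VariantAnnotation::alt(vcf), function(a)
    if (length(a)) as.character(a)[1] else NA_character_, character(1))
  anc <- if (is.null(aa)) NULL else ifelse(is.na(aa) | aa == ".", NA,
                                           toupper(aa) == toupper(ref))
  if (length(ref) == 0L) {
    gm <- genotype_matrix(character(0), integer(0), character(0),
                          character(0),
                          matrix(integer(0), 0, ncol(gt),
                                 dimnames = list(NULL, colnames(gt))),
                          rep(2L, ncol(gt)))
  } else {
    gm <- genotype_matrix(as.character(GenomicRanges::seqnames(rr)),
                          GenomicRanges::start(rr), ref, alt,
                          dosage, ploidy, anc)
  }
  attr(gm, "n_skipped") <- n_skipped
  gm
}

#' Write a GenotypeMatrix to a VCF file
#'
#' Emits a minimal VCF 4.2 with GT genotypes (unphased); tetraploid
#' genotypes are written with four alleles. Polarized sites carry an `AA`
#' INFO tag. Round-trips exactly through [read_vcf()].
#'
#' @param gm a `GenotypeMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")), con)
  if (n_sites(gm) == 0) return(invisible(path))
  gt_str <- function(d, pl) {
    if (is.na(d)) return(paste(rep(".", pl), collapse = "/"))
    paste(c(rep("0", pl - d), rep("1", d)), collapse = "/")
  }
  info <- ifelse(is.na(gm$ancestral_is_ref), ".",
                 paste0("AA=", ifelse(gm$ancestral_is_ref, gm$ref, gm$alt)))
  gts <- vapply(seq_len(n_sites(gm)), function(i)
    paste(mapply(gt_str, gm$dosage[i, ], gm$ploidy), collapse = "\t"),
    character(1))
  writeLines(paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS",
                   info, "GT", gts, sep = "\t"), con)
  invisible(path)
}

#' Read genomic intervals from BED, GFF3 or TSV
#'
#' All intervals are held internally as 0-based half-open. BED input is
#' already in that convention; GFF3 1-based closed coordinates are
#' converted (`start - 1`, `end`). TSV input must have columns
#' `chrom`, `start`, `end` (0-based half-open) and optionally `label`.
#'
#' @param path input file.
#' @param format one of `"bed"`, `"gff3"`, `"tsv"`.
#' @return a data.frame of class `IntervalSet` with columns `chrom`,
#'   `start`, `end`, `label`, `source`.
#' @export
read_intervals <- function(path, format = c("bed", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("chrom", "start", "end") %in% names(tab)))
      stop("TSV intervals need chrom/start/end columns")
    out <- interval_set(tab$chrom, tab$start, tab$end,
                        label = if ("label" %in% names(tab)) tab$label else NA,
                        source = basename(path))
    return(out)
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  label <- if (format == "bed") {
    if (!is.null(gr$name)) gr$name else rep(NA_character_, length(gr))
  } else {
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA, length(gr))
    if (!is.null(gr$type)) ifelse(is.na(ids), as.character(gr$type), ids)
    else ids
  }
  # GRanges is 1-based closed for both formats after import
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
               label = label, source = basename(path))
}

#' Construct an IntervalSet
#'
#' @param chrom,start,end vectors defining 0-based half-open intervals.
#' @param label optional feature labels (gene id, SV type, TE class...).
#' @param source provenance string.
#' @return data.frame of class `IntervalSet`.
#' @export
interval_set <- function(chrom, start, end, label = NA, source = NA) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 0)) stop("negative interval coordinates")
  if (any(start >= end)) stop("interval start must be < end")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    label = as.character(label), source = as.character(source),
                    stringsAsFactors = FALSE)
  class(out) <- c("IntervalSet", "data.frame")
  out
}

## IntervalSet -> GRanges (1-based closed) for overlap machinery
as_granges <- function(iv) {
  GenomicRanges::GRanges(iv$chrom,
                         IRanges::IRanges(start = iv$start + 1L, end = iv$end))
}

#' SNP filter settings
#'
#' Defaults reproduce the neutral-and-independent SNP filter used for
#' population-structure analyses: drop SNPs inside coding sequence plus a
#' 20 kb margin, thin to one SNP per 20 kb, and drop minor allele
#' frequency below 1%.
#'
#' @param cds_margin_bp margin added to both sides of each CDS interval.
#' @param thin_bp minimum distance between retained SNPs.
#' @param maf_min minimum minor allele frequency.
#' @return a list of class `FilterConfig`.
#' @export
filter_config <- function(cds_margin_bp = 20000L, thin_bp = 20000L,
                          maf_min = 0.01) {
  stopifnot(cds_margin_bp >= 0, thin_bp >= 0,
            maf_min >= 0, maf_min <= 0.5)
  structure(list(cds_margin_bp = as.integer(cds_margin_bp),
                 thin_bp = as.integer(thin_bp), maf_min = maf_min),
            class = "FilterConfig")
}

#' Neutral-and-independent SNP filter
#'
#' Three filters applied in fixed order: (1) remove sites overlapping any
#' CDS interval extended by `cds_margin_bp` on both sides; (2) greedy
#' left-to-right thinning per chromosome, keeping a site only if at least
#' `thin_bp` from the previously kept site; (3) remove sites with minor
#' allele frequency below `maf_min`, computed over all non-missing
#' chromosomes jointly.
#'
#' @param gm a `GenotypeMatrix`.
#' @param cds an `IntervalSet` of coding sequence, or `NULL` to skip the
#'   CDS filter.
#' @param cfg a [filter_config()].
#' @return filtered `GenotypeMatrix`.
#' @export
filter_neutral_independent <- function(gm, cds = NULL,
                                       cfg = filter_config()) {
  if (n_sites(gm) == 0) stop("empty GenotypeMatrix")
  keep <- rep(TRUE, n_sites(gm))

  if (!is.null(cds) && nrow(cds) > 0) {
    ext <- cds
    ext$start <- pmax(0L, ext$start - cfg$cds_margin_bp)
    ext$end <- ext$end + cfg$cds_margin_bp
    sites <- GenomicRanges::GRanges(gm$chrom,
                                    IRanges::IRanges(gm$pos, width = 1L))
    hits <- GenomicRanges::findOverlaps(sites, as_granges(ext))
    keep[unique(S4Vectors::queryHits(hits))] <- FALSE
  }

  # greedy thinning, smallest coordinate first within each chromosome
  for (ch in unique(gm$chrom)) {
    idx <- which(keep & gm$chrom == ch)
    if (length(idx) < 2) next
    last <- gm$pos[idx[1]]
    for (i in idx[-1]) {
      if (gm$pos[i] - last < cfg$thin_bp) keep[i] <- FALSE
      else last <- gm$pos[i]
    }
  }

  ac <- site_allele_counts(gm)
  maf <- pmin(ac$alt, ac$n - ac$alt) / ac$n
  keep[is.finite(maf) & maf < cfg$maf_min] <- FALSE
  subset_sites(gm, keep)
}

#' Random two-allele subsampling of tetraploid genotypes
#'
#' For each tetraploid genotype, draws 2 of the sample's 4 chromosomes
#' without replacement (hypergeometric on the alt dosage), producing a
#' pseudo-diploid dosage in 0..2. Diploid samples pass through unchanged.
#' Used to place tetraploids on the same sample-size footing as diploids
#' before computing frequency-spectrum statistics; downstream results are
#' checked for stability across replicates with
#' [replicate_consistency()].
#'
#' @param gm a `GenotypeMatrix` with at least one tetraploid sample.
#' @param n_replicates number of independent subsampled datasets.
#' @param seed integer seed; replicate r uses stream `seed + r`.
#' @return list of `n_replicates` diploidized `GenotypeMatrix` objects.
#' @export
subsample_two_alleles <- function(gm, n_replicates = 5L, seed = 1L) {
  tet <- which(gm$ploidy == 4L)
  if (length(tet) == 0) stop("no tetraploid samples to subsample")
  lapply(seq_len(n_replicates), function(r) {
    set.seed(seed + r)
    d <- gm$dosage
    for (s in tet) {
      x <- d[, s]
      ok <- !is.na(x)
      # drawn alt alleles among 2 of 4 chromosomes
      d[ok, s] <- stats::rhyper(sum(ok), m = x[ok], n = 4L - x[ok], k = 2L)
    }
    pl <- gm$ploidy
    pl[tet] <- 2L
    genotype_matrix(gm$chrom, gm$pos, gm$ref, gm$alt, d, pl,
                    gm$ancestral_is_ref)
  })
}

#' Rank-sum consistency of replicate window statistics
#'
#' Two-sided Wilcoxon rank-sum test between each pair of replicate window
#' tables on the chosen statistic, to confirm random two-allele
#' subsampling does not materially change the windowed statistics.
#'
#' @param stat_tables list of window statistic data.frames over identical
#'   windows (same chrom/start/end rows in the same order).
#' @param statistic column name to compare.
#' @return symmetric matrix of p-values with unit diagonal.
#' @export
replicate_consistency <- function(stat_tables, statistic) {
  k <- length(stat_tables)
  if (k < 2) stop("need at least two replicate tables")
  key <- function(t) paste(t$chrom, t$start, t$end)
  k1 <- key(stat_tables[[1]])
  for (t in stat_tables[-1])
    if (!identical(key(t), k1)) stop("replicate tables have mismatched windows")
  p <- diag(1, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    xi <- stat_tables[[i]][[statistic]]
    xj <- stat_tables[[j]][[statistic]]
    ok <- is.finite(xi) & is.finite(xj)
    p[i, j] <- p[j, i] <-
      stats::wilcox.test(xi[ok], xj[ok], exact = FALSE)$p.value
  }
  p
}
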