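#' Biallelic genotype matrix with per-sample ploidy
#'
#' Container for biallelic variant sites genotyped in a mixed-ploidy panel.
#' Each site stores the count of alternate alleles ("dosage") per sample;
#' samples are diploid (dosage 0--2) or tetraploid (dosage 0--4). Missing
#' genotypes are `NA`, distinct from dosage 0.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions (VCF convention),
#'   strictly increasing within each chromosome.
#' @param ref,alt single-character reference / alternate alleles per site.
#' @param dosage integer matrix, sites x samples; entry is the number of
#'   alternate alleles carried by the sample, `NA` if missing.
#' @param ploidy integer vector, one per sample, each 2 or 4.
#' @param ancestral_is_ref optional logical per site: `TRUE` if the
#'   reference allele is ancestral (outgroup polarization), `NA` unknown.
#'
#' @return An object of class `GenotypeMatrix`: a list with the validated
#'   fields above plus `samples` (column names of `dosage`).
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, dosage, ploidy,
                            ancestral_is_ref = NULL) {
  n_sites <- length(chrom)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("s", seq_len(ncol(dosage)))
  stopifnot(
    length(pos) == n_sites, length(ref) == n_sites, length(alt) == n_sites,
    nrow(dosage) == n_sites, length(ploidy) == ncol(dosage)
  )
  if (!all(ploidy %in% c(2L, 4L)))
    stop("per-sample ploidy must be 2 or 4")
  pos <- as.integer(pos)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  bad <- sweep(dosage, 2, as.integer(ploidy), ">")
  if (any(bad, na.rm = TRUE))
    stop("dosage exceeds sample ploidy")
  if (any(dosage < 0L, na.rm = TRUE))
    stop("negative dosage")
  if (is.null(ancestral_is_ref)) ancestral_is_ref <- rep(NA, n_sites)
  stopifnot(length(ancestral_is_ref) == n_sites)
  structure(
    list(chrom = as.character(chrom), pos = pos,
         ref = as.character(ref), alt = as.character(alt),
         dosage = dosage, ploidy = as.integer(ploidy),
         samples = colnames(dosage),
         ancestral_is_ref = as.logical(ancestral_is_ref)),
    class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", n_sites(x), "sites x", length(x$samples),
      "samples (", sum(x$ploidy == 2L), "diploid,",
      sum(x$ploidy == 4L), "tetraploid )\n")
  if (n_sites(x) > 0)
    cat("chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Number of sites in a GenotypeMatrix
#' @param gm a `GenotypeMatrix`.
#' @return integer site count.
#' @export
n_sites <- function(gm) length(gm$chrom)

#' Subset sites of a GenotypeMatrix
#'
#' @param gm a `GenotypeMatrix`.
#' @param i logical or integer index over sites.
#' @return a `GenotypeMatrix` with the selected sites.
#' @export
subset_sites <- function(gm, i) {
  genotype_matrix(gm$chrom[i], gm$pos[i], gm$ref[i], gm$alt[i],
                  gm$dosage[i, , drop = FALSE], gm$ploidy,
                  gm$ancestral_is_ref[i])
}

#' Subset sites falling in a genomic region
#'
#' Coordinates are 0-based half-open, the package-wide internal interval
#' convention; a site at 1-based position p lies in `[start, end)` iff
#' `start <= p - 1 < end`.
#'
#' @param gm a `GenotypeMatrix`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds.
#' @return a `GenotypeMatrix` restricted to the region.
#' @export
subset_region <- function(gm, chrom, start, end) {
  keep <- gm$chrom == chrom & (gm$pos - 1L) >= start & (gm$pos - 1L) < end
  subset_sites(gm, keep)
}

## Per-site alt-allele count and called chromosome count over a sample set.
## Missing genotypes drop the whole sample's chromosomes at that site.
site_allele_counts <- function(gm, samples = gm$samples) {
  idx <- match(samples, gm$samples)
  if (anyNA(idx)) stop("unknown sample id(s): ",
                       paste(samples[is.na(idx)], collapse = ", "))
  d <- gm$dosage[, idx, drop = FALSE]
  pl <- gm$ploidy[idx]
  called <- !is.na(d)
  j <- rowSums(d, na.rm = TRUE)
  n <- as.integer(called %*% pl)
  list(alt = j, n = n)
}

## Derived-allele count per site (requires polarization); NA when
## ancestral state is unknown.
site_derived_counts <- function(gm, samples = gm$samples) {
  ac <- site_allele_counts(gm, samples)
  der <- ifelse(is.na(gm$ancestral_is_ref), NA_real_,
                ifelse(gm$ancestral_is_ref, ac$alt, ac$n - ac$alt))
  list(der = der, n = ac$n)
}
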