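## Shared fixture builders: everything generated in code, nothing on disk.

write_fixture_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000000>",
    "##contig=<ID=chr2,length=10000000>",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  writeLines(c(header, lines), path)
  path
}

## small deterministic GenotypeMatrix: n_dip diploids + n_tet tetraploids
toy_gm <- function(n_sites = 20, n_dip = 3, n_tet = 2, seed = 1,
                   chrom = "chr1", spacing = 100L) {
  set.seed(seed)
  ploidy <- c(rep(2L, n_dip), rep(4L, n_tet))
  d <- sapply(ploidy, function(p) sample(0:p, n_sites, replace = TRUE))
  colnames(d) <- paste0("s", seq_along(ploidy))
  # keep every site polymorphic
  mono <- rowSums(d) == 0 | rowSums(d) == sum(ploidy)
  d[mono, 1] <- 1L
  genotype_matrix(rep(chrom, n_sites), seq_len(n_sites) * spacing,
                  rep("A", n_sites), rep("G", n_sites), d, ploidy,
                  ancestral_is_ref = rep(TRUE, n_sites))
}
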