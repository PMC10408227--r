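Package: polytetra
Title: Population Genomics of Diploid-Autotetraploid Species Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative population genomics of a diploid and a
    derived autotetraploid population: coalescent simulation of tetraploid
    site-frequency spectra under tetrasomic, disomic and mixed inheritance
    with Kolmogorov-Smirnov model comparison; windowed diversity and
    differentiation statistics (pi, Dxy, Tajima's D, Fay-Wu's H,
    Weir-Cockerham Fst) with random two-allele subsampling of tetraploid
    genotypes; a decorrelated composite of multiple signals (DCMS)
    selection scan; allele-loss association analysis against structural
    variants, transposable elements and protein-protein interaction genes;
    and rank-based nonparametric differential expression robust to batch
    effects. Includes synthetic-data generators with known ground truth
    for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
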