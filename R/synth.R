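#' Configuration for the synthetic-data generators
#'
#' Defaults describe a small diploid-autotetraploid study emulating the
#' structure the analyses assume: 12 diploid and 12 tetraploid
#' individuals, recent divergence, gene annotations with allele-loss
#' associations matching the observed odds (allele loss vs SV proximity
#' about 1.6, vs TE overlap about 1.1, vs non-PPI membership about 3.3),
#' a 30.8% baseline allele-loss rate, and bulk RNA-seq counts in two
#' batches per ploidy group (3+8 diploid, 3+6 tetraploid replicates).
#'
#' @param seed integer RNG seed; all generators are deterministic given
#'   the seed.
#' @param n_diploid,n_tetraploid sample counts for the two populations.
#' @param n_sites target number of segregating sites.
#' @param chrom_length chromosome length in bp for placed positions.
#' @param n_chrom number of synthetic chromosomes.
#' @param theta scaled mutation rate per simulated locus.
#' @param split_time population split time in units of 4N generations.
#' @param loss_rate baseline probability that a gene has lost at least
#'   one allele.
#' @param or_sv,or_te,or_ppi planted odds ratios of allele loss given SV
#'   proximity, TE overlap, and non-PPI membership.
#' @param n_genes genes in the annotation generator.
#' @param expr_genes genes in the expression generator.
#' @param dip_reps,tet_reps per-batch replicate counts for the two
#'   expression groups.
#' @param batch_shift multiplicative library-size factor of batch 2.
#' @param deg_fraction fraction of genes given a ploidy fold-change.
#' @param fold_change planted fold-change for DEG genes.
#' @param dosage_effect per-allele log2 expression increment linking mean
#'   expression to allele count.
#' @param dispersion negative-binomial dispersion (size parameter).
#' @return list of class `SynthConfig`.
#' @export
synth_config <- function(seed = 1L, n_diploid = 12L, n_tetraploid = 12L,
                         n_sites = 2000L, chrom_length = 1000000L,
                         n_chrom = 1L, theta = 2, split_time = 0.1,
                         loss_rate = 0.308, or_sv = 1.6, or_te = 1.1,
                         or_ppi = 3.3, n_genes = 5000L,
                         expr_genes = 2000L, dip_reps = c(3L, 8L),
                         tet_reps = c(3L, 6L), batch_shift = 1.5,
                         deg_fraction = 0.1, fold_change = 1,
                         dosage_effect = 0, dispersion = 0.1) {
  stopifnot(n_diploid >= 1, n_tetraploid >= 1, n_sites >= 1,
            or_sv > 0, or_te > 0, or_ppi > 0,
            loss_rate > 0, loss_rate < 1, batch_shift > 0,
            deg_fraction >= 0, deg_fraction <= 1, fold_change > 0)
  structure(as.list(environment()), class = "SynthConfig")
}

#' Simulate two-population diploid/tetraploid genotypes
#'
#' Draws independent biallelic sites from a two-deme coalescent (split at
#' `split_time` in 4N-generation units, no migration): population 1
#' contributes 2 chromosomes per diploid sample, population 2 contributes
#' 4 per tetraploid sample. Site positions are uniform over
#' `chrom_length` and strictly increasing. The derived allele is the alt
#' allele and sites are polarized (`ancestral_is_ref = TRUE`).
#'
#' @param cfg a [synth_config()].
#' @return a `GenotypeMatrix` with attribute `truth` (per-site derived
#'   frequencies in each population).
#' @export
synth_two_pop_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  n_dip <- cfg$n_diploid; n_tet <- cfg$n_tetraploid
  deme <- c(rep(1L, 2L * n_dip), rep(2L, 4L * n_tet))
  grp <- c(rep(seq_len(n_dip), each = 2L),
           n_dip + rep(seq_len(n_tet), each = 4L))
  chunks <- list(); got <- 0L
  while (got < cfg$n_sites) {
    loc <- coal_dosages(deme, sizes = c(1, 1),
                        merge_time = cfg$split_time, theta = cfg$theta,
                        group = grp, n_groups = n_dip + n_tet)
    if (nrow(loc) > 0) {
      chunks[[length(chunks) + 1L]] <- loc
      got <- got + nrow(loc)
    }
  }
  d <- do.call(rbind, chunks)[seq_len(cfg$n_sites), , drop = FALSE]
  n_per_chr <- ceiling(cfg$n_sites / cfg$n_chrom)
  chrom <- paste0("chr", rep(seq_len(cfg$n_chrom), each = n_per_chr,
                             length.out = cfg$n_sites))
  pos <- unlist(lapply(split(seq_len(cfg$n_sites), chrom), function(i)
    sort(sample.int(cfg$chrom_length - 1L, length(i))) + 1L),
    use.names = FALSE)
  chrom <- sort(chrom)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  ploidy <- c(rep(2L, n_dip), rep(4L, n_tet))
  colnames(d) <- c(paste0("dip", seq_len(n_dip)),
                   paste0("tet", seq_len(n_tet)))
  gm <- genotype_matrix(chrom, pos, ref, alt, d, ploidy,
                        ancestral_is_ref = rep(TRUE, cfg$n_sites))
  attr(gm, "truth") <- data.frame(
    freq_dip = rowSums(d[, seq_len(n_dip), drop = FALSE]) / (2 * n_dip),
    freq_tet = rowSums(d[, n_dip + seq_len(n_tet), drop = FALSE]) /
      (4 * n_tet))
  gm
}

#' Plant sweep-like windows into a genotype matrix
#'
#' Inside each designated window, a fraction `intensity` of
#' intermediate-frequency sites (derived frequency in 0.2--0.8 in the
#' tetraploid population) is removed, and the same fraction of the
#' remaining polymorphic sites is driven to high derived frequency
#' (tetraploid dosages redrawn with derived frequency 0.9). The result
#' carries the negative Tajima's D / negative Fay-Wu's H signature of a
#' selective sweep in the tetraploid population.
#'
#' @param gm a `GenotypeMatrix` from [synth_two_pop_genotypes()].
#' @param windows data.frame with chrom, start, end (0-based half-open).
#' @param intensity sweep strength in 0..1.
#' @param seed RNG seed.
#' @return a `GenotypeMatrix` with attribute `sweep_windows` (the truth
#'   set).
#' @export
synth_sweep_windows <- function(gm, windows, intensity, seed = 1L) {
  stopifnot(intensity >= 0, intensity <= 1)
  if (intensity == 0) {
    attr(gm, "sweep_windows") <- windows
    return(gm)
  }
  set.seed(seed)
  tet <- which(gm$ploidy == 4L)
  drop <- logical(n_sites(gm))
  d <- gm$dosage
  for (w in seq_len(nrow(windows))) {
    in_w <- which(gm$chrom == windows$chrom[w] &
                    (gm$pos - 1L) >= windows$start[w] &
                    (gm$pos - 1L) < windows$end[w])
    if (length(in_w) == 0) next
    f <- rowSums(d[in_w, tet, drop = FALSE], na.rm = TRUE) /
      (4 * length(tet))
    mid <- in_w[f > 0.2 & f < 0.8]
    drop[mid[sample.int(length(mid), round(intensity * length(mid)))]] <- TRUE
    rest <- setdiff(in_w, in_w[drop[in_w]])
    boost <- rest[sample.int(length(rest), round(intensity * length(rest)))]
    for (i in boost)
      d[i, tet] <- stats::rbinom(length(tet), 4L, 0.9)
  }
  out <- genotype_matrix(gm$chrom[!drop], gm$pos[!drop], gm$ref[!drop],
                         gm$alt[!drop], d[!drop, , drop = FALSE],
                         gm$ploidy, gm$ancestral_is_ref[!drop])
  attr(out, "sweep_windows") <- windows
  out
}

#' Simulate gene annotations with planted allele-loss associations
#'
#' Draws per-gene annotation flags (SV proximity, TE overlap, PPI
#' membership), then allele-loss status from a logistic model whose odds
#' ratios for loss given each flag equal the configured `or_sv`, `or_te`
#' and (for non-PPI membership) `or_ppi`. Lost genes carry 1--3 alleles
#' with relative frequencies matching the observed loss spectrum
#' (roughly 24:27:49 for one, two and three retained alleles); intact
#' genes carry 4. Gene, SV and TE intervals are laid out on synthetic
#' chromosomes so that the interval-based classifiers recover the planted
#' flags.
#'
#' @param cfg a [synth_config()].
#' @return list with `genes` (data.frame: gene_id, chrom, start, end,
#'   n_alleles, sv_flag, te_flag, ppi), `svs` and `tes` (`IntervalSet`s),
#'   `ppi_genes` (character), and `true_or` (named planted odds ratios).
#' @export
synth_gene_annotations <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  sv_flag <- stats::runif(n) < 0.2
  te_flag <- stats::runif(n) < 0.55
  ppi <- stats::runif(n) < 0.8
  base_logit <- stats::qlogis(cfg$loss_rate) -
    0.2 * log(cfg$or_sv) - 0.55 * log(cfg$or_te) - 0.2 * log(cfg$or_ppi)
  p_loss <- stats::plogis(base_logit + log(cfg$or_sv) * sv_flag +
                            log(cfg$or_te) * te_flag +
                            log(cfg$or_ppi) * (!ppi))
  loss <- stats::runif(n) < p_loss
  n_alleles <- rep(4L, n)
  n_alleles[loss] <- sample(1:3, sum(loss), replace = TRUE,
                            prob = c(0.238, 0.271, 0.491))
  gene_len <- 3000L; pitch <- 20000L
  start <- (seq_len(n) - 1L) * pitch
  genes <- data.frame(gene_id = sprintf("g%05d", seq_len(n)),
                      chrom = "chrS1", start = start,
                      end = start + gene_len,
                      n_alleles = n_alleles, sv_flag = sv_flag,
                      te_flag = te_flag, ppi = ppi,
                      stringsAsFactors = FALSE)
  # SVs overlapping flagged genes; placed well inside the margin of
  # unflagged neighbours (pitch >> classify margin)
  sv_type <- sample(c("inversion", "translocation", "duplication"),
                    sum(sv_flag), replace = TRUE)
  svs <- interval_set("chrS1", start[sv_flag] + 500L,
                      start[sv_flag] + 1500L, label = sv_type,
                      source = "synthetic")
  tes <- interval_set("chrS1", start[te_flag] + 1000L,
                      start[te_flag] + 1200L,
                      label = "TE", source = "synthetic")
  list(genes = genes, svs = svs, tes = tes,
       ppi_genes = genes$gene_id[ppi],
       true_or = c(sv = cfg$or_sv, te = cfg$or_te, ppi = cfg$or_ppi))
}

#' Simulate an RNA-seq count matrix with batch and ploidy effects
#'
#' Negative-binomial counts for `expr_genes` genes in two groups (diploid
#' and tetraploid) each split into two batches; batch 2 library sizes are
#' multiplied by `batch_shift`. A fraction `deg_fraction` of genes
#' receives a `fold_change` in the tetraploid group, and a per-gene
#' allele count in 1..4 shifts log2 mean expression by `dosage_effect`
#' per allele.
#'
#' @param cfg a [synth_config()].
#' @return list of class `ExpressionMatrix`: `counts` (genes x samples),
#'   `gene_length_bp`, `group`, `batch`, `allele_count`, and `truth`
#'   (logical DEG labels).
#' @export
synth_expression <- function(cfg) {
  set.seed(cfg$seed)
  g <- cfg$expr_genes
  n_dip <- sum(cfg$dip_reps); n_tet <- sum(cfg$tet_reps)
  group <- c(rep("diploid", n_dip), rep("tetraploid", n_tet))
  batch <- c(rep(c("b1", "b2"), cfg$dip_reps),
             rep(c("b3", "b4"), cfg$tet_reps))
  len <- sample(500:5000, g, replace = TRUE)
  base <- stats::rlnorm(g, meanlog = 4, sdlog = 1.5)
  allele_count <- sample(1:4, g, replace = TRUE,
                         prob = c(0.073, 0.084, 0.151, 0.692))
  is_deg <- stats::runif(g) < cfg$deg_fraction
  if (cfg$fold_change == 1) is_deg[] <- FALSE   # unit fold change plants nothing
  lib <- ifelse(batch %in% c("b2", "b4"), cfg$batch_shift, 1)
  mu <- outer(base, rep(1, n_dip + n_tet))
  mu[, group == "tetraploid"] <- mu[, group == "tetraploid"] *
    ifelse(is_deg, cfg$fold_change, 1) *
    2^(cfg$dosage_effect * (allele_count - 2))
  mu <- sweep(mu, 2, lib, `*`)
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$dispersion),
                   nrow = g)
  rownames(counts) <- sprintf("g%05d", seq_len(g))
  colnames(counts) <- paste0(substr(group, 1, 3), seq_along(group))
  structure(list(counts = counts, gene_length_bp = len, group = group,
                 batch = batch, allele_count = allele_count,
                 truth = is_deg),
            class = "ExpressionMatrix")
}
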