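#' Coalescent configuration for inheritance-model fitting
#'
#' Defaults mirror the published simulation design: times since disomy
#' (`td`) from 0.2 to 1.0 in steps of 0.2 (units of 4N generations) plus a
#' fully tetrasomic model, and disomic genome proportions from 10% to 90%
#' at 10% intervals.
#'
#' @param n_individuals sampled tetraploid individuals.
#' @param theta scaled mutation rate per locus.
#' @param n_loci independent loci per simulated spectrum.
#' @param td time since disomic inheritance evolved (4N generations).
#' @param disomic_proportion fraction of loci evolving disomically.
#' @param td_grid,proportion_grid grids searched by [fit_inheritance()].
#' @param seed integer RNG seed.
#' @return list of class `CoalescentConfig`.
#' @export
coalescent_config <- function(n_individuals = 12L, theta = 1, n_loci = 500L,
                              td = 0.6, disomic_proportion = 0,
                              td_grid = seq(0.2, 1, by = 0.2),
                              proportion_grid = seq(0.1, 0.9, by = 0.1),
                              seed = 1L) {
  stopifnot(n_individuals >= 1, n_loci >= 1, td >= 0,
            disomic_proportion >= 0, disomic_proportion <= 1)
  structure(list(n_individuals = as.integer(n_individuals), theta = theta,
                 n_loci = as.integer(n_loci), td = td,
                 disomic_proportion = disomic_proportion,
                 td_grid = td_grid, proportion_grid = proportion_grid,
                 seed = as.integer(seed)),
            class = "CoalescentConfig")
}

#' Simulate a folded tetraploid site-frequency spectrum
#'
#' Simulates `n_loci` independent loci, a fraction `disomic_proportion` of
#' them under disomic inheritance (subgenome isolation since `cfg$td`) and
#' the rest tetrasomic, and aggregates the folded SFS together with the
#' vector of per-site minor-allele frequencies used for KS comparison.
#'
#' @param cfg a [coalescent_config()].
#' @return list of class `SFS`: `counts` (folded classes
#'   `1..2*n_individuals`), `n_chromosomes`, `folded = TRUE`, `freqs`
#'   (per-site minor allele frequencies), plus the unfolded
#'   `derived_counts` for diagnostics.
#' @export
simulate_sfs <- function(cfg) {
  set.seed(cfg$seed)
  n_dis <- round(cfg$disomic_proportion * cfg$n_loci)
  modes <- c(rep("disomic", n_dis),
             rep("tetrasomic", cfg$n_loci - n_dis))
  n_chrom <- 4L * cfg$n_individuals
  der <- integer(0)
  for (m in modes) {
    loc <- simulate_locus(m, td = cfg$td, theta = cfg$theta,
                          n_individuals = cfg$n_individuals)
    if (nrow(loc) > 0) der <- c(der, rowSums(loc))
  }
  der <- der[der > 0L & der < n_chrom]
  new_sfs(der, n_chrom)
}

new_sfs <- function(derived_counts, n_chromosomes) {
  minor <- pmin(derived_counts, n_chromosomes - derived_counts)
  structure(list(
    counts = tabulate(minor, nbins = n_chromosomes %/% 2L),
    n_chromosomes = n_chromosomes, folded = TRUE,
    freqs = minor / n_chromosomes, derived_counts = derived_counts),
    class = "SFS")
}

#' @export
print.SFS <- function(x, ...) {
  cat("Folded SFS:", sum(x$counts), "segregating sites over",
      x$n_chromosomes, "chromosomes\n")
  print(stats::setNames(x$counts, seq_along(x$counts)))
  invisible(x)
}

#' Observed folded SFS from tetraploid genotypes
#'
#' Sites with a missing dosage in any named sample are skipped (count in
#' attribute `n_skipped`); monomorphic sites do not enter the spectrum.
#'
#' @param gm a `GenotypeMatrix`.
#' @param samples tetraploid sample ids.
#' @return an `SFS` (see [simulate_sfs()]).
#' @export
observed_sfs <- function(gm, samples) {
  idx <- match(samples, gm$samples)
  if (anyNA(idx)) stop("unknown sample id(s)")
  if (!all(gm$ploidy[idx] == 4L)) stop("all samples must be tetraploid")
  d <- gm$dosage[, idx, drop = FALSE]
  complete <- rowSums(is.na(d)) == 0L
  n_skipped <- sum(!complete)
  if (n_skipped > 0)
    message("observed_sfs: skipped ", n_skipped,
            " site(s) with missing genotypes")
  n_chrom <- 4L * length(idx)
  alt <- rowSums(d[complete, , drop = FALSE])
  alt <- alt[alt > 0L & alt < n_chrom]
  if (length(alt) == 0) stop("no polymorphic complete sites")
  out <- new_sfs(alt, n_chrom)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Two-sample Kolmogorov-Smirnov test with explicit sidedness
#'
#' `side = "less"` tests the alternative that `x` is stochastically
#' smaller than `y` (D = sup(Fx - Fy)); `side = "greater"` that `x` is
#' stochastically larger (D = sup(Fy - Fx)); `"two-sided"` uses
#' sup|Fx - Fy|. One-sided p-values use the asymptotic
#' exp(-2 m n D^2 / (m + n)); the two-sided p uses the Kolmogorov series.
#'
#' @param x,y numeric samples.
#' @param side `"greater"`, `"less"` or `"two-sided"`.
#' @return list of class `KsCompareResult` with `d_stat`, `p_value`,
#'   `side`.
#' @export
ks_two_sample <- function(x, y, side = c("two-sided", "greater", "less")) {
  side <- match.arg(side)
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("empty sample")
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) sum(x <= t), numeric(1)) / m
  fy <- vapply(pts, function(t) sum(y <= t), numeric(1)) / n
  d <- switch(side,
              "less" = max(fx - fy),
              "greater" = max(fy - fx),
              "two-sided" = max(abs(fx - fy)))
  d <- max(d, 0)
  ne <- as.numeric(m) * as.numeric(n) / (m + n)
  p <- if (side == "two-sided") {
    lambda <- sqrt(ne) * d
    if (lambda < 1e-9) 1
    else min(1, max(0, 2 * sum((-1)^(0:99) * exp(-2 * ((1:100)^2) * lambda^2))))
  } else {
    exp(-2 * ne * d^2)
  }
  structure(list(d_stat = d, p_value = p, side = side),
            class = "KsCompareResult")
}

#' Fit inheritance mode and disomic genome proportion to an observed SFS
#'
#' Compares an observed tetraploid minor-allele-frequency sample against
#' coalescent simulations over a grid of disomic proportions and times
#' since disomy (`td`), including the fully tetrasomic model (proportion
#' 0). For each model a KS test is performed; the best model minimizes the
#' KS distance, and the maximal non-rejected proportion is the largest
#' grid proportion whose best p-value over `td` is at least `alpha` (0 if
#' every proportion is rejected) -- the analogue of concluding that "at
#' most" some fraction of the genome is inherited disomically.
#'
#' @param obs an `SFS` (from [observed_sfs()] or [simulate_sfs()]) or a
#'   numeric vector of minor-allele frequencies (then `n_chromosomes`
#'   must be given).
#' @param cfg a [coalescent_config()]; its grids, `theta`, `n_loci` and
#'   `n_individuals` define the simulated models.
#' @param alpha rejection level for the KS p-value.
#' @param side KS sidedness (see [ks_two_sample()]).
#' @param n_chromosomes required when `obs` is a bare frequency vector;
#'   must equal `4 * cfg$n_individuals`.
#' @return list of class `InheritanceFit` with the per-model `grid`
#'   data.frame (td, proportion, d_stat, p_value), `best_model`, and
#'   `max_nonrejected_proportion`.
#' @export
fit_inheritance <- function(obs, cfg, alpha = 0.05,
                            side = "two-sided", n_chromosomes = NULL) {
  if (inherits(obs, "SFS")) {
    n_chromosomes <- obs$n_chromosomes
    obs <- obs$freqs
  }
  if (is.null(n_chromosomes))
    stop("n_chromosomes required for bare frequency vectors")
  if (n_chromosomes != 4L * cfg$n_individuals)
    stop("observed sample size (", n_chromosomes,
         " chromosomes) does not match simulated models (",
         4L * cfg$n_individuals, ")")
  models <- rbind(data.frame(td = NA_real_, proportion = 0),
                  expand.grid(td = cfg$td_grid,
                              proportion = cfg$proportion_grid))
  res <- lapply(seq_len(nrow(models)), function(i) {
    mcfg <- cfg
    mcfg$td <- if (is.na(models$td[i])) 0 else models$td[i]
    mcfg$disomic_proportion <- models$proportion[i]
    mcfg$seed <- cfg$seed + i
    sim <- simulate_sfs(mcfg)
    ks_two_sample(obs, sim$freqs, side = side)
  })
  grid <- cbind(models,
                d_stat = vapply(res, `[[`, numeric(1), "d_stat"),
                p_value = vapply(res, `[[`, numeric(1), "p_value"))
  best <- grid[which.min(grid$d_stat), , drop = FALSE]
  best_model <- if (best$proportion == 0) "tetrasomic"
    else sprintf("disomic p=%.1f td=%.1f", best$proportion, best$td)
  best_p_by_prop <- vapply(cfg$proportion_grid, function(p)
    max(grid$p_value[grid$proportion == p]), numeric(1))
  ok <- cfg$proportion_grid[best_p_by_prop >= alpha]
  structure(list(grid = grid, best_model = best_model,
                 max_nonrejected_proportion =
                   if (length(ok)) max(ok) else 0),
            class = "InheritanceFit")
}

#' @export
print.InheritanceFit <- function(x, ...) {
  cat("Inheritance fit over", nrow(x$grid), "models\n")
  cat("best model:", x$best_model, "\n")
  cat("max non-rejected disomic proportion:",
      x$max_nonrejected_proportion, "\n")
  invisible(x)
}
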