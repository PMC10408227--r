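## Windowed population-genetic statistics. All windows are 0-based
## half-open; per-site statistics use allele counts over the chosen
## samples with missing genotypes removed from the denominators.

#' Nucleotide diversity in sliding windows
#'
#' Per-site pi is the mean pairwise difference
#' `sum(2 j (n - j) / (n (n - 1)))` over sites, divided by the window
#' length in bp (j = alt-allele count, n = called chromosomes at the
#' site). With `subsample_k` set, `n_reps` random draws of `k` individuals
#' are averaged, emulating diversity estimates from repeated subsampling
#' of a larger tetraploid panel.
#'
#' @param gm a `GenotypeMatrix`.
#' @param samples sample ids to include.
#' @param window_bp,step_bp sliding-window size and step (defaults 50 kb /
#'   20 kb).
#' @param subsample_k optional number of individuals per random draw.
#' @param n_reps number of subsampling replicates (default 20).
#' @param seed RNG seed for subsampling.
#' @return data.frame with chrom, start, end, n_snps, pi.
#' @export
pi_windows <- function(gm, samples = gm$samples, window_bp = 50000L,
                       step_bp = 20000L, subsample_k = NULL, n_reps = 20L,
                       seed = 1L) {
  stopifnot(window_bp >= step_bp)
  wins <- sliding_windows(gm, window_bp, step_bp)
  pi_of <- function(smp) {
    ac <- site_allele_counts(gm, smp)
    persite <- ifelse(ac$n >= 2, 2 * ac$alt * (ac$n - ac$alt) /
                        (ac$n * (ac$n - 1)), NA_real_)
    vapply(seq_len(nrow(wins)), function(w) {
      i <- gm$chrom == wins$chrom[w] & (gm$pos - 1L) >= wins$start[w] &
        (gm$pos - 1L) < wins$end[w]
      sum(persite[i], na.rm = TRUE) / (wins$end[w] - wins$start[w])
    }, numeric(1))
  }
  if (is.null(subsample_k) || subsample_k >= length(samples)) {
    wins$pi <- pi_of(samples)
  } else {
    set.seed(seed)
    reps <- replicate(n_reps, pi_of(sample(samples, subsample_k)))
    wins$pi <- rowMeans(reps)
  }
  wins
}

sliding_windows <- function(gm, window_bp, step_bp) {
  # full-length windows (the per-site denominator is the window span)
  out <- lapply(unique(gm$chrom), function(ch) {
    pmax <- max(gm$pos[gm$chrom == ch])
    starts <- seq(0L, max(0L, pmax - 1L), by = step_bp)
    data.frame(chrom = ch, start = starts, end = starts + window_bp)
  })
  wins <- do.call(rbind, out)
  wins$n_snps <- vapply(seq_len(nrow(wins)), function(w)
    sum(gm$chrom == wins$chrom[w] & (gm$pos - 1L) >= wins$start[w] &
          (gm$pos - 1L) < wins$end[w]), integer(1))
  wins
}

#' Between-population divergence D_XY over a syntenic region
#'
#' Per-site `D_XY = mean(pA (1 - pB) + pB (1 - pA))` summed over sites and
#' divided by the window length. Regions of at least `window_bp` are tiled
#' into non-overlapping `window_bp` windows with any shorter remainder
#' emitted whole; regions shorter than `window_bp` are emitted as one
#' window. A window with no called sites has `dxy = 0` (identical
#' sequences under the monomorphic-equals-identical convention).
#'
#' @param gm a `GenotypeMatrix`.
#' @param popA,popB sample id vectors for the two populations.
#' @param region list or data.frame row with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param window_bp tiling window size (default 50 kb).
#' @return data.frame with chrom, start, end, n_snps, dxy.
#' @export
dxy_windows <- function(gm, popA, popB, region, window_bp = 50000L) {
  if (length(popA) == 0 || length(popB) == 0) stop("empty population")
  len <- region$end - region$start
  starts <- if (len < window_bp) region$start
            else seq(region$start, region$end - 1L, by = window_bp)
  ends <- pmin(starts + window_bp, region$end)
  acA <- site_allele_counts(gm, popA)
  acB <- site_allele_counts(gm, popB)
  pA <- acA$alt / acA$n
  pB <- acB$alt / acB$n
  persite <- pA * (1 - pB) + pB * (1 - pA)
  out <- data.frame(chrom = region$chrom, start = starts, end = ends)
  idx <- lapply(seq_along(starts), function(w)
    which(gm$chrom == region$chrom & (gm$pos - 1L) >= starts[w] &
            (gm$pos - 1L) < ends[w] & acA$n > 0 & acB$n > 0))
  out$n_snps <- lengths(idx)
  out$dxy <- vapply(seq_along(idx), function(w)
    sum(persite[idx[[w]]]) / (ends[w] - starts[w]), numeric(1))
  out
}

## Tajima (1989) constants for sample size n
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D for a set of sites
#'
#' Standard Tajima (1989) D comparing total pairwise diversity with
#' Watterson's estimator, `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))`.
#' Sites must share a common chromosome sample size (sites with missing
#' genotypes among the chosen samples are dropped). Returns `NA` when no
#' segregating site remains.
#'
#' @param gm a `GenotypeMatrix` (typically a window slice via
#'   [subset_region()]).
#' @param samples sample ids to include.
#' @return Tajima's D, or `NA`.
#' @export
tajimas_d <- function(gm, samples = gm$samples) {
  ac <- site_allele_counts(gm, samples)
  nmax <- max(ac$n)
  seg <- ac$n == nmax & ac$alt > 0 & ac$alt < ac$n
  S <- sum(seg)
  if (S == 0 || nmax < 2) return(NA_real_)
  n <- nmax
  j <- ac$alt[seg]
  pi_tot <- sum(2 * j * (n - j) / (n * (n - 1)))
  k <- tajima_constants(n)
  (pi_tot - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Fay and Wu's H for a set of polarized sites
#'
#' Unnormalized H (original 2000 form): `H = theta_pi - theta_H` with
#' `theta_H = sum(2 xi_i i^2) / (n (n - 1))` over derived-allele counts i.
#' Sites without ancestral polarization are skipped (count in attribute
#' `n_unpolarized`). Negative H indicates an excess of high-frequency
#' derived alleles, the hitchhiking signature.
#'
#' @inheritParams tajimas_d
#' @return H, or `NA` if no polarized segregating site.
#' @export
fay_wu_h <- function(gm, samples = gm$samples) {
  dc <- site_derived_counts(gm, samples)
  nmax <- max(dc$n)
  use <- !is.na(dc$der) & dc$n == nmax & dc$der > 0 & dc$der < dc$n
  n_unpolarized <- sum(is.na(dc$der))
  if (sum(use) == 0 || nmax < 2) {
    out <- NA_real_
  } else {
    n <- nmax
    i <- dc$der[use]
    theta_pi <- sum(2 * i * (n - i)) / (n * (n - 1))
    theta_h <- sum(2 * i^2) / (n * (n - 1))
    out <- theta_pi - theta_h
  }
  attr(out, "n_unpolarized") <- n_unpolarized
  out
}

#' Weir and Cockerham's F_ST between two populations
#'
#' Weir & Cockerham (1984) theta with two populations and two alleles, in
#' the allele-count (haploid) form appropriate for dosage data where
#' chromosomes are the sampling unit; the windowed value is the
#' "weighted" ratio of summed variance components across sites (the
#' VCFtools convention of dividing the summed numerator by the summed
#' denominator rather than averaging per-site ratios). Negative estimates
#' are reported as computed (not clipped). Returns `NA` for windows with
#' no usable polymorphic site.
#'
#' @param gm a `GenotypeMatrix` (typically a window slice).
#' @param popA,popB sample id vectors.
#' @return the windowed theta estimate, or `NA`.
#' @export
wc_fst <- function(gm, popA, popB) {
  comp <- wc_fst_components(gm, popA, popB)
  if (comp$den == 0) return(NA_real_)
  comp$num / comp$den
}

wc_fst_components <- function(gm, popA, popB) {
  acA <- site_allele_counts(gm, popA)
  acB <- site_allele_counts(gm, popB)
  use <- acA$n > 0 & acB$n > 0 &
    (acA$alt + acB$alt) > 0 & (acA$alt + acB$alt) < (acA$n + acB$n)
  if (!any(use)) return(list(num = 0, den = 0))
  n1 <- acA$n[use]; n2 <- acB$n[use]
  p1 <- acA$alt[use] / n1; p2 <- acB$alt[use] / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  list(num = sum(a), den = sum(a + b))
}

#' Per-window summary statistics for a selection scan
#'
#' Computes pi, Tajima's D and Fay-Wu's H per window for one population
#' and, if `popB` is given, Weir-Cockerham F_ST between `samples` and
#' `popB`. Windows come from [make_windows()] or any data.frame with
#' chrom/start/end.
#'
#' @param gm a `GenotypeMatrix`.
#' @param windows data.frame of windows (0-based half-open).
#' @param samples focal population sample ids.
#' @param popB optional second population for F_ST.
#' @param clr optional numeric vector of externally computed composite
#'   likelihood ratios, one per window.
#' @return the `windows` data.frame with columns n_snps, pi, tajima_d,
#'   fay_wu_h and optionally fst, clr appended.
#' @export
window_stats <- function(gm, windows, samples = gm$samples, popB = NULL,
                         clr = NULL) {
  res <- lapply(seq_len(nrow(windows)), function(w) {
    slice <- subset_region(gm, windows$chrom[w], windows$start[w],
                           windows$end[w])
    c(n_snps = n_sites(slice),
      pi = {
        ac <- site_allele_counts(slice, samples)
        sum(ifelse(ac$n >= 2, 2 * ac$alt * (ac$n - ac$alt) /
                     (ac$n * (ac$n - 1)), 0)) /
          (windows$end[w] - windows$start[w])
      },
      tajima_d = tajimas_d(slice, samples),
      fay_wu_h = as.numeric(fay_wu_h(slice, samples)),
      fst = if (is.null(popB)) NA_real_ else wc_fst(slice, samples, popB))
  })
  res <- as.data.frame(do.call(rbind, res))
  out <- cbind(windows[c("chrom", "start", "end")], res)
  if (is.null(popB)) out$fst <- NULL
  if (!is.null(clr)) {
    stopifnot(length(clr) == nrow(out))
    out$clr <- clr
  }
  out
}

#' Difference statistics between diploid and tetraploid window tables
#'
#' `delta_d = tajima_d(diploid) - tajima_d(tetraploid)` and
#' `delta_clr = clr(tetraploid) - clr(diploid)`, per window; sweeps in the
#' tetraploid lineage push both upward. Missing inputs propagate.
#'
#' @param dip_table,tet_table window statistic tables over identical
#'   windows (e.g. from [window_stats()]).
#' @return window data.frame with delta_d and (when CLR present in both)
#'   delta_clr, plus the tetraploid fay_wu_h and fst columns carried over.
#' @export
delta_stats <- function(dip_table, tet_table) {
  key <- function(t) paste(t$chrom, t$start, t$end)
  if (!identical(key(dip_table), key(tet_table)))
    stop("window sets differ between tables")
  out <- tet_table[c("chrom", "start", "end", "n_snps")]
  out$delta_d <- dip_table$tajima_d - tet_table$tajima_d
  if (!is.null(dip_table$clr) && !is.null(tet_table$clr))
    out$delta_clr <- tet_table$clr - dip_table$clr
  out$fay_wu_h <- tet_table$fay_wu_h
  if (!is.null(tet_table$fst)) out$fst <- tet_table$fst
  out
}

#' Molecular-clock conversion of synonymous divergence to time
#'
#' `T = Ks / (2 mu)` years: a Ks peak of 0.005 with a substitution rate of
#' 2.06e-9 per site per year dates a whole-genome duplication to roughly
#' 1.2 million years ago.
#'
#' @param ks synonymous substitutions per synonymous site.
#' @param mu substitution rate per site per year.
#' @return divergence time in years.
#' @export
ks_to_time <- function(ks, mu = 2.06e-9) {
  if (mu <= 0) stop("mu must be positive")
  if (any(ks < 0)) stop("ks must be nonnegative")
  ks / (2 * mu)
}

#' Assembly breakpoint density
#'
#' Breakpoints per megabase, a structural-correctness summary of a genome
#' assembly.
#'
#' @param n_breakpoints number of detected breakpoints.
#' @param assembly_bp anchored assembly size in bp.
#' @return breakpoints per Mb.
#' @export
breakpoint_density <- function(n_breakpoints, assembly_bp) {
  stopifnot(n_breakpoints >= 0, assembly_bp > 0)
  n_breakpoints / (assembly_bp / 1e6)
}
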