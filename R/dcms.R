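#' Non-overlapping windows for a selection scan
#'
#' Tiles each chromosome from coordinate 0 into `window_bp` windows
#' (0-based half-open; last window truncated at the last SNP) and drops
#' windows with fewer than `min_snps` SNPs, the minimum for the composite
#' statistics to be informative.
#'
#' @param gm a `GenotypeMatrix`.
#' @param window_bp window size (default 25 kb).
#' @param min_snps minimum SNPs per retained window (default 10).
#' @return data.frame with chrom, start, end, n_snps.
#' @export
make_windows <- function(gm, window_bp = 25000L, min_snps = 10L) {
  if (n_sites(gm) == 0) stop("empty GenotypeMatrix")
  out <- lapply(unique(gm$chrom), function(ch) {
    pmax <- max(gm$pos[gm$chrom == ch])
    starts <- seq(0L, pmax - 1L, by = window_bp)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_bp, as.integer(pmax)))
  })
  wins <- do.call(rbind, out)
  wins$n_snps <- vapply(seq_len(nrow(wins)), function(w)
    sum(gm$chrom == wins$chrom[w] & (gm$pos - 1L) >= wins$start[w] &
          (gm$pos - 1L) < wins$end[w]), integer(1))
  wins[wins$n_snps >= min_snps, , drop = FALSE]
}

#' Two-step rank-based normalization to Z scores
#'
#' Transforms a variable to percentile ranks `r/(n+1)` (average ranks for
#' ties, giving uniformly distributed probabilities), then applies the
#' standard-normal quantile function. Used to normalize selection
#' statistics whose raw distributions are far from Gaussian before
#' combining them. Missing values stay missing; an all-tied input maps to
#' all-zero Z scores. Invariant under any monotone transform of the
#' input.
#'
#' @param values numeric vector, may contain `NA`.
#' @return vector of Z scores, same length.
#' @export
two_step_normalize <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 3) stop("need at least 3 non-missing values")
  n <- sum(ok)
  z <- rep(NA_real_, length(values))
  z[ok] <- stats::qnorm(rank(values[ok], ties.method = "average") / (n + 1))
  z
}

#' One-sided p-values from normalized scores
#'
#' `direction = "upper"` gives `p = 1 - Phi(z)` (large values of the
#' statistic are sweep-like, as for delta-CLR, F_ST and delta-Tajima's D);
#' `"lower"` gives `p = Phi(z)` (small values are sweep-like, as for
#' Fay-Wu's H).
#'
#' @param z numeric Z scores.
#' @param direction `"upper"` or `"lower"`.
#' @return p-values in (0, 1).
#' @export
stat_p <- function(z, direction = c("upper", "lower")) {
  direction <- match.arg(direction)
  if (direction == "upper") stats::pnorm(z, lower.tail = FALSE)
  else stats::pnorm(z)
}

#' Decorrelated composite of multiple signals
#'
#' For window p-values `p_i` of k statistics,
#' `DCMS = sum_i log10((1 - p_i)/p_i) / sum_j |r_ij|` where `r_ij` is the
#' Pearson correlation of the p-value columns over windows. The weight
#' denominators discount statistics that are correlated with others, so
#' duplicating a statistic column leaves the score unchanged.
#'
#' @param p_matrix numeric matrix, windows x statistics, of one-sided
#'   p-values.
#' @return list with `dcms` (per-window score), `corr` (k x k), `weights`
#'   (per-statistic denominator `sum_j |r_ij|`).
#' @export
dcms_combine <- function(p_matrix) {
  p_matrix <- as.matrix(p_matrix)
  k <- ncol(p_matrix)
  if (nrow(p_matrix) < 3) stop("need at least 3 windows")
  if (any(apply(p_matrix, 2, stats::sd, na.rm = TRUE) == 0))
    stop("constant p-value column: correlation undefined")
  corr <- stats::cor(p_matrix, use = "pairwise.complete.obs")
  weights <- rowSums(abs(corr))
  terms <- log10((1 - p_matrix) / p_matrix)
  dcms <- as.numeric(terms %*% (1 / weights))
  list(dcms = dcms, corr = corr, weights = weights)
}

#' Call windows under putative positive selection from DCMS scores
#'
#' DCMS scores are re-normalized with the same two-step rank procedure
#' used for the component statistics, an upper-tail p-value is assigned,
#' and windows with `p < alpha` are flagged. Genes overlapping a flagged
#' window by at least 1 bp are returned once each.
#'
#' @param dcms numeric vector of composite scores, one per window.
#' @param windows data.frame of windows (chrom, start, end).
#' @param genes optional `IntervalSet` of gene spans.
#' @param alpha selection threshold on the window p-value (default 0.05).
#' @return list with `table` (windows plus dcms, p_dcms, selected) and
#'   `genes` (character vector of selected gene labels, possibly empty).
#' @export
call_selected_windows <- function(dcms, windows, genes = NULL,
                                  alpha = 0.05) {
  stopifnot(length(dcms) == nrow(windows))
  z <- two_step_normalize(dcms)
  p_dcms <- stat_p(z, "upper")
  tab <- windows
  tab$dcms <- dcms
  tab$p_dcms <- p_dcms
  tab$selected <- !is.na(p_dcms) & p_dcms < alpha
  hit_genes <- character(0)
  if (!is.null(genes) && any(tab$selected)) {
    sel <- tab[tab$selected, , drop = FALSE]
    sel_gr <- GenomicRanges::GRanges(
      sel$chrom, IRanges::IRanges(sel$start + 1L, sel$end))
    hits <- GenomicRanges::findOverlaps(as_granges(genes), sel_gr)
    hit_genes <- unique(genes$label[unique(S4Vectors::queryHits(hits))])
  }
  list(table = tab, genes = hit_genes)
}

#' Full DCMS selection scan from diploid and tetraploid window tables
#'
#' Orchestrates the composite scan: forms delta statistics between the
#' diploid and tetraploid tables, two-step normalizes each component,
#' orients the tails so that sweep-like signal maps to small p
#' (delta-Tajima's D upper, F_ST upper, delta-CLR upper, Fay-Wu's H
#' lower), combines them into DCMS scores and calls selected windows.
#' Windows where any component is missing are dropped from the
#' combination.
#'
#' @param dip_table,tet_table per-window statistic tables from
#'   [window_stats()] over identical windows; `tet_table` must carry
#'   `fst` and `fay_wu_h`; `clr` columns are optional.
#' @param genes optional `IntervalSet` of gene spans.
#' @param alpha selection threshold (default 0.05).
#' @return list of class `DcmsTable`: `table` (per-window raw values, z
#'   scores, component p-values, dcms, p_dcms, selected), `corr`,
#'   `weights`, `genes`.
#' @export
dcms_scan <- function(dip_table, tet_table, genes = NULL, alpha = 0.05) {
  d <- delta_stats(dip_table, tet_table)
  comp <- data.frame(delta_d = d$delta_d)
  dirs <- c(delta_d = "upper")
  if (!is.null(d$delta_clr)) {
    comp$delta_clr <- d$delta_clr
    dirs["delta_clr"] <- "upper"
  }
  if (!is.null(d$fst)) {
    comp$fst <- d$fst
    dirs["fst"] <- "upper"
  }
  comp$fay_wu_h <- d$fay_wu_h
  dirs["fay_wu_h"] <- "lower"

  complete <- stats::complete.cases(comp)
  z <- vapply(names(comp), function(nm) {
    out <- rep(NA_real_, nrow(comp))
    out[complete] <- two_step_normalize(comp[[nm]][complete])
    out
  }, numeric(nrow(comp)))
  p <- vapply(names(comp), function(nm)
    stat_p(z[, nm], dirs[[nm]]), numeric(nrow(comp)))
  cmb <- dcms_combine(p[complete, , drop = FALSE])
  calls <- call_selected_windows(cmb$dcms,
                                 d[complete, c("chrom", "start", "end")],
                                 genes = genes, alpha = alpha)
  tab <- cbind(d[complete, ], z = z[complete, , drop = FALSE],
               p = p[complete, , drop = FALSE],
               calls$table[c("dcms", "p_dcms", "selected")])
  structure(list(table = tab, corr = cmb$corr, weights = cmb$weights,
                 genes = calls$genes, n_dropped = sum(!complete)),
            class = "DcmsTable")
}

#' @export
print.DcmsTable <- function(x, ...) {
  cat("DCMS scan:", nrow(x$table), "windows,",
      sum(x$table$selected), "selected,",
      length(x$genes), "genes;", x$n_dropped,
      "window(s) dropped for missing components\n")
  invisible(x)
}
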