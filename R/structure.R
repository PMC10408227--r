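#' Summarize per-gene allele counts of an autotetraploid annotation
#'
#' Counts and percentages of genes by retained allele class (1, 2, 3, 4,
#' more than 4) and the mean number of alleles per gene. Fewer than four
#' alleles indicates post-polyploid allele loss; more than four indicates
#' copy gain.
#'
#' @param allele_table data.frame with columns `gene_id` and `n_alleles`,
#'   or a named integer vector of allele counts.
#' @return list with `by_class` (data.frame: class, n_genes, percent to
#'   two decimals), `n_genes`, `n_alleles`, `mean_alleles` (two
#'   decimals), `n_loss` and `percent_loss`.
#' @export
allele_summary <- function(allele_table) {
  n_all <- if (is.data.frame(allele_table)) allele_table$n_alleles
           else as.integer(allele_table)
  if (length(n_all) == 0) stop("empty allele table")
  stopifnot(all(n_all >= 0))
  cls <- cut(n_all, breaks = c(-Inf, 1:4, Inf),
             labels = c("1", "2", "3", "4", ">4"))
  tab <- table(cls)
  by_class <- data.frame(class = names(tab),
                         n_genes = as.integer(tab),
                         percent = round(100 * as.integer(tab) /
                                           length(n_all), 2))
  n_loss <- sum(n_all < 4L)
  list(by_class = by_class,
       n_genes = length(n_all),
       n_alleles = sum(n_all),
       mean_alleles = round(sum(n_all) / length(n_all), 2),
       n_loss = n_loss,
       percent_loss = round(100 * n_loss / length(n_all), 2))
}

#' Group identical structural variants across monoploid genomes
#'
#' Two SVs (each called on one of the monoploid genomes A--D against the
#' shared diploid reference) are "identical" when (1) their reference
#' intervals overlap by at least 50% of the shorter interval, (2) their
#' monoploid chromosomes belong to the same homologous (allelic) group,
#' and (3) they are of the same type. Identity may chain, so groups are
#' the connected components of the pairwise-identity graph; each group's
#' presence class is the set of monoploid genomes its members come from
#' (one of the 15 nonempty subsets of {A,B,C,D}).
#'
#' @param svs data.frame with columns `chrom`, `start`, `end` (diploid
#'   reference, 0-based half-open), `sv_type` (inversion / translocation
#'   / duplication), `monoploid` (A--D), and optionally `mono_chrom`
#'   (the monoploid chromosome the SV was called on).
#' @param allelic_map optional named vector mapping `mono_chrom` values
#'   to homologous-group ids; when absent, rule (2) is taken as satisfied
#'   (all SVs on the reference interval are comparable).
#' @return data.frame, one row per group: `group`, `presence_class`
#'   (e.g. `"ABD"`), `n_members`, `sv_type`, `chrom`, `start`, `end`
#'   (member footprint); the input row indices of members in attribute
#'   `members`.
#' @export
group_identical_svs <- function(svs, allelic_map = NULL) {
  n <- nrow(svs)
  if (!all(svs$sv_type %in% c("inversion", "translocation", "duplication")))
    stop("unknown sv_type")
  if (!all(svs$monoploid %in% c("A", "B", "C", "D")))
    stop("monoploid must be one of A-D")
  hom <- rep("h", n)
  if (!is.null(allelic_map)) {
    if (is.null(svs$mono_chrom)) stop("allelic_map given but no mono_chrom")
    hom <- unname(allelic_map[svs$mono_chrom])
    if (anyNA(hom)) stop("SV with unknown homologous group")
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  gr <- GenomicRanges::GRanges(svs$chrom,
                               IRanges::IRanges(svs$start + 1L, svs$end))
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      drop.redundant = TRUE)
  for (h in seq_len(length(hits))) {
    i <- S4Vectors::queryHits(hits)[h]
    j <- S4Vectors::subjectHits(hits)[h]
    if (svs$sv_type[i] != svs$sv_type[j] || hom[i] != hom[j]) next
    ov <- min(svs$end[i], svs$end[j]) - max(svs$start[i], svs$start[j])
    shorter <- min(svs$end[i] - svs$start[i], svs$end[j] - svs$start[j])
    if (ov >= 0.5 * shorter) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), root)
  out <- data.frame(
    group = seq_along(groups),
    presence_class = vapply(groups, function(m)
      paste(sort(unique(svs$monoploid[m])), collapse = ""), character(1)),
    n_members = lengths(groups),
    sv_type = vapply(groups, function(m) svs$sv_type[m[1]], character(1)),
    chrom = vapply(groups, function(m) svs$chrom[m[1]], character(1)),
    start = vapply(groups, function(m) min(svs$start[m]), integer(1)),
    end = vapply(groups, function(m) max(svs$end[m]), integer(1)),
    row.names = NULL)
  attr(out, "members") <- unname(groups)
  out
}

#' Classify genes by proximity to structural variants
#'
#' `within_sv` if the gene span overlaps any SV interval by at least 1
#' bp; otherwise `near_sv` if the distance to the nearest SV is at most
#' `margin_bp`; otherwise `far`. Categories are exhaustive and mutually
#' exclusive.
#'
#' @param genes data.frame with chrom, start, end (0-based half-open).
#' @param svs an `IntervalSet` (or compatible data.frame) of SVs.
#' @param margin_bp proximity margin (default 2000).
#' @return factor with levels within_sv, near_sv, far, one per gene.
#' @export
classify_gene_sv <- function(genes, svs, margin_bp = 2000L) {
  out <- factor(rep("far", nrow(genes)),
                levels = c("within_sv", "near_sv", "far"))
  if (nrow(svs) == 0) return(out)
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start + 1L, genes$end))
  s <- GenomicRanges::GRanges(svs$chrom,
                              IRanges::IRanges(svs$start + 1L, svs$end))
  # suppress seqlevel-mismatch chatter: disjoint chromosome sets simply
  # mean no overlap
  within <- suppressWarnings(GenomicRanges::countOverlaps(g, s) > 0)
  dtn <- suppressWarnings(GenomicRanges::distanceToNearest(g, s))
  near <- rep(FALSE, nrow(genes))
  q <- S4Vectors::queryHits(dtn)
  near[q] <- S4Vectors::mcols(dtn)$distance <= margin_bp
  out[near] <- "near_sv"
  out[within] <- "within_sv"
  out
}

#' Flag genes overlapping transposable elements
#'
#' `TRUE` iff the gene span overlaps any TE interval by at least 1 bp
#' (0-based half-open: abutting intervals do not overlap).
#'
#' @param genes data.frame with chrom, start, end.
#' @param tes an `IntervalSet` of TEs.
#' @return logical vector, one per gene.
#' @export
flag_te_overlap <- function(genes, tes) {
  if (nrow(tes) == 0) return(rep(FALSE, nrow(genes)))
  g <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start + 1L, genes$end))
  t <- GenomicRanges::GRanges(tes$chrom,
                              IRanges::IRanges(tes$start + 1L, tes$end))
  suppressWarnings(GenomicRanges::countOverlaps(g, t) > 0)
}

#' Reciprocal best hits between two protein sets
#'
#' `(a, b)` is returned iff `b` is `a`'s best hit in `hits_ab` and `a` is
#' `b`'s best hit in `hits_ba`. Score ties are broken deterministically
#' by lexicographic subject id, with a message reporting how many queries
#' were tied.
#'
#' @param hits_ab,hits_ba data.frames with columns `query_id`,
#'   `subject_id`, `score` (higher is better).
#' @return data.frame with columns `a_id`, `b_id`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  best <- function(h) {
    ties <- 0L
    out <- vapply(split(seq_len(nrow(h)), h$query_id), function(i) {
      top <- i[h$score[i] == max(h$score[i])]
      if (length(top) > 1) {
        ties <<- ties + 1L
        top <- top[order(h$subject_id[top])][1]
      }
      h$subject_id[top]
    }, character(1))
    if (ties > 0)
      message("reciprocal_best_hits: ", ties,
              " tied best hit(s) broken lexicographically")
    out
  }
  ab <- best(hits_ab)
  ba <- best(hits_ba)
  a_ids <- names(ab)
  keep <- !is.na(ba[ab[a_ids]]) & ba[ab[a_ids]] == a_ids
  data.frame(a_id = a_ids[keep], b_id = unname(ab[a_ids[keep]]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by minimum-likelihood hypergeometric summation (the
#' convention of standard statistical software) with the sample odds
#' ratio `(a d)/(b c)` (infinite when `b c = 0` and `a d > 0`).
#'
#' @param a,b,c,d cell counts: rows are condition 1/2, columns outcome
#'   1/2 (so `a/b` vs `c/d` are the compared ratios).
#' @return list of class `ContingencyResult`: `table`, `odds_ratio`,
#'   `p_value`.
#' @export
fisher_enrichment <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), 2)
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("counts must be nonnegative with positive margins")
  p <- stats::fisher.test(tab)$p.value
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  structure(list(table = matrix(c(a, b, c, d), 2, byrow = TRUE),
                 odds_ratio = or, p_value = p),
            class = "ContingencyResult")
}

#' Allele-loss association report against SVs, TEs and PPI membership
#'
#' For each annotation contrast (SV within-or-near vs far, TE overlap,
#' PPI membership), builds the 2x2 table of allele loss (fewer than 4
#' alleles) against the flag, reports the per-stratum proportions to two
#' decimals and Fisher's exact test. The SV contrast is reported both
#' merged (within or near) and separately by category.
#'
#' @param genes data.frame with columns `n_alleles` and any of
#'   `sv_class` (factor from [classify_gene_sv()]) or `sv_flag`
#'   (logical), `te_flag`, `ppi`.
#' @return data.frame, one row per contrast, with counts, proportions in
#'   the loss and no-loss strata, odds ratio and p-value; `NA` rows flag
#'   degenerate (empty-stratum) contrasts.
#' @export
loss_association_report <- function(genes) {
  loss <- genes$n_alleles < 4L
  if (all(loss) || !any(loss)) {
    warning("degenerate contrast: all genes in one loss stratum")
    return(data.frame(contrast = character(0)))
  }
  one <- function(name, flag) {
    a <- sum(loss & flag); b <- sum(loss & !flag)
    c <- sum(!loss & flag); d <- sum(!loss & !flag)
    fr <- tryCatch(fisher_enrichment(a, b, c, d),
                   error = function(e) list(odds_ratio = NA, p_value = NA))
    data.frame(contrast = name, loss_flagged = a, loss_unflagged = b,
               noloss_flagged = c, noloss_unflagged = d,
               pct_loss = round(100 * a / (a + b), 2),
               pct_noloss = round(100 * c / (c + d), 2),
               odds_ratio = fr$odds_ratio, p_value = fr$p_value)
  }
  rows <- list()
  if (!is.null(genes$sv_class)) {
    rows$sv <- one("sv_within_or_near", genes$sv_class != "far")
    rows$svw <- one("sv_within", genes$sv_class == "within_sv")
    rows$svn <- one("sv_near", genes$sv_class == "near_sv")
  } else if (!is.null(genes$sv_flag)) {
    rows$sv <- one("sv_within_or_near", genes$sv_flag)
  }
  if (!is.null(genes$te_flag)) rows$te <- one("te_overlap", genes$te_flag)
  if (!is.null(genes$ppi)) rows$ppi <- one("ppi_member", genes$ppi)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
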