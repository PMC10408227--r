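#' Transcripts-per-million normalization
#'
#' `rate = count / length_kb`; `TPM = rate / sum(rate) * 1e6` per sample
#' (columns sum to exactly 1e6 before the log). With `log2 = TRUE`
#' returns `log2(TPM + 1)`.
#'
#' @param em an `ExpressionMatrix` (list with `counts` genes x samples
#'   and `gene_length_bp`), e.g. from [synth_expression()] or
#'   [read_expression()].
#' @param log2 return log2(TPM + 1) instead of raw TPM.
#' @return numeric matrix, genes x samples.
#' @export
tpm <- function(em, log2 = TRUE) {
  counts <- em$counts
  len_kb <- em$gene_length_bp / 1000
  stopifnot(all(len_kb > 0), nrow(counts) == length(len_kb))
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  rate <- counts / len_kb
  out <- sweep(rate, 2, colSums(rate), `/`) * 1e6
  if (log2) base::log2(out + 1) else out
}

#' Read a count matrix with gene lengths and a sample sheet
#'
#' The counts TSV has gene ids in the first column, a `length` column in
#' bp, and one column per sample; the sample sheet TSV has columns
#' `sample`, `group`, `batch`.
#'
#' @param counts_path,samples_path input TSV paths.
#' @return an `ExpressionMatrix` list.
#' @export
read_expression <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, row.names = 1, check.names = FALSE)
  if (!"length" %in% names(tab)) stop("counts TSV needs a 'length' column")
  sheet <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "group", "batch") %in% names(sheet)))
  counts <- as.matrix(tab[, sheet$sample, drop = FALSE])
  structure(list(counts = counts, gene_length_bp = tab$length,
                 group = sheet$group, batch = sheet$batch),
            class = "ExpressionMatrix")
}

#' Expression level by per-gene allele count
#'
#' Gene expression is the mean log2 TPM over the gene's alleles
#' (averaged across samples); genes with mean TPM below
#' `expressed_min_tpm` are excluded as not expressed. Genes are grouped
#' by retained allele count and adjacent groups compared with two-sided
#' Wilcoxon rank-sum tests, quantifying whether genes retaining more
#' alleles are expressed more highly.
#'
#' @param log2_tpm matrix of log2-transformed TPM, alleles x samples.
#' @param allele_map data.frame with columns `allele_id`, `gene_id`
#'   mapping rows of `log2_tpm` to genes; or `NULL` when rows are
#'   already genes.
#' @param allele_counts named vector: gene_id -> number of alleles.
#' @param expressed_min_tpm minimum mean TPM to count as expressed
#'   (default 1.0).
#' @return list with `gene_expr` (data.frame: gene_id, n_alleles,
#'   expr), `group_medians`, and `pairwise_p` (adjacent allele-count
#'   groups; `NA` when a group has fewer than 2 genes).
#' @export
allele_dosage_expression <- function(log2_tpm, allele_map = NULL,
                                     allele_counts,
                                     expressed_min_tpm = 1) {
  per_row <- rowMeans(log2_tpm)
  if (is.null(allele_map)) {
    gene_expr <- data.frame(gene_id = rownames(log2_tpm), expr = per_row,
                            stringsAsFactors = FALSE)
  } else {
    idx <- match(rownames(log2_tpm), allele_map$allele_id)
    if (anyNA(idx)) stop("allele_map incomplete for expression rows")
    gene_expr <- stats::aggregate(
      list(expr = per_row), by = list(gene_id = allele_map$gene_id[idx]),
      FUN = mean)
  }
  gene_expr$n_alleles <- as.integer(allele_counts[gene_expr$gene_id])
  if (anyNA(gene_expr$n_alleles)) stop("allele_counts incomplete")
  gene_expr <- gene_expr[gene_expr$expr >= base::log2(expressed_min_tpm + 1), ]
  groups <- sort(unique(gene_expr$n_alleles))
  med <- vapply(groups, function(g)
    stats::median(gene_expr$expr[gene_expr$n_alleles == g]), numeric(1))
  pw <- if (length(groups) > 1) {
    vapply(seq_len(length(groups) - 1), function(i) {
      x <- gene_expr$expr[gene_expr$n_alleles == groups[i]]
      y <- gene_expr$expr[gene_expr$n_alleles == groups[i + 1]]
      if (length(x) < 2 || length(y) < 2) return(NA_real_)
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    }, numeric(1))
  } else numeric(0)
  names(med) <- groups
  if (length(pw))
    names(pw) <- paste(groups[-length(groups)], groups[-1], sep = "_vs_")
  list(gene_expr = gene_expr, group_medians = med, pairwise_p = pw)
}

#' Percentile-rank expression profiles
#'
#' Within each sample, genes are sorted from high to low expression and
#' assigned a percentile rank from 1 (highest expressed) to 100, i.e.
#' `ceil(100 * position / n)` with ties sharing their mean position
#' before bucketing. Ranks are invariant to any per-sample monotone
#' increasing transform of expression -- the property that makes the
#' downstream DEG test robust to batch effects acting as monotone
#' distortions of each library.
#'
#' @param expr numeric matrix, genes x samples (any expression scale).
#' @param bucket if `FALSE`, return the continuous percentile
#'   `100 * rank / n` without bucketing into the 100 groups.
#' @return matrix of percentile ranks, genes x samples, values in
#'   (0, 100].
#' @export
percentile_rank_profiles <- function(expr, bucket = TRUE) {
  n <- nrow(expr)
  out <- apply(expr, 2, function(x) {
    pos <- rank(-x, ties.method = "average")
    if (bucket) ceiling(100 * pos / n) else 100 * pos / n
  })
  dimnames(out) <- dimnames(expr)
  out
}

#' Rank-based nonparametric differential expression
#'
#' Per gene, a two-sided Wilcoxon rank-sum test compares the percentile
#' ranks between the two groups; p-values are Benjamini-Hochberg
#' adjusted across genes and genes with adjusted p below `alpha` are
#' called differentially expressed. Because the test sees only
#' within-sample ranks, library-size and monotone batch distortions
#' cancel by construction.
#'
#' @param rm rank matrix from [percentile_rank_profiles()].
#' @param group character/factor of length `ncol(rm)` with exactly two
#'   levels (e.g. diploid / tetraploid), each with at least 2 samples.
#' @param alpha adjusted-p threshold for the DEG call (default 0.05).
#' @return data.frame of class `DegResult` with gene, p_value, q_value,
#'   is_deg.
#' @export
rank_deg <- function(rm, group, alpha = 0.05) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("need exactly two groups")
  if (any(table(group) < 2)) stop("need at least 2 samples per group")
  g1 <- group == levels(group)[1]
  # exact null distribution when tie-free and groups are small (sharper
  # p-value floor than the normal approximation, which matters for BH)
  p <- apply(rm, 1, function(r) {
    if (length(unique(r)) == 1) return(1)
    suppressWarnings(stats::wilcox.test(r[g1], r[!g1])$p.value)
  })
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = rownames(rm), p_value = p, q_value = q,
                    is_deg = q < alpha, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("DegResult", "data.frame")
  out
}
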