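test_that("allele_summary reproduces class counts, percentages and the mean", {
  # single gene with 4 alleles
  one <- allele_summary(data.frame(gene_id = "g1", n_alleles = 4L))
  expect_equal(one$by_class$percent[one$by_class$class == "4"], 100)
  expect_equal(one$mean_alleles, 4)
  # mixed table, hand-checked arithmetic
  tab <- data.frame(gene_id = paste0("g", 1:8),
                    n_alleles = c(4, 4, 4, 3, 2, 1, 4, 6))
  s <- allele_summary(tab)
  expect_equal(s$n_genes, 8)
  expect_equal(s$n_alleles, 28)
  expect_equal(s$mean_alleles, 3.5)
  expect_equal(s$by_class$n_genes,
               c(1L, 1L, 1L, 4L, 1L))        # classes 1,2,3,4,>4
  expect_equal(s$by_class$percent, c(12.5, 12.5, 12.5, 50, 12.5))
  expect_equal(s$n_loss, 3)                  # fewer than four alleles
  expect_error(allele_summary(integer(0)), "empty")
})

test_that("SV identity grouping applies the 50%-overlap / allelic / same-type rules", {
  svs <- data.frame(
    chrom = "chr1",
    start   = c(0L,   40L,  300L, 300L, 1000L),
    end     = c(100L, 140L, 400L, 400L, 1100L),
    sv_type = c("inversion", "inversion", "translocation", "duplication",
                "inversion"),
    monoploid = c("A", "B", "C", "D", "A"))
  g <- group_identical_svs(svs)
  # [0,100) vs [40,140): overlap 60 >= 50% of 100 -> one group {A,B}
  expect_true("AB" %in% g$presence_class)
  # same interval, different type -> two singleton groups
  expect_true(all(c("C", "D") %in% g$presence_class))
  expect_equal(nrow(g), 4)
  expect_equal(sum(g$n_members), 5)          # partition: every SV in one group
  # overlap below half the shorter interval does not join
  svs2 <- data.frame(chrom = "chr1", start = c(0L, 60L), end = c(100L, 160L),
                     sv_type = "inversion", monoploid = c("A", "B"))
  expect_equal(nrow(group_identical_svs(svs2)), 2)  # overlap 40 < 50
  # chaining via connected components: A-B overlap, B-C overlap, A-C don't
  svs3 <- data.frame(chrom = "chr1",
                     start = c(0L, 50L, 100L), end = c(110L, 160L, 210L),
                     sv_type = "duplication", monoploid = c("A", "B", "C"))
  g3 <- group_identical_svs(svs3)
  expect_equal(nrow(g3), 1)
  expect_equal(g3$presence_class, "ABC")
  # allelic-chromosome rule blocks grouping across homologous groups
  svs4 <- svs2; svs4$start <- c(0L, 10L); svs4$end <- c(100L, 110L)
  svs4$mono_chrom <- c("A01", "B07")
  map <- c(A01 = "h1", B07 = "h2")
  expect_equal(nrow(group_identical_svs(svs4, map)), 2)
  expect_error(group_identical_svs(svs4, c(A01 = "h1")), "unknown")
})

test_that("gene-SV proximity classes respect the 2 kb margin exactly", {
  genes <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  expect_equal(as.character(classify_gene_sv(
    genes, interval_set("chr1", 150, 300))), "within_sv")
  # gap 1900 <= 2000 -> near
  expect_equal(as.character(classify_gene_sv(
    genes, interval_set("chr1", 2100, 2300))), "near_sv")
  # gap 2001 -> far
  expect_equal(as.character(classify_gene_sv(
    genes, interval_set("chr1", 2201, 2300))), "far")
  # gap exactly 2000 -> near (boundary inclusive)
  expect_equal(as.character(classify_gene_sv(
    genes, interval_set("chr1", 2200, 2300))), "near_sv")
  expect_equal(as.character(classify_gene_sv(
    genes, interval_set("chr2", 150, 300))), "far")   # other chromosome
})

test_that("TE overlap requires at least one shared base under half-open intervals", {
  genes <- data.frame(chrom = "chr1", start = c(100L, 500L), end = c(200L, 600L))
  expect_equal(flag_te_overlap(genes, interval_set("chr1", 150, 160)),
               c(TRUE, FALSE))
  # abutting: TE ends where gene starts -> no overlap
  expect_equal(flag_te_overlap(genes, interval_set("chr1", 50, 100)),
               c(FALSE, FALSE))
  expect_equal(flag_te_overlap(genes, interval_set("chr1", 199, 250)),
               c(TRUE, FALSE))
  expect_equal(flag_te_overlap(genes, data.frame(chrom = character(0),
                                                 start = integer(0),
                                                 end = integer(0))),
               c(FALSE, FALSE))
})

test_that("reciprocal best hits require mutual unique bests with deterministic ties", {
  ab <- data.frame(query_id = c("a1", "a1", "a2"),
                   subject_id = c("b1", "b2", "b1"),
                   score = c(90, 50, 80))
  ba <- data.frame(query_id = c("b1", "b2"),
                   subject_id = c("a1", "a1"),
                   score = c(95, 60))
  r <- reciprocal_best_hits(ab, ba)
  expect_equal(r, data.frame(a_id = "a1", b_id = "b1"))
  # a1 -> b1 best but b1 -> a2 best: no pair for a1 (a2-b1 is mutual)
  ba2 <- data.frame(query_id = "b1", subject_id = "a2", score = 95)
  r2 <- reciprocal_best_hits(ab, ba2)
  expect_false("a1" %in% r2$a_id)
  expect_equal(r2, data.frame(a_id = "a2", b_id = "b1"))
  # tie broken lexicographically and reported
  ab3 <- data.frame(query_id = c("a1", "a1"), subject_id = c("b2", "b1"),
                    score = c(70, 70))
  ba3 <- data.frame(query_id = c("b1", "b2"), subject_id = c("a1", "a1"),
                    score = c(9, 9))
  expect_message(r3 <- reciprocal_best_hits(ab3, ba3), "tied")
  expect_equal(r3$b_id, "b1")
})

test_that("Fisher's exact test matches a brute-force hypergeometric oracle", {
  brute_fisher <- function(a, b, c, d) {
    # enumerate all tables with the observed margins; two-sided p sums the
    # probabilities of tables no more likely than the observed one
    r1 <- a + b; c1 <- a + c; n <- a + b + c + d
    as <- max(0, c1 - (n - r1)):min(r1, c1)
    probs <- dhyper(as, c1, n - c1, r1)
    p_obs <- dhyper(a, c1, n - c1, r1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  # balanced table
  f <- fisher_enrichment(5, 5, 5, 5)
  expect_equal(f$odds_ratio, 1)
  expect_equal(f$p_value, 1)
  # extreme table matches enumeration
  f2 <- fisher_enrichment(10, 0, 0, 10)
  expect_equal(f2$p_value, brute_fisher(10, 0, 0, 10))
  expect_equal(f2$odds_ratio, Inf)
  # random margins <= 30
  set.seed(14)
  for (i in 1:25) {
    t <- as.vector(stats::rmultinom(1, sample(8:30, 1), rep(0.25, 4)))
    if (any(c(t[1] + t[2], t[3] + t[4], t[1] + t[3], t[2] + t[4]) == 0)) next
    expect_equal(fisher_enrichment(t[1], t[2], t[3], t[4])$p_value,
                 brute_fisher(t[1], t[2], t[3], t[4]), tolerance = 1e-7)
  }
  expect_error(fisher_enrichment(0, 0, 3, 4), "margins")
})

test_that("printed SV-category loss rates and odds ratios are reproduced", {
  # translocations 533/939, inversions 413/1546, duplications 443/992
  expect_equal(round(100 * 533 / 939, 2), 56.76)
  expect_equal(round(100 * 413 / 1546, 2), 26.71)
  expect_equal(round(100 * 443 / 992, 2), 44.66)
  f <- fisher_enrichment(533, 939 - 533, 413, 1546 - 413)
  expect_equal(f$odds_ratio, (533 * 1133) / (406 * 413), tolerance = 1e-12)
  expect_equal(f$odds_ratio, 3.60, tolerance = 0.01)
  expect_lt(f$p_value, 0.01)
})

test_that("loss_association_report recovers planted associations and flags degenerate input", {
  ann <- synth_gene_annotations(synth_config(seed = 71, n_genes = 4000,
                                             or_sv = 3, or_ppi = 3))
  genes <- ann$genes
  genes$sv_class <- classify_gene_sv(genes, ann$svs)
  rep <- loss_association_report(genes)
  expect_true(all(c("sv_within_or_near", "sv_within", "sv_near",
                    "te_overlap", "ppi_member") %in% rep$contrast))
  sv_row <- rep[rep$contrast == "sv_within_or_near", ]
  expect_lt(sv_row$p_value, 0.001)
  expect_gt(sv_row$odds_ratio, 2)
  ppi_row <- rep[rep$contrast == "ppi_member", ]
  expect_lt(ppi_row$odds_ratio, 1)           # PPI genes resist loss
  # all genes intact -> degenerate
  intact <- data.frame(n_alleles = rep(4L, 10), te_flag = rep(TRUE, 10))
  expect_warning(r0 <- loss_association_report(intact), "degenerate")
  expect_equal(nrow(r0), 0)
})
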