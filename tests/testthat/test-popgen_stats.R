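make_sites <- function(dosages, ploidy, pos = NULL, anc = TRUE) {
  d <- matrix(as.integer(dosages), ncol = length(ploidy), byrow = TRUE)
  n <- nrow(d)
  genotype_matrix(rep("chr1", n),
                  if (is.null(pos)) seq_len(n) * 100L else pos,
                  rep("A", n), rep("G", n), d, ploidy,
                  ancestral_is_ref = rep(anc, n))
}

test_that("windowed pi matches the pairwise-difference formula", {
  # 1 SNP, n = 4 chromosomes, j = 2 -> pi = (2*2*2/12)/10000
  gm <- make_sites(c(1, 1), c(2L, 2L), pos = 500L)
  w <- pi_windows(gm, window_bp = 10000, step_bp = 10000)
  expect_equal(w$pi[1], (2 * 2 * 2 / 12) / 10000)
  # monomorphic window -> 0
  gm0 <- make_sites(c(0, 0), c(2L, 2L), pos = 500L)
  expect_equal(pi_windows(gm0, window_bp = 10000, step_bp = 10000)$pi[1], 0)
})

test_that("pi agrees with a brute-force pairwise-difference oracle", {
  gm <- toy_gm(n_sites = 15, n_dip = 3, n_tet = 2, seed = 13,
               spacing = 50L)
  w <- pi_windows(gm, window_bp = 1000, step_bp = 1000)
  # oracle: expand each sample into chromosomes, count differences over
  # all chromosome pairs at each site
  total <- 0
  for (s in seq_len(n_sites(gm))) {
    chroms <- unlist(mapply(function(d, p) c(rep(1, d), rep(0, p - d)),
                            gm$dosage[s, ], gm$ploidy))
    pairs <- combn(chroms, 2)
    total <- total + mean(pairs[1, ] != pairs[2, ])
  }
  expect_equal(w$pi[1], total / 1000)
})

test_that("pi subsampling with all individuals equals no subsampling", {
  gm <- toy_gm(n_sites = 40, n_dip = 2, n_tet = 4, seed = 17)
  full <- pi_windows(gm, window_bp = 5000, step_bp = 5000)
  sub <- pi_windows(gm, window_bp = 5000, step_bp = 5000,
                    subsample_k = 6, n_reps = 5, seed = 1)
  expect_equal(sub$pi, full$pi)
})

test_that("dxy follows the between-population frequency formula and tiling rule", {
  popA <- "s1"; popB <- "s2"
  # identical fixed sequences -> 0
  gm <- make_sites(c(2, 2, 0, 0), c(2L, 2L), pos = c(100L, 200L))
  r <- dxy_windows(gm, popA, popB, list(chrom = "chr1", start = 0, end = 10000))
  expect_equal(r$dxy, 0)
  # shared intermediate frequency still contributes between-population
  # mismatch: p = 0.5 in both -> 2 p (1-p) = 0.5 per site
  gmh <- make_sites(c(1, 1), c(2L, 2L), pos = 100L)
  rh <- dxy_windows(gmh, popA, popB, list(chrom = "chr1", start = 0, end = 1000))
  expect_equal(rh$dxy, 0.5 / 1000)
  # one fixed difference in 10 kb -> 1e-4
  gm2 <- make_sites(c(2, 0), c(2L, 2L), pos = 100L)
  r2 <- dxy_windows(gm2, popA, popB, list(chrom = "chr1", start = 0, end = 10000))
  expect_equal(r2$dxy, 1e-4)
  # 120 kb region: two 50 kb windows plus a 20 kb remainder
  r3 <- dxy_windows(gm2, popA, popB,
                    list(chrom = "chr1", start = 0, end = 120000))
  expect_equal(r3$start, c(0, 50000, 100000))
  expect_equal(r3$end, c(50000, 100000, 120000))
  # region shorter than 50 kb emitted whole
  r4 <- dxy_windows(gm2, popA, popB,
                    list(chrom = "chr1", start = 0, end = 30000))
  expect_equal(nrow(r4), 1)
  expect_equal(r4$end - r4$start, 30000)
})

test_that("Tajima's D matches the 1989 constants", {
  # n = 4 chromosomes, S = 3 singletons
  gm <- make_sites(c(1, 0,
                     1, 0,
                     1, 0), c(2L, 2L))
  d <- tajimas_d(gm)
  # independent hand evaluation of the constants for n = 4
  n <- 4; S <- 3
  a1 <- sum(1 / (1:3)); a2 <- sum(1 / (1:3)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  pi_tot <- 3 * (2 * 1 * 3 / 12)
  expect_equal(d, (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * 2))
  expect_equal(d, -0.75, tolerance = 0.01)
  # S = 0 -> missing
  expect_true(is.na(tajimas_d(make_sites(c(0, 0), c(2L, 2L)))))
})

test_that("a frequency spectrum with pi equal to Watterson's theta gives D = 0", {
  # n = 8: xi_i proportional to 1/i scaled so counts are integers
  n <- 8L
  xi <- as.integer(840 / (1:7))              # 840 = lcm(1..7)
  ploidy <- rep(2L, 4)
  rows <- do.call(rbind, lapply(1:7, function(i) {
    # dosage pattern with derived count i over 8 chromosomes
    pat <- c(rep(2L, i %/% 2), rep(1L, i %% 2))
    row <- c(pat, rep(0L, 4 - length(pat)))
    matrix(rep(row, xi[i]), ncol = 4, byrow = TRUE)
  }))
  gm <- genotype_matrix(rep("chr1", nrow(rows)), seq_len(nrow(rows)) * 10L,
                        rep("A", nrow(rows)), rep("G", nrow(rows)),
                        rows, ploidy)
  expect_equal(tajimas_d(gm), 0, tolerance = 1e-10)
})

test_that("Fay-Wu's H has the expected sign and single-site value", {
  # all singletons -> H > 0 (theta_H minimized at i = 1)
  gm1 <- make_sites(c(1, 0, 1, 0), c(2L, 2L))
  expect_gt(as.numeric(fay_wu_h(gm1)), 0)
  # all at i = n - 1 -> strongly negative
  gm2 <- make_sites(c(2, 1, 2, 1), c(2L, 2L))
  expect_lt(as.numeric(fay_wu_h(gm2)), 0)
  # single site, n = 4, i = 2: theta_pi = 2*2*2/12, theta_H = 2*4/12
  gm3 <- make_sites(c(1, 1), c(2L, 2L))
  expect_equal(as.numeric(fay_wu_h(gm3)), 8 / 12 - 8 / 12)
  gm4 <- make_sites(c(2, 1), c(2L, 2L))     # i = 3: 2*3*1/12 - 2*9/12
  expect_equal(as.numeric(fay_wu_h(gm4)), 6 / 12 - 18 / 12)
  # unpolarized sites are skipped and counted
  gm5 <- make_sites(c(1, 1), c(2L, 2L), anc = NA)
  h <- fay_wu_h(gm5)
  expect_true(is.na(h))
  expect_equal(attr(h, "n_unpolarized"), 1)
})

test_that("Weir-Cockerham F_ST is 1 at fixed differences and ~0 under permutation", {
  gm <- make_sites(c(2, 2, 0, 0), c(2L, 2L, 2L, 2L))
  expect_equal(wc_fst(gm, c("s1", "s2"), c("s3", "s4")), 1)
  # monomorphic -> missing
  expect_true(is.na(wc_fst(make_sites(c(0, 0, 0, 0), rep(2L, 4)),
                           c("s1", "s2"), c("s3", "s4"))))
  # random split of one panmictic population: mean ~ 0 (permutation oracle)
  gm2 <- synth_two_pop_genotypes(synth_config(seed = 33, n_sites = 500,
                                              split_time = 0,
                                              n_tetraploid = 1))
  dips <- paste0("dip", 1:12)
  set.seed(99)
  fsts <- replicate(30, {
    grp <- sample(dips)
    wc_fst(gm2, grp[1:6], grp[7:12])
  })
  expect_lt(abs(mean(fsts)), 0.02)
})

test_that("pi and dxy are invariant under ref/alt relabeling", {
  gm <- toy_gm(n_sites = 25, seed = 19)
  flip <- genotype_matrix(gm$chrom, gm$pos, gm$alt, gm$ref,
                          sweep(-gm$dosage, 2, gm$ploidy, `+`), gm$ploidy)
  expect_equal(pi_windows(gm, window_bp = 2000, step_bp = 2000)$pi,
               pi_windows(flip, window_bp = 2000, step_bp = 2000)$pi)
  A <- c("s1", "s2"); B <- c("s4", "s5")
  reg <- list(chrom = "chr1", start = 0, end = 2000)
  expect_equal(dxy_windows(gm, A, B, reg)$dxy,
               dxy_windows(flip, A, B, reg)$dxy)
})

test_that("delta statistics subtract with the published orientation", {
  dip <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
                    n_snps = 5, tajima_d = c(1.0, 0.2), fay_wu_h = c(0, 0),
                    clr = c(2, 3))
  tet <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
                    n_snps = 5, tajima_d = c(-0.5, 0.2),
                    fay_wu_h = c(-1, 0), clr = c(10, 3), fst = c(0.5, 0))
  d <- delta_stats(dip, tet)
  expect_equal(d$delta_d, c(1.5, 0))         # D_dip - D_tet
  expect_equal(d$delta_clr, c(8, 0))         # CLR_tet - CLR_dip
  # missing CLR column: delta_clr absent, delta_d still computed
  d2 <- delta_stats(dip[-7], tet[-7])
  expect_null(d2$delta_clr)
  expect_equal(d2$delta_d, c(1.5, 0))
  # window mismatch is an error
  expect_error(delta_stats(dip, tet[2:1, ]), "differ")
})

test_that("Ks-to-time conversion dates divergence correctly", {
  expect_equal(ks_to_time(0.005, 2.06e-9) / 1e6, 1.2, tolerance = 0.02)
  expect_equal(ks_to_time(0), 0)
  expect_equal(ks_to_time(0.325, 2.06e-9), 7.89e7, tolerance = 0.001)
  expect_error(ks_to_time(0.1, 0), "positive")
})
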