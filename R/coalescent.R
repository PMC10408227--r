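## Structured-coalescent engine shared by the inheritance simulator and the
## two-population synthetic genotype generator.
##
## Time is measured in units of 4N generations, where 4N is the number of
## chromosomes in the reference pool (the natural unit for an autotetraploid
## population of N individuals). In a deme of relative size x the pairwise
## coalescence rate is 1/x per unit time, so a single deme of size 1 gives
## E[T2] = 1 and, with mutations placed as Poisson(theta/2 * branch length),
## the standard neutral expectations E[S] = theta * a1 and E[xi_i] = theta/i
## for a sample of n chromosomes.

## One locus under the structured coalescent: `deme` assigns each sampled
## lineage (leaf) to a deme; demes have relative sizes `sizes` and merge
## into a single ancestral deme of size `anc_size` at `merge_time` (ignored
## when all leaves start in one deme). Returns the derived leaf set of each
## segregating site under the infinite-sites model.
## Pure-R reference implementation; the package simulates through the
## compiled engine (coal_locus_engine) and this version is retained as an
## independent cross-check of the same process.
coal_locus_r <- function(deme, sizes, merge_time = Inf, theta = 1,
                         anc_size = 1) {
  n <- length(deme)
  desc <- as.list(seq_len(n))        # leaf sets of active lineages
  dm <- as.integer(deme)
  len <- numeric(n)                  # accrued branch length per lineage
  t <- 0
  merged <- length(unique(dm)) == 1L || merge_time <= 0
  if (merged) { dm[] <- 1L; sizes <- anc_size }
  br_set <- vector("list", 2L * n)   # finalized branches
  br_len <- numeric(2L * n)
  nb <- 0L

  while (length(desc) > 1L) {
    k <- tabulate(dm, nbins = length(sizes))
    rates <- k * (k - 1) / (2 * sizes)
    R <- sum(rates)
    if (R == 0) {                    # isolated singletons waiting for merge
      if (merged) stop("coalescent stalled")   # cannot happen
      len <- len + (merge_time - t)
      t <- merge_time
      merged <- TRUE; dm[] <- 1L; sizes <- anc_size
      next
    }
    dt <- stats::rexp(1L, R)
    if (!merged && t + dt >= merge_time) {
      len <- len + (merge_time - t)
      t <- merge_time
      merged <- TRUE; dm[] <- 1L; sizes <- anc_size
      next
    }
    len <- len + dt
    t <- t + dt
    d <- sample.int(length(sizes), 1L, prob = rates)
    pair <- sample(which(dm == d), 2L)
    i <- pair[1L]; j <- pair[2L]
    br_set[[nb + 1L]] <- desc[[i]]; br_len[nb + 1L] <- len[i]
    br_set[[nb + 2L]] <- desc[[j]]; br_len[nb + 2L] <- len[j]
    nb <- nb + 2L
    desc[[i]] <- c(desc[[i]], desc[[j]])
    len[i] <- 0
    desc[[j]] <- NULL; dm <- dm[-j]; len <- len[-j]
  }

  if (nb == 0L || theta <= 0) return(list(n_leaves = n, sites = list()))
  nmut <- stats::rpois(nb, theta / 2 * br_len[seq_len(nb)])
  idx <- rep.int(seq_len(nb), nmut)
  list(n_leaves = n, sites = br_set[idx])
}

## Dosage matrix (sites x groups) for one locus via the compiled engine.
coal_dosages <- function(deme, sizes, merge_time = Inf, theta = 1,
                         anc_size = 1, group, n_groups) {
  coal_locus_engine(as.integer(deme), as.numeric(sizes),
                    as.numeric(merge_time), theta, anc_size,
                    as.integer(group), as.integer(n_groups))
}

#' Simulate one locus of tetraploid genotypes under a given inheritance mode
#'
#' Under tetrasomic inheritance all `4 * n_individuals` sampled chromosomes
#' coalesce in a single exchangeable pool (one deme of relative size 1).
#' Under disomic inheritance each individual contributes 2 chromosomes to
#' each of two subgenome demes of relative size 0.5 that do not exchange
#' lineages more recently than `td` (time since disomy evolved, in units of
#' 4N generations); at `td` the demes merge into the size-1 ancestral pool.
#' Mutations follow the infinite-sites model with rate `theta/2` per unit
#' branch length, giving the standard neutral spectrum E[xi_i] = theta/i in
#' the tetrasomic case.
#'
#' @param mode `"tetrasomic"` or `"disomic"`.
#' @param td time since disomic inheritance evolved (4N-generation units);
#'   ignored for tetrasomic. `td = 0` is equivalent to tetrasomic.
#' @param theta scaled mutation rate per locus.
#' @param n_individuals number of sampled tetraploid individuals.
#' @return integer matrix of derived-allele dosages (0..4), segregating
#'   sites x individuals; attribute `n_chromosomes` gives `4*n_individuals`.
#' @export
simulate_locus <- function(mode = c("tetrasomic", "disomic"), td = 0,
                           theta = 1, n_individuals = 12L) {
  mode <- match.arg(mode)
  stopifnot(td >= 0, n_individuals >= 1)
  n_leaves <- 4L * n_individuals
  indiv <- rep(seq_len(n_individuals), each = 4L)
  if (mode == "tetrasomic" || td == 0) {
    out <- coal_dosages(rep(1L, n_leaves), sizes = 1, theta = theta,
                        group = indiv, n_groups = n_individuals)
  } else {
    # leaves 1,2 of each individual in subgenome deme 1; leaves 3,4 in deme 2
    dm <- rep(rep(c(1L, 2L), each = 2L), n_individuals)
    out <- coal_dosages(dm, sizes = c(0.5, 0.5), merge_time = td,
                        theta = theta, group = indiv,
                        n_groups = n_individuals)
  }
  attr(out, "n_chromosomes") <- n_leaves
  out
}
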