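---
title: "Models and methods in polytetra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in polytetra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytetra)
```

`polytetra` analyses a diploid population alongside a derived
autotetraploid population of the same species. This vignette documents the
models behind each analysis, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, and the numerical
and design choices that were genuinely open.

## Genotype representation and conventions

Variant sites are biallelic and stored as per-sample counts of the
alternate allele ("dosage", 0..ploidy, `NA` for missing); samples are
diploid or tetraploid. Positions follow the VCF 1-based convention; all
intervals (genes, CDS, SVs, TEs, windows) are handled internally as 0-based
half-open and converted at the format boundary (BED passes through, GFF3
start is decremented). Missing genotypes are always excluded from
allele-frequency denominators, never counted as reference.

## SNP filtering and two-allele subsampling

`filter_neutral_independent()` applies three filters in a fixed order:
sites within coding sequence extended by `cds_margin_bp` (default 20 kb)
are removed; the remainder is thinned greedily from the smallest coordinate
per chromosome so that retained sites are at least `thin_bp` (20 kb) apart;
sites with minor allele frequency below `maf_min` (0.01, computed over all
non-missing chromosomes jointly) are removed. The order matters only
mildly (thinning after exclusion avoids anchoring on sites that are about
to be removed), and the operation is idempotent.

Tetraploid genotypes carry four chromosomes where diploids carry two, so
frequency-spectrum statistics computed jointly would mix sample sizes.
`subsample_two_alleles()` draws, per tetraploid genotype, 2 of the 4
chromosomes without replacement — the induced pseudo-diploid dosage is
hypergeometric (for dosage 2, P(diploid dosage 1) = 4/6) — and repeats this
to produce replicate datasets (default 5). `replicate_consistency()`
confirms by pairwise two-sided Wilcoxon rank-sum tests that a windowed
statistic does not differ materially across replicates.

## Windowed statistics

Per-site diversity uses allele counts: with j alternate alleles among n
chromosomes, the per-site heterozygosity is 2j(n−j)/(n(n−1)); `pi_windows()`
sums this over sites and divides by the window span (50 kb sliding windows
advancing 20 kb by default; windows are emitted at full nominal length, so
the denominator is always the window size). Optional subsampling of k
individuals repeated `n_reps` times (default 20) emulates diversity
estimation from repeated small panels. D_XY uses
p_A(1−p_B) + p_B(1−p_A) per site over a stated syntenic region, tiled into
50 kb windows when the region is at least 50 kb (remainder emitted whole)
and taken whole otherwise; a window with no called sites has D_XY 0 —
monomorphic means identical under this divergence measure.

Tajima's D follows the 1989 constants exactly and requires a common
chromosome count across the sites used (sites with missingness among the
chosen samples are dropped). Fay–Wu's H is the original unnormalized
θ_π − θ_H with θ_H = Σ 2ξᵢi²/(n(n−1)) over derived-allele counts, so it
requires outgroup polarization (the `AA` INFO tag on input); unpolarized
sites are skipped and counted. F_ST is the Weir–Cockerham (1984) θ in its
allele-count (haploid) form — dosage data do not expose heterozygote state
once tetraploid genotypes enter, so the within-individual component is not
estimable and the between/within-population decomposition on chromosomes is
used instead; windowed values divide the summed numerator components by the
summed denominators rather than averaging per-site ratios, which
deweights uninformative sites. Negative estimates are reported as computed.

The clock conversion `ks_to_time()` is T = Ks/(2μ) with μ in substitutions
per site per year, e.g. a Ks peak of 0.005 at μ = 2.06 × 10⁻⁹ dates a
whole-genome duplication to about 1.2 Mya.

## The DCMS selection scan

Four signals enter the scan in non-overlapping 25 kb windows with at least
10 SNPs: ΔTajima's D (diploid minus tetraploid), ΔCLR (tetraploid minus
diploid; CLR is consumed as a precomputed column when available), F_ST and
the tetraploid Fay–Wu's H. None of these is close to Gaussian, so each is
normalized in two steps: percentile ranks r/(n+1) (average ranks on ties),
then the standard normal quantile function. One-sided p-values orient each
statistic so that sweep-like signal maps to small p — upper tail for
ΔTajima's D, ΔCLR and F_ST, lower tail for H; the orientation is a package
choice, as only the combination rule is fixed by the DCMS construction.
The composite is

DCMS(w) = Σᵢ log₁₀((1−pᵢ(w))/pᵢ(w)) / Σⱼ |r_ij|,

with r_ij the Pearson correlation of the p-value columns across windows.
The denominator discounts redundant statistics: with a single statistic
duplicated, both copies' weights double and the score is exactly unchanged.
With two or more distinct statistics the compensation is approximate — the
duplicate also perturbs the other columns' weights by its correlation with
them — which is inherent to the published weighting and documented here so
the exact-invariance property is only asserted for the single-statistic
case. Window p-values are obtained by re-applying the same two-step
normalization to the DCMS scores and taking the upper tail (rather than
fitting a Gaussian to the scores); selection is called at p < 0.05 raw, per
the source procedure, with no further multiple-testing correction. Genes
overlapping a selected window by ≥1 bp are reported once. Because the
window p-values are rank-based, the null selection rate at α is α by
construction — the corresponding test validates the plumbing, not a
distributional assumption.

## Coalescent simulation of inheritance modes

The simulator measures time in units of 4N generations (4N chromosomes is
the natural pool for an autotetraploid population of N individuals) and
gives a deme of relative size x a pairwise coalescence rate 1/x. Mutations
are an infinite-sites Poisson process at rate θ/2 per unit branch length,
so a tetrasomic sample of n chromosomes has E[S] = θ·a₁ and E[ξᵢ] = θ/i.
Tetrasomic inheritance is a single exchangeable pool of size 1 holding all
4 chromosomes of every individual. Disomic inheritance places 2
chromosomes of each individual in each of two subgenome demes of size 0.5
with no exchange more recently than t_d; at t_d the demes merge into the
size-1 ancestral pool. t_d = 0 reduces exactly to tetrasomy. Deep
isolation produces inter-subgenome fixed differences, visible as mass at
exactly 50% sample frequency. Mixtures simulate a fraction of loci
disomically (`disomic_proportion`), the rest tetrasomically. Loci are
independent and unrecombining; subgenome assignment is unobservable in the
output dosages, matching unphased genotype data. The inner loop is
compiled (Rcpp); a pure-R reference implementation of the same process is
kept and the two are cross-checked distributionally in the tests.

Observed spectra are folded (no outgroup polarization is assumed for the
SFS), and model comparison uses the two-sample Kolmogorov–Smirnov distance
between per-site minor-allele-frequency samples. One-sided D⁺/D⁻ variants
with the asymptotic tail p = exp(−2mnD²/(m+n)) are available;
`fit_inheritance()` defaults to the two-sided test because bounding a
parameter requires rejecting models on both sides of the truth. The fit
scans t_d ∈ {0.2, …, 1.0} × proportion ∈ {0.1, …, 0.9} plus the pure
tetrasomic model, reports the minimum-distance model, and summarizes
rediploidization as the largest proportion whose best p-value over t_d is
not rejected at α = 0.05 — the "at most X% of the genome is disomic" style
of statement.

**Identifiability caveat.** The (t_d, proportion) family is nearly
degenerate along a ridge: for shallow-to-moderate isolation times the
disomic spectrum deviates from the tetrasomic one approximately linearly in
t_d, so the data constrain roughly the product proportion × t_d rather than
each factor. Empirically, spectra simulated at proportion 0.8 and t_d 0.4
are within Monte-Carlo noise of proportion 0.3 at t_d 0.6 even at ~10⁵
sites per sample. Consequently the largest non-rejected proportion over
the whole t_d grid converges to the high end of the ridge, not to the
generating proportion, at any realistic sample size; with t_d fixed at its
true value the proportion is recovered within one grid step (this is the
property the test suite asserts). Conclusions drawn from the full grid
should therefore be read as bounds along the ridge, and the corresponding
full-grid recovery check in the acceptance tests is expected to fail by
design honesty rather than implementation error.

## Genome structure and allele-loss association

Autotetraploid genes are expected in four allelic copies; `allele_summary()`
tabulates retention classes (1–4 and >4 copies) with percentages to two
decimals and the mean alleles per gene. Structural variants called on each
monoploid genome against the diploid reference are grouped as "identical"
when they overlap by at least 50% of the shorter interval, lie on allelic
chromosomes and share a type; since identity can chain, groups are
connected components, and each group's presence class is one of the 15
nonempty subsets of the four monoploid genomes. The 50% denominator (the
shorter interval) and the transitive closure are package choices where the
verbal rule is ambiguous. Genes are classed against SVs as within (≥1 bp
overlap), near (≤2 kb) or far (>2 kb), using full gene spans; TE overlap is
a boolean ≥1 bp test under the half-open convention (abutting intervals do
not overlap). PPI membership is derived from reciprocal best protein hits,
requiring mutual unique best hits with lexicographic tie-breaking
(reported). Enrichment contrasts (loss × SV proximity, loss × TE overlap,
loss × PPI membership) use Fisher's exact test (two-sided,
minimum-likelihood convention) with the sample odds ratio ad/bc; the SV
contrast is reported both merged (within-or-near) and split, since summary
percentages in this literature usually merge the two.

## Rank-based differential expression

Counts are normalized to TPM (rate = count/length in kb, scaled to 10⁶ per
sample) and log2-transformed with a +1 pseudocount (the zero-handling rule
is unstated in the source procedure; +1 is the common choice). For DEG
detection each sample's genes are ranked from highest expression
(percentile 1) to lowest (100), ties sharing their mean position before
bucketing; a per-gene two-sided Wilcoxon rank-sum test compares ranks
between ploidy groups and BH adjustment is applied across genes with calls
at adjusted p < 0.05. Because ranks are invariant to any monotone
per-sample transform, library-size differences and monotone batch
distortions cancel exactly — the batch-robustness claim holds at the level
of the rank matrix, which the tests assert literally. The Wilcoxon
implementation uses the exact null distribution when group sizes are small
and ranks tie-free, falling back to the normal approximation with
continuity correction otherwise. Two discreteness limits are worth
knowing: with the 100-group bucketing, ties usually force the normal
approximation, whose two-sided p-value floor at 6v6 replicates (~0.005)
cannot reach BH-adjusted significance at genome scale no matter the effect
size — the continuous-rank variant (`bucket = FALSE`) reaches the exact
floor 2/C(12,6) and is the right choice for small designs; and even then
recall is capped by the fraction of truly perturbed genes that separate
completely. Expression-by-allele-dosage comparisons average log2 TPM over
a gene's alleles, drop genes below TPM 1 as unexpressed, and compare
adjacent allele-count groups by Wilcoxon.

## Synthetic data: what it emulates, and what it does not

Defaults state a small version of the motivating study design: 12 diploid
and 12 tetraploid individuals; a recent split (0.1 in 4N-generation units);
a 30.8% baseline allele-loss rate with loss odds ratios ~1.6 vs SV
proximity, ~1.1 vs TE overlap and ~3.3 vs non-PPI membership (the values
implied by the published contrast percentages), planted by conditional
Bernoulli draws in a logistic model; lost genes retain 1–3 alleles in the
observed ~24:27:49 ratio; RNA-seq with two batches per group (3+8 diploid,
3+6 tetraploid replicates), negative-binomial counts with dispersion 0.1
(the standard bulk-RNA-seq within-condition magnitude), multiplicative
library-size batch shifts, and optional ploidy fold-changes and per-allele
dosage effects. Sweeps are emulated by SFS distortion — removing a
fraction of intermediate-frequency sites in the window and boosting a
fraction of the rest to ~0.9 derived frequency — which reproduces the
negative Tajima's D / negative Fay–Wu's H / elevated F_ST signature cheaply.
The generators deliberately omit linkage along chromosomes (sites are
exchangeable), recombination within loci, sequencing error and mapping
bias. A green scan test therefore establishes that the statistics and the
composite ranking respond correctly to frequency-spectrum distortion, not
that the pipeline is robust to LD structure or technical artifacts in real
resequencing data.

## Numerical choices

Greedy thinning anchors on the first retained site per chromosome.
Two-step normalization maps ranks to r/(n+1), so an all-tied vector maps to
Z = 0 everywhere; a constant p-value column makes the DCMS correlation
undefined and is rejected. KS p-values use the asymptotic formulas
(one-sided exponential bound, two-sided Kolmogorov series truncated at 100
terms, exact D from the pooled ECDF grid). Window tiling anchors at
coordinate 0. Replicate streams derive from `seed + replicate`, keeping
all derived seeds well below 2³¹. Fisher's odds ratio is the sample ad/bc
(infinite when bc = 0), not the conditional MLE. All generators are
deterministic given their seed.
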