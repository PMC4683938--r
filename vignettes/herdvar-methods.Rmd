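---
title: "Methods: models, estimators and design choices in herdvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in herdvar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdvar)
```

`herdvar` characterizes small, recently diverging populations from biallelic
SNP-chip genotypes. This vignette documents the statistical models behind
each module, the tunable parameters with their defaults and rationale, what
the synthetic-data generators do and do not emulate, and the places where a
design choice was genuinely open and how it was resolved. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## The genotype model and allele coding

All analyses run on a samples × markers dosage matrix with entries 0/1/2
(copies of the counted allele, `allele_b`) or missing, plus per-marker
chromosome/position/allele metadata. PED/MAP files carry no reference
allele, so reading must pick a counted allele deterministically: the minor
allele, with ties broken towards the lexicographically larger label. A
consequence is that a matrix round-trips bit-identically through
write/read only when it already uses that coding; `canonicalize_alleles()`
establishes it, the simulators emit it, and every downstream statistic is
invariant to the choice (verified by relabeling tests). Coordinates are
1-based; missingness is a dedicated sentinel, never dosage 0.

## Quality control

The filter cascade runs in a fixed order — non-autosomal/unmapped markers,
marker call rate (default ≥ 0.95), sample call rate (≥ 0.95), marker
quality (≥ 0.6, only when scores are present), heterozygosity outliers
(|h − mean| ≤ 3 SD across markers), Hardy–Weinberg exact test
(p ≥ 10⁻¹⁶) — each computed on the currently retained data, in a single
pass. Marker-level filters precede sample-level ones, matching common chip
practice; the cascade is deliberately not iterated to convergence, so
under heavy, unevenly distributed missingness a second pass can remove
further markers (sample removal changes call rates). At chip-realistic
missingness the pass is stable, which is what the idempotence test
asserts. The HW test is the conditional exact test (two-sided by summing
all heterozygote counts whose conditional probability does not exceed the
observed one) and is pooled across samples by default; population-
stratified testing is available (`hwe_by_population`) but off, since
pooling is what a single global filter implies. The heterozygosity filter
uses the observed heterozygote fraction per marker; an inbreeding-style
standardization would be an alternative, but the observed fraction is the
direct reading of "heterozygosity within three standard deviations".

## Diversity and differentiation

Expected heterozygosity is reported as plain `2p(1-p)` per locus with an
`unbiased` switch for the `2n/(2n-1)` correction: the choice does not
affect the paired t-test contract (the test compares per-locus observed
vs expected values across markers, paired by locus). F_IS within a
population uses the ratio-of-sums `1 - sum(Ho)/sum(Hs)` with the
Nei–Chesser unbiased gene diversity, the standard small-sample form.

Between populations, the Weir–Cockerham (1984) variance components a, b, c
are computed per locus in the full unequal-sample-size formulation
(n̄, n_c, p̄, s², h̄); multi-locus estimators are ratios of summed
components, loci with a + b + c = 0 excluded, negative per-locus values
retained. A duplicated population (same rows twice) does *not* give
θ = 0 but the small negative bias −1/(2n−1): the estimator subtracts a
sampling variance that duplicated data do not contain. Splitting one
population at random gives θ ≈ 0, and that is the test used for the null.

Bootstrap significance for pairwise F_ST resamples loci with replacement
and reports `p = (1 + #{θ* ≤ 0})/(n_boot + 1)` for the one-sided test of
θ > 0 — the +1 convention avoids exact-zero p-values, so with a single
replicate the attainable values are {0.5, 1}, not {0, 1}. Nei's standard
distance is computed from the biallelic identity sums; opposite fixation
at all loci yields an infinite distance by construction. The F_ST scan
threshold is mean + 3 SD over markers with defined θ, strict inequality,
so a zero-variance scan flags nothing.

## LD-based effective population size

The LD signal is the Burrows composite disequilibrium, computable from
unphased genotypes: Δ̂ = cov(X, Y)/2 over samples non-missing at both loci.
The r² normalization matters more than it looks. The sample-size bias
corrections published for this estimator were calibrated for the Burrows
r² with Weir's composite denominator, which adds the within-locus
Hardy–Weinberg disequilibrium D_A = P_AA − p² to each variance term. With
the plain `p(1-p)q(1-q)` denominator the pure-sampling expectation of r²
falls measurably below the correction (0.0526-ish vs 0.0583 at S = 20) and
the resulting Ne is inflated several-fold at small S; with the Weir
denominator the package's own Wright–Fisher simulations recover census N
within a factor of 2 at N ∈ {20, 50} (the acceptance test). The default is
therefore `denominator = "weir"`, with `"plain"` exposed for comparison.

Per chromosome, r² is averaged unweighted over all within-chromosome
pairs with MAF ≥ `maf_min` (default 0.05, the customary cut-off; it is a
flag because it shifts Ne), pairs monomorphic on their shared samples are
excluded rather than zeroed, and r² values above 1 are retained — they are
legitimate outcomes of the composite formula and excluding them would bias
the mean downward. The harmonic mean of per-pair shared sample counts S
selects the correction branch: for S ≥ 30, r²' = r² − (1/S + 3.19/S²) and
Ne = (1/3 + √(1/9 − 2.76 r²'))/(2 r²'); for S < 30 the 0.0018 + 0.907/S +
4.44/S² expectation and the 0.308-coefficient quadratic. Algebraically the
S ≥ 30 branch inverts exactly at r²' = 1/(3Ne) − 0.69/Ne², which is the
round-trip the tests assert. Non-positive drift signal or a negative
discriminant returns an infinite-Ne sentinel; within a genome those
chromosomes are counted and excluded from the average. The genome value is
the arithmetic mean ± SD across chromosome estimates (harmonic mean
available), mirroring per-chromosome batching with averaging; random
mating is the only supported mating model.

Heterozygosity projection uses the exact geometric law
H_t = H₀(1 − 1/(2Ne))ᵗ over a default 50-generation horizon; the halving
time is the smallest integer t with H_t ≤ H₀/2 (10 generations at Ne = 7,
15 at Ne = 11).

## Rarefaction

Allelic richness is the expected allele count in a g-copy subsample,
A_R = Σ_a [1 − C(N−N_a, g)/C(N, g)]; private allelic richness multiplies
the focal presence probability by the absence probabilities in all other
populations (subsamples independent across populations). g is chosen
globally — the largest even value no greater than the minimum non-missing
gene-copy count over populations and loci — so values are comparable
across populations; loci where any population falls below g are skipped
for all populations and counted. Combinatorics use exact `choose()` up to
N = 500 and log-space ratios beyond. The complement set for privacy is
all other populations in the run.

## Genomic relationships and PCA

VanRaden method 1: missing dosages are replaced by the per-marker mean
allele count, Z = M − 2p, G = ZZᵀ/(2Σp(1−p)), monomorphic markers excluded
from numerator and denominator alike. Reference frequencies default to the
analysed sample set; the per-population summaries (mean diagonal, mean
upper-triangle off-diagonal) rebuild G within each population with its own
frequencies, which makes diagonals ≈ 1 and forces row sums to zero — so
within-population off-diagonals are slightly negative by construction, and
cross-population relatedness questions should use the pooled-frequency
flag instead. Sampling-design checks flag off-diagonal pairs above 0.25.
PCA is the eigendecomposition of G with a deterministic sign convention
(largest-magnitude loading positive).

## AMOVA

One level, squared Euclidean distances between mean-imputed dosage vectors
(equivalent up to scale to allele-mismatch counting for biallelic SNPs —
the distance had to be chosen, and this one is both standard and exactly
testable against literal summation): SS_total = Σ_{i<j} d²/N, within-group
sums analogously per group, σ²_w = MS_within, σ²_a = (MS_among −
MS_within)/n₀. Both the raw and the zero-truncated σ²_a are reported;
percentages use the truncated value. Significance permutes sample labels,
`p = (1 + #{σ²_a* ≥ σ²_a})/(n_perm + 1)`, default 1000 permutations. The
reported F-value is MS_among/MS_within.

## Population tree

Ward minimum-variance clustering on squared Euclidean distances between
population allele-frequency vectors, implemented agglomeratively with the
Lance–Williams update and a deterministic first-minimal-pair tie-break;
heights equal twice the within-cluster ESS increase and are non-decreasing
towards the root. Bootstrap support resamples markers with replacement
(equivalently, columns of the frequency matrix — frequencies are
per-marker), recomputes the tree, and scores each clade of the point
estimate by the percentage of replicates containing the same leaf set.
Newick output carries heights as branch-length differences and supports as
node labels. A caution built into the tests: under an island model the two
drifted islands need *not* form a clade — each is closer to the mainland
ancestor than to the other island in expectation, and the tree reflects
frequency distances, not branching order.

## Synthetic data: what the generators emulate

`balding_nichols()` draws ancestral frequencies uniformly on [0.05, 0.95]
(chip-like ascertained spectrum), population frequencies from the Beta
model with divergence F (so the expected pairwise Weir–Cockerham θ between
populations with divergences F_i, F_j is ≈ (F_i+F_j)/2), and HWE
genotypes. It provides closed-form truth for differentiation, diversity,
richness and AMOVA tests but generates **no LD** — frequencies are
independent across loci.

`wright_fisher_forward()` simulates a diploid random-mating population
(two distinct parents per offspring, so census N is also the
inbreeding/variance Ne) with unlinked chromosomes and optional
within-chromosome linkage, starting from linkage equilibrium at uniform
[0.1, 0.9] frequencies. Twenty generations of drift suffice for unlinked-
locus LD to reach quasi-equilibrium; this is the truth source for Ne
recovery and for checking the geometric decay law against realized
heterozygosity.

`korean_like_scenario()` composes the two ideas: one ancestral frequency
pool, then per-population Wright–Fisher drift — mainland N = 600 with 40
samples, two islands N = 60 with 20 samples each, 4 generations, 29
chromosomes, 29,000 markers at full scale, 0.5% missing calls. The island
census and drift time put expected island–island F_ST near 0.035 and
mainland–island near 0.015–0.02, the regime of recently separated cattle
varieties, while the same small census simultaneously produces strong
background LD (small estimated Ne) and elevated fixed-marker counts. What
a green test on this world establishes is internal consistency — the
estimators recover the generating truth and its orderings. What it does
not establish: real chips have ascertainment bias toward the discovery
breeds, LD from deep pedigree structure rather than a 4-generation
bottleneck, non-uniform marker spacing, and genotyping artifacts
correlated with probe chemistry. Reproducing the original study's point
values (Ne of 97/11/7, A_R of 1.76–1.81, AMOVA 58.3%) additionally
requires the deposited genotypes and the original tool settings, and is
out of reach of a synthetic desk-scale run; the package asserts the
orderings, not the points.

All generator randomness flows through one seeded stream per call that
never touches the caller's RNG state; identical seeds give bit-identical
datasets, and the acceptance script derives all its seeds from the single
`--seed` argument.

## Numerical choices and degenerate inputs

* HW exact test: log-factorial enumeration normalized within the margin;
  ties in the two-sided sum use a 1 + 10⁻¹² relative tolerance.
* Composite r²: pairs with fewer than 2 shared samples, or monomorphic on
  shared samples, are undefined and excluded (never zero-filled).
* Rarefaction: `choose()` exact arithmetic to N = 500, `lchoose`
  difference beyond; C(x, g) = 0 for x < g.
* Ward ties: first minimal pair in cluster-creation order, giving a
  deterministic tree for exchangeable inputs.
* Halving time: integer boundary guarded explicitly against floating-point
  undershoot of the closed-form ceiling.
* Zero-variance situations (all markers equal heterozygosity, identical
  chromosome estimates, H_obs ≡ H_exp) return the defined limits (no
  outliers, SD = 0, t = 0/p = 1) rather than NaN.

## Scale choices in the delivered tests

The acceptance suite runs the Ne-recovery loop at 40 markers per
chromosome × 29 chromosomes × 20 seeds and the island scenario at 8000
markers; both are scale reductions of the full-size defaults (the
estimator path is identical) chosen to keep the complete suite under a
minute of compute for these criteria. The tested quantities — recovery
medians within a factor of 2, orderings of F_ST, fixed counts and Ne —
are stable at these scales, which the seeds in the tests demonstrate.

## Known limitations

Only biallelic, diploid, autosomal data; no temporal or sibship Ne
methods; no monogamy correction in the Ne estimator; single-level AMOVA;
two-level (population) rarefaction without regional hierarchy; Ward/
Euclidean population trees rather than likelihood or coalescent methods;
the pipeline analyses populations jointly for distances/AMOVA/tree and
independently for diversity, Ne and GRM summaries, mirroring per-breed
versus cross-breed reporting.
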