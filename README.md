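# herdvar

Population-genetic characterization of small, recently diverging livestock
populations from SNP-chip genotypes. The motivating setting is an island
model: a large mainland population under artificial selection and one or
more small, isolated varieties drifting away from it. For such populations
the questions that matter are *how different are they already*, *how small
are they effectively*, and *how fast will they lose diversity* — and
`herdvar` answers all three from a single PED/MAP dataset.

## What it computes

* **Quality control** — marker/sample call rate (≥ 95%), per-marker quality
  score (≥ 0.6), marker heterozygosity within 3 SD of the across-marker
  mean, Hardy–Weinberg exact test (cut-off 10⁻¹⁶), removal of
  sex-chromosome/unmapped markers; each step itemized in a report.
* **Diversity** — per-population MAF, observed/expected heterozygosity with
  a paired t-test across loci, fixed-marker counts, F_IS.
* **Differentiation** — Weir–Cockerham variance components (unequal sample
  sizes): multi-locus θ = Σa / Σ(a+b+c) and f = 1 − Σc / Σ(b+c); pairwise
  F_ST with locus-bootstrap significance; Nei's standard distance
  D = −ln( J_XY / √(J_X·J_Y) ); a per-marker F_ST scan with the
  mean + 3 SD outlier threshold.
* **Effective population size** — Burrows composite LD between all
  within-chromosome marker pairs, r² = Δ̂² / ((p(1−p)+D_A)(q(1−q)+D_B)),
  bias-corrected by the Waples sample-size expectation and inverted to Ne
  per chromosome, then averaged across chromosomes (mean ± SD).
* **Forecast** — geometric heterozygosity decay H_t = H₀(1 − 1/(2Ne))ᵗ
  with the halving time.
* **Allelic richness** — Kalinowski rarefaction to a standardized number of
  gene copies g: A_R = Σ_a [1 − C(N−N_a, g)/C(N, g)], plus private allelic
  richness against all other populations.
* **Relationships** — VanRaden genomic relationship matrix
  G = ZZᵀ / (2Σp(1−p)) with per-population diagonal/off-diagonal summaries
  and PCA.
* **AMOVA** — one-level variance partition on squared Euclidean dosage
  distances with permutation significance.
* **Phylogeny** — Ward clustering of population allele-frequency vectors
  with marker-bootstrap clade support, written as Newick.
* **Simulators** — Balding–Nichols divergence and a forward Wright–Fisher
  diploid simulator provide ground truth for every estimator; the test
  suite is built on these closed loops.

## Worked example

Simulate an island scenario (mainland N = 600, two islands N = 60, four
generations of divergence, 5000 markers on 29 chromosomes) and analyse it:

```r
library(herdvar)
sim  <- korean_like_scenario(seed = 1, n_markers = 5000)
gm   <- sim$genotypes
part <- sim$partition

diversity_metrics(gm, part)[, c("population", "h_obs", "n_fixed")]
#>   population h_obs n_fixed
#> 1    island1 0.348     117
#> 2    island2 0.350     176
#> 3   mainland 0.360       6

pairwise_fst(gm, part, n_boot = 100, seed = 1)
#> pairwise distances over 3 populations ( 100 bootstrap replicates )
#> F_ST above the diagonal, Nei's D below:
#>          island1 island2 mainland
#> island1   0.0000  0.0357   0.0178
#> island2   0.0332  0.0000   0.0209
#> mainland  0.0203  0.0219   0.0000

est <- ne_genome(gm, part, "island1")
est
#> Ne = 95.6 +/- 34.0 over 29 chromosomes (0 infinite), random mating

project_heterozygosity(0.348, est$ne, 50)
#> heterozygosity decay: H0 = 0.348, Ne = 95.6, halving in 133 generations
```

The printed numbers reproduce the island-model signature: the two islands
are more differentiated from each other (F_ST 0.036) than either is from
the mainland (≈ 0.018–0.021), they carry far more fixed markers, and their
estimated Ne is a small fraction of the mainland's. With a genuinely tiny
Ne (say 7–11, as reported for endangered island cattle varieties) the same
decay law halves heterozygosity within 10–15 generations.

The full pipeline — QC through Newick tree, one directory of TSV/JSON
outputs — runs as

```r
run_full_analysis(run_config(ped = "data.ped", map = "data.map",
                             pops = "data.pops.tsv", out_dir = "out",
                             seed = 1))
```

or from the shell via `inst/scripts/herdvar run --ped ... --map ...
--pops ... --out out/`.

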