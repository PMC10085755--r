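# mutsfs

Mutation-subtype-resolved analysis of the site frequency spectrum.

## The problem

AFS-based population genetics — Tajima's D, demographic inference from the
genome-wide spectrum, window-based scans — treats segregating sites as
exchangeable. They are not: a site's mutation rate depends strongly on its
flanking bases (CpG transitions run ~an order of magnitude hot), fast
motifs recur (two independent singletons at one site surface as a single
doubleton), and GC-biased gene conversion preferentially transmits G/C
alleles, skewing weak-to-strong variants toward intermediate frequencies.
`mutsfs` is for population geneticists who want to measure how much this
heterogeneity distorts spectrum-based inference — and for anyone who needs
the machinery to do the measuring on their own cohort.

The package partitions biallelic SNVs into the 96 strand-collapsed 3-mer
**mutation subtypes** (central base change, ancestral allele collapsed to
A or C, plus both flanking bases: 4 x 6 x 4 = 96), builds one unfolded
spectrum per subtype, and provides:

* **Spectrum statistics** — theta_W, theta_pi, Tajima's D, and the
  singleton/doubleton-free statistic

  D_-2 = (theta_pi-2 − theta_W-2) / sqrt(Var(theta_pi-2 − theta_W-2)),

  where theta_pi-2 = n(n−1)/[(n−2)(n−3)] · C(n,2)^−1 ·
  [Σ η_i i(n−i) − η_1(n−1) − 2η_2(n−2)] and
  theta_W-2 = (S − η_1 − η_2)/(h_n − 3/2) stay unbiased for theta after
  removing the frequency classes recurrent mutation distorts most. The
  variance is analytic, from the neutral-coalescent second moments of the
  spectrum (Fu's sigma coefficients), so D_-2 reads the gene-conversion
  signal without the mutation-rate signal.
* **Mutation rates** — singleton-density relative rates per subtype and
  absolute per-site per-generation rates via the 60
  de-novo-mutations-per-generation normalization
  (mu_s = rel_s · 60 / Σ_t M_t rel_t, so Σ M_s mu_s = 60 exactly).
* **Demographic inference** — expected unfolded spectra under exponential
  growth and three-epoch histories from a deterministic lineage-count
  integration, Poisson composite-likelihood fits with profiled theta,
  multi-start perturbation, and bootstrap standard errors.
* **Regional analysis** — 100 kb windows over a masked genome, observed
  vs composition-weighted expected local statistics, subtype-abundance
  flags, quantile stratification, and a chromosome-clustered exchangeable
  GEE of observed on expected statistics with recombination and GC
  covariates.
* **A synthetic-genome generator** — FASTA/VCF/BED/tracks plus a complete
  truth manifest, with per-subtype rate heterogeneity, recurrent mutation,
  optional gBGC-like transmission bias, growth or bottleneck demography,
  and planted hot windows, so every step above can be validated against
  known ground truth.

## Worked example

The `analysis/` scripts run the full study on a synthetic genome
(`Rscript analysis/01_simulate_genome.R` through `06_regional.R`; outputs
land under `results/`). A condensed session:

```r
library(mutsfs)

# a synthetic genome: 8 x 1 Mb, n = 100 haploids, growth (T0 = 0.1,
# lambda = 50), CpG transitions 10x hot
cfg <- genome_config(contig_lengths = setNames(rep(1e6, 8), paste0("chr", 1:8)))
g   <- simulate_genome(cfg, "results/genome", seed = 20260925)
cl  <- classify_vcf("results/genome/variants.vcf", "results/genome/ref.fa")
sp  <- build_spectra(cl$variants, cfg$n)
st  <- subtype_statistics(sp)
range(st$d, na.rm = TRUE)
#> [1] -1.305 -0.910
```

One shared demography generated every subtype, yet Tajima's D spans
[−1.305, −0.910] across the 96 subtype spectra — purely mutational
heterogeneity. The recurrent-mutation signature is the negative
correlation between the singleton/doubleton ratio and the estimated
mutation rate (`analysis/03`):

```
eta1/eta2 vs mu_abs: Pearson rho = -0.319 (p = 0.0015)
DNM conservation: sum(motifs x mu) = 60.000000000
```

Fitting the growth model to single-subtype spectra (`analysis/05`) shows
how subtype choice confounds demographic inference — the true growth
factor is 50 for every subtype:

```
 subtype     S estimate     se    Ne
 A[C>T]G 33464    31.89  2.171 370.8   # CpG->TpG: recurrence hides growth
 A[A>G]A 10979    95.39 24.543 315.3
 A[C>T]A  7718    20.93  3.563 342.9
spread of inferred lambda across subtypes: 4.6-fold
```

The null distribution of D_-2 (`analysis/04`, 10,000 neutral replicates at
n = 100) is asymmetric with a heavier upper tail — calibrate against the
simulated null, not a normal:

```
 theta  reps  d2_mean d2_sd d2_skew d2_q025 d2_q975
   240 10000  -0.1064 0.868   0.157   -1.72    1.64
  2400 10000  -0.0901 0.881   0.158   -1.70    1.70
```

And the regional analysis (`analysis/06`) recovers the composition-null:
windows' observed statistics match their composition-weighted
expectations on average (`mean(observed − expected)` for D: 0.001 across
80 windows).

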