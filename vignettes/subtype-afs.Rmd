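---
title: "Mutation-subtype heterogeneity in the site frequency spectrum: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutation-subtype heterogeneity in the site frequency spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutsfs)
```

## The problem

The unfolded allele frequency spectrum (AFS) of a sample of $n$ haploid
genomes is the vector $(\eta_1, \dots, \eta_{n-1})$, where $\eta_i$ counts
segregating sites at which exactly $i$ copies carry the derived allele.
AFS-based inference — Tajima's D, demographic fitting, selection scans —
treats all segregating sites as exchangeable draws from one mutational
process. They are not. A site's mutation rate depends strongly on its
immediate sequence context (CpG transitions are roughly an order of
magnitude faster than the genomic average), fast-mutating sites violate the
infinite-sites assumption through recurrent mutation (two independent
singleton mutations at one site are observed as a single doubleton), and
GC-biased gene conversion (gBGC) preferentially transmits G/C alleles in
A/T–G/C heterozygotes, pushing weak-to-strong variants toward intermediate
frequencies.

`mutsfs` makes this heterogeneity measurable. It partitions biallelic SNVs
into the 96 strand-collapsed 3-mer **mutation subtypes** — the central
base-pair change plus its 5' and 3' flanking bases, with the ancestral
allele collapsed to A or C (4 × 6 × 4 = 96 classes) — builds one unfolded
spectrum per subtype, and provides the statistics, demographic-fitting and
regional-regression machinery to quantify how much the subtype-specific
spectra differ and what those differences do to inference. Because the
kind of deeply sequenced cohort this analysis needs is rarely
redistributable, the package also ships a synthetic-genome generator with
complete ground truth, and every claim the package makes is validated
against it.

## Subtype classification

A variant is classified from its VCF record and the reference 3-mer around
it. The ancestral allele is read from `INFO/AA` (upper case = high
confidence; lower-case calls are skipped by default because confidence
filtering conventions vary between annotation pipelines). Flanking bases
are always taken from the reference sequence; only the central base is
polarized. When the ancestral allele equals ALT rather than REF, the
derived count is $n - \mathrm{AC}$, so the two polarizations of one record
always sum to $n$. Records that are not biallelic SNVs, lack a usable
ancestral allele, disagree with both REF and ALT, sit in a non-ACGT or
truncated context, or are monomorphic after polarization are skipped with
an enumerated reason and counted in an audit table; a REF allele that
contradicts the reference FASTA is treated as a data inconsistency and
raises an error. gBGC direction follows the canonical-strand rule
(WS: A→C/G; SW: C→A/T; indifferent: A→T, C→G; a 32/32/32 partition), and
CpG status means a canonical ancestral C with a 3' G (12 subtypes, 4 of
them the hypermutable CpG→TpG transitions).

## Spectrum statistics

For one spectrum with $S = \sum_i \eta_i$ segregating sites,
$h_n = \sum_{i=1}^{n-1} 1/i$:

* Watterson: $\hat\theta_W = S / h_n$;
  pairwise: $\hat\theta_\pi = \binom{n}{2}^{-1}\sum_i \eta_i\, i(n-i)$.
* Tajima's D standardizes $\hat\theta_\pi - \hat\theta_W$ by the classical
  $\widehat{\mathrm{Var}} = e_1 S + e_2 S(S-1)$.
* The **D$_{-2}$ statistic** removes singletons and doubletons — the
  classes recurrent mutation distorts most — and reweights both estimators
  so they stay unbiased for $\theta$ under the neutral constant-size
  coalescent:
  $$\hat\theta_{\pi,-2} = \frac{n(n-1)}{(n-2)(n-3)}\binom{n}{2}^{-1}
  \Big[\sum_i \eta_i\, i(n-i) - \eta_1(n-1) - 2\eta_2(n-2)\Big], \qquad
  \hat\theta_{W,-2} = \frac{S - \eta_1 - \eta_2}{h_n - 3/2}.$$
  Both depend only on $\eta_3,\dots,\eta_{n-1}$, so D$_{-2}$ reads the gBGC
  signal (which lives at intermediate frequencies) without the
  recurrent-mutation signal (which lives in $\eta_1,\eta_2$).

The variance of $\hat\theta_{\pi,-2} - \hat\theta_{W,-2}$ is computed
analytically. Writing the numerator as $\sum_{i\ge3} c_i \eta_i$, the
neutral single-locus coalescent gives
$\mathrm{Var} = \theta \sum_i c_i^2/i + \theta^2 \sum_{ij} c_i c_j
\sigma_{ij}$, with $\sigma_{ij}$ the second-order covariance coefficients
of the spectrum entries (Fu 1995). The implementation validates
$\sigma$ against two independent checks: the row-sum identity
$\sum_{ij}\sigma_{ij} = \sum_i 1/i^2$ (which recovers the classical
variance of $S$) and Monte-Carlo covariances from simulated single-locus
spectra. For the plug-ins we use the singleton/doubleton-free quantities,
$\hat\theta = S_{-2}/(h_n - 3/2)$ and
$\widehat{\theta^2} = S_{-2}(S_{-2}-1)\big/\big[(h_n-3/2)^2 +
\sum_{i,j\ge3}\sigma_{ij}\big]$ with $S_{-2} = S - \eta_1 - \eta_2$; the
second is unbiased for $\theta^2$ because
$\sum_{i\ge3} 1/i = h_n - 3/2$ exactly. This choice makes D$_{-2}$ a
function of $\eta_3,\dots,\eta_{n-1}$ *only* — spiking any number of
singletons or doubletons into a spectrum leaves it bit-identical, which is
the property the statistic exists for. Other plug-ins (e.g. the full-$S$
Watterson estimate) would be equally defensible estimators but would leak
$\eta_1,\eta_2$ back into the value.

Two behaviours of D-type statistics are worth knowing before reading
results. First, they are ratios, and their null means are not zero: at the
locus scales this package simulates (e.g. $n = 100$, $\theta$ in the
hundreds), both D and D$_{-2}$ have null means near $-0.1$. Second, the
D$_{-2}$ null is asymmetric with a heavier upper tail (positive skewness in
the null simulations), so symmetric significance thresholds misstate tail
probabilities. `simulate_null_d()` exists so users can calibrate against
the simulated null instead of a normal reference.

Group contrasts (e.g. WS vs non-WS subtypes) use Welch's unequal-variance
t-test — the plain "two-sample t-test" leaves the variance assumption
unstated, and subtype groups have no reason to share variances.
Correlations default to Pearson with Spearman available, since the field
reports both without always saying which.

## Demographic inference

Two single-population families are supported, in diffusion time units of
$2N_e$ generations with sizes relative to the ancestral $N_e$:

* **growth**: constant ancestral size until time $T_0$ ago, then
  exponential change to $\lambda N_e$ at present;
* **three-epoch**: ancestral size, a bottleneck of depth
  $\lambda_1 \le 1$ lasting $T_1$, recovery at $\lambda_2$ for the last
  $T_2$.

The expected spectrum is
$\xi_i = \tfrac{\theta}{2}\sum_{k=2}^{n} k\,E[T_k]\,P(i\,|\,k)$ with
$P(i|k) = \binom{n-i-1}{k-2}/\binom{n-1}{k-1}$, and $E[T_k]$ the expected
time the sample spends with $k$ ancestral lineages. $E[T_k]$ is computed
by integrating the lineage-count pure-death process on the standard
coalescent timescale $\tau = \Lambda(t) = \int_0^t \nu(s)^{-1}ds$ (RK4,
step bounded by $0.1/\binom{k_{\max}}{2}$ and an absolute cap of
$2\times10^{-3}$, states dropped below $10^{-22}$, segments split exactly
at epoch boundaries so no integration step straddles a discontinuity in
$\nu$), with the final constant ancestral epoch handled analytically from
the survival probabilities at its boundary:
$E[\Delta T_k] = P(A \ge k)\,/\binom{k}{2}$. Under constant size the
solver returns $\theta/i$ to machine precision, and under growth and
three-epoch histories it matches the mean spectrum of $2\times10^5$
simulated genealogies within Monte-Carlo error. The lineage-count
integration is capped at $n = 200$ by default; the package's experiments
use $n \le 100$, scaled down from the thousands of haploids a biobank
cohort provides.

Fitting maximizes the Poisson random-field composite likelihood
$\sum_i [\eta_i \ln \xi_i - \xi_i - \ln \eta_i!]$. $\theta$ is profiled
out analytically (at the Poisson MLE it scales the unit-$\theta$ shape so
the totals match), which removes one dimension from the search. The
remaining shape parameters are optimized in shifted-log coordinates
$u = \log(\mathrm{par} + 10^{-3})$ — the surface spans orders of magnitude
in $\lambda$ and is badly conditioned on the raw scale — by Nelder-Mead
followed by a bounded quasi-Newton polish, keeping whichever is better.
Box bounds and starting values follow the established convention for these
models: growth $T_0 \in [0,10]$, $\lambda \in [0,750]$, starts $(3, 150)$;
three-epoch $\lambda_1 \in [0,1]$ (a bottleneck is enforced),
$\lambda_2 \in [0,150]$, $T_1, T_2 \in [0,10]$. Three-epoch starting
values $(T_1, T_2, \lambda_1, \lambda_2) = (0.1, 0.5, 0.3, 10)$ are the
package's own choice of a moderate bottleneck-and-recovery start. Each of
10 restarts (default) perturbs the starts by a uniform multiplicative
log-factor up to 2; ties go to the first-found optimum, and estimates
within $10^{-8}$ of a bound are flagged. On noise-free expected-count
data the fits recover generating parameters to well under 1% relative
error; fitting constant-size data with the growth family legitimately
returns either $\lambda \approx 1$ or $T_0 \approx 0$ (the families are
nested and the degeneracy is flagged rather than hidden).

Natural scales derive as $N_e = \theta/(4\mu L)$ — $\theta$ is defined
sequence-total, $4N_e\mu L$, so $\mu$ is the per-site rate and $L$ the
mutational target size — and times multiply by $2N_e$ generations. For
the three-epoch family the fit reports $T_1$, $T_2$ *and* their sum, since
"time since the population first changed" is the sum and readers expect
all three.

Uncertainty comes from refitting $B = 100$ multinomial bootstrap
resamples of the spectrum (sites resampled within the spectrum at fixed
$S$), warm-started at the fitted optimum; the refits are
indistinguishable from cold restarts on this surface (checked directly)
and two orders of magnitude faster. Parameter intervals use the
percentile method. Fixed-$S$ resampling deliberately conditions on the
observed number of segregating sites; for the shape parameters this
matches the Poisson sampling variance closely (verified by simulation),
but it means $\theta$'s interval excludes the (tiny, $\sqrt{S}/S$)
contribution of $S$ itself. The established route to these fits is a
diffusion-equation AFS solver with a Godambe-matrix normal approximation
for uncertainty; this package deliberately substitutes the deterministic
coalescent-expectation solver plus an explicit bootstrap — no external
solver dependency, and the uncertainty is measured rather than
approximated.

## Mutation rates

Relative rates are singleton densities: singletons per strand-collapsed
motif occurrence, normalized to mean 1 (any positive scale cancels).
Absolute rates distribute a fixed number of de novo mutations per
generation across subtypes,
$\mu_s = \mathrm{rel}_s \cdot \mathrm{DNM} / \sum_t M_t\,\mathrm{rel}_t$
with DNM = 60 (the rate human trio studies observe), so
$\sum_s M_s \mu_s = 60$ holds exactly by construction — the package
asserts it to $10^{-9}$ relative. Low/high rate classes split at the
median, "high" meaning strictly above it (ties therefore fall to "low";
with 96 distinct rates the split is exactly 48/48). Motif counts cover
whatever sequence the user supplies; whether to count the whole genome or
only callable regions is the user's masking decision, not the package's.

## Regional analysis

Windows tile each contig from coordinate 0 in 100 kb steps (0-based
half-open; a VCF position $p$ lives at coordinate $p-1$). Variants are
first restricted to a BED mask — intergenic regions, where selection is
weakest — and short terminal windows plus windows with fewer than 10
segregating sites are excluded (D is meaningless on a handful of sites;
both thresholds are configurable). A subtype is "abundant" in a window
when the window ranks in the top `ceiling(0.1 * W)` of windows by that
subtype's share of local segregating sites, ties broken deterministically
by genomic order — so a subtype concentrated in one window flags exactly
that window, and a perfectly uniform subtype flags exactly
`ceiling(0.1 * W)`. The expected value of a local statistic is the
count-weighted mean of the 96 genome-wide per-subtype values; for
proportion statistics this equality is an identity of the pooled counts,
while for Tajima's D it is the study's working approximation — exact in
the composition-only limit as window size grows, and verified within
Monte-Carlo error at the simulated window sizes. Quantile summaries
support both 10 and 20 quantiles (both granularities appear in practice)
and stratified means sum exactly to the unstratified mean because the
strata partition the 96 subtypes.

The observed-on-expected regression uses a Gaussian GEE with an
exchangeable working correlation per chromosome: iterated GLS with a
moment estimator of $\rho$ from standardized residuals (scale with a
degrees-of-freedom correction), sandwich covariance clustered by
chromosome. The implementation reproduces an established GEE
implementation to $10^{-6}$ on a shared fixture, and collapses exactly to
OLS when $\rho$ is fixed at 0. Confidence intervals use $t_{G-1}$
critical values ($G$ = clusters): with ~10–22 chromosomes the plain
normal-quantile sandwich interval is known to run anticonservative, and
the $t$ correction is the standard remedy.

## The synthetic genome

`simulate_genome()` produces FASTA + VCF + BED mask + recombination/GC
tracks + a JSON/TSV truth manifest, reproducible byte-for-byte from
(config, seed). Defaults — the package's study conditions — are: 8
chromosome-like contigs of 400 kb ($100$ kb windows, enough windows for
decile stratification and enough contigs for clustered SEs), $n = 100$
haploids, recent exponential growth $(T_0, \lambda) = (0.1, 50)$ as a
desk-scale stand-in for recent human growth, and per-site scaled mutation
rates $\theta_{\text{site}} = 0.004 \times \mathrm{rel}_s$ with a
deterministic rate profile: CpG transitions 10×, other CpG subtypes 2×,
non-CpG transitions 1.5×, transversions 1×, plus a small per-subtype
modulation so all 96 rates are distinct. The 10× CpG factor makes
recurrent mutation visible at $n = 100$ (at biobank sample sizes the same
effect appears at lower rates; the distortion scales with $n\theta$).
Null-distribution work uses the locus-scale thetas these defaults imply:
$\theta \approx 240$ for a relative-rate-1 subtype and $\theta \approx
2400$ for a CpG transition.

Allele counts are drawn per subtype from finite-sites coalescent
simulations (per-site genealogies; a leaf is derived iff a mutation lies
on its root path — union of carriers, no back mutation, since reversals
are rarer by the same rate ratio again). gBGC, when enabled, replaces the
WS subtypes' sampling distribution with one from a forward Wright–Fisher
simulation under genic transmission bias $b$ (population-scaled
$B = 4Nb$): sojourn times of new-mutation trajectories estimate the
stationary frequency distribution, binomial sampling conditions it on
segregating in $n$. At $b = 0$ this reproduces the neutral $1/i$ sampling
law, and the simulated bias shifts Tajima's D in the expected directions.
Variants are planted only at reference positions whose 3-mer context
matches the subtype (on either strand), so classification round-trips the
manifest exactly; records are emitted ancestral-as-REF (the ALT-ancestral
polarization path is exercised by targeted classifier tests instead).

What the generator does *not* emulate, and what passing tests therefore do
not show: linkage (sites are independent, so genome-wide variances of
summary statistics are understated relative to real LD-structured data),
sequencing error and coverage-dependent dropout (low-coverage cohorts
undercall exactly the rare variants these statistics lean on),
ancestral-allele misassignment, and selection. Results on real data
inherit all four.

## Problem sizes and numerical guards

The validation suite runs at: 10,000 neutral spectra for estimator
unbiasedness ($n=20$, $\theta=10$); 50,000 spectra per sample size for the
D$_{-2}$ variance oracle ($n \in \{10, 50, 100\}$); 10,000 replicates per
theta for the null distribution; 200,000 genealogies per demography for
the expected-AFS oracle; 50 replicates × 100 bootstrap refits for
coverage; 200 replicates for GEE coverage. These sizes keep every
Monte-Carlo standard error small enough for 3-SE assertions while the
whole suite stays desk-scale. Degenerate-input policy: variances below
$10^{-12}$ are errors, not zeros; empty spectra cannot be bootstrapped or
summarized; fits at box bounds are flagged; bootstrap refit failure above
20% is an error rather than a silent SE from the survivors.
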