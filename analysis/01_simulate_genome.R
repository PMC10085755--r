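#!/usr/bin/env Rscript
# Generate the synthetic study genome: a reference with planted variants in
# 96 mutation subtypes, recent exponential growth shaping allele counts,
# hypermutable CpG transitions, hot windows of skewed subtype composition,
# an intergenic mask and covariate tracks.  Ground truth is recorded
# alongside so every later step can be scored.

suppressPackageStartupMessages(library(mutsfs))

outdir <- "results/genome"
# package defaults except a larger genome (8 x 1 Mb = 80 windows of
# 100 kb), which gives the regional regression something to chew on
cfg <- genome_config(contig_lengths = setNames(rep(1e6, 8),
                                               paste0("chr", 1:8)))
g <- simulate_genome(cfg, outdir, seed = 20260925)

cat("contigs:", paste(names(cfg$contig_lengths), cfg$contig_lengths,
                      collapse = ", "), "\n")
cat("haploid sample size n =", cfg$n, "\n")
cat("planted variants:", g$truth$n_variants, "\n")
cat("hot windows:\n")
print(g$truth$hot_windows)
cat("outputs under", outdir, "\n")
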