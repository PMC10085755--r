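#!/usr/bin/env Rscript
# Regional analysis: tile the masked (intergenic) genome into 100 kb
# windows, compute observed local AFS statistics and their
# composition-weighted expectations, flag subtype abundance, stratify by
# Tajima's D quantiles, and regress observed on expected statistics with
# recombination-rate and GC covariates under a chromosome-clustered GEE.

suppressPackageStartupMessages(library(mutsfs))

truth <- jsonlite::read_json("results/genome/truth.json")
cl <- read.table("results/classified.tsv", header = TRUE, sep = "\t")
mask <- read_bed("results/genome/mask.bed")
recomb <- read_track("results/genome/recomb.tsv")
gc <- read_track("results/genome/gc.tsv")
gw_stats <- read.table("results/subtype_stats.tsv", header = TRUE,
                       sep = "\t")
contigs <- unlist(truth$contig_lengths)

rw <- make_windows(cl, contigs, mask = mask,
                   window_size = truth$window_size)
win <- window_statistics(rw, gw_stats)
ab <- abundance_flags(rw)
win$n_abundant <- ab$n_abundant
key <- paste(win$chrom, win$start)
win$recomb <- recomb$value[match(key, paste(recomb$chrom, recomb$start))]
win$gc <- gc$value[match(key, paste(gc$chrom, gc$start))]
write.table(win, "results/windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(nrow(win), "windows retained after masking;",
    "mean S per window:", round(mean(win$S)), "\n")
cat(sprintf("observed D: mean %.3f (sd %.3f); expected D: mean %.3f (sd %.3f)\n",
            mean(win$d), sd(win$d), mean(win$d_exp), sd(win$d_exp)))
cat(sprintf("mean(observed - expected): D %.3f, p1 %.4f\n",
            mean(win$d - win$d_exp), mean(win$p1 - win$p1_exp)))

# abundance by D quantile, stratified by gBGC class and rate class
st <- enumerate_subtypes()
rates <- read.table("results/rates.tsv", header = TRUE, sep = "\t")
qs <- quantile_summary(win$d, ab$flags, n_quantiles = 10, strata = st$gbgc)
qs_rate <- quantile_summary(win$d, ab$flags, n_quantiles = 10,
                            strata = rates$rate_class)
write.table(qs, "results/quantiles_gbgc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(qs_rate, "results/quantiles_rate.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nmean n_abundant by D quantile (1 = lowest D):\n")
print(round(qs$mean_n_abundant, 2))

# GEE of observed on expected statistic + covariates, clustered by contig
gee_rows <- list()
for (stat in c("d", "p1", "p2", "p3")) {
  f <- gee_fit(win[[stat]],
               cbind(exp = win[[paste0(stat, "_exp")]],
                     rr = win$recomb, gc = win$gc),
               cluster = win$chrom)
  ci <- gee_confint(f)
  gee_rows[[stat]] <- data.frame(
    statistic = stat, term = names(f$coefficients),
    estimate = unname(f$coefficients), robust_se = unname(f$robust_se),
    lower = unname(ci[, "lower"]), upper = unname(ci[, "upper"]),
    rho = f$rho)
}
gee_tab <- do.call(rbind, gee_rows)
write.table(gee_tab, "results/gee.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nGEE slope on the expected statistic (beta_exp):\n")
print(gee_tab[gee_tab$term == "exp",
              c("statistic", "estimate", "robust_se", "lower", "upper")],
      digits = 3, row.names = FALSE)
cat("\nnote: the expected statistics vary little across windows (sd",
    sprintf("%.4f", sd(win$d_exp)),
    "for D),\nso at", nrow(win), "windows the slope is weakly identified",
    "- wide intervals here are\nthe honest answer, not a defect; precision",
    "at this composition variance\nrequires orders of magnitude more",
    "windows.\n")
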