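#!/usr/bin/env Rscript
# Null behaviour of D and D-2: simulate neutral constant-size spectra at
# the locus-scale thetas of two representative subtypes (a relative-rate-1
# subtype and a tenfold-faster CpG transition) and summarize both
# statistics' distributions.

suppressPackageStartupMessages(library(mutsfs))

skew <- function(x) {
  x <- x[!is.na(x)]
  mean((x - mean(x))^3) / sd(x)^3
}

rows <- list()
for (theta in c(240, 2400)) {
  nd <- simulate_null_d(theta, n = 100, reps = 10000, seed = 400 + theta)
  rows[[length(rows) + 1]] <- data.frame(
    theta = theta, reps = nrow(nd),
    d_mean = mean(nd$d, na.rm = TRUE), d_skew = skew(nd$d),
    d2_mean = mean(nd$d_minus2, na.rm = TRUE),
    d2_sd = sd(nd$d_minus2, na.rm = TRUE),
    d2_skew = skew(nd$d_minus2),
    d2_q025 = quantile(nd$d_minus2, 0.025, na.rm = TRUE),
    d2_q975 = quantile(nd$d_minus2, 0.975, na.rm = TRUE))
  write.table(nd, sprintf("results/null_d_theta%d.tsv", theta),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
summ <- do.call(rbind, rows)
write.table(summ, "results/null_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(summ, digits = 3, row.names = FALSE)
cat("\nPositive d2_skew = the null is asymmetric with a heavier upper",
    "tail;\nextreme positive D-2 values are therefore more probable under",
    "neutrality\nthan a symmetric reference would suggest.\n")
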