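#!/usr/bin/env Rscript
# Polarize every VCF record by its ancestral allele and assign the
# strand-collapsed 3-mer mutation subtype; write the classified table and
# the skip audit.

suppressPackageStartupMessages(library(mutsfs))

cl <- classify_vcf("results/genome/variants.vcf", "results/genome/ref.fa")
write_classified(cl, "results/classified.tsv", "results/skips.tsv")

cat("classified", nrow(cl$variants), "variants\n")
cat("by gBGC class:\n")
print(table(cl$variants$gbgc))
cat("skips:\n")
print(cl$skips[cl$skips$count > 0, ])
if (sum(cl$skips$count) == 0) cat("  (none)\n")
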