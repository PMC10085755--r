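# shared fixtures built in code

# write a tiny FASTA + VCF pair; variants is a data.frame with
# chrom, pos, ref, alt, aa, ac, an (alt may contain commas)
write_mini_vcf <- function(dir, seqs, variants) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "ref.fa")
  dna <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(dna, fa)
  vcf <- file.path(dir, "test.vcf")
  con <- file(vcf, "w")
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", names(seqs), ",length=",
                      nchar(seqs), ">"),
               "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
               "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
               "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0) {
    writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                     variants$alt, ".", "PASS",
                     paste0("AA=", variants$aa, ";AC=", variants$ac,
                            ";AN=", variants$an), sep = "\t"), con)
  }
  close(con)
  list(fasta = fa, vcf = vcf)
}

# sample skewness
skewness <- function(x) {
  x <- x[!is.na(x)]
  mean((x - mean(x))^3) / sd(x)^3
}

# a small deterministic classified-variant table spread over windows
toy_variants <- function(n = 20, chrom = "chr1", positions, subtypes,
                         counts) {
  data.frame(chrom = chrom, pos = positions, subtype = subtypes,
             gbgc = NA, cpg = NA, derived_count = counts, sample_n = n,
             stringsAsFactors = FALSE)
}
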