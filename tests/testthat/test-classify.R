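test_that("single-record classification polarizes and canonicalizes", {
  # ancestral == REF: CpG->TpG class, derived count = AC
  r <- classify_variant("chr1", 10, "C", "T", "C", ac = 12, an = 100,
                        context = "ACG")
  expect_equal(r$subtype, "A[C>T]G")
  expect_true(r$cpg)
  expect_equal(r$derived_count, 12)

  # ancestral == ALT: derived allele is REF, count flips to n - AC,
  # flanks stay as read from the reference, centre is polarized
  r2 <- classify_variant("chr1", 10, "C", "T", "T", ac = 12, an = 100,
                         context = "ACG")
  expect_equal(r2$derived_count, 88)
  expect_equal(r2$subtype, "C[A>G]T")  # A[T>C]G reverse-complemented

  # polarization conservation for the same record
  expect_equal(r$derived_count + r2$derived_count, 100)
})

test_that("records violating preconditions get enumerated skip reasons", {
  expect_equal(classify_variant("c", 5, "C", "CT", "C", 3, 10, "ACG"),
               "not_snv")
  expect_equal(classify_variant("c", 5, "C", c("T", "A"), "C", 3, 10, "ACG"),
               "multiallelic")
  expect_equal(classify_variant("c", 5, "C", "T", ".", 3, 10, "ACG"),
               "no_ancestral")
  expect_equal(classify_variant("c", 5, "C", "T", "c", 3, 10, "ACG"),
               "low_conf_ancestral")
  expect_equal(classify_variant("c", 5, "C", "T", "c", 3, 10, "ACG",
                                min_aa_confidence = "any")$subtype,
               "A[C>T]G")
  expect_equal(classify_variant("c", 5, "C", "T", "G", 3, 10, "ACG"),
               "aa_mismatch")
  expect_equal(classify_variant("c", 5, "C", "T", "C", 3, 10, "NCG"),
               "bad_context")
  expect_equal(classify_variant("c", 5, "C", "T", "C", 10, 10, "ACG"),
               "monomorphic")
  expect_error(classify_variant("c", 5, "C", "T", "C", 3, 10, "AAG"),
               "disagrees")
})

test_that("VCF classification matches the per-record path and counts skips", {
  seqs <- c(chr1 = "TTACGTTAGCATTTT")
  v <- data.frame(
    chrom = "chr1",
    pos   = c(4, 8, 9, 12, 2, 1),
    ref   = c("C", "A", "G", "T", "T", "T"),
    alt   = c("T", "G", "C", "A", "T,A", "A"),
    aa    = c("C", "G", "G", ".", "T", "T"),
    ac    = c(3, 4, 5, 2, 1, 1),
    an    = 10)
  p <- write_mini_vcf(tempfile("vcf"), seqs, v)
  out <- classify_vcf(p$vcf, p$fasta)
  expect_equal(nrow(out$variants), 3)
  # pos 4: context ACG, C>T with AA=C
  expect_equal(out$variants$subtype[1], "A[C>T]G")
  expect_equal(out$variants$derived_count[1], 3)
  # pos 8: context TAG, AA=ALT(G) so derived = REF A polarized: T[G>A]C?
  # ancestral G at centre, derived A; rc -> C>T with flipped flanks
  expect_equal(out$variants$subtype[2],
               canonicalize("G", "A", "T", "G")$subtype)
  expect_equal(out$variants$derived_count[2], 10 - 4)
  # pos 9: GCA context around G; AA=G==REF, derived C
  expect_equal(out$variants$subtype[3],
               canonicalize("G", "C", "A", "C")$subtype)
  sk <- setNames(out$skips$count, out$skips$reason)
  expect_equal(unname(sk["no_ancestral"]), 1)
  expect_equal(unname(sk["multiallelic"]), 1)
  expect_equal(unname(sk["bad_context"]), 1)  # pos 1 has no 5' flank
})

test_that("REF disagreeing with the FASTA is a data inconsistency", {
  seqs <- c(chr1 = "AAAAAAA")
  v <- data.frame(chrom = "chr1", pos = 4, ref = "C", alt = "T",
                  aa = "C", ac = 2, an = 10)
  p <- write_mini_vcf(tempfile("vcf"), seqs, v)
  expect_error(classify_vcf(p$vcf, p$fasta), "disagrees")
})

test_that("classification round-trips the synthetic genome exactly", {
  cfg <- genome_config(contig_lengths = c(chrA = 1.2e5), n = 40,
                       window_size = 4e4, hot_windows = 1,
                       qdist_sites = 300)
  g <- simulate_genome(cfg, tempfile("genome"), seed = 5)
  cl <- classify_vcf(g$paths$vcf, g$paths$fasta)
  expect_equal(sum(cl$skips$count), 0)
  rw <- make_windows(cl$variants, cfg$contig_lengths,
                     window_size = cfg$window_size, min_s = 0,
                     drop_short = FALSE)
  expect_equal(unname(rw$counts), unname(g$planted + 0))
})
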