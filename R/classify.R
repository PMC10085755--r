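SKIP_REASONS <- c("not_snv", "multiallelic", "no_ancestral",
                  "low_conf_ancestral", "aa_mismatch", "bad_context",
                  "monomorphic")

#' Classify one biallelic SNV into a mutation subtype
#'
#' Polarizes the record by its ancestral-allele annotation and assigns the
#' strand-collapsed 3-mer subtype.  Flanking bases are always taken from the
#' reference context as supplied; only the central base is polarized.  The
#' derived allele count is the ALT count when the ancestral allele equals
#' REF, and `n - AC` when it equals ALT.
#'
#' @param chrom,pos contig and 1-based position (VCF convention).
#' @param ref,alt REF and ALT alleles; `alt` may have length > 1
#'   (multiallelic records are skipped).
#' @param aa ancestral-allele annotation (INFO/AA); lower case is treated as
#'   low confidence.
#' @param ac,an ALT allele count and total called alleles; `an` is the
#'   haploid sample size n.
#' @param context reference 3-mer centred on `pos`.
#' @param min_aa_confidence `"high"` (default) skips lower-case AA calls;
#'   `"any"` accepts them (upper-cased).
#' @return A one-row data.frame (`chrom`, `pos`, `subtype`, `gbgc`, `cpg`,
#'   `derived_count`, `sample_n`) on success, otherwise a skip reason
#'   (character scalar, one of `r paste(SKIP_REASONS, collapse = ", ")`).
#'   A REF allele disagreeing with the centre of `context` is a data
#'   inconsistency and raises an error.
#' @export
classify_variant <- function(chrom, pos, ref, alt, aa, ac, an, context,
                             min_aa_confidence = c("high", "any")) {
  min_aa_confidence <- match.arg(min_aa_confidence)
  if (length(alt) > 1) return("multiallelic")
  if (nchar(ref) != 1 || nchar(alt) != 1) return("not_snv")
  if (!ref %in% BASES || !alt %in% BASES) return("not_snv")
  if (is.null(aa) || is.na(aa) || !nzchar(aa) || aa %in% c(".", "-", "N"))
    return("no_ancestral")
  if (aa %in% c("a", "c", "g", "t")) {
    if (min_aa_confidence == "high") return("low_conf_ancestral")
    aa <- toupper(aa)
  }
  if (!aa %in% BASES) return("no_ancestral")
  if (nchar(context) != 3) return("bad_context")
  ctx <- strsplit(context, "")[[1]]
  if (ctx[2] != ref) {
    stop("REF allele disagrees with reference context at ", chrom, ":", pos)
  }
  if (any(!ctx %in% BASES)) return("bad_context")
  if (aa == ref) {
    derived <- alt
    derived_count <- ac
  } else if (aa == alt) {
    derived <- ref
    derived_count <- an - ac
  } else {
    return("aa_mismatch")
  }
  if (derived_count < 1 || derived_count > an - 1) return("monomorphic")
  key <- canonicalize(aa, derived, ctx[1], ctx[3])
  data.frame(chrom = chrom, pos = pos, subtype = key$subtype,
             gbgc = key$gbgc, cpg = key$cpg,
             derived_count = derived_count, sample_n = an,
             stringsAsFactors = FALSE)
}

#' Classify all variants in a VCF against a reference FASTA
#'
#' Reads biallelic SNVs with AC/AN and an INFO/AA ancestral-allele
#' annotation, extracts the reference 3-mer around each site, and runs
#' [classify_variant()] on every record.  Records at contig edges (no
#' flanking base) are skipped with reason `bad_context`.
#'
#' @param vcf_path path to a VCF 4.x file (plain or bgzipped).
#' @param fasta_path path to the reference FASTA.
#' @param min_aa_confidence passed to [classify_variant()].
#' @return A list with `variants` (data.frame of classified variants) and
#'   `skips` (data.frame `reason`/`count` over the enumerated skip reasons).
#' @export
classify_vcf <- function(vcf_path, fasta_path,
                         min_aa_confidence = c("high", "any")) {
  min_aa_confidence <- match.arg(min_aa_confidence)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fx <- vcf@fix
  ref_seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(ref_seqs) <- sub("\\s.*$", "", names(ref_seqs))

  chrom <- fx[, "CHROM"]
  pos <- as.integer(fx[, "POS"])
  ref <- fx[, "REF"]
  alt <- fx[, "ALT"]
  info <- fx[, "INFO"]
  aa <- vcf_info_field(info, "AA")
  ac <- suppressWarnings(as.integer(vcf_info_field(info, "AC")))
  an <- suppressWarnings(as.integer(vcf_info_field(info, "AN")))
  if (anyNA(an) || anyNA(ac)) stop("every record needs integer INFO/AC and INFO/AN")

  if (any(!chrom %in% names(ref_seqs))) {
    stop("contig ", setdiff(chrom, names(ref_seqs))[1], " absent from FASTA")
  }
  clen <- setNames(Biostrings::width(ref_seqs), names(ref_seqs))
  if (any(pos > clen[chrom])) stop("variant beyond contig end")

  # vectorized reference 3-mer extraction (edge records -> bad_context)
  interior <- pos >= 2 & pos <= clen[chrom] - 1
  ctx <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch & interior)
    if (!length(sel)) next
    v <- Biostrings::Views(ref_seqs[[ch]], start = pos[sel] - 1L,
                           width = 3L)
    ctx[sel] <- as.character(v)
  }

  reason <- rep(NA_character_, length(pos))
  reason[!interior] <- "bad_context"
  snv <- ref %in% BASES & alt %in% BASES
  reason[is.na(reason) & grepl(",", alt, fixed = TRUE)] <- "multiallelic"
  reason[is.na(reason) & !snv] <- "not_snv"
  bad_ctx <- !grepl("^[ACGT]{3}$", ctx)
  reason[is.na(reason) & bad_ctx] <- "bad_context"
  ok <- is.na(reason)
  if (any(substr(ctx[ok], 2, 2) != ref[ok])) {
    stop("REF allele disagrees with reference context")
  }
  aa_low <- aa %in% c("a", "c", "g", "t")
  if (min_aa_confidence == "high") {
    reason[is.na(reason) & aa_low] <- "low_conf_ancestral"
  } else {
    aa[aa_low] <- toupper(aa[aa_low])
  }
  reason[is.na(reason) & (is.na(aa) | !aa %in% BASES)] <- "no_ancestral"
  ok <- is.na(reason)
  mismatch <- ok & aa != ref & aa != alt
  reason[mismatch] <- "aa_mismatch"
  ok <- is.na(reason)
  derived <- ifelse(aa == ref, alt, ref)
  dcount <- ifelse(aa == ref, ac, an - ac)
  mono <- ok & (dcount < 1 | dcount > an - 1)
  reason[mono] <- "monomorphic"
  ok <- is.na(reason)

  skips <- setNames(integer(length(SKIP_REASONS)), SKIP_REASONS)
  tab <- table(factor(reason, levels = SKIP_REASONS))
  skips[names(tab)] <- as.integer(tab)

  # vectorized canonicalization: reverse-complement where ancestral is G/T
  five <- substr(ctx, 1, 1)
  three <- substr(ctx, 3, 3)
  flip <- ok & !aa %in% c("A", "C")
  comp1 <- function(x) chartr("ACGT", "TGCA", x)
  anc_c <- ifelse(flip, comp1(aa), aa)
  der_c <- ifelse(flip, comp1(derived), derived)
  five_c <- ifelse(flip, comp1(three), five)
  three_c <- ifelse(flip, comp1(five), three)

  variants <- data.frame(
    chrom = chrom[ok], pos = pos[ok],
    subtype = subtype_label(five_c[ok], anc_c[ok], der_c[ok], three_c[ok]),
    gbgc = gbgc_category(anc_c[ok], der_c[ok]),
    cpg = is_cpg(anc_c[ok], three_c[ok]),
    derived_count = as.integer(dcount[ok]), sample_n = an[ok],
    stringsAsFactors = FALSE)
  rownames(variants) <- NULL
  list(variants = variants,
       skips = data.frame(reason = names(skips), count = unname(skips)))
}

vcf_info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Write classified variants and the skip summary to TSV
#' @param classified result of [classify_vcf()].
#' @param variants_path,skips_path output TSV paths.
#' @export
write_classified <- function(classified, variants_path, skips_path = NULL) {
  write.table(classified$variants, variants_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(skips_path)) {
    write.table(classified$skips, skips_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(variants_path)
}
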