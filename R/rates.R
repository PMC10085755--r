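#' Count strand-collapsed 3-mer motif occurrences in a reference
#'
#' Every interior position whose 3-mer window is pure A/C/G/T contributes
#' one count to the canonical context of its central base: windows with a
#' central A or C count as-is, windows with a central G or T count under
#' the reverse-complemented context.  All six subtypes sharing a context
#' share its motif count.
#'
#' @param seqs a `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @return named integer vector of counts for the 32 canonical contexts
#'   (e.g. `"ACG"`), in the order induced by [enumerate_subtypes()].
#' @export
count_motifs <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::readDNAStringSet(seqs)
  if (sum(Biostrings::width(seqs)) == 0) {
    warning("empty sequence: all motif counts zero")
  }
  freq <- Biostrings::trinucleotideFrequency(seqs, step = 1)
  freq <- if (is.matrix(freq)) colSums(freq) else freq
  st <- enumerate_subtypes()
  ctx <- unique(paste0(st$five_prime, st$ancestral, st$three_prime))
  out <- vapply(ctx, function(cc) {
    rc <- paste(rev_comp(strsplit(cc, "")[[1]]), collapse = "")
    unname(freq[cc] + freq[rc])
  }, numeric(1))
  out
}

motif_context <- function(subtype_table = enumerate_subtypes()) {
  paste0(subtype_table$five_prime, subtype_table$ancestral,
         subtype_table$three_prime)
}

#' Relative mutation rates from singleton densities
#'
#' `rel_rate` is proportional to singletons per motif occurrence, normalized
#' to mean 1 across the 96 subtypes (any positive scale cancels in the
#' absolute-rate conversion).
#'
#' @param singleton_counts named (by subtype) or ordered numeric vector of
#'   singleton counts per subtype.
#' @param num_motifs motif counts per subtype (each subtype's canonical
#'   context count); positive wherever singletons are observed.
#' @return numeric vector of relative rates, mean 1.
#' @export
relative_rates <- function(singleton_counts, num_motifs) {
  stopifnot(length(singleton_counts) == length(num_motifs))
  if (any(num_motifs <= 0 & singleton_counts > 0)) {
    stop("zero motif count with non-zero singletons")
  }
  r <- ifelse(num_motifs > 0, singleton_counts / num_motifs, 0)
  r / mean(r)
}

#' Absolute per-site per-generation mutation rates
#'
#' Distributes a fixed number of de novo mutations per generation (60 by
#' default, the rate observed in human trio studies) across subtypes in
#' proportion to `rel_rate * num_motifs`:
#' `mu_s = rel_rate_s * dnm / sum_t(num_motifs_t * rel_rate_t)`.
#' By construction `sum_s num_motifs_s * mu_s = dnm` exactly.
#'
#' @param rel_rates relative rates (any positive scale).
#' @param num_motifs motif counts per subtype.
#' @param dnm_per_generation de novo mutations per generation (default 60).
#' @return numeric vector of absolute rates `mu_s`.
#' @export
absolute_rates <- function(rel_rates, num_motifs, dnm_per_generation = 60) {
  stopifnot(length(rel_rates) == length(num_motifs), all(rel_rates >= 0))
  denom <- sum(num_motifs * rel_rates)
  if (denom <= 0) stop("all relative rates are zero")
  rel_rates * dnm_per_generation / denom
}

#' Classify subtypes into low/high mutation-rate classes
#'
#' `"high"` iff strictly above the median rate; with 96 distinct values
#' this yields an exact 48/48 split, and with all values equal nothing is
#' classified high (documented tie rule).
#'
#' @param mu_abs numeric vector of rates (one per subtype).
#' @return character vector in `{"low","high"}`.
#' @export
rate_class <- function(mu_abs) {
  ifelse(mu_abs > median(mu_abs), "high", "low")
}

#' Build a full mutation-rate table
#'
#' @param singleton_counts per-subtype singleton counts, ordered as
#'   [enumerate_subtypes()].
#' @param motif_counts named counts per canonical context from
#'   [count_motifs()], or a per-subtype vector.
#' @param dnm_per_generation passed to [absolute_rates()].
#' @return data.frame: subtype, num_motifs, rel_rate, mu_abs, rate_class.
#' @export
mutation_rate_table <- function(singleton_counts, motif_counts,
                                dnm_per_generation = 60) {
  st <- enumerate_subtypes()
  ctx <- motif_context(st)
  num_motifs <- if (!is.null(names(motif_counts)) &&
                    all(ctx %in% names(motif_counts))) {
    unname(motif_counts[ctx])
  } else {
    stopifnot(length(motif_counts) == nrow(st))
    as.numeric(motif_counts)
  }
  rel <- relative_rates(singleton_counts, num_motifs)
  mu <- absolute_rates(rel, num_motifs, dnm_per_generation)
  data.frame(subtype = st$subtype, num_motifs = num_motifs,
             rel_rate = rel, mu_abs = mu, rate_class = rate_class(mu),
             stringsAsFactors = FALSE)
}
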