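#' @useDynLib mutsfs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rmultinom rnorm runif median quantile sd var cor cor.test
#'   t.test optim setNames dbinom complete.cases pnorm qt rbinom rpois
#' @importFrom utils write.table read.table head tail
NULL

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a base vector
#' @param x character vector of single bases
#' @keywords internal
rev_comp <- function(x) unname(COMP[rev(x)])

#' Enumerate the 96 strand-collapsed 3-mer mutation subtypes
#'
#' A subtype is the central base-pair change plus its immediate 5' and 3'
#' flanking bases, collapsed over strand so that the central ancestral base
#' is A or C.  With 2 canonical ancestral bases x 3 derived alleles x 4
#' five-prime x 4 three-prime flanks there are exactly 96 classes.
#'
#' @return A data.frame with one row per subtype, ordered lexicographically
#'   by (five_prime, ancestral, derived, three_prime), with columns
#'   `five_prime`, `ancestral`, `derived`, `three_prime`, `subtype` (the
#'   label, e.g. `"A[C>T]G"`), `gbgc` (`WS`/`SW`/`IND`) and `cpg` (logical).
#' @export
#' @examples
#' st <- enumerate_subtypes()
#' nrow(st)          # 96
#' table(st$gbgc)    # 32 per category
enumerate_subtypes <- function() {
  grid <- expand.grid(
    three_prime = BASES, derived = BASES, ancestral = c("A", "C"),
    five_prime = BASES,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("five_prime", "ancestral", "derived", "three_prime")]
  grid <- grid[grid$derived != grid$ancestral, ]
  grid <- grid[order(grid$five_prime, grid$ancestral, grid$derived,
                     grid$three_prime), ]
  rownames(grid) <- NULL
  grid$subtype <- subtype_label(grid$five_prime, grid$ancestral,
                                grid$derived, grid$three_prime)
  grid$gbgc <- gbgc_category(grid$ancestral, grid$derived)
  grid$cpg <- is_cpg(grid$ancestral, grid$three_prime)
  grid
}

subtype_label <- function(five, anc, der, three) {
  paste0(five, "[", anc, ">", der, "]", three)
}

#' Canonicalize a mutation and its 3-mer context by strand collapsing
#'
#' If the ancestral allele is already A or C the key is returned unchanged;
#' otherwise the triplet and both alleles are reverse-complemented (the 5'
#' and 3' flanks swap and complement) so that the same biological event
#' observed on either strand maps to one key.
#'
#' @param anc,der ancestral and derived alleles (single bases).
#' @param five_prime,three_prime flanking reference bases.
#' @return A one-row data.frame like a row of [enumerate_subtypes()], or an
#'   error if any base is not A/C/G/T or `anc == der`.
#' @export
#' @examples
#' canonicalize("T", "G", "C", "A")$subtype  # "T[A>C]G"
canonicalize <- function(anc, der, five_prime, three_prime) {
  b <- c(anc, der, five_prime, three_prime)
  if (any(!b %in% BASES)) {
    stop("ambiguous or invalid base: ", paste(setdiff(b, BASES), collapse = ","))
  }
  if (anc == der) stop("ancestral and derived alleles must differ")
  if (!anc %in% c("A", "C")) {
    tmp <- five_prime
    five_prime <- unname(COMP[three_prime])
    three_prime <- unname(COMP[tmp])
    anc <- unname(COMP[anc])
    der <- unname(COMP[der])
  }
  data.frame(five_prime = five_prime, ancestral = anc, derived = der,
             three_prime = three_prime,
             subtype = subtype_label(five_prime, anc, der, three_prime),
             gbgc = gbgc_category(anc, der),
             cpg = is_cpg(anc, three_prime),
             stringsAsFactors = FALSE)
}

#' gBGC direction of a canonical mutation class
#'
#' Weak-to-strong (`WS`) mutations create a G/C allele from an A/T ancestor
#' (A>C, A>G on the canonical strand) and are favoured by GC-biased gene
#' conversion; strong-to-weak (`SW`) mutations (C>A, C>T) are disfavoured;
#' A>T and C>G are indifferent (`IND`).  The rule partitions the 96 subtypes
#' 32/32/32.
#'
#' @param anc,der canonical ancestral (A or C) and derived alleles;
#'   vectorized.
#' @return character vector in `{"WS","SW","IND"}`.
#' @export
gbgc_category <- function(anc, der) {
  stopifnot(all(anc %in% c("A", "C")))
  out <- ifelse(anc == "A" & der %in% c("C", "G"), "WS",
         ifelse(anc == "C" & der %in% c("A", "T"), "SW", "IND"))
  out
}

#' CpG status of a canonical mutation class
#'
#' True iff the canonical ancestral base is C and the 3' flank is G, i.e.
#' the ancestral site sits in a CpG dinucleotide (hypermutable through
#' methylation-driven deamination).  12 of the 96 subtypes are CpG, 4 of
#' them C>T (the CpG->TpG classes).
#'
#' @param anc,three_prime canonical ancestral base and 3' flank; vectorized.
#' @return logical vector.
#' @export
is_cpg <- function(anc, three_prime) {
  anc == "C" & three_prime == "G"
}
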