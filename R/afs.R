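#' Construct an unfolded site frequency spectrum
#'
#' @param counts integer vector `eta_1 ... eta_{n-1}` of segregating-site
#'   counts by derived-allele count.
#' @param n haploid sample size; `length(counts)` must be `n - 1`.
#' @return An object of class `sfs`: the counts vector with attribute `n`.
#' @export
sfs <- function(counts, n) {
  counts <- as.numeric(counts)
  if (length(counts) != n - 1) stop("counts must have length n - 1")
  if (any(counts < 0)) stop("spectrum entries must be non-negative")
  structure(counts, n = as.integer(n), class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat("unfolded SFS, n =", attr(x, "n"), ", S =", sum(x), "\n")
  print(unclass(x)[seq_len(min(length(x), 12L))])
  if (length(x) > 12L) cat("... (", length(x) - 12L, " more classes)\n")
  invisible(x)
}

sfs_n <- function(afs) attr(afs, "n")
sfs_S <- function(afs) sum(afs)

#' Build per-subtype spectra from classified variants
#'
#' Tallies derived-allele counts per subtype.  Subtypes absent from the
#' input get all-zero spectra so the result always covers the full set of
#' 96 classes.
#'
#' @param variants data.frame with columns `subtype` and `derived_count`
#'   (e.g. from [classify_vcf()]).
#' @param n shared haploid sample size.
#' @return An object of class `subtype_spectra`: a list with `counts`
#'   (96 x (n-1) matrix, rows named by subtype) and `n`.
#' @export
build_spectra <- function(variants, n) {
  st <- enumerate_subtypes()
  if (nrow(variants) > 0) {
    if (any(variants$derived_count < 1 | variants$derived_count > n - 1)) {
      stop("derived_count outside [1, n-1]; filter monomorphic sites upstream")
    }
    if (any(!variants$subtype %in% st$subtype)) {
      stop("unknown subtype label in input")
    }
  }
  counts <- matrix(0, nrow = nrow(st), ncol = n - 1,
                   dimnames = list(st$subtype, NULL))
  if (nrow(variants) > 0) {
    tab <- table(factor(variants$subtype, levels = st$subtype),
                 factor(variants$derived_count, levels = seq_len(n - 1)))
    counts <- counts + unclass(tab)
  }
  structure(list(counts = counts, n = as.integer(n)),
            class = "subtype_spectra")
}

#' @export
print.subtype_spectra <- function(x, ...) {
  cat("subtype spectra: 96 x (n-1) with n =", x$n,
      ", total S =", sum(x$counts), "\n")
  invisible(x)
}

#' Extract one subtype's spectrum
#' @param spectra a `subtype_spectra` object.
#' @param subtype subtype label, e.g. `"A[C>T]G"`.
#' @export
subtype_sfs <- function(spectra, subtype) {
  sfs(spectra$counts[subtype, ], spectra$n)
}

#' Aggregate spectrum over all subtypes
#' @param spectra a `subtype_spectra` object.
#' @export
total_sfs <- function(spectra) {
  sfs(colSums(spectra$counts), spectra$n)
}

#' Singleton, doubleton and tripleton proportions
#'
#' @param afs an `sfs` with S > 0.
#' @return named numeric vector `(p1, p2, p3)` with `p_i = eta_i / S`.
#' @export
rare_proportions <- function(afs) {
  S <- sfs_S(afs)
  if (S <= 0) stop("rare proportions undefined for an empty spectrum")
  if (length(afs) < 3) stop("need n >= 4 for tripleton proportions")
  p <- as.numeric(afs[1:3]) / S
  setNames(p, c("p1", "p2", "p3"))
}

#' Ratio of singletons to doubletons
#'
#' The depletion of this ratio flags recurrent mutation at fast-mutating
#' motifs: independent singleton mutations at the same site merge into
#' doubletons (and higher counts).
#'
#' @param afs an `sfs` with `eta_2 > 0`.
#' @export
singleton_doubleton_ratio <- function(afs) {
  if (afs[2] <= 0) stop("eta_2 is zero: singleton/doubleton ratio undefined")
  as.numeric(afs[1] / afs[2])
}

#' Multinomial bootstrap resample of a spectrum
#'
#' Resamples the S segregating sites with replacement across frequency
#' classes (probabilities `eta_i / S`), preserving S exactly.
#'
#' @param afs an `sfs` with S > 0.
#' @param seed optional integer seed for reproducibility.
#' @return An `sfs` of the same n and S.
#' @export
bootstrap_resample <- function(afs, seed = NULL) {
  S <- sfs_S(afs)
  if (S <= 0) stop("cannot bootstrap an empty spectrum")
  if (!is.null(seed)) set.seed(seed)
  draw <- rmultinom(1, size = S, prob = as.numeric(afs) / S)[, 1]
  sfs(draw, sfs_n(afs))
}

#' Write / read a spectrum as a two-column TSV (`i`, `count`)
#' @param afs an `sfs`.
#' @param path output path.
#' @export
write_sfs <- function(afs, path) {
  write.table(data.frame(i = seq_along(afs), count = as.numeric(afs)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  sfs(d$count[order(d$i)], n = max(d$i) + 1L)
}

#' Write per-subtype spectra to a directory (one TSV per subtype + index)
#' @param spectra a `subtype_spectra` object.
#' @param dir output directory (created if missing).
#' @export
write_spectra <- function(spectra, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- rownames(spectra$counts)
  files <- paste0(gsub("[^ACGT]", "_", labels), ".tsv")
  for (i in seq_along(labels)) {
    write_sfs(sfs(spectra$counts[i, ], spectra$n), file.path(dir, files[i]))
  }
  write.table(data.frame(subtype = labels, file = files, n = spectra$n),
              file.path(dir, "index.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(dir) {
  idx <- read.table(file.path(dir, "index.tsv"), header = TRUE, sep = "\t")
  n <- idx$n[1]
  counts <- t(vapply(idx$file, function(f) {
    as.numeric(read_sfs(file.path(dir, f)))
  }, numeric(n - 1)))
  rownames(counts) <- idx$subtype
  structure(list(counts = counts, n = as.integer(n)),
            class = "subtype_spectra")
}
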