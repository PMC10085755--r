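#' Simulate a single-locus unfolded spectrum (linked sites)
#'
#' Draws one Kingman genealogy per replicate under the demography
#' (time-rescaled for non-constant size) and drops Poisson(theta/2 x branch
#' length) infinite-sites mutations on it.  All sites of a replicate share
#' the genealogy, which is what gives spectrum entries their second-order
#' (theta^2) covariances.
#'
#' @param n haploid sample size.
#' @param theta locus-scaled mutation rate `4*Ne*mu*L`.
#' @param reps number of replicates.
#' @param demography a `demography` (default constant size).
#' @param seed optional integer seed.
#' @return an `sfs` if `reps = 1`, else an `(n-1) x reps` matrix.
#' @export
sim_locus_spectrum <- function(n, theta, reps = 1,
                               demography = demog_constant(), seed = NULL) {
  stopifnot(n >= 4, theta > 0, reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  eta <- .cpp_sim_linked_spectra(n, theta, reps, demog_encode(demography))
  if (reps == 1) sfs(eta[, 1], n) else eta
}

#' Simulate a spectrum from independent per-site genealogies
#'
#' Each of L sites gets its own genealogy and Poisson(theta_site/2 x branch
#' length) mutations.  Under `recurrent = TRUE` (finite sites) a leaf
#' carries the derived allele iff at least one mutation lies on its root
#' path, so independent mutations at the same site merge carriers; with
#' `back_mutation = TRUE` each event instead toggles the allele (a leaf is
#' derived iff its root path holds an odd number of mutations).  Reversals
#' are intrinsically rarer than forward recurrences by the same rate
#' ratio, so the toggle is off by default.  With `recurrent = FALSE` only
#' the earliest mutation is kept (infinite-sites behaviour).  Sites with 0
#' or n derived copies are dropped.
#'
#' @param n haploid sample size.
#' @param theta_site per-site scaled mutation rate `4*Ne*mu_site`.
#' @param L number of independent sites.
#' @param demography a `demography`.
#' @param recurrent finite-sites recurrent mutation (default TRUE).
#' @param back_mutation parity rule for repeat mutations (default FALSE).
#' @param seed optional integer seed.
#' @return an `sfs`.
#' @export
sim_sites_spectrum <- function(n, theta_site, L,
                               demography = demog_constant(),
                               recurrent = TRUE, back_mutation = FALSE,
                               seed = NULL) {
  stopifnot(n >= 4, theta_site > 0, L >= 1)
  if (!is.null(seed)) set.seed(seed)
  eta <- .cpp_sim_site_spectrum(n, theta_site, L, demog_encode(demography),
                                recurrent, back_mutation)
  sfs(eta, n)
}

#' Sampling distribution of derived counts under gBGC-like bias
#'
#' Forward Wright-Fisher simulation of new derived mutations with genic
#' transmission bias b (transmission probability of a derived allele at
#' count x of 2N copies is `x(1+b) / (2N + x b)`).  Sojourn times over all
#' trajectories estimate the stationary frequency distribution of
#' segregating sites under recurrent mutational influx; binomial sampling
#' of n haploids then gives the probability of each derived count
#' conditional on segregating in the sample.
#'
#' @param n haploid sample size.
#' @param b transmission bias per generation (0 = neutral; B = 4Nb is the
#'   population-scaled bias).
#' @param N diploid population size of the forward simulation.
#' @param n_traj number of mutation trajectories.
#' @param seed optional integer seed.
#' @return numeric vector of length n - 1 summing to 1.
#' @export
gbgc_sample_probs <- function(n, b, N = 500, n_traj = 20000, seed = NULL) {
  stopifnot(n >= 4, N >= 10)
  if (!is.null(seed)) set.seed(seed)
  twoN <- 2L * N
  H <- .cpp_wf_sojourn(twoN, b, n_traj)
  x <- seq_len(twoN - 1) / twoN
  q <- vapply(seq_len(n - 1), function(i) sum(H * dbinom(i, n, x)),
              numeric(1))
  q / sum(q)
}

#' Simulate a segregating-site spectrum under gBGC-like transmission bias
#'
#' Draws `sites` segregating sites from the sampling distribution of
#' [gbgc_sample_probs()].
#'
#' @inheritParams gbgc_sample_probs
#' @param sites number of segregating sites in the returned spectrum.
#' @param probs optionally reuse a precomputed [gbgc_sample_probs()] vector.
#' @return an `sfs`.
#' @export
sim_gbgc_spectrum <- function(n, b, sites, N = 500, n_traj = 20000,
                              seed = NULL, probs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(probs)) probs <- gbgc_sample_probs(n, b, N, n_traj)
  sfs(rmultinom(1, sites, probs)[, 1], n)
}

#' Default configuration for the synthetic-genome generator
#'
#' The defaults emulate, at desk scale, the features the analysis is
#' sensitive to: per-subtype mutation-rate heterogeneity with hypermutable
#' CpG transitions, recent exponential growth, windows of varying subtype
#' composition with planted hot windows, an intergenic mask, and
#' recombination/GC covariate tracks.
#'
#' @param contig_lengths named contig lengths (bp).
#' @param n haploid sample size.
#' @param window_size window width for the composition plan.
#' @param demography a `demography` shaping allele counts.
#' @param theta_site_scale per-site scaled mutation rate of a rel-rate-1
#'   subtype; CpG transitions are ~10x this.
#' @param gbgc_b transmission bias applied to WS subtypes (0 = off).
#' @param hot_windows number of windows to make hot in a random subtype.
#' @param hot_factor rate multiplier in hot windows.
#' @param mask_keep fraction of each contig kept in the intergenic mask.
#' @param base_comp reference base composition (A, C, G, T).
#' @param qdist_sites target segregating sites per subtype when estimating
#'   the derived-count sampling distributions (more = smoother truth).
#' @return list of class `genome_config`.
#' @export
genome_config <- function(contig_lengths = setNames(rep(4e5, 8),
                                                    paste0("chr", 1:8)),
                          n = 100,
                          window_size = 1e5,
                          demography = demog_growth(T0 = 0.1, lambda = 50),
                          theta_site_scale = 0.004,
                          gbgc_b = 0,
                          hot_windows = 3,
                          hot_factor = 4,
                          mask_keep = 0.8,
                          base_comp = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                          qdist_sites = 2000) {
  structure(list(contig_lengths = contig_lengths, n = n,
                 window_size = window_size, demography = demography,
                 theta_site_scale = theta_site_scale, gbgc_b = gbgc_b,
                 hot_windows = hot_windows, hot_factor = hot_factor,
                 mask_keep = mask_keep, base_comp = base_comp,
                 qdist_sites = qdist_sites),
            class = "genome_config")
}

#' Deterministic synthetic relative-rate profile over the 96 subtypes
#'
#' CpG C>T transitions get a 10x rate, other CpG subtypes 2x, non-CpG
#' transitions (A>G, C>T) 1.5x, transversions 1x, with a small
#' deterministic per-subtype modulation so all 96 rates are distinct.
#'
#' @return numeric vector of 96 relative rates (ordered as
#'   [enumerate_subtypes()]), mean 1.
#' @export
synthetic_rate_profile <- function() {
  st <- enumerate_subtypes()
  r <- rep(1, nrow(st))
  transition <- (st$ancestral == "A" & st$derived == "G") |
    (st$ancestral == "C" & st$derived == "T")
  r[transition] <- 1.5
  r[st$cpg] <- 2
  r[st$cpg & transition] <- 10
  r <- r * (1 + 0.005 * seq_len(nrow(st)))
  r / mean(r)
}

#' Generate a synthetic genome with known ground truth
#'
#' Writes a reference FASTA, a VCF of biallelic SNVs with AC/AN and
#' INFO/AA, a BED mask of "intergenic" regions, recombination-rate and
#' GC-content tracks, and a truth manifest.  Variants are planted at
#' reference positions whose 3-mer context matches their subtype (on
#' either strand), with per-window counts drawn from subtype- and
#' window-specific rates (hot windows are boosted) and derived-allele
#' counts drawn from subtype-specific simulated spectra (gBGC-biased
#' sampling for WS subtypes when `gbgc_b > 0`).
#'
#' @param config a [genome_config()].
#' @param outdir output directory (created).
#' @param seed integer seed; identical config + seed reproduce the outputs
#'   byte for byte.
#' @return list with file `paths` and the `truth` manifest (also written as
#'   JSON + TSVs).
#' @export
simulate_genome <- function(config = genome_config(), outdir, seed = 1) {
  stopifnot(inherits(config, "genome_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  st <- enumerate_subtypes()
  n <- config$n
  rel <- synthetic_rate_profile()
  theta_site <- config$theta_site_scale * rel

  # reference sequences
  seqs <- lapply(config$contig_lengths, function(len) {
    paste(sample(BASES, len, replace = TRUE, prob = config$base_comp),
          collapse = "")
  })
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- names(config$contig_lengths)

  # windows of the composition plan
  win <- do.call(rbind, lapply(names(config$contig_lengths), function(ch) {
    len <- config$contig_lengths[[ch]]
    start <- seq(0, len - 1, by = config$window_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + config$window_size, len))
  }))
  W <- nrow(win)

  # per-subtype derived-count sampling distributions (generating truth)
  ET <- .cpp_expected_Tk(n, demog_encode(config$demography))
  ttot <- sum((2:n) * ET)
  qdist <- matrix(0, nrow(st), n - 1, dimnames = list(st$subtype, NULL))
  gbgc_q <- NULL
  if (config$gbgc_b > 0) {
    gbgc_q <- gbgc_sample_probs(n, config$gbgc_b)
  }
  for (k in seq_len(nrow(st))) {
    if (!is.null(gbgc_q) && st$gbgc[k] == "WS") {
      qdist[k, ] <- gbgc_q
      next
    }
    Lk <- min(ceiling(config$qdist_sites / (theta_site[k] / 2 * ttot)), 8e5)
    eta <- .cpp_sim_site_spectrum(n, theta_site[k], Lk,
                                  demog_encode(config$demography), TRUE)
    if (sum(eta) == 0) stop("no segregating sites simulated for subtype ",
                            st$subtype[k])
    qdist[k, ] <- eta / sum(eta)
  }

  # motif positions per canonical context and strand
  ctx32 <- unique(motif_context(st))
  motif_pos <- list()
  for (ch in names(config$contig_lengths)) {
    sq <- dna[[ch]]
    motif_pos[[ch]] <- lapply(setNames(ctx32, ctx32), function(cc) {
      rc <- paste(rev_comp(strsplit(cc, "")[[1]]), collapse = "")
      fwd <- Biostrings::start(Biostrings::matchPattern(cc, sq)) + 1L
      rev <- Biostrings::start(Biostrings::matchPattern(rc, sq)) + 1L
      list(fwd = fwd, rev = rev)
    })
  }

  # hot-window plan
  hot <- data.frame(window = integer(0), subtype = character(0))
  if (config$hot_windows > 0) {
    hw <- sample(W, min(config$hot_windows, W))
    hs <- sample(st$subtype[!st$cpg], length(hw), replace = TRUE)
    hot <- data.frame(window = hw, subtype = hs)
  }

  # plant variants window by window
  seg_prob <- pmin(theta_site / 2 * ttot, 0.5)  # per motif site, per subtype
  records <- vector("list", W)
  planted <- matrix(0L, W, nrow(st), dimnames = list(NULL, st$subtype))
  used <- lapply(config$contig_lengths, function(len) logical(len))
  st_ctx <- motif_context(st)
  for (w in seq_len(W)) {
    ch <- win$chrom[w]
    rows <- list()
    for (k in seq_len(nrow(st))) {
      boost <- if (any(hot$window == w & hot$subtype == st$subtype[k])) {
        config$hot_factor
      } else 1
      mp <- motif_pos[[ch]][[st_ctx[k]]]
      cand_f <- mp$fwd[mp$fwd > win$start[w] & mp$fwd <= win$end[w]]
      cand_r <- mp$rev[mp$rev > win$start[w] & mp$rev <= win$end[w]]
      cand <- c(cand_f, cand_r)
      strand <- rep(c("+", "-"), c(length(cand_f), length(cand_r)))
      free <- !used[[ch]][cand]
      cand <- cand[free]; strand <- strand[free]
      cnt <- rpois(1, seg_prob[k] * boost * length(cand))
      if (cnt == 0) next
      if (cnt > length(cand)) {
        stop("composition plan infeasible: window ", ch, ":", win$start[w],
             "-", win$end[w], " has too few free ", st_ctx[k], " motifs")
      }
      pick <- sample(length(cand), cnt)
      pos <- cand[pick]; sdr <- strand[pick]
      used[[ch]][pos] <- TRUE
      anc <- ifelse(sdr == "+", st$ancestral[k], COMP[st$ancestral[k]])
      der <- ifelse(sdr == "+", st$derived[k], COMP[st$derived[k]])
      dc <- sample.int(n - 1, cnt, replace = TRUE, prob = qdist[k, ])
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, pos = pos, ref = unname(anc), alt = unname(der),
        aa = unname(anc), ac = dc, an = n, subtype = st$subtype[k],
        stringsAsFactors = FALSE)
      planted[w, k] <- planted[w, k] + cnt
    }
    if (length(rows)) records[[w]] <- do.call(rbind, rows)
  }
  vcf_df <- do.call(rbind, records[!vapply(records, is.null, logical(1))])
  vcf_df <- vcf_df[order(vcf_df$chrom, vcf_df$pos), ]

  # intergenic mask: keep a random mask_keep fraction of 10 kb chunks
  chunk <- 1e4
  mask <- do.call(rbind, lapply(names(config$contig_lengths), function(ch) {
    len <- config$contig_lengths[[ch]]
    start <- seq(0, len - 1, by = chunk)
    keep <- runif(length(start)) < config$mask_keep
    data.frame(chrom = ch, start = start[keep],
               end = pmin(start[keep] + chunk, len))
  }))

  # covariate tracks per window
  recomb <- exp(rnorm(W, 0, 0.5))
  gc <- vapply(seq_len(W), function(w) {
    sq <- Biostrings::subseq(dna[[win$chrom[w]]], win$start[w] + 1, win$end[w])
    f <- Biostrings::alphabetFrequency(sq)[c("C", "G")]
    sum(f) / (win$end[w] - win$start[w])
  }, numeric(1))

  paths <- list(
    fasta = file.path(outdir, "ref.fa"),
    vcf = file.path(outdir, "variants.vcf"),
    mask = file.path(outdir, "mask.bed"),
    recomb = file.path(outdir, "recomb.tsv"),
    gc = file.path(outdir, "gc.tsv"),
    truth = file.path(outdir, "truth.json"),
    planted = file.path(outdir, "planted_counts.tsv"),
    qdist = file.path(outdir, "qdist.tsv"))

  Biostrings::writeXStringSet(dna, paths$fasta)
  write_vcf(vcf_df, paths$vcf, names(config$contig_lengths),
            config$contig_lengths)
  write.table(mask, paths$mask, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tracks <- cbind(win, recomb = recomb, gc = gc)
  write.table(tracks[, c("chrom", "start", "end", "recomb")], paths$recomb,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tracks[, c("chrom", "start", "end", "gc")], paths$gc,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(win[, c("chrom", "start", "end")], planted),
              paths$planted, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(subtype = st$subtype, round(qdist, 8)),
              paths$qdist, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    seed = seed,
    n = n,
    contig_lengths = as.list(config$contig_lengths),
    window_size = config$window_size,
    demography = unclass(config$demography),
    theta_site_scale = config$theta_site_scale,
    gbgc_b = config$gbgc_b,
    rel_rates = setNames(as.list(rel), st$subtype),
    hot_windows = hot,
    n_variants = nrow(vcf_df))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(paths = paths, truth = truth, planted = planted, windows = win,
       qdist = qdist)
}

write_vcf <- function(df, path, contigs, contig_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", contigs, ",length=", contig_lengths, ">"),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alt allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total alleles\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(df) > 0) {
    writeLines(paste(df$chrom, df$pos, ".", df$ref, df$alt, ".", "PASS",
                     paste0("AA=", df$aa, ";AC=", df$ac, ";AN=", df$an),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a window-level covariate track (chrom, start, end, value TSV)
#' @param path TSV path with a header row.
#' @export
read_track <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  names(d)[4] <- "value"
  d
}

#' Read a BED mask (no header, 0-based half-open)
#' @param path BED path.
#' @export
read_bed <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)[, 1:3]
  names(d) <- c("chrom", "start", "end")
  d
}
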