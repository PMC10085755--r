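test_that("neutral per-site simulation reproduces the theta/i shape", {
  a <- sim_sites_spectrum(20, theta_site = 0.005, L = 1e6,
                          recurrent = FALSE, seed = 2)
  # E[eta_i] proportional to 1/i under the neutral coalescent; compare the
  # realized shape against the multinomial expectation at the observed S
  S <- sum(a)
  expected <- S * (1 / (1:19)) / sum(1 / (1:19))
  se <- sqrt(expected)
  expect_true(all(abs(as.numeric(a) - expected) <= 4 * se))
  # and the absolute scale is within the infinite-sites approximation
  expect_lt(abs(S - 0.005 * 1e6 * sum(1 / (1:19))) / S, 0.03)
})

test_that("finite- and infinite-sites modes agree as mutation rate -> 0", {
  rec <- sim_sites_spectrum(15, 1e-3, 3e5, recurrent = TRUE, seed = 5)
  inf <- sim_sites_spectrum(15, 1e-3, 3e5, recurrent = FALSE, seed = 5)
  # identical RNG stream, recurrence almost never triggered
  expect_lt(sum(abs(as.numeric(rec) - as.numeric(inf))),
            0.01 * sum(rec))
})

test_that("back mutation only matters when repeat hits are common", {
  # identical RNG stream: at low rates the parity rule and the
  # union-of-carriers rule almost never disagree
  lo_or <- sim_sites_spectrum(15, 0.002, 1e5, seed = 19)
  lo_xor <- sim_sites_spectrum(15, 0.002, 1e5, back_mutation = TRUE,
                               seed = 19)
  expect_lt(sum(abs(as.numeric(lo_or) - as.numeric(lo_xor))),
            0.02 * sum(lo_or))
  # at high rates the rules genuinely diverge: parity strips carriers off
  # multi-hit root paths, shifting mass to lower derived counts
  hi_or <- sim_sites_spectrum(15, 2, 2e4, seed = 20)
  hi_xor <- sim_sites_spectrum(15, 2, 2e4, back_mutation = TRUE, seed = 20)
  mean_count <- function(a) sum(seq_along(a) * as.numeric(a)) / sum(a)
  expect_lt(mean_count(hi_xor), mean_count(hi_or))
})

test_that("recurrent mutation depletes singletons as rates grow", {
  set.seed(7)
  ratios <- vapply(c(0.02, 0.2, 0.8), function(th) {
    e <- sim_sites_spectrum(60, th, ceiling(3e4 / th))
    e[1] / e[2]
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("linked-spectrum simulation is reproducible and demography-aware", {
  a <- sim_locus_spectrum(20, 50, seed = 11)
  b <- sim_locus_spectrum(20, 50, seed = 11)
  expect_identical(as.numeric(a), as.numeric(b))
  # growth shifts mass toward singletons relative to constant size
  set.seed(3)
  g <- rowSums(mutsfs:::.cpp_sim_linked_spectra(
    20, 50, 2000, mutsfs:::demog_encode(demog_growth(0.1, 100))))
  set.seed(3)
  c0 <- rowSums(mutsfs:::.cpp_sim_linked_spectra(20, 50, 2000, 0))
  expect_gt(g[1] / sum(g), c0[1] / sum(c0))
})

test_that("transmission bias reduces to neutrality at b = 0", {
  q0 <- gbgc_sample_probs(30, b = 0, N = 300, n_traj = 60000, seed = 8)
  neutral <- (1 / (1:29)) / sum(1 / (1:29))
  # sampling distribution of a segregating site under neutrality ~ 1/i
  expect_lt(max(abs(q0 - neutral)), 0.02)
})

test_that("transmission bias shifts Tajima's D in the expected direction", {
  qp <- gbgc_sample_probs(30, b = 0.004, N = 300, n_traj = 40000, seed = 9)
  qm <- gbgc_sample_probs(30, b = -0.004, N = 300, n_traj = 40000, seed = 10)
  q0 <- gbgc_sample_probs(30, b = 0, N = 300, n_traj = 40000, seed = 11)
  d_of <- function(q) tajimas_d(sfs(round(q * 1e5), 30))$d
  expect_gt(d_of(qp), d_of(q0))
  expect_lt(d_of(qm), d_of(q0))
  s <- sim_gbgc_spectrum(30, 0.004, sites = 5000, probs = qp, seed = 3)
  expect_equal(sum(s), 5000)
})

test_that("genome generation is byte-reproducible and self-consistent", {
  cfg <- genome_config(contig_lengths = c(chrZ = 8e4), n = 30,
                       window_size = 2e4, hot_windows = 0,
                       qdist_sites = 200)
  d1 <- tempfile("g1"); d2 <- tempfile("g2")
  g1 <- simulate_genome(cfg, d1, seed = 33)
  g2 <- simulate_genome(cfg, d2, seed = 33)
  for (f in c("fasta", "vcf", "mask", "recomb", "gc", "planted")) {
    expect_identical(readLines(g1$paths[[f]]), readLines(g2$paths[[f]]))
  }
  # VCF round trip: records re-read equal what was written
  vcf <- vcfR::read.vcfR(g1$paths$vcf, verbose = FALSE)
  expect_equal(nrow(vcf@fix), g1$truth$n_variants)
  fa <- Biostrings::readDNAStringSet(g1$paths$fasta)
  expect_equal(unname(Biostrings::width(fa)), 8e4)
  # planted variants all lie at motif-compatible positions: classification
  # recovers every record with zero skips
  cl <- classify_vcf(g1$paths$vcf, g1$paths$fasta)
  expect_equal(sum(cl$skips$count), 0)
  expect_equal(nrow(cl$variants), g1$truth$n_variants)
  # per-subtype totals match the planted composition matrix
  sp <- build_spectra(cl$variants, cfg$n)
  expect_equal(unname(rowSums(sp$counts)), unname(colSums(g1$planted)))
})
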