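test_that("windows tile contigs and flag short terminal pieces", {
  v <- toy_variants(n = 20, positions = c(5, 99999, 100000, 100001, 249999),
                    subtypes = rep("A[A>G]A", 5), counts = rep(1, 5))
  rw <- make_windows(v, c(chr1 = 250000), window_size = 1e5, min_s = 0,
                     drop_short = FALSE)
  expect_equal(rw$windows$start, c(0, 1e5, 2e5))
  expect_equal(rw$windows$end, c(1e5, 2e5, 2.5e5))
  expect_true(rw$windows$short[3])
  # VCF pos 100000 (1-based) is 0-based 99999 -> first window;
  # pos 249999 sits inside the short terminal window
  expect_equal(rw$windows$S, c(3, 1, 1))
  expect_error(make_windows(toy_variants(20, positions = 3e5,
                                         subtypes = "A[A>G]A", counts = 1),
                            c(chr1 = 250000)), "beyond")
})

test_that("mask filtering equals the brute-force oracle", {
  set.seed(14)
  v <- toy_variants(n = 20, positions = sample.int(5e4, 800),
                    subtypes = "A[A>G]A", counts = 1)
  mask <- data.frame(chrom = "chr1",
                     start = c(0, 20000, 40000),
                     end = c(5000, 30000, 41000))
  kept <- mask_variants(v, mask)
  brute <- vapply(v$pos, function(p) {
    any(p - 1 >= mask$start & p - 1 < mask$end)
  }, logical(1))
  expect_equal(sort(kept$pos), sort(v$pos[brute]))
  rw <- make_windows(v, c(chr1 = 5e4), mask = mask, window_size = 1e4,
                     min_s = 0, drop_short = FALSE)
  expect_equal(sum(rw$windows$S), sum(brute))
  # window-local spectra aggregate to the masked genome-wide spectrum
  masked_sp <- build_spectra(kept, n = 20)
  expect_equal(unname(colSums(rw$afs)),
               unname(as.numeric(total_sfs(masked_sp))))
})

test_that("abundance flags pick out concentrated subtypes", {
  st <- enumerate_subtypes()$subtype
  pos <- c(seq(5, 1e5, length.out = 40),   # subtype 1 spread everywhere
           rep(15, 30))                     # subtype 2 concentrated in w1
  subs <- c(rep(st[1], 40), rep(st[2], 30))
  v <- toy_variants(n = 20, positions = round(pos), subtypes = subs,
                    counts = 1)
  rw <- make_windows(v, c(chr1 = 1e5), window_size = 1e4, min_s = 0,
                     drop_short = FALSE)
  expect_warning(ab <- abundance_flags(rw), "absent")
  expect_equal(sum(ab$flags[, st[2]]), 1)
  expect_true(ab$flags[1, st[2]])
  # uniform composition: ceiling(0.1 W) flagged per observed subtype
  expect_equal(sum(ab$flags[, st[1]]), ceiling(0.1 * 10))
  expect_equal(ab$n_abundant, rowSums(ab$flags))
})

test_that("planted hot windows are exactly the flagged ones", {
  cfg <- genome_config(contig_lengths = c(chr1 = 5e5), n = 40,
                       window_size = 5e4, hot_windows = 1, hot_factor = 8,
                       qdist_sites = 300, mask_keep = 1)
  g <- simulate_genome(cfg, tempfile("hot"), seed = 21)
  cl <- classify_vcf(g$paths$vcf, g$paths$fasta)
  rw <- make_windows(cl$variants, cfg$contig_lengths,
                     window_size = cfg$window_size, min_s = 1)
  ab <- abundance_flags(rw)
  hs <- g$truth$hot_windows$subtype[1]
  hw <- g$truth$hot_windows$window[1]
  expect_true(ab$flags[hw, hs])
})

test_that("quantile summaries conserve stratified counts", {
  set.seed(2)
  W <- 50
  flags <- matrix(runif(W * 96) < 0.1, W, 96)
  stat <- rnorm(W)
  strata <- enumerate_subtypes()$gbgc
  qs <- quantile_summary(stat, flags, n_quantiles = 10, strata = strata)
  expect_equal(sum(qs$n_windows), W)
  expect_equal(qs$mean_n_abundant,
               qs$mean_IND + qs$mean_SW + qs$mean_WS, tolerance = 1e-12)
  # constant abundance gives a flat profile
  qs2 <- quantile_summary(stat, matrix(TRUE, W, 96), n_quantiles = 5)
  expect_true(all(qs2$mean_n_abundant == 96))
  expect_error(quantile_summary(stat[1:3], flags[1:3, ], 10), "fewer")
})

test_that("expected statistics are count-weighted means with bounds", {
  w <- c(5, 5, rep(0, 94))
  gw <- c(-2, -1, rep(NA, 94))
  expect_equal(expected_statistic(w, gw), -1.5)
  expect_equal(expected_statistic(c(3, 0, rep(0, 94)), gw), -2)
  set.seed(4)
  Wm <- matrix(rpois(10 * 96, 4), 10, 96)
  gw2 <- rnorm(96)
  e <- expected_statistic(Wm, gw2)
  expect_true(all(e >= min(gw2) & e <= max(gw2)))
  expect_error(expected_statistic(rep(0, 96), gw2), "no usable")
})

test_that("GEE with rho = 0 reduces to ordinary least squares", {
  set.seed(33)
  W <- 40
  X <- cbind(a = rnorm(W), b = runif(W))
  y <- 1 + 0.5 * X[, 1] - 2 * X[, 2] + rnorm(W, 0, 0.3)
  cl <- rep(c("c1", "c2", "c3", "c4"), each = 10)
  g <- gee_fit(y, X, cl, rho = 0)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(g$coefficients), unname(ols), tolerance = 1e-10)
})

test_that("GEE matches an established implementation on a fixture", {
  # fixture regenerated deterministically; reference values computed with
  # statsmodels GEE (Gaussian family, exchangeable covariance, clusters =
  # chromosome) on the identical CSV
  set.seed(99)
  W <- 60
  chrom <- rep(paste0("chr", 1:4), each = 15)
  x1 <- rnorm(W, -2, 0.3); rr <- exp(rnorm(W)); gc <- runif(W, 0.3, 0.6)
  cl_eff <- rep(rnorm(4, 0, 0.2), each = 15)
  y <- 0.5 + 1.2 * x1 + 0.1 * rr - 0.5 * gc + cl_eff + rnorm(W, 0, 0.25)
  f <- gee_fit(y, cbind(x1 = x1, rr = rr, gc = gc), chrom)
  expect_equal(unname(f$coefficients),
               c(0.22068238, 1.09449804, 0.08536994, -0.39266622),
               tolerance = 1e-6)
  expect_equal(unname(f$robust_se),
               c(0.10064430, 0.03743232, 0.01169600, 0.14681481),
               tolerance = 1e-5)
  expect_equal(f$rho, 0.32024850, tolerance = 1e-6)
  expect_equal(f$scale, 0.10253093, tolerance = 1e-6)
})

test_that("GEE recovers a unit slope on expected statistics", {
  set.seed(55)
  W <- 200
  chrom <- rep(paste0("chr", 1:10), each = 20)
  x <- rnorm(W, -2, 0.2)
  y <- x + rnorm(W, 0, 0.3)
  f <- gee_fit(y, cbind(exp = x), chrom)
  expect_lt(abs(f$coefficients[["exp"]] - 1), 3 * f$robust_se[["exp"]])
  expect_error(gee_fit(y, cbind(x, x), chrom), "singular")
  expect_error(gee_fit(y, cbind(x), rep("c1", W)), "clusters")
})
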