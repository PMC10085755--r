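test_that("constant-size expected spectrum is theta/i to machine precision", {
  for (n in c(4, 20, 100)) {
    xi <- expected_afs(demog_constant(), n, theta = 10)
    expect_equal(xi, 10 / seq_len(n - 1), tolerance = 1e-9)
  }
  # degenerate growth parameters collapse to the constant model
  expect_equal(expected_afs(demog_growth(0, 50), 20, theta = 2),
               2 / (1:19), tolerance = 1e-9)
  expect_equal(expected_afs(demog_growth(1, 1), 20, theta = 2),
               2 / (1:19), tolerance = 1e-9)
  expect_error(expected_afs(demog_constant(), 300), "cap")
})

test_that("growth expectations match coalescent Monte Carlo", {
  xi <- expected_afs(demog_growth(0.05, 50), 20, theta = 100)
  mc <- mc_expected_afs(demog_growth(0.05, 50), 20, reps = 60000,
                        theta = 100, seed = 3)
  expect_true(all(abs(xi - mc$mean) <= 3.5 * mc$se))
})

test_that("three-epoch expectations match coalescent Monte Carlo", {
  m <- demog_three_epoch(0.3, 0.1, 0.2, 10)
  xi <- expected_afs(m, 20, theta = 100)
  mc <- mc_expected_afs(m, 20, reps = 60000, theta = 100, seed = 4)
  expect_true(all(abs(xi - mc$mean) <= 3.5 * mc$se))
})

test_that("stronger growth pushes expectation mass toward singletons", {
  shares <- vapply(c(2, 10, 50, 250), function(lam) {
    xi <- expected_afs(demog_growth(0.1, lam), 30)
    xi[1] / sum(xi)
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})

test_that("the Poisson objective behaves like a likelihood", {
  xi <- expected_afs(demog_growth(0.2, 20), 20, theta = 500)
  eta <- round(xi)
  # theta rescaling: observed == expected sits at the profile optimum
  lls <- vapply(c(0.5, 0.8, 1, 1.25, 2), function(f) {
    poisson_loglik(eta, f * eta)
  }, numeric(1))
  expect_equal(which.max(lls), 3)
  expect_lt(poisson_loglik(eta, 2 * xi), poisson_loglik(eta, xi))
  # agreement with a direct dpois evaluation
  expect_equal(poisson_loglik(eta, xi),
               sum(dpois(eta, xi, log = TRUE)), tolerance = 1e-10)
  expect_error(poisson_loglik(eta, c(-1, xi[-1])), "positive")
})

test_that("noise-free growth data are recovered to high precision", {
  xi <- expected_afs(demog_growth(0.1, 100), 50, theta = 5000)
  fit <- fit_model(sfs(xi, 50), "growth", seed = 1)
  expect_lt(abs(fit$params[["T0"]] - 0.1) / 0.1, 0.01)
  expect_lt(abs(fit$params[["lambda"]] - 100) / 100, 0.01)
  expect_lt(abs(fit$params[["theta"]] - 5000) / 5000, 0.01)
})

test_that("constant-size data fit with the growth family degenerate cleanly", {
  xi <- expected_afs(demog_constant(), 30, theta = 2000)
  fit <- fit_model(sfs(xi, 30), "growth", seed = 2, n_restarts = 4)
  # either lambda ~ 1 or T0 ~ 0 is an acceptable degeneracy
  expect_true(abs(fit$params[["lambda"]] - 1) < 0.05 ||
                fit$params[["T0"]] < 0.01)
  expect_lt(abs(fit$params[["theta"]] - 2000) / 2000, 0.01)
})

test_that("natural scales derive from theta and the mutation rate", {
  fit <- structure(list(family = "growth",
                        params = c(theta = 4000, T0 = 0.05, lambda = 10)),
                   class = "demographic_fit")
  sc <- derive_scales(fit, mu_abs = 1e-8, L = 1e8)
  expect_equal(sc$Ne, 1000)
  expect_equal(unname(sc$times_generations["T0"]), 100)
  fit3 <- structure(list(family = "three_epoch",
                         params = c(theta = 4000, T1 = 0.1, T2 = 0.2,
                                    lambda1 = 0.5, lambda2 = 2)),
                    class = "demographic_fit")
  sc3 <- derive_scales(fit3, 1e-8, 1e8)
  expect_equal(unname(sc3$times_generations["T_total"]), 600)
})

test_that("bootstrap SEs are reproducible and shrink with data", {
  xi <- expected_afs(demog_growth(0.1, 50), 30, theta = 1)
  set.seed(5)
  obs <- sfs(rpois(29, 2e4 / sum(xi) * xi), 30)
  fit <- fit_model(obs, "growth", n_restarts = 2, seed = 1)
  b1 <- bootstrap_se(obs, fit, B = 8, seed = 9)
  b2 <- bootstrap_se(obs, fit, B = 8, seed = 9)
  expect_identical(b1$se, b2$se)
  expect_true(all(b1$se[c("T0", "lambda")] > 0))
  # 100x more sites: SEs drop roughly like 1/sqrt(S)
  set.seed(6)
  obs2 <- sfs(rpois(29, 2e6 / sum(xi) * xi), 30)
  fit2 <- fit_model(obs2, "growth", n_restarts = 2, seed = 2)
  b3 <- bootstrap_se(obs2, fit2, B = 8, seed = 10)
  expect_lt(b3$se[["lambda"]], b1$se[["lambda"]] / 3)
})

test_that("degenerate spectra surface refit failures without crashing", {
  degen <- sfs(c(0, 0, 50, rep(0, 26)), 30)
  fit <- suppressWarnings(fit_model(degen, "growth", n_restarts = 1,
                                    seed = 3))
  expect_s3_class(fit, "demographic_fit")
  # the one-class bootstrap keeps refitting the same degenerate spectrum;
  # a flagged boundary or zero-variance SE is reported, never a crash
  bs <- tryCatch(bootstrap_se(degen, fit, B = 4, seed = 4),
                 error = function(e) e)
  expect_true(inherits(bs, "error") || all(is.finite(bs$se)))
})
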