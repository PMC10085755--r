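test_that("Tajima's D matches the textbook hand computation", {
  td <- tajimas_d(sfs(c(3, 0, 0), 4))
  expect_equal(td$theta_w, 3 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-12)
  expect_equal(td$theta_pi, 1.5, tolerance = 1e-12)
  expect_equal(td$d, -0.7544511, tolerance = 1e-6)
  expect_error(tajimas_d(sfs(c(1, 0, 0), 4)), "insufficient")
})

test_that("D is zero when the two estimators coincide", {
  # choose eta with theta_pi == theta_w: n = 4, eta = (5, 3, 1) gives
  # theta_pi = (5*3 + 3*4 + 1*3)/6 = 5, theta_w = 9/(11/6) != 5; construct
  # instead via proportional neutral expectation eta_i ~ 1/i scaled
  n <- 7
  eta <- 420 / (1:6)  # exactly theta/i with theta = 420
  td <- tajimas_d(sfs(eta, n))
  expect_equal(td$theta_pi, td$theta_w, tolerance = 1e-12)
  expect_equal(td$d, 0, tolerance = 1e-12)
})

test_that("minus-2 estimators match hand evaluation and drop eta1/eta2", {
  th <- theta_estimators_minus2(sfs(c(0, 0, 1, 0, 0), 6))
  expect_equal(unname(th[1]), 1.5, tolerance = 1e-12)
  expect_equal(unname(th[2]), 1 / (sum(1 / (1:5)) - 1.5), tolerance = 1e-9)
  # only eta1/eta2 present -> both zero
  expect_equal(unname(theta_estimators_minus2(sfs(c(7, 3, 0, 0, 0), 6))),
               c(0, 0))
  expect_error(theta_estimators_minus2(sfs(c(1, 1, 1, 1), 5)), "n >= 6")
})

test_that("estimators are unbiased under the neutral coalescent", {
  set.seed(21)
  n <- 20; theta <- 10; reps <- 6000
  eta <- mutsfs:::.cpp_sim_linked_spectra(n, theta, reps, 0)
  i <- seq_len(n - 1)
  tw <- colSums(eta) / sum(1 / i)
  tp <- colSums(eta * i * (n - i)) / choose(n, 2)
  m2 <- apply(eta, 2, function(e) theta_estimators_minus2(sfs(e, n)))
  for (est in list(tw, tp, m2[1, ], m2[2, ])) {
    expect_lt(abs(mean(est) - theta), 3 * sd(est) / sqrt(reps))
  }
  # per-class neutral means E[eta_i] = theta / i
  se_i <- apply(eta, 1, sd) / sqrt(reps)
  expect_true(all(abs(rowMeans(eta) - theta / i) <= 3.5 * se_i))
})

test_that("the covariance matrix satisfies its structural identities", {
  for (n in c(6, 10, 25)) {
    sig <- fu_covariance_matrix(n)
    expect_equal(sig, t(sig))
    # row/column sum identity recovering Var(S) = a1 theta + a2 theta^2
    expect_equal(sum(sig), sum(1 / (1:(n - 1))^2), tolerance = 1e-10)
  }
  expect_error(fu_covariance_matrix(3), "n >= 4")
  expect_error(fu_covariance_matrix(300, cap = 200), "cap")
})

test_that("second moments of the spectrum match Fu's coefficients", {
  set.seed(13)
  n <- 10; theta <- 5; reps <- 60000
  eta <- mutsfs:::.cpp_sim_linked_spectra(n, theta, reps, 0)
  sig <- fu_covariance_matrix(n)
  # Var(eta_1) = theta + sigma_11 theta^2 within Monte-Carlo error
  v1 <- var(eta[1, ])
  se_v1 <- sd((eta[1, ] - mean(eta[1, ]))^2) / sqrt(reps)
  expect_lt(abs(v1 - (theta + sig[1, 1] * theta^2)), 3 * se_v1)
  # a representative covariance
  cv <- cov(eta[2, ], eta[5, ])
  prod25 <- (eta[2, ] - mean(eta[2, ])) * (eta[5, ] - mean(eta[5, ]))
  expect_lt(abs(cv - sig[2, 5] * theta^2), 3 * sd(prod25) / sqrt(reps))
})

test_that("D-2 is exactly invariant to singletons and doubletons", {
  base <- sfs(c(0, 0, 9, 4, 2, 1, 0, 3, 1), 10)
  spiked <- sfs(c(250, 60, 9, 4, 2, 1, 0, 3, 1), 10)
  r1 <- d_minus2(base)
  r2 <- d_minus2(spiked)
  expect_equal(r1$d_minus2, r2$d_minus2, tolerance = 1e-12)
  expect_equal(r1$variance, r2$variance, tolerance = 1e-12)
  expect_error(d_minus2(sfs(c(5, 3, 1, 0, 0, 0, 0, 0, 0), 10)),
               "insufficient")
})

test_that("analytic D-2 numerator variance matches simulation", {
  set.seed(17)
  for (n in c(10, 50)) {
    theta <- 10; reps <- 30000
    eta <- mutsfs:::.cpp_sim_linked_spectra(n, theta, reps, 0)
    num <- apply(eta, 2, function(e) {
      th <- theta_estimators_minus2(sfs(e, n))
      th[1] - th[2]
    })
    v_emp <- var(num)
    se_v <- sd((num - mean(num))^2) / sqrt(reps)
    expect_lt(abs(v_emp - var_d_minus2_numerator(theta, n)), 3 * se_v)
  }
})

test_that("null simulation is reproducible and behaves like the analytics", {
  n1 <- simulate_null_d(20, 20, 5, seed = 3)
  n2 <- simulate_null_d(20, 20, 5, seed = 3)
  expect_identical(n1, n2)
  nd <- simulate_null_d(10, 20, 5000, seed = 5)
  # mean D near a small negative value
  expect_lt(abs(mean(nd$d, na.rm = TRUE)), 0.15)
  # D-2 close to centred as well
  expect_lt(abs(mean(nd$d_minus2, na.rm = TRUE)), 0.2)
})

test_that("group comparison separates shifted groups", {
  x <- c(-2.0, -2.01, -1.99, -2.02)
  y <- c(-1.0, -1.01, -0.99, -1.02, -1.0)
  g <- group_comparison(c(x, y), c(rep(TRUE, 4), rep(FALSE, 5)))
  expect_equal(g$group_mean, mean(x))
  expect_equal(g$nongroup_mean, mean(y))
  expect_lt(g$p_value, 1e-6)
  expect_error(group_comparison(rep(1, 6), rep(c(TRUE, FALSE), 3)),
               "degenerate")
  expect_error(group_comparison(1:5, c(TRUE, rep(FALSE, 4))), ">= 2")
})

test_that("correlations recover exact linear relations", {
  x <- 1:10
  expect_equal(unname(correlate(x, 2 * x)["rho"]), 1)
  expect_equal(unname(correlate(x, -x + 5)["rho"]), -1)
  expect_equal(unname(correlate(x, x^3, method = "spearman")["rho"]), 1)
  expect_error(correlate(rep(1, 5), 1:5), "zero-variance")
})
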