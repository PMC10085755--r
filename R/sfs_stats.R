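harmonic <- function(n, p = 1) sum(1 / seq_len(n)^p)

#' Tajima's D for an unfolded spectrum
#'
#' Compares Watterson's estimator `theta_W = S / h_n` with the pairwise
#' estimator `theta_pi = choose(n,2)^-1 sum eta_i i (n-i)`, standardized by
#' the classical variance estimate `Var = e1 S + e2 S (S-1)`.  An excess of
#' rare variants (population growth, purifying selection) drives D negative;
#' an excess of intermediate-frequency variants (gBGC, balancing selection)
#' drives it positive.
#'
#' @param afs an `sfs` with S >= 2 and n >= 4.
#' @return list of class `tajimas_d`: `theta_w`, `theta_pi`, `variance`, `d`.
#' @export
tajimas_d <- function(afs) {
  n <- sfs_n(afs)
  S <- sfs_S(afs)
  if (n < 4) stop("Tajima's D needs n >= 4")
  if (S < 2) stop("insufficient segregating sites (S < 2)")
  i <- seq_len(n - 1)
  a1 <- harmonic(n - 1)
  a2 <- harmonic(n - 1, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  theta_w <- S / a1
  theta_pi <- sum(as.numeric(afs) * i * (n - i)) / choose(n, 2)
  v <- e1 * S + e2 * S * (S - 1)
  structure(list(theta_w = theta_w, theta_pi = theta_pi, variance = v,
                 d = (theta_pi - theta_w) / sqrt(v)),
            class = "tajimas_d")
}

#' @export
print.tajimas_d <- function(x, ...) {
  cat(sprintf("theta_W = %.4f  theta_pi = %.4f  D = %.4f\n",
              x$theta_w, x$theta_pi, x$d))
  invisible(x)
}

#' Singleton/doubleton-free theta estimators
#'
#' Removes the `eta_1` and `eta_2` contributions from the pairwise and
#' Watterson estimators and reweights so both remain unbiased for theta
#' under the neutral constant-size coalescent (`E[eta_i] = theta / i`):
#' `theta_pi-2 = n(n-1)/((n-2)(n-3)) * choose(n,2)^-1 *
#'   (sum eta_i i(n-i) - eta_1 (n-1) - 2 eta_2 (n-2))` and
#' `theta_W-2 = (S - eta_1 - eta_2) / (h_n - 3/2)`.  Both depend only on
#' `eta_3 ... eta_{n-1}`.
#'
#' @param afs an `sfs` with n >= 6.
#' @return named vector `(theta_pi_minus2, theta_w_minus2)`.
#' @export
theta_estimators_minus2 <- function(afs) {
  n <- sfs_n(afs)
  if (n < 6) stop("minus-2 estimators need n >= 6")
  i <- seq_len(n - 1)
  eta <- as.numeric(afs)
  pre <- n * (n - 1) / ((n - 2) * (n - 3))
  theta_pi2 <- pre / choose(n, 2) *
    (sum(eta * i * (n - i)) - eta[1] * (n - 1) - 2 * eta[2] * (n - 2))
  theta_w2 <- (sum(eta) - eta[1] - eta[2]) / (harmonic(n - 1) - 1.5)
  c(theta_pi_minus2 = theta_pi2, theta_w_minus2 = theta_w2)
}

# per-n cache for the quadratic covariance coefficients
.sigma_cache <- new.env(parent = emptyenv())

#' Second-order covariance coefficients of unfolded spectrum entries
#'
#' Under the neutral constant-size coalescent (one non-recombining locus,
#' infinite sites), `Var(eta_i) = theta/i + sigma_ii theta^2` and
#' `Cov(eta_i, eta_j) = sigma_ij theta^2` (Fu 1995).  The full matrix
#' satisfies `sum_ij sigma_ij = a2 = sum 1/i^2`, which recovers the
#' classical variance of S.
#'
#' @param n haploid sample size, `4 <= n <= cap`.
#' @param cap guard against accidentally huge allocations (default 2000).
#' @return symmetric `(n-1) x (n-1)` matrix of `sigma_ij`.
#' @export
fu_covariance_matrix <- function(n, cap = 2000) {
  if (n < 4) stop("need n >= 4")
  if (n > cap) stop("n exceeds the stability cap (", cap, ")")
  key <- as.character(n)
  if (!is.null(.sigma_cache[[key]])) return(.sigma_cache[[key]])
  an <- harmonic(n - 1)
  an1 <- harmonic(n)
  ai <- c(0, cumsum(1 / seq_len(n - 1)))  # ai[i] = a_i = sum_{k=1}^{i-1} 1/k
  beta <- function(i) {
    2 * n / ((n - i + 1) * (n - i)) * (an1 - ai[i]) - 2 / (n - i)
  }
  sig <- matrix(0, n - 1, n - 1)
  for (i in seq_len(n - 1)) {
    for (j in seq_len(i)) {
      if (i == j) {
        v <- if (2 * i < n) {
          beta(i + 1)
        } else if (2 * i == n) {
          2 * (an - ai[i]) / (n - i) - 1 / i^2
        } else {
          beta(i) - 1 / i^2
        }
      } else {
        # here i > j
        v <- if (i + j < n) {
          (beta(i + 1) - beta(i)) / 2
        } else if (i + j == n) {
          (an - ai[i]) / (n - i) + (an - ai[j]) / (n - j) -
            (beta(i) + beta(j + 1)) / 2 - 1 / (i * j)
        } else {
          (beta(j) - beta(j + 1)) / 2 - 1 / (i * j)
        }
      }
      sig[i, j] <- v
      sig[j, i] <- v
    }
  }
  .sigma_cache[[key]] <- sig
  sig
}

#' The D-2 statistic: Tajima's D without singletons and doubletons
#'
#' Standardizes `theta_pi-2 - theta_w-2` by an analytic variance obtained
#' from the neutral-coalescent first and second moments of the spectrum.
#' Writing the numerator as `sum_{i>=3} c_i eta_i`, the variance is
#' `theta * sum c_i^2 / i + theta^2 * sum_ij c_i c_j sigma_ij`, with theta
#' and theta^2 replaced by unbiased plug-ins built from the
#' singleton/doubleton-free count `S-2 = S - eta_1 - eta_2`:
#' `theta_hat = S-2 / (h_n - 3/2)` and
#' `theta2_hat = S-2 (S-2 - 1) / ((h_n - 3/2)^2 + sum_{i,j>=3} sigma_ij)`.
#' By construction the statistic is exactly invariant to `eta_1`, `eta_2`.
#'
#' @param afs an `sfs` with n >= 6 and `S - eta_1 - eta_2 >= 2`.
#' @return list of class `d_minus2`: `theta_pi_minus2`, `theta_w_minus2`,
#'   `variance`, `d_minus2`.
#' @export
d_minus2 <- function(afs) {
  n <- sfs_n(afs)
  if (n < 6) stop("D-2 needs n >= 6")
  eta <- as.numeric(afs)
  S2 <- sum(eta) - eta[1] - eta[2]
  if (S2 < 2) stop("insufficient segregating sites beyond doubletons (S-2 < 2)")
  th <- theta_estimators_minus2(afs)
  hn2 <- harmonic(n - 1) - 1.5
  i <- 3:(n - 1)
  c_pi <- 2 * i * (n - i) / ((n - 2) * (n - 3))
  c_w <- rep(1 / hn2, length(i))
  ci <- c_pi - c_w
  sig <- fu_covariance_matrix(n)[i, i, drop = FALSE]
  theta_hat <- S2 / hn2
  theta2_hat <- S2 * (S2 - 1) / (hn2^2 + sum(sig))
  v <- theta_hat * sum(ci^2 / i) +
    theta2_hat * as.numeric(t(ci) %*% sig %*% ci)
  if (v < 1e-12) stop("degenerate variance estimate for D-2 (", v, ")")
  structure(list(theta_pi_minus2 = unname(th[1]),
                 theta_w_minus2 = unname(th[2]),
                 variance = v,
                 d_minus2 = unname(th[1] - th[2]) / sqrt(v)),
            class = "d_minus2")
}

#' @export
print.d_minus2 <- function(x, ...) {
  cat(sprintf("theta_pi-2 = %.4f  theta_W-2 = %.4f  D-2 = %.4f\n",
              x$theta_pi_minus2, x$theta_w_minus2, x$d_minus2))
  invisible(x)
}

#' Analytic variance of theta_pi-2 - theta_w-2 at a known theta
#'
#' Evaluates the same quadratic form as [d_minus2()] at the true theta
#' instead of plug-in estimates; used to validate the variance against
#' simulation.
#'
#' @param theta population-scaled mutation rate of the locus.
#' @param n haploid sample size.
#' @export
var_d_minus2_numerator <- function(theta, n) {
  hn2 <- harmonic(n - 1) - 1.5
  i <- 3:(n - 1)
  ci <- 2 * i * (n - i) / ((n - 2) * (n - 3)) - 1 / hn2
  sig <- fu_covariance_matrix(n)[i, i, drop = FALSE]
  theta * sum(ci^2 / i) + theta^2 * as.numeric(t(ci) %*% sig %*% ci)
}

#' Simulate the null distribution of D and D-2
#'
#' Draws neutral constant-size (or other demography) spectra for a single
#' non-recombining locus with scaled mutation rate theta and computes both
#' statistics per replicate.  Replicates failing the statistics'
#' preconditions (too few segregating sites) yield NA and are counted.
#'
#' @param theta locus-scaled mutation rate 4*Ne*mu*L.
#' @param n haploid sample size.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param demography a demography from [demog_constant()] etc.
#' @return data.frame with columns `S`, `d`, `d_minus2`.
#' @export
simulate_null_d <- function(theta, n, reps, seed = NULL,
                            demography = demog_constant()) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  eta <- .cpp_sim_linked_spectra(n, theta, reps, demog_encode(demography))
  d <- d2 <- rep(NA_real_, reps)
  S <- colSums(eta)
  for (r in seq_len(reps)) {
    a <- sfs(eta[, r], n)
    if (S[r] >= 2) d[r] <- tajimas_d(a)$d
    if (S[r] - eta[1, r] - eta[2, r] >= 2) d2[r] <- d_minus2(a)$d_minus2
  }
  data.frame(S = S, d = d, d_minus2 = d2)
}

#' Welch two-sample comparison of a per-subtype statistic
#'
#' Compares group members against non-members (e.g. WS subtypes vs the
#' rest) with an unequal-variance t-test.
#'
#' @param values numeric per-subtype statistic.
#' @param membership logical group indicator, same length.
#' @return list of class `group_comparison`: `group_mean`, `nongroup_mean`,
#'   `statistic`, `p_value`.
#' @export
group_comparison <- function(values, membership) {
  stopifnot(length(values) == length(membership))
  g <- values[membership]
  ng <- values[!membership]
  if (length(g) < 2 || length(ng) < 2) stop("need >= 2 subtypes per group")
  if (var(g) + var(ng) < 1e-24) stop("degenerate variance in both groups")
  tt <- t.test(g, ng)
  structure(list(group_mean = mean(g), nongroup_mean = mean(ng),
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group %.4f vs non-group %.4f (t = %.3f, p = %.3g)\n",
              x$group_mean, x$nongroup_mean, x$statistic, x$p_value))
  invisible(x)
}

#' Correlation between two per-subtype quantities
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return named vector `(rho, p)`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) < 1e-24 || var(y) < 1e-24) stop("zero-variance input")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Per-subtype summary table of spectrum statistics
#'
#' Computes, for every subtype with enough data, theta_W, theta_pi, D,
#' theta_pi-2, theta_W-2, D-2, the singleton/doubleton ratio and the rare
#' proportions.  Subtypes failing a statistic's precondition get NA there.
#'
#' @param spectra a `subtype_spectra` object.
#' @return data.frame with one row per subtype.
#' @export
subtype_statistics <- function(spectra) {
  st <- enumerate_subtypes()
  rows <- lapply(seq_len(nrow(st)), function(k) {
    a <- sfs(spectra$counts[k, ], spectra$n)
    S <- sfs_S(a)
    out <- data.frame(subtype = st$subtype[k], gbgc = st$gbgc[k],
                      cpg = st$cpg[k], S = S,
                      theta_w = NA_real_, theta_pi = NA_real_, d = NA_real_,
                      theta_pi_minus2 = NA_real_, theta_w_minus2 = NA_real_,
                      d_minus2 = NA_real_, eta1_eta2 = NA_real_,
                      p1 = NA_real_, p2 = NA_real_, p3 = NA_real_)
    if (S >= 2) {
      td <- tajimas_d(a)
      out$theta_w <- td$theta_w; out$theta_pi <- td$theta_pi; out$d <- td$d
    }
    if (S - a[1] - a[2] >= 2) {
      d2 <- d_minus2(a)
      out$theta_pi_minus2 <- d2$theta_pi_minus2
      out$theta_w_minus2 <- d2$theta_w_minus2
      out$d_minus2 <- d2$d_minus2
    }
    if (a[2] > 0) out$eta1_eta2 <- singleton_doubleton_ratio(a)
    if (S > 0) {
      p <- rare_proportions(a)
      out$p1 <- p[1]; out$p2 <- p[2]; out$p3 <- p[3]
    }
    out
  })
  do.call(rbind, rows)
}
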