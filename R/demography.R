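#' Demographic models for a single population
#'
#' Time is backwards from the present in units of 2*Ne generations, where Ne
#' is the ancestral effective size; sizes are ratios to Ne.
#'
#' * `demog_constant()`: constant size Ne.
#' * `demog_growth(T0, lambda)`: size lambda*Ne today, exponential change
#'   back to Ne at time T0, constant earlier.
#' * `demog_three_epoch(T1, T2, lambda1, lambda2)`: size lambda2*Ne for the
#'   last T2, a bottleneck at lambda1*Ne (`0 < lambda1 <= 1`) for the T1
#'   before that, ancestral size Ne earlier.
#'
#' @param T0,T1,T2 epoch durations (2*Ne generations), all `>= 0`.
#' @param lambda,lambda2 present/recovery size ratios, `> 0`.
#' @param lambda1 bottleneck depth in `(0, 1]`.
#' @return list of class `demography`.
#' @export
demog_constant <- function() {
  structure(list(family = "constant"), class = "demography")
}

#' @rdname demog_constant
#' @export
demog_growth <- function(T0, lambda) {
  stopifnot(T0 >= 0, lambda > 0)
  structure(list(family = "growth", T0 = T0, lambda = lambda),
            class = "demography")
}

#' @rdname demog_constant
#' @export
demog_three_epoch <- function(T1, T2, lambda1, lambda2) {
  stopifnot(T1 >= 0, T2 >= 0, lambda1 > 0, lambda1 <= 1, lambda2 > 0)
  structure(list(family = "three_epoch", T1 = T1, T2 = T2,
                 lambda1 = lambda1, lambda2 = lambda2),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("demography:", x$family,
      paste(sprintf("%s=%.4g", setdiff(names(x), "family"),
                    unlist(x[setdiff(names(x), "family")])), collapse = " "),
      "\n")
  invisible(x)
}

demog_encode <- function(d) {
  stopifnot(inherits(d, "demography"))
  switch(d$family,
         constant = 0,
         growth = c(1, d$T0, d$lambda),
         three_epoch = c(2, d$T1, d$T2, d$lambda1, d$lambda2))
}

#' Expected unfolded AFS under a demographic model
#'
#' Computes `xi_i = (theta/2) * sum_k k E[T_k] P(i|k)` where `E[T_k]` is the
#' expected time during which the sample has k ancestral lineages (obtained
#' by integrating the lineage-count pure-death process with coalescent
#' intensity `choose(k,2)/nu(t)`) and
#' `P(i|k) = choose(n-i-1, k-2) / choose(n-1, k-1)` is the probability that
#' a lineage present when k remain subtends i of the n leaves.  Under
#' constant size this reduces to the closed form `xi_i = theta / i`.
#'
#' @param model a `demography`.
#' @param n haploid sample size (4 <= n <= cap).
#' @param theta locus-scaled mutation rate `4*Ne*mu*L` (default 1, so the
#'   result is the spectrum shape per unit theta).
#' @param cap stability cap on n for the lineage-count integration.
#' @return numeric vector `xi_1 ... xi_{n-1}`, all positive.
#' @export
expected_afs <- function(model, n, theta = 1, cap = 200) {
  stopifnot(n >= 4)
  if (n > cap) stop("n exceeds the lineage-count integration cap (", cap, ")")
  ET <- .cpp_expected_Tk(n, demog_encode(model))  # E[T_k], k = 2..n
  if (any(!is.finite(ET))) stop("lineage-count integration failed")
  P <- subtend_probs(n)
  xi <- as.numeric(P %*% ((2:n) * ET)) * theta / 2
  if (any(xi <= 0)) stop("non-positive expected AFS entry")
  xi
}

.subtend_cache <- new.env(parent = emptyenv())

# P(i|k) = choose(n-i-1, k-2) / choose(n-1, k-1), cached per n
subtend_probs <- function(n) {
  key <- as.character(n)
  if (!is.null(.subtend_cache[[key]])) return(.subtend_cache[[key]])
  i <- seq_len(n - 1)
  k <- 2:n
  lp <- outer(i, k, function(ii, kk) {
    lchoose(n - ii - 1, kk - 2) - lchoose(n - 1, kk - 1)
  })
  P <- exp(lp)
  P[!is.finite(P)] <- 0
  .subtend_cache[[key]] <- P
  P
}

#' Monte-Carlo expected AFS from simulated genealogies
#'
#' Independent oracle for [expected_afs()]: simulates coalescent trees under
#' the demography and averages `theta/2` times the branch length subtending
#' each leaf count.
#'
#' @param model a `demography`.
#' @param n haploid sample size.
#' @param reps number of trees.
#' @param theta locus-scaled mutation rate.
#' @param seed optional seed.
#' @return list with `mean` and `se` vectors of length n - 1.
#' @export
mc_expected_afs <- function(model, n, reps, theta = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- .cpp_sim_branch_lengths(n, reps, demog_encode(model))
  m <- rowMeans(L) * theta / 2
  se <- apply(L, 1, sd) / sqrt(reps) * theta / 2
  list(mean = m, se = se)
}

#' Poisson composite log-likelihood of an observed spectrum
#'
#' `sum_i eta_i log xi_i - xi_i - log(eta_i!)`, the Poisson random-field
#' objective used for AFS fitting.
#'
#' @param observed an `sfs` (or numeric vector of counts).
#' @param expected expected counts `xi_i > 0`, same length.
#' @export
poisson_loglik <- function(observed, expected) {
  eta <- as.numeric(observed)
  if (length(eta) != length(expected)) stop("length mismatch")
  if (any(expected <= 0)) stop("expected counts must be positive")
  sum(eta * log(expected) - expected - lfactorial(eta))
}

# Bounded maximization of the profiled Poisson likelihood.  The search runs
# in shifted-log coordinates u = log(par + delta), which keeps the box
# bounds [0, upper] attainable and conditions the surface across the orders
# of magnitude that lambda spans.  A derivative-free Nelder-Mead
# search (robust to the ridged surface) is followed by a bounded
# quasi-Newton polish.
optimize_afs_loglik <- function(eta, S, n, family, start, b,
                                delta = 1e-3, polish_only = FALSE) {
  ulo <- log(b$lower + delta)
  uhi <- log(b$upper + delta)
  objective <- function(u) {
    pen <- sum(pmax(u - uhi, 0)^2 + pmax(ulo - u, 0)^2)
    par <- exp(pmin(pmax(u, ulo), uhi)) - delta
    par <- pmin(pmax(par, b$lower), b$upper)
    model <- model_from_params(family, par)
    xi1 <- tryCatch(expected_afs(model, n, theta = 1),
                    error = function(e) NULL)
    if (is.null(xi1)) return(1e10)
    -poisson_loglik(eta, S / sum(xi1) * xi1) + 1e4 * pen
  }
  if (polish_only) {
    # warm start at a previous optimum: quasi-Newton refinement suffices
    res <- tryCatch(
      optim(log(start + delta), objective, method = "L-BFGS-B",
            lower = ulo, upper = uhi,
            control = list(maxit = 200, factr = 1e6)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    par <- pmin(pmax(exp(pmin(pmax(res$par, ulo), uhi)) - delta,
                     b$lower), b$upper)
    return(list(par = setNames(par, names(b$start)), value = res$value))
  }
  nm <- tryCatch(
    optim(log(start + delta), objective, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(nm)) return(NULL)
  res <- tryCatch(
    optim(pmin(pmax(nm$par, ulo), uhi), objective, method = "L-BFGS-B",
          lower = ulo, upper = uhi,
          control = list(maxit = 500, factr = 1e4)),
    error = function(e) NULL)
  if (is.null(res) || res$value > nm$value) res <- nm
  par <- pmin(pmax(exp(pmin(pmax(res$par, ulo), uhi)) - delta,
                   b$lower), b$upper)
  list(par = setNames(par, names(b$start)), value = res$value)
}

model_from_params <- function(family, par) {
  if (family == "growth") demog_growth(T0 = par[1], lambda = par[2])
  else demog_three_epoch(T1 = par[1], T2 = par[2],
                         lambda1 = par[3], lambda2 = par[4])
}

fit_bounds <- function(family) {
  if (family == "growth") {
    list(lower = c(T0 = 0, lambda = 1e-3),
         upper = c(T0 = 10, lambda = 750),
         start = c(T0 = 3, lambda = 150))
  } else {
    list(lower = c(T1 = 0, T2 = 0, lambda1 = 1e-3, lambda2 = 1e-3),
         upper = c(T1 = 10, T2 = 10, lambda1 = 1, lambda2 = 150),
         start = c(T1 = 0.1, T2 = 0.5, lambda1 = 0.3, lambda2 = 10))
  }
}

#' Fit a demographic model to an observed spectrum
#'
#' Maximizes the Poisson composite likelihood over the model's shape
#' parameters with bounded quasi-Newton search, profiling theta out
#' analytically (at the Poisson MLE, theta scales the unit-theta expected
#' spectrum so its total matches S).  The search restarts from
#' multiplicatively perturbed versions of the default starting values
#' (uniform log-factor up to 2) and keeps the best restart.
#'
#' @param afs an `sfs` with S > 0.
#' @param family `"growth"` or `"three_epoch"`.
#' @param n_restarts number of perturbed restarts (default 10).
#' @param seed optional integer seed for the perturbations.
#' @param bounds optional list with `lower`/`upper`/`start` named vectors to
#'   override the defaults (growth: T0 in 0..10, lambda in 0..750, starts
#'   (3, 150); three-epoch: T1, T2 in 0..10, lambda1 in 0..1, lambda2 in
#'   0..150, starts (0.1, 0.5, 0.3, 10)).
#' @return list of class `demographic_fit`: `family`, `params` (including
#'   the profiled theta), `loglik`, `at_boundary` flags, `restarts` trace.
#' @export
fit_model <- function(afs, family = c("growth", "three_epoch"),
                      n_restarts = 10, seed = NULL, bounds = NULL) {
  family <- match.arg(family)
  S <- sfs_S(afs)
  if (S <= 0) stop("cannot fit an empty spectrum")
  n <- sfs_n(afs)
  eta <- as.numeric(afs)
  b <- fit_bounds(family)
  if (!is.null(bounds)) b[names(bounds)] <- bounds
  if (!is.null(seed)) set.seed(seed)

  starts <- matrix(rep(b$start, n_restarts), ncol = length(b$start),
                   byrow = TRUE)
  if (n_restarts > 1) {
    fac <- matrix(exp(runif((n_restarts - 1) * length(b$start),
                            -log(2), log(2))), ncol = length(b$start))
    starts[-1, ] <- pmin(pmax(t(t(fac) * b$start), b$lower), b$upper)
  }
  colnames(starts) <- names(b$start)

  best <- NULL
  trace <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    res <- optimize_afs_loglik(eta, S, n, family, starts[r, ], b)
    trace[[r]] <- if (is.null(res)) list(start = starts[r, ], failed = TRUE)
      else list(start = starts[r, ], par = res$par, loglik = -res$value)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) stop("all restarts failed")
  par <- best$par
  model <- model_from_params(family, par)
  xi1 <- expected_afs(model, n, theta = 1)
  theta_hat <- S / sum(xi1)
  at_bound <- par <= b$lower + 1e-8 | par >= b$upper - 1e-8
  structure(list(family = family,
                 params = c(theta = theta_hat, par),
                 loglik = -best$value,
                 model = model,
                 n = n, S = S,
                 at_boundary = at_bound,
                 restarts = trace),
            class = "demographic_fit")
}

#' @export
print.demographic_fit <- function(x, ...) {
  cat("demographic fit (", x$family, "), loglik = ",
      sprintf("%.3f", x$loglik), "\n", sep = "")
  print(round(x$params, 5))
  if (any(x$at_boundary)) {
    cat("note: parameters at bounds:",
        paste(names(x$at_boundary)[x$at_boundary], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a fit to natural scales
#'
#' `Ne = theta / (4 mu_abs L)` (theta is the sequence-total scaled mutation
#' rate `4 Ne mu L`) and times in generations are the diffusion-scaled times
#' multiplied by `2 Ne`.
#'
#' @param fit a `demographic_fit`.
#' @param mu_abs per-site per-generation mutation rate.
#' @param L number of mutational target sites.
#' @return list with `Ne` and `times_generations`.
#' @export
derive_scales <- function(fit, mu_abs, L) {
  stopifnot(mu_abs > 0, L > 0)
  Ne <- unname(fit$params["theta"]) / (4 * mu_abs * L)
  tpar <- grep("^T", names(fit$params), value = TRUE)
  times <- fit$params[tpar] * 2 * Ne
  if (fit$family == "three_epoch") {
    times <- c(times, T_total = unname(sum(fit$params[c("T1", "T2")])) * 2 * Ne)
  }
  list(Ne = Ne, times_generations = times)
}

#' Bootstrap standard errors for a demographic fit
#'
#' Multinomially resamples the observed spectrum B times, refits each
#' resample from the fitted optimum (single start), and reports the sample
#' standard deviation of each parameter.  Failed refits are counted; more
#' than 20% failures is an error.
#'
#' @param afs the observed `sfs`.
#' @param fit the `demographic_fit` to perturb around.
#' @param B number of bootstrap resamples (default 100).
#' @param seed optional integer seed.
#' @return list with `se` (named vector, including theta), `estimates`
#'   (B x p matrix) and `failures`.
#' @export
bootstrap_se <- function(afs, fit, B = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- fit_bounds(fit$family)
  start <- fit$params[names(b$start)]
  n <- sfs_n(afs)
  ests <- matrix(NA_real_, B, length(fit$params),
                 dimnames = list(NULL, names(fit$params)))
  fails <- 0L
  for (r in seq_len(B)) {
    res <- tryCatch({
      boot <- bootstrap_resample(afs)
      S <- sfs_S(boot)
      eta <- as.numeric(boot)
      o <- optimize_afs_loglik(eta, S, n, fit$family, start, b,
                               polish_only = TRUE)
      if (is.null(o)) stop("refit failed")
      xi1 <- expected_afs(model_from_params(fit$family, o$par), n, theta = 1)
      c(theta = S / sum(xi1), o$par)
    }, error = function(e) NULL)
    if (is.null(res)) fails <- fails + 1L else ests[r, ] <- res
  }
  if (fails > 0.2 * B) {
    stop("bootstrap refit failure rate too high (", fails, "/", B, ")")
  }
  list(se = apply(ests, 2, sd, na.rm = TRUE), estimates = ests,
       failures = fails)
}
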