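#' Tile the genome into windows and tally per-subtype variant counts
#'
#' Variants are optionally restricted to a BED-style mask (0-based
#' half-open intervals, e.g. intergenic regions) before windowing.  Windows
#' tile each contig from 0 in steps of `window_size`; a short terminal
#' window is flagged and excluded by default, as are windows with fewer
#' than `min_s` segregating sites (local spectrum statistics are unstable
#' below that).
#'
#' @param variants classified-variant data.frame (`chrom`, `pos` 1-based,
#'   `subtype`, `derived_count`, `sample_n`).
#' @param contig_lengths named integer vector of contig lengths.
#' @param mask optional data.frame `chrom`, `start`, `end` (0-based
#'   half-open) of regions to keep.
#' @param window_size window width in bp (default 100 kb).
#' @param min_s minimum local segregating sites (default 10).
#' @param drop_short exclude short terminal windows (default TRUE).
#' @return list of class `region_windows`: `windows` (data.frame with
#'   `chrom`, `start`, `end`, `S`, `short`, `excluded`), `counts`
#'   (windows x 96 subtype counts), `afs` (windows x (n-1) local spectra)
#'   and `n`.
#' @export
make_windows <- function(variants, contig_lengths, mask = NULL,
                         window_size = 1e5, min_s = 10, drop_short = TRUE) {
  stopifnot(!is.null(names(contig_lengths)))
  n <- unique(variants$sample_n)
  if (length(n) != 1) stop("all variants must share one sample size")
  bad <- variants$pos > contig_lengths[variants$chrom]
  if (any(is.na(bad)) || any(bad)) {
    stop("variant beyond contig length (or unknown contig)")
  }
  if (!is.null(mask)) variants <- mask_variants(variants, mask)

  win <- do.call(rbind, lapply(names(contig_lengths), function(ch) {
    len <- contig_lengths[[ch]]
    start <- seq(0, len - 1, by = window_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + window_size, len))
  }))
  win$short <- (win$end - win$start) < window_size
  st <- enumerate_subtypes()
  counts <- matrix(0, nrow(win), nrow(st),
                   dimnames = list(NULL, st$subtype))
  afs <- matrix(0, nrow(win), n - 1)
  if (nrow(variants) > 0) {
    # VCF pos is 1-based: site pos occupies 0-based coordinate pos - 1
    wid <- match(
      paste(variants$chrom, (variants$pos - 1) %/% window_size),
      paste(win$chrom, win$start %/% window_size))
    tab <- table(factor(wid, levels = seq_len(nrow(win))),
                 factor(variants$subtype, levels = st$subtype))
    counts <- counts + unclass(tab)
    fab <- table(factor(wid, levels = seq_len(nrow(win))),
                 factor(variants$derived_count, levels = seq_len(n - 1)))
    afs <- afs + unclass(fab)
  }
  win$S <- rowSums(afs)
  win$excluded <- (drop_short & win$short) | win$S < min_s
  rownames(win) <- NULL
  structure(list(windows = win, counts = counts, afs = afs, n = n),
            class = "region_windows")
}

#' Restrict variants to a BED-style mask
#' @param variants classified-variant data.frame.
#' @param mask data.frame `chrom`, `start`, `end`, 0-based half-open.
#' @export
mask_variants <- function(variants, mask) {
  keep <- logical(nrow(variants))
  for (ch in unique(variants$chrom)) {
    iv <- mask[mask$chrom == ch, , drop = FALSE]
    vi <- which(variants$chrom == ch)
    if (nrow(iv) == 0 || length(vi) == 0) next
    iv <- iv[order(iv$start), , drop = FALSE]
    p0 <- variants$pos[vi] - 1  # 0-based site coordinate
    idx <- findInterval(p0, iv$start)
    ok <- idx >= 1 & p0 < iv$end[pmax(idx, 1)]
    keep[vi[ok]] <- TRUE
  }
  variants[keep, , drop = FALSE]
}

#' @export
print.region_windows <- function(x, ...) {
  cat("region windows:", nrow(x$windows), "windows,",
      sum(!x$windows$excluded), "retained, n =", x$n, "\n")
  invisible(x)
}

#' Flag subtype abundance in windows
#'
#' For each subtype, windows are ranked by the subtype's proportion of the
#' local segregating sites; the top `ceiling(top_fraction * W)` windows are
#' flagged abundant (ties broken by window order).  `n_abundant` is the
#' per-window count of abundant subtypes out of 96.
#'
#' @param rw a `region_windows` object.
#' @param top_fraction fraction of windows to flag (default 0.1).
#' @return list with `flags` (retained-windows x 96 logical matrix),
#'   `n_abundant` (vector over retained windows) and `window_index` (row
#'   indices of retained windows in `rw$windows`).
#' @export
abundance_flags <- function(rw, top_fraction = 0.1) {
  keep <- which(!rw$windows$excluded)
  if (length(keep) < 10) stop("need >= 10 retained windows")
  counts <- rw$counts[keep, , drop = FALSE]
  S <- rw$windows$S[keep]
  prop <- counts / S
  W <- length(keep)
  m <- ceiling(top_fraction * W)
  flags <- matrix(FALSE, W, ncol(counts), dimnames = dimnames(counts))
  zero <- colSums(counts) == 0
  if (any(zero)) {
    warning(sum(zero), " subtypes absent from all windows: no flags for them")
  }
  for (j in which(!zero)) {
    ord <- order(-prop[, j])
    flags[ord[seq_len(m)], j] <- TRUE
  }
  list(flags = flags, n_abundant = rowSums(flags), window_index = keep)
}

#' Composition-weighted expected statistic for windows
#'
#' The expected value of a local spectrum statistic in a window is the mean
#' of the 96 genome-wide per-subtype values weighted by the window's
#' subtype counts.  Subtypes whose genome-wide value is NA are dropped from
#' both numerator and denominator.
#'
#' @param weights numeric vector (one window) or matrix (windows x 96) of
#'   subtype counts.
#' @param stat_gw genome-wide per-subtype statistic values (length 96).
#' @return expected statistic per window.
#' @export
expected_statistic <- function(weights, stat_gw) {
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1)
  stopifnot(ncol(weights) == length(stat_gw))
  ok <- !is.na(stat_gw)
  num <- weights[, ok, drop = FALSE] %*% stat_gw[ok]
  den <- rowSums(weights[, ok, drop = FALSE])
  if (any(den <= 0)) stop("window with no usable subtype counts")
  as.numeric(num / den)
}

#' Observed and expected local spectrum statistics per window
#'
#' Computes Tajima's D and rare proportions from each retained window's
#' local spectrum, and their composition-weighted expectations from the
#' genome-wide per-subtype statistics.
#'
#' @param rw a `region_windows` object.
#' @param gw_stats per-subtype statistics table from [subtype_statistics()]
#'   (rows ordered like [enumerate_subtypes()]).
#' @return data.frame (one row per retained window) with window
#'   coordinates, S, observed `d`, `p1`, `p2`, `p3`, expected `d_exp`,
#'   `p1_exp`, `p2_exp`, `p3_exp`.
#' @export
window_statistics <- function(rw, gw_stats) {
  keep <- which(!rw$windows$excluded)
  win <- rw$windows[keep, c("chrom", "start", "end", "S")]
  afs <- rw$afs[keep, , drop = FALSE]
  counts <- rw$counts[keep, , drop = FALSE]
  obs <- t(apply(afs, 1, function(eta) {
    a <- sfs(eta, rw$n)
    d <- if (sum(eta) >= 2) tajimas_d(a)$d else NA_real_
    c(d = d, rare_proportions(a))
  }))
  win$d <- obs[, "d"]
  win$p1 <- obs[, "p1"]; win$p2 <- obs[, "p2"]; win$p3 <- obs[, "p3"]
  win$d_exp <- expected_statistic(counts, gw_stats$d)
  win$p1_exp <- expected_statistic(counts, gw_stats$p1)
  win$p2_exp <- expected_statistic(counts, gw_stats$p2)
  win$p3_exp <- expected_statistic(counts, gw_stats$p3)
  rownames(win) <- NULL
  win
}

#' Mean abundance by quantile of a window statistic
#'
#' Ranks retained windows by a statistic, splits them into equal-count
#' quantiles, and reports the mean number of abundant subtypes per
#' quantile, optionally stratified by a partition of the 96 subtypes
#' (e.g. gBGC category or rate class).  Stratified means sum to the
#' unstratified mean by construction.
#'
#' @param statistic numeric vector over retained windows.
#' @param flags abundance flag matrix from [abundance_flags()].
#' @param n_quantiles number of equal-count quantiles (10 or 20 typical).
#' @param strata optional factor/character vector of length 96 labelling
#'   each subtype's stratum.
#' @return data.frame with `quantile`, `n_windows`, `mean_n_abundant`, and
#'   one `mean_<stratum>` column per stratum.
#' @export
quantile_summary <- function(statistic, flags, n_quantiles = 10,
                             strata = NULL) {
  W <- length(statistic)
  stopifnot(nrow(flags) == W)
  if (W < n_quantiles) stop("fewer windows than quantiles")
  rk <- rank(statistic, ties.method = "first")
  qid <- ceiling(rk * n_quantiles / W)
  out <- data.frame(quantile = seq_len(n_quantiles),
                    n_windows = as.integer(table(factor(qid,
                      levels = seq_len(n_quantiles)))))
  nab <- rowSums(flags)
  out$mean_n_abundant <- tapply(nab, qid, mean)[as.character(out$quantile)]
  if (!is.null(strata)) {
    stopifnot(length(strata) == ncol(flags))
    for (s in sort(unique(strata))) {
      cnt <- rowSums(flags[, strata == s, drop = FALSE])
      out[[paste0("mean_", s)]] <-
        tapply(cnt, qid, mean)[as.character(out$quantile)]
    }
  }
  rownames(out) <- NULL
  out
}

#' Gaussian GEE with exchangeable working correlation
#'
#' Fits `y = X beta` by iterated generalized least squares with an
#' exchangeable working correlation within clusters (moment estimator of
#' rho from standardized residuals, scale estimated with a degrees-of-
#' freedom correction) and reports cluster-robust sandwich standard
#' errors.  With `rho` fixed at 0 the coefficients equal ordinary least
#' squares exactly.
#'
#' @param y response vector (one observation per window).
#' @param X covariate matrix (an intercept column is added).
#' @param cluster cluster labels (e.g. chromosome per window).
#' @param rho NULL to estimate, or a fixed value.
#' @param max_iter,tol iteration controls.
#' @return list of class `gee_fit`: `coefficients`, `robust_se`, `rho`,
#'   `scale`, `iterations`, `converged`.
#' @export
gee_fit <- function(y, X, cluster, rho = NULL, max_iter = 100, tol = 1e-8) {
  X <- cbind("(Intercept)" = 1, as.matrix(X))
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X")
  N <- length(y)
  p <- ncol(X)
  cluster <- as.character(cluster)
  if (length(unique(cluster)) < 2) stop("need >= 2 clusters")
  idx <- split(seq_len(N), cluster)
  if (qr(X)$rank < p) stop("singular design matrix")

  beta <- qr.solve(X, y)
  est_rho <- is.null(rho)
  rho_hat <- if (est_rho) 0 else rho
  converged <- FALSE
  it <- 0
  phi <- 1
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    phi <- sum(r^2) / (N - p)
    if (est_rho) {
      e <- r / sqrt(phi)
      num <- 0; den <- 0
      for (ii in idx) {
        ni <- length(ii)
        if (ni < 2) next
        ei <- e[ii]
        num <- num + (sum(ei)^2 - sum(ei^2)) / 2
        den <- den + ni * (ni - 1) / 2
      }
      rho_hat <- num / (den - p)
      nmax <- max(lengths(idx))
      rho_hat <- max(min(rho_hat, 0.999), -1 / (nmax - 1) + 1e-6)
    }
    # GLS step with V_c = phi * ((1 - rho) I + rho J), Woodbury inverse
    A <- matrix(0, p, p)
    bvec <- numeric(p)
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]
      yi <- y[ii]
      ni <- length(ii)
      f <- rho_hat / (1 + (ni - 1) * rho_hat)
      Vi_X <- (Xi - f * matrix(colSums(Xi), ni, p, byrow = TRUE)) /
        (phi * (1 - rho_hat))
      A <- A + crossprod(Xi, Vi_X)
      bvec <- bvec + crossprod(Vi_X, yi)
    }
    beta_new <- solve(A, bvec)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (!converged && max_iter > 1) {
    stop("GEE did not converge in ", max_iter, " iterations")
  }
  # sandwich covariance clustered on the working correlation
  r <- y - X %*% beta
  A <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ii in idx) {
    Xi <- X[ii, , drop = FALSE]
    ri <- r[ii]
    ni <- length(ii)
    f <- rho_hat / (1 + (ni - 1) * rho_hat)
    Vi_X <- (Xi - f * matrix(colSums(Xi), ni, p, byrow = TRUE)) /
      (phi * (1 - rho_hat))
    A <- A + crossprod(Xi, Vi_X)
    u <- crossprod(Vi_X, ri)
    M <- M + tcrossprod(u)
  }
  Ainv <- solve(A)
  cov <- Ainv %*% M %*% Ainv
  se <- sqrt(diag(cov))
  structure(list(coefficients = setNames(as.numeric(beta), colnames(X)),
                 robust_se = setNames(se, colnames(X)),
                 vcov = cov,
                 rho = rho_hat, scale = phi,
                 n_clusters = length(idx),
                 iterations = it, converged = converged),
            class = "gee_fit")
}

#' Cluster-robust confidence intervals for a GEE fit
#'
#' Uses a t critical value with (clusters - 1) degrees of freedom rather
#' than the normal quantile: with a modest number of clusters (22
#' chromosomes, say) sandwich standard errors are known to run small, and
#' the t correction is the standard remedy.
#'
#' @param fit a [gee_fit()] result.
#' @param level confidence level (default 0.95).
#' @return matrix with columns `lower`, `upper` (rows = coefficients).
#' @export
gee_confint <- function(fit, level = 0.95) {
  crit <- qt(1 - (1 - level) / 2, df = fit$n_clusters - 1)
  cbind(lower = fit$coefficients - crit * fit$robust_se,
        upper = fit$coefficients + crit * fit$robust_se)
}

#' @export
print.gee_fit <- function(x, ...) {
  tab <- data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                    z = x$coefficients / x$robust_se)
  tab$p <- 2 * pnorm(-abs(tab$z))
  print(round(tab, 5))
  cat(sprintf("working rho = %.4f, scale = %.4f (%d iterations)\n",
              x$rho, x$scale, x$iterations))
  invisible(x)
}
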