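# Monte Carlo comparison of the efficiency estimators: the same noisy point
# sets are analyzed by the direct fit, the naive independent-differences fit
# and the weighted pairwise ratio estimator, and the *apparent* precision
# (a priori SEs) is confronted with the *actual* precision (ensemble SD of
# the point estimates across simulations).

#' Monte Carlo study configuration
#'
#' @param design A [point_design()].
#' @param n_sim Number of simulated replicate sets (default `4e4`,
#'   `>= 100`).
#' @param seed Integer RNG seed (required).
#' @param estimators Subset of `c("direct", "naive_diffs",
#'   "pairwise_ratio")`.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(design = point_design(), n_sim = 4e4, seed,
                      estimators = c("direct", "naive_diffs",
                                     "pairwise_ratio")) {
  stopifnot(inherits(design, "point_design"), n_sim >= 100)
  if (missing(seed)) stop("a seed is required")
  estimators <- match.arg(estimators, several.ok = TRUE)
  structure(list(design = design, n_sim = as.integer(n_sim), seed = seed,
                 estimators = estimators), class = "mc_config")
}

#' Run the apparent-vs-actual precision comparison
#'
#' For every simulated noisy replicate of the design, each requested
#' estimator is run on the *same* data.  Per estimator the result carries
#' the vector of point estimates `E`, the vector of apparent (a priori)
#' SEs, their variance-scale average `mean_apparent_se = sqrt(mean(se^2))`
#' (unbiased on the variance scale, unlike the plain mean of SEs), the
#' ensemble `actual_sd` of the point estimates, and
#' `sd_ratio = actual_sd / mean_apparent_se` — the factor by which the
#' apparent precision overstates reality.  For a statistically sound
#' estimator `sd_ratio` is near 1; for estimators built on correlated
#' pairwise data it is well above 1.
#'
#' The pairwise estimator's weights use the per-set direct-fit `s_y` as the
#' noise scale, so each replicate analysis is fully self-contained.
#' Non-convergent fits are dropped and counted; more than 1% of them is a
#' hard error (design too noisy for a meaningful comparison).
#'
#' @param config An [mc_config()].
#' @return An object of class `mc_result`: per-estimator lists plus
#'   `sd_pairs_over_direct`, the ratio of the pairwise estimator's actual
#'   SD to the direct fit's.
#' @export
run_mc_comparison <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  des <- config$design
  sims <- simulate_points(des, n_sim = config$n_sim, seed = config$seed)
  lay <- des$layout
  n <- nrow(lay)
  x <- lay$x; j <- lay$j; D <- des$D
  want <- config$estimators
  # fixed pair structure shared by all replicates
  cb <- utils::combn(n, 2L)
  pa <- cb[1L, ]; pb <- cb[2L, ]
  # ratio pairs: orient by cycle, drop equal cycles
  swap <- x[pa] > x[pb]
  ri <- ifelse(swap, pb, pa); rj <- ifelse(swap, pa, pb)
  keep <- x[ri] != x[rj]
  ri <- ri[keep]; rj <- rj[keep]
  rdx <- x[rj] - x[ri]
  rdj <- j[rj] - j[ri]
  res <- list()
  for (nm in c("direct", "naive_diffs", "pairwise_ratio"))
    res[[nm]] <- list(E = rep(NA_real_, config$n_sim),
                      se = rep(NA_real_, config$n_sim))
  n_fail <- 0L
  need_direct <- "direct" %in% want || "pairwise_ratio" %in% want
  for (i in seq_len(config$n_sim)) {
    y <- sims$y[i, ]
    dfit <- NULL
    if (need_direct) {
      dfit <- tryCatch({
        start <- .exp_init(x, j, y, D)
        fit <- .lm_engine(start,
          resid_fn = function(th) y - .exp_predict(th, x, j, D),
          jac_fn = function(th) .exp_jacobian(th, x, j, D))
        .new_exp_fit(fit, n_obs = n, method = "direct")
      }, error = function(e) NULL)
      if (is.null(dfit) || !dfit$converged) { n_fail <- n_fail + 1L; next }
      if ("direct" %in% want) {
        res$direct$E[i] <- dfit$E_hat
        res$direct$se[i] <- dfit$se_E
      }
    }
    if ("naive_diffs" %in% want) {
      d <- y[pa] - y[pb]
      nfit <- tryCatch({
        start <- .exp_init(x, j, y, D)
        fit <- .lm_engine(start,
          resid_fn = function(th) {
            f <- .exp_predict(th, x, j, D); d - (f[pa] - f[pb])
          },
          jac_fn = function(th) {
            Jf <- .exp_jacobian(th, x, j, D)
            Jf[pa, , drop = FALSE] - Jf[pb, , drop = FALSE]
          })
        .new_exp_fit(fit, n_obs = length(d), method = "naive_differences")
      }, error = function(e) NULL)
      if (is.null(nfit) || !nfit$converged) { n_fail <- n_fail + 1L; next }
      res$naive_diffs$E[i] <- nfit$E_hat
      res$naive_diffs$se[i] <- nfit$se_E
    }
    if ("pairwise_ratio" %in% want) {
      if (any(y[ri] <= 0 | y[rj] <= 0)) { n_fail <- n_fail + 1L; next }
      Z <- (log(y[rj]) - log(y[ri]) + rdj * log(D)) / rdx
      E <- exp(Z)
      sZ2 <- (dfit$s_y / rdx)^2 * (1 / y[ri]^2 + 1 / y[rj]^2)
      Eref <- mean(E)
      for (pass in 1:2) {          # one re-weighting pass with the weighted mean
        sE2 <- Eref^2 * sZ2
        w <- 1 / sE2
        Eref <- sum(w * E) / sum(w)
      }
      res$pairwise_ratio$E[i] <- Eref
      res$pairwise_ratio$se[i] <- 1 / sqrt(sum(w))
    }
  }
  if (n_fail > 0.01 * config$n_sim)
    stop(sprintf("%d of %d replicates failed to converge (> 1%%): design too noisy",
                 n_fail, config$n_sim))
  out <- list()
  for (nm in want) {
    ok <- !is.na(res[[nm]]$E)
    Ev <- res[[nm]]$E[ok]; sev <- res[[nm]]$se[ok]
    actual_sd <- stats::sd(Ev)
    mean_se <- sqrt(mean(sev^2))
    out[[nm]] <- list(E = Ev, se = sev, actual_sd = actual_sd,
                      mean_apparent_se = mean_se,
                      sd_ratio = actual_sd / mean_se, n_used = sum(ok))
  }
  sd_pairs_over_direct <- if (all(c("direct", "pairwise_ratio") %in% want))
    out$pairwise_ratio$actual_sd / out$direct$actual_sd else NA_real_
  structure(list(estimators = out, n_sim = config$n_sim, seed = config$seed,
                 n_nonconverged = n_fail, design = des,
                 sd_pairs_over_direct = sd_pairs_over_direct),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %d simulations (seed %s, %d non-converged)\n",
              x$n_sim, format(x$seed), x$n_nonconverged))
  for (nm in names(x$estimators)) {
    e <- x$estimators[[nm]]
    cat(sprintf("  %-15s actual SD %.5f | apparent SE %.5f | ratio %.2f\n",
                nm, e$actual_sd, e$mean_apparent_se, e$sd_ratio))
  }
  if (is.finite(x$sd_pairs_over_direct))
    cat(sprintf("  actual SD, pairs / direct: %.3f\n", x$sd_pairs_over_direct))
  invisible(x)
}

#' Fit a histogram of values to the normal distribution
#'
#' Equal-width bins spanning `mean +/- 4 SD`; zero-count bins are excluded
#' (their Poisson weight `1/count` is undefined), and the remaining counts
#' are fitted to `A exp(-(v - mu)^2 / (2 sigma^2))` by weighted NLS with
#' weights `1/count` (Poisson approximation).  `chisq/nu` near 1 indicates
#' consistency with normality; for estimates derived from correlated
#' pairwise data it is typically far above 1.
#'
#' @param values Numeric vector, `>= 500` values.
#' @param n_bins Number of bins, `>= 8` (default 30).
#' @return An object of class `normal_fit`: `mu`, `sigma`, `amplitude`,
#'   `chisq`, `nu` (`= n_used_bins - 3`), `breaks`, `counts`, `used`.
#' @export
histogram_normal_fit <- function(values, n_bins = 30L) {
  stopifnot(length(values) >= 500L, n_bins >= 8L)
  m <- mean(values); s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("degenerate values: zero spread")
  breaks <- seq(m - 4 * s, m + 4 * s, length.out = n_bins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx[idx >= 1L & idx <= n_bins], nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  used <- counts > 0L
  if (sum(used) < 4L) stop("fewer than 4 non-empty bins")
  v <- mids[used]; cts <- counts[used]
  wh <- function(z) z / sqrt(cts)   # weight 1/count on the variance scale
  model <- function(th) th[1] * exp(-(v - th[2])^2 / (2 * th[3]^2))
  fit <- .lm_engine(c(max(cts), m, s),
    resid_fn = function(th) cts - model(th),
    jac_fn = function(th) {
      e <- exp(-(v - th[2])^2 / (2 * th[3]^2))
      cbind(e,
            th[1] * e * (v - th[2]) / th[3]^2,
            th[1] * e * (v - th[2])^2 / th[3]^3)
    },
    whiten = wh)
  nu <- sum(used) - 3L
  structure(list(amplitude = fit$par[1], mu = fit$par[2],
                 sigma = abs(fit$par[3]), chisq = fit$chisq, nu = nu,
                 breaks = breaks, counts = counts, used = used,
                 converged = fit$converged),
            class = "normal_fit")
}

#' @export
print.normal_fit <- function(x, ...) {
  cat(sprintf("<normal_fit> mu = %.5g, sigma = %.5g, A = %.4g\n",
              x$mu, x$sigma, x$amplitude))
  cat(sprintf("  chisq = %.4g on nu = %d (chisq/nu = %.2f)\n",
              x$chisq, x$nu, x$chisq / x$nu))
  invisible(x)
}
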