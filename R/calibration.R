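# Cq-marker extraction from full amplification curves and standard-curve
# calibration of the amplification efficiency.
#
# Full curves are fitted with a log-logistic (Richards-type) sigmoid plus a
# sloping linear baseline:
#   y(x) = a + b x + ymax / (1 + exp(-k (x - xm)))^s
# At s = 1 the growth term is exactly the symmetric logistic with
# E0 = exp(k) and half-rise at xm; s != 1 allows asymmetry.  The sloping
# baseline absorbs residual systematic error left by upstream baselining.

.sigmoid_growth <- function(x, ymax, k, xm, s) {
  ymax * (1 + exp(-k * (x - xm)))^(-s)
}

.sigmoid_d1 <- function(x, ymax, k, xm, s) {
  u <- exp(-k * (x - xm))
  ymax * s * k * u * (1 + u)^(-s - 1)
}

.sigmoid_d2 <- function(x, ymax, k, xm, s) {
  u <- exp(-k * (x - xm))
  ymax * s * k^2 * u * (1 + u)^(-s - 2) * (s * u - 1)
}

.sigmoid_full <- function(theta, x) {
  # theta = (log ymax, log k, xm, log s, a, b)
  theta[5] + theta[6] * x +
    .sigmoid_growth(x, exp(theta[1]), exp(theta[2]), theta[3], exp(theta[4]))
}

.num_jacobian <- function(fn, theta, n_out) {
  p <- length(theta)
  J <- matrix(0, n_out, p)
  for (kk in seq_len(p)) {
    h <- 1e-6 * (abs(theta[kk]) + 1e-6)
    tp <- theta; tp[kk] <- tp[kk] + h
    tm <- theta; tm[kk] <- tm[kk] - h
    J[, kk] <- (fn(tp) - fn(tm)) / (2 * h)
  }
  J
}

#' Fit a sigmoid (log-logistic + sloping baseline) to a full curve
#'
#' Unit-weight NLS of all cycles to a four-parameter log-logistic growth
#' term (`ymax`, rate `k = ln E0`, half-rise position `xm`, asymmetry `s`)
#' plus a linear baseline `a + b x`.  Positivity of `ymax`, `k`, `s` is
#' enforced by fitting on the log scale.  Initialization: baseline from the
#' early cycles, `ymax` from the curve maximum, `xm` from the half-maximum
#' crossing.
#'
#' @param curve An [amp_curve()] with at least 8 cycles and a visible rise.
#' @return An object of class `sigmoid_fit` with `params`
#'   (`ymax, k, xm, s, a, b`), `E0 = exp(k)`, `cov` (on the internal
#'   transformed scale), `chisq`, `nu`, `s_y`, `converged`, `n_iter`, and
#'   the fitted cycle range `x_range`.
#' @export
fit_sigmoid_curve <- function(curve) {
  stopifnot(inherits(curve, "amp_curve"))
  x <- curve$cycles; y <- curve$fluorescence
  n <- length(x)
  if (n < 8L) stop("need at least 8 cycles to fit a sigmoid")
  n_early <- max(5L, n %/% 5L)
  early <- seq_len(n_early)
  early_sd <- stats::sd(y[early])
  if (max(y) - stats::median(y) < 5 * max(early_sd, .Machine$double.eps))
    stop("flat curve: no rise above baseline noise detected")
  bfit <- stats::lm.fit(cbind(1, x[early]), y[early])
  a0 <- unname(bfit$coefficients[1]); b0 <- unname(bfit$coefficients[2])
  g <- y - (a0 + b0 * x)
  ymax0 <- max(g)
  xm0 <- x[which(g >= ymax0 / 2)[1]]
  theta0 <- c(log(ymax0), log(0.6), xm0, 0, a0, b0)
  fit <- .lm_engine(theta0,
    resid_fn = function(th) y - .sigmoid_full(th, x),
    jac_fn = function(th) .num_jacobian(function(t2) .sigmoid_full(t2, x), th, n))
  nu <- n - 6L
  s_y <- if (nu > 0) sqrt(fit$chisq / nu) else NA_real_
  cov <- tryCatch(s_y^2 * solve(fit$JtJ),
                  error = function(e) matrix(NA_real_, 6, 6))
  th <- unname(fit$par)
  res <- structure(list(
    params = list(ymax = exp(th[1]), k = exp(th[2]), xm = th[3],
                  s = exp(th[4]), a = th[5], b = th[6]),
    E0 = exp(exp(th[2])),
    cov = cov, chisq = fit$chisq, nu = nu, s_y = s_y,
    residuals = fit$residuals, converged = fit$converged,
    n_iter = fit$n_iter, well_id = curve$well_id,
    x_range = range(x)), class = "sigmoid_fit")
  if (!res$converged)
    warning(sprintf("sigmoid fit for well '%s' did not converge", curve$well_id))
  res
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("<sigmoid_fit well '%s'>\n", x$well_id))
  cat(sprintf("  ymax = %.4g  k = %.4g (E0 = %.4f)  xm = %.4g  s = %.4g\n",
              p$ymax, p$k, x$E0, p$xm, p$s))
  cat(sprintf("  baseline %.4g %+.4g x;  chisq = %.4g on nu = %d (s_y = %.3g)\n",
              p$a, p$b, x$chisq, x$nu, x$s_y))
  invisible(x)
}

#' Quantification-cycle (Cq) markers from a fitted curve
#'
#' All markers are evaluated on the baseline-subtracted fitted curve `g(x)`
#' with analytic derivatives:
#' \describe{
#'   \item{threshold}{fractional cycle where `g(x)` crosses `threshold`
#'     (monotone root-finding to 1e-6 cycle).}
#'   \item{FDM}{argmax of `g'(x)` (golden-section search to 1e-6).}
#'   \item{SDM}{argmax of `g''(x)`; always precedes the FDM.}
#'   \item{Cy0}{x-intercept of the tangent at the FDM:
#'     `Cy0 = x_FDM - g(x_FDM)/g'(x_FDM)`.}
#' }
#' A marker falling outside the observed cycle range, or a threshold never
#' crossed, is an error.  For an `exp_fit` (pure exponential model) only the
#' threshold marker is defined, with the closed form
#' `cq = log(T / y0) / log(E)`.
#'
#' @param fit A [fit_sigmoid_curve()] result (or an `exp_fit` for the
#'   threshold marker).
#' @param marker One of `"Cy0"`, `"FDM"`, `"SDM"`, `"threshold"`.
#' @param threshold RFU level for the threshold marker, in `(0, ymax)`.
#' @return An object of class `cq_estimate`: list with `well_id`, `marker`,
#'   `cq` and (threshold marker) `threshold_value`.
#' @export
compute_cq <- function(fit, marker = c("Cy0", "FDM", "SDM", "threshold"),
                       threshold = NULL) {
  marker <- match.arg(marker)
  if (inherits(fit, "exp_fit")) {
    if (marker != "threshold")
      stop("only the threshold marker is defined for a pure exponential fit")
    stopifnot(!is.null(threshold), threshold > 0)
    cq <- log(threshold / fit$y0_hat) / log(fit$E_hat)
    return(structure(list(well_id = NA_character_, marker = marker, cq = cq,
                          threshold_value = threshold), class = "cq_estimate"))
  }
  stopifnot(inherits(fit, "sigmoid_fit"))
  if (marker != "threshold" && !fit$converged)
    stop("derivative markers require a converged sigmoid fit")
  p <- fit$params
  g  <- function(x) .sigmoid_growth(x, p$ymax, p$k, p$xm, p$s)
  g1 <- function(x) .sigmoid_d1(x, p$ymax, p$k, p$xm, p$s)
  g2 <- function(x) .sigmoid_d2(x, p$ymax, p$k, p$xm, p$s)
  rng <- fit$x_range
  interior <- function(v, what) {
    if (v <= rng[1] + 1e-3 || v >= rng[2] - 1e-3)
      stop(sprintf("%s marker falls outside the observed cycle range", what))
    v
  }
  # derivative curves are flat far from the rise, so bracket the maximum on
  # a fine grid first, then refine by golden-section in the bracket
  argmax <- function(fn) {
    grid <- seq(rng[1], rng[2], length.out = 401L)
    k <- which.max(fn(grid))
    lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
    if (lo == hi) return(grid[k])
    stats::optimize(fn, c(lo, hi), maximum = TRUE, tol = 1e-6)$maximum
  }
  cq <- switch(marker,
    threshold = {
      stopifnot(!is.null(threshold), threshold > 0, threshold < p$ymax)
      lo <- g(rng[1]); hi <- g(rng[2])
      if (threshold <= lo || threshold >= hi)
        stop("threshold is never crossed within the observed cycle range")
      stats::uniroot(function(x) g(x) - threshold, interval = rng,
                     tol = 1e-6)$root
    },
    FDM = interior(argmax(g1), "FDM"),
    SDM = interior(argmax(g2), "SDM"),
    Cy0 = {
      fdm <- interior(argmax(g1), "FDM")
      fdm - g(fdm) / g1(fdm)
    })
  structure(list(well_id = fit$well_id, marker = marker, cq = cq,
                 threshold_value = if (marker == "threshold") threshold else NULL),
            class = "cq_estimate")
}

#' Standard-curve (calibration) fit of Cq against log concentration
#'
#' Linear (optionally weighted) least squares of `cq` on `log_n0`.  Under
#' exponential growth the relation is linear with `slope = -1/log(E)`, so
#' `E_hat = base^(-1/slope)`, where `base` is the logarithm base of the
#' abscissa; `E_hat` is invariant to that choice when applied consistently.
#' `se_E` follows by first-order propagation from the slope SE.
#'
#' With `weights` supplied (typically `1/se^2` of replicate Cq means) the
#' slope SE is the a priori value `sqrt[(X'WX)^{-1}]`; unweighted fits use
#' the usual residual-based SE.
#'
#' @param cqs Numeric Cq values (or a list of `cq_estimate` objects).
#' @param log_n0 Matching log-concentrations, in base `base`.
#' @param weights Optional positive weights.
#' @param base Logarithm base of `log_n0` (default 10).
#' @return An object of class `calibration_fit` with `slope`, `intercept`,
#'   `se_slope`, `E_hat`, `se_E`, `chisq`, `nu`, `n`.
#' @export
standard_curve_fit <- function(cqs, log_n0, weights = NULL, base = 10) {
  if (is.list(cqs) && !is.numeric(cqs))
    cqs <- vapply(cqs, function(q) q$cq, numeric(1))
  stopifnot(length(cqs) == length(log_n0))
  if (length(unique(log_n0)) < 3L)
    stop("need at least 3 distinct concentrations")
  n <- length(cqs)
  w <- if (is.null(weights)) rep(1, n) else weights
  stopifnot(all(w > 0))
  X <- cbind(1, log_n0)
  XtWX <- crossprod(X * w, X)
  beta <- solve(XtWX, crossprod(X * w, cqs))
  r <- cqs - as.vector(X %*% beta)
  chisq <- sum(w * r^2)
  nu <- n - 2L
  covb <- solve(XtWX)
  if (is.null(weights)) covb <- covb * chisq / nu  # residual-based scale
  se_slope <- sqrt(covb[2, 2])
  slope <- beta[2]
  E_hat <- base^(-1 / slope)
  se_E <- E_hat * log(base) / slope^2 * se_slope
  structure(list(slope = unname(slope), intercept = unname(beta[1]),
                 se_slope = se_slope, E_hat = unname(E_hat), se_E = unname(se_E),
                 chisq = chisq, nu = nu, n = n, base = base),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> slope = %.5g (se %.3g), E = %.5f (se %.4g)\n",
              x$slope, x$se_slope, x$E_hat, x$se_E))
  cat(sprintf("  chisq = %.4g on nu = %d (n = %d, log base %g)\n",
              x$chisq, x$nu, x$n, x$base))
  invisible(x)
}

#' Effective single-set SD from a post-fit SE of a weighted mean
#'
#' The post-fit SE of a weighted mean over `n_sets` replicate sets converts
#' to the effective per-set SD by multiplying by `sqrt(n_sets)`.
#'
#' @param post_se Post-fit standard error of the mean.
#' @param n_sets Number of replicate sets averaged.
#' @return Effective SD.
#' @export
effective_sd <- function(post_se, n_sets) {
  stopifnot(post_se >= 0, n_sets >= 1)
  post_se * sqrt(n_sets)
}

#' Relative sampling uncertainty of an SD estimate
#'
#' A sample SD on `nu` degrees of freedom has relative SD approximately
#' `(2 nu)^(-1/2)` — 18% at `nu = 15`, which is why per-ensemble SDs from a
#' handful of replicate sets must be compared loosely.
#'
#' @param nu Degrees of freedom.
#' @return Relative SD of the SD estimate.
#' @export
sd_relative_sd <- function(nu) {
  stopifnot(nu >= 1)
  1 / sqrt(2 * nu)
}

#' Ensemble statistics across replicate-set estimates
#'
#' Inverse-variance weighted mean of per-set estimates with a priori SE
#' `(sum w)^{-1/2}`, `chisq = sum w (v - mean)^2` on `nu = n_sets - 1`,
#' post-fit SE `se_apriori * sqrt(chisq/nu)`, and the effective per-set SD
#' `post_se * sqrt(n_sets)`; the unweighted mean and SE are reported
#' alongside.
#'
#' @param values Per-set estimates (e.g. per-set `E_hat`).
#' @param ses Matching per-set standard errors, all `> 0`.
#' @return An object of class `ensemble_stats`.
#' @export
ensemble_stats <- function(values, ses) {
  stopifnot(length(values) == length(ses), all(ses > 0))
  n <- length(values)
  if (n < 2L) stop("need at least 2 replicate sets")
  w <- 1 / ses^2
  m <- sum(w * values) / sum(w)
  se_apriori <- 1 / sqrt(sum(w))
  chisq <- sum(w * (values - m)^2)
  nu <- n - 1L
  post_se <- se_apriori * sqrt(chisq / nu)
  structure(list(mean_weighted = m, se_apriori = se_apriori,
                 post_se = post_se, chisq = chisq, nu = nu,
                 mean_unweighted = mean(values),
                 se_unweighted = stats::sd(values) / sqrt(n),
                 effective_sd = effective_sd(post_se, n),
                 n_sets = n),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("<ensemble_stats> %d sets\n", x$n_sets))
  cat(sprintf("  weighted mean %.5f (a priori se %.4g, post-se %.4g)\n",
              x$mean_weighted, x$se_apriori, x$post_se))
  cat(sprintf("  unweighted    %.5f (se %.4g)\n",
              x$mean_unweighted, x$se_unweighted))
  cat(sprintf("  chisq = %.4g on nu = %d; effective per-set SD %.4g\n",
              x$chisq, x$nu, x$effective_sd))
  invisible(x)
}
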