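# The pairwise intensity-ratio estimator and its error-propagation weights.
# Each unordered pair of growth-zone points with distinct cycles yields one
# efficiency estimate; taking ratios cancels y0, and the dilution exponents
# enter as an additive log-scale correction.

#' Per-pair efficiency estimates from intensity ratios
#'
#' For every unordered pair of points with distinct cycle numbers, oriented
#' so that `x_j > x_i`,
#' \deqn{\ln E_{ij} = [\ln y_j - \ln y_i + (j_j - j_i)\ln D] / (x_j - x_i).}
#' Pairs sharing a cycle number are excluded (the denominator vanishes) and
#' counted; pairs containing a non-positive signal are dropped with a
#' warning (logs are required).
#'
#' @param points A `growth_points` data frame.
#' @param D Dilution factor (default from `points`).
#' @return A `pairwise_estimates` data frame with columns `idx_i`, `idx_j`,
#'   `x_i`, `x_j`, `j_i`, `j_j`, `y_i`, `y_j`, `E`, `Z` (`= ln E`), and
#'   placeholder columns `sigma_Z`, `sigma_E`, `weight`, `norm_resid`;
#'   attributes `n_same_cycle`, `n_nonpositive`, `dilution_factor`.
#' @export
pairwise_ratio_estimates <- function(points, D = NULL) {
  D <- .points_D(points, D)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  cb <- utils::combn(n, 2L)
  a <- cb[1L, ]; b <- cb[2L, ]
  # orient so the second member has the larger cycle
  swap <- points$x[a] > points$x[b]
  i <- ifelse(swap, b, a); jdx <- ifelse(swap, a, b)
  same <- points$x[i] == points$x[jdx]
  n_same <- sum(same)
  i <- i[!same]; jdx <- jdx[!same]
  nonpos <- points$y[i] <= 0 | points$y[jdx] <= 0
  if (any(nonpos))
    warning(sprintf("%d pair(s) dropped: non-positive signal", sum(nonpos)))
  i <- i[!nonpos]; jdx <- jdx[!nonpos]
  dx <- points$x[jdx] - points$x[i]
  Z <- (log(points$y[jdx]) - log(points$y[i]) +
          (points$j[jdx] - points$j[i]) * log(D)) / dx
  out <- data.frame(idx_i = i, idx_j = jdx,
                    x_i = points$x[i], x_j = points$x[jdx],
                    j_i = points$j[i], j_j = points$j[jdx],
                    y_i = points$y[i], y_j = points$y[jdx],
                    E = exp(Z), Z = Z,
                    sigma_Z = NA_real_, sigma_E = NA_real_,
                    weight = NA_real_, norm_resid = NA_real_)
  structure(out, n_same_cycle = n_same, n_nonpositive = sum(nonpos),
            dilution_factor = D,
            class = c("pairwise_estimates", "data.frame"))
}

#' Error-propagation uncertainties and weights for pairwise estimates
#'
#' First-order propagation of a constant signal noise `sigma_y` through the
#' log-ratio gives
#' \deqn{\sigma_Z^2 = \frac{\sigma_y^2}{(\Delta x)^2}
#'       \left(\frac{1}{y_i^2} + \frac{1}{y_j^2}\right),}
#' `sigma_E = E_ref * sigma_Z` (the estimates being narrowly distributed, a
#' single reference efficiency serves for all pairs), and the relative
#' weight
#' \deqn{w_{ij} = \frac{(\Delta x)^2 \, y_i^2 y_j^2}{y_i^2 + y_j^2},}
#' which heavily favors large cycle separations.  The common factor
#' `E_ref^2/sigma_y^2` is omitted from `weight` (it cancels in averaging);
#' `sigma_E` carries the absolute scale.
#'
#' @param estimates A [pairwise_ratio_estimates()] data frame.
#' @param sigma_y Constant additive noise SD of the raw signals (RFU).
#' @param E_ref Reference efficiency used to convert `sigma_Z` to `sigma_E`.
#' @return The estimates with `sigma_Z`, `sigma_E`, `weight` filled.
#' @export
pairwise_sigma_weights <- function(estimates, sigma_y, E_ref) {
  stopifnot(sigma_y > 0, E_ref > 0)
  dx <- estimates$x_j - estimates$x_i
  estimates$sigma_Z <- sigma_y / abs(dx) *
    sqrt(1 / estimates$y_i^2 + 1 / estimates$y_j^2)
  estimates$sigma_E <- E_ref * estimates$sigma_Z
  estimates$weight <- dx^2 * estimates$y_i^2 * estimates$y_j^2 /
    (estimates$y_i^2 + estimates$y_j^2)
  estimates
}

#' Weighted and unweighted averages of pairwise efficiency estimates
#'
#' Inverse-variance weighted mean with `w = 1/sigma_E^2`:
#' `E_bar = sum(w E)/sum(w)`, a priori SE `(sum w)^{-1/2}`,
#' `chisq = sum w (E - E_bar)^2` on `nu = n - 1` degrees of freedom, and the
#' post-fit SE `se_apriori * sqrt(chisq/nu)`.  Normalized residuals
#' `(E - E_bar)/sigma_E` are filled into the returned estimates.  The
#' unweighted mean and its SE are reported alongside.
#'
#' These SEs describe the *apparent* precision only: the pairwise estimates
#' reuse each raw point many times and are strongly correlated, so the true
#' ensemble scatter is substantially larger (see [run_mc_comparison()]).
#'
#' @param estimates Pairwise estimates with `sigma_E` filled.
#' @return An object of class `pairwise_summary`.
#' @export
weighted_mean_pairwise <- function(estimates) {
  if (nrow(estimates) < 2L)
    stop("need at least 2 estimates (nu = 0 otherwise)")
  if (anyNA(estimates$sigma_E))
    stop("sigma_E not filled; run pairwise_sigma_weights() first")
  w <- 1 / estimates$sigma_E^2
  E <- estimates$E
  Ebar <- sum(w * E) / sum(w)
  se_apriori <- 1 / sqrt(sum(w))
  chisq <- sum(w * (E - Ebar)^2)
  nu <- length(E) - 1L
  post_se <- se_apriori * sqrt(chisq / nu)
  estimates$norm_resid <- (E - Ebar) / estimates$sigma_E
  structure(list(E_bar_weighted = Ebar, se_apriori = se_apriori,
                 E_bar_unweighted = mean(E),
                 se_unweighted = stats::sd(E) / sqrt(length(E)),
                 chisq = chisq, nu = nu, post_se = post_se,
                 n_pairs = length(E),
                 n_flagged = if (!is.null(estimates$outlier))
                   sum(estimates$outlier) else NA_integer_,
                 estimates = estimates),
            class = "pairwise_summary")
}

#' @export
print.pairwise_summary <- function(x, ...) {
  cat("<pairwise_summary>\n")
  cat(sprintf("  weighted   E = %.4f (a priori se %.4f, post-se %.4f)\n",
              x$E_bar_weighted, x$se_apriori, x$post_se))
  cat(sprintf("  unweighted E = %.4f (se %.4f)\n",
              x$E_bar_unweighted, x$se_unweighted))
  cat(sprintf("  chisq = %.4g on nu = %d; %d pairs\n", x$chisq, x$nu, x$n_pairs))
  cat("  NOTE: apparent SEs only; pairwise estimates are correlated\n")
  invisible(x)
}

#' Outlier zone for pairwise efficiency estimates
#'
#' @param lo_E,hi_E Efficiency bounds of the zone (defaults 1.60 and 2.15).
#' @return An object of class `outlier_zone`.
#' @export
outlier_zone <- function(lo_E = 1.60, hi_E = 2.15) {
  stopifnot(lo_E < hi_E)
  structure(list(lo_E = lo_E, hi_E = hi_E), class = "outlier_zone")
}

#' Flag pairwise estimates in the outlier zone
#'
#' Marks estimates with `E < lo_E` or `E > hi_E`.  Flagged values are never
#' deleted: with proper weighting, estimates landing that far out carry
#' weights orders of magnitude below the maximum and are ipso facto
#' insignificant in the average — the diagnostics report the maximum
#' in-zone weight against the overall maximum to make that visible.
#'
#' @param estimates Pairwise estimates (weights filled for diagnostics).
#' @param zone An [outlier_zone()].
#' @return List with `estimates` (an added logical column `outlier`),
#'   `n_flagged`, `max_weight_flagged`, `max_weight_overall`.
#' @export
flag_outlier_zone <- function(estimates, zone = outlier_zone()) {
  stopifnot(inherits(zone, "outlier_zone"))
  flg <- estimates$E < zone$lo_E | estimates$E > zone$hi_E
  estimates$outlier <- flg
  list(estimates = estimates,
       n_flagged = sum(flg),
       max_weight_flagged = if (any(flg)) max(estimates$weight[flg]) else NA_real_,
       max_weight_overall = if (nrow(estimates)) max(estimates$weight) else NA_real_)
}

#' Full pairwise-ratio pipeline for one growth-zone point set
#'
#' Convenience wrapper: per-pair estimates, noise scale `sigma_y` from the
#' direct fit's `s_y` unless supplied, a first pass with the unweighted mean
#' as `E_ref`, then one re-weighting pass using the weighted mean (the
#' estimates are narrowly distributed, so further passes change nothing
#' material), and outlier-zone flagging.
#'
#' @param points A `growth_points` data frame.
#' @param D Dilution factor (default from `points`).
#' @param sigma_y Noise SD; default `fit_direct(points, D)$s_y`.
#' @param zone An [outlier_zone()].
#' @return A `pairwise_summary` whose `estimates` carry weights, normalized
#'   residuals and outlier flags; `sigma_y` used is stored on the object.
#' @export
estimate_pairwise <- function(points, D = NULL, sigma_y = NULL,
                              zone = outlier_zone()) {
  D <- .points_D(points, D)
  est <- pairwise_ratio_estimates(points, D)
  if (is.null(sigma_y)) sigma_y <- fit_direct(points, D)$s_y
  if (!is.finite(sigma_y) || sigma_y <= 0)
    stop("sigma_y must be positive; supply it explicitly for noiseless data")
  est <- pairwise_sigma_weights(est, sigma_y, E_ref = mean(est$E))
  pass1 <- weighted_mean_pairwise(est)
  est <- pairwise_sigma_weights(est, sigma_y, E_ref = pass1$E_bar_weighted)
  est <- flag_outlier_zone(est, zone)$estimates
  out <- weighted_mean_pairwise(est)
  out$sigma_y <- sigma_y
  out
}
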