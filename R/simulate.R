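# Synthetic-data generation: growth-zone point designs (for the Monte Carlo
# estimator study) and full logistic amplification curves (for the Cq
# calibration pipeline).  Noise is additive, homoscedastic Gaussian with SD
# sigma_y, matching the roughly constant noise of baselined qPCR signals in
# the baseline and early growth regions.

#' A growth-zone point design for simulation
#'
#' The default reproduces a 9-point, 3-curve dilution-series design:
#' dilution exponents 0, 1, 2 with cycles \{14,15,16\}, \{15,16,17\},
#' \{16,17,18\} (a one-cycle stagger approximates the factor-2 dilution
#' shift at E near 1.85), `E = 1.85`, `sigma_y = 2.4` RFU, and `y0` chosen
#' so the nine exact values (42.4 to 169.4 RFU) sit centrally inside the
#' 20-180 RFU growth zone.  With this layout 5 of the 36 point pairs share
#' a cycle number, leaving 31 pairwise ratio estimates.
#'
#' @param E Generating amplification efficiency.
#' @param y0 Cycle-0 signal of the `j = 0` curve.
#' @param D Dilution factor.
#' @param sigma_y Additive noise SD (RFU), `>= 0`.
#' @param layout Data frame with columns `j`, `x`, one row per point.
#' @return An object of class `point_design` carrying the exact (noiseless)
#'   values in `$exact`.
#' @export
point_design <- function(E = 1.85, y0 = 0.009, D = 2, sigma_y = 2.4,
                         layout = data.frame(j = rep(0:2, each = 3),
                                             x = c(14:16, 15:17, 16:18))) {
  stopifnot(sigma_y >= 0, nrow(layout) >= 3L,
            all(c("j", "x") %in% names(layout)))
  exact <- exp_model_value(y0, E, layout$x, layout$j, D)
  structure(list(E = E, y0 = y0, D = D, sigma_y = sigma_y,
                 layout = layout, exact = exact),
            class = "point_design")
}

#' Simulate noisy replicates of a point design
#'
#' Adds independent `N(0, sigma_y^2)` noise to the exact model values,
#' `n_sim` times.  The generator state is fully determined by `seed`; the
#' exact values are recorded alongside the draws.
#'
#' @param design A [point_design()].
#' @param n_sim Number of replicate sets, `>= 1`.
#' @param seed Integer RNG seed (required: every stochastic output in this
#'   package is reproducible by construction).
#' @return An object of class `point_sims`: list with `design`, `seed`,
#'   `n_sim`, `exact`, and `y`, an `n_sim x n_points` matrix.
#' @export
simulate_points <- function(design, n_sim = 1L, seed) {
  stopifnot(inherits(design, "point_design"), n_sim >= 1L)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  n <- nrow(design$layout)
  noise <- matrix(stats::rnorm(n_sim * n, 0, design$sigma_y), n_sim, n)
  y <- sweep(noise, 2L, design$exact, `+`)
  structure(list(design = design, seed = seed, n_sim = n_sim,
                 exact = design$exact, y = y),
            class = "point_sims")
}

#' Extract one simulated replicate as growth points
#'
#' @param sims A [simulate_points()] result.
#' @param i Replicate index.
#' @return A `growth_points` data frame usable by every estimator.
#' @export
sim_growth_points <- function(sims, i = 1L) {
  stopifnot(inherits(sims, "point_sims"), i >= 1L, i <= sims$n_sim)
  growth_points(j = sims$design$layout$j, x = sims$design$layout$x,
                y = sims$y[i, ], D = sims$design$D)
}

#' A full-curve dilution-series design
#'
#' Logistic growth on top of a linear baseline, emulating replicate
#' 6-concentration, dilution-factor-2 series with plateaus near 600 RFU.
#' The most concentrated curve must reach its plateau (99% of `ymax`)
#' within `n_cycles`.
#'
#' @param n_concentrations Number of curves (dilution exponents
#'   `0:(n_concentrations-1)`).
#' @param D Dilution factor.
#' @param y0 Cycle-0 signal of the most concentrated reaction.
#' @param ymax Plateau RFU.
#' @param E0 Baseline-region efficiency.
#' @param baseline Length-2 numeric `(a, b)`: baseline `a + b x` added to
#'   every curve.
#' @param n_cycles Number of cycles recorded (1..n_cycles).
#' @param sigma_y Additive noise SD (RFU).
#' @return An object of class `curve_design`.
#' @export
curve_design <- function(n_concentrations = 6, D = 2, y0 = 0.02, ymax = 600,
                         E0 = 1.9, baseline = c(0, 0), n_cycles = 40,
                         sigma_y = 2.4) {
  stopifnot(n_concentrations >= 1, D > 1, y0 > 0, ymax > y0, E0 > 1,
            length(baseline) == 2L, n_cycles >= 8, sigma_y >= 0)
  if (logistic_model_value(y0, ymax, E0, n_cycles) < 0.99 * ymax)
    stop("plateau not reached within n_cycles for the most concentrated curve")
  structure(list(n_concentrations = n_concentrations, D = D, y0 = y0,
                 ymax = ymax, E0 = E0, baseline = baseline,
                 n_cycles = n_cycles, sigma_y = sigma_y),
            class = "curve_design")
}

#' Simulate replicate dilution-series of full amplification curves
#'
#' Each curve is `baseline + logistic growth + noise`; the curve with
#' dilution exponent `j` starts from `y0 / D^j`.  With `sigma_y = 0` the
#' curves are the exact model values.
#'
#' @param design A [curve_design()].
#' @param n_sets Number of replicate series.
#' @param seed Integer RNG seed (required).
#' @return A list of `n_sets` [dilution_series()] objects; the seed is
#'   attached as attribute `seed`.
#' @export
simulate_curves <- function(design, n_sets = 1L, seed) {
  stopifnot(inherits(design, "curve_design"), n_sets >= 1L)
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  x <- seq_len(design$n_cycles)
  out <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    curves <- vector("list", design$n_concentrations)
    for (jj in seq_len(design$n_concentrations)) {
      j <- jj - 1L
      mu <- design$baseline[1] + design$baseline[2] * x +
        logistic_model_value(design$y0 / design$D^j, design$ymax, design$E0, x)
      y <- mu + stats::rnorm(length(x), 0, design$sigma_y)
      curves[[jj]] <- amp_curve(sprintf("S%d_J%d", s, j), j, x, y)
    }
    out[[s]] <- dilution_series(curves, dilution_factor = design$D)
  }
  attr(out, "seed") <- seed
  out
}
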