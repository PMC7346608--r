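test_that("sigmoid fit recovers a noiseless logistic curve", {
  x <- 1:40
  y <- logistic_model_value(0.04, 600, 1.9, x)
  fit <- fit_sigmoid_curve(amp_curve("A1", 0L, x, y))
  expect_true(fit$converged)
  expect_equal(fit$params$ymax, 600, tolerance = 1e-3)
  expect_lt(fit$chisq, 1e-10)
  # fitted growth term is monotone nondecreasing over the data range
  g <- ampeff:::.sigmoid_growth(seq(1, 40, by = 0.25), fit$params$ymax,
                                fit$params$k, fit$params$xm, fit$params$s)
  expect_true(all(diff(g) >= 0))
})

test_that("sloping baseline is recovered from noisy data", {
  x <- 1:40
  set.seed(3)
  y <- 3 + 0.1 * x + logistic_model_value(0.04, 600, 1.9, x) + rnorm(40, 0, 2.4)
  fit <- fit_sigmoid_curve(amp_curve("A2", 0L, x, y))
  se_b <- sqrt(fit$cov[6, 6])
  expect_lt(abs(fit$params$b - 0.1), 3 * se_b)
})

test_that("flat curves are rejected", {
  expect_error(fit_sigmoid_curve(amp_curve("F", 0L, 1:20, rep(5, 20))),
               "flat curve")
})

test_that("threshold Cq on a pure exponential has the closed form", {
  pts <- exact_points(E = 2, y0 = 0.04)
  fit <- fit_direct(pts)
  cq <- compute_cq(fit, "threshold", threshold = 20)
  expect_equal(cq$cq, log2(500), tolerance = 1e-9)
  expect_error(compute_cq(fit, "FDM"), "threshold marker")
})

test_that("derivative markers match closed-form and tangent oracles", {
  y0 <- 0.04; ymax <- 600; E0 <- 1.9
  x <- 1:40
  fit <- fit_sigmoid_curve(amp_curve("A1", 0L, x,
                                     logistic_model_value(y0, ymax, E0, x)))
  fdm <- compute_cq(fit, "FDM")$cq
  # symmetric logistic: FDM = log_E0((ymax - y0)/y0)
  expect_equal(fdm, log((ymax - y0) / y0) / log(E0), tolerance = 1e-4)
  # Cy0 against a numeric tangent construction at the FDM
  g <- function(z) ampeff:::.sigmoid_growth(z, fit$params$ymax, fit$params$k,
                                            fit$params$xm, fit$params$s)
  slope <- (g(fdm + 1e-5) - g(fdm - 1e-5)) / 2e-5
  cy0_oracle <- fdm - g(fdm) / slope
  expect_equal(compute_cq(fit, "Cy0")$cq, cy0_oracle, tolerance = 1e-5)
  # half-height at the FDM implies Cy0 = FDM - (ymax/2) / g'(FDM)
  expect_equal(compute_cq(fit, "Cy0")$cq, fdm - (ymax / 2) / slope,
               tolerance = 1e-3)
})

test_that("marker ordering and translation equivariance hold", {
  x <- 1:40
  y <- logistic_model_value(0.05, 550, 1.8, x)
  f1 <- fit_sigmoid_curve(amp_curve("A", 0L, x, y))
  m1 <- vapply(c("SDM", "Cy0", "FDM"),
               function(m) compute_cq(f1, m)$cq, numeric(1))
  expect_lt(m1["SDM"], m1["FDM"])
  expect_lt(m1["Cy0"], m1["FDM"])
  t1 <- compute_cq(f1, "threshold", threshold = 20)$cq
  # shift all cycles by +3 and refit: every marker shifts by +3
  f2 <- fit_sigmoid_curve(amp_curve("A", 0L, x + 3, y))
  for (m in names(m1))
    expect_equal(compute_cq(f2, m)$cq, m1[[m]] + 3, tolerance = 1e-3)
  expect_equal(compute_cq(f2, "threshold", threshold = 20)$cq, t1 + 3,
               tolerance = 1e-4)
})

test_that("standard-curve fit inverts the slope to E", {
  D <- 2; y0 <- 0.04; Tq <- 20
  j <- 0:5
  # noiseless Cq oracle from the closed form on each diluted curve
  for (E in c(2, 1.8)) {
    cq <- log(Tq / (y0 / D^j)) / log(E)
    cal <- standard_curve_fit(cq, -j * log10(D), base = 10)
    expect_equal(cal$E_hat, E, tolerance = 1e-9)
    if (E == 2) {
      cal2 <- standard_curve_fit(cq, -j * log2(D), base = 2)
      expect_equal(cal2$slope, -1, tolerance = 1e-9)
      expect_equal(cal2$E_hat, cal$E_hat, tolerance = 1e-12)  # base invariance
    }
  }
  # rescaling all concentrations by a common factor leaves E unchanged
  cq <- log(Tq / (y0 / D^j)) / log(1.8)
  base_fit <- standard_curve_fit(cq, -j * log10(D))
  shifted <- standard_curve_fit(cq, -j * log10(D) + log10(7))
  expect_equal(shifted$E_hat, base_fit$E_hat, tolerance = 1e-12)
  expect_error(standard_curve_fit(cq[1:3], rep(0, 3)), "distinct concentrations")
})

test_that("ensemble statistics follow the weighted-mean algebra", {
  es <- ensemble_stats(values = c(1.78, 1.80, 1.79, 1.81),
                       ses = rep(0.01, 4))
  expect_equal(es$mean_weighted, es$mean_unweighted)
  expect_equal(es$nu, 3L)
  expect_equal(es$effective_sd, es$post_se * 2)
  expect_error(ensemble_stats(1.8, 0.01), "at least 2")
  expect_equal(effective_sd(0.0045, 16), 0.018)
  expect_equal(sd_relative_sd(15), 1 / sqrt(30))
  expect_equal(round(sd_relative_sd(15), 2), 0.18)
})

test_that("Cy0 standard curves recover the generating E0 from simulated series", {
  des <- curve_design(sigma_y = 2.4)
  n_rep <- 200
  sets <- simulate_curves(des, n_sets = n_rep, seed = 424242)
  hits <- 0L; n_ok <- 0L
  for (s in seq_len(n_rep)) {
    cal <- tryCatch({
      cqs <- vapply(sets[[s]]$curves, function(crv)
        compute_cq(fit_sigmoid_curve(crv), "Cy0")$cq, numeric(1))
      js <- vapply(sets[[s]]$curves, `[[`, integer(1), "dilution_exponent")
      standard_curve_fit(cqs, -js * log10(des$D), base = 10)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(cal)) next
    n_ok <- n_ok + 1L
    if (abs(cal$E_hat - des$E0) <= 3 * cal$se_E) hits <- hits + 1L
  }
  expect_gt(n_ok, 0.9 * n_rep)
  expect_gte(hits / n_ok, 0.90)
})
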