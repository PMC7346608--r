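test_that("per-pair ratios recover E exactly on noiseless points", {
  # same-curve pair
  same <- growth_points(j = c(0, 0), x = c(14, 16),
                        y = exp_model_value(0.04, 1.85, c(14, 16)))
  expect_equal(pairwise_ratio_estimates(same)$E, 1.85, tolerance = 1e-12)
  # cross-curve pair: the dilution correction must cancel the factor D
  cross <- growth_points(j = c(0, 1), x = c(15, 17),
                         y = exp_model_value(0.04, 1.85, c(15, 17), c(0, 1)))
  expect_equal(pairwise_ratio_estimates(cross)$E, 1.85, tolerance = 1e-12)
})

test_that("same-cycle exclusion matches brute-force enumeration on the 9-point layout", {
  pts <- exact_points()
  est <- pairwise_ratio_estimates(pts)
  # oracle: enumerate all C(9,2) pairs and count distinct-cycle ones
  cb <- utils::combn(9, 2)
  n_distinct <- sum(pts$x[cb[1, ]] != pts$x[cb[2, ]])
  expect_equal(nrow(est), n_distinct)
  expect_equal(nrow(est), 31)
  expect_equal(attr(est, "n_same_cycle"), 5)
  expect_true(all(est$x_j > est$x_i))
})

test_that("pairwise count is C(n,2) when all cycles are distinct", {
  for (n in c(3L, 6L, 10L)) {
    pts <- growth_points(j = rep(0, n), x = seq_len(n), y = 2^(seq_len(n)))
    expect_equal(nrow(pairwise_ratio_estimates(pts)), choose(n, 2))
  }
})

test_that("non-positive signals drop the affected pairs with a warning", {
  pts <- growth_points(j = c(0, 0, 0), x = 1:3, y = c(30, -2, 120))
  expect_warning(est <- pairwise_ratio_estimates(pts), "non-positive")
  expect_equal(nrow(est), 1)
})

test_that("propagated sigma matches a numeric error-propagation oracle", {
  est <- data.frame(idx_i = 1, idx_j = 2, x_i = 14, x_j = 17,
                    j_i = 0, j_j = 1, y_i = 30, y_j = 120,
                    E = NA, Z = NA, sigma_Z = NA, sigma_E = NA,
                    weight = NA, norm_resid = NA)
  out <- pairwise_sigma_weights(est, sigma_y = 2.4, E_ref = 1.8)
  # oracle: numeric partials of Z(y_i, y_j) through the log-ratio
  Zfun <- function(yi, yj) (log(yj) - log(yi) + (1 - 0) * log(2)) / (17 - 14)
  h <- 1e-6
  dZi <- (Zfun(30 + h, 120) - Zfun(30 - h, 120)) / (2 * h)
  dZj <- (Zfun(30, 120 + h) - Zfun(30, 120 - h)) / (2 * h)
  sZ_oracle <- sqrt((dZi^2 + dZj^2) * 2.4^2)
  expect_equal(out$sigma_Z, sZ_oracle, tolerance = 1e-8)
  expect_equal(out$sigma_E, 1.8 * sZ_oracle, tolerance = 1e-8)
})

test_that("weights follow the closed form and its symmetries", {
  mk <- function(yi, yj, dx) {
    est <- data.frame(idx_i = 1, idx_j = 2, x_i = 10, x_j = 10 + dx,
                      j_i = 0, j_j = 0, y_i = yi, y_j = yj,
                      E = NA, Z = NA, sigma_Z = NA, sigma_E = NA,
                      weight = NA, norm_resid = NA)
    pairwise_sigma_weights(est, sigma_y = 1, E_ref = 1.8)$weight
  }
  expect_equal(mk(50, 50, 1), 50^2 / 2)            # y_i = y_j, dx = 1
  expect_equal(mk(30, 120, 4), 4 * mk(30, 120, 2)) # (dx)^2 scaling
  expect_equal(mk(30, 120, 3), mk(120, 30, 3))     # symmetric in (i, j)
  # strictly increasing in |dx|
  w <- vapply(1:5, function(d) mk(30, 120, d), numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("weighted averaging reproduces hand-computed oracles", {
  base <- data.frame(idx_i = 1:2, idx_j = 3:4, x_i = 1, x_j = 2,
                     j_i = 0, j_j = 0, y_i = 1, y_j = 1,
                     E = c(1.8, 1.9), Z = log(c(1.8, 1.9)),
                     sigma_Z = NA, sigma_E = c(0.01, 0.02),
                     weight = 1, norm_resid = NA)
  s <- weighted_mean_pairwise(base)
  expect_equal(s$E_bar_weighted, 1.82, tolerance = 1e-12)
  expect_equal(s$se_apriori, sqrt(1 / 12500), tolerance = 1e-12)
  expect_equal(s$nu, 1L)
  # equal sigmas reduce to the unweighted mean
  eq <- base; eq$sigma_E <- 0.015
  s2 <- weighted_mean_pairwise(eq)
  expect_equal(s2$E_bar_weighted, s2$E_bar_unweighted)
  # identical estimates: zero scatter
  id <- base; id$E <- 1.85
  s3 <- weighted_mean_pairwise(id)
  expect_equal(s3$chisq, 0)
  expect_equal(s3$post_se, 0)
  expect_true(all(s3$estimates$norm_resid == 0))
  expect_error(weighted_mean_pairwise(base[1, ]), "at least 2")
})

test_that("outlier-zone flagging marks without deleting", {
  est <- data.frame(idx_i = 1:3, idx_j = 4:6, x_i = 1, x_j = 3,
                    j_i = 0, j_j = 0, y_i = 1, y_j = 1,
                    E = c(1.58, 1.80, 2.20), Z = NA, sigma_Z = NA,
                    sigma_E = 0.01, weight = c(351, 2000, 30),
                    norm_resid = NA)
  out <- flag_outlier_zone(est)
  expect_equal(out$estimates$outlier, c(TRUE, FALSE, TRUE))
  expect_equal(out$n_flagged, 2)
  expect_equal(out$max_weight_flagged, 351)
  expect_equal(out$max_weight_overall, 2000)
  empty <- flag_outlier_zone(est[0, ])
  expect_equal(empty$n_flagged, 0)
})

test_that("the full pairwise pipeline is consistent on noiseless and noisy data", {
  pts0 <- exact_points()
  s0 <- estimate_pairwise(pts0, sigma_y = 1)  # supplied sigma: data are exact
  expect_equal(s0$E_bar_weighted, 1.85, tolerance = 1e-10)
  expect_equal(s0$chisq, 0, tolerance = 1e-16)
  pts <- noisy_points(seed = 8)
  s <- estimate_pairwise(pts)
  expect_equal(s$n_pairs, 31L)
  expect_false(anyNA(s$estimates$weight))
  expect_false(anyNA(s$estimates$norm_resid))
  expect_gt(s$sigma_y, 0)
})
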