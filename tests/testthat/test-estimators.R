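test_that("fit_direct recovers noiseless parameters exactly", {
  pts <- exact_points()
  fit <- fit_direct(pts)
  expect_true(fit$converged)
  expect_equal(fit$E_hat, 1.85, tolerance = 1e-10)
  expect_equal(fit$y0_hat, 0.009, tolerance = 1e-8)
  expect_lt(fit$chisq, 1e-16)
  expect_equal(fit$nu, 7L)
})

test_that("fit_direct SEs match a finite-difference Jacobian oracle", {
  pts <- noisy_points(seed = 21)
  fit <- fit_direct(pts)
  expect_lt(abs(fit$E_hat - 1.85), 4 * fit$se_E)
  # independent oracle: numeric Jacobian of the model at the fitted params
  model <- function(th) th[1] * th[2]^pts$x / 2^pts$j
  th <- c(fit$y0_hat, fit$E_hat)
  J <- sapply(1:2, function(k) {
    h <- 1e-7 * abs(th[k])
    tp <- th; tp[k] <- tp[k] + h
    tm <- th; tm[k] <- tm[k] - h
    (model(tp) - model(tm)) / (2 * h)
  })
  cov_oracle <- fit$s_y^2 * solve(crossprod(J))
  expect_equal(fit$se_E, sqrt(cov_oracle[2, 2]), tolerance = 1e-6)
  expect_equal(fit$se_y0, sqrt(cov_oracle[1, 1]), tolerance = 1e-6)
})

test_that("degenerate designs are rejected", {
  pts <- growth_points(j = c(0, 0), x = c(14, 15), y = c(50, 90))
  expect_error(fit_direct(pts), "at least 3 points")
  pts1 <- growth_points(j = c(0, 1, 2), x = c(14, 14, 14), y = c(50, 40, 30))
  expect_error(fit_direct(pts1), "single cycle")
})

test_that("make_difference_pairs builds the full lexicographic L system", {
  pts <- noisy_points(seed = 2)
  diffs <- make_difference_pairs(pts)
  expect_equal(nrow(diffs$pairs), 36)
  expect_true(all(diffs$pairs$a < diffs$pairs$b))
  expect_true(all(rowSums(diffs$L) == 0))
  expect_equal(diffs$d, as.vector(diffs$L %*% pts$y))
  expect_equal(qr(diffs$L)$rank, 8)      # rank oracle: n - 1
  two <- growth_points(j = c(0, 0), x = c(1, 2), y = c(3, 5))
  d2 <- make_difference_pairs(two)
  expect_equal(unname(d2$L), matrix(c(1, -1), 1))
  expect_equal(d2$d, -2)
})

test_that("naive difference fit is exact on noiseless data and falsely precise on noise", {
  pts0 <- exact_points()
  d0 <- make_difference_pairs(pts0)
  f0 <- fit_differences_naive(d0, pts0)
  expect_equal(f0$E_hat, 1.85, tolerance = 1e-9)
  expect_lt(f0$chisq, 1e-14)
  for (seed in c(3, 17, 101)) {
    pts <- noisy_points(seed)
    diffs <- make_difference_pairs(pts)
    fn <- fit_differences_naive(diffs, pts)
    fd <- fit_direct(pts)
    expect_equal(fn$n_obs, 36L)
    expect_lt(fn$se_E, fd$se_E)   # the pseudo-replication fallacy
  }
  two <- growth_points(j = c(0, 0), x = c(1, 2), y = c(30, 60))
  expect_error(fit_differences_naive(make_difference_pairs(two), two),
               "fewer than 3 points")
})

test_that("GLS on any spanning set + anchor equals the direct fit", {
  pts <- noisy_points(seed = 31)
  diffs <- make_difference_pairs(pts)
  fd <- fit_direct(pts)
  for (tree_seed in c(1, 2, 3)) {
    rows <- random_spanning_rows(diffs, tree_seed)
    for (anchor in c(1L, 5L, 9L)) {
      fg <- fit_differences_gls(diffs, pts, rows = rows, anchor = anchor)
      expect_equal(fg$E_hat, fd$E_hat, tolerance = 1e-8)
      expect_equal(fg$y0_hat, fd$y0_hat, tolerance = 1e-8)
      expect_equal(fg$se_E, fd$se_E, tolerance = 1e-8)
      expect_equal(fg$se_y0, fd$se_y0, tolerance = 1e-8)
      expect_equal(fg$nu, fd$nu)
    }
  }
})

test_that("GLS rejects over-complete and non-spanning difference sets", {
  pts <- noisy_points(seed = 4)
  diffs <- make_difference_pairs(pts)
  # 9 rows from 9 points: the Gram matrix is singular
  expect_error(fit_differences_gls(diffs, pts, rows = 1:9),
               "singular weight matrix.*det\\(L L'\\)")
  # the full 36-row set fails the same way
  expect_error(fit_differences_gls(diffs, pts), "singular weight matrix")
  # 8 rows covering only points 1..8 (graph-connectivity oracle: point 9
  # is isolated, so the set cannot span)
  within8 <- which(diffs$pairs$b <= 8)[1:8]
  expect_true(all(c(diffs$pairs$a[within8], diffs$pairs$b[within8]) <= 8))
  expect_error(fit_differences_gls(diffs, pts, rows = within8),
               "connectivity error")
})

test_that("all estimators are invariant under uniform signal rescaling", {
  pts <- noisy_points(seed = 12)
  fd <- fit_direct(pts)
  d1 <- make_difference_pairs(pts)
  fn1 <- fit_differences_naive(d1, pts)
  summ <- estimate_pairwise(pts)
  for (cc in c(0.5, 3)) {
    sc <- pts; sc$y <- pts$y * cc
    fd2 <- fit_direct(sc)
    expect_equal(fd2$E_hat, fd$E_hat, tolerance = 1e-9)
    expect_equal(fd2$y0_hat, fd$y0_hat * cc, tolerance = 1e-8)
    d2 <- make_difference_pairs(sc)
    expect_equal(fit_differences_naive(d2, sc)$E_hat, fn1$E_hat,
                 tolerance = 1e-7)
    expect_equal(fit_differences_gls(d2, sc,
                                     rows = spanning_tree_rows(d2))$E_hat,
                 fd$E_hat, tolerance = 1e-8)
    expect_equal(estimate_pairwise(sc)$E_bar_weighted, summ$E_bar_weighted,
                 tolerance = 1e-9)
  }
})

test_that("max_disjoint_pairs is the matching number floor(n/2)", {
  for (n in c(2L, 4L, 5L, 9L)) {
    pts <- growth_points(j = rep(0, n), x = seq_len(n), y = 2^(seq_len(n)))
    expect_equal(max_disjoint_pairs(make_difference_pairs(pts)), n %/% 2L)
  }
})
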