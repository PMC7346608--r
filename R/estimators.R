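# Exponential-model machinery shared by the direct, naive-difference and
# correlated-GLS estimators.  The model is y = y0 E^x / D^j with parameters
# theta = (y0, E); cycles are used as written (E is invariant to the cycle
# origin, which is absorbed into y0).

.exp_predict <- function(theta, x, j, D) theta[1] * theta[2]^x / D^j

.exp_jacobian <- function(theta, x, j, D) {
  cbind(theta[2]^x / D^j,
        theta[1] * x * theta[2]^(x - 1) / D^j)
}

# Log-linear initialization: log(y) + j log(D) = log(y0) + x log(E).
.exp_init <- function(x, j, y, D) {
  ok <- y > 0
  if (sum(ok) < 2L) stop("need at least 2 positive signals to initialize")
  z <- log(y[ok]) + j[ok] * log(D)
  xx <- x[ok]
  vx <- sum((xx - mean(xx))^2)
  if (vx == 0) stop("rank-deficient design: all points share a single cycle")
  b <- sum((xx - mean(xx)) * (z - mean(z))) / vx
  a <- mean(z) - b * mean(xx)
  c(y0 = exp(a), E = exp(b))
}

.points_D <- function(points, D) {
  if (!is.null(D)) return(D)
  d <- attr(points, "dilution_factor")
  if (is.null(d)) 2 else d
}

#' Direct exponential fit of growth-zone points
#'
#' Unweighted nonlinear least squares of all growth-zone points to
#' `y = y0 E^x / D^j`, the statistically correct "global" estimator for a
#' dilution series with constant additive noise.  Initialization is a linear
#' regression of `log(y) + j log(D)` on `x`; iteration stops when the largest
#' relative parameter change is below `1e-10` (max 200 iterations).  A priori
#' standard errors are `s_y^2 (J'J)^{-1}` with `s_y^2 = chisq / nu`,
#' `nu = n - 2`.
#'
#' @param points A `growth_points` data frame (see [select_growth_zone()]).
#' @param D Dilution factor; defaults to the attribute carried by `points`.
#' @return An object of class `exp_fit` with fields `y0_hat`, `E_hat`,
#'   `se_y0`, `se_E`, `cov`, `chisq`, `nu`, `s_y`, `residuals`, `converged`,
#'   `n_iter`.
#' @export
fit_direct <- function(points, D = NULL) {
  D <- .points_D(points, D)
  x <- points$x; j <- points$j; y <- points$y
  if (length(y) < 3L) stop("fit_direct needs at least 3 points")
  if (length(unique(x)) < 2L)
    stop("rank-deficient design: all points share a single cycle")
  start <- .exp_init(x, j, y, D)
  fit <- .lm_engine(start,
                    resid_fn = function(th) y - .exp_predict(th, x, j, D),
                    jac_fn = function(th) .exp_jacobian(th, x, j, D))
  res <- .new_exp_fit(fit, n_obs = length(y), method = "direct")
  if (!res$converged)
    warning("fit_direct did not reach the convergence tolerance")
  res
}

#' All pairwise differences of growth-zone points
#'
#' Builds every unordered pair `(a, b)`, `a < b` in lexicographic order, the
#' observed differences `d = y_a - y_b`, and the transformation matrix `L`
#' (one `+1` and one `-1` per row) such that `d = L y` exactly.  `rank(L)`
#' is at most `n - 1`: the differences carry strictly less information than
#' the points themselves.
#'
#' @param points A `growth_points` data frame with at least 2 rows.
#' @return An object of class `difference_set` with elements `pairs`
#'   (data frame `a`, `b`), `L`, `d` and `n_points`.
#' @export
make_difference_pairs <- function(points) {
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points to form differences")
  cb <- utils::combn(n, 2L)
  a <- cb[1L, ]; b <- cb[2L, ]
  m <- length(a)
  L <- matrix(0, m, n)
  L[cbind(seq_len(m), a)] <- 1
  L[cbind(seq_len(m), b)] <- -1
  structure(list(pairs = data.frame(a = a, b = b),
                 L = L, d = points$y[a] - points$y[b], n_points = n),
            class = "difference_set")
}

#' Naive (fallacious) least-squares fit of all pairwise differences
#'
#' Fits the `C(n,2)` differences to
#' `d = y0 (E^{x_a}/D^{j_a} - E^{x_b}/D^{j_b})` by unweighted NLS,
#' deliberately treating the differences as independent observations of
#' common variance.  Because each raw point is reused `n - 1` times, the
#' reported a priori standard errors are falsely optimistic — this estimator
#' exists to demonstrate the correlated-data fallacy, and its result records
#' the independence assumption in `notes`.
#'
#' @param diffs A [make_difference_pairs()] result.
#' @param points The `growth_points` the differences were built from.
#' @param D Dilution factor (default from `points`).
#' @return An `exp_fit` with `n_obs` equal to the number of pairs.
#' @export
fit_differences_naive <- function(diffs, points, D = NULL) {
  stopifnot(inherits(diffs, "difference_set"))
  D <- .points_D(points, D)
  if (diffs$n_points < 3L)
    stop("differences from fewer than 3 points leave no degrees of freedom")
  x <- points$x; j <- points$j
  a <- diffs$pairs$a; b <- diffs$pairs$b
  d <- diffs$d
  start <- .exp_init(x, j, points$y, D)
  fit <- .lm_engine(start,
    resid_fn = function(th) {
      f <- .exp_predict(th, x, j, D); d - (f[a] - f[b])
    },
    jac_fn = function(th) {
      Jf <- .exp_jacobian(th, x, j, D); Jf[a, , drop = FALSE] - Jf[b, , drop = FALSE]
    })
  .new_exp_fit(fit, n_obs = length(d), method = "naive_differences",
               notes = "SEs assume independent differences (pseudo-replication)")
}

# Union-find connectivity over the pair graph of selected difference rows.
.rows_span_points <- function(pairs, n) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs$a[k]); rb <- find(pairs$b[k])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
}

#' Row indices of a simple spanning chain of differences
#'
#' Convenience selector: the `n - 1` consecutive-point differences
#' `(1,2), (2,3), ..., (n-1,n)`, which always span the point set.
#'
#' @param diffs A [make_difference_pairs()] result.
#' @return Integer row indices into `diffs$pairs`.
#' @export
spanning_tree_rows <- function(diffs) {
  n <- diffs$n_points
  which(diffs$pairs$a == diffs$pairs$b - 1L &
          diffs$pairs$b - diffs$pairs$a == 1L)[seq_len(n - 1L)]
}

#' Correlated-data GLS fit of a spanning set of differences
#'
#' The statistically correct way to fit differences: `n - 1` difference rows
#' whose pair graph spans all `n` points are stacked with one identity row
#' for the `anchor` point, giving an invertible transform `M` of the original
#' data.  Minimizing `r' (M M')^{-1} r` on the transformed observations
#' reproduces the direct fit's parameters *and* standard errors exactly —
#' the transformation neither creates nor destroys information.
#'
#' Supplying `n` or more difference rows makes the Gram matrix `L L'`
#' singular (an attempt to exceed the information content of the data) and
#' raises an error reporting its determinant; a row set that fails to span
#' all points raises a connectivity error.
#'
#' @param diffs A [make_difference_pairs()] result.
#' @param points The source `growth_points`.
#' @param D Dilution factor (default from `points`).
#' @param rows Indices into `diffs$pairs` selecting the difference rows to
#'   fit; default all rows (so passing the full pair set demonstrates the
#'   singularity).
#' @param anchor Index of the point supplying the identity row (default 1).
#' @return An `exp_fit` with `n_obs = n` (the stacked system).
#' @export
fit_differences_gls <- function(diffs, points, D = NULL,
                                rows = seq_len(nrow(diffs$pairs)),
                                anchor = 1L) {
  stopifnot(inherits(diffs, "difference_set"))
  D <- .points_D(points, D)
  n <- diffs$n_points
  Lr <- diffs$L[rows, , drop = FALSE]
  m <- nrow(Lr)
  if (m >= n) {
    detG <- det(tcrossprod(Lr))
    stop(sprintf(paste0("singular weight matrix: det(L L') = %.3g with %d ",
                        "difference rows for %d points; at most %d rows are usable"),
                 detG, m, n, n - 1L))
  }
  pr <- diffs$pairs[rows, , drop = FALSE]
  if (m < n - 1L || !.rows_span_points(pr, n))
    stop("connectivity error: the selected difference rows do not span all points")
  stopifnot(anchor >= 1L, anchor <= n)
  e <- matrix(0, 1L, n); e[1L, anchor] <- 1
  M <- rbind(Lr, e)
  z <- as.vector(M %*% points$y)
  U <- chol(tcrossprod(M))           # M M' = U'U, whiten with solve(U', .)
  wh <- function(v) forwardsolve(t(U), v)
  x <- points$x; j <- points$j
  start <- .exp_init(x, j, points$y, D)
  fit <- .lm_engine(start,
    resid_fn = function(th) z - as.vector(M %*% .exp_predict(th, x, j, D)),
    jac_fn = function(th) M %*% .exp_jacobian(th, x, j, D),
    whiten = wh)
  .new_exp_fit(fit, n_obs = n, method = "gls_differences",
               notes = sprintf("%d spanning differences + anchor point %d", m, anchor))
}

#' Maximum number of mutually disjoint pairs
#'
#' Size of a maximum matching in the pair graph: the largest set of pairs in
#' which no raw point is reused.  For the complete pair set on `n` points
#' this is `floor(n / 2)` — e.g. only 4 statistically independent pairs can
#' be formed from 9 points, which is why pairwise schemes that use all
#' `C(n,2)` pairs manufacture no extra information.
#'
#' Exact branch-and-bound search; intended for the small point sets of a
#' growth zone.
#'
#' @param diffs A [make_difference_pairs()] result.
#' @return Integer matching number.
#' @export
max_disjoint_pairs <- function(diffs) {
  stopifnot(inherits(diffs, "difference_set"))
  pairs <- diffs$pairs
  n <- diffs$n_points
  adj <- lapply(seq_len(n), function(v)
    sort(unique(c(pairs$b[pairs$a == v], pairs$a[pairs$b == v]))))
  best <- 0L
  rec <- function(avail, count) {
    if (count + length(avail) %/% 2L <= best) return(invisible())
    v <- avail[1L]
    partners <- intersect(adj[[v]], avail)
    for (u in partners) {
      rest <- setdiff(avail, c(v, u))
      if (count + 1L > best) best <<- count + 1L
      if (length(rest) >= 2L) rec(rest, count + 1L)
    }
    rest <- setdiff(avail, v)   # leave v unmatched
    if (length(rest) >= 2L) rec(rest, count)
  }
  if (n >= 2L) rec(seq_len(n), 0L)
  best
}
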