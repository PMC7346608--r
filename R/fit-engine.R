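# Internal damped Gauss-Newton (Levenberg-Marquardt) engine.
#
# All least-squares fits in the package share this routine so that the
# convergence contract is uniform: stop when the largest relative parameter
# change falls below `tol` (default 1e-10) or after `max_iter` iterations.
#
# resid_fn(theta): observed - model residual vector.
# jac_fn(theta):   d(model)/d(theta), n x p.
# whiten:          optional function applied to both residuals and Jacobian
#                  (used for generalized least squares / per-point weights).

.lm_engine <- function(start, resid_fn, jac_fn, whiten = NULL,
                       tol = 1e-10, max_iter = 200L) {
  theta <- start
  p <- length(theta)
  eval_at <- function(th) {
    r <- resid_fn(th)
    if (!is.null(whiten)) r <- whiten(r)
    r
  }
  jac_at <- function(th) {
    J <- jac_fn(th)
    if (!is.null(whiten)) J <- whiten(J)
    J
  }
  r <- eval_at(theta)
  ssq <- sum(r^2)
  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- jac_at(theta)
    A <- crossprod(J)
    dA <- diag(A)
    if (any(!is.finite(dA)) || any(dA <= 0))
      stop("rank-deficient design: a parameter has no leverage in the fit")
    g <- crossprod(J, r)
    repeat {
      step <- tryCatch(
        solve(A + lambda * diag(dA, nrow = p), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + as.vector(step)
        rc <- tryCatch(eval_at(cand), error = function(e) NULL)
        if (!is.null(rc) && all(is.finite(rc)) && sum(rc^2) <= ssq) break
      }
      lambda <- lambda * 10
      if (lambda > 1e12) {  # cannot improve: treat as converged-in-place
        step <- rep(0, p)
        cand <- theta
        rc <- r
        break
      }
    }
    rel <- max(abs(step) / (abs(theta) + 1e-300))
    theta <- cand
    r <- rc
    ssq <- sum(r^2)
    lambda <- max(lambda / 10, 1e-12)
    if (rel < tol) { converged <- TRUE; break }
  }
  J <- jac_at(theta)
  list(par = theta, residuals = as.vector(r), chisq = ssq,
       JtJ = crossprod(J), converged = converged, n_iter = iter)
}

# Build an ExpFitResult-style object shared by all exponential-model fits.
.new_exp_fit <- function(fit, n_obs, method, notes = NULL) {
  nu <- n_obs - 2L
  s_y <- if (nu > 0) sqrt(fit$chisq / nu) else NA_real_
  JtJinv <- tryCatch(solve(fit$JtJ), error = function(e)
    matrix(NA_real_, 2, 2))
  cov <- s_y^2 * JtJinv
  se <- sqrt(pmax(diag(cov), 0))
  structure(list(y0_hat = unname(fit$par[1]), E_hat = unname(fit$par[2]),
                 se_y0 = se[1], se_E = se[2], cov = cov,
                 chisq = fit$chisq, nu = nu, s_y = s_y,
                 residuals = fit$residuals, converged = fit$converged,
                 n_iter = fit$n_iter, n_obs = n_obs, method = method,
                 notes = notes),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit: %s>\n", x$method))
  cat(sprintf("  E  = %.6g (se %.3g)\n  y0 = %.6g (se %.3g)\n",
              x$E_hat, x$se_E, x$y0_hat, x$se_y0))
  cat(sprintf("  chisq = %.6g on nu = %d  (s_y = %.4g); %s in %d iter\n",
              x$chisq, x$nu, x$s_y,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}
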