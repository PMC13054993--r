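# Damped Levenberg-Marquardt least squares with box constraints.
#
# Small, dependency-free engine for the 2-4 parameter exponential models used
# throughout the package. Deliberately tolerant of zero-residual (noiseless)
# data, which stats::nls() refuses. Box constraints are enforced by projecting
# trial steps onto [lower, upper]; with the generous physical bounds used by
# the fitters the solution is interior except in pathological cases.
#
# resid_fn(par) -> residual vector (model - data)
# jac_fn(par)   -> Jacobian of the residuals, n x p
.lm_least_squares <- function(par, resid_fn, jac_fn, lower, upper,
                              tol = 1e-8, maxit = 500) {
  par <- pmin(pmax(par, lower), upper)
  r <- resid_fn(par)
  rss <- sum(r * r)
  lambda <- 1e-3
  it <- 0L
  converged <- FALSE
  p <- length(par)
  while (it < maxit) {
    it <- it + 1L
    J <- jac_fn(par)
    g <- crossprod(J, r)                       # 0.5 * gradient of RSS
    if (max(abs(g)) < tol * max(1, rss)) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    d <- diag(JtJ)
    d[d < 1e-12] <- 1e-12
    improved <- FALSE
    for (k in 1:40) {
      A <- JtJ + lambda * diag(d, p)
      delta <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        trial <- pmin(pmax(par + as.vector(delta), lower), upper)
        rt <- resid_fn(trial)
        rsst <- sum(rt * rt)
        if (is.finite(rsst) && rsst <= rss) {
          rel <- (rss - rsst) / max(rss, .Machine$double.eps)
          par <- trial; r <- rt; rss <- rsst
          lambda <- max(lambda / 10, 1e-12)
          improved <- TRUE
          if (rel < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved || converged) {
      if (!improved && rss < 1e-20) converged <- TRUE
      break
    }
  }
  # condition number of the Jacobian at the solution, for conditioning flags
  kappa <- tryCatch({
    sv <- svd(jac_fn(par), nu = 0, nv = 0)$d
    if (min(sv) <= 0) Inf else max(sv) / min(sv)
  }, error = function(e) Inf)
  list(par = par, rss = rss, iterations = it,
       converged = converged || rss < 1e-20, condition = kappa)
}
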