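# Independent oracles and shared fixtures for the test suite.
# Oracles deliberately avoid the package's Levenberg-Marquardt path.

# Exhaustive grid search for the mono-exponential model. Returns the grid
# minimizer and the grid resolutions.
grid_search_mono <- function(te, y, s0_range, t2_range,
                             n_s0 = 201, n_t2 = 401) {
  s0g <- seq(s0_range[1], s0_range[2], length.out = n_s0)
  t2g <- seq(t2_range[1], t2_range[2], length.out = n_t2)
  E <- exp(-outer(te, 1 / t2g))              # n x n_t2
  ee <- colSums(E * E)
  ye <- colSums(y * E)
  yy <- sum(y * y)
  # rss(s0, t2) = s0^2 ee - 2 s0 ye + yy, vectorized over the s0 grid
  rss <- outer(s0g^2, ee) - 2 * outer(s0g, ye) + yy
  ix <- arrayInd(which.min(rss), dim(rss))
  list(s0 = s0g[ix[1]], t2 = t2g[ix[2]],
       rss = min(rss),
       step_s0 = diff(s0g[1:2]), step_t2 = diff(t2g[1:2]))
}

# Coarse 4-D grid search for the bi-exponential model, refined locally with
# Nelder-Mead (a different optimizer than the package's LM engine).
grid_search_bi <- function(te, y, a_range, tf_range, ts_range,
                           n_a = 7, n_t = 13) {
  a1g <- seq(a_range[1], a_range[2], length.out = n_a)
  a2g <- a1g
  tfg <- seq(tf_range[1], tf_range[2], length.out = n_t)
  tsg <- seq(ts_range[1], ts_range[2], length.out = n_t)
  grid <- expand.grid(a1 = a1g, a2 = a2g, tf = tfg, ts = tsg)
  E1 <- exp(-outer(te, 1 / tfg))
  E2 <- exp(-outer(te, 1 / tsg))
  best <- NULL
  best_rss <- Inf
  for (i in seq_along(tfg)) for (j in seq_along(tsg)) {
    e1 <- E1[, i]; e2 <- E2[, j]
    for (a1 in a1g) for (a2 in a2g) {
      r <- a1 * e1 + a2 * e2 - y
      rss <- sum(r * r)
      if (rss < best_rss) {
        best_rss <- rss
        best <- c(a1, a2, tfg[i], tsg[j])
      }
    }
  }
  ref <- stats::optim(best, function(p) {
    if (any(p[1:2] < 0) || p[3] <= 0 || p[4] <= p[3]) return(Inf)
    r <- p[1] * exp(-te / p[3]) + p[2] * exp(-te / p[4]) - y
    sum(r * r)
  }, method = "Nelder-Mead",
  control = list(maxit = 5000, reltol = 1e-12))
  list(par = ref$par, rss = ref$value)
}

# Closed-form simple-OLS oracle
ols_oracle <- function(x, y) {
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Small phantom spec that keeps whole-volume tests fast
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 1), tube_radius = 2, ...)
}
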