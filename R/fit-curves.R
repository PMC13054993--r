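#' @rdname fit_mono
#' @param model one of `"mono"`, `"bi"`, `"ir"`.
#' @param params fitted parameter object, or `NULL` when the fit failed.
#' @param rss residual sum of squares.
#' @param n number of samples.
#' @param converged logical convergence flag.
#' @param iterations optimizer iteration count.
#' @param signal_max largest absolute signal in the fitted curve (used for
#'   the information-criterion RSS floor).
#' @param flags character vector of quality flags, e.g. `"effectively_mono"`,
#'   `"ill_conditioned"`.
#' @export
fit_result <- function(model, params, rss, n, converged, iterations = 0L,
                       signal_max = 1, flags = character()) {
  structure(list(model = model, params = params, rss = rss, n = n,
                 converged = converged, iterations = iterations,
                 signal_max = signal_max, flags = flags),
            class = "relaxo_fit")
}

#' @export
print.relaxo_fit <- function(x, ...) {
  cat(sprintf("<relaxo_fit> %s, n = %d, rss = %.6g, converged = %s%s\n",
              x$model, x$n, x$rss, x$converged,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  if (!is.null(x$params)) utils::str(unclass(x$params), give.attr = FALSE)
  invisible(x)
}

.failed_fit <- function(model, n, signal_max = 0) {
  fit_result(model, NULL, rss = NA_real_, n = n, converged = FALSE,
             signal_max = signal_max, flags = "degenerate_input")
}

# shared physical bounds (ms / signal units)
.T_MIN <- 1
.T_MAX <- 5000

#' Fit relaxation curves
#'
#' `fit_mono()` fits the single-compartment decay `S0 * exp(-TE/T2)` to a
#' multi-echo curve by damped Levenberg-Marquardt least squares, started from
#' a log-linear ordinary-least-squares guess. `fit_bi()` fits the
#' two-compartment model, initialized from the mono fit
#' (`A1 = A2 = S0/2`, `T2_fast = T2/2`, `T2_slow = 2 T2`), reorders the
#' components so that `T2_fast < T2_slow`, and flags the result
#' `"effectively_mono"` when the components collapse
#' (`T2_slow / T2_fast < 1.2` or either amplitude below 1% of their sum).
#' `fit_t1_ir()` fits the inversion-recovery model, optionally with a free
#' inversion-efficiency factor and optionally on magnitude (unsigned) data.
#'
#' Degenerate input (all-zero or non-finite curves) yields a result with
#' `converged = FALSE` rather than an error, so whole-volume runs never die
#' on a single voxel. T2/T1 estimates are constrained to \[1, 5000\] ms and
#' amplitudes to \[0, 10 x max signal\]; convergence is declared at relative
#' RSS change below 1e-8 (at most 500 iterations).
#'
#' @param curve a [decay_curve()]; `fit_mono` needs >= 3 samples, `fit_bi`
#'   needs >= 5, `fit_t1_ir` needs >= 3 and an IR schedule.
#' @return a `relaxo_fit` object (see [fit_result()]).
#' @examples
#' sch <- msme_schedule()
#' y <- mono_decay(mono_params(100, 50), sch$times)
#' fit_mono(decay_curve(sch, y))
#' @export
fit_mono <- function(curve) {
  stopifnot(inherits(curve, "decay_curve"))
  te <- curve$schedule$times
  y <- curve$signal
  n <- length(y)
  if (n < 3L) stop("fit_mono needs at least 3 samples")
  smax <- suppressWarnings(max(abs(y[is.finite(y)]), -Inf))
  if (!all(is.finite(y)) || smax <= 0)
    return(.failed_fit("mono", n, max(smax, 0)))

  # log-linear OLS on positive samples for the starting point
  pos <- which(y > 0)
  if (length(pos) >= 2L) {
    cf <- stats::lm.fit(cbind(1, te[pos]), log(y[pos]))$coefficients
    t0 <- if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else stats::median(te)
    s0 <- if (is.finite(cf[1])) exp(cf[1]) else smax
  } else {
    t0 <- stats::median(te)
    s0 <- smax
  }
  lower <- c(0, .T_MIN)
  upper <- c(10 * smax, .T_MAX)
  start <- pmin(pmax(c(s0, t0), lower), upper)

  resid_fn <- function(p) .mono_model(te, p[1], p[2]) - y
  jac_fn <- function(p) {
    e <- exp(-te / p[2])
    cbind(e, p[1] * te * e / p[2]^2)
  }
  sol <- .lm_least_squares(start, resid_fn, jac_fn, lower, upper)
  fit_result("mono", mono_params(sol$par[1], max(sol$par[2], .T_MIN)),
             rss = sol$rss, n = n, converged = sol$converged,
             iterations = sol$iterations, signal_max = smax)
}

#' @rdname fit_mono
#' @export
fit_bi <- function(curve) {
  stopifnot(inherits(curve, "decay_curve"))
  te <- curve$schedule$times
  y <- curve$signal
  n <- length(y)
  if (n < 5L) stop("fit_bi needs at least 5 samples")
  fm <- fit_mono(curve)
  smax <- fm$signal_max
  if (!fm$converged && is.null(fm$params))
    return(.failed_fit("bi", n, smax))

  s0 <- fm$params$s0
  t2 <- fm$params$t
  start <- c(s0 / 2, s0 / 2,
             max(t2 / 2, .T_MIN), min(2 * t2, .T_MAX))
  if (start[4] <= start[3]) start[4] <- min(start[3] * 4, .T_MAX)
  lower <- c(0, 0, .T_MIN, .T_MIN)
  upper <- c(10 * smax, 10 * smax, .T_MAX, .T_MAX)

  resid_fn <- function(p) .bi_model(te, p[1], p[2], p[3], p[4]) - y
  jac_fn <- function(p) {
    e1 <- exp(-te / p[3]); e2 <- exp(-te / p[4])
    cbind(e1, e2, p[1] * te * e1 / p[3]^2, p[2] * te * e2 / p[4]^2)
  }
  sol <- .lm_least_squares(start, resid_fn, jac_fn, lower, upper)

  p <- sol$par
  if (p[3] > p[4]) p <- p[c(2, 1, 4, 3)]
  rss <- sol$rss
  converged <- sol$converged
  flags <- character()

  # nested models: bi must never fit worse than mono; if the optimizer got
  # stuck, fall back to the mono solution expressed as a degenerate bi fit
  if (!is.na(fm$rss) && rss > fm$rss + 1e-9 * max(1, fm$rss)) {
    p <- c(s0, 0, max(t2, .T_MIN), min(max(2 * t2, t2 * 1.5), .T_MAX))
    if (p[4] <= p[3]) p[3] <- p[4] / 2
    rss <- fm$rss
    converged <- fm$converged
    flags <- "fallback_to_mono"
  }
  total <- p[1] + p[2]
  if (p[4] / p[3] < 1.2 || (total > 0 && min(p[1], p[2]) < 0.01 * total))
    flags <- union(flags, "effectively_mono")
  if (p[4] <= p[3]) p[4] <- p[3] * (1 + 1e-9)   # guard the type invariant
  fit_result("bi", bi_params(p[1], p[2], p[3], p[4]),
             rss = rss, n = n, converged = converged,
             iterations = sol$iterations, signal_max = smax, flags = flags)
}

#' @rdname fit_mono
#' @param beta_free fit the inversion-efficiency factor as a free parameter
#'   in \[1, 2\] instead of fixing it at the ideal value 2.
#' @param magnitude the data are magnitude-valued (unsigned): the model is
#'   fitted through `|S(TI)|`.
#' @export
fit_t1_ir <- function(curve, beta_free = FALSE, magnitude = FALSE) {
  stopifnot(inherits(curve, "decay_curve"))
  if (curve$schedule$kind != "IR")
    stop("fit_t1_ir needs an IR schedule")
  ti <- curve$schedule$times
  y <- curve$signal
  n <- length(y)
  if (n < 3L) stop("fit_t1_ir needs at least 3 samples")
  smax <- suppressWarnings(max(abs(y[is.finite(y)]), -Inf))
  if (!all(is.finite(y)) || smax <= 0)
    return(.failed_fit("ir", n, max(smax, 0)))

  # T1 guess from the null point: |S| is smallest near TI = T1 ln 2
  t1_0 <- ti[which.min(abs(y))] / log(2)
  t1_0 <- min(max(t1_0, .T_MIN), .T_MAX)
  start <- c(smax, t1_0)
  lower <- c(0, .T_MIN)
  upper <- c(10 * smax, .T_MAX)
  if (beta_free) {
    start <- c(start, 2)
    lower <- c(lower, 1)
    upper <- c(upper, 2)
  }
  bfix <- 2
  model <- function(p) .ir_model(ti, p[1], p[2], if (beta_free) p[3] else bfix)
  resid_fn <- function(p) {
    m <- model(p)
    (if (magnitude) abs(m) else m) - y
  }
  jac_fn <- function(p) {
    b <- if (beta_free) p[3] else bfix
    e <- exp(-ti / p[2])
    m <- p[1] * (1 - b * e)
    J <- cbind(1 - b * e, -p[1] * b * ti * e / p[2]^2)
    if (beta_free) J <- cbind(J, -p[1] * e)
    if (magnitude) J * sign(m) else J
  }
  sol <- .lm_least_squares(start, resid_fn, jac_fn, lower, upper)
  flags <- character()
  if (is.finite(sol$condition) && sol$condition > 1e6 || !is.finite(sol$condition))
    flags <- "ill_conditioned"
  res <- fit_result("ir", mono_params(sol$par[1], max(sol$par[2], .T_MIN)),
                    rss = sol$rss, n = n, converged = sol$converged,
                    iterations = sol$iterations, signal_max = smax,
                    flags = flags)
  res$beta <- if (beta_free) sol$par[3] else bfix
  res
}

#' Subtract the background (agarose) relaxation rate
#'
#' The agarose block contributes a bulk transverse rate that must be removed
#' from each tube's measured R2 before calibrating relaxivity. The
#' difference is returned as-is: blank replicates scattering below the
#' background rate give slightly negative corrected rates, which are kept so
#' the blank standard deviation used by the limit of detection is unbiased.
#'
#' @param r2_sample measured rate(s), s^-1.
#' @param r2_background background rate, s^-1.
#' @return corrected rate(s), s^-1 (possibly negative).
#' @export
subtract_background <- function(r2_sample, r2_background) {
  if (any(!is.finite(r2_sample)) || any(!is.finite(r2_background)))
    stop("rates must be finite")
  r2_sample - r2_background
}
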