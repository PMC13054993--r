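#' Akaike and Bayesian information criteria from a residual sum of squares
#'
#' `AIC = n ln(RSS) + 2k` and `BIC = n ln(RSS) + k ln(n)`, with `n` the
#' number of samples, `k` the number of fitted parameters and RSS the
#' residual sum of squares. Before the logarithm, RSS is floored at
#' `1e-12 * n * signal_max^2` so that noiseless (zero-residual) fits remain
#' comparable instead of producing `-Inf`; at a common floor the criteria
#' differ only by their parsimony penalties.
#'
#' Note the criteria use `ln(RSS)` rather than the also-common `ln(RSS/n)`;
#' at fixed `n` the two differ by a constant, so model ranking between
#' candidates fitted to the same curve is unaffected.
#'
#' @param rss residual sum of squares, >= 0 (vectorized).
#' @param n number of samples, >= 1.
#' @param k number of model parameters (mono: 2, bi: 4).
#' @param signal_max signal scale used in the RSS floor; use the curve's
#'   maximum absolute signal.
#' @return list with numeric components `aic` and `bic`.
#' @examples
#' information_criteria(1, 40, 2)  # aic = 4, bic = 2 ln 40
#' @export
information_criteria <- function(rss, n, k, signal_max = 1) {
  if (any(n < 1) || any(k < 1) || any(rss < 0, na.rm = TRUE))
    stop("need n >= 1, k >= 1, rss >= 0")
  floor_eps <- 1e-12 * n * signal_max^2
  rss_f <- pmax(rss, floor_eps)
  list(aic = n * log(rss_f) + 2 * k,
       bic = n * log(rss_f) + k * log(n))
}

#' Choose between mono- and bi-exponential fits of one curve
#'
#' Computes AIC and BIC for both fits (`k = 2` for mono, `k = 4` for bi) and
#' the differences `delta = criterion(mono) - criterion(bi)`, so positive
#' deltas favor the bi-exponential model. The bi model is selected when the
#' delta(s) exceed `threshold` (default 10) under the chosen rule:
#' `"AND"` requires both ΔAIC and ΔBIC above threshold (the conservative
#' default used for binary maps), `"OR"` either one. A bi fit flagged
#' `"effectively_mono"` always yields `chosen = "mono"`.
#'
#' @param fit_mono,fit_bi `relaxo_fit` objects for the same curve.
#' @param rule `"AND"` or `"OR"`.
#' @param threshold selection threshold on the deltas, default 10.
#' @return an object of class `relaxo_selection` with the criterion values,
#'   `delta_aic`, `delta_bic`, `chosen` and the rule used.
#' @export
select_model <- function(fit_mono, fit_bi, rule = c("AND", "OR"),
                         threshold = 10) {
  rule <- match.arg(rule)
  stopifnot(inherits(fit_mono, "relaxo_fit"), inherits(fit_bi, "relaxo_fit"))
  if (fit_mono$n != fit_bi$n)
    stop("fits compare different curves (n mismatch)")
  n <- fit_mono$n
  smax <- max(fit_mono$signal_max, fit_bi$signal_max)
  icm <- information_criteria(fit_mono$rss, n, 2, smax)
  icb <- information_criteria(fit_bi$rss, n, 4, smax)
  delta_aic <- icm$aic - icb$aic
  delta_bic <- icm$bic - icb$bic
  pass <- if (rule == "AND") delta_aic > threshold && delta_bic > threshold
          else delta_aic > threshold || delta_bic > threshold
  chosen <- if (pass && !("effectively_mono" %in% fit_bi$flags)) "bi" else "mono"
  structure(list(aic_mono = icm$aic, aic_bi = icb$aic,
                 bic_mono = icm$bic, bic_bi = icb$bic,
                 delta_aic = delta_aic, delta_bic = delta_bic,
                 chosen = chosen, rule = rule, threshold = threshold),
            class = "relaxo_selection")
}

#' @export
print.relaxo_selection <- function(x, ...) {
  cat(sprintf("<relaxo_selection> chosen = %s (dAIC = %.3g, dBIC = %.3g, %s > %g)\n",
              x$chosen, x$delta_aic, x$delta_bic, x$rule, x$threshold))
  invisible(x)
}

#' Build parametric and binary model-selection maps
#'
#' Applies the AIC/BIC comparison voxel-wise to a fitted volume and
#' assembles the parametric maps: the fast and slow T2 components where the
#' bi-exponential model is selected (missing elsewhere), the mono T2
#' everywhere in the mask, and the binary map marking dual-component voxels
#' (1 = bi selected, 0 = mono, NA outside the mask or where fitting failed).
#'
#' @param fits a `relaxo_volume_fits` from [fit_volume()] with `bi = TRUE`.
#' @param rule,threshold see [select_model()].
#' @return an object of class `parametric_maps`: arrays `t2_fast_map`,
#'   `t2_slow_map`, `t2_mono_map`, `binary_map`, `delta_aic`, `delta_bic`,
#'   plus `voxel_size` and the selection parameters.
#' @export
build_maps <- function(fits, rule = c("AND", "OR"), threshold = 10) {
  rule <- match.arg(rule)
  stopifnot(inherits(fits, "relaxo_volume_fits"))
  if (!isTRUE(fits$has_bi))
    stop("fit_volume() must be run with bi = TRUE for model selection")
  gs <- dim(fits$mask)
  smax <- fits$signal_max
  n <- fits$n

  icm <- information_criteria(fits$mono_rss, n, 2, smax)
  icb <- information_criteria(fits$bi_rss, n, 4, smax)
  delta_aic <- icm$aic - icb$aic
  delta_bic <- icm$bic - icb$bic

  pass <- if (rule == "AND") delta_aic > threshold & delta_bic > threshold
          else delta_aic > threshold | delta_bic > threshold
  pass[is.na(pass)] <- FALSE
  pass <- pass & !fits$bi_effectively_mono

  binary <- array(NA_real_, dim = gs)
  ok <- fits$mask & !is.na(fits$mono_rss) & !is.na(fits$bi_rss)
  binary[ok] <- as.numeric(pass[ok])

  t2_fast <- array(NA_real_, dim = gs)
  t2_slow <- array(NA_real_, dim = gs)
  sel <- ok & pass
  t2_fast[sel] <- fits$bi_t2_fast[sel]
  t2_slow[sel] <- fits$bi_t2_slow[sel]
  t2_mono <- array(NA_real_, dim = gs)
  inm <- fits$mask & !is.na(fits$mono_t2)
  t2_mono[inm] <- fits$mono_t2[inm]

  structure(list(t2_fast_map = t2_fast, t2_slow_map = t2_slow,
                 t2_mono_map = t2_mono, binary_map = binary,
                 delta_aic = delta_aic, delta_bic = delta_bic,
                 voxel_size = fits$voxel_size, rule = rule,
                 threshold = threshold),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  nbi <- sum(x$binary_map == 1, na.rm = TRUE)
  nok <- sum(!is.na(x$binary_map))
  cat(sprintf("<parametric_maps> %s grid, %d/%d voxels bi-exponential (%s > %g)\n",
              paste(dim(x$binary_map), collapse = "x"), nbi, nok,
              x$rule, x$threshold))
  invisible(x)
}

#' One-call voxel-wise mapping pipeline
#'
#' Convenience wrapper: mask, fit mono and bi models per voxel, and build the
#' selection maps.
#'
#' @param volume a [relaxo_volume()].
#' @param mask_fraction masking threshold, see [mask_volume()].
#' @param rule,threshold see [select_model()].
#' @return list with `fits` (the [fit_volume()] result) and `maps`
#'   (the [build_maps()] result).
#' @export
fit_maps <- function(volume, mask_fraction = 0.05, rule = c("AND", "OR"),
                     threshold = 10) {
  rule <- match.arg(rule)
  fits <- fit_volume(volume, mask_fraction = mask_fraction, bi = TRUE)
  list(fits = fits, maps = build_maps(fits, rule = rule, threshold = threshold))
}
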