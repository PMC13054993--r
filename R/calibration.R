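# proton gyromagnetic ratio over 2*pi, MHz per tesla
.GAMMA_MHZ_PER_T <- 42.577

#' Concentration series for relaxivity calibration
#'
#' @param fe_mM iron concentrations, mM, >= 0.
#' @param rates background-corrected relaxation rates, s^-1.
#' @param labels optional sample labels.
#' @param rate_sd optional per-level replicate standard deviations, s^-1.
#' @return an object of class `concentration_series` (also a data.frame).
#' @export
concentration_series <- function(fe_mM, rates, labels = NULL, rate_sd = NULL) {
  fe_mM <- as.numeric(fe_mM)
  rates <- as.numeric(rates)
  if (length(fe_mM) != length(rates))
    stop("fe_mM and rates must have the same length")
  if (any(!is.finite(fe_mM)) || any(fe_mM < 0))
    stop("concentrations must be finite and >= 0")
  if (any(!is.finite(rates))) stop("rates must be finite")
  if (is.null(labels)) labels <- sprintf("s%02d", seq_along(fe_mM))
  df <- data.frame(label = labels, fe_mM = fe_mM, rate_s1 = rates,
                   stringsAsFactors = FALSE)
  if (!is.null(rate_sd)) df$rate_sd <- as.numeric(rate_sd)
  class(df) <- c("concentration_series", "data.frame")
  df
}

#' Relaxivity calibration by ordinary least squares
#'
#' Regresses the (background-corrected) relaxation rate on iron
#' concentration. The slope is the relaxivity in mM^-1 s^-1 and the
#' intercept the diamagnetic/background rate in s^-1. When the blank
#' standard deviation is available — either supplied directly, taken from
#' the blank's `rate_sd` column, or computed across replicate 0 mM entries —
#' the 3-sigma limit of detection is attached.
#'
#' @param series a [concentration_series()] (or anything coercible: a
#'   data.frame with columns `fe_mM` and `rate_s1`).
#' @param sigma_blank blank standard deviation in s^-1, overriding anything
#'   in the series.
#' @return an object of class `calibration_fit`: `slope`, `intercept`,
#'   `sigma_blank`, `lod_mM`, `r_squared`, `n`.
#' @examples
#' x <- c(0, 0.0025, 0.005, 0.01, 0.025, 0.05, 0.075, 0.1)
#' fit_calibration(concentration_series(x, 145 * x + 7), sigma_blank = 0.5)
#' @export
fit_calibration <- function(series, sigma_blank = NULL) {
  if (!inherits(series, "concentration_series"))
    series <- concentration_series(series$fe_mM, series$rate_s1,
                                   labels = series$label)
  x <- series$fe_mM
  y <- series$rate_s1
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct concentrations")
  if (stats::var(x) == 0) stop("zero concentration variance")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_

  if (is.null(sigma_blank)) {
    blanks <- which(x == 0)
    if (!is.null(series$rate_sd) && length(blanks))
      sigma_blank <- series$rate_sd[blanks[1]]
    else if (length(blanks) >= 2L)
      sigma_blank <- stats::sd(y[blanks])
  }
  lod <- if (!is.null(sigma_blank) && is.finite(slope) && slope > 0)
    limit_of_detection(slope, sigma_blank) else NA_real_

  structure(list(slope = slope, intercept = intercept,
                 sigma_blank = if (is.null(sigma_blank)) NA_real_ else sigma_blank,
                 lod_mM = lod, r_squared = r2, n = length(y)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> rate = %.4g * [Fe] + %.4g  (r^2 = %.5f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  if (is.finite(x$lod_mM))
    cat(sprintf("  LOD (3 sigma, sigma_blank = %.3g s^-1): %.4g mM (%.3g uM)\n",
                x$sigma_blank, x$lod_mM, 1000 * x$lod_mM))
  invisible(x)
}

#' 3-sigma limit of detection
#'
#' `LOD = 3 * sigma_blank / slope`: the smallest concentration whose signal
#' exceeds the blank by three blank standard deviations.
#'
#' @param slope calibration slope (relaxivity), mM^-1 s^-1, > 0.
#' @param sigma_blank standard deviation of the blank (0 mM) rate, s^-1.
#' @return limit of detection in mM.
#' @examples
#' limit_of_detection(145, 0.5) * 1000  # ~10.3 uM
#' @export
limit_of_detection <- function(slope, sigma_blank) {
  if (!is.finite(slope) || slope <= 0)
    stop("limit of detection needs a positive calibration slope")
  if (!is.finite(sigma_blank) || sigma_blank < 0)
    stop("sigma_blank must be >= 0")
  3 * sigma_blank / slope
}

#' Iron concentration from the longitudinal relaxation rate
#'
#' Inverts the standard curve `R1 = Rdia + [Fe] * r1p` used for relaxometric
#' iron quantification of mineralized samples. The defaults are the nitric
#' acid diamagnetic contribution (0.52 s^-1) and the iron relaxivity of the
#' mineralized standards (1.29 mM^-1 s^-1). Measured rates below `r_dia`
#' give negative concentrations; these are returned unclamped with a
#' warning, since honest blank scatter must survive for downstream
#' statistics.
#'
#' @param r1_measured measured R1, s^-1 (vectorized).
#' @param r_dia diamagnetic rate, s^-1.
#' @param r1p iron relaxivity, mM^-1 s^-1, non-zero.
#' @return iron concentration(s) in mM, with attribute `flagged` marking
#'   negative values.
#' @examples
#' iron_from_r1(1.81)  # 1 mM
#' @export
iron_from_r1 <- function(r1_measured, r_dia = 0.52, r1p = 1.29) {
  if (r1p == 0) stop("r1p must be non-zero")
  if (any(!is.finite(r1_measured))) stop("r1_measured must be finite")
  fe <- (r1_measured - r_dia) / r1p
  flagged <- fe < 0
  if (any(flagged))
    warning("negative iron concentration(s): measured R1 below the ",
            "diamagnetic rate (blank scatter); values not clamped")
  attr(fe, "flagged") <- flagged
  fe
}

#' Assemble an NMRD profile
#'
#' Builds an ordered nuclear-magnetic-relaxation-dispersion profile from
#' relaxivity points measured at various magnetic fields. Each point must
#' carry the field (tesla) or the proton Larmor frequency (MHz); the missing
#' axis is filled with `frequency = 42.577 * field`. Points are sorted by
#' field and duplicate fields are averaged.
#'
#' @param points data.frame with columns `relaxivity` (mM^-1 s^-1) and at
#'   least one of `field_T`, `freq_MHz`; optional `channel` (`"r1"`/`"r2"`).
#' @return data.frame of class `nmrd_profile`, sorted by field, with columns
#'   `field_T`, `freq_MHz`, `relaxivity`, `channel`.
#' @export
assemble_nmrd <- function(points) {
  points <- as.data.frame(points)
  if (nrow(points) < 1L) stop("need at least one point")
  if (is.null(points$relaxivity)) stop("points need a relaxivity column")
  f <- if (!is.null(points$field_T)) as.numeric(points$field_T)
       else rep(NA_real_, nrow(points))
  mhz <- if (!is.null(points$freq_MHz)) as.numeric(points$freq_MHz)
         else rep(NA_real_, nrow(points))
  if (any(is.na(f) & is.na(mhz)))
    stop("every point needs a field or a frequency")
  # cross-check points that carry both axes (1% tolerance on gamma)
  both <- !is.na(f) & !is.na(mhz)
  if (any(both)) {
    ratio <- mhz[both] / (f[both] * .GAMMA_MHZ_PER_T)
    if (any(abs(ratio - 1) > 0.01))
      warning("field/frequency pairs inconsistent with 42.577 MHz/T")
  }
  f[is.na(f)] <- mhz[is.na(f)] / .GAMMA_MHZ_PER_T
  mhz[is.na(mhz)] <- f[is.na(mhz)] * .GAMMA_MHZ_PER_T
  ch <- if (!is.null(points$channel)) as.character(points$channel)
        else rep("r1", nrow(points))
  df <- data.frame(field_T = f, freq_MHz = mhz,
                   relaxivity = as.numeric(points$relaxivity),
                   channel = ch, stringsAsFactors = FALSE)
  agg <- stats::aggregate(cbind(freq_MHz, relaxivity) ~ field_T + channel,
                          data = df, FUN = mean)
  agg <- agg[order(agg$field_T), c("field_T", "freq_MHz", "relaxivity",
                                   "channel")]
  rownames(agg) <- NULL
  class(agg) <- c("nmrd_profile", "data.frame")
  agg
}

#' Classify a magnetic field strength
#'
#' Field-regime bins used when tabulating relaxivities: ultralow field
#' (< 0.1 T), intermediate field (0.5-1.5 T, clinical MRI), high field
#' (> 3 T). Fields in the gaps (e.g. 2 T) are `"other"`.
#'
#' @param field field strength(s) in tesla, > 0.
#' @return character vector in `{"ULF", "IF", "HF", "other"}`.
#' @export
classify_field_regime <- function(field) {
  field <- as.numeric(field)
  if (any(!is.finite(field)) || any(field <= 0))
    stop("field must be positive")
  out <- rep("other", length(field))
  out[field < 0.1] <- "ULF"
  out[field >= 0.5 & field <= 1.5] <- "IF"
  out[field > 3] <- "HF"
  out
}

#' Classify a contrast agent by its r2/r1 ratio
#'
#' Low ratios (< 5) indicate T1-dominant behavior, high ratios (> 10)
#' predominant T2 contrast, intermediate values potential dual-mode
#' behavior.
#'
#' @param r1 longitudinal relaxivity, mM^-1 s^-1, > 0.
#' @param r2 transverse relaxivity, mM^-1 s^-1.
#' @return list with `ratio` and `class` in
#'   `{"T1-dominant", "intermediate", "T2-dominant"}`.
#' @examples
#' classify_contrast_agent(1, 12)$class  # T2-dominant
#' @export
classify_contrast_agent <- function(r1, r2) {
  if (!is.finite(r1) || r1 <= 0) stop("r1 must be positive")
  ratio <- r2 / r1
  cls <- if (ratio < 5) "T1-dominant"
         else if (ratio > 10) "T2-dominant"
         else "intermediate"
  list(ratio = ratio, class = cls)
}
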