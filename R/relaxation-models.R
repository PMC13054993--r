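#' Mono-exponential parameters
#'
#' Amplitude and relaxation time of a single-compartment decay (T2) or
#' recovery (T1) model.
#'
#' @param s0 signal amplitude, arbitrary units; must be >= 0.
#' @param t relaxation time in ms (T2 for decay, T1 for recovery); must be
#'   positive (`Inf` is tolerated and means "no decay").
#' @return an object of class `mono_params`.
#' @export
mono_params <- function(s0, t) {
  if (!is.finite(s0) || s0 < 0) stop("s0 must be finite and >= 0")
  if (is.na(t) || t <= 0) stop("relaxation time must be positive")
  structure(list(s0 = as.numeric(s0), t = as.numeric(t)),
            class = "mono_params")
}

#' Bi-exponential parameters
#'
#' Two-compartment transverse decay: a fast component (water protons close to
#' magnetic particles) and a slow component (bulk-like water). The ordering
#' convention `t2_fast < t2_slow` is enforced.
#'
#' @param a1,a2 component amplitudes, arbitrary units, >= 0.
#' @param t2_fast,t2_slow component relaxation times in ms with
#'   `0 < t2_fast < t2_slow`.
#' @return an object of class `bi_params`.
#' @export
bi_params <- function(a1, a2, t2_fast, t2_slow) {
  if (any(!is.finite(c(a1, a2))) || a1 < 0 || a2 < 0)
    stop("amplitudes must be finite and >= 0")
  if (!is.finite(t2_fast) || !is.finite(t2_slow) ||
      t2_fast <= 0 || t2_slow <= t2_fast)
    stop("need 0 < t2_fast < t2_slow")
  structure(list(a1 = as.numeric(a1), a2 = as.numeric(a2),
                 t2_fast = as.numeric(t2_fast),
                 t2_slow = as.numeric(t2_slow)),
            class = "bi_params")
}

# internal vectorized kernels used by generators and fitters
.mono_model <- function(te, s0, t) s0 * exp(-te / t)
.bi_model <- function(te, a1, a2, tf, ts) a1 * exp(-te / tf) + a2 * exp(-te / ts)
.ir_model <- function(ti, s0, t1, beta = 2) s0 * (1 - beta * exp(-ti / t1))

#' Mono-exponential decay signal
#'
#' Forward model `S(TE) = S0 * exp(-TE / T)` of single-compartment transverse
#' decay (or, with `t` read as T1, any single-exponential relaxation).
#'
#' @param p a [mono_params()] object.
#' @param te echo time(s), ms, >= 0; vectorized.
#' @return signal value(s), arbitrary units.
#' @examples
#' mono_decay(mono_params(100, 50), c(0, 50))  # 100, 100/e
#' @export
mono_decay <- function(p, te) {
  stopifnot(inherits(p, "mono_params"))
  te <- as.numeric(te)
  if (any(te < 0)) stop("te must be >= 0")
  .mono_model(te, p$s0, p$t)
}

#' Bi-exponential decay signal
#'
#' Forward model `S(TE) = A1 * exp(-TE / T2_fast) + A2 * exp(-TE / T2_slow)`.
#' At `TE = 0` the signal equals `A1 + A2`.
#'
#' @param p a [bi_params()] object.
#' @param te echo time(s), ms, >= 0; vectorized.
#' @return signal value(s), arbitrary units.
#' @export
bi_decay <- function(p, te) {
  stopifnot(inherits(p, "bi_params"))
  te <- as.numeric(te)
  if (any(te < 0)) stop("te must be >= 0")
  .bi_model(te, p$a1, p$a2, p$t2_fast, p$t2_slow)
}

#' Inversion-recovery signal
#'
#' Longitudinal recovery after a 180-degree inversion pulse,
#' `S(TI) = S0 * (1 - beta * exp(-TI / T1))`. With ideal inversion
#' (`beta = 2`) the signal starts at `-S0`, crosses zero at `TI = T1 * ln 2`
#' and recovers to `S0`. `beta` may be fitted as a free parameter when the
#' inversion is imperfect or the data are magnitude-valued.
#'
#' @param p a [mono_params()] object whose `t` field is T1 (ms).
#' @param ti inversion time(s), ms, >= 0; vectorized.
#' @param beta inversion efficiency factor; 2 = ideal inversion.
#' @return signal value(s), arbitrary units (signed).
#' @export
ir_signal <- function(p, ti, beta = 2) {
  stopifnot(inherits(p, "mono_params"))
  ti <- as.numeric(ti)
  if (any(ti < 0)) stop("ti must be >= 0")
  .ir_model(ti, p$s0, p$t, beta)
}

#' Convert between relaxation time and rate
#'
#' `R [1/s] = 1000 / T [ms]` and conversely; the conversion is an involution
#' (applying it twice returns the input).
#'
#' @param value positive time (ms) or rate (1/s).
#' @param direction `"time_to_rate"` or `"rate_to_time"`; both apply the same
#'   reciprocal-with-unit-factor formula and the argument exists to make call
#'   sites self-documenting.
#' @return the converted value.
#' @examples
#' rate_time_convert(100, "time_to_rate")  # 10 s^-1
#' @export
rate_time_convert <- function(value,
                              direction = c("time_to_rate", "rate_to_time")) {
  direction <- match.arg(direction)
  value <- as.numeric(value)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("value must be finite and positive")
  1000 / value
}
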