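#' Acquisition schedule
#'
#' An ordered set of sampling times for a relaxometry acquisition: echo times
#' (TE) for a CPMG/MSME transverse-decay experiment, or inversion times (TI)
#' for an inversion-recovery (IR) longitudinal experiment. All times are in
#' milliseconds.
#'
#' @param times numeric vector of sampling times in ms; strictly increasing,
#'   all positive.
#' @param kind `"CPMG"` (multi-echo transverse decay, the MSME imaging case)
#'   or `"IR"` (inversion recovery).
#' @param repetition_time optional TR in ms, carried as metadata.
#' @return an object of class `acq_schedule`.
#' @examples
#' sch <- msme_schedule()
#' range(sch$times)  # 10 .. 400 ms
#' @export
acq_schedule <- function(times, kind = c("CPMG", "IR"), repetition_time = NULL) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  if (length(times) < 1L || anyNA(times) || any(!is.finite(times)))
    stop("schedule times must be finite and non-empty")
  if (any(times <= 0))
    stop("schedule times must be positive")
  if (is.unsorted(times, strictly = TRUE))
    stop("schedule times must be strictly increasing")
  structure(list(times = times, kind = kind,
                 repetition_time = repetition_time),
            class = "acq_schedule")
}

#' Default multi-slice multi-echo schedule
#'
#' 40 echo times evenly spaced between 10 and 400 ms, the schedule used for
#' voxel-wise T2 mapping of the injected-brain volumes.
#'
#' @param n_echoes number of echoes.
#' @param first,last first and last echo times, ms.
#' @param repetition_time TR in ms (metadata only).
#' @return an `acq_schedule` of kind `"CPMG"`.
#' @export
msme_schedule <- function(n_echoes = 40, first = 10, last = 400,
                          repetition_time = 5000) {
  acq_schedule(seq(first, last, length.out = n_echoes), kind = "CPMG",
               repetition_time = repetition_time)
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat(sprintf("<acq_schedule> %s, %d samples, %.6g-%.6g ms\n",
              x$kind, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Decay (or recovery) curve
#'
#' One voxel's or one sample's signal versus sampling time. Time/signal pairs
#' are sorted jointly into increasing-time order, so fits are invariant to
#' the order in which the pairs are supplied.
#'
#' @param times an `acq_schedule`, or a numeric vector of sampling times (ms).
#' @param signal numeric signal values, same length as the times.
#' @param kind used only when `times` is a bare numeric vector.
#' @return an object of class `decay_curve` with fields `schedule` and
#'   `signal`.
#' @export
decay_curve <- function(times, signal, kind = c("CPMG", "IR")) {
  if (inherits(times, "acq_schedule")) {
    sch <- times
  } else {
    kind <- match.arg(kind)
    times <- as.numeric(times)
    ord <- order(times)
    times <- times[ord]
    signal <- signal[ord]
    sch <- acq_schedule(times, kind = kind)
  }
  signal <- as.numeric(signal)
  if (length(signal) != length(sch$times))
    stop("signal length must match the number of sampling times")
  structure(list(schedule = sch, signal = signal), class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %s, n = %d\n", x$schedule$kind,
              length(x$signal)))
  invisible(x)
}
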