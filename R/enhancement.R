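#' Signal enhancement percentage
#'
#' `100 * (post - pre) / pre`: the relative signal change of an ROI after
#' contrast-agent administration. T2 agents darken the tissue, so their
#' enhancement is negative; the signed value is canonical and its magnitude
#' is what contrast time-course plots typically show.
#'
#' @param pre_mean baseline ROI mean signal, a.u., non-zero.
#' @param post_mean post-injection ROI mean signal(s), a.u. (vectorized).
#' @return enhancement in percent (signed).
#' @examples
#' enhancement(100, 55)  # -45
#' @export
enhancement <- function(pre_mean, post_mean) {
  if (!is.finite(pre_mean) || pre_mean == 0)
    stop("pre_mean must be finite and non-zero")
  100 * (post_mean - pre_mean) / pre_mean
}

#' ROI enhancement time course
#'
#' Computes the ROI mean of each serial volume and the enhancement of every
#' post time relative to the pre (baseline) volume.
#'
#' @param volumes list of 3-D arrays (or [relaxo_volume()] objects, whose
#'   first time point is used), all of the same shape.
#' @param roi logical 3-D array or integer index matrix (columns x, y, z);
#'   must be non-empty and inside the grid.
#' @param times character or numeric labels, one per volume.
#' @param pre_index which volume is the baseline; default the first.
#' @return data.frame of class `roi_timeseries` with columns `time`, `mean`,
#'   `enhancement_percent` (signed; `NA` for the pre time) and
#'   `enhancement_abs`.
#' @export
roi_timeseries <- function(volumes, roi, times = seq_along(volumes),
                           pre_index = 1L) {
  vols <- lapply(volumes, function(v) {
    if (inherits(v, "relaxo_volume")) {
      x <- v$data[, , , 1, drop = FALSE]
      dim(x) <- dim(v$data)[1:3]
      x
    } else v
  })
  if (length(vols) < 1L) stop("need at least one volume")
  if (length(times) != length(vols))
    stop("times must label every volume")
  shp <- dim(vols[[1]])
  if (length(shp) != 3L) stop("volumes must be 3-D")
  for (v in vols)
    if (!identical(dim(v), shp)) stop("all volumes must share one shape")
  if (is.logical(roi)) {
    if (!identical(dim(roi), shp)) stop("roi mask shape mismatch")
    if (!any(roi)) stop("empty ROI")
    pick <- function(v) mean(v[roi])
  } else {
    roi <- as.matrix(roi)
    if (nrow(roi) == 0L) stop("empty ROI")
    if (ncol(roi) != 3L) stop("roi index matrix needs columns x, y, z")
    if (any(roi < 1L) || any(sweep(roi, 2, shp, `>`)))
      stop("ROI extends outside the grid")
    pick <- function(v) mean(v[roi])
  }
  means <- vapply(vols, pick, numeric(1))
  pre <- means[pre_index]
  enh <- enhancement(pre, means)
  enh[pre_index] <- NA_real_
  out <- data.frame(time = times, mean = means,
                    enhancement_percent = enh,
                    enhancement_abs = abs(enh))
  class(out) <- c("roi_timeseries", "data.frame")
  out
}

#' Blank-corrected organ iron content
#'
#' Normalizes the iron mass recovered from an organ to its tissue mass and
#' subtracts the matching blank (untreated control animal) level. Negative
#' corrected values (blank scatter) are kept and flagged with a warning.
#'
#' @param fe_mass_ug iron mass in the organ, ug.
#' @param tissue_mass_g organ mass, g, > 0.
#' @param blank_fe_per_g blank iron level of the same organ, ug/g.
#' @return corrected iron content, ug Fe per g tissue.
#' @examples
#' organ_iron_normalize(10.8, 2.0)  # 5.4 ug/g
#' @export
organ_iron_normalize <- function(fe_mass_ug, tissue_mass_g,
                                 blank_fe_per_g = 0) {
  if (!is.finite(tissue_mass_g) || tissue_mass_g <= 0)
    stop("tissue mass must be positive")
  corrected <- fe_mass_ug / tissue_mass_g - blank_fe_per_g
  if (any(corrected < 0))
    warning("corrected iron content below blank; value kept (not clamped)")
  corrected
}
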