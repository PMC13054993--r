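#' Foreground mask from the first time point
#'
#' A voxel is kept iff its signal at the first sampling time is at least
#' `fraction_threshold` times the volume-wide maximum. Fitting skips
#' excluded voxels.
#'
#' @param volume a [relaxo_volume()] or 4-D array.
#' @param fraction_threshold fraction of the global maximum, default 0.05.
#' @return logical 3-D array.
#' @export
mask_volume <- function(volume, fraction_threshold = 0.05) {
  x <- if (inherits(volume, "relaxo_volume")) volume$data else volume
  if (length(dim(x)) != 4L) stop("need a 4-D volume")
  first <- x[, , , 1, drop = FALSE]
  dim(first) <- dim(x)[1:3]
  first >= fraction_threshold * max(x)
}

#' Voxel-wise relaxation fitting of a 4-D volume
#'
#' Runs [fit_mono()] (and, unless `bi = FALSE`, [fit_bi()]) on every voxel
#' inside the mask and collects the results into parameter arrays. Per-voxel
#' failures are recorded in the convergence arrays and never abort the run.
#'
#' @param volume a [relaxo_volume()].
#' @param mask logical 3-D array; default from [mask_volume()].
#' @param bi also fit the bi-exponential model (needed for model selection).
#' @param mask_fraction threshold passed to [mask_volume()] when `mask` is
#'   not supplied.
#' @return an object of class `relaxo_volume_fits`: 3-D arrays
#'   `mono_s0`, `mono_t2`, `mono_rss`, `mono_converged` and (if `bi`)
#'   `bi_a1`, `bi_a2`, `bi_t2_fast`, `bi_t2_slow`, `bi_rss`,
#'   `bi_converged`, `bi_effectively_mono`, plus `mask`, `n`, `signal_max`,
#'   `voxel_size` and the schedule.
#' @export
fit_volume <- function(volume, mask = NULL, bi = TRUE, mask_fraction = 0.05) {
  stopifnot(inherits(volume, "relaxo_volume"))
  x <- volume$data
  gs <- dim(x)[1:3]
  if (is.null(mask)) mask <- mask_volume(volume, mask_fraction)
  stopifnot(identical(dim(mask), gs))
  sch <- volume$schedule

  na3 <- array(NA_real_, dim = gs)
  out <- list(mono_s0 = na3, mono_t2 = na3, mono_rss = na3,
              mono_converged = array(FALSE, dim = gs))
  if (bi) {
    out <- c(out, list(bi_a1 = na3, bi_a2 = na3, bi_t2_fast = na3,
                       bi_t2_slow = na3, bi_rss = na3,
                       bi_converged = array(FALSE, dim = gs),
                       bi_effectively_mono = array(FALSE, dim = gs)))
  }
  idx <- which(mask)
  nt <- dim(x)[4]
  flat <- matrix(x, nrow = prod(gs), ncol = nt)
  for (v in idx) {
    curve <- decay_curve(sch, flat[v, ])
    fm <- tryCatch(fit_mono(curve), error = function(e) NULL)
    if (!is.null(fm) && !is.null(fm$params)) {
      out$mono_s0[v] <- fm$params$s0
      out$mono_t2[v] <- fm$params$t
      out$mono_rss[v] <- fm$rss
      out$mono_converged[v] <- fm$converged
    }
    if (bi) {
      fb <- tryCatch(fit_bi(curve), error = function(e) NULL)
      if (!is.null(fb) && !is.null(fb$params)) {
        out$bi_a1[v] <- fb$params$a1
        out$bi_a2[v] <- fb$params$a2
        out$bi_t2_fast[v] <- fb$params$t2_fast
        out$bi_t2_slow[v] <- fb$params$t2_slow
        out$bi_rss[v] <- fb$rss
        out$bi_converged[v] <- fb$converged
        out$bi_effectively_mono[v] <- "effectively_mono" %in% fb$flags
      }
    }
  }
  out$mask <- mask
  out$n <- nt
  out$signal_max <- max(abs(x))
  out$schedule <- sch
  out$voxel_size <- volume$voxel_size
  out$has_bi <- bi
  class(out) <- "relaxo_volume_fits"
  out
}

#' @export
print.relaxo_volume_fits <- function(x, ...) {
  cat(sprintf("<relaxo_volume_fits> %d fitted voxels / %s grid, n = %d%s\n",
              sum(x$mask), paste(dim(x$mask), collapse = "x"), x$n,
              if (x$has_bi) ", mono+bi" else ", mono only"))
  invisible(x)
}
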