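#' In-memory 4-D relaxometry volume
#'
#' A 4-D magnitude volume (x, y, z, sampling time) together with its
#' acquisition schedule and voxel size.
#'
#' @param data 4-D numeric array, last dimension indexed by sampling time.
#' @param schedule an [acq_schedule()]; length must equal `dim(data)[4]`.
#' @param voxel_size numeric length-3, voxel edge lengths in mm.
#' @return an object of class `relaxo_volume`.
#' @export
relaxo_volume <- function(data, schedule, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(schedule, "acq_schedule"))
  if (length(dim(data)) != 4L)
    stop("data must be a 4-D array (x, y, z, time)")
  if (dim(data)[4] != length(schedule$times))
    stop("4th dimension must match the number of sampling times")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths (mm)")
  structure(list(data = data, schedule = schedule, voxel_size = voxel_size),
            class = "relaxo_volume")
}

#' @export
print.relaxo_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<relaxo_volume> %dx%dx%d voxels, %d time points (%s), voxel %.3gx%.3gx%.3g mm\n",
    d[1], d[2], d[3], d[4], x$schedule$kind,
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' @export
dim.relaxo_volume <- function(x) dim(x$data)
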