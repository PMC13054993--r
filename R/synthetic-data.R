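#' Synthetic phantom specification
#'
#' Describes a multi-tube agarose phantom: eight tubes (water control plus
#' seven nanoparticle dilutions, 2.5-100 uM Fe by default) embedded in an
#' agarose block, imaged with a multi-echo schedule. Each tube's transverse
#' rate follows the linear calibration relation
#' `R2 = background_rate + relaxivity_slope * [Fe]`; the agarose background
#' relaxes at `background_rate` alone.
#'
#' @param tube_concentrations iron concentrations in mM, unique, >= 0. The
#'   0 mM entry is the water control tube.
#' @param relaxivity_slope transverse relaxivity in mM^-1 s^-1.
#' @param background_rate agarose R2 in s^-1 (the calibration intercept).
#' @param grid_shape voxels per axis (x, y, z).
#' @param voxel_size mm per axis; default (0.08, 0.1, 0.5) mm.
#' @param tube_radius tube radius in voxels; tubes are cylinders along z,
#'   placed on a ring in the axial plane.
#' @param s0 proton-density amplitude, identical in all compartments (a.u.).
#' @param schedule an [acq_schedule()] of kind CPMG.
#' @param noise_sd noise standard deviation in signal units; 0 = noiseless.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param seed integer RNG seed used when noise is added; `NULL` leaves the
#'   RNG state alone.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(tube_concentrations = c(0, 0.0025, 0.005, 0.01,
                                                 0.025, 0.05, 0.075, 0.1),
                         relaxivity_slope = 145,
                         background_rate = 7,
                         grid_shape = c(64, 64, 4),
                         voxel_size = c(0.08, 0.1, 0.5),
                         tube_radius = 3,
                         s0 = 100,
                         schedule = msme_schedule(),
                         noise_sd = 0,
                         noise_model = c("gaussian", "rician"),
                         seed = NULL) {
  noise_model <- match.arg(noise_model)
  conc <- as.numeric(tube_concentrations)
  if (any(conc < 0) || anyDuplicated(conc))
    stop("tube concentrations must be unique and >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(inherits(schedule, "acq_schedule"), schedule$kind == "CPMG")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be 3 positive integers")
  structure(list(tube_concentrations = conc,
                 relaxivity_slope = relaxivity_slope,
                 background_rate = background_rate,
                 grid_shape = grid_shape,
                 voxel_size = as.numeric(voxel_size),
                 tube_radius = tube_radius,
                 s0 = s0,
                 schedule = schedule,
                 noise_sd = noise_sd,
                 noise_model = noise_model,
                 seed = seed),
            class = "phantom_spec")
}

# tube centers on a ring in the axial plane; cylinders run the full z extent
.tube_centers <- function(grid_shape, n_tubes, tube_radius) {
  nx <- grid_shape[1]; ny <- grid_shape[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  ring_r <- min(nx, ny) / 2 - tube_radius - 2
  if (ring_r <= tube_radius)
    stop("tube layout does not fit in the grid")
  ang <- 2 * pi * (seq_len(n_tubes) - 1) / n_tubes
  cbind(x = cx + ring_r * cos(ang), y = cy + ring_r * sin(ang))
}

#' Generate a synthetic multi-tube phantom
#'
#' Builds the 4-D multi-echo volume implied by a [phantom_spec()]: every voxel
#' decays mono-exponentially with `R2 = background_rate + slope * [Fe]` inside
#' a tube and `R2 = background_rate` in the agarose background. With
#' `noise_sd = 0` each voxel equals the forward model exactly; the same spec
#' and seed always reproduce the same volume.
#'
#' @param spec a [phantom_spec()].
#' @return a list with elements `volume` (a [relaxo_volume()]) and `truth`
#'   (ground truth: `labels`, a 3-D integer array with 0 = agarose and k = k-th
#'   tube; `tubes`, a data.frame of per-tube concentration and true R2/T2; and
#'   the generating parameters).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  conc <- spec$tube_concentrations
  n_tubes <- length(conc)
  gs <- spec$grid_shape
  centers <- .tube_centers(gs, n_tubes, spec$tube_radius)

  labels <- array(0L, dim = gs)
  xs <- seq_len(gs[1]); ys <- seq_len(gs[2])
  dx2 <- outer(xs, centers[, "x"], function(x, c) (x - c)^2)
  dy2 <- outer(ys, centers[, "y"], function(y, c) (y - c)^2)
  plane <- matrix(0L, gs[1], gs[2])
  for (k in seq_len(n_tubes)) {
    inside <- outer(dx2[, k], dy2[, k], `+`) <= spec$tube_radius^2
    if (any(plane[inside] != 0L))
      stop("tube regions overlap; reduce tube_radius or enlarge the grid")
    if (any(inside[c(1, gs[1]), ]) || any(inside[, c(1, gs[2])]))
      stop("tube layout does not fit in the grid")
    plane[inside] <- k
  }
  for (z in seq_len(gs[3])) labels[, , z] <- plane

  r2_true <- spec$background_rate + spec$relaxivity_slope * conc   # s^-1
  rate_map <- array(spec$background_rate, dim = gs)                # s^-1
  for (k in seq_len(n_tubes)) rate_map[labels == k] <- r2_true[k]

  times <- spec$schedule$times
  vol <- array(0, dim = c(gs, length(times)))
  for (i in seq_along(times)) {
    # R2 [s^-1] * TE [ms] / 1000 is the dimensionless decay exponent
    vol[, , , i] <- spec$s0 * exp(-times[i] * rate_map / 1000)
  }
  vol <- .apply_noise(vol, spec$noise_sd, spec$noise_model, spec$seed)

  truth <- list(
    labels = labels,
    tubes = data.frame(tube = seq_len(n_tubes), fe_mM = conc,
                       r2_true = r2_true, t2_true_ms = 1000 / r2_true),
    model = "mono",
    s0 = spec$s0,
    background_rate = spec$background_rate,
    relaxivity_slope = spec$relaxivity_slope)

  list(volume = relaxo_volume(vol, spec$schedule, spec$voxel_size),
       truth = truth)
}

#' Disc-shaped voxel region
#'
#' Convenience builder for region index sets: all voxels within `radius` of
#' `center` in the axial plane, across the given z slices.
#'
#' @param center length-2 (x, y) center in voxel coordinates.
#' @param radius radius in voxels.
#' @param grid_shape 3-vector of grid dimensions.
#' @param z_slices z indices to include; default all.
#' @return integer matrix with columns x, y, z, one row per voxel.
#' @export
disc_region <- function(center, radius, grid_shape,
                        z_slices = seq_len(grid_shape[3])) {
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]))
  keep <- (g$x - center[1])^2 + (g$y - center[2])^2 <= radius^2
  g <- g[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(z_slices, function(z)
    cbind(x = g$x, y = g$y, z = z)))
  storage.mode(out) <- "integer"
  out
}

#' Synthetic injected-tissue volume specification
#'
#' Emulates an injected brain-like slab: voxels in the injection-site region
#' decay bi-exponentially (fast compartment from water near the particles,
#' slow bulk compartment), while the contralateral control region and the
#' rest of the tissue decay mono-exponentially.
#'
#' @param grid_shape voxels per axis.
#' @param injection_region,contralateral_region integer matrices of voxel
#'   indices (columns x, y, z), e.g. from [disc_region()]; must be disjoint.
#'   Defaults are two mirrored discs of radius 4 in a 32x32x1 slab.
#' @param injection_params a [bi_params()] for injection-site voxels.
#' @param background_params a [mono_params()] for all other voxels (the
#'   contralateral region is ordinary background, only labelled for analysis).
#' @param voxel_size mm per axis.
#' @param schedule,noise_sd,noise_model,seed as in [phantom_spec()].
#' @return an object of class `injection_spec`.
#' @export
injection_spec <- function(grid_shape = c(32, 32, 1),
                           injection_region =
                             disc_region(c(10, 16), 4, grid_shape),
                           contralateral_region =
                             disc_region(c(23, 16), 4, grid_shape),
                           injection_params = bi_params(50, 50, 20, 200),
                           background_params = mono_params(100, 120),
                           voxel_size = c(0.08, 0.1, 0.5),
                           schedule = msme_schedule(),
                           noise_sd = 0,
                           noise_model = c("gaussian", "rician"),
                           seed = NULL) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(injection_params, "bi_params"),
            inherits(background_params, "mono_params"),
            inherits(schedule, "acq_schedule"))
  grid_shape <- as.integer(grid_shape)
  .check_region <- function(r, name) {
    if (is.null(r) || nrow(r) == 0L) return(invisible())
    if (ncol(r) != 3L) stop(name, " must have columns x, y, z")
    if (any(r < 1L) || any(sweep(r, 2, grid_shape, `>`)))
      stop(name, " extends outside the grid")
  }
  .check_region(injection_region, "injection_region")
  .check_region(contralateral_region, "contralateral_region")
  if (!is.null(injection_region) && !is.null(contralateral_region) &&
      nrow(injection_region) && nrow(contralateral_region)) {
    key <- function(r) paste(r[, 1], r[, 2], r[, 3])
    if (any(key(injection_region) %in% key(contralateral_region)))
      stop("injection and contralateral regions overlap")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(grid_shape = grid_shape,
                 injection_region = injection_region,
                 contralateral_region = contralateral_region,
                 injection_params = injection_params,
                 background_params = background_params,
                 voxel_size = as.numeric(voxel_size),
                 schedule = schedule,
                 noise_sd = noise_sd,
                 noise_model = noise_model,
                 seed = seed),
            class = "injection_spec")
}

#' Generate a synthetic injected-tissue volume
#'
#' @param spec an [injection_spec()].
#' @return list with `volume` (a [relaxo_volume()]) and `truth` (`labels`:
#'   3-D integer array, 0 = background, 1 = contralateral, 2 = injection;
#'   `model`: 3-D character array `"mono"`/`"bi"`; the generating parameters).
#' @export
generate_injection_volume <- function(spec) {
  stopifnot(inherits(spec, "injection_spec"))
  gs <- spec$grid_shape
  labels <- array(0L, dim = gs)
  if (!is.null(spec$contralateral_region) && nrow(spec$contralateral_region))
    labels[spec$contralateral_region] <- 1L
  if (!is.null(spec$injection_region) && nrow(spec$injection_region))
    labels[spec$injection_region] <- 2L

  times <- spec$schedule$times
  bp <- spec$background_params
  ip <- spec$injection_params
  vol <- array(0, dim = c(gs, length(times)))
  is_bi <- labels == 2L
  for (i in seq_along(times)) {
    plane <- array(.mono_model(times[i], bp$s0, bp$t), dim = gs)
    plane[is_bi] <- .bi_model(times[i], ip$a1, ip$a2, ip$t2_fast, ip$t2_slow)
    vol[, , , i] <- plane
  }
  vol <- .apply_noise(vol, spec$noise_sd, spec$noise_model, spec$seed)

  model <- array("mono", dim = gs)
  model[is_bi] <- "bi"
  truth <- list(labels = labels, model = model,
                injection_params = ip, background_params = bp)
  list(volume = relaxo_volume(vol, spec$schedule, spec$voxel_size),
       truth = truth)
}

.apply_noise <- function(x, noise_sd, noise_model, seed) {
  if (noise_sd == 0) return(x)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  if (noise_model == "gaussian") {
    x + array(stats::rnorm(n, sd = noise_sd), dim = dim(x))
  } else if (noise_model == "rician") {
    # magnitude of a complex signal with independent Gaussian channels
    re <- x + array(stats::rnorm(n, sd = noise_sd), dim = dim(x))
    im <- array(stats::rnorm(n, sd = noise_sd), dim = dim(x))
    sqrt(re^2 + im^2)
  } else {
    stop("unknown noise model: ", noise_model)
  }
}

#' Add measurement noise to a volume
#'
#' Gaussian noise adds zero-mean signed noise per voxel per time point (no
#' clipping, so negative samples can occur). Rician noise takes the magnitude
#' of `(signal + n1, n2)` with independent Gaussian components of the given
#' SD, the standard model for magnitude MR images; it never produces negative
#' signals and on zero-signal background follows a Rayleigh distribution with
#' mean `noise_sd * sqrt(pi / 2)`.
#'
#' @param volume a [relaxo_volume()] or a numeric array.
#' @param noise_sd standard deviation of each Gaussian component, >= 0;
#'   `noise_sd = 0` returns the input unchanged.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @return object of the same type as `volume`.
#' @export
add_noise <- function(volume, noise_sd,
                      noise_model = c("gaussian", "rician"), seed = NULL) {
  noise_model <- match.arg(noise_model)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (inherits(volume, "relaxo_volume")) {
    volume$data <- .apply_noise(volume$data, noise_sd, noise_model, seed)
    volume
  } else {
    .apply_noise(volume, noise_sd, noise_model, seed)
  }
}
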