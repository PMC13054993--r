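#' Write a 4-D volume with its sampling-time sidecar
#'
#' The volume goes to an uncompressed NIfTI-1 file and the acquisition
#' schedule to a plain-text CSV sidecar (`<stem>_times.csv`, columns
#' `index`, `time_ms`) next to it. Data are stored as float64 so that a
#' write/read round-trip is bit-exact.
#'
#' @param volume a [relaxo_volume()].
#' @param path output `.nii` path.
#' @return list with the two file names, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "relaxo_volume"))
  times <- volume$schedule$times
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  write_nifti(volume$data, path, voxel_size = volume$voxel_size,
              time_step = dt, datatype = "float64")
  sidecar <- .sidecar_path(path)
  utils::write.csv(data.frame(index = seq_along(times), time_ms = times),
                   sidecar, row.names = FALSE)
  invisible(list(volume = path, sidecar = sidecar))
}

.sidecar_path <- function(path) paste0(sub("\\.nii$", "", path), "_times.csv")

#' Read a 4-D volume and its sampling-time sidecar
#'
#' @param path `.nii` file; the sidecar `<stem>_times.csv` must sit next to
#'   it unless given explicitly.
#' @param sidecar optional explicit sidecar path.
#' @param kind schedule kind, `"CPMG"` or `"IR"`.
#' @return a [relaxo_volume()] with voxel size taken from the NIfTI header.
#' @export
read_volume <- function(path, sidecar = NULL, kind = c("CPMG", "IR")) {
  kind <- match.arg(kind)
  if (is.null(sidecar)) sidecar <- .sidecar_path(path)
  if (!file.exists(sidecar))
    stop("missing sampling-time sidecar: ", sidecar)
  nii <- read_nifti(path)
  if (length(nii$dim) != 4L)
    stop("expected a 4-D volume: ", path)
  tab <- utils::read.csv(sidecar)
  if (is.null(tab$time_ms))
    stop("sidecar needs a time_ms column: ", sidecar)
  if (nrow(tab) != nii$dim[4])
    stop(sprintf("sidecar has %d rows but the volume has %d time points",
                 nrow(tab), nii$dim[4]))
  relaxo_volume(nii$data, acq_schedule(tab$time_ms, kind = kind),
                voxel_size = nii$voxel_size)
}

#' Default pipeline configuration
#'
#' Flat named list of every stage parameter, with defaults equal to the
#' published acquisition and analysis settings where one exists: 40 echoes
#' from 10 to 400 ms, selection threshold 10 (rule AND), masking fraction
#' 0.05, calibration slope 145 mM^-1 s^-1 and intercept 7 s^-1,
#' sigma_blank 0.5 s^-1, Rdia 0.52 s^-1, r1p 1.29 mM^-1 s^-1. Units are
#' embedded in the key names.
#'
#' @return named list.
#' @export
default_run_config <- function() {
  list(
    n_echoes = 40,
    te_first_ms = 10,
    te_last_ms = 400,
    repetition_time_ms = 5000,
    grid_x = 64, grid_y = 64, grid_z = 4,
    voxel_x_mm = 0.08, voxel_y_mm = 0.1, voxel_z_mm = 0.5,
    tube_radius_vox = 3,
    s0_au = 100,
    relaxivity_slope_mM1s1 = 145,
    background_rate_s1 = 7,
    sigma_blank_s1 = 0.5,
    r_dia_s1 = 0.52,
    r1p_mM1s1 = 1.29,
    noise_sd = 0,
    noise_model = "gaussian",
    mask_fraction = 0.05,
    selection_rule = "AND",
    selection_threshold = 10,
    seed = 1
  )
}

#' Read / write a flat key-value run configuration
#'
#' The format is one `key = value` pair per line, `#` comments allowed;
#' numeric-looking values are coerced to numbers. Unknown keys are kept, so
#' stage-specific extensions pass through.
#'
#' @param path configuration file.
#' @return named list merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_run_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("bad config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' @rdname read_run_config
#' @param config named list of parameters.
#' @export
write_run_config <- function(config, path) {
  keys <- names(config)
  lines <- vapply(keys, function(k)
    sprintf("%s = %s", k, format(config[[k]], scientific = FALSE)),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

# stable hash of a configuration, for the run manifest
.config_hash <- function(config) {
  keys <- sort(names(config))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(vapply(keys, function(k)
    paste0(k, "=", paste(format(config[[k]], digits = 15), collapse = ",")),
    character(1)), tmp)
  unname(tools::md5sum(tmp))
}

#' Write stage outputs with a run manifest
#'
#' Writes every element of `results` under `out_dir` using a deterministic
#' layout chosen by class — [relaxo_volume()] as NIfTI + sidecar,
#' `parametric_maps` as one NIfTI per map plus a CSV selection tally,
#' data.frames as CSV, everything else as JSON — and records a
#' `manifest.json` listing each artifact together with the stage name, the
#' configuration hash and the seed. Two runs with the same inputs produce
#' identical artifacts and manifests up to the timestamp field.
#'
#' @param results named list of stage outputs.
#' @param out_dir output directory, created if missing.
#' @param stage stage name recorded in the manifest.
#' @param config configuration list (hashed into the manifest).
#' @param seed seed recorded in the manifest.
#' @return the manifest, invisibly.
#' @export
write_outputs <- function(results, out_dir, stage = "run",
                          config = default_run_config(), seed = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  artifacts <- list()
  add <- function(name, file, what)
    artifacts[[length(artifacts) + 1L]] <<- list(name = name,
                                                 file = basename(file),
                                                 type = what)
  for (name in names(results)) {
    obj <- results[[name]]
    if (inherits(obj, "relaxo_volume")) {
      f <- file.path(out_dir, paste0(name, ".nii"))
      write_volume(obj, f)
      add(name, f, "volume")
    } else if (inherits(obj, "parametric_maps")) {
      for (m in c("t2_fast_map", "t2_slow_map", "t2_mono_map", "binary_map")) {
        f <- file.path(out_dir, paste0(name, "_", m, ".nii"))
        arr <- obj[[m]]
        arr[is.na(arr)] <- -1   # NIfTI has no NA; -1 marks missing
        write_nifti(arr, f, voxel_size = obj$voxel_size,
                    datatype = "float64")
        add(paste0(name, "_", m), f, "map")
      }
      tal <- data.frame(voxel = seq_along(obj$binary_map),
                        delta_aic = as.vector(obj$delta_aic),
                        delta_bic = as.vector(obj$delta_bic),
                        chosen = ifelse(is.na(obj$binary_map), "",
                                        ifelse(obj$binary_map == 1,
                                               "bi", "mono")))
      f <- file.path(out_dir, paste0(name, "_selection.csv"))
      utils::write.csv(tal, f, row.names = FALSE)
      add(paste0(name, "_selection"), f, "table")
    } else if (is.data.frame(obj)) {
      f <- file.path(out_dir, paste0(name, ".csv"))
      utils::write.csv(obj, f, row.names = FALSE)
      add(name, f, "table")
    } else {
      f <- file.path(out_dir, paste0(name, ".json"))
      jsonlite::write_json(.jsonable(obj), f, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      add(name, f, "json")
    }
  }
  manifest <- list(stage = stage,
                   seed = seed,
                   config_hash = .config_hash(config),
                   artifacts = artifacts,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# strip classes/arrays down to JSON-friendly structures
.jsonable <- function(x) {
  if (inherits(x, c("mono_params", "bi_params", "calibration_fit",
                    "relaxo_selection")))
    return(unclass(x))
  if (inherits(x, "relaxo_fit")) {
    x <- unclass(x)
    x$params <- if (is.null(x$params)) NULL else unclass(x$params)
    return(x)
  }
  if (is.array(x)) return(as.vector(x))
  if (is.list(x)) return(lapply(x, .jsonable))
  x
}
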