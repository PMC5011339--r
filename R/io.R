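#' Write / read a complex frame series on disk
#'
#' Frames are stored as paired NIfTI volumes (`frame_NNNN_mag.nii.gz`,
#' `frame_NNNN_phase.nii.gz`) plus a JSON sidecar `series.json` carrying the
#' acquisition metadata (TE, B0, FOV, frame period, dummy-frame count,
#' timestamps). The round trip is lossless and reading re-sorts frames by
#' timestamp.
#'
#' @param frames List of [complex_frame()]s.
#' @param dir Directory (created if needed).
#' @param frame_period_s,dummy_frames Stream metadata stored in the sidecar.
#' @return `write_frame_series()` returns `dir` invisibly;
#'   `read_frame_series()` a list of frames; `frame_source_from_dir()` a
#'   frame source (see [frame_source_from_list()]).
#' @export
write_frame_series <- function(frames, dir, frame_period_s = 3,
                               dummy_frames = 2L) {
  stopifnot(all(vapply(frames, inherits, logical(1), "complex_frame")))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f1 <- frames[[1]]
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (!identical(fr$matrix, f1$matrix) ||
        !isTRUE(all.equal(fr$te_s, f1$te_s)))
      stop("inconsistent frame shapes or echo times in series")
    RNifti::writeNifti(Mod(fr$data),
                       file.path(dir, sprintf("frame_%04d_mag.nii.gz", i)),
                       datatype = "double")
    RNifti::writeNifti(Arg(fr$data),
                       file.path(dir, sprintf("frame_%04d_phase.nii.gz", i)),
                       datatype = "double")
  }
  side <- list(te_s = f1$te_s, b0_T = f1$b0_T, fov_mm = f1$fov_mm,
               frame_period_s = frame_period_s, dummy_frames = dummy_frames,
               n_frames = length(frames),
               timestamps_s = vapply(frames, `[[`, numeric(1), "timestamp_s"))
  jsonlite::write_json(side, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_frame_series
#' @export
read_frame_series <- function(dir) {
  sidef <- file.path(dir, "series.json")
  if (!file.exists(sidef)) stop("missing sidecar series.json in ", dir)
  side <- jsonlite::fromJSON(sidef)
  frames <- vector("list", side$n_frames)
  for (i in seq_len(side$n_frames)) {
    magf <- file.path(dir, sprintf("frame_%04d_mag.nii.gz", i))
    phaf <- file.path(dir, sprintf("frame_%04d_phase.nii.gz", i))
    if (!file.exists(magf) || !file.exists(phaf))
      stop("missing frame files for index ", i)
    mag <- RNifti::readNifti(magf)
    pha <- RNifti::readNifti(phaf)
    if (!identical(dim(mag), dim(pha)))
      stop("magnitude/phase shape mismatch at frame ", i)
    frames[[i]] <- complex_frame(matrix(complex(modulus = as.vector(mag),
                                                argument = as.vector(pha)),
                                        nrow(mag), ncol(mag)),
                                 te_s = side$te_s,
                                 timestamp_s = side$timestamps_s[i],
                                 b0_T = side$b0_T, fov_mm = side$fov_mm)
  }
  ts <- vapply(frames, `[[`, numeric(1), "timestamp_s")
  frames[order(ts)]
}

#' @rdname write_frame_series
#' @export
frame_source_from_dir <- function(dir) {
  frame_source_from_list(read_frame_series(dir))
}

#' Write a sonication log as CSV
#'
#' Columns are exactly `timestamp_s, focal_mean_C, v_out, cem43_min,
#' shutoff_flag`.
#'
#' @param log A `sonication_log`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_sonication_log <- function(log, file) {
  stopifnot(inherits(log, "sonication_log"))
  utils::write.csv(as.data.frame(log)[, c("timestamp_s", "focal_mean_C",
                                          "v_out", "cem43_min",
                                          "shutoff_flag")],
                   file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sonication_log
#' @export
read_sonication_log <- function(file) {
  log <- utils::read.csv(file)
  class(log) <- c("sonication_log", "data.frame")
  log
}

#' Write reconstructed temperature maps as a NIfTI stack plus a CSV series
#'
#' @param log A `sonication_log` produced with `collect_maps = TRUE`.
#' @param nii_file Output NIfTI path for the 3-D (x, y, time) stack of
#'   temperature-change maps.
#' @param csv_file Optional CSV path for the focal time series
#'   (`timestamp_s, focal_mean_C, drift_ref_mean_C`).
#' @return `nii_file`, invisibly.
#' @export
write_temperature_stack <- function(log, nii_file, csv_file = NULL) {
  maps <- attr(log, "maps")
  if (is.null(maps)) stop("log carries no temperature maps; rerun with collect_maps = TRUE")
  arr <- vapply(maps, function(m) m$delta_T_C,
                matrix(0, nrow(maps[[1]]$delta_T_C), ncol(maps[[1]]$delta_T_C)))
  RNifti::writeNifti(arr, nii_file, datatype = "double")
  if (!is.null(csv_file)) {
    dr <- attr(log, "drift_ref_mean_C")
    utils::write.csv(data.frame(
      timestamp_s = log$timestamp_s,
      focal_mean_C = log$focal_mean_C,
      drift_ref_mean_C = if (is.null(dr)) NA_real_ else dr),
      csv_file, row.names = FALSE)
  }
  invisible(nii_file)
}

config_defaults <- function() {
  list(preset = "agar-phantom",
       thermometry = list(), pid = list(), dose = list(threshold_min = Inf),
       rig = list(tissue = list(), source = list(), scanner = list()),
       roi = list(focus = NULL, drift = NULL),
       run = list(duration_s = 600, dummy_frames = 2L),
       seed = 1L,
       output = list(dir = "."))
}

merge_section <- function(base, user, path) {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) && length(base))
    stop("unknown config key(s) under '", path, "': ",
         paste(unknown, collapse = ", "))
  for (nm in names(user)) base[[nm]] <- user[[nm]]
  base
}

#' Load and validate a run configuration
#'
#' JSON configuration with sections `thermometry`, `pid`, `dose`, `rig`
#' (subsections `tissue`, `source`, `scanner`), `roi` (`focus`, `drift`,
#' each `{center_mm, size_mm}`), `run` (`duration_s`, `dummy_frames`),
#' `preset`, `seed` and `output`. Missing values are filled from the named
#' preset and the package defaults; unknown keys and invalid units are
#' rejected by the component constructors. The fully resolved configuration
#' is echoed in the returned object.
#'
#' @param path JSON file path.
#' @return An object of class `run_config`: component objects (`rig`, `pid`,
#'   `dose`, `cfg`, `focus`, `drift`), run settings, and the resolved raw
#'   configuration in `$echo`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw <- config_defaults()
  top_unknown <- setdiff(names(user), names(raw))
  if (length(top_unknown))
    stop("unknown top-level config key(s): ", paste(top_unknown, collapse = ", "))
  for (nm in setdiff(names(user), c("rig", "roi", "run", "output")))
    raw[[nm]] <- if (is.list(raw[[nm]])) merge_section(raw[[nm]], user[[nm]], nm)
                 else user[[nm]]
  for (nm in c("roi", "run", "output"))
    raw[[nm]] <- merge_section(raw[[nm]], user[[nm]], nm)
  if (!is.null(user$rig))
    for (nm in names(user$rig))
      raw$rig[[merge_check_rig(nm)]] <-
        merge_section(raw$rig[[nm]], user$rig[[nm]], paste0("rig$", nm))

  allowed <- list(thermometry = names(formals(thermometry_config)),
                  pid = names(formals(pid_params)),
                  dose = c(names(formals(dose_params)), "threshold_min"))
  for (sec in names(allowed)) {
    bad <- setdiff(names(raw[[sec]]), allowed[[sec]])
    if (length(bad))
      stop("unknown config key(s) under '", sec, "': ",
           paste(bad, collapse = ", "))
  }

  preset <- rig_preset(raw$preset)
  tissue <- do.call(tissue_params,
                    merge_params(preset$tissue, raw$rig$tissue))
  source <- do.call(source_model,
                    merge_params(preset$source, raw$rig$source))
  scanner <- do.call(scanner_model,
                     merge_params(preset$scanner, raw$rig$scanner))
  scanner$rng_seed <- as.integer(raw$seed)
  rig <- list(tissue = tissue, source = source, scanner = scanner)

  cfg <- do.call(thermometry_config, raw$thermometry)
  pid <- do.call(pid_params, raw$pid)
  dose_thr <- as.numeric(raw$dose$threshold_min)
  dose <- do.call(dose_params, raw$dose[setdiff(names(raw$dose), "threshold_min")])

  focus <- if (is.null(raw$roi$focus)) rig_focal_roi(rig) else
    roi_rect(raw$roi$focus$center_mm, raw$roi$focus$size_mm,
             scanner$matrix_dim, scanner$fov_mm, "focus")
  drift <- if (is.null(raw$roi$drift)) NULL else
    roi_rect(raw$roi$drift$center_mm, raw$roi$drift$size_mm,
             scanner$matrix_dim, scanner$fov_mm, "drift-reference")

  structure(list(rig = rig, cfg = cfg, pid = pid, dose = dose,
                 dose_threshold_min = dose_thr,
                 focus = focus, drift = drift,
                 duration_s = raw$run$duration_s,
                 dummy_frames = as.integer(raw$run$dummy_frames),
                 seed = as.integer(raw$seed),
                 output_dir = raw$output$dir,
                 echo = raw),
            class = "run_config")
}

merge_check_rig <- function(nm) {
  if (!nm %in% c("tissue", "source", "scanner"))
    stop("unknown config key under 'rig': ", nm)
  nm
}

merge_params <- function(obj, overrides) {
  vals <- unclass(obj)
  vals$matrix <- NULL  # derived field, not a constructor argument
  for (nm in names(overrides)) {
    if (!nm %in% names(vals))
      stop("unknown parameter '", nm, "' for ", class(obj)[1])
    vals[[nm]] <- overrides[[nm]]
  }
  vals
}

#' Save the resolved configuration back to JSON
#'
#' Writes the `$echo` of a [load_config()] result; loading the written file
#' yields an identical configuration (round trip).
#'
#' @param config A `run_config`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(config$echo, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Write a provenance record for a run
#'
#' Machine-readable record (resolved config echo, seed, package version,
#' timestamp) written alongside run outputs.
#'
#' @param config A `run_config`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(config, path) {
  jsonlite::write_json(list(package = "mrgfus",
                            version = as.character(utils::packageVersion("mrgfus")),
                            seed = config$seed,
                            written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                            config = config$echo),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
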