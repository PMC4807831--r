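series_paths <- function(stem) {
  list(volume = paste0(stem, ".nii"),
       frames = paste0(stem, "_frames.csv"),
       meta = paste0(stem, "_meta.json"))
}

#' Write a dynamic image series to disk
#'
#' Stores the 4D lattice as a NIfTI-1 volume (`<stem>.nii`, float64), the
#' frame timing as a sidecar CSV (`<stem>_frames.csv`, columns `frame`,
#' `t_start_s`, `duration_s`) and the units/correction metadata as
#' `<stem>_meta.json`.
#'
#' @param series A `dynamic_image_series`.
#' @param stem Output path without extension.
#'
#' @return Invisibly, the three file paths.
#' @export
write_series <- function(series, stem) {
  stopifnot(inherits(series, "dynamic_image_series"))
  paths <- series_paths(stem)
  nii <- RNifti::asNifti(series$values)
  RNifti::pixdim(nii) <- c(series$voxel_size, 1)
  RNifti::writeNifti(nii, paths$volume, datatype = "double")
  utils::write.csv(
    data.frame(frame = series$frame_timing$frame,
               t_start_s = series$frame_timing$t_start,
               duration_s = series$frame_timing$duration),
    paths$frames, row.names = FALSE)
  jsonlite::write_json(
    list(units = series$units,
         decay_corrected = series$decay_corrected,
         sensitivity = series$sensitivity,
         noise = series$noise,
         seed = series$seed),
    paths$meta, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(paths)
}

#' Read a dynamic image series written by [write_series()]
#'
#' @param stem Path stem used at write time (or the `.nii` path itself).
#'
#' @return A `dynamic_image_series`.
#' @export
load_series <- function(stem) {
  stem <- sub("\\.nii(\\.gz)?$", "", stem)
  paths <- series_paths(stem)
  for (p in paths) {
    if (!file.exists(p)) stop(sprintf("missing file: %s", p), call. = FALSE)
  }
  img <- RNifti::readNifti(paths$volume)
  values <- array(as.numeric(img), dim = dim(img))
  if (length(dim(values)) != 4L) {
    stop("volume is not a 4D dynamic series", call. = FALSE)
  }
  voxel_size <- RNifti::pixdim(img)[1:3]
  frames <- utils::read.csv(paths$frames)
  req <- c("frame", "t_start_s", "duration_s")
  if (!all(req %in% names(frames))) {
    stop("frame sidecar must have columns frame, t_start_s, duration_s",
         call. = FALSE)
  }
  nf <- dim(values)[4]
  if (nrow(frames) != nf) {
    stop(sprintf("volume has %d frames but sidecar lists %d rows",
                 nf, nrow(frames)), call. = FALSE)
  }
  missing <- setdiff(seq_len(nf), frames$frame)
  if (length(missing) > 0L) {
    stop(sprintf("frame sidecar is missing frame index(es): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  frames <- frames[order(frames$frame), ]
  meta <- jsonlite::read_json(paths$meta, simplifyVector = TRUE)
  timing <- tibble::tibble(
    frame = as.integer(frames$frame),
    t_start = frames$t_start_s,
    duration = frames$duration_s,
    t_mid = frames$t_start_s + frames$duration_s / 2,
    t_end = frames$t_start_s + frames$duration_s
  )
  structure(
    list(values = values,
         frame_timing = timing,
         voxel_size = as.numeric(voxel_size),
         units = meta$units,
         decay_corrected = isTRUE(meta$decay_corrected),
         sensitivity = meta$sensitivity,
         noise = isTRUE(meta$noise),
         seed = meta$seed),
    class = "dynamic_image_series"
  )
}

#' Write an ROI mask as a NIfTI volume
#'
#' @param roi An `roi_mask`.
#' @param series The series the mask was drawn on (for voxel geometry).
#' @param path Output `.nii` path.
#' @return Invisibly, `path`.
#' @export
write_roi <- function(roi, series, path) {
  stopifnot(inherits(roi, "roi_mask"),
            inherits(series, "dynamic_image_series"))
  nii <- RNifti::asNifti(array(as.integer(roi$mask), dim = dim(roi$mask)))
  RNifti::pixdim(nii) <- series$voxel_size
  RNifti::writeNifti(nii, path, datatype = "uint8")
  invisible(path)
}

#' Write a time-activity curve as CSV
#'
#' Columns: `frame`, `t_start_s`, `t_mid_s`, `duration_s`, `value`,
#' `decay_corrected`.
#'
#' @param tac A `tac` tibble.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_tac <- function(tac, path) {
  stopifnot(inherits(tac, "tac"))
  utils::write.csv(
    data.frame(frame = tac$frame, t_start_s = tac$t_start,
               t_mid_s = tac$t_mid, duration_s = tac$duration,
               value = tac$value,
               decay_corrected = is_decay_corrected(tac)),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a time-activity curve CSV written by [write_tac()]
#'
#' @param path CSV path.
#' @return A `tac` tibble; files with non-increasing frame times or
#'   negative values are rejected.
#' @export
load_tac <- function(path) {
  if (!file.exists(path)) stop(sprintf("missing file: %s", path), call. = FALSE)
  d <- utils::read.csv(path)
  req <- c("frame", "t_start_s", "t_mid_s", "duration_s", "value",
           "decay_corrected")
  if (!all(req %in% names(d))) {
    stop(sprintf("TAC file must have columns: %s", paste(req, collapse = ", ")),
         call. = FALSE)
  }
  new_tac(
    tibble::tibble(frame = d$frame, t_start = d$t_start_s, t_mid = d$t_mid_s,
                   duration = d$duration_s, value = d$value),
    decay_corrected = all(d$decay_corrected),
    provenance = list(source = path)
  )
}

config_defaults <- function() {
  list(
    tissue = "brain",
    n_animals = 4L,
    inter_animal_cv = 0.1,
    seed = 1L,
    noise = FALSE,
    scanner = list(psf_fwhm = 1.5, sensitivity = 0.10, voxel_size = 0.5,
                   grid_shape = c(32L, 32L, 32L)),
    injection = list(activity = c(0.7e6, 1.1e6), position = "center",
                     source_sigma = 0.6),
    frame_durations = c(rep(30, 10), rep(60, 5), rep(300, 10)),
    isotope = list(name = "11C", half_life = 1223.4),
    fit = list(threshold_fraction = 0.5, mode = "subtraction",
               window = c(0, Inf), weighting = "none")
  )
}

merge_config_group <- function(defaults, user, group) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s) in %s: %s", group,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  utils::modifyList(defaults, user)
}

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the package defaults and rejects unknown
#' keys. Nested groups (`scanner`, `injection`, `isotope`, `fit`) merge
#' key-wise.
#'
#' @param ... Top-level config entries (see [config_defaults] in the
#'   source for the schema): `tissue`, `n_animals`, `inter_animal_cv`,
#'   `seed`, `noise`, `scanner`, `injection`, `frame_durations`,
#'   `isotope`, `fit`.
#'
#' @return A validated config list of class `pipeline_config`.
#' @export
#' @examples
#' pipeline_config(tissue = "muscle", n_animals = 2, seed = 42)
pipeline_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg <- defaults
  for (k in setdiff(names(user), c("scanner", "injection", "isotope", "fit"))) {
    cfg[[k]] <- user[[k]]
  }
  for (g in c("scanner", "injection", "isotope", "fit")) {
    cfg[[g]] <- merge_config_group(defaults[[g]], user[[g]], g)
  }
  if (!cfg$tissue %in% tissue_presets()$tissue) {
    stop(sprintf("unknown tissue preset '%s'", cfg$tissue), call. = FALSE)
  }
  stopifnot(cfg$n_animals >= 1, cfg$inter_animal_cv >= 0)
  cfg$n_animals <- as.integer(cfg$n_animals)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file path; keys validated by [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Write a resolved pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_objects <- function(cfg) {
  list(
    scanner = scanner_model(cfg$scanner$psf_fwhm, cfg$scanner$sensitivity,
                            cfg$scanner$voxel_size, cfg$scanner$grid_shape),
    injection = injection_spec(
      cfg$injection$activity,
      if (is.character(cfg$injection$position)) NULL else cfg$injection$position,
      cfg$injection$source_sigma),
    protocol = acquisition_protocol(cfg$frame_durations),
    isotope = isotope_spec(cfg$isotope$name, cfg$isotope$half_life),
    params = preset_params(cfg$tissue)
  )
}

#' Run the full washout pipeline from a configuration
#'
#' Simulates a paired alive/dead study for the configured tissue preset,
#' writes the 4D volumes with sidecars, ROI masks, TAC CSVs, per-animal
#' fit and decomposition tables, group summaries (CSV and JSON), TAC
#' plots, the resolved configuration and a run manifest with MD5
#' checksums of every output.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @param out_dir Output directory (created if needed).
#'
#' @return Invisibly, a list with the per-animal `animals` tibble, the
#'   `summary` tibble, the full `study` tibble and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  obj <- config_objects(config)

  message(sprintf("[simulate] tissue=%s n=%d noise=%s seed=%d",
                  config$tissue, config$n_animals, config$noise, config$seed))
  t0 <- proc.time()["elapsed"]
  design <- study_design(obj$params, n_animals = config$n_animals,
                         inter_animal_cv = config$inter_animal_cv,
                         seed = config$seed)
  study <- simulate_study(design, obj$scanner, obj$injection, obj$protocol,
                          obj$isotope, noise = config$noise)

  message(sprintf("[extract] ROI threshold %.0f%% (%.1fs elapsed)",
                  100 * config$fit$threshold_fraction,
                  proc.time()["elapsed"] - t0))
  study <- extract_study_tacs(study,
                              threshold_fraction = config$fit$threshold_fraction,
                              isotope = obj$isotope)

  message(sprintf("[fit] weighting=%s mode=%s (%.1fs elapsed)",
                  config$fit$weighting, config$fit$mode,
                  proc.time()["elapsed"] - t0))
  study <- fit_study_tacs(study, window = config$fit$window,
                          weighting = config$fit$weighting)
  animals <- decompose_study(study, mode = config$fit$mode)

  summary <- dplyr::bind_rows(
    summarize_group(animals$halflife_tiss_hat, config$tissue, "tissular"),
    summarize_group(animals$halflife_wash_hat[is.finite(animals$halflife_wash_hat)],
                    config$tissue, "washout")
  )

  message(sprintf("[report] writing outputs to %s (%.1fs elapsed)",
                  out_dir, proc.time()["elapsed"] - t0))
  files <- character(0)
  for (i in seq_len(nrow(study))) {
    stem <- file.path(out_dir, sprintf("animal%02d_%s", study$animal_id[i],
                                       study$condition[i]))
    p <- write_series(study$series[[i]], stem)
    files <- c(files, unlist(p))
    mp <- paste0(stem, "_mask.nii")
    write_roi(study$roi[[i]], study$series[[i]], mp)
    tp <- paste0(stem, "_tac.csv")
    write_tac(study$tac[[i]], tp)
    files <- c(files, mp, tp)
  }

  fits_tbl <- dplyr::bind_cols(
    study[c("animal_id", "condition")],
    purrr::map_dfr(study$fit, glance)
  )
  fits_path <- file.path(out_dir, "fits.csv")
  utils::write.csv(fits_tbl, fits_path, row.names = FALSE)
  animals_path <- file.path(out_dir, "animals.csv")
  utils::write.csv(animals, animals_path, row.names = FALSE)
  summary_csv <- file.path(out_dir, "group_summary.csv")
  utils::write.csv(summary, summary_csv, row.names = FALSE)
  summary_json <- file.path(out_dir, "group_summary.json")
  jsonlite::write_json(summary, summary_json, dataframe = "rows", digits = NA)
  files <- c(files, fits_path, animals_path, summary_csv, summary_json)

  plot_path <- file.path(out_dir, "tacs.png")
  ggplot2::ggsave(plot_path, plot_study_tacs(study), width = 8, height = 4,
                  dpi = 120)
  files <- c(files, plot_path)

  cfg_path <- file.path(out_dir, "config_resolved.yaml")
  write_pipeline_config(config, cfg_path)
  files <- c(files, cfg_path)

  manifest <- list(
    tool = "washoutpet",
    version = as.character(utils::packageVersion("washoutpet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    files = data.frame(
      path = basename(files),
      md5 = unname(tools::md5sum(files)),
      row.names = NULL
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)

  message(sprintf("[done] %d files, %.1fs total", length(files) + 1L,
                  proc.time()["elapsed"] - t0))
  invisible(list(animals = animals, summary = summary, study = study,
                 manifest = manifest, manifest_path = manifest_path))
}
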