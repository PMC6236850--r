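# Experiment configuration: YAML round-trip, validation, orchestration.

#' Default experiment configuration
#'
#' A complete configuration list with the standard scanner geometry, the
#' sinusoidal superior-inferior phantom, and clinical-default weighting
#' (EXPO steepness fixed at 2). Sections: `scanner`, `phantom`, `waveform`,
#' `weighting`, `reconstruction`, `metrics`.
#'
#' @param grid_n Reconstruction/phantom grid size (default 128).
#' @return Named list of class `experiment_config`.
#' @export
default_experiment_config <- function(grid_n = 128) {
  suite <- standard_phantom_suite("si_sinusoid_grid")
  cfg <- list(
    scanner = list(source_isocenter_distance = 570, fov = 500,
                   collimation = 24, rotation_time = 0.5, pitch = 0.1,
                   projections_per_rotation = 360),
    phantom = list(
      grid_n = grid_n,
      background = suite$background,
      objects = lapply(suite$phantom, function(o) {
        list(shape = o$shape, center = o$center, size = o$size,
             attenuation = o$attenuation, motion_axis = o$motion_axis,
             excursion = o$excursion)
      })
    ),
    waveform = list(kind = "sinusoidal", breathing_rate_bpm = 12,
                    amplitude = 30, sample_rate = 100, irregularity = 0,
                    cycles = 3),
    weighting = list(scheme = "expo", ef = 2.0),
    reconstruction = list(n_phases = 10, noise_sigma = 0, seed = 1),
    metrics = list(
      rois = list(list(label = "background", center = c(0, 0), radius = 50))
    )
  )
  class(cfg) <- c("experiment_config", "list")
  cfg
}

#' Read and validate an experiment configuration
#'
#' Loads the key-value (YAML) configuration and validates every section
#' against the module preconditions, with field-level error messages.
#' Missing fields fall back to the defaults of
#' [default_experiment_config()].
#'
#' @param path Path to a YAML configuration file.
#' @return Validated `experiment_config` list.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- default_experiment_config()
  for (sec in names(raw)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec)
    if (sec == "phantom" && !is.null(raw$phantom$objects)) {
      cfg$phantom$objects <- raw$phantom$objects
      raw$phantom$objects <- NULL
    }
    for (f in names(raw[[sec]])) cfg[[sec]][[f]] <- raw[[sec]][[f]]
  }
  validate_config(cfg)
}

#' Write an experiment configuration as YAML
#'
#' @param cfg An `experiment_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Validate an experiment configuration
#'
#' @param cfg Configuration list.
#' @return The config (classed), or an error naming the offending field.
#' @export
validate_config <- function(cfg) {
  sc <- cfg$scanner
  check <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("config field ", field, ": ", msg, call. = FALSE)
  }
  check(is.numeric(sc$source_isocenter_distance) &&
          sc$source_isocenter_distance > 0,
        "scanner.source_isocenter_distance", "must be > 0")
  check(is.numeric(sc$fov) && sc$fov > 0 &&
          sc$fov < 2 * sc$source_isocenter_distance,
        "scanner.fov", "must be in (0, 2 * source_isocenter_distance)")
  check(is.numeric(sc$collimation) && sc$collimation > 0,
        "scanner.collimation", "must be > 0")
  check(is.numeric(sc$rotation_time) && sc$rotation_time > 0,
        "scanner.rotation_time", "must be > 0")
  check(is.numeric(sc$pitch) && sc$pitch >= 0, "scanner.pitch",
        "must be >= 0")
  check(sc$projections_per_rotation >= 2,
        "scanner.projections_per_rotation", "must be >= 2")
  check(cfg$phantom$grid_n >= 8, "phantom.grid_n", "must be >= 8")
  check(length(cfg$phantom$objects) >= 1, "phantom.objects",
        "at least one object required")
  wf <- cfg$waveform
  check(wf$kind %in% c("sinusoidal", "sawtooth", "irregular"),
        "waveform.kind", "must be sinusoidal, sawtooth or irregular")
  check(wf$breathing_rate_bpm > 0, "waveform.breathing_rate_bpm",
        "must be > 0")
  check(wf$amplitude >= 0, "waveform.amplitude", "must be >= 0")
  check(wf$cycles >= 2, "waveform.cycles",
        "insufficient cycles for phase sorting (need >= 2)")
  check(cfg$weighting$scheme %in% c("cosine2", "cosine_squared", "expo",
                                    "both", "uniform"),
        "weighting.scheme", "must be cosine2, expo, both or uniform")
  check(cfg$weighting$ef >= 0, "weighting.ef", "must be >= 0")
  check(cfg$reconstruction$n_phases >= 1, "reconstruction.n_phases",
        "must be >= 1")
  check(cfg$reconstruction$noise_sigma >= 0, "reconstruction.noise_sigma",
        "must be >= 0")
  class(cfg) <- c("experiment_config", "list")
  cfg
}

config_phantom <- function(cfg) {
  lapply(cfg$phantom$objects, function(o) {
    phantom_object(o$shape, unlist(o$center), unlist(o$size), o$attenuation,
                   o$motion_axis, o$excursion)
  })
}

scheme_name <- function(s) {
  switch(s, cosine2 = "cosine_squared", cos2 = "cosine_squared", s)
}

version_string <- function() {
  paste0("expo4dct-", as.character(utils::packageVersion("expo4dct")))
}

#' Simulate: phantom + waveform -> dynamic sinogram container
#'
#' Runs the forward simulation described by the configuration, tags the
#' projections with respiratory phase, and writes a single-file container
#' (RDS) holding the sinogram, the per-projection metadata and a config
#' echo sufficient for bit-identical reproduction, plus a metadata CSV
#' alongside. Logs the gating budget: whether the breathing-period
#' condition holds, the window widening and the window projection count.
#'
#' @param cfg An `experiment_config` (list or path to YAML).
#' @param out Output container path (`.rds`).
#' @return The `dynamic_sinogram`, invisibly.
#' @export
cmd_simulate <- function(cfg, out) {
  if (is.character(cfg)) cfg <- read_experiment_config(cfg)
  cfg <- validate_config(cfg)
  sc <- cfg$scanner
  geom <- scanner_geometry(sc$source_isocenter_distance, sc$fov,
                           sc$collimation, sc$rotation_time, sc$pitch,
                           sc$projections_per_rotation)
  grid <- image_grid(cfg$phantom$grid_n, sc$fov)
  phantom <- config_phantom(cfg)
  wfc <- cfg$waveform
  bp <- 60 / wfc$breathing_rate_bpm
  duration <- wfc$cycles * bp
  wf <- generate_waveform(wfc$kind, wfc$breathing_rate_bpm, wfc$amplitude,
                          duration + 0.5, wfc$sample_rate,
                          wfc$irregularity,
                          seed = cfg$reconstruction$seed)
  sino <- acquire(phantom, wf, geom, duration, grid,
                  noise_sigma = cfg$reconstruction$noise_sigma,
                  seed = cfg$reconstruction$seed,
                  background = cfg$phantom$background)
  if (wfc$amplitude > 0) {
    sino <- assign_phases(sino, cfg$reconstruction$n_phases)
  }
  budget <- tryCatch(gating_budget(geom, bp), error = function(e) NULL)
  if (!is.null(budget)) {
    message(sprintf(
      "breathing-period condition %s (BP %.3g s, bound %.3g s); Tw = %.3g s; window = %d projections; scheme = %s; Ef = %g",
      if (budget$condition_satisfied) "satisfied" else "violated",
      bp, budget$max_breathing_period, budget$window_widening,
      budget$window_projection_count, cfg$weighting$scheme,
      cfg$weighting$ef))
  }
  container <- list(sinogram = sino, config = unclass(cfg),
                    version = version_string(),
                    seed = cfg$reconstruction$seed)
  saveRDS(container, out)
  export_projection_metadata(sino, sub("\\.rds$", "_metadata.csv", out))
  invisible(sino)
}

# write one 2-D image as a single-slice NIfTI volume (HU by default)
write_image_nifti <- function(img, grid, path, mu_water = 0.019,
                              convert_hu = TRUE) {
  hu <- if (convert_hu) to_hu(img, mu_water) else img
  arr <- array(hu, dim = c(dim(hu), 1L))
  nii <- RNifti::asNifti(arr)
  RNifti::pixdim(nii) <- c(grid$spacing, grid$spacing, 1)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Reconstruct: container -> phase volumes + derivative images
#'
#' Reads a [cmd_simulate()] container and reconstructs every phase with
#' the requested weighting scheme(s), writing HU-scaled NIfTI volumes (one
#' per phase plus MIP, minIP and average CT) and a sidecar YAML echoing
#' the scheme, steepness and configuration.
#'
#' @param container Path to the `.rds` container.
#' @param scheme `"cosine2"`, `"expo"` or `"both"`.
#' @param n_phases Phase bins (default from the container config).
#' @param out_dir Output directory (one subdirectory per scheme).
#' @param steepness EXPO steepness (default 2, the clinical value).
#' @return Named list of lists of `phase_image`s, invisibly.
#' @export
cmd_reconstruct <- function(container, scheme = c("both", "cosine2", "expo"),
                            n_phases = NULL, out_dir, steepness = 2) {
  scheme <- match.arg(scheme)
  if (!file.exists(container)) stop("container not found: ", container)
  box <- readRDS(container)
  sino <- box$sinogram
  if (is.null(n_phases)) n_phases <- box$config$reconstruction$n_phases
  schemes <- if (scheme == "both") c("cosine2", "expo") else scheme
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(sino$phase_fraction) && sino$waveform$amplitude > 0) {
    sino <- assign_phases(sino, n_phases)
  }
  result <- list()
  for (s in schemes) {
    sdir <- file.path(out_dir, s)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    if (sino$waveform$amplitude > 0) {
      phases <- reconstruct_4dct(sino, n_phases, scheme_name(s),
                                 steepness = steepness)
    } else {
      phases <- list(reconstruct_static(sino))
    }
    for (i in seq_along(phases)) {
      write_image_nifti(phases[[i]]$pixels, sino$grid,
                        file.path(sdir, sprintf("phase_%02d.nii.gz", i - 1L)))
    }
    der <- derivative_images(phases)
    for (nm in c("mip", "minip", "avg")) {
      write_image_nifti(der[[nm]], sino$grid,
                        file.path(sdir, paste0(nm, ".nii.gz")))
    }
    yaml::write_yaml(list(scheme = s, steepness = steepness,
                          n_phases = n_phases, version = version_string(),
                          seed = box$seed, config = box$config),
                     file.path(sdir, "reconstruction.yaml"))
    result[[s]] <- phases
  }
  invisible(result)
}

#' Analyze: reconstruction directories -> blur/ROI reports + difference maps
#'
#' Compares matched cosine-squared and EXPO reconstruction directories
#' against a static-truth reconstruction: per-phase FWHM and residual blur
#' for each moving object, per-phase difference maps (cosine-squared less
#' EXPO, written as NIfTI), and ROI statistics for the configured ROIs.
#'
#' @param cos2_dir Directory of cosine-squared phase NIfTIs.
#' @param expo_dir Directory of EXPO phase NIfTIs.
#' @param static_dir Directory holding the static-truth reconstruction
#'   (`phase_00.nii.gz`).
#' @param cfg The `experiment_config` used (list or YAML path).
#' @param out_dir Output directory for `blur_report.csv`,
#'   `roi_stats.csv` and `diff_phase_XX.nii.gz`.
#' @return List with `blur` and `roi` data.frames, invisibly.
#' @export
cmd_analyze <- function(cos2_dir, expo_dir, static_dir, cfg, out_dir) {
  if (is.character(cfg)) cfg <- read_experiment_config(cfg)
  if (!dir.exists(static_dir) ||
      !file.exists(file.path(static_dir, "phase_00.nii.gz"))) {
    stop("static truth required: no static reconstruction in ", static_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- image_grid(cfg$phantom$grid_n, cfg$scanner$fov)
  read_phase <- function(dir, i) {
    f <- file.path(dir, sprintf("phase_%02d.nii.gz", i))
    if (!file.exists(f)) stop("missing phase image: ", f)
    arr <- RNifti::readNifti(f)
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    matrix(as.numeric(arr), nrow(arr), ncol(arr))
  }
  static_img <- read_phase(static_dir, 0L)
  phantom <- config_phantom(cfg)
  moving <- which(vapply(phantom, function(o)
    o$motion_axis != "none" && o$excursion > 0, logical(1)))
  n_phases <- cfg$reconstruction$n_phases
  blur <- list(); roi <- list()
  for (i in seq_len(n_phases) - 1L) {
    ic <- read_phase(cos2_dir, i)
    ie <- read_phase(expo_dir, i)
    dm <- difference_map(ic, ie)  # already HU: images were written in HU
    write_image_nifti(dm, grid,
                      file.path(out_dir, sprintf("diff_phase_%02d.nii.gz", i)),
                      convert_hu = FALSE)
    for (s in list(list(n = "cosine2", img = ic), list(n = "expo", img = ie))) {
      for (j in moving) {
        o <- phantom[[j]]
        fw <- tryCatch(profile_fwhm(s$img, o$motion_axis, o$center, grid),
                       error = function(e) NA_real_)
        st <- tryCatch(profile_fwhm(static_img, o$motion_axis, o$center, grid),
                       error = function(e) NA_real_)
        blur[[length(blur) + 1L]] <- data.frame(
          object_id = j, motion_axis = o$motion_axis, phase = i,
          scheme = s$n, fwhm_mm = fw, static_mm = st,
          residual_mm = fw - st)
      }
      rs <- roi_stats(s$img, cfg$metrics$rois, grid)
      rs$phase <- i; rs$scheme <- s$n
      roi[[length(roi) + 1L]] <- rs
    }
  }
  blur <- do.call(rbind, blur)
  roi <- do.call(rbind, roi)
  utils::write.csv(blur, file.path(out_dir, "blur_report.csv"),
                   row.names = FALSE)
  utils::write.csv(roi, file.path(out_dir, "roi_stats.csv"),
                   row.names = FALSE)
  invisible(list(blur = blur, roi = roi))
}

#' Suite: run a full factorial phantom study
#'
#' Reproduces a motion-platform factorial in one call: runs
#' [blur_sweep()] on the named suite and writes the blur report CSV plus a
#' per-scheme summary.
#'
#' @param name Suite name for [standard_phantom_suite()].
#' @param out_dir Output directory.
#' @param grid_n Grid size (default 128).
#' @param ppr Projections per rotation (default 360).
#' @param configs Optional subset of `bpm`/`pitch` rows.
#' @param seed Master seed.
#' @return The blur report, invisibly.
#' @export
cmd_suite <- function(name, out_dir, grid_n = 128, ppr = 360L,
                      configs = NULL, seed = 1L) {
  suite <- standard_phantom_suite(name)
  geom <- scanner_geometry(projections_per_rotation = ppr)
  report <- blur_sweep(suite, grid = image_grid(grid_n, geom$fov),
                       geom_template = geom, configs = configs, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  export_blur_report(report, file.path(out_dir, "blur_report.csv"))
  utils::write.csv(summary(report), file.path(out_dir, "blur_summary.csv"),
                   row.names = FALSE)
  invisible(report)
}
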