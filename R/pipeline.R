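# End-to-end pipeline: validated run configuration and the three stages
# (simulate, correlate, track), each runnable independently on saved
# intermediates through the documented file formats.

.runKeys <- c("optics", "scene", "backend", "input_stack", "window",
              "normalize", "threshold_sigma", "candidate_lags", "min_snr",
              "exclude_radius_px", "memory_range_mm", "seed", "out_dir",
              "noise", "log_level")

.sceneKeys <- c("type", "n_dots", "dot_radius", "star_size", "grid",
                "n_frames", "star_anchor_mm", "step_mm", "rot_step_deg",
                "scale_step", "margin_px", "min_sep_px", "shapes")

#' Read and validate a pipeline run configuration
#'
#' A flat, human-editable YAML file.  Top-level keys: \code{optics} (inline
#' mapping with the [readOpticalConfig()] keys, or a path), \code{scene}
#' (scene spec for simulate mode), \code{backend}
#' ("physical"/"statistical"), \code{input_stack} (for correlate/track on
#' saved stacks), \code{window}, \code{normalize}, \code{threshold_sigma},
#' \code{candidate_lags}, \code{min_snr}, \code{exclude_radius_px},
#' \code{memory_range_mm} (overrides the layer thickness to yield this
#' object-plane memory range), \code{seed}, \code{out_dir}, \code{noise}
#' (mapping of [addCameraNoise()] arguments), \code{log_level}.  Unknown
#' keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file values (CLI flags
#'   take precedence over file values).
#' @return A validated named list with an `optics` element of class
#'   [OpticalConfig-class].
#' @export
readRunConfig <- function(path, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (nm in names(overrides))
    if (!is.null(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  unknown <- setdiff(names(cfg), .runKeys)
  if (length(unknown))
    stop("unknown run-config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$scene)) {
    unknown <- setdiff(names(cfg$scene), .sceneKeys)
    if (length(unknown))
      stop("unknown scene keys: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  if (is.character(cfg$optics)) cfg$optics <- readOpticalConfig(cfg$optics)
  else if (is.list(cfg$optics)) {
    tmp <- tempfile(fileext = ".yml")
    on.exit(unlink(tmp))
    yaml::write_yaml(cfg$optics, tmp)
    cfg$optics <- readOpticalConfig(tmp)
  } else if (is.null(cfg$optics)) cfg$optics <- opticalConfig()
  if (!is.null(cfg$memory_range_mm)) {
    oc <- cfg$optics
    cfg$optics <- opticalConfig(
      wavelength = oc@wavelength, sigma = oc@sigma,
      L = thicknessForMemoryRange(oc, cfg$memory_range_mm),
      L_o = oc@L_o, L_s = oc@L_s, detectorPitch = oc@detectorPitch,
      objectPitch = oc@objectPitch, flipAxes = oc@flipAxes)
  }
  defaults <- list(backend = "statistical", window = "none",
                   normalize = "coeff", threshold_sigma = 5,
                   candidate_lags = c(1L, 2L, 5L), min_snr = 5, seed = 1L,
                   out_dir = ".", log_level = "INFO")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (!cfg$backend %in% c("physical", "statistical"))
    stop("backend must be 'physical' or 'statistical'", call. = FALSE)
  cfg
}

.logMsg <- function(cfg, level, ...) {
  lv <- c(DEBUG = 1, INFO = 2, WARN = 3)
  if (lv[[level]] >= lv[[cfg$log_level]])
    message(format(Sys.time(), "%H:%M:%S "), "[", level, "] ", ...)
}

.sceneFromSpec <- function(spec, optics, seed) {
  grid <- as.integer(rep(if (is.null(spec$grid)) 128L else spec$grid,
                         length.out = 2))
  nFrames <- if (is.null(spec$n_frames)) 10L else spec$n_frames
  pitch <- optics@objectPitch
  type <- if (is.null(spec$type)) "dotfield" else spec$type
  seq <- if (type == "dotfield") {
    makeDotfieldScene(
      nDots = if (is.null(spec$n_dots)) 30L else spec$n_dots,
      dotRadius = if (is.null(spec$dot_radius)) 1.5 else spec$dot_radius,
      starSize = if (is.null(spec$star_size)) 9 else spec$star_size,
      dim = grid, pitch = pitch, seed = seed, nFrames = nFrames,
      starAnchor = if (is.null(spec$star_anchor_mm)) c(0, 0)
                   else spec$star_anchor_mm,
      margin = if (is.null(spec$margin_px)) 6 else spec$margin_px,
      minSepPx = spec$min_sep_px)
  } else if (type == "multishape") {
    shapes <- lapply(spec$shapes, function(sh) {
      sh$anchor <- as.numeric(sh$anchor); sh
    })
    makeMultishapeScene(shapes, dim = grid, pitch = pitch,
                        nFrames = nFrames)
  } else stop("unknown scene type: ", type, call. = FALSE)
  step <- if (is.null(spec$step_mm)) c(pitch * 2, 0) else spec$step_mm
  rotStep <- if (is.null(spec$rot_step_deg)) 0 else spec$rot_step_deg
  scaleStep <- if (is.null(spec$scale_step)) 1 else spec$scale_step
  mobIdx <- which(vapply(seq@frames[[1]]@subObjects, function(s) s@mobile,
                         logical(1)))[1]
  if (!is.na(mobIdx) && nFrames > 1)
    seq <- applyMotion(seq, mobIdx,
                       linearMotion(nFrames, step, rotStep, scaleStep))
  seq
}

#' Run the end-to-end pipeline
#'
#' \describe{
#'   \item{simulate}{Generate the scene sequence and speckle stack
#'     (scene.tif, speckle.tif).}
#'   \item{correlate}{Auto-, cross- (vs frame 1) and differential
#'     correlation stacks of an input or freshly simulated stack.}
#'   \item{track}{Trajectory table (trajectory.tsv) plus per-frame
#'     differential-map renderings.}
#' }
#' Every run writes \code{manifest.yml} (config echo, seed, package
#' version) so it can be replayed; all randomness flows from the single
#' top-level seed through named sub-streams.
#'
#' @param config A run configuration from [readRunConfig()] (or a path to
#'   one).
#' @param mode "simulate", "correlate" or "track".
#' @return Named list of output paths and a machine-readable summary,
#'   invisibly.
#' @export
runPipeline <- function(config, mode = c("simulate", "correlate", "track")) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- readRunConfig(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  artifacts <- list()
  frames <- NULL
  if (!is.null(config$input_stack) && mode != "simulate") {
    .logMsg(config, "INFO", "reading stack ", config$input_stack)
    frames <- stage("read", readStack(config$input_stack))
  } else {
    .logMsg(config, "INFO", "simulating scene + speckle (backend: ",
            config$backend, ")")
    frames <- stage("simulate", {
      seq <- .sceneFromSpec(config$scene, config$optics, config$seed)
      grid <- dim(seq@frames[[1]]@intensity)
      screen <- scatteringScreen(config$optics, grid,
                                 seed = .deriveSeed(config$seed, "screen"),
                                 backend = config$backend)
      fr <- renderSequence(seq, screen, noise = config$noise,
                           seed = config$seed)
      scenePath <- file.path(out, "scene.tif")
      writeStack(lapply(seq@frames, function(f)
        speckleFrame(f@intensity, f@pitch)), scenePath)
      artifacts$scene <- scenePath
      if (mode == "simulate" || is.null(config$input_stack)) {
        spPath <- file.path(out, "speckle.tif")
        writeStack(fr, spPath, meta = list(seed = config$seed,
                                           backend = config$backend))
        artifacts$speckle <- spPath
      }
      fr
    })
  }
  summary <- list(mode = mode, n_frames = length(frames),
                  seed = config$seed)
  if (mode == "correlate") {
    .logMsg(config, "INFO", "correlating ", length(frames), " frames")
    stage("correlate", {
      acs <- lapply(frames, autocorrelate, window = config$window,
                    normalize = config$normalize)
      xcs <- lapply(frames[-1], crossCorrelate, frame_b = frames[[1]],
                    window = config$window, normalize = config$normalize)
      dcs <- lapply(frames[-1], differentialCorrelation,
                    frame_b = frames[[1]], window = config$window,
                    normalize = config$normalize)
      artifacts$auto <- writeStack(lapply(acs, function(m)
        speckleFrame(m@values - min(m@values), m@pitch)),
        file.path(out, "auto.tif"))
      artifacts$cross <- writeStack(lapply(xcs, function(m)
        speckleFrame(m@values - min(m@values), m@pitch)),
        file.path(out, "cross.tif"))
      artifacts$diff <- writeStack(lapply(dcs, function(m)
        speckleFrame(m@values - min(m@values), m@pitch)),
        file.path(out, "diff.tif"))
      for (i in seq_along(dcs))
        writeCorrelationPNG(dcs[[i]],
                            file.path(out, sprintf("diff_%03d.png", i)))
      summary$n_auto <- length(acs)
      summary$n_cross <- length(xcs)
      summary$n_diff <- length(dcs)
    })
  }
  if (mode == "track") {
    .logMsg(config, "INFO", "tracking across ", length(frames), " frames")
    stage("track", {
      traj <- buildTrajectory(frames, config$optics,
                              thresholdSigma = config$threshold_sigma,
                              candidateLags = config$candidate_lags,
                              minSnr = config$min_snr,
                              window = config$window,
                              normalize = config$normalize,
                              excludeRadiusPx = config$exclude_radius_px)
      artifacts$trajectory <- writeTrajectory(traj,
        file.path(out, "trajectory.tsv"))
      for (t in 2:length(frames)) {
        dm <- differentialCorrelation(frames[[t]], frames[[t - 1]],
                                      window = config$window,
                                      normalize = config$normalize)
        writeCorrelationPNG(dm, file.path(out, sprintf("diff_%03d.png",
                                                       t - 1)))
        .logMsg(config, "DEBUG", sprintf(
          "frame %d: ref_lag %s snr %.1f", t,
          traj@table$ref_lag[t - 1], traj@table$snr[t - 1]))
      }
      summary$n_steps <- nrow(traj@table)
      summary$final_cum_mm <- c(traj@table$cum_x_mm[nrow(traj@table)],
                                 traj@table$cum_y_mm[nrow(traj@table)])
    })
  }
  manifest <- list(mode = mode, seed = config$seed,
                   backend = config$backend,
                   package_version = as.character(
                     utils::packageVersion("speckletrack")),
                   optics = list(wavelength_mm = config$optics@wavelength,
                                 sigma_mm = config$optics@sigma,
                                 L_mm = config$optics@L,
                                 L_o_mm = config$optics@L_o,
                                 L_s_mm = config$optics@L_s))
  yaml::write_yaml(manifest, file.path(out, "manifest.yml"))
  artifacts$manifest <- file.path(out, "manifest.yml")
  invisible(list(artifacts = artifacts, summary = summary))
}
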