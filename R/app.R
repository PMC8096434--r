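# Configuration registry, plain-text config files, and the batch pipeline
# (simulate -> convert -> track -> identify -> export -> evaluate) with
# on-disk artifacts and a line-delimited JSON run log.

registry_defaults <- function() {
  list(
    # synthetic scene
    n_agents = list(8L, "integer", "count", "number of agents"),
    frame_width = list(360L, "integer", "px", "video width"),
    frame_height = list(360L, "integer", "px", "video height"),
    n_frames = list(1000L, "integer", "frames", "video length"),
    fps = list(25, "numeric", "Hz", "frame rate"),
    agent_length = list(30, "numeric", "px", "agent body length"),
    agent_width = list(10, "numeric", "px", "agent body width"),
    speed_mean = list(2.5, "numeric", "px/frame", "mean speed"),
    speed_sd = list(0.8, "numeric", "px/frame", "speed standard deviation"),
    turn_sd = list(0.25, "numeric", "rad/frame", "heading increment sd"),
    texture_contrast = list(40, "numeric", "gray", "texture amplitude"),
    overlap_rate = list(1, "numeric", "1/(agent*min)", "crossing rate"),
    disappear_prob = list(0.001, "numeric", "1/frame", "disappearance probability"),
    background_level = list(210, "numeric", "gray", "background intensity"),
    noise_sd = list(3, "numeric", "gray", "pixel noise sd"),
    # segmentation
    track_threshold = list(25, "numeric", "gray", "segmentation threshold"),
    blob_size_min = list(40, "numeric", "px", "minimum blob size"),
    blob_size_max = list(10000, "numeric", "px", "maximum blob size"),
    equalize_luminance = list(FALSE, "logical", "", "mean-match frames to background"),
    background_mode = list("mode", "character", "", "background estimator: min/max/mode/mean"),
    # tracking
    track_max_individuals = list(8L, "integer", "count", "expected individuals (0 = unknown)"),
    track_max_speed = list(500, "numeric", "px/s", "maximal plausible speed"),
    matching_probability_threshold = list(0.1, "numeric", "", "assignment edge threshold"),
    max_reassign_time = list(0.5, "numeric", "s", "time lost individuals stay eligible"),
    clique_node_cap = list(1e5, "numeric", "nodes", "tree-search budget"),
    matcher = list("tree", "character", "", "tree / hungarian / approximate"),
    # posture
    smoothing = list("eft", "character", "", "outline smoothing: eft / weighted / none"),
    n_efd = list(8L, "integer", "count", "elliptic Fourier descriptors"),
    smooth_window = list(5L, "integer", "points", "weighted smoothing window"),
    pointiest_is = list("tail", "character", "", "pointiest outline end: tail / head"),
    midline_resolution = list(25L, "integer", "points", "midline sample points"),
    normalized_zoom = list(1.6, "numeric", "x", "normalized crop magnification"),
    # visual identification
    keep_per_bin = list(4L, "integer", "count", "global-segment candidates per quarter"),
    coverage_grid = list(10L, "integer", "cells", "spatial coverage grid"),
    uniqueness_samples = list(100L, "integer", "frames", "frames sampled for uniqueness"),
    max_epochs = list(150L, "integer", "epochs", "training epoch cap"),
    memory_budget = list(1e9, "numeric", "bytes", "training image memory budget"),
    median_window = list(25L, "integer", "frames", "switch-detection median window"),
    # general
    seed = list(1L, "integer", "", "master seed")
  )
}

#' Load and resolve the parameter registry
#'
#' Precedence: command-line overrides > config file > defaults.  The config
#' file is plain text, one `key = value` per line, `#` starts a comment.
#' Unknown keys raise an error naming the nearest registered parameters;
#' values are validated against the registered type.
#'
#' @param file optional config file path.
#' @param overrides named character vector or list of `key=value` overrides.
#' @return named list of resolved parameter values, class `btx_params`.
#' @export
load_config <- function(file = NULL, overrides = NULL) {
  reg <- registry_defaults()
  vals <- lapply(reg, `[[`, 1)
  set1 <- function(key, value, origin) {
    if (!key %in% names(reg)) {
      near <- agrep(key, names(reg), max.distance = 0.3, value = TRUE)
      stopf("unknown parameter '%s' (%s)%s", key, origin,
            if (length(near)) paste0("; did you mean: ",
                                     paste(near, collapse = ", ")) else "")
    }
    type <- reg[[key]][[2]]
    parsed <- switch(type,
      integer = suppressWarnings(as.integer(value)),
      numeric = suppressWarnings(as.numeric(value)),
      logical = as.logical(value),
      character = as.character(value))
    if (is.na(parsed) && !identical(toupper(value), "NA"))
      stopf("parameter '%s' expects type %s, got '%s'", key, type, value)
    vals[[key]] <<- parsed
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stopf("config file '%s' not found", file)
    for (line in readLines(file, warn = FALSE)) {
      line <- sub("#.*", "", line)
      if (!grepl("=", line, fixed = TRUE)) next
      kv <- strsplit(line, "=", fixed = TRUE)[[1]]
      set1(trimws(kv[1]), trimws(paste(kv[-1], collapse = "=")), "config file")
    }
  }
  if (!is.null(overrides)) {
    ov <- as.list(overrides)
    for (k in names(ov)) set1(k, as.character(ov[[k]]), "command line")
  }
  structure(vals, class = "btx_params")
}

params_to_configs <- function(p) {
  list(
    scene = scene_config(
      n_agents = p$n_agents, frame_size = c(p$frame_width, p$frame_height),
      n_frames = p$n_frames, fps = p$fps, agent_length = p$agent_length,
      agent_width = p$agent_width, speed_mean = p$speed_mean,
      speed_sd = p$speed_sd, turn_sd = p$turn_sd,
      texture_contrast = p$texture_contrast, overlap_rate = p$overlap_rate,
      disappear_prob = p$disappear_prob,
      background_level = p$background_level, noise_sd = p$noise_sd,
      seed = p$seed),
    seg = seg_config(threshold = p$track_threshold,
                     blob_size_range = c(p$blob_size_min, p$blob_size_max),
                     equalize_luminance = p$equalize_luminance),
    tracker = tracker_config(
      track_max_individuals = if (p$track_max_individuals == 0) "unknown"
                              else p$track_max_individuals,
      track_max_speed = p$track_max_speed,
      matching_probability_threshold = p$matching_probability_threshold,
      max_reassign_time = p$max_reassign_time,
      clique_node_cap = p$clique_node_cap, matcher = p$matcher),
    posture = posture_config(smoothing = p$smoothing, n_efd = p$n_efd,
                             smooth_window = p$smooth_window,
                             pointiest_is = p$pointiest_is,
                             midline_resolution = p$midline_resolution,
                             normalized_zoom = p$normalized_zoom),
    id = id_config(grid = p$coverage_grid, keep_per_bin = p$keep_per_bin,
                   uniqueness_samples = p$uniqueness_samples,
                   max_epochs = p$max_epochs, memory_budget = p$memory_budget,
                   median_window = p$median_window, seed = p$seed))
}

log_stage <- function(out_dir, stage, status, extra = list()) {
  rec <- c(list(stage = stage, status = status,
                time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = file.path(out_dir, "run_log.jsonl"), append = TRUE, sep = "")
}

need_artifact <- function(path, produced_by) {
  if (!file.exists(path))
    stopf("missing artifact '%s'; run the '%s' stage first", path, produced_by)
  path
}

#' Run one pipeline stage
#'
#' Stages communicate through on-disk artifacts in `out_dir`:
#' `simulate` writes the ground truth; `convert` renders the scene and
#' segments it into a `.pvs` container; `track` produces trajectories;
#' `identify` runs visual identification and writes corrected tracks;
#' `export` writes per-individual tables; `evaluate` scores a solution
#' against the ground truth.  Every stage appends to a machine-readable run
#' log.  Batch-safe: no display, deterministic given the seed.
#'
#' Each stage also writes the resolved configuration to
#' `<out_dir>/params.cfg`, which the `btx` command line reads back
#' automatically, so parameters given at `simulate` time carry through the
#' whole chain.
#'
#' @param command one of `simulate`, `convert`, `track`, `identify`,
#'   `export`, `evaluate`.
#' @param params a [load_config()] result.
#' @param out_dir artifact directory (created if needed).
#' @return stage-specific result, invisibly.
#' @export
run_pipeline <- function(command, params = load_config(), out_dir = "btx_out") {
  command <- match.arg(command, c("simulate", "convert", "track", "identify",
                                  "export", "evaluate"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", out_dir)
  cfgs <- params_to_configs(params)
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(paste(names(params),
                      vapply(params, function(v) paste(format(v), collapse=","), ""),
                      collapse = ";"))))
  # persist the resolved configuration so later stages (and reruns) agree
  writeLines(vapply(names(params), function(k)
    sprintf("%s = %s", k, format(params[[k]], scientific = FALSE)),
    character(1)), file.path(out_dir, "params.cfg"))
  res <- switch(command,
    simulate = {
      truth <- simulate_trajectories(cfgs$scene)
      utils::write.csv(as.data.frame(truth), file.path(out_dir, "truth.csv"),
                       row.names = FALSE)
      ts <- data.frame(frame = 0:(cfgs$scene$n_frames - 1L),
                       timestamp_us = round(1e6 * (0:(cfgs$scene$n_frames - 1L)) /
                                            cfgs$scene$fps))
      utils::write.csv(ts, file.path(out_dir, "timestamps.csv"), row.names = FALSE)
      truth
    },
    convert = {
      need_artifact(file.path(out_dir, "truth.csv"), "simulate")
      truth <- utils::read.csv(file.path(out_dir, "truth.csv"))
      class(truth) <- c("btx_ground_truth", "data.frame")
      ts_us <- read_timestamps(file.path(out_dir, "timestamps.csv"))
      sc <- cfgs$scene
      sample_idx <- unique(round(seq(0, sc$n_frames - 1L,
                                     length.out = min(20, sc$n_frames))))
      bg <- estimate_background(lapply(sample_idx, function(t)
        render_frame(truth, sc, t)), params$background_mode)
      frames <- vector("list", sc$n_frames)
      for (t in 0:(sc$n_frames - 1L)) {
        fr <- render_frame(truth, sc, t)
        frames[[t + 1L]] <- list(timestamp_us = ts_us[t + 1L],
                                 blobs = segment_frame(fr, bg, cfgs$seg))
      }
      pv_write(file.path(out_dir, "video.pvs"), sc$frame_size[1],
               sc$frame_size[2], bg$image, frames)
      file.path(out_dir, "video.pvs")
    },
    track = {
      pv <- pv_read(need_artifact(file.path(out_dir, "video.pvs"), "convert"))
      times <- vapply(pv$frames, function(f) f$timestamp_us, numeric(1)) / 1e6
      blobs <- lapply(pv$frames, `[[`, "blobs")
      tk <- track_frames(blobs, times, cfgs$tracker,
                         background = pv$header$background,
                         seg_threshold = params$track_threshold)
      saveRDS(tk, file.path(out_dir, "tracks.rds"))
      utils::write.csv(tracks_table(tk), file.path(out_dir, "tracks.csv"),
                       row.names = FALSE)
      tk
    },
    identify = {
      tk <- readRDS(need_artifact(file.path(out_dir, "tracks.rds"), "track"))
      hdr <- pv_header(need_artifact(file.path(out_dir, "video.pvs"), "convert"))
      N <- if (identical(cfgs$tracker$track_max_individuals, "unknown"))
        length(tk$individuals) else cfgs$tracker$track_max_individuals
      vid <- run_visual_id(tk, hdr$width, hdr$height, N, cfgs$id, cfgs$posture)
      if (vid$status != "ok")
        stopf("visual identification failed: %s", vid$reason)
      utils::write.csv(vid$table, file.path(out_dir, "corrected.csv"),
                       row.names = FALSE)
      utils::write.csv(vid$report, file.path(out_dir, "segment_report.csv"),
                       row.names = FALSE)
      vid
    },
    export = {
      tk <- readRDS(need_artifact(file.path(out_dir, "tracks.rds"), "track"))
      export_trajectories(tk, file.path(out_dir, "trajectories"))
    },
    evaluate = {
      truth <- utils::read.csv(need_artifact(file.path(out_dir, "truth.csv"),
                                             "simulate"))
      sol_file <- file.path(out_dir, "corrected.csv")
      if (!file.exists(sol_file)) sol_file <- file.path(out_dir, "tracks.csv")
      need_artifact(sol_file, "track (or identify)")
      sol <- utils::read.csv(sol_file)
      truth <- truth[truth$visible == TRUE | truth$visible == "TRUE", ]
      sc <- score_identity_accuracy(sol, truth, width = params$frame_width)
      cat(jsonlite::toJSON(list(similarity = sc$similarity,
                                n_pairs = sc$n_pairs,
                                solution = basename(sol_file)),
                           auto_unbox = TRUE, digits = NA), "\n")
      sc
    })
  log_stage(out_dir, command, "ok", list(seed = params$seed,
                                         config_hash = cfg_hash))
  invisible(res)
}
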