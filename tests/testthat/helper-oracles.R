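# Shared fixtures and independent oracles, built in code at test time.

# exhaustive optimum over all conflict-free partial assignments
brute_force_assignment <- function(p) {
  n <- nrow(p); m <- ncol(p)
  best <- 0
  rec <- function(i, used, tot) {
    if (i > n) { best <<- max(best, tot); return() }
    rec(i + 1, used, tot)
    for (j in seq_len(m)) if (!used[j] && p[i, j] > 0) {
      used[j] <- TRUE
      rec(i + 1, used, tot + p[i, j])
      used[j] <- FALSE
    }
  }
  rec(1, rep(FALSE, m), 0)
  best
}

# one rendered agent at a given pose; returns the segmented blob
agent_blob <- function(id = 1, ang = 0, cx = 80, cy = 80,
                       frame_size = c(160, 160), noise_sd = 0,
                       agent_length = 30, agent_width = 10,
                       texture_contrast = 40, seed = 9) {
  cfg <- scene_config(n_agents = 1, n_frames = 1, noise_sd = noise_sd,
                      seed = seed, frame_size = frame_size,
                      agent_length = agent_length, agent_width = agent_width,
                      texture_contrast = texture_contrast)
  tr <- data.frame(frame = 0, id = id, x = cx, y = cy, heading = ang,
                   visible = TRUE)
  class(tr) <- c("btx_ground_truth", "data.frame")
  f <- render_frame(tr, cfg, 0)
  bg <- matrix(cfg$background_level, frame_size[2], frame_size[1])
  segment_frame(f, bg, seg_config(threshold = 25,
                                  blob_size_range = c(10, 1e5)))[[1]]
}

# posture bundle for visual-field tests
agent_posture_at <- function(id, cx, cy, ang, ...) {
  b <- agent_blob(id = id, ang = ang, cx = cx, cy = cy,
                  frame_size = c(260, 260), ...)
  po <- blob_posture(b, posture_config(normalized_zoom = 1.6))
  list(outline = po$smoothed, midline = po$midline,
       head_index = po$endpoints$head_index)
}

# random simply-connected pixel mask (holes filled)
random_filled_mask <- function(n = 20, p = 0.55) {
  mm <- matrix(stats::runif(n * n) < p, n, n)
  lab <- btx:::label_components(mm)
  if (max(lab) == 0) return(NULL)
  sizes <- tabulate(lab[lab > 0])
  fill_holes(lab == which.max(sizes))
}

# a small tracked scene shared by several test files
tracked_scene <- function(n_agents = 4, n_frames = 120, seed = 5,
                          overlap_rate = 0, disappear_prob = 0,
                          frame_size = c(300, 300), agent_length = 20,
                          agent_width = 7) {
  cfg <- scene_config(n_agents = n_agents, n_frames = n_frames,
                      noise_sd = 2, overlap_rate = overlap_rate,
                      disappear_prob = disappear_prob, seed = seed,
                      frame_size = frame_size, agent_length = agent_length,
                      agent_width = agent_width)
  d <- generate_dataset(cfg)
  bg <- estimate_background(d$frames[seq(1, n_frames, 10)], "mode")
  sc <- seg_config(threshold = 25, blob_size_range = c(20, 8000))
  bf <- lapply(d$frames, segment_frame, background = bg, config = sc)
  tc <- tracker_config(track_max_individuals = n_agents,
                       track_max_speed = 8 * cfg$speed_mean * cfg$fps)
  tk <- track_frames(bf, (0:(n_frames - 1)) / cfg$fps, tc, background = bg,
                     seg_threshold = 25)
  list(cfg = cfg, data = d, bg = bg, tracks = tk,
       truth = d$truth[d$truth$visible, ])
}
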