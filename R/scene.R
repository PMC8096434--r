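# Synthetic scenes: ground-truthed correlated-random-walk agents rendered as
# textured, elongated bodies on a static background.  Used throughout the
# test-suite as the source of videos with known identities.

#' Configuration for a synthetic scene
#'
#' Defines the statistical structure of a generated scene: the number of
#' agents, their geometry, motion model, appearance, and noise.  All
#' randomness in scene generation flows from `seed`; identical
#' (config, seed) pairs reproduce scenes bit-exactly.
#'
#' @param n_agents number of agents (>= 1).
#' @param frame_size c(width, height) in pixels.
#' @param n_frames number of frames to simulate.
#' @param fps nominal frame rate in Hz (used for timestamps).
#' @param agent_length,agent_width body dimensions in pixels.
#' @param speed_mean,speed_sd per-frame speed distribution (px/frame); speeds
#'   are drawn from a normal clipped at zero.
#' @param turn_sd standard deviation of per-frame heading increments (rad).
#' @param texture_contrast amplitude (grayscale units) of the per-identity
#'   body texture; 0 makes all agents visually identical.
#' @param overlap_rate expected crossings per agent per minute; crossings are
#'   Poisson-scheduled steering events that drive pairs through each other.
#' @param disappear_prob per-frame probability that a visible agent leaves
#'   view; hidden agents keep moving and reappear stochastically.
#' @param background_level background grayscale value (0-255).
#' @param noise_sd standard deviation of additive pixel noise.
#' @param seed integer seed driving all scene randomness.
#' @return an object of class `btx_scene_config`.
#' @export
scene_config <- function(n_agents = 8, frame_size = c(256, 256), n_frames = 1000,
                         fps = 25, agent_length = 20, agent_width = 7,
                         speed_mean = 2.5, speed_sd = 0.8, turn_sd = 0.25,
                         texture_contrast = 40, overlap_rate = 1,
                         disappear_prob = 0.001, background_level = 210,
                         noise_sd = 3, seed = 1) {
  cfg <- list(n_agents = as.integer(n_agents), frame_size = as.integer(frame_size),
              n_frames = as.integer(n_frames), fps = fps,
              agent_length = agent_length, agent_width = agent_width,
              speed_mean = speed_mean, speed_sd = speed_sd, turn_sd = turn_sd,
              texture_contrast = texture_contrast, overlap_rate = overlap_rate,
              disappear_prob = disappear_prob,
              background_level = background_level, noise_sd = noise_sd,
              seed = as.integer(seed))
  if (cfg$n_agents < 1) stopf("invalid scene config: n_agents must be >= 1")
  if (length(cfg$frame_size) != 2 || any(cfg$frame_size <= 0))
    stopf("invalid scene config: frame_size must be two positive dimensions")
  if (cfg$n_frames < 1) stopf("invalid scene config: n_frames must be >= 1")
  if (cfg$agent_length <= 0 || cfg$agent_width <= 0)
    stopf("invalid scene config: agent dimensions must be > 0")
  if (cfg$speed_mean < 0) stopf("invalid scene config: speed_mean must be >= 0")
  if (cfg$disappear_prob < 0 || cfg$disappear_prob > 1)
    stopf("invalid scene config: disappear_prob must be in [0,1]")
  if (cfg$background_level < 0 || cfg$background_level > 255)
    stopf("invalid scene config: background_level must be in [0,255]")
  class(cfg) <- "btx_scene_config"
  cfg
}

#' Simulate ground-truth trajectories
#'
#' Correlated random walks with reflecting borders: per-frame speeds are
#' clipped normals, heading increments are zero-mean normals.  Crossing events
#' are Poisson-scheduled at `overlap_rate`; during an event a chosen pair
#' steers towards a common meeting point until the two bodies touch.  An
#' agent's visibility is a two-state Markov chain: a visible agent hides with
#' probability `disappear_prob` per frame and a hidden one reappears with
#' probability `0.25 * (1 - disappear_prob)`.
#'
#' @param config a [scene_config()].
#' @return a `data.frame` of class `btx_ground_truth` with columns
#'   `frame` (0-based), `id` (1-based), `x`, `y` (pixel coordinates of the
#'   body centroid), `heading` (rad, in (-pi, pi]) and `visible`.
#' @export
simulate_trajectories <- function(config) {
  if (!inherits(config, "btx_scene_config")) config <- do.call(scene_config, config)
  n <- config$n_agents
  W <- config$frame_size[1]; H <- config$frame_size[2]
  Tn <- config$n_frames
  margin <- config$agent_length * 0.65 + config$agent_width / 2 + 1
  if (2 * margin >= W || 2 * margin >= H)
    stopf("invalid scene config: frame_size too small for agent_length")
  with_seed(config$seed, {
    x <- runif(n, margin, W - margin)
    y <- runif(n, margin, H - margin)
    heading <- runif(n, -pi, pi)
    visible <- rep(TRUE, n)

    # Poisson-scheduled crossing events (each event drives one pair together)
    minutes <- Tn / config$fps / 60
    n_events <- if (n >= 2 && config$overlap_rate > 0)
      rpois(1, config$overlap_rate * n * minutes / 2) else 0L
    ev_start <- sort(sample.int(max(Tn - 40, 1), n_events, replace = TRUE))
    events <- list()   # active events: list(i, j, until)

    out_x <- matrix(NA_real_, Tn, n); out_y <- matrix(NA_real_, Tn, n)
    out_h <- matrix(NA_real_, Tn, n); out_v <- matrix(NA, Tn, n)
    ev_idx <- 1L
    for (t in seq_len(Tn)) {
      # activate scheduled events
      while (ev_idx <= n_events && ev_start[ev_idx] == t - 1L) {
        pair <- sample.int(n, 2)
        events[[length(events) + 1]] <- list(i = pair[1], j = pair[2],
                                             until = t + 60L)
        ev_idx <- ev_idx + 1L
      }
      steer <- rep(NA_real_, n)
      keep <- logical(length(events))
      for (k in seq_along(events)) {
        ev <- events[[k]]
        d <- sqrt((x[ev$i] - x[ev$j])^2 + (y[ev$i] - y[ev$j])^2)
        if (t <= ev$until && d > config$agent_width * 0.8) {
          # head straight at the partner: momentum carries each agent
          # through the encounter, so contact stays brief (a crossing, not
          # a rendezvous)
          steer[ev$i] <- atan2(y[ev$j] - y[ev$i], x[ev$j] - x[ev$i])
          steer[ev$j] <- atan2(y[ev$i] - y[ev$j], x[ev$i] - x[ev$j])
          keep[k] <- TRUE
        }
      }
      events <- events[keep]

      # soft repulsion keeps non-event pairs separated, so crossings happen
      # only through scheduled events
      targeted <- !is.na(steer)
      if (n >= 2) {
        sep <- 1.8 * config$agent_length
        dmat <- as.matrix(stats::dist(cbind(x, y)))
        diag(dmat) <- Inf
        for (i in which(!targeted)) {
          j <- which.min(dmat[i, ])
          if (dmat[i, j] < sep && !targeted[j])
            steer[i] <- atan2(y[i] - y[j], x[i] - x[j])
        }
        targeted <- !is.na(steer)
      }
      dh <- rnorm(n, 0, config$turn_sd)
      if (any(targeted)) {
        diff <- wrap_angle(steer[targeted] - heading[targeted])
        dh[targeted] <- clip(diff, -0.35, 0.35)
      }
      heading <- wrap_angle(heading + dh)
      spd <- clip(rnorm(n, config$speed_mean, config$speed_sd), 0, Inf)
      x <- x + spd * cos(heading)
      y <- y + spd * sin(heading)

      # reflect at borders
      ref_lo_x <- x < margin; ref_hi_x <- x > W - margin
      x[ref_lo_x] <- 2 * margin - x[ref_lo_x]
      x[ref_hi_x] <- 2 * (W - margin) - x[ref_hi_x]
      ref_lo_y <- y < margin; ref_hi_y <- y > H - margin
      y[ref_lo_y] <- 2 * margin - y[ref_lo_y]
      y[ref_hi_y] <- 2 * (H - margin) - y[ref_hi_y]
      flipx <- ref_lo_x | ref_hi_x; flipy <- ref_lo_y | ref_hi_y
      heading[flipx] <- wrap_angle(pi - heading[flipx])
      heading[flipy] <- wrap_angle(-heading[flipy])
      x <- clip(x, margin, W - margin); y <- clip(y, margin, H - margin)

      # visibility chain (frame 0 is always fully visible)
      if (t > 1) {
        u <- runif(n)
        reappear <- 0.25 * (1 - config$disappear_prob)
        visible <- ifelse(visible, u >= config$disappear_prob, u < reappear)
      }
      out_x[t, ] <- x; out_y[t, ] <- y; out_h[t, ] <- heading; out_v[t, ] <- visible
    }
    truth <- data.frame(frame = rep(0:(Tn - 1L), each = n),
                        id = rep(seq_len(n), Tn),
                        x = as.vector(t(out_x)), y = as.vector(t(out_y)),
                        heading = as.vector(t(out_h)),
                        visible = as.vector(t(out_v)))
    attr(truth, "config") <- config
    class(truth) <- c("btx_ground_truth", "data.frame")
    truth
  })
}

# Per-identity texture parameters.  The first eight identities form a binary
# attribute code (lateral stripe frequency, stripe phase, mean shade), so any
# two differ strongly in at least one attribute; a slowly increasing
# longitudinal frequency separates identities beyond eight.  The generator's
# contract is that appearances are learnable whenever texture_contrast
# exceeds the noise level.
texture_params <- function(config, id) {
  i <- (id - 1) %% 8
  list(f_long = 1 + 0.3 * (id - 1),
       f_lat = if (i %% 2 == 0) 1 else 2.5,
       phase = if ((i %/% 2) %% 2 == 0) 0 else pi,
       bias = if ((i %/% 4) %% 2 == 0) -0.8 else 0.8)
}

# teardrop half-width profile: blunt head (s = 0), pointed tail (s = 1)
body_halfwidth <- function(s, width) {
  hw <- numeric(length(s))
  head_r <- 0.12
  shoulder <- 0.35
  i1 <- s < head_r
  hw[i1] <- sqrt(pmax(0, 1 - ((head_r - s[i1]) / head_r)^2))
  i2 <- s >= head_r & s < shoulder
  hw[i2] <- 1
  i3 <- s >= shoulder
  hw[i3] <- pmax(0, (1 - s[i3]) / (1 - shoulder))^1.1
  hw * width / 2
}

.scene_cache <- new.env(parent = emptyenv())

# axial position (fraction of body length from the head tip) of the body's
# area centroid, so rendered mass centres coincide with ground-truth centroids
body_centroid_frac <- function() {
  if (is.null(.scene_cache$sbar)) {
    s <- seq(0, 1, length.out = 20001)
    hw <- body_halfwidth(s, 2)
    .scene_cache$sbar <- sum(s * hw) / sum(hw)
  }
  .scene_cache$sbar
}

# Render one agent into an existing frame matrix (darker pixels win).
render_agent <- function(frame_mat, cx, cy, heading, id, config) {
  W <- ncol(frame_mat); H <- nrow(frame_mat)
  L <- config$agent_length; Wd <- config$agent_width
  ux <- cos(heading); uy <- sin(heading)
  sbar <- body_centroid_frac()
  hx <- cx + ux * sbar * L; hy <- cy + uy * sbar * L   # head tip
  r <- L + Wd
  x0 <- max(0L, floor(cx - r)); x1 <- min(W - 1L, ceiling(cx + r))
  y0 <- max(0L, floor(cy - r)); y1 <- min(H - 1L, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(frame_mat)
  xs <- x0:x1; ys <- y0:y1
  px <- rep(xs + 0.5, each = length(ys))
  py <- rep(ys + 0.5, times = length(xs))
  # body coordinate s in [0,1] from head tip to tail tip
  dx <- px - hx; dy <- py - hy
  s <- clip((dx * (-ux) + dy * (-uy)) / L, 0, 1)
  ax <- hx - ux * s * L; ay <- hy - uy * s * L
  lat <- sqrt((px - ax)^2 + (py - ay)^2)
  hw <- body_halfwidth(s, Wd)
  inside <- lat <= hw & hw > 0
  if (!any(inside)) return(frame_mat)
  tp <- texture_params(config, id)
  rel <- ifelse(hw > 0, lat / pmax(hw, 1e-9), 0)
  pattern <- 0.6 * sin(2 * pi * (tp$f_long * s + tp$phase / (2 * pi))) *
    cos(pi * tp$f_lat * rel / 2) + 0.4 * tp$bias
  val <- clip(config$background_level - 60 -
              config$texture_contrast * 0.5 * (pattern + 1), 0, 255)
  idx <- cbind(py[inside] + 0.5, px[inside] + 0.5)  # row = y+1, col = x+1
  frame_mat[idx] <- pmin(frame_mat[idx], val[inside])
  frame_mat
}

#' Render a single frame of a scene
#'
#' @param truth ground truth from [simulate_trajectories()].
#' @param config the matching [scene_config()].
#' @param t frame index (0-based).
#' @return an integer matrix of dim `c(height, width)` with values 0-255,
#'   indexed `[y + 1, x + 1]`.
#' @export
render_frame <- function(truth, config, t) {
  W <- config$frame_size[1]; H <- config$frame_size[2]
  fr <- matrix(config$background_level, H, W)
  rows <- truth[truth$frame == t & truth$visible, , drop = FALSE]
  for (k in seq_len(nrow(rows)))
    fr <- render_agent(fr, rows$x[k], rows$y[k], rows$heading[k], rows$id[k], config)
  if (config$noise_sd > 0) {
    noise <- with_seed(derive_seed(config$seed, 104729L, t),
                       rnorm(W * H, 0, config$noise_sd))
    fr <- clip(fr + noise, 0, 255)
  }
  matrix(as.integer(round(fr)), H, W)
}

#' Render a scene into a list of frames
#'
#' @inheritParams render_frame
#' @param frames 0-based frame indices to render (default: all).
#' @return list of integer frame matrices.
#' @export
render_scene <- function(truth, config, frames = NULL) {
  if (is.null(frames)) frames <- 0:(config$n_frames - 1L)
  lapply(frames, function(t) render_frame(truth, config, t))
}

#' Generate a complete synthetic dataset
#'
#' Composition of [simulate_trajectories()] and [render_scene()].  When `dir`
#' is given, frames are written as 8-bit grayscale PNGs and the ground truth
#' as a CSV (`frame, id, x, y, heading, visible`).
#'
#' @param config a [scene_config()].
#' @param dir optional output directory for fixtures.
#' @return `list(frames = <list of matrices>, truth = <btx_ground_truth>)`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  truth <- simulate_trajectories(config)
  frames <- render_scene(truth, config)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stopf("cannot create output directory '%s'", dir)
    if (!requireNamespace("png", quietly = TRUE))
      stopf("writing PNG fixtures requires the 'png' package")
    for (i in seq_along(frames))
      png::writePNG(frames[[i]] / 255,
                    file.path(dir, sprintf("frame_%06d.png", i - 1L)))
    utils::write.csv(as.data.frame(truth),
                     file.path(dir, "ground_truth.csv"), row.names = FALSE)
  }
  list(frames = frames, truth = truth)
}

#' Score agreement between two tracking solutions
#'
#' Identities of the two solutions are first matched globally by minimising
#' the mean per-frame euclidean distance between paired trajectories
#' (bipartite assignment).  Then, per frame, a matched individual counts as
#' wrongly assigned when the distance between the two solutions exceeds 1% of
#' the video width.  The returned similarity is the fraction of correct
#' (frame, individual) pairs among those present in both solutions.
#'
#' @param a,b trajectory tables with columns `frame`, `id`, `x`, `y`.
#' @param width video width in pixels (the 1% threshold scale).
#' @return `list(similarity, n_pairs, matching, coverage)` where `coverage`
#'   gives, per matched identity pair, the fraction of common frames in which
#'   both solutions track the individual.
#' @export
score_identity_accuracy <- function(a, b, width) {
  need <- c("frame", "id", "x", "y")
  if (!all(need %in% names(a)) || !all(need %in% names(b)))
    stopf("trajectory tables need columns frame, id, x, y")
  a <- a[!is.na(a$x) & !is.na(a$y), need]
  b <- b[!is.na(b$x) & !is.na(b$y), need]
  common <- intersect(unique(a$frame), unique(b$frame))
  if (length(common) == 0) stopf("undefined result: no overlapping frames")
  a <- a[a$frame %in% common, ]; b <- b[b$frame %in% common, ]
  ids_a <- sort(unique(a$id)); ids_b <- sort(unique(b$id))
  na <- length(ids_a); nb <- length(ids_b)
  # mean distance between each identity pair over frames common to the pair
  key_a <- split(a, a$id); key_b <- split(b, b$id)
  meand <- matrix(Inf, na, nb)
  for (i in seq_len(na)) {
    ta <- key_a[[as.character(ids_a[i])]]
    for (j in seq_len(nb)) {
      tb <- key_b[[as.character(ids_b[j])]]
      m <- merge(ta, tb, by = "frame")
      if (nrow(m) > 0)
        meand[i, j] <- mean(sqrt((m$x.x - m$x.y)^2 + (m$y.x - m$y.y)^2))
    }
  }
  finite <- is.finite(meand)
  big <- if (any(finite)) max(meand[finite]) + 1 else 1
  wts <- (big - ifelse(finite, meand, big))
  asg <- lsap_max(wts)   # row i (id in a) -> column (id in b)
  thr <- 0.01 * width
  n_ok <- 0L; n_tot <- 0L
  coverage <- numeric(0)
  for (i in seq_len(na)) {
    j <- asg[i]
    if (is.na(j) || !finite[i, j]) next
    ta <- key_a[[as.character(ids_a[i])]]
    tb <- key_b[[as.character(ids_b[j])]]
    m <- merge(ta, tb, by = "frame")
    d <- sqrt((m$x.x - m$x.y)^2 + (m$y.x - m$y.y)^2)
    n_ok <- n_ok + sum(d <= thr); n_tot <- n_tot + nrow(m)
    frames_union <- union(ta$frame, tb$frame)
    coverage <- c(coverage, nrow(m) / length(frames_union))
  }
  if (n_tot == 0) stopf("undefined result: matched identities share no frames")
  list(similarity = n_ok / n_tot, n_pairs = n_tot,
       matching = asg, coverage = coverage)
}
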