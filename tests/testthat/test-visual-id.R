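test_that("frame uniqueness matches a direct evaluation of its definition", {
  # independent oracle, written from the definition
  oracle <- function(P) {
    uids <- list()
    for (r in seq_len(nrow(P))) {
      m <- which.max(P[r, ])
      key <- as.character(m)
      uids[[key]] <- max(c(uids[[key]], P[r, m]))
    }
    E <- function(v) (1 + exp(-pi)) / (1 + exp(-pi * v))
    (length(uids) / nrow(P)) * E(mean(unlist(uids)))
  }

  # distinct one-hot predictions score exactly 1
  P1 <- diag(4)
  expect_identical(frame_uniqueness(P1), 1)

  # worked two-object case
  P2 <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(frame_uniqueness(P2), 1 * (1 + exp(-pi)) / (1 + exp(-pi * 0.85)),
               tolerance = 1e-12)
  expect_equal(frame_uniqueness(P2), 0.976, tolerance = 1e-3)

  # an argmax collision strictly decreases the score
  P3 <- rbind(c(0.9, 0.1), c(0.8, 0.2))
  expect_lt(frame_uniqueness(P3), frame_uniqueness(P2))
  expect_equal(frame_uniqueness(P3),
               (1 / 2) * (1 + exp(-pi)) / (1 + exp(-pi * 0.9)),
               tolerance = 1e-12)

  set.seed(31)
  for (k in 1:300) {
    n <- sample(2:8, 1); N <- sample(2:8, 1)
    P <- matrix(stats::rexp(n * N), n, N)
    P <- P / rowSums(P)
    expect_equal(frame_uniqueness(P), oracle(P), tolerance = 1e-12)
    expect_gte(frame_uniqueness(P), 0)
    expect_lte(frame_uniqueness(P), 1)
  }
})

test_that("global segments are the per-frame intersection of consecutive segments", {
  seg <- function(ind, start, end)
    list(ind = ind, identity = ind, start = start, end = end, reason = "start")
  gs <- find_global_segments(structure(list(seg(1, 0, 100), seg(2, 50, 150)),
                                       class = "btx_segments"), 2, 151)
  expect_length(gs, 1)
  expect_equal(c(gs[[1]]$start, gs[[1]]$end), c(50, 100))

  # one individual never tracked: nothing qualifies
  gs2 <- find_global_segments(structure(list(seg(1, 0, 100)),
                                        class = "btx_segments"), 2, 151)
  expect_length(gs2, 0)

  # staircase pattern against a per-frame brute-force oracle
  segs <- structure(list(seg(1, 0, 40), seg(1, 42, 99), seg(2, 10, 60),
                         seg(2, 61, 90), seg(3, 5, 95)),
                    class = "btx_segments")
  gs3 <- find_global_segments(segs, 3, 100)
  # oracle: frame-by-frame membership key
  keyf <- function(f) {
    hit <- vapply(segs, function(s) s$start <= f && f <= s$end, logical(1))
    if (sum(hit) != 3) return(NA_character_)
    paste(which(hit), collapse = ",")
  }
  keys <- vapply(0:99, keyf, character(1))
  runs <- rle(keys)
  expect_equal(length(gs3), sum(!is.na(runs$values)))
  ends <- cumsum(runs$lengths) - 1
  starts <- ends - runs$lengths + 1
  expect_equal(vapply(gs3, function(g) g$start, numeric(1)),
               starts[!is.na(runs$values)])
  expect_equal(vapply(gs3, function(g) g$end, numeric(1)),
               ends[!is.na(runs$values)])
})

fake_tracks <- function(paths) {
  # paths: list per individual of data.frame(frame, x, y)
  inds <- lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    list(identity = i - 1L, frames = p$frame, times = p$frame / 25,
         x = p$x, y = p$y, heading = rep(0, nrow(p)), p = rep(1, nrow(p)),
         blob_i = rep(1L, nrow(p)),
         segments = data.frame(start = min(p$frame), end = max(p$frame),
                               reason = "start"))
  })
  structure(list(individuals = inds, blobs = list(), times = 0:max(paths[[1]]$frame) / 25,
                 config = NULL), class = "btx_tracks")
}

test_that("spatial coverage counts cell transitions, taking the per-segment minimum", {
  frames <- 0:99
  still <- data.frame(frame = frames, x = 55, y = 55)
  # crossing 5 cell borders (cells are 10 px wide in a 100-px arena)
  five <- data.frame(frame = frames, x = seq(5, 55, length.out = 100), y = 5)
  ten <- data.frame(frame = frames, x = seq(2, 98, length.out = 100), y = 5)
  tk <- fake_tracks(list(still, five, ten))
  gs <- list(start = 0, end = 99, members = data.frame(ind = 1:3, seg = 1:3))
  q <- segment_quality(gs, tk, width = 100, height = 100, grid = 10)
  expect_equal(q$min_cells_visited, 0)

  tk2 <- fake_tracks(list(five, ten))
  gs2 <- list(start = 0, end = 99, members = data.frame(ind = 1:2, seg = 1:2))
  q2 <- segment_quality(gs2, tk2, width = 100, height = 100, grid = 10)
  expect_equal(q2$min_cells_visited, 5)

  # a full-arena diagonal sweep beats tight circling of equal path length
  sweep_ <- data.frame(frame = frames,
                       x = seq(5, 95, length.out = 100),
                       y = seq(5, 95, length.out = 100))
  th <- seq(0, 2 * pi * 6.4, length.out = 100)   # ~ same path length, r = 3.16
  circ <- data.frame(frame = frames, x = 55 + 3.16 * cos(th),
                     y = 55 + 3.16 * sin(th))
  tks <- fake_tracks(list(sweep_)); tkc <- fake_tracks(list(circ))
  gs1 <- list(start = 0, end = 99, members = data.frame(ind = 1, seg = 1))
  qs <- segment_quality(gs1, tks, 100, 100, 10)
  qc <- segment_quality(gs1, tkc, 100, 100, 10)
  expect_gt(qs$min_cells_visited, qc$min_cells_visited)
})

test_that("candidate ranking keeps the best per video quarter, ties broken by samples", {
  mkgs <- function(start, end) list(start = start, end = end,
                                    members = data.frame(ind = 1, seg = 1))
  # 20 candidates all in the first quarter
  gss <- lapply(1:20, function(i) mkgs(0, 10))
  q <- lapply(1:20, function(i) list(min_cells_visited = i, avg_samples = 100))
  keep <- rank_global_segments(gss, q, n_frames = 1000, keep_per_bin = 4)
  expect_length(keep, 4)
  expect_setequal(keep, 17:20)

  # equal coverage: average sample count decides
  q2 <- lapply(1:20, function(i) list(min_cells_visited = 5, avg_samples = i))
  keep2 <- rank_global_segments(gss, q2, 1000, 4)
  expect_setequal(keep2, 17:20)

  # survivors dominate the discarded candidates within each bin
  set.seed(2)
  gss3 <- lapply(1:40, function(i) mkgs(sample(0:900, 1), 950))
  q3 <- lapply(1:40, function(i) list(min_cells_visited = sample(0:30, 1),
                                      avg_samples = stats::runif(1, 0, 200)))
  keep3 <- rank_global_segments(gss3, q3, 1000, 4)
  mid <- vapply(gss3, function(g) (g$start + g$end) / 2, numeric(1))
  bin <- pmin(1L + floor(4 * mid / 1000), 4)
  for (b in 1:4) {
    inb <- which(bin == b)
    kin <- intersect(keep3, inb)
    out <- setdiff(inb, kin)
    if (length(kin) && length(out)) {
      worst_kept <- min(vapply(kin, function(i)
        q3[[i]]$min_cells_visited * 1000 + q3[[i]]$avg_samples, numeric(1)))
      best_drop <- max(vapply(out, function(i)
        q3[[i]]$min_cells_visited * 1000 + q3[[i]]$avg_samples, numeric(1)))
      expect_gte(worst_kept, best_drop - 1000)  # dominance on the primary key
    }
  }
})

test_that("contested-identity scoring follows the printed sigmoid rule", {
  expect_equal(sig_scale(0.5), 0.5, tolerance = 1e-15)
  # strictly increasing in both arguments
  ps <- seq(0.05, 0.95, 0.1)
  expect_true(all(diff(sig_scale(ps)) > 0))
  for (p in c(0.2, 0.6, 0.9)) {
    s <- vapply(c(10, 50, 100, 400), function(n) eq2_score(p, n, 100), numeric(1))
    expect_true(all(diff(s) > 0))
  }
  # worked contested case: 100 samples at p=0.8 beat 10 samples at p=0.9
  Sme <- eq2_score(0.8, 100, 10)
  She <- eq2_score(0.9, 10, 100)
  expect_equal(Sme, 1.797, tolerance = 1e-3)
  expect_equal(She, 0.996, tolerance = 1e-3)
  expect_gt(Sme, She)
})

test_that("stopping thresholds and epoch caps follow their closed forms", {
  st <- new.env()
  st$N <- 2; st$best_uniqueness <- 0.80
  st$id_data <- list(n_frames = 100, meta = data.frame(frame = 0, ind = 1))
  st$training <- data.frame(row = 1, class = 0)
  expect_true(check_stopping(st)$done)        # 0.80 > 1 - 0.5/2
  st$best_uniqueness <- 0.70
  expect_false(check_stopping(st)$done)

  # threshold is monotone increasing in N
  thr <- function(N) 1 - 0.5 / N
  expect_true(all(diff(thr(2:20)) > 0))
  expect_equal(thr(10), 0.95)
  expect_equal(thr(2), 0.75)

  # coverage rule: one individual with a 30% gap keeps training going
  st$N <- 2; st$best_uniqueness <- 0
  st$id_data <- list(n_frames = 100,
                     meta = data.frame(ind = c(1, 2), frame = c(0, 0)))
  rows_cl0 <- data.frame(row = 1:80, class = 0)
  st$id_data$meta <- data.frame(ind = 1, frame = 0:79)
  st$training <- rbind(rows_cl0, data.frame(row = 1:60, class = 1))
  expect_false(check_stopping(st)$done)

  expect_equal(final_epoch_cap(150), 37L)
  expect_equal(final_epoch_cap(8), 3L)
})

test_that("switch correction splits at persistent median changes only", {
  expect_length(correct_switches(rep(3L, 400), 25), 1)
  flip <- c(rep(1L, 200), rep(4L, 200))
  parts <- correct_switches(flip, 25)
  expect_length(parts, 2)
  expect_equal(parts[[1]]$to, 200)
  expect_equal(parts[[2]]$from, 201)
  # single-frame glitches are absorbed by the median
  glitchy <- rep(2L, 300); glitchy[c(50, 120, 121, 250)] <- 7L
  expect_length(correct_switches(glitchy, 25), 1)
})

test_that("the linear backend is deterministic, normalized and honours its stopping rules", {
  set.seed(5)
  X <- rbind(matrix(stats::rnorm(50 * 16, -1), 50, 16),
             matrix(stats::rnorm(50 * 16, +1), 50, 16))
  y <- rep(0:1, each = 50)
  be1 <- backend_linear(2, input_size = 4, seed = 7)
  r1 <- be1$fit(X, y, max_epochs = 150)
  be2 <- backend_linear(2, input_size = 4, seed = 7)
  r2 <- be2$fit(X, y, max_epochs = 150)
  expect_identical(be1$get_state(), be2$get_state())
  expect_identical(r1$history, r2$history)
  P <- be1$predict(X)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  expect_gt(r1$val_acc, 0.9)
  expect_lte(r1$epochs, 150)

  # unlearnable labels stop without reaching high validation accuracy
  be3 <- backend_linear(2, input_size = 4, seed = 7)
  r3 <- be3$fit(X, sample(y), max_epochs = 60)
  expect_lt(r3$val_acc, 0.8)
  # epoch cap honoured
  be4 <- backend_linear(2, input_size = 4, seed = 7)
  r4 <- be4$fit(X, y, max_epochs = 5)
  expect_lte(r4$epochs, 5)
})

test_that("uniqueness evaluation on the cached image set is reproducible", {
  sc <- tracked_scene(n_agents = 3, n_frames = 80, seed = 21,
                      agent_length = 30, agent_width = 10,
                      frame_size = c(320, 320))
  idd <- prepare_id_data(sc$tracks, 320, 320, id_config(seed = 1),
                         posture_config(normalized_zoom = 1.6))
  be <- backend_linear(3, seed = 1)
  rows <- idd$rowmap[cbind(idd$meta$ind, idd$meta$frame + 1L)]
  be$fit(idd$features, match(idd$meta$ind, sort(unique(idd$meta$ind))) - 1L,
         max_epochs = 40)
  u1 <- average_uniqueness(be, idd)
  u2 <- average_uniqueness(be, idd)
  expect_identical(u1, u2)
  expect_true(all(u1$uniqueness >= 0 & u1$uniqueness <= 1))
  expect_equal(u1$valley_threshold, 1 - 0.5 / 3)
})

test_that("model updates that lose uniqueness are rejected and rolled back", {
  sc <- tracked_scene(n_agents = 3, n_frames = 150, seed = 23,
                      agent_length = 30, agent_width = 10,
                      frame_size = c(320, 320), disappear_prob = 0.01)
  cfgid <- id_config(seed = 1)
  idd <- prepare_id_data(sc$tracks, 320, 320, cfgid,
                         posture_config(normalized_zoom = 1.6))
  gss <- find_global_segments(idd$segments, 3, idd$n_frames)
  skip_if(length(gss) < 2, "scene produced too few global segments")
  qual <- lapply(gss, segment_quality, tracks = sc$tracks, width = 320,
                 height = 320, grid = 10, id_data = idd)
  cand <- rank_global_segments(gss, qual, idd$n_frames)
  be <- backend_linear(3, seed = 1)
  st <- train_initial(cand, gss, idd, be, cfgid)
  skip_if(st$failed, "initial unit failed on this fixture")
  u_before <- st$best_uniqueness
  w_before <- st$best_state

  # sabotage: a fit that wrecks the weights
  real_fit <- be$fit
  be$fit <- function(X, y, ...) {
    be$W[] <- stats::rnorm(length(be$W), sd = 10)
    list(history = data.frame(), stop_reason = "sabotage", val_acc = 0,
         epochs = 0)
  }
  accumulation_step(st, qual)
  be$fit <- real_fit
  expect_true(any(st$status == "rejected") || isTRUE(st$exhausted) ||
              any(st$status == "failed"))
  expect_identical(be$get_state(), w_before)
  expect_equal(st$best_uniqueness, u_before)

  # 99%-of-best arithmetic: 0.97 against best 0.99 is rejected
  expect_lt(0.97, 0.99 * 0.99)
})
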