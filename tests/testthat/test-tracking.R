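test_that("clean scenes track perfectly: one segment per individual, full accuracy", {
  sc <- tracked_scene(n_agents = 4, n_frames = 120, seed = 5)
  tk <- sc$tracks
  expect_length(tk$individuals, 4)
  for (ind in tk$individuals) {
    expect_equal(nrow(ind$segments), 1L)
    expect_length(ind$frames, 120)
  }
  r <- score_identity_accuracy(tracks_table(tk), sc$truth,
                               width = sc$cfg$frame_size[1])
  expect_equal(r$similarity, 1.0)
})

test_that("a hidden individual resumes its identity with a 'lost' segment", {
  sc <- tracked_scene(n_agents = 2, n_frames = 80, seed = 3)
  # drop agent 1's blob for frames 30..32 (scripted disappearance)
  cfg <- sc$cfg
  bf <- lapply(sc$data$frames, segment_frame, background = sc$bg,
               config = seg_config(threshold = 25, blob_size_range = c(20, 8000)))
  tr0 <- sc$truth[sc$truth$id == 1, ]
  for (f in 30:32) {
    cents <- vapply(bf[[f + 1]], blob_centroid, numeric(2))
    tx <- tr0$x[tr0$frame == f]; ty <- tr0$y[tr0$frame == f]
    drop <- which.min((cents[1, ] - tx)^2 + (cents[2, ] - ty)^2)
    bf[[f + 1]] <- bf[[f + 1]][-drop]
  }
  tc <- tracker_config(track_max_individuals = 2, track_max_speed = 800,
                       max_reassign_time = 0.5)
  tk <- track_frames(bf, (0:79) / cfg$fps, tc, background = sc$bg)
  expect_length(tk$individuals, 2)
  segs <- do.call(rbind, lapply(tk$individuals, function(i) i$segments))
  expect_true("lost" %in% segs$reason)
  r <- score_identity_accuracy(tracks_table(tk), sc$truth,
                               width = cfg$frame_size[1])
  expect_equal(r$similarity, 1.0, tolerance = 0.02)
})

test_that("a timestamp jump opens a segment with reason timestamp_gap", {
  sc <- tracked_scene(n_agents = 2, n_frames = 60, seed = 8)
  bf <- lapply(sc$data$frames, segment_frame, background = sc$bg,
               config = seg_config(threshold = 25, blob_size_range = c(20, 8000)))
  times <- (0:59) / sc$cfg$fps
  times[41:60] <- times[41:60] + 5 * (1 / sc$cfg$fps)   # 5x interval at frame 40
  tc <- tracker_config(track_max_individuals = 2, track_max_speed = 2000,
                       max_reassign_time = 2)
  tk <- track_frames(bf, times, tc, background = sc$bg)
  reasons <- unlist(lapply(tk$individuals, function(i) i$segments$reason))
  expect_true("timestamp_gap" %in% reasons)
})

test_that("overlap splitting separates bodies with distinct intensities", {
  bg <- matrix(200, 40, 60)
  fr <- bg
  # two touching discs with the radial shading of 3D bodies: dark centres
  # (means about 80 and 120), lighter rims
  for (yy in 1:40) for (xx in 1:60) {
    r1 <- sqrt((xx - 22)^2 + (yy - 20)^2) / 9
    r2 <- sqrt((xx - 39)^2 + (yy - 20)^2) / 9
    if (r1 <= 1) fr[yy, xx] <- 20 + 120 * r1
    else if (r2 <= 1) fr[yy, xx] <- 70 + 100 * r2
  }
  bl <- segment_frame(fr, bg, seg_config(threshold = 25,
                                         blob_size_range = c(10, 1e5)))
  expect_length(bl, 1)          # they touch: one blob
  sp <- split_overlapping(bl[[1]], 2, bg, base_threshold = 25)
  expect_length(sp, 2)
  cents <- vapply(sp, blob_centroid, numeric(2))
  expect_lt(min(abs(cents[1, ] - 22.5)), 2)
  expect_lt(min(abs(cents[1, ] - 39.5)), 2)
  # the split conserves every original pixel
  expect_equal(sum(vapply(sp, function(b) length(b$x), numeric(1))),
               length(bl[[1]]$x))

  # a uniform blob offers no gradient: flagged unsplittable
  fr2 <- bg; fr2[10:30, 20:40] <- 100
  bl2 <- segment_frame(fr2, bg, seg_config(threshold = 25,
                                           blob_size_range = c(10, 1e5)))
  sp2 <- split_overlapping(bl2[[1]], 2, bg, base_threshold = 25)
  expect_length(sp2, 1)
  expect_true(isTRUE(attr(sp2[[1]], "unsplittable")))

  # already-separated components at the next threshold are returned directly
  fr3 <- bg; fr3[5:15, 5:15] <- 150; fr3[5:15, 30:40] <- 150
  comb <- blob(c(which(fr3 < 200, arr.ind = TRUE)[, 2] - 1),
               c(which(fr3 < 200, arr.ind = TRUE)[, 1] - 1),
               fr3[fr3 < 200])
  sp3 <- split_overlapping(comb, 2, bg, base_threshold = 25)
  expect_length(sp3, 2)
})

test_that("no blob is ever assigned twice", {
  sc <- tracked_scene(n_agents = 5, n_frames = 100, seed = 12,
                      overlap_rate = 3, frame_size = c(320, 320))
  tk <- sc$tracks
  tab <- tracks_table(tk)
  dup <- duplicated(tab[, c("frame", "blob_i")])
  expect_false(any(dup))
  per_frame <- table(tab$frame, tab$id)
  expect_true(all(per_frame <= 1))
})
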