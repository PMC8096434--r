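make_pv_frames <- function(n = 6, seed = 4) {
  cfg <- scene_config(n_agents = 3, n_frames = n, noise_sd = 2, seed = seed,
                      frame_size = c(120, 120))
  d <- generate_dataset(cfg)
  bg <- matrix(cfg$background_level, 120, 120)
  frames <- lapply(seq_len(n), function(i)
    list(timestamp_us = round((i - 1) * 1e6 / 25),
         blobs = segment_frame(d$frames[[i]], bg, seg_config())))
  list(bg = bg, frames = frames)
}

frames_equal <- function(a, b) {
  identical(lapply(a$blobs, unclass), lapply(b$blobs, unclass)) &&
    a$timestamp_us == b$timestamp_us
}

test_that("container round trips bit-exactly, compressed or not", {
  pv <- make_pv_frames()
  for (compress in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".pvs")
    pv_write(path, 120, 120, pv$bg, pv$frames, compress = compress)
    rt <- pv_read(path)
    expect_true(all(mapply(frames_equal, rt$frames, pv$frames)))
    expect_equal(rt$header$width, 120)
    expect_equal(rt$header$frame_count, 6)
    expect_identical(rt$header$background,
                     matrix(as.integer(pv$bg), 120, 120))
    for (i in seq_along(pv$frames) - 1L)
      expect_true(frames_equal(pv_read_frame(path, i), pv$frames[[i + 1]]))
    unlink(path)
  }
  # an empty container still round-trips
  p0 <- tempfile(fileext = ".pvs")
  pv_write(p0, 16, 16, matrix(0, 16, 16), list())
  expect_equal(pv_header(p0)$frame_count, 0)
  unlink(p0)
})

test_that("random access touches only the requested frame's bytes", {
  pv <- make_pv_frames()
  path <- tempfile(fileext = ".pvs")
  pv_write(path, 120, 120, pv$bg, pv$frames)
  hdr <- pv_header(path)
  raw <- readBin(path, "raw", file.size(path))
  con <- file(path, "rb"); seek(con, hdr$index_offset)
  offs <- vapply(1:6, function(i) btx:::read_u(con, 8), numeric(1))
  close(con)
  # destroy every frame payload except frame 2
  for (i in c(1, 2, 4, 5, 6)) {
    a <- offs[i] + 6
    b <- if (i < 6) offs[i + 1] else hdr$index_offset
    if (b > a) raw[(a + 1):b] <- as.raw(255)
  }
  path2 <- tempfile(fileext = ".pvs")
  writeBin(raw, path2)
  expect_true(frames_equal(pv_read_frame(path2, 2), pv$frames[[3]]))
  unlink(c(path, path2))
})

test_that("corrupt and invalid inputs raise format errors, not crashes", {
  pv <- make_pv_frames(2)
  path <- tempfile(fileext = ".pvs")
  pv_write(path, 120, 120, pv$bg, pv$frames)
  raw <- readBin(path, "raw", file.size(path))
  trunc <- tempfile(); writeBin(raw[1:50], trunc)
  expect_error(pv_header(trunc), "truncated|magic")
  bad <- tempfile(); writeBin(c(charToRaw("NOPE"), raw[-(1:4)]), bad)
  expect_error(pv_header(bad), "magic")
  expect_error(pv_read_frame(path, 99), "range")
  expect_error(pv_read_frame(path, -1), "range")
  # non-monotone timestamps refused at write time
  fr <- pv$frames; fr[[2]]$timestamp_us <- 0
  expect_error(pv_write(tempfile(), 120, 120, pv$bg, fr), "increasing")
  unlink(c(path, trunc, bad))
})

test_that("trajectory export writes one row per frame with missing-value sentinels", {
  sc <- tracked_scene(n_agents = 2, n_frames = 40, seed = 3)
  dir <- tempfile(); dir.create(dir)
  files <- export_trajectories(sc$tracks, dir)
  expect_length(list.files(dir, pattern = "csv$"), 2)
  tab <- utils::read.csv(list.files(dir, full.names = TRUE)[1])
  ind <- sc$tracks$individuals[[1]]
  expect_equal(nrow(tab), ind$frames[length(ind$frames)] - ind$frames[1] + 1)
  expect_true(all(c("frame", "time", "x", "y", "speed", "heading",
                    "segment_id", "identity") %in% names(tab)))
  # CSV and feather dialects parse to the same table
  skip_if_not_installed("arrow")
  files2 <- export_trajectories(sc$tracks, dir, format = c("csv", "feather"))
  csvf <- grep("individual_000.csv", files2, value = TRUE)
  fthf <- grep("individual_000.feather", files2, value = TRUE)
  a <- utils::read.csv(csvf)
  b <- as.data.frame(arrow::read_feather(fthf))
  a$midline_length <- as.numeric(a$midline_length)
  b$midline_length <- as.numeric(b$midline_length)
  b$segment_id <- as.integer(b$segment_id)
  expect_equal(a, b, tolerance = 1e-9)
  unlink(dir, recursive = TRUE)
})

test_that("timestamp sidecars are keyed by frame index", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(frame = c(2, 0, 1),
                              timestamp_us = c(200, 0, 100)), f,
                   row.names = FALSE)
  expect_equal(read_timestamps(f), c(0, 100, 200))
  unlink(f)
})
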