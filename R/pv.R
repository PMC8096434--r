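# The .pvs blob container: a seekable, little-endian format storing only the
# segmented foreground objects (pixel runs with grayscale values), the
# background image, per-frame timestamps and a trailing offset index for
# O(1) random frame access.  Optional per-frame deflate compression is
# marked by a flag byte.
#
# Layout:
#   header:  magic "PVS1" | u16 version | u32 width | u32 height |
#            u8 channels | u64 frame_count | u64 index_offset |
#            width*height bytes background (column-major, [y+1, x+1])
#   frame:   u8 flags (bit 0: deflate) | u32 payload_size | payload
#   payload: u64 timestamp_us | u16 n_blobs | blobs...
#   blob:    u16 x0 | u16 y0 | u16 w | u16 h | u16 n_lines | lines...
#   line:    u16 y | u16 x_start | u16 length | `length` grayscale bytes
#   index:   frame_count u64 byte offsets (at index_offset)

PV_MAGIC <- charToRaw("PVS1")

write_u <- function(con, x, size) {
  if (size == 8) {
    # 64-bit values written as two little-endian u32 halves (values < 2^53)
    lo <- x %% 2^32; hi <- x %/% 2^32
    writeBin(as.integer(lo), con, size = 4, endian = "little")
    writeBin(as.integer(hi), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(x), con, size = size, endian = "little")
  }
}
read_u <- function(con, size, n = 1) {
  if (size == 8) {
    v <- numeric(n)
    for (i in seq_len(n)) {
      lo <- readBin(con, "integer", size = 4, endian = "little")
      hi <- readBin(con, "integer", size = 4, endian = "little")
      if (length(lo) == 0) stopf("pv: truncated file")
      if (lo < 0) lo <- lo + 2^32
      if (hi < 0) hi <- hi + 2^32
      v[i] <- hi * 2^32 + lo
    }
    v
  } else {
    v <- readBin(con, "integer", n = n, size = size, endian = "little",
                 signed = size == 4)
    if (length(v) < n) stopf("pv: truncated file")
    if (size < 4 && any(v < 0)) v[v < 0] <- v[v < 0] + 2L^(8L * size)
    v
  }
}

blob_to_raw <- function(b) {
  parts <- list(writeBin(as.integer(c(b$bbox[1], b$bbox[2], b$bbox[3], b$bbox[4])),
                         raw(), size = 2, endian = "little"))
  ord <- order(b$y, b$x)
  ys <- b$y[ord]; xs <- b$x[ord]; vs <- as.integer(round(b$v[ord]))
  runs <- list()
  i <- 1L; n <- length(xs)
  while (i <= n) {
    j <- i
    while (j < n && ys[j + 1L] == ys[i] && xs[j + 1L] == xs[j] + 1L) j <- j + 1L
    runs[[length(runs) + 1]] <- c(ys[i], xs[i], j - i + 1L, vs[i:j])
    i <- j + 1L
  }
  parts[[2]] <- writeBin(length(runs), raw(), size = 2, endian = "little")
  parts <- c(parts, lapply(runs, function(r) {
    c(writeBin(as.integer(r[1:3]), raw(), size = 2, endian = "little"),
      as.raw(r[-(1:3)]))
  }))
  do.call(c, parts)
}

frame_payload <- function(timestamp_us, blobs) {
  lo <- timestamp_us %% 2^32; hi <- timestamp_us %/% 2^32
  c(writeBin(as.integer(c(lo, hi)), raw(), size = 4, endian = "little"),
    writeBin(as.integer(length(blobs)), raw(), size = 2, endian = "little"),
    do.call(c, c(list(raw(0)), lapply(blobs, blob_to_raw))))
}

#' Write a blob container
#'
#' @param path output file path (conventionally `.pvs`).
#' @param width,height frame dimensions (px).
#' @param background background image matrix (`c(height, width)`).
#' @param frames list of frames, each `list(timestamp_us, blobs)` with
#'   strictly increasing integer timestamps (microseconds).
#' @param compress deflate each frame payload (lossless).
#' @return `path`, invisibly.
#' @export
pv_write <- function(path, width, height, background, frames,
                     compress = FALSE) {
  if (!all(dim(background) == c(height, width)))
    stopf("pv_write: background dimensions do not match width/height")
  ts <- vapply(frames, function(f) f$timestamp_us, numeric(1))
  if (length(ts) > 1 && any(diff(ts) <= 0))
    stopf("pv_write: timestamps must be strictly increasing")
  for (f in frames)
    for (b in f$blobs)
      if (b$bbox[1] + b$bbox[3] > width || b$bbox[2] + b$bbox[4] > height)
        stopf("pv_write: blob outside frame dimensions")
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(PV_MAGIC, con)
  write_u(con, 1, 2)
  write_u(con, width, 4); write_u(con, height, 4)
  write_u(con, 1, 1)                       # channels
  write_u(con, length(frames), 8)
  index_offset_pos <- seek(con)
  write_u(con, 0, 8)                       # index offset placeholder
  writeBin(as.raw(as.integer(round(background))), con)
  offsets <- numeric(length(frames))
  for (i in seq_along(frames)) {
    offsets[i] <- seek(con)
    payload <- frame_payload(frames[[i]]$timestamp_us, frames[[i]]$blobs)
    flags <- 0L
    if (compress) {
      payload <- memCompress(payload, type = "gzip")
      flags <- 1L
    }
    write_u(con, flags, 1)
    write_u(con, length(payload), 4)
    writeBin(payload, con)
  }
  index_offset <- seek(con)
  for (o in offsets) write_u(con, o, 8)
  seek(con, index_offset_pos)
  write_u(con, index_offset, 8)
  invisible(path)
}

#' Read a container header
#'
#' @param path a `.pvs` file.
#' @return `list(version, width, height, channels, frame_count, background,
#'   index_offset)`.
#' @export
pv_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, "raw", 4)
  if (length(magic) < 4 || !identical(magic, PV_MAGIC))
    stopf("pv: bad magic, not a PVS file")
  version <- read_u(con, 2)
  if (version != 1) stopf("pv: unsupported version %d", version)
  width <- read_u(con, 4); height <- read_u(con, 4)
  channels <- read_u(con, 1)
  frame_count <- read_u(con, 8)
  index_offset <- read_u(con, 8)
  bg <- readBin(con, "raw", width * height)
  if (length(bg) < width * height) stopf("pv: truncated background")
  list(version = version, width = width, height = height,
       channels = channels, frame_count = frame_count,
       background = matrix(as.integer(bg), height, width),
       index_offset = index_offset)
}

#' Read one frame from a container
#'
#' Seeks via the trailing index, touching only the header, the index entry
#' and the requested frame's bytes.
#'
#' @param path a `.pvs` file.
#' @param index 0-based frame number.
#' @return `list(timestamp_us, blobs)`.
#' @export
pv_read_frame <- function(path, index) {
  hdr <- pv_header(path)
  if (index < 0 || index >= hdr$frame_count)
    stopf("pv_read_frame: frame %d out of range [0, %d)", index, hdr$frame_count)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  seek(con, hdr$index_offset + 8 * index)
  off <- read_u(con, 8)
  seek(con, off)
  flags <- read_u(con, 1)
  size <- read_u(con, 4)
  payload <- readBin(con, "raw", size)
  if (length(payload) < size) stopf("pv: truncated frame payload")
  if (bitwAnd(flags, 1L) == 1L)
    payload <- memDecompress(payload, type = "gzip")
  pcon <- rawConnection(payload)
  on.exit(close(pcon), add = TRUE)
  ts <- read_u(pcon, 8)
  n_blobs <- read_u(pcon, 2)
  blobs <- vector("list", n_blobs)
  for (bi in seq_len(n_blobs)) {
    bbox <- read_u(pcon, 2, 4)
    n_lines <- read_u(pcon, 2)
    xs <- list(); ys <- list(); vs <- list()
    for (li in seq_len(n_lines)) {
      hdr3 <- read_u(pcon, 2, 3)
      vals <- readBin(pcon, "raw", hdr3[3])
      xs[[li]] <- hdr3[2] + 0:(hdr3[3] - 1L)
      ys[[li]] <- rep(hdr3[1], hdr3[3])
      vs[[li]] <- as.integer(vals)
    }
    blobs[[bi]] <- blob(unlist(xs), unlist(ys), unlist(vs))
  }
  list(timestamp_us = ts, blobs = blobs)
}

#' Read all frames of a container
#'
#' @param path a `.pvs` file.
#' @return `list(header, frames)` where frames are as in [pv_read_frame()].
#' @export
pv_read <- function(path) {
  hdr <- pv_header(path)
  frames <- lapply(seq_len(hdr$frame_count) - 1L, pv_read_frame, path = path)
  list(header = hdr, frames = frames)
}

#' Export per-individual trajectory tables
#'
#' One table per individual with columns `frame`, `time` (s), `x`, `y` (px),
#' `speed` (px/s), `heading` (rad), `midline_length` (px, `NA` unless
#' posture was computed), `segment_id` and `identity`.  Frames inside the
#' individual's tracked range where it was lost are present with
#' missing-value sentinels (empty CSV fields / `NA`).
#'
#' @param tracks a `btx_tracks`.
#' @param dir output directory.
#' @param format `"csv"` (plain text) and/or `"feather"` (columnar binary,
#'   requires the `arrow` package).
#' @param midline_lengths optional list (parallel to individuals) of
#'   per-assignment midline lengths.
#' @return invisible character vector of files written.
#' @export
export_trajectories <- function(tracks, dir, format = "csv",
                                midline_lengths = NULL) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("export_trajectories: cannot create '%s'", dir)
  files <- character(0)
  for (i in seq_along(tracks$individuals)) {
    ind <- tracks$individuals[[i]]
    if (!length(ind$frames)) next
    fr_all <- ind$frames[1]:ind$frames[length(ind$frames)]
    m <- match(fr_all, ind$frames)
    seg_id <- rep(NA_integer_, length(fr_all))
    segs <- ind$segments
    for (k in seq_len(nrow(segs)))
      seg_id[fr_all >= segs$start[k] & fr_all <= segs$end[k] & !is.na(m)] <- k
    spd <- c(NA, sqrt(diff(ind$x)^2 + diff(ind$y)^2) / diff(ind$times))
    tab <- data.frame(
      frame = fr_all,
      time = tracks$times[fr_all + 1L],
      x = ind$x[m], y = ind$y[m],
      speed = spd[m], heading = ind$heading[m],
      midline_length = if (is.null(midline_lengths)) NA_real_
                       else midline_lengths[[i]][m],
      segment_id = seg_id,
      identity = ind$identity)
    base <- file.path(dir, sprintf("individual_%03d", ind$identity))
    if ("csv" %in% format) {
      f <- paste0(base, ".csv")
      utils::write.csv(tab, f, row.names = FALSE, na = "")
      files <- c(files, f)
    }
    if ("feather" %in% format) {
      if (!requireNamespace("arrow", quietly = TRUE))
        stopf("feather export requires the 'arrow' package")
      f <- paste0(base, ".feather")
      arrow::write_feather(tab, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Read a timestamp sidecar table
#'
#' Accepts a CSV with columns `frame` and `timestamp_us` keyed by frame
#' index, as produced by recording tools that store frame timings separately.
#'
#' @param path CSV file.
#' @return numeric vector of timestamps (microseconds) ordered by frame.
#' @export
read_timestamps <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("frame", "timestamp_us") %in% names(tab)))
    stopf("timestamp sidecar needs columns frame, timestamp_us")
  tab$timestamp_us[order(tab$frame)]
}
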