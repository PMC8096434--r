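# Background modelling and blob segmentation.
#
# Frames are integer matrices of dim c(height, width), values 0..255, indexed
# [y + 1, x + 1].  Pixel coordinates are 0-based; pixel (x, y) occupies the
# unit square [x, x+1) x [y, y+1) and has its centre at (x + 0.5, y + 0.5).

#' Construct a blob
#'
#' A blob is one segmented foreground object: its pixel coordinates, their
#' original grayscale values, and the bounding box.
#'
#' @param x,y 0-based integer pixel coordinates.
#' @param v grayscale values (0-255) of those pixels in the source frame.
#' @return object of class `btx_blob` with fields `x`, `y`, `v` and
#'   `bbox = c(x0, y0, w, h)`.
#' @export
blob <- function(x, y, v) {
  if (length(x) == 0) stopf("blob: empty pixel set")
  if (length(x) != length(y) || length(x) != length(v))
    stopf("blob: x, y, v must have equal length")
  x0 <- min(x); y0 <- min(y)
  ord <- order(y, x)   # canonical raster order
  x <- x[ord]; y <- y[ord]; v <- v[ord]
  structure(list(x = as.integer(x), y = as.integer(y), v = as.numeric(v),
                 bbox = c(x0 = as.integer(x0), y0 = as.integer(y0),
                          w = as.integer(max(x) - x0 + 1),
                          h = as.integer(max(y) - y0 + 1))),
            class = "btx_blob")
}

#' @export
print.btx_blob <- function(x, ...) {
  cat(sprintf("<blob: %d px, bbox [%d,%d %dx%d]>\n", length(x$x),
              x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4]))
  invisible(x)
}

#' Centroid of a blob (pixel-centre convention)
#' @param b a `btx_blob`.
#' @return `c(x, y)`.
#' @export
blob_centroid <- function(b) c(mean(b$x) + 0.5, mean(b$y) + 0.5)

#' Binary mask of a blob on its bounding box
#' @param b a `btx_blob`.
#' @return logical matrix of dim `c(h, w)`; entry `[y - y0 + 1, x - x0 + 1]`.
#' @export
blob_mask <- function(b) {
  m <- matrix(FALSE, b$bbox[4], b$bbox[3])
  m[cbind(b$y - b$bbox[2] + 1L, b$x - b$bbox[1] + 1L)] <- TRUE
  m
}

#' Grayscale crop of a blob on its bounding box
#' @param b a `btx_blob`.
#' @param bg value for pixels outside the blob mask.
#' @return numeric matrix of dim `c(h, w)`.
#' @export
blob_image <- function(b, bg = 0) {
  m <- matrix(bg, b$bbox[4], b$bbox[3])
  m[cbind(b$y - b$bbox[2] + 1L, b$x - b$bbox[1] + 1L)] <- b$v
  m
}

# Connected component labelling of a logical matrix (8- or 4-connectivity).
# Returns an integer matrix: 0 = background, 1..k = component labels,
# numbered deterministically in column-major order of first occurrence.
label_components <- function(mask, connectivity = 8) {
  n <- sum(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (n == 0) return(lab)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[mask] <- seq_len(n)
  H <- nrow(mask); W <- ncol(mask)
  edges <- NULL
  pair_up <- function(a, b) cbind(a[a > 0 & b > 0], b[a > 0 & b > 0])
  # horizontal, vertical and the two diagonal adjacencies
  if (W > 1) edges <- rbind(edges, pair_up(id[, -W], id[, -1]))
  if (H > 1) edges <- rbind(edges, pair_up(id[-H, ], id[-1, ]))
  if (connectivity == 8 && H > 1 && W > 1) {
    edges <- rbind(edges, pair_up(id[-H, -W], id[-1, -1]))
    edges <- rbind(edges, pair_up(id[-1, -W], id[-H, -1]))
  }
  if (is.null(edges) || nrow(edges) == 0) {
    memb <- seq_len(n)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  }
  # renumber components by first occurrence in column-major order
  first <- match(unique(memb[id[mask]]), memb[id[mask]])
  renum <- integer(max(memb))
  renum[unique(memb[id[mask]])] <- seq_along(unique(memb[id[mask]]))
  lab[mask] <- renum[memb[id[mask]]]
  lab
}

#' Estimate a static background model
#'
#' Pixelwise min, max, mode or mean over a uniform sample of frames.  The
#' mode is computed on the 8-bit histogram with ties broken toward the larger
#' value.
#'
#' @param frames list of integer frame matrices (a uniform sample of the
#'   video).
#' @param mode one of `"min"`, `"max"`, `"mode"`, `"mean"`.
#' @return object of class `btx_background` with fields `image`, `mode`,
#'   `sample_count`.
#' @export
estimate_background <- function(frames, mode = c("mode", "min", "max", "mean")) {
  mode <- match.arg(mode)
  if (length(frames) == 0) stopf("estimate_background: empty frame sample")
  img <- switch(mode,
    min  = Reduce(pmin, frames),
    max  = Reduce(pmax, frames),
    mean = Reduce(`+`, lapply(frames, as.numeric)) / length(frames),
    mode = {
      best_cnt <- matrix(-1L, nrow(frames[[1]]), ncol(frames[[1]]))
      best_val <- matrix(0L, nrow(frames[[1]]), ncol(frames[[1]]))
      vals <- sort(unique(unlist(lapply(frames, function(f) unique(as.vector(f))))))
      for (v in vals) {
        cnt <- Reduce(`+`, lapply(frames, function(f) (f == v) + 0L))
        upd <- cnt >= best_cnt      # >= : ties go to the larger value
        best_cnt[upd] <- cnt[upd]
        best_val[upd] <- v
      }
      best_val
    })
  if (mode == "mean") img <- matrix(img, nrow(frames[[1]]), ncol(frames[[1]]))
  structure(list(image = img, mode = mode, sample_count = length(frames)),
            class = "btx_background")
}

#' Segmentation parameters
#'
#' @param threshold grayscale difference threshold (0 < threshold <= 255).
#' @param blob_size_range `c(min_px, max_px)` accepted component sizes.
#' @param use_mask segment from a provided binary mask instead of the
#'   background difference.
#' @param equalize_luminance scale each frame so its global mean matches the
#'   background's before differencing.
#' @param dark_only restrict to objects darker than the background.
#' @return object of class `btx_seg_config`.
#' @export
seg_config <- function(threshold = 25, blob_size_range = c(10, 1e6),
                       use_mask = FALSE, equalize_luminance = FALSE,
                       dark_only = FALSE) {
  if (threshold <= 0 || threshold > 255)
    stopf("invalid seg config: threshold must be in (0, 255]")
  if (blob_size_range[1] > blob_size_range[2])
    stopf("invalid seg config: blob_size_range min > max")
  structure(list(threshold = threshold, blob_size_range = blob_size_range,
                 use_mask = use_mask, equalize_luminance = equalize_luminance,
                 dark_only = dark_only),
            class = "btx_seg_config")
}

#' Preprocess a frame before segmentation
#'
#' When luminance equalization is enabled, the frame is scaled so its global
#' mean intensity matches that of the background model (useful when lighting
#' flickers between frames); otherwise the frame passes through unchanged.
#' An all-zero frame is returned unchanged with a warning, since the scaling
#' is undefined.
#'
#' @param frame integer frame matrix.
#' @param background a `btx_background` (or plain matrix).
#' @param config a [seg_config()].
#' @return processed frame matrix.
#' @export
preprocess_frame <- function(frame, background, config) {
  bg <- if (inherits(background, "btx_background")) background$image else background
  if (!all(dim(frame) == dim(bg)))
    stopf("preprocess_frame: frame/background dimension mismatch")
  if (!isTRUE(config$equalize_luminance)) return(frame)
  mu <- mean(frame)
  if (mu == 0) {
    warning("preprocess_frame: all-zero frame, equalization skipped")
    return(frame)
  }
  clip(frame * (mean(bg) / mu), 0, 255)
}

#' Segment a frame into foreground blobs
#'
#' Foreground is `|frame - background| >= threshold` (or, with
#' `use_mask = TRUE`, the white pixels of `mask`).  Connected components use
#' 8-connectivity; components outside `blob_size_range` are discarded.  Each
#' blob carries the original grayscale values of its pixels.  Blobs are
#' ordered top-left to bottom-right by bounding-box origin `(y0, x0)`.
#'
#' @inheritParams preprocess_frame
#' @param mask optional binary matrix (required when `config$use_mask`).
#' @return list of [blob()] objects.
#' @export
segment_frame <- function(frame, background, config = seg_config(), mask = NULL) {
  bg <- if (inherits(background, "btx_background")) background$image else background
  if (!all(dim(frame) == dim(bg)))
    stopf("segment_frame: frame/background dimension mismatch")
  frame2 <- preprocess_frame(frame, bg, config)
  if (isTRUE(config$use_mask)) {
    if (is.null(mask)) stopf("segment_frame: use_mask = TRUE but no mask given")
    if (!all(dim(mask) == dim(frame))) stopf("segment_frame: mask dimension mismatch")
    fg <- mask > 0
  } else {
    d <- if (isTRUE(config$dark_only)) bg - frame2 else abs(frame2 - bg)
    fg <- d >= config$threshold
  }
  lab <- label_components(fg)
  k <- max(lab)
  if (k == 0) return(list())
  sizes <- tabulate(lab[lab > 0], nbins = k)
  keep <- which(sizes >= config$blob_size_range[1] &
                sizes <= config$blob_size_range[2])
  blobs <- lapply(keep, function(ci) {
    idx <- which(lab == ci, arr.ind = TRUE)
    blob(x = idx[, 2] - 1L, y = idx[, 1] - 1L, v = frame[idx])
  })
  if (length(blobs) == 0) return(list())
  ord <- order(vapply(blobs, function(b) b$bbox[2], numeric(1)),
               vapply(blobs, function(b) b$bbox[1], numeric(1)))
  blobs[ord]
}

#' Fill interior holes of a binary mask
#'
#' Background pixels not reachable from the image border (under
#' 4-connectivity, the dual of the 8-connected foreground) are set to
#' foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(mask) {
  inv <- label_components(!mask, connectivity = 4)
  border <- setdiff(unique(c(inv[1, ], inv[nrow(inv), ],
                             inv[, 1], inv[, ncol(inv)])), 0L)
  mask | (inv > 0 & !matrix(inv %in% border, nrow(inv), ncol(inv)))
}
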