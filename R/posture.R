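# 2D posture estimation: pixel-corner outline tracing, outline smoothing
# (elliptic Fourier or weighted moving average), head/tail detection, midline
# extraction with body thickness, and pose-normalized image generation.
#
# Outline vertices live at integer pixel corners: pixel (x, y) occupies
# [x, x+1) x [y, y+1).  Outlines are closed (first vertex not repeated) and
# run clockwise in image coordinates (x right, y down).

#' Posture parameters
#'
#' @param smoothing `"eft"` (elliptic Fourier), `"weighted"` (triangular
#'   moving average) or `"none"`.
#' @param n_efd number of elliptic Fourier descriptors kept (>= 2); 2 is
#'   equivalent to fitting an ellipse.
#' @param smooth_window odd window width for weighted smoothing.
#' @param pointiest_is whether the pointiest outline end is the `"tail"`
#'   (fish-like bodies, the default) or the `"head"`.
#' @param midline_resolution number of midline points returned.
#' @param normalized_image_size `c(width, height)` of pose-normalized crops.
#' @param normalized_zoom magnification of the normalized crop; pick it so
#'   the body roughly fills the crop (for bodies of length L, about
#'   `0.6 * width / L`).
#' @return object of class `btx_posture_config`.
#' @export
posture_config <- function(smoothing = c("eft", "weighted", "none"), n_efd = 8,
                           smooth_window = 5, pointiest_is = c("tail", "head"),
                           midline_resolution = 25,
                           normalized_image_size = c(80, 80),
                           normalized_zoom = 2.5) {
  smoothing <- match.arg(smoothing)
  pointiest_is <- match.arg(pointiest_is)
  if (n_efd < 2) stopf("invalid posture config: n_efd must be >= 2")
  if (smooth_window %% 2 == 0) stopf("invalid posture config: smooth_window must be odd")
  structure(list(smoothing = smoothing, n_efd = n_efd,
                 smooth_window = smooth_window, pointiest_is = pointiest_is,
                 midline_resolution = as.integer(midline_resolution),
                 normalized_image_size = as.integer(normalized_image_size),
                 normalized_zoom = normalized_zoom),
            class = "btx_posture_config")
}

#' Trace the outline of a blob at pixel-corner resolution
#'
#' Follows the cracks between foreground and background pixels clockwise (in
#' image coordinates), so that a single pixel yields its four unit-square
#' corners.  For simply connected masks the shoelace area of the traced
#' polygon equals the pixel count exactly.  A disconnected mask is traced on
#' its largest component, with a warning.
#'
#' @param b a [blob()] or a logical mask matrix.
#' @return matrix (n x 2) of corner coordinates `(x, y)`, class
#'   `btx_outline`; for a blob input the coordinates are global.
#' @export
trace_outline <- function(b) {
  if (inherits(b, "btx_blob")) {
    mask <- blob_mask(b)
    off <- c(b$bbox[1], b$bbox[2])
  } else {
    mask <- b
    off <- c(0, 0)
  }
  if (!any(mask)) stopf("trace_outline: empty mask")
  lab <- label_components(mask)
  if (max(lab) > 1) {
    warning("trace_outline: disconnected mask, tracing largest component")
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  h <- nrow(mask); w <- ncol(mask)
  # pad so pixel lookups at the border never leave the matrix
  pm <- matrix(FALSE, h + 2, w + 2)
  pm[2:(h + 1), 2:(w + 1)] <- mask
  fg <- function(px, py) pm[py + 2, px + 2]   # 0-based pixel coords, local
  # start: topmost then leftmost foreground pixel; its top-left corner, east
  idx <- which(mask, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  sy <- idx[ord[1], 1] - 1L; sx <- idx[ord[1], 2] - 1L
  cx <- sx; cy <- sy
  dir <- 0L   # 0 = E, 1 = S, 2 = W, 3 = N
  dx <- c(1L, 0L, -1L, 0L); dy <- c(0L, 1L, 0L, -1L)
  # pixels sharing the current corner, ahead-left / ahead-right of direction
  alx <- c(0L, 0L, -1L, -1L); aly <- c(-1L, 0L, 0L, -1L)
  arx <- c(0L, -1L, -1L, 0L); ary <- c(0L, 0L, -1L, -1L)
  n_max <- 4L * (sum(mask) + 1L) + 8L
  xs <- integer(n_max); ys <- integer(n_max)
  k <- 0L
  repeat {
    k <- k + 1L
    if (k > n_max) stopf("trace_outline: runaway boundary walk")
    xs[k] <- cx; ys[k] <- cy
    if (fg(cx + alx[dir + 1], cy + aly[dir + 1])) {
      dir <- (dir + 3L) %% 4L            # turn left
    } else if (!fg(cx + arx[dir + 1], cy + ary[dir + 1])) {
      dir <- (dir + 1L) %% 4L            # turn right
    }                                     # else go straight
    cx <- cx + dx[dir + 1]; cy <- cy + dy[dir + 1]
    # the start corner (top-left of the topmost-leftmost pixel) touches
    # exactly one foreground pixel, so it is visited once per loop
    if (cx == sx && cy == sy) break
  }
  out <- cbind(x = xs[1:k] + off[1], y = ys[1:k] + off[2])
  class(out) <- c("btx_outline", class(out))
  out
}

#' Signed shoelace area of a closed polygon
#'
#' Positive for clockwise orientation in image coordinates (y down).
#' @param pts n x 2 matrix of vertices (closed implicitly).
#' @return signed area.
#' @export
polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# cumulative arc length of a closed polygon (length n + 1; last = perimeter)
arc_lengths <- function(pts) {
  d <- sqrt(rowSums((rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE]) - pts)^2))
  c(0, cumsum(d))
}

# points at arc positions s (recycled modulo perimeter) on a closed polygon
point_at_arc <- function(pts, s) {
  cl <- arc_lengths(pts)
  P <- cl[length(cl)]
  s <- s %% P
  seg <- findInterval(s, cl, rightmost.closed = TRUE)
  seg[seg > nrow(pts)] <- nrow(pts)
  nxt <- seg %% nrow(pts) + 1
  denom <- cl[seg + 1] - cl[seg]
  f <- ifelse(denom > 0, (s - cl[seg]) / denom, 0)
  pts[seg, , drop = FALSE] * (1 - f) + pts[nxt, , drop = FALSE] * f
}

# resample a closed polygon to k points of equal arc spacing
resample_closed <- function(pts, k) {
  P <- arc_lengths(pts)[nrow(pts) + 1]
  point_at_arc(pts, seq(0, P, length.out = k + 1)[-(k + 1)])
}

#' Smooth an outline with a truncated elliptic Fourier series
#'
#' The closed contour is resampled to uniform arc spacing and decomposed into
#' its elliptic Fourier series; the lowest `n_efd - 1` harmonics are kept and
#' the contour reconstructed at the original point count.  With `n_efd = 2`
#' only the first harmonic survives and the result is exactly an ellipse;
#' larger values approximate the contour increasingly closely.
#'
#' @param outline n x 2 outline matrix.
#' @param n_efd number of descriptors (>= 2).
#' @return smoothed outline, same point count.
#' @export
smooth_outline_eft <- function(outline, n_efd) {
  if (n_efd < 2) stopf("smooth_outline_eft: n_efd must be >= 2")
  K <- nrow(outline)
  if (K < 4 || max(apply(outline, 2, function(v) diff(range(v)))) == 0)
    stopf("smooth_outline_eft: degenerate outline")
  pts <- resample_closed(outline, K)
  z <- complex(real = pts[, 1], imaginary = pts[, 2])
  zf <- stats::fft(z)
  freq <- c(0:(K %/% 2), -(((K - 1) %/% 2):1))
  H <- n_efd - 1
  zf[abs(freq) > H] <- 0
  zs <- stats::fft(zf, inverse = TRUE) / K
  out <- cbind(x = Re(zs), y = Im(zs))
  class(out) <- c("btx_outline", class(out))
  out
}

#' Smooth an outline with a circular triangular-weighted moving average
#'
#' @param outline n x 2 outline matrix.
#' @param window odd window width; 1 returns the outline unchanged.
#' @return smoothed outline.
#' @export
smooth_outline_weighted <- function(outline, window) {
  if (window %% 2 == 0) stopf("smooth_outline_weighted: window must be odd")
  if (window >= nrow(outline)) stopf("smooth_outline_weighted: window too large")
  if (window == 1) return(outline)
  half <- (window - 1) / 2
  wts <- half + 1 - abs(-half:half)
  wts <- wts / sum(wts)
  n <- nrow(outline)
  out <- outline
  for (j in 1:2) {
    acc <- numeric(n)
    for (k in -half:half) {
      idx <- ((seq_len(n) - 1 + k) %% n) + 1
      acc <- acc + wts[k + half + 1] * outline[idx, j]
    }
    out[, j] <- acc
  }
  out
}

#' Find the head and tail vertices of an outline
#'
#' Scores every vertex by pointedness: the turning angle between the outline
#' points one window ahead and behind (window = 5% of the perimeter),
#' discounted by the normalized area of the enclosed triangle.  The global
#' maximum is the pointiest end, assigned to head or tail according to
#' `config$pointiest_is`; the opposite endpoint is the vertex at maximal arc
#' distance.  Near-circular shapes, whose score spread is tiny, are flagged
#' `ambiguous` (posture is still returned; downstream visual-field
#' reconstruction refuses such shapes).
#'
#' @param outline n x 2 (smoothed) outline.
#' @param config a [posture_config()].
#' @return `list(head_index, tail_index, scores, ambiguous)`.
#' @export
find_endpoints <- function(outline, config = posture_config()) {
  n <- nrow(outline)
  cl <- arc_lengths(outline)
  P <- cl[n + 1]
  delta <- 0.05 * P
  a <- point_at_arc(outline, cl[1:n] - delta)
  c_ <- point_at_arc(outline, cl[1:n] + delta)
  v1 <- outline - a; v2 <- c_ - outline
  dot <- rowSums(v1 * v2)
  nn <- sqrt(rowSums(v1^2) * rowSums(v2^2))
  turn <- acos(clip(ifelse(nn > 0, dot / nn, 1), -1, 1))
  area <- abs((a[, 1] - outline[, 1]) * (c_[, 2] - outline[, 2]) -
              (c_[, 1] - outline[, 1]) * (a[, 2] - outline[, 2])) / 2
  score <- turn / pi - area / delta^2
  pointiest <- which.max(score)
  # opposite endpoint: maximal arc distance (half perimeter away)
  arcd <- abs(cl[1:n] - cl[pointiest])
  arcd <- pmin(arcd, P - arcd)
  opposite <- which.max(arcd)
  ambiguous <- (max(score) - min(score)) < 0.05
  if (config$pointiest_is == "tail")
    list(head_index = opposite, tail_index = pointiest,
         scores = score, ambiguous = ambiguous)
  else
    list(head_index = pointiest, tail_index = opposite,
         scores = score, ambiguous = ambiguous)
}

#' Compute the midline of an outline
#'
#' Two cursors start at the head vertex and advance along the two outline
#' directions in steps of approximately equal arc length (25% wiggle room),
#' each step chosen to minimize the left-right chord.  Midline points are
#' chord midpoints, the local body thickness is the chord length; the path is
#' resampled to `midline_resolution` points.
#'
#' @param outline n x 2 (smoothed) outline.
#' @param head_index index of the head vertex in `outline`.
#' @param config a [posture_config()].
#' @return object of class `btx_midline`: `points` (m x 2), `thickness` (m),
#'   `length` (arc length, px), `head_index`, `failed`.
#' @export
compute_midline <- function(outline, head_index, config = posture_config()) {
  n <- nrow(outline)
  cl <- arc_lengths(outline)
  P <- cl[n + 1]
  m_out <- config$midline_resolution
  n_steps <- max(2 * m_out, 16)
  h <- P / n_steps
  s0 <- cl[head_index]
  # arc positions of the two cursors, both measured from the head
  lpos <- 0; rpos <- P
  mids <- matrix(NA_real_, n_steps + 2, 2)
  thick <- numeric(n_steps + 2)
  head_pt <- outline[head_index, ]
  mids[1, ] <- head_pt; thick[1] <- 0
  k <- 1L
  fr <- c(0.75, 0.875, 1, 1.125, 1.25)
  failed <- FALSE
  while (rpos - lpos > 1.5 * h) {
    cand_l <- lpos + fr * h
    cand_r <- rpos - fr * h
    pl <- point_at_arc(outline, s0 + cand_l)
    pr <- point_at_arc(outline, s0 + cand_r)
    # all 5 x 5 non-crossing pairings; pick the shortest chord
    d2 <- outer(seq_len(5), seq_len(5), function(i, j)
      (pl[i, 1] - pr[j, 1])^2 + (pl[i, 2] - pr[j, 2])^2)
    valid <- outer(cand_l, cand_r, `<`)
    if (!any(valid)) {
      # cursors about to cross: normal at the tail, a failure earlier on
      if (rpos - lpos > 0.2 * P) failed <- TRUE
      break
    }
    d2[!valid] <- Inf
    best <- arrayInd(which.min(d2), dim(d2))
    il <- best[1]; ir <- best[2]
    lpos <- cand_l[il]; rpos <- cand_r[ir]
    k <- k + 1L
    mids[k, ] <- (pl[il, ] + pr[ir, ]) / 2
    thick[k] <- sqrt(d2[il, ir])
    if (k >= n_steps + 1L) break
  }
  # close at the far end (tail tip)
  tailpt <- point_at_arc(outline, s0 + (lpos + rpos) / 2)
  k <- k + 1L
  mids[k, ] <- tailpt; thick[k] <- 0
  mids <- mids[1:k, , drop = FALSE]; thick <- thick[1:k]
  # resample to midline_resolution points by arc length
  seglen <- sqrt(rowSums(diff(mids)^2))
  arc <- c(0, cumsum(seglen))
  total <- arc[length(arc)]
  if (total <= 0) failed <- TRUE
  if (failed && k < 3) {
    return(structure(list(points = mids, thickness = thick, length = total,
                          head_index = head_index, failed = TRUE),
                     class = "btx_midline"))
  }
  ts <- seq(0, total, length.out = m_out)
  seg <- pmin(pmax(findInterval(ts, arc, rightmost.closed = TRUE), 1), k - 1)
  f <- (ts - arc[seg]) / pmax(arc[seg + 1] - arc[seg], 1e-12)
  pts <- mids[seg, , drop = FALSE] * (1 - f) + mids[seg + 1, , drop = FALSE] * f
  th <- thick[seg] * (1 - f) + thick[seg + 1] * f
  len <- sum(sqrt(rowSums(diff(pts)^2)))
  structure(list(points = pts, thickness = th, length = len,
                 head_index = head_index, failed = failed),
            class = "btx_midline")
}

#' Orientation of a blob from image moments
#'
#' `0.5 * atan2(2 mu11, mu20 - mu02)` from the central second moments of the
#' pixel set, mapped to `[0, 180)` degrees.  The 180-degree head/tail
#' ambiguity is inherent to this estimator.  Isotropic blobs return 0 with
#' attribute `ambiguous = TRUE`.
#'
#' @param b a [blob()].
#' @return angle in degrees in `[0, 180)`.
#' @export
moments_orientation <- function(b) {
  if (length(b$x) < 2) stopf("moments_orientation: need at least 2 pixels")
  px <- b$x + 0.5; py <- b$y + 0.5
  mx <- mean(px); my <- mean(py)
  mu20 <- mean((px - mx)^2); mu02 <- mean((py - my)^2)
  mu11 <- mean((px - mx) * (py - my))
  if (abs(mu20 - mu02) < 1e-12 && abs(mu11) < 1e-12) {
    ang <- 0
    attr(ang, "ambiguous") <- TRUE
    return(ang)
  }
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  ang %% 180
}

#' Full posture for one blob
#'
#' Convenience pipeline: trace, smooth, endpoints, midline.
#'
#' @param b a [blob()].
#' @param config a [posture_config()].
#' @return `list(outline, smoothed, endpoints, midline)`, class `btx_posture`;
#'   `midline` is `NULL` when the blob is too small to trace a midline.
#' @export
blob_posture <- function(b, config = posture_config()) {
  outline <- trace_outline(b)
  smoothed <- switch(config$smoothing,
    eft = tryCatch(smooth_outline_eft(outline, config$n_efd),
                   error = function(e) outline),
    weighted = smooth_outline_weighted(outline,
                 min(config$smooth_window,
                     nrow(outline) - 1 - (nrow(outline) %% 2 == 0))),
    none = outline)
  ep <- find_endpoints(smoothed, config)
  ml <- compute_midline(smoothed, ep$head_index, config)
  structure(list(outline = outline, smoothed = smoothed, endpoints = ep,
                 midline = ml), class = "btx_posture")
}

#' Pose-normalized crop of a blob
#'
#' Rigidly maps the blob so the head sits at a fixed anchor (25% from the
#' left edge, vertical centre) and the initial midline direction points along
#' +x, then samples bilinearly into a fixed-size grayscale image with the
#' background zeroed.  When the midline failed (or `midline` is `NULL`) the
#' crop falls back to moment-based alignment: rotation by the image-moment
#' orientation about the centroid, centred in the output.
#'
#' @param b a [blob()].
#' @param midline a `btx_midline` or `NULL`.
#' @param config a [posture_config()].
#' @return numeric matrix `normalized_image_size` (dim `c(h, w)`), values
#'   0-255, attribute `mode` either `"posture"` or `"moments"`.
#' @export
normalize_image <- function(b, midline, config = posture_config()) {
  wh <- config$normalized_image_size
  W <- wh[1]; H <- wh[2]
  img <- blob_image(b, bg = NA)
  x0 <- b$bbox[1]; y0 <- b$bbox[2]
  use_posture <- !is.null(midline) && !isTRUE(midline$failed) &&
    nrow(midline$points) >= 2
  if (use_posture) {
    anchor <- c(0.25 * W, 0.5 * H)
    headp <- midline$points[1, ]
    k <- max(2, ceiling(nrow(midline$points) * 0.25))
    dir <- midline$points[k, ] - headp
    ang <- atan2(dir[2], dir[1])
    mode <- "posture"
  } else {
    anchor <- c(0.5 * W, 0.5 * H)
    cen <- blob_centroid(b)
    headp <- cen
    ang <- as.numeric(moments_orientation(b)) * pi / 180
    mode <- "moments"
  }
  ca <- cos(ang); sa <- sin(ang)
  z <- config$normalized_zoom %||% 1
  ox <- rep(seq_len(W) - 0.5, each = H)
  oy <- rep(seq_len(H) - 0.5, times = W)
  rx <- (ox - anchor[1]) / z; ry <- (oy - anchor[2]) / z
  sx <- headp[1] + ca * rx - sa * ry
  sy <- headp[2] + sa * rx + ca * ry
  # bilinear sample in local crop coordinates (pixel centres at +0.5)
  lx <- sx - x0 - 0.5; ly <- sy - y0 - 0.5
  i0 <- floor(ly); j0 <- floor(lx)
  fy <- ly - i0; fx <- lx - j0
  h <- nrow(img); w <- ncol(img)
  gv <- function(i, j) {
    ok <- i >= 0 & i < h & j >= 0 & j < w
    v <- rep(0, length(i))
    v[ok] <- img[cbind(i[ok] + 1, j[ok] + 1)]
    v[is.na(v)] <- 0
    v
  }
  val <- gv(i0, j0) * (1 - fy) * (1 - fx) + gv(i0 + 1, j0) * fy * (1 - fx) +
         gv(i0, j0 + 1) * (1 - fy) * fx + gv(i0 + 1, j0 + 1) * fy * fx
  out <- matrix(val, H, W)
  attr(out, "mode") <- mode
  out
}
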