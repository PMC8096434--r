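# 2D visual-field reconstruction: per-eye ray casting against the posture
# outlines of all individuals, with multiple occlusion orders.

#' Eye-model parameters
#'
#' @param fov field of view per eye, degrees.
#' @param rays number of angular bins over the full circle.
#' @param eye_offset_ratio eye anchor position along the midline, as a
#'   fraction of midline length behind the snout.
#' @param eye_separation_ratio lateral eye separation as a fraction of the
#'   local body thickness.
#' @param eye_rotation degrees each gaze is rotated forward from lateral;
#'   at 0 the eyes look sideways (+-90 degrees off the body axis), which for
#'   `fov > 180` leaves a frontal binocular overlap of `2 fov - 360` degrees.
#' @param max_orders number of occlusion layers to record.
#' @return object of class `btx_eye_config`.
#' @export
eye_config <- function(fov = 260, rays = 512, eye_offset_ratio = 0.1,
                       eye_separation_ratio = 0.9, eye_rotation = 0,
                       max_orders = 2) {
  if (fov <= 0 || fov > 360) stopf("invalid eye config: fov must be in (0, 360]")
  if (rays < 8) stopf("invalid eye config: rays must be >= 8")
  if (max_orders < 1) stopf("invalid eye config: max_orders must be >= 1")
  structure(list(fov = fov, rays = as.integer(rays),
                 eye_offset_ratio = eye_offset_ratio,
                 eye_separation_ratio = eye_separation_ratio,
                 eye_rotation = eye_rotation, max_orders = as.integer(max_orders)),
            class = "btx_eye_config")
}

# point/tangent/thickness on a midline at an arc fraction from the head
midline_at <- function(ml, frac) {
  pts <- ml$points
  seglen <- sqrt(rowSums(diff(pts)^2))
  arc <- c(0, cumsum(seglen))
  s <- frac * arc[length(arc)]
  seg <- pmin(pmax(findInterval(s, arc, rightmost.closed = TRUE), 1), nrow(pts) - 1)
  f <- (s - arc[seg]) / pmax(arc[seg + 1] - arc[seg], 1e-12)
  p <- pts[seg, ] * (1 - f) + pts[seg + 1, ] * f
  tang <- pts[seg + 1, ] - pts[seg, ]
  list(point = p, angle = atan2(tang[2], tang[1]),
       thickness = ml$thickness[seg] * (1 - f) + ml$thickness[seg + 1] * f)
}

#' Place the two eyes on a posture
#'
#' The anchor sits `eye_offset_ratio` of the midline length behind the snout;
#' the eyes are offset symmetrically left and right by
#' `eye_separation_ratio * thickness / 2` perpendicular to the local midline
#' direction.  Each gaze points sideways (rotated `90 - eye_rotation` degrees
#' off the local body axis towards its own side).
#'
#' @param midline a `btx_midline` (head to tail).
#' @param outline the matching outline (currently unused, kept for the
#'   module surface).
#' @param config an [eye_config()].
#' @return list of two eyes, each `list(position, gaze)`, gaze in radians.
#' @export
place_eyes <- function(midline, outline = NULL, config = eye_config()) {
  if (is.null(midline) || isTRUE(midline$failed))
    stopf("place_eyes: valid midline required (round/failed postures have no visual field)")
  loc <- midline_at(midline, config$eye_offset_ratio)
  off <- config$eye_separation_ratio * loc$thickness / 2
  n <- c(cos(loc$angle + pi / 2), sin(loc$angle + pi / 2))
  # loc$angle is the head->tail tangent; rotating it by +-(90 + eye_rotation)
  # yields a lateral gaze that tilts forward as eye_rotation grows
  rot <- config$eye_rotation * pi / 180
  list(
    list(position = loc$point + off * n,
         gaze = wrap_angle(loc$angle + pi / 2 + rot), side = "plus"),
    list(position = loc$point - off * n,
         gaze = wrap_angle(loc$angle - pi / 2 - rot), side = "minus"))
}

# all intersections of ray (origin e, unit direction u) with a closed polygon;
# returns t (distance) and arc position of the hit along the outline
ray_polygon_hits <- function(e, u, pts) {
  p <- pts
  q <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  dx <- q[, 1] - p[, 1]; dy <- q[, 2] - p[, 2]
  denom <- u[1] * dy - u[2] * dx
  ex <- p[, 1] - e[1]; ey <- p[, 2] - e[2]
  t <- (ex * dy - ey * dx) / denom
  s <- (ex * u[2] - ey * u[1]) / (-denom)
  ok <- is.finite(t) & t > 1e-9 & s >= 0 & s < 1
  if (!any(ok)) return(NULL)
  cl <- arc_lengths(pts)
  seg <- which(ok)
  list(t = t[ok], arc = cl[seg] + s[ok] * (cl[seg + 1] - cl[seg]))
}

#' Reconstruct the 2D visual field of one individual
#'
#' For each eye, rays are cast at the centres of `rays` equal angular bins
#' spanning (-180, 180] relative to the focal body axis; bins outside the
#' eye's field of view stay empty.  Ray intersections with every outline
#' (including the focal individual's own) are ordered by distance; the first
#' hit fills the order-1 layers and subsequent hits on distinct occluders
#' fill orders 2..`max_orders`.  Own-body intersections closer than the local
#' body thickness at the eye are discarded: the eye sits essentially on the
#' body surface and its immediate surroundings lie below the line of sight.
#' Channels per (eye, order, bin): occluder identity, distance (px), and the
#' body part hit (outline arc position from the occluder's head, percent).
#'
#' @param focal identity (name in `postures`) of the focal individual.
#' @param postures named list: identity -> `list(outline, midline,
#'   head_index)`; stale postures (last available) may be flagged with
#'   `attr(x, "stale")`.
#' @param config an [eye_config()].
#' @return object of class `btx_visual_field` with arrays `identity`,
#'   `distance`, `body_part` of dim `c(2, max_orders, rays)`, bin centre
#'   angles in degrees, and the eye placements.
#' @export
compute_visual_field <- function(focal, postures, config = eye_config()) {
  focal <- as.character(focal)
  if (is.null(postures[[focal]])) stopf("compute_visual_field: focal posture missing")
  fp <- postures[[focal]]
  eyes <- place_eyes(fp$midline, fp$outline, config)
  axis_dir <- midline_at(fp$midline, 0.05)
  # the midline tangent points head -> tail; the body axis faces forward
  axis <- wrap_angle(axis_dir$angle + pi)
  nb <- config$rays
  bin_centers <- -180 + (seq_len(nb) - 0.5) * 360 / nb   # degrees, (-180,180]
  ids <- names(postures)
  out_id <- array(NA_character_, c(2, config$max_orders, nb))
  covered <- matrix(FALSE, 2, nb)
  out_d <- array(NA_real_, c(2, config$max_orders, nb))
  out_bp <- array(NA_real_, c(2, config$max_orders, nb))
  # precompute outline data
  odat <- lapply(postures, function(ps) {
    cl <- arc_lengths(ps$outline)
    head_arc <- cl[ps$head_index %||% 1]
    list(pts = ps$outline, P = cl[length(cl)], head_arc = head_arc)
  })
  eye_thick <- midline_at(fp$midline, config$eye_offset_ratio)$thickness
  for (ei in 1:2) {
    eye <- eyes[[ei]]
    for (bi in seq_len(nb)) {
      bin_global <- wrap_angle(axis + bin_centers[bi] * pi / 180)
      rel <- abs(wrap_angle(bin_global - eye$gaze)) * 180 / pi
      if (rel > config$fov / 2) next
      covered[ei, bi] <- TRUE
      u <- c(cos(bin_global), sin(bin_global))
      hits_t <- numeric(0); hits_id <- character(0); hits_bp <- numeric(0)
      for (id in ids) {
        h <- ray_polygon_hits(eye$position, u, odat[[id]]$pts)
        if (is.null(h)) next
        if (id == focal) {
          keep <- h$t > eye_thick
          if (!any(keep)) next
          h$t <- h$t[keep]; h$arc <- h$arc[keep]
        }
        bp <- ((h$arc - odat[[id]]$head_arc) %% odat[[id]]$P) / odat[[id]]$P * 100
        hits_t <- c(hits_t, h$t); hits_id <- c(hits_id, rep(id, length(h$t)))
        hits_bp <- c(hits_bp, bp)
      }
      if (!length(hits_t)) next
      ord <- order(hits_t)
      hits_t <- hits_t[ord]; hits_id <- hits_id[ord]; hits_bp <- hits_bp[ord]
      first <- !duplicated(hits_id)
      hits_t <- hits_t[first]; hits_id <- hits_id[first]; hits_bp <- hits_bp[first]
      k <- min(length(hits_t), config$max_orders)
      out_id[ei, 1:k, bi] <- hits_id[1:k]
      out_d[ei, 1:k, bi] <- hits_t[1:k]
      out_bp[ei, 1:k, bi] <- hits_bp[1:k]
    }
  }
  structure(list(identity = out_id, distance = out_d, body_part = out_bp,
                 covered = covered, angles = bin_centers, eyes = eyes,
                 focal = focal, config = config),
            class = "btx_visual_field")
}

#' @export
print.btx_visual_field <- function(x, ...) {
  nb <- length(x$angles)
  filled <- sum(!is.na(x$identity[, 1, ]))
  cat(sprintf("<visual field of '%s': %d bins/eye, %d order-1 hits>\n",
              x$focal, nb, filled))
  invisible(x)
}
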