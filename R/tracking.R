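# Frame-by-frame tracking: maintains per-identity trajectories, applies the
# matchers from matching.R per local clique, splits touching blobs on demand,
# and records segment boundaries (lost / uncertain / timestamp_gap).

#' Tracker configuration
#'
#' @param track_max_individuals expected number of individuals, or
#'   `"unknown"` for open-ended tracking.
#' @param track_max_speed maximal plausible speed (px/s); defines both the
#'   hard search radius and the width of the match-probability kernel.
#' @param matching_probability_threshold assignment edges must exceed this.
#' @param max_reassign_time seconds a lost individual stays eligible for
#'   re-assignment before it is retired.
#' @param clique_node_cap tree-search node budget before the Hungarian
#'   fallback kicks in.
#' @param matcher `"tree"` (exact, with fallback), `"hungarian"`, or
#'   `"approximate"` (greedy).
#' @return object of class `btx_tracker_config`.
#' @export
tracker_config <- function(track_max_individuals = "unknown",
                           track_max_speed = 250,
                           matching_probability_threshold = 0.1,
                           max_reassign_time = 0.5,
                           clique_node_cap = 1e5,
                           matcher = c("tree", "hungarian", "approximate")) {
  matcher <- match.arg(matcher)
  if (track_max_speed <= 0) stopf("invalid tracker config: track_max_speed must be > 0")
  if (matching_probability_threshold <= 0 || matching_probability_threshold >= 1)
    stopf("invalid tracker config: matching_probability_threshold must be in (0,1)")
  if (!identical(track_max_individuals, "unknown"))
    track_max_individuals <- as.integer(track_max_individuals)
  structure(list(track_max_individuals = track_max_individuals,
                 track_max_speed = track_max_speed,
                 matching_probability_threshold = matching_probability_threshold,
                 max_reassign_time = max_reassign_time,
                 clique_node_cap = clique_node_cap, matcher = matcher),
            class = "btx_tracker_config")
}

#' Split a blob suspected to contain overlapping individuals
#'
#' Raises the segmentation threshold on the blob's background-difference
#' image in steps of 1 until at least `expected_count` similarly sized
#' components emerge (each at least 60% of the median component size).
#' Pixels lost to the higher threshold (including too-small fragments) are
#' re-attached to the nearest surviving component, so no original pixel is
#' dropped.  If no threshold up to 254 separates the blob, the original blob
#' is returned with attribute `unsplittable = TRUE`; such blobs stay
#' unassigned rather than being force-split.
#'
#' @param b a [blob()].
#' @param expected_count number of individuals believed inside (>= 2).
#' @param background background model image (matrix) or `btx_background`.
#' @param base_threshold the segmentation threshold splitting starts from.
#' @return list of blobs (length >= 2 on success, length 1 with the
#'   `unsplittable` attribute on failure).
#' @export
split_overlapping <- function(b, expected_count, background, base_threshold = 25) {
  if (expected_count < 2) stopf("split_overlapping: expected_count must be >= 2")
  bg <- if (inherits(background, "btx_background")) background$image else background
  bgv <- bg[cbind(b$y + 1L, b$x + 1L)]
  diffv <- abs(b$v - bgv)
  h <- b$bbox[4]; w <- b$bbox[3]
  ly <- b$y - b$bbox[2] + 1L; lx <- b$x - b$bbox[1] + 1L
  for (thr in seq(floor(base_threshold) + 1, 254)) {
    keep <- diffv >= thr
    if (sum(keep) < expected_count) break
    m <- matrix(FALSE, h, w)
    m[cbind(ly[keep], lx[keep])] <- TRUE
    lab <- label_components(m)
    k <- max(lab)
    if (k < expected_count) next
    sizes <- tabulate(lab[lab > 0], nbins = k)
    similar <- which(sizes >= 0.6 * stats::median(sizes))
    if (length(similar) < expected_count) next
    # pixel labels in blob order; drop dissimilar fragments
    plab <- integer(length(b$x))
    plab[keep] <- lab[cbind(ly[keep], lx[keep])]
    plab[!(plab %in% similar)] <- 0L
    # regenerate lost pixels: grow the components outward in order of
    # decreasing background difference (watershed-style), so the dividing
    # line settles in the intensity valley between the bodies
    if (any(plab == 0L)) {
      lmat <- matrix(0L, h, w)
      lmat[cbind(ly, lx)] <- plab
      dmat <- matrix(-1, h, w)
      dmat[cbind(ly, lx)] <- diffv
      dilate8 <- function(m) {
        p <- matrix(FALSE, h + 2, w + 2)
        p[2:(h + 1), 2:(w + 1)] <- m
        out <- matrix(FALSE, h, w)
        for (dy in -1:1) for (dx in -1:1)
          out <- out | p[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)]
        out
      }
      nb_min_label <- function(yy, xx) {
        nb <- lmat[max(1, yy - 1):min(h, yy + 1),
                   max(1, xx - 1):min(w, xx + 1)]
        min(nb[nb > 0])
      }
      repeat {
        frontier <- lmat == 0L & dmat >= 0 & dilate8(lmat > 0L)
        if (!any(frontier)) {
          # disconnected leftovers: nearest component by euclidean distance
          left <- which(lmat == 0L & dmat >= 0, arr.ind = TRUE)
          for (k in seq_len(nrow(left))) {
            gx <- left[k, 2] - 1L + b$bbox[1]
            gy <- left[k, 1] - 1L + b$bbox[2]
            d2 <- (gx - b$x[plab > 0])^2 + (gy - b$y[plab > 0])^2
            lmat[left[k, 1], left[k, 2]] <- plab[plab > 0][which.min(d2)]
          }
          break
        }
        fi <- which(frontier, arr.ind = TRUE)
        dv <- dmat[frontier]
        pick <- fi[dv == max(dv), , drop = FALSE]
        for (k in seq_len(nrow(pick)))
          lmat[pick[k, 1], pick[k, 2]] <- nb_min_label(pick[k, 1], pick[k, 2])
      }
      plab <- lmat[cbind(ly, lx)]
    }
    comps <- sort(unique(plab))
    out <- lapply(comps, function(ci) {
      sel <- plab == ci
      blob(b$x[sel], b$y[sel], b$v[sel])
    })
    ord <- order(vapply(out, function(bb) bb$bbox[2], numeric(1)),
                 vapply(out, function(bb) bb$bbox[1], numeric(1)))
    return(out[ord])
  }
  attr(b, "unsplittable") <- TRUE
  list(b)
}

new_individual <- function(identity) {
  ind <- new.env(parent = emptyenv())
  ind$identity <- identity
  ind$frames <- integer(0); ind$times <- numeric(0)
  ind$x <- numeric(0); ind$y <- numeric(0)
  ind$heading <- numeric(0); ind$p <- numeric(0)
  ind$blob_i <- integer(0)
  ind$seg_start <- integer(0); ind$seg_reason <- character(0)
  ind$retired <- FALSE
  class(ind) <- "btx_individual"
  ind
}

append_obs <- function(ind, fr, t, cen, p, bi, reason) {
  n <- length(ind$frames)
  if (n == 0) {
    ind$seg_start <- fr; ind$seg_reason <- "start"
    hd <- 0
  } else {
    if (!is.na(reason)) {
      ind$seg_start <- c(ind$seg_start, fr)
      ind$seg_reason <- c(ind$seg_reason, reason)
    }
    dx <- cen[1] - ind$x[n]; dy <- cen[2] - ind$y[n]
    hd <- if (dx^2 + dy^2 > 0.25) atan2(dy, dx) else ind$heading[n]
  }
  ind$frames <- c(ind$frames, fr); ind$times <- c(ind$times, t)
  ind$x <- c(ind$x, cen[1]); ind$y <- c(ind$y, cen[2])
  ind$heading <- c(ind$heading, hd); ind$p <- c(ind$p, p)
  ind$blob_i <- c(ind$blob_i, bi)
  invisible(ind)
}

#' Create an empty tracker state
#'
#' @param config a [tracker_config()].
#' @param background optional background image, enabling overlap splitting.
#' @param seg_threshold the segmentation threshold (start value for
#'   [split_overlapping()]).
#' @return a mutable tracker state of class `btx_tracker`.
#' @export
tracker_state <- function(config = tracker_config(), background = NULL,
                          seg_threshold = 25) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$background <- if (inherits(background, "btx_background")) background$image else background
  st$seg_threshold <- seg_threshold
  st$individuals <- list()
  st$frame <- -1L
  st$times <- numeric(0)
  st$blobs <- list()
  class(st) <- "btx_tracker"
  st
}

#' Advance the tracker by one frame
#'
#' The core association step: (1) in known-count mode, when fewer blobs than
#' recently present individuals are found, the largest blobs claimed by
#' several predictions are passed to [split_overlapping()]; (2) cliques are
#' built and matched (tree search with Hungarian fallback by default);
#' (3) assignments are applied, opening a new segment when the assignment
#' uncertainty `1 - p` exceeds 0.5, when the individual was lost for at least
#' one frame, or when the inter-frame timestamp exceeds 1.5x the running
#' median frame interval; (4) unmatched individuals are marked lost and
#' retired after `max_reassign_time`; (5) unmatched blobs found new
#' identities (in known-count mode only while the active identity count is
#' below the cap).  In the very first frame blobs are assigned identities
#' 0..k in top-left to bottom-right order.
#'
#' @param state a [tracker_state()].
#' @param blobs list of [blob()]s for this frame (ordered top-left to
#'   bottom-right, as produced by [segment_frame()]).
#' @param t frame timestamp in seconds (strictly increasing).
#' @return the state, invisibly (modified in place).
#' @export
advance_frame <- function(state, blobs, t) {
  cfg <- state$config
  known <- !identical(cfg$track_max_individuals, "unknown")
  state$frame <- state$frame + 1L
  fr <- state$frame
  prev_t <- if (length(state$times)) state$times[length(state$times)] else NA
  state$times <- c(state$times, t)
  nominal_dt <- if (length(state$times) >= 2)
    stats::median(diff(utils::tail(state$times, 51))) else NA

  # retire individuals lost for too long
  for (ind in state$individuals) {
    if (!ind$retired && length(ind$times) &&
        t - ind$times[length(ind$times)] > cfg$max_reassign_time)
      ind$retired <- TRUE
  }
  active <- Filter(function(ind) !ind$retired, state$individuals)

  if (fr > 0L && known && length(active) > 0 && length(blobs) < length(active) &&
      !is.null(state$background) && length(blobs) > 0) {
    # overlap suspicion: several predictions landing on one blob
    preds <- lapply(active, predict_state, t = t)
    cents <- t(vapply(blobs, blob_centroid, numeric(2)))
    claims <- integer(length(blobs))
    for (j in seq_along(active)) {
      dts <- t - active[[j]]$times[length(active[[j]]$times)]
      d <- sqrt((cents[, 1] - preds[[j]]$x)^2 + (cents[, 2] - preds[[j]]$y)^2)
      jb <- which.min(d)
      if (d[jb] <= cfg$track_max_speed * dts) claims[jb] <- claims[jb] + 1L
    }
    multi <- which(claims >= 2)
    if (length(multi)) {
      sizes <- vapply(blobs, function(b) length(b$x), numeric(1))
      repl <- list()
      drop <- integer(0)
      n_after <- length(blobs)
      for (jb in multi[order(-sizes[multi])]) {
        res <- split_overlapping(blobs[[jb]], claims[jb], state$background,
                                 state$seg_threshold)
        if (length(res) > 1) {
          repl[[as.character(jb)]] <- res
          n_after <- n_after + length(res) - 1L
        } else if (isTRUE(attr(res[[1]], "unsplittable"))) {
          # several individuals merged into one inseparable object: nobody
          # gets it; the involved individuals stay lost until they separate
          drop <- c(drop, jb)
        }
        if (n_after >= length(active)) break
      }
      if (length(repl) || length(drop)) {
        out <- list()
        for (j in seq_along(blobs)) {
          if (j %in% drop) next
          key <- as.character(j)
          if (!is.null(repl[[key]])) out <- c(out, repl[[key]])
          else out <- c(out, blobs[j])
        }
        ord <- if (length(out))
          order(vapply(out, function(b) b$bbox[2], numeric(1)),
                vapply(out, function(b) b$bbox[1], numeric(1))) else integer(0)
        blobs <- out[ord]
      }
    }
  }
  state$blobs[[fr + 1L]] <- blobs

  assigned_blob <- rep(FALSE, length(blobs))
  if (fr > 0L && length(active) > 0 && length(blobs) > 0) {
    nd <- if (is.na(nominal_dt)) t - prev_t else nominal_dt
    P <- matrix(0, length(active), length(blobs))
    for (i in seq_along(active))
      for (j in seq_along(blobs))
        P[i, j] <- match_probability(active[[i]], blobs[[j]], t, cfg, nd)
    cliques <- build_cliques(P, cfg$matching_probability_threshold)
    ts_gap <- !is.na(prev_t) && !is.na(nominal_dt) &&
      (t - prev_t) > 1.5 * nominal_dt
    for (cl in cliques) {
      res <- switch(cfg$matcher,
        tree = tree_match(cl$p, cfg$clique_node_cap),
        hungarian = hungarian_match(cl$p),
        approximate = greedy_match(cl$p))
      for (ii in seq_along(cl$tr)) {
        jj <- res$assignment[ii]
        if (is.na(jj)) next
        bj <- cl$bl[jj]
        if (assigned_blob[bj]) stopf("internal invariant violated: blob assigned twice")
        assigned_blob[bj] <- TRUE
        ind <- active[[cl$tr[ii]]]
        p <- cl$p[ii, jj]
        lost <- ind$frames[length(ind$frames)] < fr - 1L
        reason <- if (lost) "lost"
          else if (1 - p > 0.5) "uncertain"
          else if (ts_gap) "timestamp_gap"
          else NA_character_
        append_obs(ind, fr, t, blob_centroid(blobs[[bj]]), p, bj, reason)
      }
    }
  }

  # new identities for viable unmatched blobs
  free <- which(!assigned_blob)
  if (length(free)) {
    n_active <- sum(!vapply(state$individuals, function(i) i$retired, logical(1)))
    for (bj in free) {
      if (known && n_active >= cfg$track_max_individuals) break
      ind <- new_individual(length(state$individuals))
      append_obs(ind, fr, t, blob_centroid(blobs[[bj]]), 1, bj, NA_character_)
      state$individuals[[length(state$individuals) + 1L]] <- ind
      n_active <- n_active + 1L
      assigned_blob[bj] <- TRUE
    }
  }
  invisible(state)
}

#' Track a sequence of segmented frames
#'
#' Runs [advance_frame()] over per-frame blob lists and packages the result.
#'
#' @param blob_frames list (one entry per frame) of blob lists.
#' @param times frame timestamps in seconds.
#' @param config a [tracker_config()].
#' @param background optional background image (enables overlap splitting).
#' @param seg_threshold segmentation threshold used to produce the blobs.
#' @return object of class `btx_tracks`: `individuals` (each with `identity`,
#'   per-frame kinematics, and a `segments` data frame), the per-frame blob
#'   store, timestamps and the configuration.
#' @export
track_frames <- function(blob_frames, times, config = tracker_config(),
                         background = NULL, seg_threshold = 25) {
  if (length(blob_frames) != length(times))
    stopf("track_frames: blob_frames and times lengths differ")
  if (length(times) > 1 && any(diff(times) <= 0))
    stopf("track_frames: timestamps must be strictly increasing")
  st <- tracker_state(config, background, seg_threshold)
  for (i in seq_along(blob_frames)) advance_frame(st, blob_frames[[i]], times[i])
  finalize_tracks(st)
}

finalize_tracks <- function(state) {
  inds <- lapply(state$individuals, function(ind) {
    segs <- if (length(ind$seg_start)) {
      ends <- c(vapply(seq_along(ind$seg_start)[-1], function(k) {
        max(ind$frames[ind$frames < ind$seg_start[k]])
      }, numeric(1)), max(ind$frames))
      data.frame(start = ind$seg_start, end = as.integer(ends),
                 reason = ind$seg_reason, stringsAsFactors = FALSE)
    } else data.frame(start = integer(0), end = integer(0), reason = character(0))
    list(identity = ind$identity, frames = ind$frames, times = ind$times,
         x = ind$x, y = ind$y, heading = ind$heading, p = ind$p,
         blob_i = ind$blob_i, segments = segs, retired = ind$retired)
  })
  structure(list(individuals = inds, blobs = state$blobs,
                 times = state$times, config = state$config),
            class = "btx_tracks")
}

#' @export
print.btx_tracks <- function(x, ...) {
  cat(sprintf("<tracks: %d individuals over %d frames>\n",
              length(x$individuals), length(x$times)))
  invisible(x)
}

#' Flatten tracks to a per-frame table
#'
#' @param tracks a `btx_tracks`.
#' @return data frame with columns `frame`, `time`, `id`, `x`, `y`,
#'   `heading`, `p`, `blob_i`.
#' @export
tracks_table <- function(tracks) {
  do.call(rbind, lapply(tracks$individuals, function(ind) {
    if (!length(ind$frames)) return(NULL)
    data.frame(frame = ind$frames, time = ind$times, id = ind$identity,
               x = ind$x, y = ind$y, heading = ind$heading, p = ind$p,
               blob_i = ind$blob_i)
  }))
}
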