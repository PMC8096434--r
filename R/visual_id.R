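# Uniqueness-guided visual identification: preparing per-individual crops,
# carving trajectories into switch-free segments, selecting global segments
# for training, growing the training set by accumulation, and correcting
# tracker identities from classifier predictions.

#' Visual-identification parameters
#'
#' @param grid spatial-coverage grid resolution (cells along the width; the
#'   other axis is scaled by the arena aspect ratio).
#' @param keep_per_bin global-segment candidates kept per video quarter.
#' @param uniqueness_samples number of evenly spaced frames used to estimate
#'   mean uniqueness.
#' @param max_epochs training epoch cap per unit.
#' @param memory_budget bytes available for training images; together with
#'   the normalized crop size this yields `samples_max`.
#' @param median_window running-median window (frames) for switch detection.
#' @param min_images minimum images per individual for a usable training
#'   candidate.
#' @param min_claim_images minimum images a segment piece needs before its
#'   averaged prediction may claim an identity during assignment; shorter
#'   pieces are filled in by within-segment inheritance.
#' @param input_size backend input side length (crops are down-sampled to
#'   `input_size` x `input_size`).
#' @param seed seed for every stochastic component.
#' @return object of class `btx_id_config`.
#' @export
id_config <- function(grid = 10, keep_per_bin = 4, uniqueness_samples = 100,
                      max_epochs = 150, memory_budget = 1e9,
                      median_window = 25, min_images = 5,
                      min_claim_images = 25, input_size = 32,
                      seed = 1) {
  if (median_window %% 2 == 0) median_window <- median_window + 1L
  structure(list(grid = as.integer(grid), keep_per_bin = as.integer(keep_per_bin),
                 uniqueness_samples = as.integer(uniqueness_samples),
                 max_epochs = as.integer(max_epochs),
                 memory_budget = memory_budget,
                 median_window = as.integer(median_window),
                 min_images = as.integer(min_images),
                 min_claim_images = as.integer(min_claim_images),
                 input_size = as.integer(input_size), seed = as.integer(seed)),
            class = "btx_id_config")
}

#' Cut trajectories into switch-free consecutive segments
#'
#' Trajectories are split wherever the tracker flagged a problematic event:
#' the individual was lost for at least one frame, the assignment uncertainty
#' exceeded 50%, or timestamps suggest skipped frames.  Within a segment the
#' tracker is assumed never to have switched identities.
#'
#' @param tracks a `btx_tracks`.
#' @return list of segments `list(ind, identity, start, end, reason)`, class
#'   `btx_segments`; `ind` indexes `tracks$individuals`.
#' @export
split_into_segments <- function(tracks) {
  out <- list()
  for (i in seq_along(tracks$individuals)) {
    ind <- tracks$individuals[[i]]
    segs <- ind$segments
    for (k in seq_len(nrow(segs))) {
      out[[length(out) + 1]] <- list(ind = i, identity = ind$identity,
                                     start = segs$start[k], end = segs$end[k],
                                     reason = segs$reason[k])
    }
  }
  class(out) <- "btx_segments"
  out
}

#' Find global segments
#'
#' Maximal frame ranges in which exactly `N` individuals are tracked and each
#' stays within a single consecutive segment.  Only such ranges provide safe,
#' switch-free identity labels across all individuals simultaneously.
#'
#' @param segments a `btx_segments` (see [split_into_segments()]).
#' @param N expected number of individuals.
#' @param n_frames video length in frames.
#' @return list of `list(start, end, members)` where `members` is a data
#'   frame (`ind`, `seg`) of individual list-indices and their segment ids.
#' @export
find_global_segments <- function(segments, N, n_frames) {
  inds <- sort(unique(vapply(segments, function(s) s$ind, numeric(1))))
  cover <- matrix(NA_integer_, length(inds), n_frames)
  rownames(cover) <- inds
  for (si in seq_along(segments)) {
    s <- segments[[si]]
    r <- which(inds == s$ind)
    cover[r, (s$start:s$end) + 1L] <- si
  }
  n_present <- colSums(!is.na(cover))
  key <- apply(cover, 2, function(col) paste(col[!is.na(col)], collapse = ","))
  ok <- n_present == N
  out <- list()
  t <- 1L
  while (t <= n_frames) {
    if (!ok[t]) { t <- t + 1L; next }
    t2 <- t
    while (t2 + 1L <= n_frames && ok[t2 + 1L] && key[t2 + 1L] == key[t]) t2 <- t2 + 1L
    segids <- cover[, t][!is.na(cover[, t])]
    out[[length(out) + 1]] <- list(
      start = t - 1L, end = t2 - 1L,
      members = data.frame(ind = vapply(segments[segids], function(s) s$ind, numeric(1)),
                           seg = segids))
    t <- t2 + 1L
  }
  out
}

#' Quality metrics of a global segment
#'
#' Spatial coverage is the number of grid-cell transitions of an
#' individual's centre point; the minimum over individuals represents the
#' segment (a single stationary individual spoils it, by design).  A tight
#' circling path scores low even when the distance travelled is large.
#'
#' @param gs one global segment (see [find_global_segments()]).
#' @param tracks a `btx_tracks`.
#' @param width,height arena dimensions in pixels.
#' @param grid cells along the width; rows scale with the aspect ratio.
#' @param id_data optional [prepare_id_data()] result, used to count actual
#'   images per individual (else frames are counted).
#' @return `list(min_cells_visited, avg_samples)`.
#' @export
segment_quality <- function(gs, tracks, width, height, grid = 10, id_data = NULL) {
  nx <- grid
  ny <- max(1L, as.integer(round(grid * height / width)))
  cw <- width / nx; ch <- height / ny
  cells_v <- numeric(nrow(gs$members)); samples <- numeric(nrow(gs$members))
  for (k in seq_len(nrow(gs$members))) {
    ind <- tracks$individuals[[gs$members$ind[k]]]
    sel <- ind$frames >= gs$start & ind$frames <= gs$end
    cx <- pmin(floor(ind$x[sel] / cw), nx - 1)
    cy <- pmin(floor(ind$y[sel] / ch), ny - 1)
    cell <- cx + nx * cy
    cells_v[k] <- if (length(cell) > 1) sum(diff(cell) != 0) else 0
    samples[k] <- if (is.null(id_data)) sum(sel) else {
      sum(!is.na(id_data$rowmap[gs$members$ind[k], (gs$start:gs$end) + 1L]))
    }
  }
  list(min_cells_visited = min(cells_v), avg_samples = mean(samples))
}

#' Rank global-segment candidates
#'
#' Candidates are binned by their middle frame into video quarters; within a
#' bin they sort by spatial coverage (then average sample count), the best
#' `keep_per_bin` survive, and the output interleaves the bins round-robin
#' starting from the bin holding the best candidate overall -- spreading
#' training data across the whole video to limit auto-correlation.
#'
#' @param gss list of global segments.
#' @param qualities list of [segment_quality()] results, parallel to `gss`.
#' @param n_frames video length.
#' @param keep_per_bin candidates kept per quarter.
#' @return integer vector: indices into `gss` in consideration order.
#' @export
rank_global_segments <- function(gss, qualities, n_frames, keep_per_bin = 4) {
  if (!length(gss)) return(integer(0))
  mid <- vapply(gss, function(g) (g$start + g$end) / 2, numeric(1))
  bin <- pmin(1L + as.integer(floor(4 * mid / n_frames)), 4L)
  mc <- vapply(qualities, function(q) q$min_cells_visited, numeric(1))
  as_ <- vapply(qualities, function(q) q$avg_samples, numeric(1))
  kept <- lapply(1:4, function(b) {
    ix <- which(bin == b)
    ix <- ix[order(-mc[ix], -as_[ix], ix)]
    utils::head(ix, keep_per_bin)
  })
  best <- order(-mc, -as_)[1]
  b0 <- bin[best]
  bins <- ((b0 - 1 + 0:3) %% 4) + 1
  out <- integer(0)
  for (k in seq_len(keep_per_bin))
    for (b in bins)
      if (length(kept[[b]]) >= k) out <- c(out, kept[[b]][k])
  out
}

#' Prepare identification data: normalized crops for every assignment
#'
#' Runs posture estimation and pose normalization for every (individual,
#' frame) assignment in the tracks and stores the down-sampled feature rows
#' used by the classifier backend.
#'
#' @param tracks a `btx_tracks`.
#' @param width,height arena dimensions (px).
#' @param config an [id_config()].
#' @param posture_cfg a [posture_config()].
#' @return object of class `btx_id_data`: `features` (rows), `meta`
#'   (`ind`, `frame`), `rowmap` (ind x frame row lookup), `segments`,
#'   dimensions and configs.
#' @export
prepare_id_data <- function(tracks, width, height, config = id_config(),
                            posture_cfg = posture_config()) {
  n_frames <- length(tracks$times)
  n_inds <- length(tracks$individuals)
  rows <- list(); meta_ind <- integer(0); meta_frame <- integer(0)
  rowmap <- matrix(NA_integer_, n_inds, n_frames)
  for (i in seq_len(n_inds)) {
    ind <- tracks$individuals[[i]]
    for (k in seq_along(ind$frames)) {
      fr <- ind$frames[k]
      b <- tracks$blobs[[fr + 1L]][[ind$blob_i[k]]]
      feat <- tryCatch({
        po <- blob_posture(b, posture_cfg)
        crop_features(normalize_image(b, po$midline, posture_cfg),
                      config$input_size)
      }, error = function(e) NULL)
      if (is.null(feat)) next
      rows[[length(rows) + 1]] <- feat
      meta_ind <- c(meta_ind, i); meta_frame <- c(meta_frame, fr)
      rowmap[i, fr + 1L] <- length(rows)
    }
  }
  structure(list(features = do.call(rbind, rows),
                 meta = data.frame(ind = meta_ind, frame = meta_frame),
                 rowmap = rowmap,
                 segments = split_into_segments(tracks),
                 n_frames = n_frames, width = width, height = height,
                 config = config),
            class = "btx_id_data")
}

# non-linear rescaling of mean claimed probability (roughly +0.5 and a
# logistic stretch); maps [0,1] -> ((1+e^-pi)/(1+e^0), 1] with E(1) = 1
E_scale <- function(v) (1 + exp(-pi)) / (1 + exp(-pi * v))

#' Logistic rescaling used in contested-identity scoring
#'
#' `sig(x) = (1 + e^(2 pi (0.5 - x)))^-1`; `sig(0.5) = 0.5`, steep around
#' the midpoint, exaggerating differences between low values and damping
#' differences between high ones.
#'
#' @param x numeric vector.
#' @return rescaled values in (0, 1).
#' @export
sig_scale <- function(x) 1 / (1 + exp(2 * pi * (0.5 - x)))

#' Contested-identity score of a segment
#'
#' `S(p, x) = sig(p) + sig(n_own / (n_own + n_other))`: the average claimed
#' probability and the relative sample count both count, so a long segment
#' with slightly weaker probabilities outranks a short noisy one.
#'
#' @param p average probability of the contested identity in this segment.
#' @param n_own,n_other image counts of this and the competing segment.
#' @return the score (larger wins).
#' @export
eq2_score <- function(p, n_own, n_other) {
  sig_scale(p) + sig_scale(n_own / (n_own + n_other))
}

#' Epoch cap of the final training unit
#'
#' @param max_epochs configured epoch budget.
#' @return `max(3, floor(0.25 * max_epochs))`.
#' @export
final_epoch_cap <- function(max_epochs) max(3L, as.integer(floor(0.25 * max_epochs)))

#' Uniqueness of one frame's identity predictions
#'
#' Every tracked object claims its argmax identity; collisions shrink the
#' unique fraction `|uids| / n_objects`, and weak predictions shrink the
#' rescaled mean claimed probability.  The score is their product:
#' `(|uids| / n) * E(mean(uids))` with `E(v) = (1+e^-pi)/(1+e^-pi v)`.
#' It equals 1 exactly when all argmaxes are distinct with probability 1.
#'
#' @param P probability matrix, one row per tracked object in the frame.
#' @return score in `[0, 1]`.
#' @export
frame_uniqueness <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) == 0) stopf("frame_uniqueness: empty frame")
  maxid <- max.col(P, ties.method = "first")
  pmax_ <- P[cbind(seq_len(nrow(P)), maxid)]
  uids <- tapply(pmax_, maxid, max)
  (length(uids) / nrow(P)) * E_scale(mean(uids))
}

#' Mean uniqueness over evenly spaced frames
#'
#' @param backend a fitted classifier backend.
#' @param id_data a [prepare_id_data()] result.
#' @param frames 0-based frames to score (default: `uniqueness_samples`
#'   evenly spaced frames that contain tracked images).
#' @return `list(frames, uniqueness, mean, valley_threshold, valleys)`;
#'   valleys are frames scoring below `1 - 0.5/N`.
#' @export
average_uniqueness <- function(backend, id_data, frames = NULL) {
  N <- backend$n_classes
  have <- sort(unique(id_data$meta$frame))
  if (is.null(frames)) {
    ns <- min(id_data$config$uniqueness_samples, length(have))
    frames <- have[unique(round(seq(1, length(have), length.out = ns)))]
  }
  u <- rep(NA_real_, length(frames))
  for (k in seq_along(frames)) {
    rws <- id_data$rowmap[, frames[k] + 1L]
    rws <- rws[!is.na(rws)]
    if (!length(rws)) next
    u[k] <- frame_uniqueness(backend$predict(
      id_data$features[rws, , drop = FALSE]))
  }
  keep <- !is.na(u)
  thr <- 1 - 0.5 / N
  list(frames = frames[keep], uniqueness = u[keep], mean = mean(u[keep]),
       valley_threshold = thr, valleys = frames[keep][u[keep] < thr])
}

# evenly spaced deterministic down-sample of indices
take_evenly <- function(ix, k) {
  if (length(ix) <= k) return(ix)
  ix[unique(round(seq(1, length(ix), length.out = k)))]
}

#' Train the initial identification unit
#'
#' Tries ranked global-segment candidates in order: a candidate is usable
#' when every individual contributes at least `min_images` crops.  Classes
#' are balanced by down-sampling to about 1.2x the smallest class, split 4:1
#' into training and validation, and fitted with the focal-loss backend.
#' The individuals of the accepted segment define the global identity
#' labels.  If the fitted model barely beats chance the candidate (and
#' finally the whole attempt) is marked failed -- visually identical
#' individuals are reported, never silently shuffled.
#'
#' @param candidates indices into `gss` in consideration order.
#' @param gss global segments.
#' @param id_data a [prepare_id_data()] result.
#' @param backend a classifier backend (e.g. [backend_linear()]).
#' @param config an [id_config()].
#' @return an accumulation state (class `btx_accum`), possibly with
#'   `$failed = TRUE`.
#' @export
train_initial <- function(candidates, gss, id_data, backend, config = id_config()) {
  st <- new.env(parent = emptyenv())
  st$backend <- backend; st$id_data <- id_data; st$config <- config
  st$N <- backend$n_classes
  st$gss <- gss
  st$status <- rep("untried", length(gss))
  st$failed <- TRUE
  st$step <- 0L
  st$u_hist <- numeric(0)
  bytes_per_crop <- 80 * 80 * 8
  st$samples_max <- max(1000, floor(config$memory_budget / bytes_per_crop))
  for (ci in candidates) {
    gs <- gss[[ci]]
    rows_by_class <- lapply(seq_len(nrow(gs$members)), function(k) {
      r <- id_data$rowmap[gs$members$ind[k], (gs$start:gs$end) + 1L]
      r[!is.na(r)]
    })
    if (any(vapply(rows_by_class, length, numeric(1)) < config$min_images)) {
      st$status[ci] <- "rejected"; next
    }
    target <- min(vapply(rows_by_class, length, numeric(1)))
    cap <- ceiling(1.2 * target)
    rows_by_class <- lapply(rows_by_class, take_evenly, k = cap)
    rows <- unlist(rows_by_class)
    cls <- rep(seq_len(nrow(gs$members)) - 1L,
               vapply(rows_by_class, length, numeric(1)))
    fit <- backend$fit(id_data$features[rows, , drop = FALSE], cls,
                       max_epochs = config$max_epochs)
    if (fit$val_acc < 0.5 + 0.5 / st$N) { st$status[ci] <- "failed"; next }
    st$class_map <- stats::setNames(seq_len(nrow(gs$members)) - 1L,
                                    gs$members$ind)
    st$training <- data.frame(row = rows, class = cls, gs = ci)
    st$status[ci] <- "initial"
    st$initial_fit <- fit
    un <- average_uniqueness(backend, id_data)
    st$best_uniqueness <- un$mean
    st$U_prev <- un$mean
    st$best_state <- backend$get_state()
    st$failed <- FALSE
    break
  }
  class(st) <- "btx_accum"
  st
}

# mean uniqueness of a model over the frames of one global segment
segment_uniqueness <- function(st, gs, max_frames = 30) {
  fr <- take_evenly(gs$start:gs$end, max_frames)
  mean(average_uniqueness(st$backend, st$id_data, frames = fr)$uniqueness)
}

#' One accumulation step
#'
#' Re-scores untried candidates by (uniqueness rounded to 5% steps,
#' ascending -- valleys first; distance to trained regions rounded down to a
#' power of two, descending; spatial coverage and sample count, descending),
#' disqualifies candidates below half the previous best uniqueness after
#' five steps, and tries the best one: its identities are predicted with the
#' current model and accepted only when unique across individuals
#' (plausibility); the new samples are merged with stride-sub-sampled prior
#' segments and the model retrained.  The new model is kept only if mean
#' uniqueness stays within 99% of the best; otherwise the best snapshot is
#' restored and the candidate marked rejected.
#'
#' @param st accumulation state from [train_initial()].
#' @param qualities per-candidate [segment_quality()] list (parallel to the
#'   global segment list).
#' @return the state, invisibly; `st$exhausted` becomes `TRUE` when no
#'   viable candidate remains.
#' @export
accumulation_step <- function(st, qualities) {
  st$step <- st$step + 1L
  cand <- which(st$status %in% c("untried", "failed"))
  if (!length(cand)) { st$exhausted <- TRUE; return(invisible(st)) }
  u_c <- vapply(cand, function(ci) segment_uniqueness(st, st$gss[[ci]]), numeric(1))
  if (st$step > 5L) {
    dq <- u_c < st$U_prev / 2
    if (any(dq)) {
      st$status[cand[dq]] <- "disqualified"
      cand <- cand[!dq]; u_c <- u_c[!dq]
      if (!length(cand)) { st$exhausted <- TRUE; return(invisible(st)) }
    }
  }
  trained <- sort(unique(st$id_data$meta$frame[st$training$row]))
  mids <- vapply(cand, function(ci) (st$gss[[ci]]$start + st$gss[[ci]]$end) / 2,
                 numeric(1))
  dist2 <- vapply(mids, function(m) {
    d <- min(abs(trained - m)); 2^floor(log2(max(d, 1)))
  }, numeric(1))
  u_r <- round(u_c * 20) / 20
  mc <- vapply(cand, function(ci) qualities[[ci]]$min_cells_visited, numeric(1))
  as_ <- vapply(cand, function(ci) qualities[[ci]]$avg_samples, numeric(1))
  # candidates that already failed plausibility re-enter the queue behind
  # the untried ones
  was_failed <- st$status[cand] == "failed"
  ord <- order(was_failed, u_r, -dist2, -mc, -as_, cand)
  ci <- cand[ord[1]]
  gs <- st$gss[[ci]]
  # plausibility: predicted identities must be unique across individuals
  pred <- integer(nrow(gs$members)); rows_by_member <- list()
  for (k in seq_len(nrow(gs$members))) {
    r <- st$id_data$rowmap[gs$members$ind[k], (gs$start:gs$end) + 1L]
    r <- r[!is.na(r)]
    rows_by_member[[k]] <- r
    if (!length(r)) { pred[k] <- NA_integer_; next }
    P <- st$backend$predict(st$id_data$features[r, , drop = FALSE])
    pred[k] <- which.max(colMeans(P)) - 1L
  }
  if (anyNA(pred) || anyDuplicated(pred)) {
    st$status[ci] <- "failed"
    return(invisible(st))
  }
  # merge: new segment in full, prior segments sub-sampled by stride
  new_rows <- unlist(rows_by_member)
  new_cls <- rep(pred, vapply(rows_by_member, length, numeric(1)))
  prior <- st$training
  added_gs <- unique(prior$gs)
  total_frames <- sum(vapply(added_gs, function(g)
    st$gss[[g]]$end - st$gss[[g]]$start + 1L, numeric(1)))
  keep <- unlist(lapply(added_gs, function(g) {
    sel <- which(prior$gs == g)
    RS <- length(sel)
    Rlen <- st$gss[[g]]$end - st$gss[[g]]$start + 1L
    quota <- st$samples_max * Rlen / max(total_frames, 1)
    k <- max(1L, ceiling(RS / max(quota, 1)))
    sel[seq(1, RS, by = k)]
  }))
  X <- rbind(st$id_data$features[prior$row[keep], , drop = FALSE],
             st$id_data$features[new_rows, , drop = FALSE])
  y <- c(prior$class[keep], new_cls)
  st$backend$fit(X, y, max_epochs = st$config$max_epochs, reset = FALSE)
  un <- average_uniqueness(st$backend, st$id_data)
  st$U_prev <- st$best_uniqueness
  st$u_hist <- c(st$u_hist, un$mean)
  if (un$mean >= 0.99 * st$best_uniqueness) {
    st$status[ci] <- "added"
    st$training <- rbind(prior,
                         data.frame(row = new_rows, class = new_cls, gs = ci))
    if (un$mean > st$best_uniqueness) {
      st$best_uniqueness <- un$mean
      st$best_state <- st$backend$get_state()
    }
  } else {
    st$backend$set_state(st$best_state)
    st$status[ci] <- "rejected"
  }
  invisible(st)
}

#' Check the global stopping criteria
#'
#' Training is done when (i) for every identity the frames not covered by
#' trained-on segments amount to less than 25% of the video, or (ii) mean
#' uniqueness exceeds `1 - 0.5/N` (nearly every identity present exactly
#' once per frame).
#'
#' @param st accumulation state.
#' @return `list(done, reason)`.
#' @export
check_stopping <- function(st) {
  N <- st$N
  if (st$best_uniqueness > 1 - 0.5 / N)
    return(list(done = TRUE, reason = "uniqueness"))
  nf <- st$id_data$n_frames
  covered <- vapply(0:(N - 1L), function(cl) {
    length(unique(st$id_data$meta$frame[st$training$row[st$training$class == cl]]))
  }, numeric(1))
  if (all(nf - covered < 0.25 * nf))
    return(list(done = TRUE, reason = "coverage"))
  list(done = FALSE, reason = "continue")
}

#' Final training unit
#'
#' One last fit on the merged dataset (no held-out validation), sub-sampled
#' under the memory budget, for at most `max(3, 0.25 * max_epochs)` epochs.
#' The result is kept only if mean uniqueness improves.
#'
#' @param st accumulation state.
#' @return the state, invisibly.
#' @export
train_final <- function(st) {
  rows <- take_evenly(seq_len(nrow(st$training)), st$samples_max)
  ep <- final_epoch_cap(st$config$max_epochs)
  st$backend$fit(st$id_data$features[st$training$row[rows], , drop = FALSE],
                 st$training$class[rows], max_epochs = ep,
                 validation_split = 0, reset = FALSE)
  un <- average_uniqueness(st$backend, st$id_data)
  if (un$mean > st$best_uniqueness) {
    st$best_uniqueness <- un$mean
    st$best_state <- st$backend$get_state()
  } else {
    st$backend$set_state(st$best_state)
  }
  invisible(st)
}

#' Detect and split mid-segment identity switches
#'
#' A running-window median over the framewise argmax identities; when the
#' median changes to a value that persists for at least `window` frames the
#' segment is split at the first change point.
#'
#' @param pred integer vector of framewise argmax identities.
#' @param window odd window length in frames.
#' @return list of index ranges (`list(from, to)`) partitioning `seq_along(pred)`.
#' @export
correct_switches <- function(pred, window = 25) {
  n <- length(pred)
  if (n < 2 * window) return(list(list(from = 1L, to = n)))
  med <- as.vector(stats::runmed(pred, k = window, endrule = "constant"))
  r <- rle(med)
  persistent <- r$lengths >= window
  if (sum(persistent) <= 1) return(list(list(from = 1L, to = n)))
  bounds <- cumsum(r$lengths)
  cuts <- integer(0)
  last_val <- NULL
  pos <- 0L
  for (k in seq_along(r$lengths)) {
    if (persistent[k]) {
      if (!is.null(last_val) && r$values[k] != last_val)
        cuts <- c(cuts, pos + 1L)
      last_val <- r$values[k]
    }
    pos <- bounds[k]
  }
  if (!length(cuts)) return(list(list(from = 1L, to = n)))
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, n)
  mapply(function(f, t) list(from = f, to = t), starts, ends,
         SIMPLIFY = FALSE)
}

#' Assign final identities to segments from classifier predictions
#'
#' Every consecutive segment's images are predicted and averaged into
#' `P(i|S)`; segments first pass through [correct_switches()].  When
#' temporally overlapping segments claim the same identity, the ratio of
#' their maximal probabilities (inverted into (0,1]) decides: above 0.6 the
#' conflict is ambiguous and resolution is deferred to the kinematic
#' tracker; otherwise the segment with the larger
#' `S(p, x) = sig(p) + sig(x / (N_me + N_he))`,
#' `sig(x) = (1 + e^(2 pi (0.5 - x)))^-1`, wins -- preferring segments with
#' many samples.  Segments without a usable prediction inherit the identity
#' of the temporally nearest assigned segment of the same tracker
#' individual, and keep their tracker identity otherwise.
#'
#' @param st accumulation state (trained).
#' @param tracks the `btx_tracks` the identification ran on.
#' @return `list(table, report)`: a per-frame corrected table (`frame`,
#'   `time`, `id`, `tracker_id`, `x`, `y`) where `id` is the final class (or
#'   `1000 + ind` for unassigned segments), and a per-segment report.
#' @export
assign_identities <- function(st, tracks) {
  idd <- st$id_data
  segs <- idd$segments
  win <- st$config$median_window
  # per (sub)segment average prediction vectors
  pieces <- list()
  for (si in seq_along(segs)) {
    s <- segs[[si]]
    fr <- s$start:s$end
    rws <- idd$rowmap[s$ind, fr + 1L]
    ok <- !is.na(rws)
    if (!any(ok)) {
      pieces[[length(pieces) + 1]] <- list(ind = s$ind, seg = si,
                                           start = s$start, end = s$end,
                                           P = NULL, n = 0)
      next
    }
    P <- st$backend$predict(idd$features[rws[ok], , drop = FALSE])
    pred <- max.col(P, ties.method = "first") - 1L
    parts <- correct_switches(pred, win)
    okfr <- fr[ok]
    for (pp in parts) {
      sel <- pp$from:pp$to
      pieces[[length(pieces) + 1]] <- list(
        ind = s$ind, seg = si, start = okfr[pp$from], end = okfr[pp$to],
        P = colMeans(P[sel, , drop = FALSE]), n = length(sel))
    }
  }
  np <- length(pieces)
  # pieces with too few images do not claim identities themselves: an
  # averaged vector over a handful of crossing-contaminated frames is noise,
  # and one such claim can defer a long correct piece via the ratio rule.
  # They are filled in by inheritance afterwards.
  min_claim <- st$config$min_claim_images %||% st$config$min_images
  claim <- vapply(pieces, function(p) {
    if (is.null(p$P) || p$n < min_claim) NA_integer_
    else which.max(p$P) - 1L
  }, integer(1))
  assigned <- rep(NA_integer_, np)
  resolution <- rep("unassigned", np)
  for (cl in sort(unique(claim[!is.na(claim)]))) {
    cs <- which(claim == cl)
    # group temporally overlapping claimants
    ord <- cs[order(vapply(pieces[cs], function(p) p$start, numeric(1)))]
    grp <- list(); cur <- ord[1]; cur_end <- pieces[[ord[1]]]$end
    for (k in ord[-1]) {
      if (pieces[[k]]$start <= cur_end) {
        cur <- c(cur, k); cur_end <- max(cur_end, pieces[[k]]$end)
      } else {
        grp[[length(grp) + 1]] <- cur; cur <- k; cur_end <- pieces[[k]]$end
      }
    }
    grp[[length(grp) + 1]] <- cur
    for (g in grp) {
      if (length(g) == 1) {
        assigned[g] <- cl; resolution[g] <- "unambiguous"; next
      }
      pmaxs <- vapply(pieces[g], function(p) p$P[cl + 1L], numeric(1))
      rat <- outer(pmaxs, pmaxs, function(a, b) pmin(a / b, b / a))
      ambiguous <- any(rat[upper.tri(rat)] > 0.6)
      if (ambiguous) { resolution[g] <- "deferred"; next }
      # pairwise tournament by S(p, x), preferring larger sample counts
      winner <- g[1]
      for (k in g[-1]) {
        nme <- pieces[[winner]]$n; nhe <- pieces[[k]]$n
        Sme <- eq2_score(pieces[[winner]]$P[cl + 1L], nme, nhe)
        She <- eq2_score(pieces[[k]]$P[cl + 1L], nhe, nme)
        if (She > Sme || (She == Sme && (nhe > nme ||
            (nhe == nme && pieces[[k]]$start < pieces[[winner]]$start))))
          winner <- k
      }
      assigned[winner] <- cl; resolution[winner] <- "eq2"
      resolution[setdiff(g, winner)] <- "deferred"
    }
  }
  # deferred / unassigned pieces inherit from the nearest assigned piece of
  # the same consecutive segment; inheriting across segment boundaries
  # (lost / uncertain / timestamp gaps) would cross exactly the events where
  # switches happen.  Pieces too short to claim for themselves may inherit
  # across boundaries from their tracker individual -- the possible damage is
  # bounded by their few frames, whereas leaving them as singleton labels
  # distorts any global identity matching of the output.
  seg_of <- vapply(pieces, function(p) p$seg, numeric(1))
  ind_of <- vapply(pieces, function(p) p$ind, numeric(1))
  nearest <- function(k, pool) {
    d <- vapply(pool, function(j) {
      max(0, pieces[[j]]$start - pieces[[k]]$end,
          pieces[[k]]$start - pieces[[j]]$end)
    }, numeric(1))
    pool[which.min(d)]
  }
  for (k in which(is.na(assigned))) {
    pool <- which(!is.na(assigned) & seg_of == seg_of[k])
    if (!length(pool)) next
    j <- nearest(k, pool)
    assigned[k] <- assigned[j]
    if (resolution[k] == "unassigned") resolution[k] <- "inherited"
    else resolution[k] <- paste0(resolution[k], "+inherited")
  }
  # corrected per-frame table
  tabs <- list()
  for (k in seq_len(np)) {
    p <- pieces[[k]]
    if (is.na(assigned[k]) && p$n < min_claim) next  # unresolvable fragment
    ind <- tracks$individuals[[p$ind]]
    sel <- ind$frames >= p$start & ind$frames <= p$end
    if (!any(sel)) next
    fid <- if (!is.na(assigned[k])) assigned[k] else 1000L + p$ind
    tabs[[length(tabs) + 1]] <- data.frame(
      frame = ind$frames[sel], time = ind$times[sel], id = fid,
      tracker_id = ind$identity, x = ind$x[sel], y = ind$y[sel])
  }
  report <- data.frame(
    ind = vapply(pieces, function(p) p$ind, numeric(1)),
    start = vapply(pieces, function(p) p$start, numeric(1)),
    end = vapply(pieces, function(p) p$end, numeric(1)),
    n_images = vapply(pieces, function(p) p$n, numeric(1)),
    class = assigned, resolution = resolution)
  list(table = do.call(rbind, tabs), report = report)
}

#' Run the full visual-identification pipeline
#'
#' Orchestrates crop preparation, segment construction, candidate ranking,
#' initial training, accumulation with stopping rules, the final training
#' unit and identity assignment.
#'
#' @param tracks a `btx_tracks`.
#' @param width,height arena dimensions (px).
#' @param N number of real individuals.
#' @param config an [id_config()].
#' @param posture_cfg a [posture_config()].
#' @param backend optional pre-built backend (default [backend_linear()]).
#' @param max_steps accumulation step budget.
#' @return object of class `btx_visual_id`: `status` (`"ok"` or
#'   `"failed"`), corrected `table`, per-segment `report`, `uniqueness`
#'   history, per-candidate `segment_status`, and the trained backend.
#' @export
run_visual_id <- function(tracks, width, height, N, config = id_config(),
                          posture_cfg = posture_config(), backend = NULL,
                          max_steps = 20) {
  idd <- prepare_id_data(tracks, width, height, config, posture_cfg)
  gss <- find_global_segments(idd$segments, N, idd$n_frames)
  if (!length(gss))
    return(structure(list(status = "failed", reason = "no_global_segments"),
                     class = "btx_visual_id"))
  qualities <- lapply(gss, segment_quality, tracks = tracks, width = width,
                      height = height, grid = config$grid, id_data = idd)
  cand <- rank_global_segments(gss, qualities, idd$n_frames, config$keep_per_bin)
  if (is.null(backend))
    backend <- backend_linear(N, input_size = config$input_size,
                              seed = config$seed)
  st <- train_initial(cand, gss, idd, backend, config)
  if (st$failed)
    return(structure(list(status = "failed", reason = "initial_training",
                          state = st), class = "btx_visual_id"))
  steps <- 0L
  while (!check_stopping(st)$done && steps < max_steps) {
    accumulation_step(st, qualities)
    if (isTRUE(st$exhausted)) break
    steps <- steps + 1L
  }
  train_final(st)
  asg <- assign_identities(st, tracks)
  structure(list(status = "ok", table = asg$table, report = asg$report,
                 uniqueness = st$best_uniqueness, u_hist = st$u_hist,
                 stopping = check_stopping(st),
                 segment_status = st$status, state = st, backend = backend),
            class = "btx_visual_id")
}

#' @export
print.btx_visual_id <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("<visual id: FAILED (%s)>\n", x$reason))
  } else {
    cat(sprintf("<visual id: mean uniqueness %.3f, %d segments>\n",
                x$uniqueness, nrow(x$report)))
  }
  invisible(x)
}
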