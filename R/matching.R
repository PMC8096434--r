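# Frame-to-frame data association: motion prediction, assignment
# probabilities, clique construction, and three matchers (exact tree search,
# Hungarian, greedy).

#' Maximum-weight bipartite assignment (Hungarian method)
#'
#' Solves the rectangular assignment problem for a non-negative weight
#' matrix using the Kuhn-Munkres algorithm with potentials (O(n^3)).  The
#' matrix is padded to square with zero weights, so rows may effectively stay
#' unassigned; an assignment to a zero-weight column is reported as `NA`.
#'
#' @param w numeric matrix of non-negative weights (rows: trajectories,
#'   columns: candidate objects; 0 encodes a missing edge).
#' @return integer vector of length `nrow(w)`: for each row the assigned
#'   column, or `NA` for no (zero-weight) assignment.
#' @export
lsap_max <- function(w) {
  w <- as.matrix(w)
  if (any(w < 0)) stopf("lsap_max expects non-negative weights")
  n <- nrow(w); m <- ncol(w)
  if (n == 0) return(integer(0))
  k <- max(n, m)
  cost <- matrix(0, k, k)
  cost[seq_len(n), seq_len(m)] <- max(w) - w
  # shortest augmenting paths with potentials; indices offset by +1 so that
  # the virtual column 0 lives at position 1
  INF <- Inf
  u <- numeric(k + 1); v <- numeric(k + 1)
  p <- integer(k + 1); way <- integer(k + 1)
  for (i in seq_len(k)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(INF, k + 1); used <- rep(FALSE, k + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      js <- which(!used[2:(k + 1)])
      if (length(js)) {
        cur <- cost[i0, js] - u[i0 + 1] - v[js + 1]
        upd <- cur < minv[js + 1]
        minv[js[upd] + 1] <- cur[upd]
        way[js[upd] + 1] <- j0
        jmin <- js[which.min(minv[js + 1])]
        delta <- minv[jmin + 1]; j1 <- jmin
      }
      idx <- which(used)
      u[p[idx] + 1] <- u[p[idx] + 1] + delta
      v[idx] <- v[idx] - delta
      nidx <- which(!used)
      minv[nidx] <- minv[nidx] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- rep(NA_integer_, n)
  for (j in seq_len(k)) {
    i <- p[j + 1]
    if (i >= 1 && i <= n && j <= m && w[i, j] > 0) ans[i] <- j
  }
  ans
}

#' Optimal assignment within a clique by Hungarian matching
#'
#' Returns the same optimum as [tree_match()] (guaranteed by the assignment
#' LP); used as the fallback when the tree search exceeds its node budget.
#'
#' @param p probability matrix (rows: trajectories, cols: blobs; 0 = no edge).
#' @return `list(assignment, total)`; `assignment[i]` is the blob column for
#'   trajectory row `i` or `NA`.
#' @export
hungarian_match <- function(p) {
  p <- as.matrix(p)
  asg <- lsap_max(p)
  tot <- sum(p[cbind(which(!is.na(asg)), asg[!is.na(asg)])])
  list(assignment = asg, total = tot, method = "hungarian")
}

#' Exact assignment by depth-first tree search with branch-and-bound
#'
#' Explores conflict-free partial assignments of trajectories to blobs,
#' maximising the probability sum.  Trajectories are visited in order of
#' their best edge (descending, ties towards the lower row index); at each
#' node candidate blobs are tried best-first, with "leave unassigned" (zero
#' contribution) as the final branch.  An optimistic bound (sum of the best
#' remaining edges) prunes the search.  If more than `node_cap` nodes are
#' explored, the search aborts and signals that the caller should fall back
#' on [hungarian_match()].
#'
#' @inheritParams hungarian_match
#' @param node_cap maximum number of explored nodes before giving up.
#' @return `list(assignment, total, nodes, fallback)`; when `fallback` is
#'   `TRUE` the assignment fields are from [hungarian_match()].
#' @export
tree_match <- function(p, node_cap = 1e5) {
  p <- as.matrix(p)
  n <- nrow(p); m <- ncol(p)
  if (n == 0) return(list(assignment = integer(0), total = 0,
                          nodes = 0L, fallback = FALSE, method = "tree"))
  best_edge <- apply(p, 1, max)
  ord <- order(-best_edge, seq_len(n))
  suffix <- rev(cumsum(rev(best_edge[ord])))
  suffix <- c(suffix, 0)
  env <- new.env()
  env$best_total <- -1
  env$best_asg <- rep(NA_integer_, n)
  env$nodes <- 0L
  env$overflow <- FALSE
  used <- rep(FALSE, m)
  cur <- rep(NA_integer_, n)
  dfs <- function(d, total) {
    if (env$overflow) return()
    env$nodes <- env$nodes + 1L
    if (env$nodes > node_cap) { env$overflow <- TRUE; return() }
    if (d > n) {
      if (total > env$best_total + 1e-15) {
        env$best_total <- total
        env$best_asg <- cur
      }
      return()
    }
    if (total + suffix[d] <= env$best_total + 1e-15) return()
    i <- ord[d]
    cand <- which(p[i, ] > 0 & !used)
    if (length(cand)) cand <- cand[order(-p[i, cand], cand)]
    for (b in cand) {
      used[b] <<- TRUE; cur[i] <<- b
      dfs(d + 1, total + p[i, b])
      used[b] <<- FALSE; cur[i] <<- NA_integer_
    }
    dfs(d + 1, total)   # leave trajectory i unassigned
  }
  dfs(1, 0)
  if (env$overflow) {
    res <- hungarian_match(p)
    return(list(assignment = res$assignment, total = res$total,
                nodes = env$nodes, fallback = TRUE, method = "hungarian"))
  }
  list(assignment = env$best_asg, total = env$best_total,
       nodes = env$nodes, fallback = FALSE, method = "tree")
}

#' Greedy approximate assignment
#'
#' Processes blobs in their given (top-left to bottom-right) order; each blob
#' takes the highest-probability trajectory still available, without
#' backtracking.  The result can be suboptimal but never exceeds the optimum.
#'
#' @inheritParams hungarian_match
#' @return `list(assignment, total)` as in [hungarian_match()].
#' @export
greedy_match <- function(p) {
  p <- as.matrix(p)
  n <- nrow(p); m <- ncol(p)
  asg <- rep(NA_integer_, n)
  taken <- rep(FALSE, n)
  for (b in seq_len(m)) {
    avail <- which(!taken & p[, b] > 0)
    if (!length(avail)) next
    i <- avail[which.max(p[avail, b])]
    asg[i] <- b; taken[i] <- TRUE
  }
  tot <- sum(p[cbind(which(!is.na(asg)), asg[!is.na(asg)])])
  list(assignment = asg, total = tot, method = "greedy")
}

#' Decompose the probability matrix into local cliques
#'
#' Edges at or below the matching probability threshold are dropped; the
#' remaining bipartite graph is split into connected components.  Each clique
#' can then be matched independently.
#'
#' @param P full probability matrix (rows: trajectories, cols: blobs).
#' @param threshold matching probability threshold; edges must exceed it.
#' @return list of cliques, each `list(tr, bl, p)` with the row/column
#'   indices into `P` and the probability sub-matrix.  Trajectories and blobs
#'   with no surviving edge appear in no clique.
#' @export
build_cliques <- function(P, threshold) {
  P <- as.matrix(P)
  n <- nrow(P); m <- ncol(P)
  A <- P > threshold
  if (!any(A)) return(list())
  # union-find over n trajectories + m blobs
  parent <- seq_len(n + m)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  idx <- which(A, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    a <- find(idx[k, 1]); b <- find(n + idx[k, 2])
    if (a != b) parent[a] <- b
  }
  tr_root <- vapply(seq_len(n), find, integer(1))
  bl_root <- vapply(n + seq_len(m), find, integer(1))
  has_tr <- apply(A, 1, any); has_bl <- apply(A, 2, any)
  roots <- unique(tr_root[has_tr])
  lapply(roots, function(r) {
    tr <- which(tr_root == r & has_tr)
    bl <- which(bl_root == r & has_bl)
    sub <- P[tr, bl, drop = FALSE]
    sub[sub <= threshold] <- 0
    list(tr = tr, bl = bl, p = sub)
  })
}

#' Predict an individual's next position and heading
#'
#' Extrapolates with an exponentially weighted mean of the most recent (up to
#' five) velocities, with a half-life of two frames, rotated by the mean
#' angular speed over the same window -- a light-weight stand-in for a Kalman
#' prediction step.  With a single observation the prediction is the last
#' position.
#'
#' @param ind an individual (see [track_frames()]), or any list with numeric
#'   vectors `times`, `x`, `y`, `heading` of past assignments.
#' @param t prediction time (seconds).
#' @return `list(x, y, heading)`.
#' @export
predict_state <- function(ind, t) {
  k <- length(ind$times)
  if (k == 0) stopf("predict_state: individual has no history")
  last <- c(ind$x[k], ind$y[k])
  if (k == 1)
    return(list(x = last[1], y = last[2], heading = ind$heading[k]))
  take <- max(1, k - 5):k
  ts <- ind$times[take]; xs <- ind$x[take]; ys <- ind$y[take]; hs <- ind$heading[take]
  dt <- diff(ts)
  dt[dt <= 0] <- min(dt[dt > 0], 1e-3)
  vx <- diff(xs) / dt; vy <- diff(ys) / dt
  w <- diff(hs); w <- wrap_angle(w) / dt
  # weights by age in frames (most recent velocity has age 0), half-life 2
  nominal <- stats::median(dt)
  age <- rev(seq_along(vx)) - 1
  wt <- 0.5^(age / 2)
  vbar <- c(sum(vx * wt), sum(vy * wt)) / sum(wt)
  wbar <- sum(w * wt) / sum(wt)
  dtp <- t - ts[length(ts)]
  rot <- wbar * dtp
  R <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2, 2)
  vrot <- R %*% vbar
  list(x = last[1] + vrot[1] * dtp, y = last[2] + vrot[2] * dtp,
       heading = wrap_angle(ind$heading[k] + wbar * dtp))
}

#' Probability that a blob continues an individual's trajectory
#'
#' A Gaussian kernel on the prediction error with a hard search radius:
#' `p = exp(-d^2 / (2 sigma^2)) * g` with `sigma = track_max_speed * dt / 3`,
#' zero beyond `track_max_speed * dt`, and a time-gap decay
#' `g = 0.5^(gap / max_reassign_time)` where the gap is the time since the
#' last assignment in excess of one nominal frame interval.
#'
#' @param ind individual with history (see [predict_state()]).
#' @param blob a blob (uses its centroid), or `c(x, y)`.
#' @param t current time (seconds).
#' @param config a [tracker_config()].
#' @param nominal_dt typical frame interval (seconds).
#' @return probability in `[0, 1]`.
#' @export
match_probability <- function(ind, blob, t, config, nominal_dt) {
  pred <- predict_state(ind, t)
  cen <- if (inherits(blob, "btx_blob")) blob_centroid(blob) else blob
  k <- length(ind$times)
  dt <- t - ind$times[k]
  if (dt <= 0) return(0)
  d <- sqrt((pred$x - cen[1])^2 + (pred$y - cen[2])^2)
  radius <- config$track_max_speed * dt
  if (d > radius) return(0)
  sigma <- radius / 3
  gap <- max(0, dt - nominal_dt)
  g <- 0.5^(gap / config$max_reassign_time)
  exp(-d^2 / (2 * sigma^2)) * g
}
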