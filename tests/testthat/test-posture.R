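test_that("corner tracing yields exact unit-square outlines and areas", {
  m <- matrix(FALSE, 8, 8); m[6, 4] <- TRUE    # pixel (x=3, y=5)
  o <- trace_outline(m)
  expect_equal(unclass(o), cbind(x = c(3, 4, 4, 3), y = c(5, 5, 6, 6)),
               ignore_attr = TRUE)

  m2 <- matrix(FALSE, 6, 6); m2[3:4, 3:4] <- TRUE
  expect_equal(polygon_area(trace_outline(m2)), 4)

  m3 <- matrix(FALSE, 7, 7); m3[4, 3:5] <- TRUE; m3[3:5, 4] <- TRUE
  o3 <- trace_outline(m3)
  expect_equal(nrow(o3), 12)
  expect_equal(polygon_area(o3), 5)

  set.seed(7)
  for (i in 1:80) {
    mask <- random_filled_mask()
    if (is.null(mask)) next
    o <- suppressWarnings(trace_outline(mask))
    expect_equal(polygon_area(o), sum(mask))
  }

  expect_error(trace_outline(matrix(FALSE, 3, 3)), "empty")
  expect_warning(trace_outline(rbind(c(TRUE, FALSE, FALSE),
                                     c(FALSE, FALSE, TRUE),
                                     c(FALSE, FALSE, TRUE))), "disconnected")
})

test_that("elliptic Fourier smoothing reduces to an ellipse at 2 descriptors", {
  blobmask <- matrix(FALSE, 40, 60)
  for (yy in 1:40) for (xx in 1:60)
    blobmask[yy, xx] <- ((xx - 30) / 25)^2 + ((yy - 20) / 10)^2 <= 1
  oe <- trace_outline(blobmask)
  se <- smooth_outline_eft(oe, 2)
  # independent conic oracle: the points must satisfy one ellipse equation
  A <- cbind(se[, 1]^2, se[, 1] * se[, 2], se[, 2]^2, se[, 1], se[, 2], 1)
  sv <- svd(A)$d
  expect_lt(sv[6] / sv[1], 1e-9)
  v <- svd(A)$v[, 6]
  expect_lt(v[2]^2 - 4 * v[1] * v[3], 0)   # discriminant: an ellipse

  # analytic circle: reconstruction within 1% radial error for any n_efd
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  circ <- cbind(x = 50 + 20 * cos(th), y = 50 + 20 * sin(th))
  for (ne in c(2, 5, 16)) {
    sc <- smooth_outline_eft(circ, ne)
    r <- sqrt((sc[, 1] - 50)^2 + (sc[, 2] - 50)^2)
    expect_lt(max(abs(r - 20)) / 20, 0.01)
  }

  # keeping every harmonic reproduces the resampled contour
  K <- nrow(oe)
  full <- smooth_outline_eft(oe, K)
  expect_lt(max(abs(full - btx:::resample_closed(oe, K))), 1e-9)

  expect_error(smooth_outline_eft(cbind(rep(1, 10), rep(2, 10)), 4),
               "degenerate")
})

test_that("weighted smoothing is identity at window 1, shrinks, and preserves the centroid", {
  m2 <- matrix(FALSE, 12, 12); m2[4:9, 4:9] <- TRUE
  o <- btx:::resample_closed(trace_outline(m2), 48)
  expect_equal(smooth_outline_weighted(o, 1), o)
  sm <- smooth_outline_weighted(o, 5)
  per <- function(p) btx:::arc_lengths(p)[nrow(p) + 1]
  expect_lt(per(sm), per(o))
  expect_lt(max(abs(colMeans(sm) - colMeans(o))), 0.5)
  # repeated smoothing collapses toward the centroid
  x <- o
  for (i in 1:200) x <- smooth_outline_weighted(x, 5)
  rad <- sqrt(rowSums(sweep(x, 2, colMeans(o))^2))
  expect_lt(max(rad), 0.2 * max(sqrt(rowSums(sweep(o, 2, colMeans(o))^2))))
  # EFT smoothing also preserves the centroid
  se <- smooth_outline_eft(o, 4)
  expect_lt(max(abs(colMeans(se) - colMeans(o))), 0.5)
})

test_that("endpoint detection finds the sharp tip and flags circles as ambiguous", {
  b <- agent_blob(ang = 0.7)
  po <- blob_posture(b)
  expect_false(po$endpoints$ambiguous)
  sm <- po$smoothed
  tailp <- sm[po$endpoints$tail_index, ]
  headp <- sm[po$endpoints$head_index, ]
  # the rendered body points its blunt head along the heading
  cen <- blob_centroid(b)
  head_proj <- (headp[1] - cen[1]) * cos(0.7) + (headp[2] - cen[2]) * sin(0.7)
  tail_proj <- (tailp[1] - cen[1]) * cos(0.7) + (tailp[2] - cen[2]) * sin(0.7)
  expect_gt(head_proj, 0)
  expect_lt(tail_proj, 0)

  # pointiest_is = "head" swaps the labels
  po2 <- blob_posture(b, posture_config(pointiest_is = "head",
                                        normalized_zoom = 1.6))
  expect_equal(po2$endpoints$head_index, po$endpoints$tail_index)

  cm <- matrix(FALSE, 41, 41)
  for (yy in 1:41) for (xx in 1:41) cm[yy, xx] <- (xx - 21)^2 + (yy - 21)^2 <= 225
  ep <- find_endpoints(smooth_outline_eft(trace_outline(cm), 8))
  expect_true(ep$ambiguous)
})

test_that("midlines run along the long axis with correct length and thickness", {
  rm_ <- matrix(FALSE, 30, 110); rm_[6:25, 6:105] <- TRUE
  idx <- which(rm_, arr.ind = TRUE)
  b <- blob(idx[, 2] - 1, idx[, 1] - 1, rep(100, nrow(idx)))
  po <- blob_posture(b, posture_config(smoothing = "none"))
  expect_false(po$midline$failed)
  expect_lt(abs(po$midline$length - 100) / 100, 0.05)
  interior <- po$midline$thickness[8:18]
  expect_lt(abs(stats::median(interior) - 20) / 20, 0.15)
  # straight along the long axis: y spread small in the interior
  expect_lt(diff(range(po$midline$points[5:20, 2])), 3)

  # rotation/translation invariance of midline length within 1%
  l0 <- blob_posture(agent_blob(ang = 0, cx = 60, cy = 60))$midline$length
  l1 <- blob_posture(agent_blob(ang = 2.1, cx = 100, cy = 90))$midline$length
  expect_lt(abs(l1 - l0) / l0, 0.01 + 0.02)  # sub-pixel rendering tolerance
})

test_that("image-moment orientation returns [0,180) with the inherent 180-degree ambiguity", {
  bar <- matrix(FALSE, 20, 60); bar[9:12, 6:55] <- TRUE
  idx <- which(bar, arr.ind = TRUE)
  b <- blob(idx[, 2] - 1, idx[, 1] - 1, rep(1, nrow(idx)))
  expect_equal(as.numeric(moments_orientation(b)), 0)

  # diagonal bar at 45 degrees
  n <- 40
  db <- blob(0:(n - 1) + rep(0:2, each = n),
             rep(0:(n - 1), 3), rep(1, 3 * n))
  expect_lt(abs(as.numeric(moments_orientation(db)) - 45), 1)
  # flipping 180 degrees leaves the angle unchanged
  db2 <- blob(max(db$x) - db$x, max(db$y) - db$y, db$v)
  expect_equal(as.numeric(moments_orientation(db2)),
               as.numeric(moments_orientation(db)))

  iso <- blob(c(0, 1, 0, 1), c(0, 0, 1, 1), rep(1, 4))
  a <- moments_orientation(iso)
  expect_equal(as.numeric(a), 0)
  expect_true(isTRUE(attr(a, "ambiguous")))
})

test_that("pose normalization is rotation invariant and falls back to moments", {
  imgs <- lapply(c(0, pi / 2, -pi / 4, 2.2), function(a) {
    b <- agent_blob(ang = a, cx = 80, cy = 80)
    po <- blob_posture(b, posture_config(normalized_zoom = 1.6))
    normalize_image(b, po$midline, posture_config(normalized_zoom = 1.6))
  })
  for (i in 1:3) for (j in (i + 1):4) {
    rms <- sqrt(mean((imgs[[i]] - imgs[[j]])^2))
    expect_lt(rms / 255, 0.05)
  }
  # disc: midline fails or is ambiguous; moments fallback centres the blob
  cm <- matrix(FALSE, 31, 31)
  for (yy in 1:31) for (xx in 1:31) cm[yy, xx] <- (xx - 16)^2 + (yy - 16)^2 <= 100
  idx <- which(cm, arr.ind = TRUE)
  db <- blob(idx[, 2] - 1, idx[, 1] - 1, rep(120, nrow(idx)))
  out <- normalize_image(db, NULL, posture_config())
  expect_equal(attr(out, "mode"), "moments")
  nz <- which(out > 0, arr.ind = TRUE)
  expect_lt(abs(mean(nz[, 2]) - ncol(out) / 2), 2)
})
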