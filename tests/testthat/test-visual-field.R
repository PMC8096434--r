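test_that("eye placement is symmetric and follows the local body axis", {
  pf <- agent_posture_at(1, 130, 130, 0)
  eyes <- place_eyes(pf$midline, pf$outline, eye_config())
  # mirrored about the midline: same x, opposite y offsets (horizontal body)
  expect_lt(abs(eyes[[1]]$position[1] - eyes[[2]]$position[1]), 1)
  mid_y <- mean(c(eyes[[1]]$position[2], eyes[[2]]$position[2]))
  expect_lt(abs((eyes[[1]]$position[2] - mid_y) +
                (eyes[[2]]$position[2] - mid_y)), 1e-9)
  # lateral gazes point perpendicular to the body axis
  expect_lt(abs(abs(sin(eyes[[1]]$gaze)) - 1), 0.2)

  e0 <- place_eyes(pf$midline, pf$outline, eye_config(eye_separation_ratio = 0))
  expect_equal(e0[[1]]$position, e0[[2]]$position)

  expect_error(place_eyes(structure(list(failed = TRUE), class = "btx_midline")),
               "midline")
})

test_that("a solitary individual sees only itself", {
  pf <- agent_posture_at(1, 130, 130, 0.5)
  vf <- compute_visual_field("1", list("1" = pf), eye_config(rays = 360))
  ids <- unique(as.vector(vf$identity[!is.na(vf$identity)]))
  expect_equal(ids, "1")
})

test_that("an unobstructed neighbour is seen at the analytic distance", {
  pf <- agent_posture_at(1, 60, 130, 0)
  pn <- agent_posture_at(2, 160, 130, pi / 2)   # broadside towards the focal
  vf <- compute_visual_field("1", list("1" = pf, "2" = pn),
                             eye_config(rays = 720))
  b0 <- which.min(abs(vf$angles))
  for (ei in 1:2) {
    expect_equal(vf$identity[ei, 1, b0], "2")
    # analytic oracle: distance from the eye to the nearest outline
    # intersection along the reported ray direction
    eye <- vf$eyes[[ei]]$position
    errs <- sapply((b0 - 2):(b0 + 2), function(bb) {
      ang <- vf$angles[bb] * pi / 180
      # the ray direction actually used: relative to the focal body axis
      hits <- btx:::ray_polygon_hits(eye, c(cos(ang), sin(ang)), pn$outline)
      if (is.null(hits)) return(Inf)
      abs(vf$distance[ei, 1, bb] - min(hits$t))
    })
    expect_lt(min(errs, na.rm = TRUE), 1)
    expect_false(is.na(vf$body_part[ei, 1, b0]))
    expect_gte(vf$body_part[ei, 1, b0], 0)
    expect_lte(vf$body_part[ei, 1, b0], 100)
  }
})

test_that("occlusion layers record what lies behind, with monotone distances", {
  pf <- agent_posture_at(1, 40, 130, 0)
  pb <- agent_posture_at(2, 120, 130, 0)
  pa <- agent_posture_at(3, 200, 130, 0)
  vf <- compute_visual_field("1", list("1" = pf, "2" = pb, "3" = pa),
                             eye_config(rays = 360, max_orders = 3))
  # in the frontal bins the nearer body occludes the farther one
  front <- which(abs(vf$angles) < 15)
  o1 <- vf$identity[1, 1, front]
  expect_true("2" %in% o1)
  expect_true(any(vf$identity[1, 2, front] == "3", na.rm = TRUE))
  d <- vf$distance
  for (ei in 1:2) for (k in 1:2) {
    both <- !is.na(d[ei, k, ]) & !is.na(d[ei, k + 1, ])
    if (any(both)) expect_true(all(d[ei, k, both] < d[ei, k + 1, both]))
  }
})

test_that("field of view cropping yields the documented binocular width", {
  pf <- agent_posture_at(1, 130, 130, 0.3)
  vf <- compute_visual_field("1", list("1" = pf),
                             eye_config(rays = 720, fov = 260))
  expect_equal(sum(vf$covered[1, ]), 720 * 260 / 360)
  expect_equal(sum(vf$covered[1, ] & vf$covered[2, ]), 720 * (2 * 260 - 360) / 360)
  # order-1 occupancy can never exceed the fov share of bins
  expect_lte(sum(!is.na(vf$identity[1, 1, ])), 720 * 260 / 360)
})

test_that("the visual field is invariant under rigid motion of the whole scene", {
  mk <- function(dx, dy, rot) {
    p1 <- agent_posture_at(1, 100, 130, 0.2 + rot)
    p2 <- agent_posture_at(2, 170, 140, 1.1 + rot)
    if (rot == 0) {
      p1$outline <- p1$outline + rep(c(dx, dy), each = nrow(p1$outline))
      p1$midline$points <- p1$midline$points + rep(c(dx, dy), each = nrow(p1$midline$points))
      p2$outline <- p2$outline + rep(c(dx, dy), each = nrow(p2$outline))
      p2$midline$points <- p2$midline$points + rep(c(dx, dy), each = nrow(p2$midline$points))
    }
    compute_visual_field("1", list("1" = p1, "2" = p2), eye_config(rays = 180))
  }
  v0 <- mk(0, 0, 0)
  vt <- mk(31.5, -12.25, 0)
  expect_identical(v0$identity, vt$identity)
  expect_equal(v0$distance, vt$distance, tolerance = 1e-9)
  expect_equal(v0$body_part, vt$body_part, tolerance = 1e-9)
})
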