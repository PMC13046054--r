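# Cost-map construction, shortest-path optimality, contour tracing and
# waypoint editing.

test_that("cost map honors its feature contracts", {
  # constant image: no edges anywhere
  cm <- compute_cost_map(matrix(7, 20, 20))
  expect_true(all(cm$gradient_cost == 1))
  expect_true(all(cm$laplacian_cost == 1))
  expect_true(all(cm$grad_row == 0) && all(cm$grad_col == 0))

  # weight normalization
  cm2 <- compute_cost_map(matrix(7, 20, 20), weights = c(1, 1, 2))
  expect_equal(unname(cm2$weights), c(0.25, 0.25, 0.5))

  # vertical step edge: per-row argmin of gradient cost sits on the edge
  img <- matrix(0, 24, 24); img[, 13:24] <- 100
  cm3 <- compute_cost_map(img)
  expect_true(all(cm3$gradient_cost >= 0 & cm3$gradient_cost <= 1))
  expect_true(any(cm3$gradient_cost == 0))
  for (r in 5:20) {
    expect_true(which.min(cm3$gradient_cost[r, ]) %in% c(12L, 13L))
  }
  # zero-crossing band hugs the edge
  zc_cols <- unique(which(cm3$laplacian_cost[5:20, ] == 0, arr.ind = TRUE)[, 2])
  expect_true(all(abs(zc_cols - 12.5) <= 2))
})

test_that("shortest_path is optimal, deterministic and degenerate-safe", {
  cm <- compute_cost_map(matrix(5, 32, 32))
  p0 <- shortest_path(cm, c(5, 5), c(5, 5))
  expect_identical(nrow(p0$points), 1L)
  expect_identical(p0$cost, 0)

  # uniform image: cost of a 7-step axial geodesic is 7 (w_Z + w_G)
  p <- shortest_path(cm, c(5, 5), c(5, 12))
  expect_equal(p$cost, 7 * (0.43 + 0.43), tolerance = 1e-12)
  d <- diff(p$points)
  expect_true(all(pmax(abs(d[, 1]), abs(d[, 2])) == 1))  # 8-connected steps
  expect_identical(nrow(p$points), 8L)                    # monotone geodesic

  # agreement with the brute-force oracle on random images
  set.seed(101)
  for (i in 1:6) {
    img <- matrix(runif(32 * 32, 0, 100), 32, 32)
    cmr <- compute_cost_map(img)
    ends <- matrix(sample(3:30, 4), 2)
    got <- shortest_path(cmr, ends[1, ], ends[2, ])
    want <- oracle_dijkstra_cost(cmr, ends[1, ], ends[2, ])
    expect_equal(got$cost, want, tolerance = 1e-12)
    # lower bound: Chebyshev distance times the cheapest pixel cost
    w <- cmr$weights
    floor_cost <- min(w[["z"]] * cmr$laplacian_cost +
                        w[["g"]] * cmr$gradient_cost)
    expect_gte(got$cost, max(abs(ends[1, ] - ends[2, ])) * floor_cost - 1e-12)
    # determinism across repeated runs
    again <- shortest_path(cmr, ends[1, ], ends[2, ])
    expect_identical(got$points, again$points)
  }
})

test_that("trace_contour closes through waypoints and finds the disk edge", {
  # triangle on a uniform image: closed 8-connected chain through 3 waypoints
  img <- matrix(1, 40, 40)
  wp <- rbind(c(10, 10), c(10, 30), c(30, 20))
  ctr <- trace_contour(img, wp)
  expect_s3_class(ctr, "mt_contour")
  expect_identical(ctr$mode, "assisted")
  steps <- diff(rbind(ctr$points, ctr$points[1, , drop = FALSE]))
  expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) == 1))  # closed chain
  expect_identical(ctr$waypoint_indices[1], 1L)
  expect_true(all(diff(ctr$waypoint_indices) > 0))
  expect_equal(ctr$points[ctr$waypoint_indices, ], wp, ignore_attr = TRUE)
  expect_error(trace_contour(img, wp[1:2, ]), "at least 3 waypoints")

  # phantom disk: mean absolute radial error of the traced edge under 2 px
  fx <- disk_phantom_fixture(seed = 1)
  ctr2 <- trace_contour(fx$img, circle_waypoints(c(256, 256), 60, 12))
  radial <- sqrt((ctr2$points[, 1] - 256)^2 + (ctr2$points[, 2] - 256)^2)
  expect_lt(mean(abs(radial - 60)), 2)
})

test_that("clockwise and counterclockwise tracings agree closely", {
  # the local cost is evaluated at the destination pixel, so the pixel graph
  # is directed and exact reversal symmetry is not guaranteed; the two
  # orientations must still land on the same edge
  fx <- disk_phantom_fixture(seed = 1)
  wp <- circle_waypoints(c(256, 256), 60, 12)
  cw <- trace_contour(fx$img, wp)
  ccw <- trace_contour(fx$img, wp[c(1, 12:2), , drop = FALSE])
  m1 <- rasterize(cw, 512, 512)
  m2 <- rasterize(ccw, 512, 512)
  expect_gt(dice_coef(m1, m2), 0.99)
})

test_that("waypoint edits are local, idempotent and retrace-equivalent", {
  fx <- disk_phantom_fixture(seed = 1)
  cm <- compute_cost_map(fx$img)
  wp <- circle_waypoints(c(256, 256), 60, 12)
  ctr <- trace_contour(fx$img, wp, cost_map = cm)

  # idempotence
  same <- adjust_waypoint(fx$img, ctr, 3, wp[3, ], cost_map = cm)
  expect_identical(ctr$points, same$points)

  # locality: only the two incident segments change
  moved <- adjust_waypoint(fx$img, ctr, 3, wp[3, ] + c(6, -5), cost_map = cm)
  segs_old <- mammotrace:::.contour_segments(ctr)
  segs_new <- mammotrace:::.contour_segments(moved)
  for (i in setdiff(1:12, c(2, 3))) {
    expect_identical(segs_old[[i]], segs_new[[i]])
  }

  # equivalence with a full retrace on the updated list
  wp2 <- wp; wp2[3, ] <- wp[3, ] + c(6, -5)
  retraced <- trace_contour(fx$img, wp2, cost_map = cm)
  expect_identical(moved$points, retraced$points)
  expect_identical(moved$waypoint_indices, retraced$waypoint_indices)

  # add equals retrace on the 13-point list; add-then-remove restores
  added <- add_waypoint(fx$img, ctr, 3, c(200, 310), cost_map = cm)
  wp3 <- rbind(wp[1:3, ], c(200, 310), wp[4:12, ])
  expect_identical(added$points, trace_contour(fx$img, wp3, cost_map = cm)$points)
  restored <- remove_waypoint(fx$img, added, 4, cost_map = cm)
  expect_identical(restored$points, ctr$points)

  # bound checks
  tri <- trace_contour(matrix(1, 40, 40), rbind(c(5, 5), c(5, 30), c(30, 15)))
  expect_error(remove_waypoint(matrix(1, 40, 40), tri, 1), "at least 3")
  expect_error(adjust_waypoint(fx$img, ctr, 3, c(0, 5), cost_map = cm),
               "bounds")
})

test_that("freehand strokes become closed 8-connected contours", {
  # 4-corner square stroke, padded with duplicates to reach 8 samples
  stroke <- rbind(c(1, 1), c(1, 1), c(1, 41), c(1, 41), c(41, 41), c(41, 41),
                  c(41, 1), c(41, 1))
  ctr <- freehand_to_contour(stroke)
  expect_identical(ctr$mode, "freehand")
  expect_identical(nrow(ctr$points), 160L)  # 4 x 40 unit steps
  expect_gte(length(ctr$waypoint_indices), 4L)
  expect_identical(ctr$waypoint_indices[1], 1L)
  steps <- diff(rbind(ctr$points, ctr$points[1, , drop = FALSE]))
  expect_true(all(pmax(abs(steps[, 1]), abs(steps[, 2])) == 1))

  # an already closed 8-connected chain is preserved verbatim
  chain <- ctr$points
  ctr2 <- freehand_to_contour(chain)
  expect_identical(ctr2$points, chain)

  expect_error(freehand_to_contour(stroke[1:5, ]), "at least 8")
})
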