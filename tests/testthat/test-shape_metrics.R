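test_that("local angles: straight edges give 180, circles the closed form", {
  sq <- square_outline(20)
  ang <- shapeback:::local_angles(sq$points, 101L)
  # points whose whole 101-point window lies on one edge are exactly straight
  mid <- ang[90:110]   # middle of the first 200-point edge
  expect_true(all(abs(mid - 180) < 1e-9))

  circ <- circle_outline(12.5)
  cdf <- local_angle_distribution(circ)
  # continuum closed form: 180 - (180/pi) * (half-span arc / r); at 0.1 mm
  # sampling the realized arc is 50 * P/N, within 0.02 deg of 5.0 mm
  expect_lt(max(abs(cdf$angles - (180 - (180 / pi) * (5.0 / 12.5)))), 0.05)
  expect_lt(diff(range(cdf$angles)), 1e-3)   # chordal discretization spread
  expect_error(local_angle_distribution(
    circ, metric_config(span_points = 1001)), "span")
})

test_that("angle CDF is rotation invariant and its SSE matches a brute force", {
  s <- shared_shapes()[[2]]
  a <- local_angle_distribution(s)
  b <- local_angle_distribution(rotate_shape(s, 90))
  expect_lt(max(abs(a$angles - b$angles)), 1e-6)

  t <- local_angle_distribution(shared_shapes()[[3]])
  expect_identical(curvature_cdf_sse(a, a), 0)
  expect_equal(curvature_cdf_sse(a, t), curvature_cdf_sse(t, a))
  # independent loop oracle on the same grid
  grid <- a$grid
  fa <- vapply(grid, function(g) mean(a$angles <= g), 0)
  ft <- vapply(grid, function(g) mean(t$angles <= g), 0)
  expect_equal(curvature_cdf_sse(a, t), sum((fa - ft)^2), tolerance = 1e-12)
  bad <- local_angle_distribution(s, metric_config(span_points = 51))
  expect_error(curvature_cdf_sse(a, bad), "span")
})

test_that("aspect ratio: analytic fixtures and the @actual frame convention", {
  expect_equal(aspect_ratio(rect_outline(2, 1)), 2, tolerance = 1e-9)
  expect_equal(aspect_ratio(circle_outline(5)), 1, tolerance = 1e-3)
  expect_equal(aspect_ratio(square_outline(4)), 1, tolerance = 1e-9)

  r <- rect_outline(2, 1)
  r90 <- rotate_shape(r, 90)
  expect_equal(aspect_ratio_dissimilarity(r, r90, "actual"), 2.25,
               tolerance = 1e-9)
  expect_equal(aspect_ratio_dissimilarity(r, r90, "optimal"), 0,
               tolerance = 1e-12)
  expect_equal(aspect_ratio_dissimilarity(r, r, "actual"), 0, tolerance = 1e-12)
})

test_that("optimal-mode aspect ratio is invariant to presented orientations", {
  a <- shared_shapes()[[4]]; b <- shared_shapes()[[5]]
  vals <- c()
  for (oa in c(0, 90, 180, 270)) for (ob in c(0, 90, 180, 270))
    vals <- c(vals, aspect_ratio_dissimilarity(rotate_shape(a, oa),
                                               rotate_shape(b, ob), "optimal"))
  expect_lt(diff(range(vals)), 1e-9)
})

test_that("area, hull area and compactness match direct geometry", {
  sq <- square_outline(1)
  expect_equal(shape_area(sq), 1, tolerance = 1e-12)
  expect_equal(hull_area(sq), 1, tolerance = 1e-12)
  expect_equal(compactness(sq), 1, tolerance = 1e-12)
  expect_equal(compactness(circle_outline(10)), 1, tolerance = 1e-9)

  ns <- notched_square_outline()
  expect_equal(shape_area(ns), 75, tolerance = 1e-9)
  expect_equal(hull_area(ns), 100, tolerance = 1e-9)
  expect_equal(compactness(ns), 0.75, tolerance = 1e-9)

  expect_identical(scalar_sq_diff(3, 3), 0)
  expect_identical(scalar_sq_diff(2, 0.5), 2.25)
})

test_that("turning function: square steps, total turning, scale invariance", {
  sq <- square_outline(10)
  tf <- turning_function(sq)
  expect_equal(tf$total_turning, 360, tolerance = 1e-9)
  # four +90 steps at quarter points of normalized arc length
  jumps <- which(diff(tf$theta) > 45)
  expect_length(jumps, 3)            # plus the closing turn at s = 1
  expect_equal(tf$s_end[jumps], c(0.25, 0.5, 0.75), tolerance = 1e-9)

  for (s in shared_shapes()[1:5])
    expect_equal(turning_function(s)$total_turning, 360, tolerance = 1e-6)

  s <- shared_shapes()[[6]]
  scaled <- s; scaled$points <- s$points * 3.7
  expect_equal(turning_distance(s, scaled), 0, tolerance = 1e-9)
  expect_warning(turning_function(s$points[nrow(s$points):1, ]), "clockwise")
})

test_that("turning distance: identity, start-shift invariance, oracle", {
  sq <- square_outline(10)
  expect_lt(turning_distance(sq, sq), 1e-9)
  # same square listed from a different starting vertex
  pts <- sq$points
  shifted <- shape_outline(pts[c(150:nrow(pts), 1:149), ], validate = FALSE)
  expect_lt(turning_distance(sq, shifted), 1e-9)

  set.seed(99)
  cfg <- metric_config(turning_grid = 512)
  for (k in 1:4) {
    a <- random_polygon_outline(12, spacing = 0.5)
    b <- random_polygon_outline(12, spacing = 0.5)
    expect_equal(turning_distance(a, b, cfg), oracle_turning(a, b, 512),
                 tolerance = 1e-6)
    expect_equal(turning_distance(a, b, cfg), turning_distance(b, a, cfg),
                 tolerance = 1e-6)
  }
})

test_that("IoU: identity, concentric circles, degenerate input", {
  s <- shared_shapes()[[7]]
  expect_equal(intersection_over_union(s, s, "actual"), 1, tolerance = 1e-9)
  expect_equal(intersection_over_union(circle_outline(6.25), circle_outline(12.5),
                                       "actual"), 0.25, tolerance = 2e-3)
  degen <- list(points = cbind(c(0, 1, 2), c(0, 0, 0)))
  expect_error(intersection_over_union(degen, s, "actual"), "degenerate")
})

test_that("Hausdorff: identity, concentric circles, brute-force oracle", {
  s <- shared_shapes()[[8]]
  expect_equal(hausdorff_distance(s, s, "actual"), 0, tolerance = 1e-9)
  expect_equal(hausdorff_distance(circle_outline(8), circle_outline(10),
                                  "actual"), 2, tolerance = 2e-3)
  set.seed(123)
  for (k in 1:5) {
    a <- random_polygon_outline(15, spacing = 0.4)
    b <- random_polygon_outline(15, spacing = 0.4)
    expect_equal(hausdorff_distance(a, b, "actual"), oracle_hausdorff(a, b),
                 tolerance = 1e-9)
  }
})

test_that("dissimilarity table: row count, identity trials, determinism", {
  tr <- shared_session()
  dt <- shared_dissim()
  expect_s3_class(dt, "dissimilarity_table")
  expect_identical(nrow(dt), 8L * 71L)
  expect_true(all(metric_columns(TRUE) %in% names(dt)))

  m <- merge(dt, tr[, c("trial_id", "is_match", "orientation_delta")],
             by = "trial_id")
  id0 <- m$is_match & !is.na(m$orientation_delta) & m$orientation_delta == 0
  expect_gt(sum(id0), 0)
  expect_true(all(abs(m$hausdorff_actual[id0]) < 1e-9))
  expect_true(all(abs(m$iou_actual[id0] - 1) < 1e-9))
  expect_true(all(m$curvature_cdf_sse[m$is_match] < 1e-12))

  expect_true(all(dt$iou_actual >= 0 & dt$iou_actual <= 1))
  expect_true(all(dt$iou_optimal >= 0 & dt$iou_optimal <= 1))
  expect_true(all(dt$random_u >= 0 & dt$random_u <= 1))
  nonneg <- c("curvature_cdf_sse", "aspect_ratio_sq_diff_actual",
              "aspect_ratio_sq_diff_optimal", "area_sq_diff",
              "hull_area_sq_diff", "compactness_sq_diff", "turning_distance",
              "hausdorff_actual", "hausdorff_optimal")
  for (nm in nonneg) expect_true(all(dt[[nm]] >= 0), label = nm)

  # random_u reproducible under the seed
  dt2 <- compute_dissimilarity_table(tr[tr$block_id == 1, ], shared_shapes(),
                                     fast_metric_config(), seed = 7)
  dt3 <- compute_dissimilarity_table(tr[tr$block_id == 1, ], shared_shapes(),
                                     fast_metric_config(), seed = 7)
  expect_identical(dt2$random_u, dt3$random_u)

  bad <- tr[tr$block_id == 1, ]
  bad$current_shape_id[5] <- "nope"
  expect_error(compute_dissimilarity_table(bad, shared_shapes(),
                                           fast_metric_config()), "nope")
})
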