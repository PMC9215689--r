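#' Metric configuration
#'
#' Settings shared by the pairwise shape-dissimilarity metrics.
#'
#' @param span_points Odd window (in perimeter points) for the local-angle
#'   measure: the angle at point p is formed by the chords to p - span/2 and
#'   p + span/2. At 0.1 mm spacing the default 101 spans 5 mm to either side.
#' @param rotation_step_deg Granularity of the rotation search used by the
#'   `@optimal` variants of IoU and Hausdorff distance. Must divide 360. The
#'   search grid always contains 0 (the presented relative orientation), so
#'   the optimal variant can never be worse than the actual one.
#' @param cdf_grid_step_deg Evaluation grid step for the angle CDF metric.
#' @param turning_grid Number of uniform arc-length samples used when
#'   comparing turning functions.
#' @param iou_points Perimeter points per shape used for polygon overlap
#'   computations (downsampled from the 0.1 mm outline for speed).
#' @param hausdorff_points Points per shape for Hausdorff computations;
#'   `NA` uses the full outline.
#' @export
metric_config <- function(span_points = 101L, rotation_step_deg = 1,
                          cdf_grid_step_deg = 0.5, turning_grid = 1024L,
                          iou_points = 256L, hausdorff_points = NA_integer_) {
  if (span_points < 3 || span_points %% 2 == 0)
    stopf("span_points must be odd and >= 3")
  if (rotation_step_deg <= 0 || (360 %% rotation_step_deg) != 0)
    stopf("rotation_step_deg must be positive and divide 360")
  structure(list(span_points = as.integer(span_points),
                 rotation_step_deg = rotation_step_deg,
                 cdf_grid_step_deg = cdf_grid_step_deg,
                 turning_grid = as.integer(turning_grid),
                 iou_points = as.integer(iou_points),
                 hausdorff_points = as.integer(hausdorff_points)),
            class = "metric_config")
}

#' Names of the dissimilarity metrics
#'
#' @param include_random Append the `random_u` uniform baseline column.
#' @return Character vector of metric column names in their table order.
#' @export
metric_columns <- function(include_random = FALSE) {
  cols <- c("curvature_cdf_sse",
            "aspect_ratio_sq_diff_actual", "aspect_ratio_sq_diff_optimal",
            "area_sq_diff", "hull_area_sq_diff", "compactness_sq_diff",
            "turning_distance",
            "iou_actual", "iou_optimal",
            "hausdorff_actual", "hausdorff_optimal")
  if (include_random) c(cols, "random_u") else cols
}

shape_pts <- function(shape) {
  if (is.list(shape) && !is.null(shape$points)) shape$points
  else as.matrix(shape)
}

# resample a closed CCW polygon to exactly n points by arc length
resample_n <- function(pts, n) {
  seg <- sqrt(rowSums((pts[c(2:nrow(pts), 1), , drop = FALSE] - pts)^2))
  per <- sum(seg)
  s_cum <- c(0, cumsum(seg))
  s_new <- (0:(n - 1)) * (per / n)
  idx <- findInterval(s_new, s_cum, rightmost.closed = TRUE)
  idx[idx > nrow(pts)] <- nrow(pts)
  frac <- (s_new - s_cum[idx]) / seg[idx]
  nxt <- c(2:nrow(pts), 1)
  pts[idx, , drop = FALSE] +
    frac * (pts[nxt[idx], , drop = FALSE] - pts[idx, , drop = FALSE])
}

## ---- per-shape measures -------------------------------------------------

#' Local angle distribution of a shape outline
#'
#' At every perimeter point p the angle between the chord vectors from p to
#' the points half a span behind and ahead (circular indexing) is recorded;
#' straight stretches give 180 degrees, convex regions less, concavities
#' more. The empirical CDF of these angles is the shape's curvature
#' signature; it is invariant to rotation and to the presented orientation.
#'
#' @param shape A [shape_outline()].
#' @param config A [metric_config()].
#' @return An object of class `angle_cdf` holding the sorted angle samples,
#'   the evaluation grid, and the CDF values on that grid.
#' @export
local_angle_distribution <- function(shape, config = metric_config()) {
  pts <- shape_pts(shape)
  n <- nrow(pts)
  if (n <= config$span_points)
    stopf("span (%d) must be smaller than the point count (%d)",
          config$span_points, n)
  h <- (config$span_points - 1L) %/% 2L
  ib <- ((seq_len(n) - 1L - h) %% n) + 1L   # p - h
  ifw <- ((seq_len(n) - 1L + h) %% n) + 1L  # p + h
  v1x <- pts[ib, 1] - pts[, 1];  v1y <- pts[ib, 2] - pts[, 2]
  v2x <- pts[ifw, 1] - pts[, 1]; v2y <- pts[ifw, 2] - pts[, 2]
  ang <- (atan2(v1y, v1x) - atan2(v2y, v2x)) * 180 / pi
  ang <- ang %% 360
  grid <- seq(0, 360, by = config$cdf_grid_step_deg)
  sorted <- sort(ang)
  cdf <- findInterval(grid, sorted) / n
  structure(list(angles = sorted, grid = grid, cdf = cdf,
                 span_points = config$span_points), class = "angle_cdf")
}

#' Sum squared error between two angle CDFs
#'
#' @param a,b `angle_cdf` objects built with the same span and grid.
#' @return Nonnegative scalar; 0 for identical distributions. Symmetric.
#' @export
curvature_cdf_sse <- function(a, b) {
  stopifnot(inherits(a, "angle_cdf"), inherits(b, "angle_cdf"))
  if (a$span_points != b$span_points || length(a$grid) != length(b$grid) ||
      any(a$grid != b$grid))
    stopf("angle CDFs were built with different span/grid settings")
  sum((a$cdf - b$cdf)^2)
}

# xspan/yspan of the bounding box after rotating the shape by each angle in
# `angles` (degrees). Vectorized over angles via one matrix product.
ar_profile <- function(pts, angles) {
  th <- angles * pi / 180
  # rotated x' = x cos - y sin ; y' = x sin + y cos, all angles at once
  Xr <- pts[, 1] %o% cos(th) - pts[, 2] %o% sin(th)
  Yr <- pts[, 1] %o% sin(th) + pts[, 2] %o% cos(th)
  xs <- apply(Xr, 2, function(v) diff(range(v)))
  ys <- apply(Yr, 2, function(v) diff(range(v)))
  xs / ys
}

#' Rotation-maximized aspect ratio of a shape
#'
#' The bounding-box ratio xspan/yspan is evaluated with the shape rotated at
#' 1 degree increments over a full turn; the aspect ratio is the largest of
#' the 360 values (>= 1, since a 90 degree rotation inverts the ratio).
#'
#' @inheritParams local_angle_distribution
#' @return Scalar >= 1.
#' @export
aspect_ratio <- function(shape, config = metric_config()) {
  pts <- shape_pts(shape)
  if (diff(range(pts[, 1])) == 0 || diff(range(pts[, 2])) == 0)
    stopf("degenerate shape: zero axis span")
  max(ar_profile(pts, 0:359))
}

#' Aspect-ratio dissimilarity between consecutive shapes
#'
#' `mode = "optimal"` compares the rotation-maximized aspect ratios of the
#' two shapes (orientation invariant). `mode = "actual"` assumes no mental
#' rotation: the frame angle phi at which the previous shape (as presented)
#' attains its maximal bounding-box ratio is found, the current shape's
#' bounding-box ratio is measured at that same absolute frame angle, and the
#' squared difference is returned.
#'
#' @param prev,curr [shape_outline()]s as presented (orientation applied to
#'   the coordinates).
#' @param mode `"actual"` or `"optimal"`.
#' @inheritParams local_angle_distribution
#' @export
aspect_ratio_dissimilarity <- function(prev, curr, mode = c("optimal", "actual"),
                                       config = metric_config()) {
  mode <- match.arg(mode)
  if (mode == "optimal") {
    d <- aspect_ratio(prev, config) - aspect_ratio(curr, config)
    return(d * d)
  }
  prof_prev <- ar_profile(shape_pts(prev), 0:359)
  phi <- which.max(prof_prev) - 1L
  r_prev <- prof_prev[phi + 1L]
  r_curr <- ar_profile(shape_pts(curr), phi)
  (r_prev - r_curr)^2
}

#' Area, convex hull area and compactness
#'
#' Polygon area by the shoelace formula; hull area from the convex hull of
#' the perimeter points; compactness is their quotient (1 for convex shapes,
#' smaller with concavities).
#'
#' @param shape A [shape_outline()] or n x 2 point matrix (simple polygon).
#' @return Scalar in mm^2 (`shape_area`, `hull_area`) or in (0, 1]
#'   (`compactness`).
#' @export
shape_area <- function(shape) {
  abs(poly_signed_area(shape_pts(shape)))
}

#' @rdname shape_area
#' @export
hull_area <- function(shape) {
  pts <- shape_pts(shape)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  abs(poly_signed_area(pts[h, , drop = FALSE]))
}

#' @rdname shape_area
#' @export
compactness <- function(shape) shape_area(shape) / hull_area(shape)

#' Squared difference of two scalar measures
#'
#' @param x,y Finite scalars.
#' @export
scalar_sq_diff <- function(x, y) {
  stopifnot(is.finite(x), is.finite(y))
  (x - y)^2
}

## ---- turning function ---------------------------------------------------

#' Turning function of a closed outline
#'
#' The cumulative counterclockwise tangent angle as a piecewise-constant
#' function of normalized arc length in [0, 1). For a simple
#' counterclockwise polygon the total turning over one traversal is +360
#' degrees. Invariant to uniform scaling and translation. Clockwise inputs
#' are reoriented with a warning.
#'
#' @inheritParams local_angle_distribution
#' @return Object of class `turning_function` with fields `s_end` (arc
#'   position at which each segment ends), `theta` (tangent angle over each
#'   segment, degrees) and `total_turning` (sum of all turning increments
#'   including the closing one; +360 for a counterclockwise simple polygon).
#' @export
turning_function <- function(shape) {
  pts <- shape_pts(shape)
  if (poly_signed_area(pts) < 0) {
    warning("clockwise outline reoriented to counterclockwise")
    pts <- pts[nrow(pts):1, , drop = FALSE]
  }
  d <- pts[c(2:nrow(pts), 1), , drop = FALSE] - pts
  seg <- sqrt(rowSums(d^2))
  hdg <- atan2(d[, 2], d[, 1]) * 180 / pi
  inc <- diff(c(hdg, hdg[1]))             # includes the closing turn
  inc <- ((inc + 180) %% 360) - 180       # wrap to (-180, 180]
  theta <- hdg[1] + c(0, cumsum(inc[-length(inc)]))
  s_end <- cumsum(seg) / sum(seg)
  structure(list(s_end = s_end, theta = theta,
                 total_turning = sum(inc)), class = "turning_function")
}

# evaluate a turning function at arc positions s in [0, 1)
eval_turning <- function(tf, s) {
  idx <- findInterval(s, c(0, tf$s_end), rightmost.closed = TRUE)
  idx[idx > length(tf$theta)] <- length(tf$theta)
  tf$theta[idx]
}

#' Turning distance between two shapes
#'
#' L2 distance between the turning functions evaluated on a common uniform
#' arc-length grid, minimized over all circular shifts of one shape's start
#' position, with the constant angular offset optimized in closed form at
#' each shift. Size and translation invariant; symmetric by construction on
#' the common grid.
#'
#' @param a,b [shape_outline()]s.
#' @inheritParams local_angle_distribution
#' @return Nonnegative scalar (degrees, RMS over arc length).
#' @export
turning_distance <- function(a, b, config = metric_config()) {
  m <- config$turning_grid
  s <- (seq_len(m) - 0.5) / m
  # psi(s) = theta(s) - 360 s is 1-periodic, which turns the start-shift
  # search into a circular cross-correlation
  pa <- eval_turning(turning_function(a), s) - 360 * s
  pb <- eval_turning(turning_function(b), s) - 360 * s
  ca <- mean(pa^2); cb <- mean(pb^2)
  cc <- Re(fft(fft(pa) * Conj(fft(pb)), inverse = TRUE)) / m  # sum_i pa_i pb_{i-k}
  cmax <- max(cc) / m
  d2 <- ca + cb - 2 * cmax - (mean(pa) - mean(pb))^2
  sqrt(max(d2, 0))
}

## ---- pairwise overlap metrics -------------------------------------------

center_pts <- function(pts) sweep(pts, 2, poly_centroid(pts))

rotate_pts <- function(pts, angle_deg) {
  th <- angle_deg * pi / 180
  cbind(pts[, 1] * cos(th) - pts[, 2] * sin(th),
        pts[, 1] * sin(th) + pts[, 2] * cos(th))
}

pts_identical <- function(a, b, tol = 1e-9) {
  nrow(a) == nrow(b) && max(abs(a - b)) < tol
}

optimal_angle_grid <- function(config) {
  # always includes 0, i.e. the presented relative orientation
  seq(0, 360 - config$rotation_step_deg, by = config$rotation_step_deg)
}

#' Intersection over union of two shapes
#'
#' The shapes are overlaid with aligned area centroids; IoU is the area of
#' intersection divided by the area of union. `mode = "actual"` evaluates at
#' the presented orientations; `mode = "optimal"` maximizes over rotations of
#' the second shape on a grid of `rotation_step_deg` steps that includes the
#' presented orientation, so the optimal value is never below the actual.
#'
#' @param a,b [shape_outline()]s as presented.
#' @inheritParams aspect_ratio_dissimilarity
#' @return Scalar in [0, 1]; 1 means identical overlap.
#' @export
intersection_over_union <- function(a, b, mode = c("actual", "optimal"),
                                    config = metric_config()) {
  mode <- match.arg(mode)
  pa0 <- shape_pts(a); pb0 <- shape_pts(b)
  if (abs(poly_signed_area(pa0)) < 1e-12 || abs(poly_signed_area(pb0)) < 1e-12)
    stopf("degenerate zero-area input")
  pa <- center_pts(resample_n(ensure_ccw(pa0), config$iou_points))
  pb <- center_pts(resample_n(ensure_ccw(pb0), config$iou_points))
  aa <- abs(poly_signed_area(pa)); ab <- abs(poly_signed_area(pb))
  one <- function(pbr) {
    if (pts_identical(pa, pbr)) return(1)
    inter <- cpp_intersection_area(pa[, 1], pa[, 2], pbr[, 1], pbr[, 2])
    inter <- min(inter, aa, ab)
    inter / (aa + ab - inter)
  }
  if (mode == "actual") return(one(pb))
  max(vapply(optimal_angle_grid(config),
             function(ang) one(rotate_pts(pb, ang)), 0))
}

#' Hausdorff distance between two shapes
#'
#' Symmetric Hausdorff distance between the perimeter point sets after
#' aligning area centroids: the largest of all nearest-point distances, in
#' mm. `mode = "optimal"` minimizes over rotations of the second shape on a
#' grid that includes the presented orientation, so the optimal value is
#' never above the actual.
#'
#' @inheritParams intersection_over_union
#' @return Nonnegative scalar in mm.
#' @export
hausdorff_distance <- function(a, b, mode = c("actual", "optimal"),
                               config = metric_config()) {
  mode <- match.arg(mode)
  pa <- shape_pts(a); pb <- shape_pts(b)
  if (!is.na(config$hausdorff_points)) {
    pa <- resample_n(ensure_ccw(pa), config$hausdorff_points)
    pb <- resample_n(ensure_ccw(pb), config$hausdorff_points)
  }
  pa <- center_pts(pa); pb <- center_pts(pb)
  one <- function(pbr) {
    if (pts_identical(pa, pbr)) return(0)
    cpp_hausdorff(pa[, 1], pa[, 2], pbr[, 1], pbr[, 2])
  }
  if (mode == "actual") return(one(pb))
  min(vapply(optimal_angle_grid(config),
             function(ang) one(rotate_pts(pb, ang)), 0))
}

## ---- the per-trial dissimilarity table ----------------------------------

#' Compute the per-trial dissimilarity table
#'
#' One row per analyzable (non-warmup) trial, with every metric evaluated on
#' the (previous, current) shape pair at the presented orientations, plus a
#' `random_u` column drawn once per trial from U(0, 1) under the given seed.
#' Orientation-invariant quantities and pairwise values are cached across
#' trials, so repeated pairs cost nothing.
#'
#' @param trials Trial data frame from [generate_session()] (or with the same
#'   columns).
#' @param shapes Named list of [shape_outline()]s at orientation 0 covering
#'   every shape id referenced by `trials`.
#' @param config A [metric_config()].
#' @param seed Integer seed for the `random_u` baseline column.
#' @return A data.frame of class `dissimilarity_table`, keyed by `trial_id`,
#'   with the columns of [metric_columns()] plus `random_u`.
#' @export
compute_dissimilarity_table <- function(trials, shapes,
                                        config = metric_config(), seed = 1L) {
  need <- c("trial_id", "condition", "current_shape_id", "prev_shape_id",
            "current_orientation_deg", "prev_orientation_deg")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stopf("trials table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  use <- trials[trials$condition != "warmup", , drop = FALSE]
  bad <- unique(c(use$current_shape_id, use$prev_shape_id))
  bad <- bad[!bad %in% names(shapes)]
  if (length(bad)) stopf("trial references unknown shape id(s): %s",
                         paste(bad, collapse = ", "))

  cache <- new.env(parent = emptyenv())
  memo <- function(key, fn) {
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- fn()
    cache[[key]]
  }
  base_cached <- function(id) memo(paste0("base|", id), function() {
    s <- shapes[[id]]
    pts <- s$points
    list(shape = s,
         cdf = local_angle_distribution(s, config),
         profile = ar_profile(pts, 0:359),
         area = shape_area(pts),
         hull = hull_area(pts),
         tf = turning_function(s))
  })
  rotated_cached <- function(id, orient) memo(sprintf("rot|%s|%g", id, orient),
    function() {
      if (orient == 0) shapes[[id]] else rotate_shape(shapes[[id]], orient)
    })
  pair_key <- function(id1, id2, delta) {
    if (id1 <= id2) sprintf("%s|%s|%g", id1, id2, delta %% 360)
    else sprintf("%s|%s|%g", id2, id1, (-delta) %% 360)
  }

  n <- nrow(use)
  out <- as.data.frame(matrix(NA_real_, n, length(metric_columns())))
  names(out) <- metric_columns()
  for (r in seq_len(n)) {
    id_p <- use$prev_shape_id[r];  o_p <- use$prev_orientation_deg[r]
    id_c <- use$current_shape_id[r]; o_c <- use$current_orientation_deg[r]
    bp <- base_cached(id_p); bc <- base_cached(id_c)
    sp <- rotated_cached(id_p, o_p); sc <- rotated_cached(id_c, o_c)
    delta <- (o_c - o_p) %% 360

    out$curvature_cdf_sse[r] <- curvature_cdf_sse(bp$cdf, bc$cdf)
    # aspect ratio from cached 0..359 profiles: rotating the shape by o
    # shifts its profile, so presented profiles are circular shifts
    prof_p <- bp$profile[(((0:359) + o_p) %% 360) + 1L]
    phi <- which.max(prof_p) - 1L
    r_prev <- prof_p[phi + 1L]
    r_curr <- bc$profile[(((phi + o_c) %% 360)) + 1L]
    out$aspect_ratio_sq_diff_actual[r] <- (r_prev - r_curr)^2
    out$aspect_ratio_sq_diff_optimal[r] <- (max(bp$profile) - max(bc$profile))^2
    out$area_sq_diff[r] <- (bp$area - bc$area)^2
    out$hull_area_sq_diff[r] <- (bp$hull - bc$hull)^2
    out$compactness_sq_diff[r] <- (bp$area / bp$hull - bc$area / bc$hull)^2
    out$turning_distance[r] <- memo(paste0("turn|", pair_key(id_p, id_c, 0)),
      function() turning_distance(sp, sc, config))
    out$iou_actual[r] <- memo(paste0("ioua|", pair_key(id_p, id_c, delta)),
      function() intersection_over_union(sp, sc, "actual", config))
    out$iou_optimal[r] <- memo(paste0("iouo|", pair_key(id_p, id_c, delta)),
      function() intersection_over_union(sp, sc, "optimal", config))
    out$hausdorff_actual[r] <- memo(paste0("hda|", pair_key(id_p, id_c, delta)),
      function() hausdorff_distance(sp, sc, "actual", config))
    out$hausdorff_optimal[r] <- memo(paste0("hdo|", pair_key(id_p, id_c, delta)),
      function() hausdorff_distance(sp, sc, "optimal", config))
  }
  out$random_u <- with_seed(derive_seed(seed, 77L), runif(n))
  out <- cbind(trial_id = use$trial_id, out)
  class(out) <- c("dissimilarity_table", "data.frame")
  out
}
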