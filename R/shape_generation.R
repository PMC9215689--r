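#' Generator configuration for blob-union shapes
#'
#' Bundles the knobs of the stimulus generator: how many spline blobs are
#' unioned, how many control points define each blob, the physical scale of
#' the finished silhouette and the perimeter sampling density.
#'
#' @param n_blobs Number of blobs per shape, 2 or 3. `NA` (default) lets the
#'   set generator pick 2 or 3 at random per shape.
#' @param n_control_points Control points per blob spline (>= 3).
#' @param target_extent_mm Maximum axis extent of the finished shape, mm.
#' @param spacing_mm Nominal perimeter point spacing, mm.
#' @param seed Integer seed; `NULL` uses the ambient RNG stream.
#' @param max_rejections Retry budget for rejected blobs/unions.
#' @param blob_points Number of points sampled along each blob spline before
#'   the union is formed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_blobs = NA_integer_, n_control_points = 3L,
                             target_extent_mm = 25, spacing_mm = 0.1,
                             seed = NULL, max_rejections = 200L,
                             blob_points = 400L) {
  if (!is.na(n_blobs) && !n_blobs %in% c(2L, 3L))
    stopf("n_blobs must be 2 or 3 (got %s)", n_blobs)
  if (n_control_points < 3) stopf("n_control_points must be >= 3")
  if (target_extent_mm <= 0 || spacing_mm <= 0 || blob_points < 10)
    stopf("target_extent_mm, spacing_mm and blob_points must be positive")
  structure(list(n_blobs = as.integer(n_blobs),
                 n_control_points = as.integer(n_control_points),
                 target_extent_mm = target_extent_mm,
                 spacing_mm = spacing_mm, seed = seed,
                 max_rejections = as.integer(max_rejections),
                 blob_points = as.integer(blob_points)),
            class = "generator_config")
}

## ---- polygon primitives -------------------------------------------------

poly_signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

poly_centroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  c(sum((x + x2) * cr) / (6 * a), sum((y + y2) * cr) / (6 * a))
}

poly_perimeter <- function(pts) {
  d <- sqrt(rowSums((pts[c(2:nrow(pts), 1), , drop = FALSE] - pts)^2))
  sum(d)
}

ensure_ccw <- function(pts) {
  if (poly_signed_area(pts) < 0) pts[nrow(pts):1, , drop = FALSE] else pts
}

# rotate indexing so the vertex with minimal (y, then x) comes first
canonicalize_start <- function(pts) {
  i <- order(pts[, 2], pts[, 1])[1]
  if (i > 1) pts <- pts[c(i:nrow(pts), 1:(i - 1)), , drop = FALSE]
  pts
}

max_extent <- function(pts) {
  max(diff(range(pts[, 1])), diff(range(pts[, 2])))
}

## ---- shape_outline class ------------------------------------------------

#' Construct a shape outline object
#'
#' Low-level constructor wrapping an ordered closed perimeter point list
#' (no repeated final vertex) with identity and orientation metadata.
#' Use [polygon_outline()] to build one from an arbitrary closed polyline
#' with resampling and canonicalization applied.
#'
#' @param points Numeric n x 2 matrix of (x, y) in mm, counterclockwise.
#' @param shape_id Identifier string.
#' @param orientation_deg Presented orientation, one of 0/90/180/270 for task
#'   stimuli (arbitrary reals are tolerated for intermediate objects).
#' @param spacing_mm Nominal sampling interval used to build the outline.
#' @param validate Check simplicity and orientation invariants.
#' @return An object of class `shape_outline`.
#' @export
shape_outline <- function(points, shape_id = "shape", orientation_deg = 0,
                          spacing_mm = 0.1, validate = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (ncol(points) != 2 || nrow(points) < 3) stopf("points must be n x 2, n >= 3")
  if (validate) {
    if (poly_signed_area(points) <= 0) stopf("outline must be counterclockwise")
    if (!cpp_is_simple(points[, 1], points[, 2]))
      stopf("outline is self-intersecting")
  }
  structure(list(shape_id = as.character(shape_id), points = points,
                 orientation_deg = orientation_deg %% 360,
                 max_extent_mm = max_extent(points),
                 perimeter_mm = poly_perimeter(points),
                 spacing_mm = spacing_mm),
            class = "shape_outline")
}

#' @export
print.shape_outline <- function(x, ...) {
  cat(sprintf("<shape_outline %s: %d pts, perimeter %.1f mm, extent %.2f mm, orient %g deg>\n",
              x$shape_id, nrow(x$points), x$perimeter_mm, x$max_extent_mm,
              x$orientation_deg))
  invisible(x)
}

#' Build a canonical outline from a closed polyline
#'
#' Reorients the input counterclockwise, resamples the perimeter at uniform
#' arc-length spacing and canonicalizes the start point, returning a
#' [shape_outline()].
#'
#' @param points n x 2 matrix tracing a closed curve (final vertex may or may
#'   not repeat the first).
#' @param spacing_mm Target sampling interval.
#' @inheritParams shape_outline
#' @export
polygon_outline <- function(points, spacing_mm = 0.1, shape_id = "shape",
                            orientation_deg = 0) {
  points <- as.matrix(points)
  if (nrow(points) > 1 && all(points[1, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]
  resample_perimeter(closed_curve(points), spacing_mm,
                     shape_id = shape_id, orientation_deg = orientation_deg)
}

#' Closed curve container
#'
#' @param points n x 2 matrix of vertices, no repeated final vertex.
#' @export
closed_curve <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  structure(list(points = points), class = "closed_curve")
}

## ---- resampling ---------------------------------------------------------

#' Resample a closed curve at uniform arc-length spacing
#'
#' Places `N = round(perimeter / spacing_mm)` points equally spaced by arc
#' length along the curve (actual spacing `perimeter / N`, so there is no
#' short closing segment), orders them counterclockwise and starts at the
#' vertex with minimal y (ties broken by x).
#'
#' @param curve A [closed_curve()] or n x 2 matrix.
#' @param spacing_mm Target spacing in mm.
#' @param shape_id,orientation_deg Metadata forwarded to the result.
#' @return A [shape_outline()].
#' @export
resample_perimeter <- function(curve, spacing_mm = 0.1, shape_id = "shape",
                               orientation_deg = 0) {
  pts <- if (inherits(curve, "closed_curve")) curve$points else as.matrix(curve)
  if (spacing_mm <= 0) stopf("spacing_mm must be positive")
  pts <- ensure_ccw(pts)
  seg <- sqrt(rowSums((pts[c(2:nrow(pts), 1), , drop = FALSE] - pts)^2))
  if (any(seg == 0)) {
    keep <- seg > 0
    pts <- pts[keep, , drop = FALSE]
    seg <- seg[keep]
  }
  per <- sum(seg)
  if (per < 3 * spacing_mm) stopf("degenerate shape: perimeter %.3g < 3 * spacing", per)
  n_out <- max(3L, as.integer(round(per / spacing_mm)))
  s_cum <- c(0, cumsum(seg))                 # arc position of each vertex
  s_new <- (0:(n_out - 1)) * (per / n_out)
  idx <- findInterval(s_new, s_cum, rightmost.closed = TRUE)
  idx[idx > nrow(pts)] <- nrow(pts)
  frac <- (s_new - s_cum[idx]) / seg[idx]
  nxt <- c(2:nrow(pts), 1)
  out <- pts[idx, , drop = FALSE] +
    frac * (pts[nxt[idx], , drop = FALSE] - pts[idx, , drop = FALSE])
  out <- canonicalize_start(out)
  shape_outline(out, shape_id = shape_id, orientation_deg = orientation_deg,
                spacing_mm = spacing_mm, validate = FALSE)
}

#' Rotate a shape about its area centroid
#'
#' @param shape A [shape_outline()].
#' @param angle_deg Rotation angle, degrees counterclockwise.
#' @return The rotated [shape_outline()]; `orientation_deg` is advanced
#'   modulo 360 and point coordinates are rotated rigidly about the area
#'   centroid (which stays fixed).
#' @export
rotate_shape <- function(shape, angle_deg) {
  stopifnot(inherits(shape, "shape_outline"))
  ctr <- poly_centroid(shape$points)
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- sweep(shape$points, 2, ctr) %*% t(R)
  pts <- sweep(pts, 2, ctr, "+")
  out <- shape
  out$points <- pts
  out$orientation_deg <- (shape$orientation_deg + angle_deg) %% 360
  out$max_extent_mm <- max_extent(pts)
  out
}

## ---- blob generation ----------------------------------------------------

# Periodic cubic spline through control points, chord-length parameterized.
spline_through <- function(ctrl, n_out) {
  # order control points by angle about their mean so the traversal is sane
  ctr <- colMeans(ctrl)
  ord <- order(atan2(ctrl[, 2] - ctr[2], ctrl[, 1] - ctr[1]))
  ctrl <- ctrl[ord, , drop = FALSE]
  closed <- rbind(ctrl, ctrl[1, ])
  chord <- sqrt(rowSums(diff(closed)^2))
  if (any(chord == 0)) return(NULL)
  t_knot <- c(0, cumsum(chord))
  t_eval <- seq(0, t_knot[length(t_knot)], length.out = n_out + 1)[-(n_out + 1)]
  # include the knots so the sampled polyline passes through every control point
  t_eval <- sort(unique(c(t_eval, t_knot[-length(t_knot)])))
  x <- spline(t_knot, closed[, 1], method = "periodic", xout = t_eval)$y
  y <- spline(t_knot, closed[, 2], method = "periodic", xout = t_eval)$y
  cbind(x, y)
}

#' Generate one random blob
#'
#' Draws control points uniformly in the unit disc and joins them with a
#' periodic (closed) cubic spline, rejecting self-intersecting curves.
#'
#' @param config A [generator_config()].
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return A [closed_curve()]; the spline passes through every control point
#'   (stored in attribute `control_points`).
#' @export
generate_blob <- function(config = generator_config(), seed = NULL) {
  run <- function() {
    for (k in seq_len(config$max_rejections)) {
      r <- sqrt(runif(config$n_control_points))
      a <- runif(config$n_control_points, 0, 2 * pi)
      ctrl <- cbind(r * cos(a), r * sin(a))
      pts <- spline_through(ctrl, config$blob_points)
      if (is.null(pts)) next
      if (cpp_is_simple(pts[, 1], pts[, 2])) {
        cc <- closed_curve(ensure_ccw(pts))
        attr(cc, "control_points") <- ctrl
        return(cc)
      }
    }
    stopf("blob generation failed after %d rejections (seed=%s)",
          config$max_rejections, format(seed %||% config$seed %||% NA))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

## ---- union of blobs -----------------------------------------------------

# Split every edge of every polygon at crossings with the other polygons and
# keep the sub-segments whose midpoints lie outside all other polygons; those
# directed sub-segments are exactly the boundary of the union.
union_boundary_segments <- function(polys) {
  segs <- list()
  for (i in seq_along(polys)) {
    A <- polys[[i]]
    n <- nrow(A)
    nxt <- c(2:n, 1)
    tl <- vector("list", n)
    for (j in seq_along(polys)[-i]) {
      B <- polys[[j]]
      M <- cpp_poly_edge_intersections(A[, 1], A[, 2], B[, 1], B[, 2])
      if (nrow(M)) for (r in seq_len(nrow(M)))
        tl[[M[r, 1]]] <- c(tl[[M[r, 1]]], M[r, 2])
    }
    p0s <- p1s <- mids <- NULL
    for (e in seq_len(n)) {
      ts <- sort(unique(c(0, tl[[e]], 1)))
      a <- A[e, ]; b <- A[nxt[e], ]
      for (k in seq_len(length(ts) - 1)) {
        t0 <- ts[k]; t1 <- ts[k + 1]
        q0 <- if (t0 == 0) a else a + t0 * (b - a)
        q1 <- if (t1 == 1) b else a + t1 * (b - a)
        p0s <- rbind(p0s, q0); p1s <- rbind(p1s, q1)
        mids <- rbind(mids, a + 0.5 * (t0 + t1) * (b - a))
      }
    }
    keep <- rep(TRUE, nrow(mids))
    for (j in seq_along(polys)[-i]) {
      B <- polys[[j]]
      keep <- keep & !cpp_point_in_poly(mids[, 1], mids[, 2], B[, 1], B[, 2])
    }
    if (any(keep))
      segs[[length(segs) + 1]] <-
        list(p0 = p0s[keep, , drop = FALSE], p1 = p1s[keep, , drop = FALSE])
  }
  if (!length(segs)) return(NULL)
  list(p0 = do.call(rbind, lapply(segs, `[[`, "p0")),
       p1 = do.call(rbind, lapply(segs, `[[`, "p1")))
}

# Chain directed segments into closed loops by endpoint proximity.
stitch_loops <- function(p0, p1, tol = 1e-9) {
  k <- nrow(p0)
  used <- rep(FALSE, k)
  loops <- list()
  while (any(!used)) {
    cur <- which(!used)[1]
    used[cur] <- TRUE
    loop <- p0[cur, , drop = FALSE]
    head_pt <- p0[cur, ]
    end_pt <- p1[cur, ]
    repeat {
      if (sum((end_pt - head_pt)^2) < tol^2 && nrow(loop) > 2) break
      cand <- which(!used)
      if (!length(cand)) return(NULL)     # open chain: stitch failure
      d2 <- (p0[cand, 1] - end_pt[1])^2 + (p0[cand, 2] - end_pt[2])^2
      jm <- cand[which.min(d2)]
      if (min(d2) > 1e-10) return(NULL)
      used[jm] <- TRUE
      loop <- rbind(loop, p0[jm, ])
      end_pt <- p1[jm, ]
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

# Connectivity of the blob-union via the pairwise-overlap graph.
blobs_connected <- function(polys) {
  nb <- length(polys)
  if (nb == 1) return(TRUE)
  adj <- matrix(FALSE, nb, nb)
  for (i in 1:(nb - 1)) for (j in (i + 1):nb) {
    ia <- cpp_intersection_area(polys[[i]][, 1], polys[[i]][, 2],
                                polys[[j]][, 1], polys[[j]][, 2])
    adj[i, j] <- adj[j, i] <- ia > 1e-12
  }
  seen <- c(1L)
  repeat {
    grow <- which(apply(adj[seen, , drop = FALSE], 2, any))
    grow <- setdiff(grow, seen)
    if (!length(grow)) break
    seen <- c(seen, grow)
  }
  length(seen) == nb
}

#' Generate one blob-union shape
#'
#' Generates `n_blobs` spline blobs, offsets them so overlap is probable,
#' rejects configurations whose union is not a single connected region,
#' extracts the outer boundary (holes dropped), scales the result so the
#' maximum axis extent equals `target_extent_mm` and resamples the perimeter
#' at `spacing_mm`.
#'
#' @inheritParams generate_blob
#' @param shape_id Identifier for the resulting outline.
#' @return A [shape_outline()] with attributes `n_blobs` and `rejections`.
#' @export
generate_shape <- function(config = generator_config(), seed = NULL,
                           shape_id = "shape") {
  run <- function() {
    n_blobs <- config$n_blobs
    if (is.na(n_blobs)) n_blobs <- sample(2:3, 1)
    rejections <- 0L
    for (k in seq_len(config$max_rejections)) {
      polys <- vector("list", n_blobs)
      for (b in seq_len(n_blobs)) {
        blob <- generate_blob(config)
        pts <- blob$points
        ctr <- poly_centroid(pts)
        r <- 0.5 * sqrt(runif(1)); a <- runif(1, 0, 2 * pi)
        polys[[b]] <- sweep(pts, 2, ctr) +
          matrix(c(r * cos(a), r * sin(a)), nrow(pts), 2, byrow = TRUE)
      }
      if (!blobs_connected(polys)) { rejections <- rejections + 1L; next }
      segs <- union_boundary_segments(polys)
      if (is.null(segs)) { rejections <- rejections + 1L; next }
      loops <- stitch_loops(segs$p0, segs$p1)
      if (is.null(loops) || !length(loops)) { rejections <- rejections + 1L; next }
      areas <- vapply(loops, function(L) abs(poly_signed_area(L)), 0)
      outer <- loops[[which.max(areas)]]
      blob_area_max <- max(vapply(polys, function(P) abs(poly_signed_area(P)), 0))
      if (max(areas) < blob_area_max - 1e-9) { rejections <- rejections + 1L; next }
      scale <- config$target_extent_mm / max_extent(outer)
      outer <- outer * scale
      if (!cpp_is_simple(outer[, 1], outer[, 2])) { rejections <- rejections + 1L; next }
      out <- resample_perimeter(closed_curve(outer), config$spacing_mm,
                                shape_id = shape_id)
      # resampling cuts corners and shrinks the extent by O(spacing^2/R);
      # a final uniform rescale restores the target extent exactly while
      # preserving equal arc spacing and the canonical start
      out$points <- out$points * (config$target_extent_mm / out$max_extent_mm)
      out$max_extent_mm <- max_extent(out$points)
      out$perimeter_mm <- poly_perimeter(out$points)
      attr(out, "n_blobs") <- n_blobs
      attr(out, "rejections") <- rejections
      return(out)
    }
    stopf("shape generation failed after %d rejections (seed=%s)",
          config$max_rejections, format(seed %||% config$seed %||% NA))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Generate a stimulus set of blob-union shapes
#'
#' @param n Number of shapes (the task uses a pool of 48).
#' @param config A [generator_config()]; `config$seed` seeds the whole set,
#'   with one derived seed per shape recorded in the manifest.
#' @return A list of [shape_outline()]s named by `shape_id`, with a
#'   `manifest` attribute (`shape_id`, `seed`, `n_blobs`, `perimeter_mm`).
#' @export
generate_shape_set <- function(n = 48L, config = generator_config(seed = 1L)) {
  base_seed <- config$seed %||% 1L
  ids <- sprintf("shape%03d", seq_len(n))
  shapes <- vector("list", n)
  seeds <- integer(n)
  for (i in seq_len(n)) {
    seeds[i] <- derive_seed(base_seed, 1000L + i)
    shapes[[i]] <- generate_shape(config, seed = seeds[i], shape_id = ids[i])
  }
  names(shapes) <- ids
  attr(shapes, "manifest") <- data.frame(
    shape_id = ids, seed = seeds,
    n_blobs = vapply(shapes, function(s) attr(s, "n_blobs"), 0L),
    perimeter_mm = vapply(shapes, function(s) s$perimeter_mm, 0),
    stringsAsFactors = FALSE)
  shapes
}
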