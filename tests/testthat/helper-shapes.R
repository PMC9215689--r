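# Fixture outlines built in code (the deliverable carries no binary data).

circle_outline <- function(r, spacing = 0.1, id = sprintf("circle%g", r)) {
  th <- seq(0, 2 * pi, length.out = 4000)[-4000]
  polygon_outline(cbind(r * cos(th), r * sin(th)), spacing, shape_id = id)
}

square_outline <- function(side = 10, spacing = 0.1, id = "square") {
  polygon_outline(cbind(c(0, side, side, 0), c(0, 0, side, side)),
                  spacing, shape_id = id)
}

rect_outline <- function(w, h, spacing = 0.1, id = "rect") {
  polygon_outline(cbind(c(0, w, w, 0), c(0, 0, h, h)), spacing, shape_id = id)
}

# 10x10 square with a 5x5 notch cut into the top edge: area 75 and hull
# area 100 (a notch at a corner would shrink the hull too)
notched_square_outline <- function(spacing = 0.1) {
  polygon_outline(cbind(c(0, 10, 10, 7.5, 7.5, 2.5, 2.5, 0),
                        c(0, 0, 10, 10, 5, 5, 10, 10)),
                  spacing, shape_id = "notched")
}

random_polygon_outline <- function(n_vert, spacing = 0.1, id = "rand") {
  # star-shaped random polygon: angles sorted, radii jittered -> always simple
  th <- sort(runif(n_vert, 0, 2 * pi))
  r <- runif(n_vert, 4, 12)
  polygon_outline(cbind(r * cos(th), r * sin(th)), spacing, shape_id = id)
}

# scaled-down metric config used by the bulk simulation tests (see the
# methods vignette: the spec-default 1-degree search at full resolution costs
# minutes per session; dominance and recovery properties are step-invariant)
fast_metric_config <- function() {
  metric_config(rotation_step_deg = 15, iou_points = 96,
                hausdorff_points = 96)
}

small_generator <- function(seed) generator_config(seed = seed)

# Brute-force oracles, kept independent of the package implementation -------

# IoU by dense grid sampling over the joint bounding box
oracle_iou_grid <- function(a, b, n_grid = 400) {
  pa <- sweep(a$points, 2, shapeback:::poly_centroid(a$points))
  pb <- sweep(b$points, 2, shapeback:::poly_centroid(b$points))
  xr <- range(pa[, 1], pb[, 1]); yr <- range(pa[, 2], pb[, 2])
  gx <- seq(xr[1], xr[2], length.out = n_grid)
  gy <- seq(yr[1], yr[2], length.out = n_grid)
  pts <- expand.grid(x = gx, y = gy)
  ina <- sp_point_in_poly(pts$x, pts$y, pa)
  inb <- sp_point_in_poly(pts$x, pts$y, pb)
  sum(ina & inb) / sum(ina | inb)
}

# plain-R even-odd point-in-polygon (no package code)
sp_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (yi > py) != (yj > py)
    xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

# symmetric Hausdorff by the naive double loop
oracle_hausdorff <- function(a, b) {
  pa <- sweep(a$points, 2, shapeback:::poly_centroid(a$points))
  pb <- sweep(b$points, 2, shapeback:::poly_centroid(b$points))
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

# turning distance by brute-force shift search on a dense common grid
oracle_turning <- function(a, b, m = 1024) {
  theta_of <- function(s) {
    pts <- s$points
    d <- pts[c(2:nrow(pts), 1), , drop = FALSE] - pts
    hdg <- atan2(d[, 2], d[, 1]) * 180 / pi
    inc <- diff(hdg)
    inc <- ((inc + 180) %% 360) - 180
    theta <- hdg[1] + c(0, cumsum(inc))
    seg <- sqrt(rowSums(d^2))
    list(theta = theta, s_end = cumsum(seg) / sum(seg))
  }
  eval_tf <- function(tf, s) {
    idx <- findInterval(s, c(0, tf$s_end), rightmost.closed = TRUE)
    idx[idx > length(tf$theta)] <- length(tf$theta)
    tf$theta[idx]
  }
  s <- (seq_len(m) - 0.5) / m
  ta <- eval_tf(theta_of(a), s)
  tb <- eval_tf(theta_of(b), s)
  best <- Inf
  for (k in 0:(m - 1)) {
    # restart b at arc position k/m: wrap the samples and add a full turn
    # (+360) to the wrapped-around stretch, then optimize the constant
    # angular offset in closed form (the mean difference)
    i <- seq_len(m) - 1
    wrapped <- (i + k) >= m
    tbk <- tb[((i + k) %% m) + 1] + 360 * wrapped
    diffs <- ta - tbk
    d2 <- mean(diffs^2) - mean(diffs)^2
    if (d2 < best) best <- d2
  }
  sqrt(max(best, 0))
}
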