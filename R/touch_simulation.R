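#' Monte Carlo touch-baseline parameters
#'
#' A sampled point counts as a touch when it lies outside the shape with its
#' distance to the perimeter between the rigid core radius and the finger
#' radius; every pad at least partly within the finger radius of the point
#' is credited.
#'
#' @param n_samples Random points per shape (default 100,000).
#' @param finger_radius_mm Finger radius: a touch must lie within this
#'   distance of an edge (default 6).
#' @param rigid_radius_mm Rigid core: a touch must not lie within this
#'   distance of an edge (default 4).
#' @export
touch_mc_params <- function(n_samples = 100000L, finger_radius_mm = 6,
                            rigid_radius_mm = 4) {
  if (rigid_radius_mm >= finger_radius_mm)
    stopf("rigid_radius_mm must be smaller than finger_radius_mm")
  if (n_samples < 1000) stopf("n_samples too small for a stable baseline")
  structure(list(n_samples = as.integer(n_samples),
                 finger_radius_mm = finger_radius_mm,
                 rigid_radius_mm = rigid_radius_mm),
            class = "touch_mc_params")
}

#' Partition a shape perimeter into touchpads
#'
#' Six (by default) contiguous equal-arc-length intervals starting at the
#' canonical start point. Because the partition is arc-length based it is
#' invariant under rigid rotation of the shape.
#'
#' @param shape A [shape_outline()].
#' @param n_pads Number of pads.
#' @return Object of class `pad_partition` with the 1-based pad index of
#'   every perimeter point (`pad_of_point`) and the interval breaks in mm.
#' @export
partition_pads <- function(shape, n_pads = 6L) {
  n <- nrow(shape$points)
  pad <- as.integer(floor(n_pads * (seq_len(n) - 1L) / n)) + 1L
  structure(list(shape_id = shape$shape_id, n_pads = as.integer(n_pads),
                 pad_of_point = pad,
                 breaks_mm = shape$perimeter_mm * (0:n_pads) / n_pads),
            class = "pad_partition")
}

# per-point local angles (unsorted), shared with the curvature CDF
local_angles <- function(pts, span_points) {
  n <- nrow(pts)
  h <- (span_points - 1L) %/% 2L
  ib <- ((seq_len(n) - 1L - h) %% n) + 1L
  ifw <- ((seq_len(n) - 1L + h) %% n) + 1L
  ang <- (atan2(pts[ib, 2] - pts[, 2], pts[ib, 1] - pts[, 1]) -
          atan2(pts[ifw, 2] - pts[, 2], pts[ifw, 1] - pts[, 1])) * 180 / pi
  ang %% 360
}

#' Per-pad curvature scores
#'
#' Mean absolute deviation of the local angle (see
#' [local_angle_distribution()]) from 180 degrees over each pad's points:
#' 0 for straight stretches, larger where the outline bends either way.
#'
#' @param shape A [shape_outline()].
#' @param pads A [partition_pads()] result.
#' @param config A [metric_config()] (for the span).
#' @return Numeric vector, one score per pad.
#' @export
pad_curvature_scores <- function(shape, pads, config = metric_config()) {
  ang <- local_angles(shape$points, config$span_points)
  as.numeric(tapply(abs(ang - 180), pads$pad_of_point, mean))
}

#' Classify candidate finger positions as touches
#'
#' Applies the touch rule to arbitrary points: outside the polygon and with
#' perimeter distance inside `[rigid_radius_mm, finger_radius_mm]`. Also
#' returns the per-pad credit matrix (any pad within the finger radius).
#'
#' @param shape A [shape_outline()].
#' @param pads A [partition_pads()] result.
#' @param px,py Candidate point coordinates (mm).
#' @param params A [touch_mc_params()].
#' @return List with `is_touch` (logical) and `credits` (n x n_pads logical
#'   matrix, rows of non-touch points all FALSE).
#' @export
classify_touch_points <- function(shape, pads, px, py,
                                  params = touch_mc_params()) {
  pts <- shape$points
  dmat <- cpp_pad_min_dists(px, py, pts[, 1], pts[, 2],
                            pads$pad_of_point, pads$n_pads)
  dmin <- do.call(pmin, as.data.frame(dmat))
  inside <- cpp_point_in_poly(px, py, pts[, 1], pts[, 2])
  is_touch <- !inside & dmin >= params$rigid_radius_mm &
    dmin <= params$finger_radius_mm
  credits <- dmat <= params$finger_radius_mm & is_touch
  list(is_touch = is_touch, credits = credits)
}

#' Monte Carlo baseline touch ratios
#'
#' Samples points uniformly in the shape's bounding box padded by the finger
#' radius, applies the touch rule of [classify_touch_points()], credits every
#' pad within the finger radius of each touch, and normalizes the per-pad
#' credits to ratios.
#'
#' @inheritParams classify_touch_points
#' @param seed Integer seed.
#' @return Numeric vector of pad ratios summing to 1, with attributes
#'   `n_touches` and `n_credits`.
#' @export
monte_carlo_baseline <- function(shape, pads = partition_pads(shape),
                                 params = touch_mc_params(), seed = 1L) {
  pts <- shape$points
  fr <- params$finger_radius_mm
  xr <- range(pts[, 1]) + c(-fr, fr)
  yr <- range(pts[, 2]) + c(-fr, fr)
  cl <- with_seed(derive_seed(seed, 404L), {
    px <- runif(params$n_samples, xr[1], xr[2])
    py <- runif(params$n_samples, yr[1], yr[2])
    classify_touch_points(shape, pads, px, py, params)
  })
  n_touch <- sum(cl$is_touch)
  if (n_touch == 0) stopf("no touches after %d samples: degenerate geometry",
                          params$n_samples)
  credits <- colSums(cl$credits)
  ratios <- credits / sum(credits)
  attr(ratios, "n_touches") <- n_touch
  attr(ratios, "n_credits") <- sum(credits)
  ratios
}

#' Full pad profile of a shape
#'
#' Convenience wrapper building the pad partition, the Monte Carlo baseline
#' ratios and the curvature scores in one data frame (pads indexed 0-5 to
#' match the touch-event format).
#'
#' @inheritParams monte_carlo_baseline
#' @param config A [metric_config()].
#' @export
pad_profile <- function(shape, params = touch_mc_params(), seed = 1L,
                        config = metric_config()) {
  pads <- partition_pads(shape)
  base <- monte_carlo_baseline(shape, pads, params, seed)
  data.frame(shape_id = shape$shape_id, pad = 0:(pads$n_pads - 1L),
             baseline_ratio = as.numeric(base),
             curvature = pad_curvature_scores(shape, pads, config),
             stringsAsFactors = FALSE)
}

#' Curvature enrichment of observed touches
#'
#' Compares observed per-pad touch ratios (duration-weighted by default)
#' with the Monte Carlo baseline, pad by pad and shape by shape, and
#' correlates the enrichment (observed / baseline) with the pad curvature
#' score across all pads of all shapes. Positive r means curved regions are
#' touched more than chance predicts.
#'
#' @param touches Touch-event table (`trial_id`, `pad_index`, `onset_ms`,
#'   `duration_ms`).
#' @param trials Trial table mapping `trial_id` to `current_shape_id`.
#' @param pad_profiles Named list of [pad_profile()] data frames.
#' @param weight `"duration"` (dwell-weighted) or `"count"`.
#' @return List with `pad_stats` (per shape x pad: baseline, observed,
#'   curvature, enrichment), `r` and `p_value`.
#' @export
touch_enrichment <- function(touches, trials, pad_profiles,
                             weight = c("duration", "count")) {
  weight <- match.arg(weight)
  if (!nrow(touches)) stopf("no touch events supplied")
  sid <- trials$current_shape_id[match(touches$trial_id, trials$trial_id)]
  if (anyNA(sid)) stopf("touch events reference unknown trials")
  w <- if (weight == "duration") touches$duration_ms else rep(1, nrow(touches))
  stats_list <- lapply(names(pad_profiles), function(id) {
    prof <- pad_profiles[[id]]
    sel <- sid == id
    if (!any(sel)) return(NULL)
    obs <- vapply(prof$pad, function(p)
      sum(w[sel & touches$pad_index == p]), 0)
    if (sum(obs) == 0) return(NULL)
    obs <- obs / sum(obs)
    cbind(prof, observed_ratio = obs,
          enrichment = ifelse(prof$baseline_ratio > 0,
                              obs / prof$baseline_ratio, NA_real_))
  })
  stats <- do.call(rbind, stats_list)
  if (anyNA(stats$enrichment)) {
    warning("pads with zero baseline ratio excluded from the correlation")
    stats_ok <- stats[!is.na(stats$enrichment), , drop = FALSE]
  } else stats_ok <- stats
  ct <- suppressWarnings(cor.test(stats_ok$curvature, stats_ok$enrichment))
  list(pad_stats = stats, r = unname(ct$estimate), p_value = ct$p.value)
}
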