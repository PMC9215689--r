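#' Generate one block of one-back trials
#'
#' A block holds 72 trials drawing on exactly 48 unique shapes, with 24 match
#' ("same") trials whose orientation change is 0/90/180 degrees in an 8:8:8
#' split (the 90 class split at random between +90 and -90). Alternating
#' blocks strictly alternate visual and haptic presentation. There is no cap
#' on consecutive same or different trials. The block-initial trial has no
#' referent and is labeled `warmup`; its nominal condition (used for design
#' tallies) is recorded separately.
#'
#' @param block_type `"visual_only"`, `"haptic_only"` or `"alternating"`.
#' @param shape_pool Character vector of shape ids, or a named list of
#'   [shape_outline()]s, of length >= 48.
#' @param block_id Integer label for the block.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return A 72-row data.frame of trials.
#' @export
generate_block <- function(block_type = c("visual_only", "haptic_only",
                                          "alternating"),
                           shape_pool, block_id = 1L, seed = NULL) {
  block_type <- match.arg(block_type)
  ids <- if (is.list(shape_pool)) names(shape_pool) else as.character(shape_pool)
  if (length(ids) < 48) stopf("shape pool must hold >= 48 shapes (got %d)",
                              length(ids))
  run <- function() {
    n_trials <- 72L
    is_match <- rep(FALSE, n_trials)
    is_match[sample(2:n_trials, 24L)] <- TRUE
    new_ids <- sample(ids, 48L)           # one per non-match trial (incl. trial 1)
    shape <- character(n_trials)
    k <- 0L
    for (i in seq_len(n_trials)) {
      if (i > 1 && is_match[i]) shape[i] <- shape[i - 1]
      else { k <- k + 1L; shape[i] <- new_ids[k] }
    }
    deltas <- sample(c(rep(0, 8), sample(c(-90, 90), 8, replace = TRUE),
                       rep(180, 8)))
    orient <- numeric(n_trials)
    dcls <- rep(NA_real_, n_trials)
    j <- 0L
    for (i in seq_len(n_trials)) {
      if (i > 1 && is_match[i]) {
        j <- j + 1L
        orient[i] <- (orient[i - 1] + deltas[j]) %% 360
        dcls[i] <- abs(deltas[j]) %% 360
      } else orient[i] <- sample(c(0, 90, 180, 270), 1)
    }
    modality <- switch(block_type,
      visual_only = rep("V", n_trials),
      haptic_only = rep("H", n_trials),
      alternating = rep(if (sample(c(TRUE, FALSE), 1)) c("V", "H") else c("H", "V"),
                        length.out = n_trials))
    prev_mod <- c(NA, modality[-n_trials])
    cond <- ifelse(is.na(prev_mod), "warmup",
                   paste0(prev_mod, modality))
    # nominal condition of the warmup trial: what its condition would be had
    # the block pattern already been running (used for the design tally)
    nominal <- cond
    nominal[1] <- switch(block_type,
      visual_only = "VV", haptic_only = "HH",
      alternating = paste0(if (modality[1] == "V") "H" else "V", modality[1]))
    data.frame(
      trial_id = NA_integer_, block_id = block_id, block_type = block_type,
      trial_in_block = seq_len(n_trials),
      condition = cond, nominal_condition = nominal,
      current_modality = modality, prev_modality = prev_mod,
      current_shape_id = shape, prev_shape_id = c(NA, shape[-n_trials]),
      current_orientation_deg = orient,
      prev_orientation_deg = c(NA, orient[-n_trials]),
      is_match = is_match, orientation_delta = dcls,
      response = NA_character_, rt_ms = NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  out
}

#' Generate a full one-back session
#'
#' Eight blocks - two visual-only, two haptic-only, four alternating - in a
#' permuted order, 72 trials each. Counting each block-initial warmup trial
#' under its nominal condition, the design yields exactly 144 trials per
#' condition (VV, HH, VH, HV), one third of them match trials.
#'
#' @inheritParams generate_block
#' @param seed Integer seed controlling the whole session.
#' @return A 576-row data.frame of trials with globally unique `trial_id`.
#' @export
generate_session <- function(shape_pool, seed = 1L) {
  run <- function() {
    types <- sample(c("visual_only", "visual_only", "haptic_only",
                      "haptic_only", rep("alternating", 4)))
    blocks <- lapply(seq_along(types), function(b)
      generate_block(types[b], shape_pool, block_id = b))
    out <- do.call(rbind, blocks)
    out$trial_id <- seq_len(nrow(out))
    out
  }
  with_seed(derive_seed(seed, 101L), run())
}

#' Synthetic observer parameters
#'
#' The observer responds "different" with probability
#' `(1 - lapse) * plogis(beta0 + sum_k beta_k * d_k) + lapse / 2`,
#' where `d_k` are dissimilarity-table columns. Weight names may end in
#' `"_@"` (e.g. `"hausdorff_@"`), in which case the variant (`actual` or
#' `optimal`) is resolved per trial from `mode_per_condition`.
#'
#' @param beta0 Intercept of the linear predictor.
#' @param weights Named numeric vector; names are dissimilarity columns or
#'   `"_@"` placeholders.
#' @param lapse Lapse rate in [0, 1]: probability of a uniform random guess.
#' @param mode_per_condition Named character vector mapping conditions
#'   (VV/HH/VH/HV) to `"actual"` or `"optimal"`; only needed with `"_@"`
#'   weight names.
#' @param standardize Z-score each referenced metric column over the
#'   analyzable trials before applying the weights (convenient when mixing
#'   metrics whose raw scales differ by orders of magnitude).
#' @export
observer_params <- function(beta0 = 0, weights = numeric(), lapse = 0,
                            mode_per_condition = NULL, standardize = FALSE) {
  if (lapse < 0 || lapse > 1) stopf("lapse must lie in [0, 1]")
  if (length(weights) && is.null(names(weights)))
    stopf("weights must be named by metric column")
  structure(list(beta0 = beta0, weights = weights, lapse = lapse,
                 mode_per_condition = mode_per_condition,
                 standardize = standardize),
            class = "observer_params")
}

#' Simulate observer responses for a session
#'
#' @param trials Trial table from [generate_session()].
#' @param dissim [compute_dissimilarity_table()] output for those trials.
#' @param params An [observer_params()].
#' @param seed Integer seed for response sampling.
#' @param rt_meanlog Optional meanlog (log ms) for log-normal reaction times;
#'   `NULL` leaves `rt_ms` as NA.
#' @return `trials` with the `response` column filled (`"same"`,
#'   `"different"`; warmup trials get `"none"`) and an attached
#'   `p_different` attribute.
#' @export
simulate_observer <- function(trials, dissim, params, seed = 1L,
                              rt_meanlog = NULL) {
  stopifnot(inherits(params, "observer_params"))
  use <- trials$condition != "warmup"
  d <- dissim[match(trials$trial_id[use], dissim$trial_id), , drop = FALSE]
  if (anyNA(d$trial_id)) stopf("dissimilarity row missing for some trials")

  wn <- names(params$weights)
  resolve <- function(nm, cond) {
    if (!endsWith(nm, "_@")) return(nm)
    base <- substr(nm, 1, nchar(nm) - 2)
    mpc <- as.list(params$mode_per_condition)
    if (!cond %in% names(mpc))
      stopf("no mode_per_condition entry for condition %s", cond)
    mode <- mpc[[cond]]
    paste0(base, "_", mode)
  }
  conds <- trials$condition[use]
  lp <- rep(params$beta0, sum(use))
  if (length(params$weights)) {
    for (k in seq_along(params$weights)) {
      cols <- vapply(conds, function(cc) resolve(wn[k], cc), "")
      miss <- setdiff(unique(cols), names(d))
      if (length(miss)) stopf("metric column(s) absent from table: %s",
                              paste(miss, collapse = ", "))
      vals <- vapply(seq_along(cols), function(i) d[[cols[i]]][i], 0)
      if (params$standardize) {
        mu <- mean(vals); sg <- sd(vals)
        vals <- if (sg > 0) (vals - mu) / sg else vals * 0
      }
      lp <- lp + params$weights[k] * vals
    }
  }
  p_diff <- (1 - params$lapse) * plogis(lp) + params$lapse / 2
  out <- trials
  out$response <- NA_character_
  out$response[!use] <- "none"
  draws <- with_seed(derive_seed(seed, 202L), runif(sum(use)))
  out$response[use] <- ifelse(draws < p_diff, "different", "same")
  if (!is.null(rt_meanlog)) {
    out$rt_ms[use] <- with_seed(derive_seed(seed, 203L),
                                rlnorm(sum(use), rt_meanlog, 0.4))
  }
  attr(out, "p_different") <- p_diff
  out
}

#' Sample pad visits with a curvature bias
#'
#' Visit probabilities are proportional to
#' `baseline_ratio * (1 + gamma * n(curvature))`, where `n()` centers the pad
#' curvature scores and scales them into (-0.455, 0.455) (deviation from the
#' shape's mean divided by 2.2 times the largest absolute deviation), so
#' every gain in `[-2.2, 2.2]` yields valid probabilities; `gamma = 0`
#' reduces to the Monte Carlo baseline.
#'
#' @param profile Data frame with columns `baseline_ratio` and `curvature`
#'   (one row per pad; see [pad_profile()]).
#' @param gamma Curvature gain; magnitudes beyond about 2.2 drive some pad
#'   probability to zero or below and raise an error.
#' @param n Number of visits to draw.
#' @return Integer vector of pad indices (0-based, length `n`).
#' @export
sample_pad_visits <- function(profile, gamma, n) {
  cz <- profile$curvature - mean(profile$curvature)
  if (max(abs(cz)) > 0) cz <- cz / (2.2 * max(abs(cz)))
  w <- profile$baseline_ratio * (1 + gamma * cz)
  if (any(w <= 0)) stopf("curvature gain %.3g yields nonpositive pad weight", gamma)
  sample.int(length(w), n, replace = TRUE, prob = w / sum(w)) - 1L
}

#' Simulate curvature-biased touch sequences
#'
#' For every haptic trial, a Poisson number of pad visits (mean
#' `mean_visits`, matching observed per-trial pad-touch counts) is sampled
#' with curvature-biased probabilities via [sample_pad_visits()]; dwell
#' durations are log-normal.
#'
#' @inheritParams simulate_observer
#' @param pad_profiles Named list (by shape id) of pad profile data frames
#'   with `baseline_ratio` and `curvature` columns (see [pad_profile()]).
#' @param gamma Curvature gain passed to [sample_pad_visits()].
#' @param mean_visits Mean pad visits per trial.
#' @param dwell_meanlog,dwell_sdlog Log-normal dwell-duration parameters
#'   (log ms).
#' @return Data frame with `trial_id`, `pad_index` (0-5), `onset_ms`,
#'   `duration_ms`.
#' @export
simulate_touch_sequences <- function(trials, pad_profiles, gamma = 0,
                                     seed = 1L, mean_visits = 12,
                                     dwell_meanlog = log(300),
                                     dwell_sdlog = 0.5) {
  hap <- trials[trials$current_modality == "H", , drop = FALSE]
  miss <- setdiff(unique(hap$current_shape_id), names(pad_profiles))
  if (length(miss)) stopf("pad profiles missing for shape(s): %s",
                          paste(miss, collapse = ", "))
  with_seed(derive_seed(seed, 303L), {
    rows <- lapply(seq_len(nrow(hap)), function(i) {
      nv <- max(1L, rpois(1, mean_visits))
      pads <- sample_pad_visits(pad_profiles[[hap$current_shape_id[i]]],
                                gamma, nv)
      dur <- rlnorm(nv, dwell_meanlog, dwell_sdlog)
      onset <- cumsum(c(0, dur[-nv] + 50))
      data.frame(trial_id = hap$trial_id[i], pad_index = pads,
                 onset_ms = onset, duration_ms = dur)
    })
    do.call(rbind, rows)
  })
}
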