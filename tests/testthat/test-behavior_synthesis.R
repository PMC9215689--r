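# Minimal synthetic trial/dissimilarity pair for observer-model tests that
# do not need real shapes: match trials get dissimilarity exactly 0.
fake_world <- function(n, seed = 1) {
  set.seed(seed)
  is_match <- runif(n) < 1 / 3
  tr <- data.frame(trial_id = seq_len(n), block_id = 1L,
                   block_type = "visual_only", condition = "VV",
                   nominal_condition = "VV", current_modality = "V",
                   prev_modality = "V",
                   current_shape_id = "a", prev_shape_id = "a",
                   current_orientation_deg = 0, prev_orientation_deg = 0,
                   is_match = is_match, orientation_delta = NA_real_,
                   response = NA_character_, rt_ms = NA_real_,
                   stringsAsFactors = FALSE)
  d <- data.frame(trial_id = seq_len(n),
                  compactness_sq_diff = ifelse(is_match, 0, abs(rnorm(n, 2, 1))),
                  random_u = runif(n))
  list(trials = tr, dissim = d)
}

accuracy_of <- function(tr) {
  u <- tr$response %in% c("same", "different")
  mean(ifelse(tr$is_match[u], tr$response[u] == "same",
              tr$response[u] == "different"))
}

test_that("block design counts hold for every seed", {
  pool <- sprintf("s%02d", 1:48)
  for (seed in 1:5) {
    b <- generate_block("alternating", pool, seed = seed)
    expect_identical(nrow(b), 72L)
    expect_identical(sum(b$is_match), 24L)
    expect_identical(length(unique(b$current_shape_id)), 48L)
    deltas <- table(b$orientation_delta[b$is_match])
    expect_identical(as.integer(deltas[c("0", "90", "180")]), c(8L, 8L, 8L))
    expect_true(all(b$current_modality == rep(b$current_modality[1:2],
                                              length.out = 72)))
    expect_true(all(b$current_modality[1:2] %in% c("V", "H")))
    # match trials repeat the previous shape; different trials never do
    expect_true(all((b$current_shape_id == b$prev_shape_id)[-1] == b$is_match[-1]))
  }
  expect_error(generate_block("visual_only", pool[1:30]), "48")
})

test_that("session design: 8 blocks, 144 per condition, 2/3 nonmatch", {
  tr <- shared_session()
  expect_identical(nrow(tr), 576L)
  expect_identical(length(unique(tr$block_id)), 8L)
  expect_identical(as.integer(table(tr$nominal_condition)[c("VV", "HH", "VH", "HV")]),
                   rep(144L, 4))
  types <- unique(tr[, c("block_id", "block_type")])$block_type
  expect_identical(sum(types == "visual_only"), 2L)
  expect_identical(sum(types == "haptic_only"), 2L)
  expect_identical(sum(types == "alternating"), 4L)
  per_block_nonmatch <- tapply(!tr$is_match, tr$block_id, sum)
  expect_true(all(per_block_nonmatch == 48))
  expect_identical(generate_session(sprintf("s%02d", 1:48), seed = 9),
                   generate_session(sprintf("s%02d", 1:48), seed = 9))
})

test_that("lapse-1 observer is a coin flip; base-rate responder tracks 2/3", {
  w <- fake_world(10000, seed = 2)
  coin <- simulate_observer(w$trials, w$dissim, observer_params(lapse = 1),
                            seed = 3)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(accuracy_of(coin) - 0.5), 3 * se)

  # a strongly positive intercept saturates the logistic (at +10 a handful
  # of 10,000 draws can still flip; +40 is 1 to double precision)
  always_diff <- simulate_observer(
    w$trials, w$dissim, observer_params(beta0 = 40, lapse = 0), seed = 3)
  expect_true(all(always_diff$response == "different"))
  expect_equal(accuracy_of(always_diff), mean(!w$trials$is_match),
               tolerance = 1e-12)
})

test_that("metric-driven observer: near-perfect hits at beta0 = -4", {
  w <- fake_world(6000, seed = 4)
  obs <- observer_params(beta0 = -4, weights = c(compactness_sq_diff = 6),
                         lapse = 0)
  tr <- simulate_observer(w$trials, w$dissim, obs, seed = 5)
  hit <- mean(tr$response[tr$is_match] == "same")
  # on match trials d = 0 so p(different) = plogis(-4) = 0.018
  expect_gt(hit, 0.95)
  p <- attr(tr, "p_different")
  expect_equal(unique(p[w$trials$is_match]), plogis(-4), tolerance = 1e-12)
})

test_that("accuracy is monotone nonincreasing in the lapse rate", {
  w <- fake_world(10000, seed = 6)
  acc <- vapply(c(0, 0.25, 0.5, 1), function(eps) {
    obs <- observer_params(beta0 = -2, weights = c(compactness_sq_diff = 3),
                           lapse = eps)
    accuracy_of(simulate_observer(w$trials, w$dissim, obs, seed = 7))
  }, 0)
  expect_true(all(diff(acc) <= 0.02))   # binomial noise allowance
  expect_gt(acc[1], 0.85)
})

test_that("p(different) is monotone in a singly weighted metric", {
  w <- fake_world(2000, seed = 8)
  obs <- observer_params(beta0 = -1, weights = c(compactness_sq_diff = 2),
                         lapse = 0.1)
  tr <- simulate_observer(w$trials, w$dissim, obs, seed = 9)
  p <- attr(tr, "p_different")
  d <- w$dissim$compactness_sq_diff
  expect_true(all(diff(p[order(d)]) >= -1e-12))
})

test_that("observer errors on absent metric columns", {
  w <- fake_world(100, seed = 10)
  obs <- observer_params(weights = c(no_such_metric = 1))
  expect_error(simulate_observer(w$trials, w$dissim, obs), "no_such_metric")
})

test_that("mode_per_condition resolves @ placeholders per trial", {
  w <- fake_world(200, seed = 11)
  w$dissim$hausdorff_actual <- abs(rnorm(200))
  w$dissim$hausdorff_optimal <- abs(rnorm(200))
  obs <- observer_params(beta0 = 0, weights = c("hausdorff_@" = 1),
                         mode_per_condition = c(VV = "actual"))
  tr <- simulate_observer(w$trials, w$dissim, obs, seed = 12)
  expect_equal(attr(tr, "p_different"),
               plogis(w$dissim$hausdorff_actual), tolerance = 1e-12)
  obs2 <- observer_params(beta0 = 0, weights = c("hausdorff_@" = 1),
                          mode_per_condition = c(HH = "actual"))
  expect_error(simulate_observer(w$trials, w$dissim, obs2), "VV")
})

test_that("touch sequences: determinism and curvature-gain validation", {
  prof <- data.frame(shape_id = "a", pad = 0:5,
                     baseline_ratio = rep(1 / 6, 6),
                     curvature = c(1, 2, 3, 4, 5, 6))
  tr <- data.frame(trial_id = 1:4, current_modality = "H",
                   current_shape_id = "a", stringsAsFactors = FALSE)
  t1 <- simulate_touch_sequences(tr, list(a = prof), gamma = 0.5, seed = 13)
  t2 <- simulate_touch_sequences(tr, list(a = prof), gamma = 0.5, seed = 13)
  expect_identical(t1, t2)
  expect_true(all(t1$pad_index %in% 0:5))
  expect_true(all(t1$duration_ms > 0))
  expect_error(sample_pad_visits(prof, gamma = -3, 10), "nonpositive")
})
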