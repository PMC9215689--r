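logistic_data <- function(n, beta0, beta1, seed) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(beta0 + beta1 * x))
  data.frame(x = x, y = y)
}

test_that("null-model AIC matches the closed form on balanced data", {
  y <- rep(c(0, 1), 50)
  fit <- fit_binomial_glm(y)
  expect_equal(fit$log_likelihood, 100 * log(0.5), tolerance = 1e-9)
  expect_equal(fit$aic, 2 - 2 * 100 * log(0.5), tolerance = 1e-9)
  expect_identical(fit$k, 1L)
})

test_that("AIC identity and label-flip symmetry hold", {
  d <- logistic_data(400, -0.5, 1, seed = 1)
  fit <- fit_binomial_glm(d$y, d["x"])
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$log_likelihood, tolerance = 1e-9)
  flip <- fit_binomial_glm(1 - d$y, d["x"])
  expect_equal(flip$aic, fit$aic, tolerance = 1e-6)
  expect_equal(unname(flip$coefficients), -unname(fit$coefficients),
               tolerance = 1e-4)
})

test_that("coefficients are recovered within 3 SE at n = 5000", {
  d <- logistic_data(5000, 0.3, 0.8, seed = 2)
  fit <- fit_binomial_glm(d$y, d["x"])
  # predictor is standardized internally; x already ~ N(0,1) so the slope
  # target is beta1 * sd(x)
  expect_lt(abs(fit$coefficients[1] - 0.3), 3 * fit$se[1])
  expect_lt(abs(fit$coefficients[2] - 0.8 * sd(d$x)), 3 * fit$se[2])
  expect_true(fit$converged)
})

test_that("separation is flagged, constant predictors error", {
  x <- c(rep(-1, 30), rep(1, 30))
  y <- c(rep(0, 30), rep(1, 30))
  fit <- fit_binomial_glm(y, data.frame(x = x))
  expect_false(fit$converged)
  expect_error(fit_binomial_glm(y, data.frame(x = rep(1, 60))), "constant")
  expect_error(fit_binomial_glm(y, data.frame(x = c(Inf, x[-1]))), "finite")
})

test_that("evaluate_metrics ranks deterministically and ignores affine scaling", {
  dt <- shared_dissim()
  tr <- simulate_observer(shared_session(), dt,
                          observer_params(beta0 = 0,
                                          weights = c(turning_distance = 2),
                                          lapse = 0.1, standardize = TRUE),
                          seed = 21)
  r1 <- evaluate_metrics(dt, tr, "all")
  r2 <- evaluate_metrics(dt, tr, "all")
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(r1$metric[1], "turning_distance")
  expect_true(r1$predictive[1])
  expect_identical(r1$delta_aic_vs_best[1], 0)
  expect_true(all(diff(r1$aic) >= 0))

  dt_scaled <- dt
  dt_scaled$turning_distance <- 1000 * dt_scaled$turning_distance + 5
  r3 <- evaluate_metrics(dt_scaled, tr, "all")
  expect_equal(r3$aic, r1$aic, tolerance = 1e-6)
})

test_that("per-condition evaluation warns when trials are scarce", {
  dt <- shared_dissim()
  tr <- simulate_observer(shared_session(), dt,
                          observer_params(lapse = 1), seed = 22)
  vv <- tr[tr$condition == "VV", ]
  small <- vv[seq_len(45), ]     # enough per-fit observations, below 50
  expect_warning(evaluate_metrics(dt, small, "VV"), "usable")
})

test_that("stepwise selection recovers the generating factors", {
  set.seed(30)
  hits2 <- hits1 <- 0L
  for (rep in 1:8) {
    n <- 1500
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    d$trial_id <- seq_len(n)
    tr <- data.frame(trial_id = seq_len(n), condition = "VV",
                     is_match = FALSE, stringsAsFactors = FALSE)
    y2 <- rbinom(n, 1, plogis(0.9 * d$x1 + 0.9 * d$x2))
    tr$response <- ifelse(y2 == 1, "different", "same")
    sel <- select_multimetric(d, tr, "all", candidates = c("x1", "x2", "x3"))
    if (setequal(sel$metrics, c("x1", "x2"))) hits2 <- hits2 + 1L
    y1 <- rbinom(n, 1, plogis(1.2 * d$x1))
    tr$response <- ifelse(y1 == 1, "different", "same")
    sel1 <- select_multimetric(d, tr, "all", candidates = c("x1", "x2", "x3"))
    if (identical(sel1$metrics, "x1")) hits1 <- hits1 + 1L
  }
  expect_gte(hits2, 6L)
  expect_gte(hits1, 7L)
})

test_that("stepwise stops at the base model when nothing improves by 3", {
  set.seed(31)
  n <- 800
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), trial_id = seq_len(n))
  tr <- data.frame(trial_id = seq_len(n), condition = "VV", is_match = FALSE,
                   response = ifelse(rbinom(n, 1, plogis(1.5 * d$x1)) == 1,
                                     "different", "same"),
                   stringsAsFactors = FALSE)
  sel <- select_multimetric(d, tr, "all", candidates = c("x1", "x2"))
  expect_identical(sel$metrics, "x1")
  expect_identical(sel$fit$k, 2L)
})

test_that("actual-vs-optimal contrast points toward the generating variant", {
  dt <- shared_dissim()
  wins_actual <- wins_optimal <- 0L
  for (s in 1:6) {
    tr_a <- simulate_observer(shared_session(), dt,
      observer_params(beta0 = 0, weights = c(hausdorff_actual = 2.5),
                      lapse = 0.1, standardize = TRUE), seed = 40 + s)
    ca <- actual_vs_optimal_contrast(dt, tr_a, "all")
    if (ca$delta_aic[ca$metric == "hausdorff"] > 0) wins_actual <- wins_actual + 1L
    tr_o <- simulate_observer(shared_session(), dt,
      observer_params(beta0 = 0, weights = c(hausdorff_optimal = 2.5),
                      lapse = 0.1, standardize = TRUE), seed = 60 + s)
    co <- actual_vs_optimal_contrast(dt, tr_o, "all")
    if (co$delta_aic[co$metric == "hausdorff"] < 0) wins_optimal <- wins_optimal + 1L
  }
  expect_gte(wins_actual, 5L)
  expect_gte(wins_optimal, 5L)
})

test_that("binned accuracy curve: monotone observer, null observer, errors", {
  set.seed(50)
  n <- 2000
  d <- data.frame(trial_id = seq_len(n), m = runif(n, 0, 4))
  tr <- data.frame(trial_id = seq_len(n), condition = "VV", is_match = FALSE,
                   response = ifelse(rbinom(n, 1, plogis(-2 + 1.5 * d$m)) == 1,
                                     "different", "same"),
                   stringsAsFactors = FALSE)
  bc <- binned_accuracy_curve(d, tr, "m", n_bins = 10)
  expect_gt(bc$r, 0.8)
  expect_length(bc$bin_center, 10)

  tr$response <- sample(c("same", "different"), n, replace = TRUE)
  bc0 <- binned_accuracy_curve(d, tr, "m", n_bins = 10)
  expect_lt(abs(bc0$r), 0.9)        # no systematic relation
  expect_error(binned_accuracy_curve(d, tr, "m", n_bins = 1), "n_bins")
})

test_that("behavior summary: d-prime fixtures and extreme-rate correction", {
  expect_equal(dprime(0.5, 0.5), 0)
  expect_equal(dprime(0.84, 0.16), 2 * qnorm(0.84), tolerance = 1e-9)
  expect_equal(dprime(0.84, 0.16), 1.989, tolerance = 1e-3)

  mk <- function(resp_match, resp_nonmatch) {
    nm <- 48; nn <- 96
    data.frame(trial_id = 1:(nm + nn), condition = "HH",
               is_match = c(rep(TRUE, nm), rep(FALSE, nn)),
               response = c(rep(resp_match, nm), rep(resp_nonmatch, nn)),
               rt_ms = NA_real_, stringsAsFactors = FALSE)
  }
  perfect <- suppressWarnings(behavior_summary(mk("same", "different")))
  expect_true(is.finite(perfect$d_prime))
  expect_equal(perfect$d_prime, qnorm(1 - 1 / 96) - qnorm(1 / 192),
               tolerance = 1e-9)
  expect_equal(perfect$percent_correct, 100)
  expect_warning(behavior_summary(mk("same", "different")), "omitted")
})
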