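#' Fit a binomial GLM predicting choices from dissimilarity metrics
#'
#' Maximum-likelihood logistic regression (IRLS, convergence 1e-8) of a
#' binary response on one or more metric columns, each standardized to zero
#' mean and unit variance before fitting. The AIC is `2k - 2 lnL` with
#' `k = 1 + #predictors`.
#'
#' @param responses Logical or 0/1 vector (1 = responded "different").
#' @param predictors Data frame (or named matrix) of metric columns.
#' @return An object of class `model_fit` with fields `metric_names`,
#'   `coefficients`, `log_likelihood`, `k`, `aic`, `n_obs`, `converged`.
#' @export
fit_binomial_glm <- function(responses, predictors = NULL) {
  y <- as.numeric(responses)
  if (!all(y %in% c(0, 1))) stopf("responses must be binary")
  if (is.null(predictors) || NCOL(predictors) == 0) {
    df <- data.frame(y = y)
    form <- y ~ 1
    nms <- character()
  } else {
    X <- as.data.frame(predictors)
    if (!all(vapply(X, function(v) all(is.finite(v)), TRUE)))
      stopf("predictors must be finite")
    sds <- vapply(X, sd, 0)
    if (any(sds == 0))
      stopf("constant predictor column(s): %s",
            paste(names(X)[sds == 0], collapse = ", "))
    X <- as.data.frame(scale(X))
    nms <- names(X)
    df <- cbind(y = y, X)
    form <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", nms),
                                                 collapse = " + ")))
  }
  k <- 1L + length(nms)
  if (length(y) < 10 * k)
    warning(sprintf("only %d observations for %d parameters", length(y), k))
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = df, family = binomial(),
        control = list(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  # glm does not always warn under complete separation: also flag fits whose
  # fitted probabilities are all numerically 0/1 (deterministic prediction)
  fv <- fit$fitted.values
  if (length(nms) && all(fv < 1e-6 | fv > 1 - 1e-6)) separated <- TRUE
  ll <- as.numeric(logLik(fit))
  structure(list(metric_names = nms, coefficients = coef(fit),
                 se = sqrt(diag(stats::vcov(fit))),
                 log_likelihood = ll, k = k, aic = 2 * k - 2 * ll,
                 n_obs = length(y),
                 converged = fit$converged && !separated),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("<model_fit k=%d lnL=%.3f AIC=%.3f n=%d%s>\n  predictors: %s\n",
              x$k, x$log_likelihood, x$aic, x$n_obs,
              if (x$converged) "" else " NOT CONVERGED",
              if (length(x$metric_names)) paste(x$metric_names, collapse = ", ")
              else "(intercept only)"))
  invisible(x)
}

# filter to analyzable trials of a condition and join with the metric table
usable_rows <- function(dissim, trials, condition) {
  keep <- trials$condition != "warmup" &
    trials$response %in% c("same", "different")
  if (!identical(condition, "all"))
    keep <- keep & trials$condition == condition
  tr <- trials[keep, , drop = FALSE]
  if (!nrow(tr)) stopf("no usable trials for condition %s", condition)
  d <- dissim[match(tr$trial_id, dissim$trial_id), , drop = FALSE]
  if (anyNA(d$trial_id)) stopf("dissimilarity rows missing for some trials")
  list(trials = tr, dissim = d, y = as.numeric(tr$response == "different"))
}

#' Rank metrics by single-predictor GLM AIC
#'
#' Fits one binomial GLM per metric column (plus the stored `random_u`
#' baseline) on the requested condition's analyzable trials and ranks them
#' by AIC. A metric is flagged predictive when it beats the random baseline
#' by at least 3 AIC units. Ties are broken by metric name.
#'
#' @param dissim A [compute_dissimilarity_table()] result.
#' @param trials Trial table with responses filled in.
#' @param condition One of `"VV"`, `"HH"`, `"VH"`, `"HV"`, or `"all"` to pool.
#' @param metrics Metric columns to evaluate (default all eleven).
#' @return A data.frame of class `metric_ranking` sorted by AIC ascending,
#'   with columns `metric`, `aic`, `delta_aic_vs_random`, `delta_aic_vs_best`
#'   and `predictive`; fits are attached as attribute `fits`.
#' @export
evaluate_metrics <- function(dissim, trials, condition = "all",
                             metrics = metric_columns()) {
  u <- usable_rows(dissim, trials, condition)
  if (length(u$y) < 50)
    warning(sprintf("only %d usable trials for condition %s", length(u$y),
                    condition))
  all_m <- c(metrics, "random_u")
  fits <- lapply(all_m, function(m)
    fit_binomial_glm(u$y, u$dissim[, m, drop = FALSE]))
  names(fits) <- all_m
  aic <- vapply(fits, `[[`, 0, "aic")
  random_aic <- aic[["random_u"]]
  out <- data.frame(metric = all_m, aic = unname(aic),
                    stringsAsFactors = FALSE)
  out <- out[order(out$aic, out$metric), , drop = FALSE]
  out$delta_aic_vs_random <- out$aic - random_aic
  out$delta_aic_vs_best <- out$aic - out$aic[1]
  out$predictive <- (random_aic - out$aic) >= 3
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "condition") <- condition
  class(out) <- c("metric_ranking", "data.frame")
  out
}

#' Forward stepwise multimetric selection
#'
#' Starting from the best single metric (by AIC), repeatedly adds the
#' candidate producing the largest AIC decrease; stops when no addition
#' improves the AIC by at least 3 units, returning the model with the fewest
#' variables not improved by that margin.
#'
#' @inheritParams evaluate_metrics
#' @param candidates Candidate metric columns.
#' @return List with `metrics` (selected columns in inclusion order) and
#'   `fit` (the final [fit_binomial_glm()] object).
#' @export
select_multimetric <- function(dissim, trials, condition = "all",
                               candidates = metric_columns()) {
  u <- usable_rows(dissim, trials, condition)
  bad <- setdiff(candidates, names(u$dissim))
  if (length(bad)) stopf("unknown candidate column(s): %s",
                         paste(bad, collapse = ", "))
  singles <- vapply(candidates, function(m)
    fit_binomial_glm(u$y, u$dissim[, m, drop = FALSE])$aic, 0)
  chosen <- candidates[order(singles, candidates)[1]]
  best <- fit_binomial_glm(u$y, u$dissim[, chosen, drop = FALSE])
  repeat {
    rest <- setdiff(candidates, chosen)
    if (!length(rest)) break
    trial_aic <- vapply(rest, function(m)
      fit_binomial_glm(u$y, u$dissim[, c(chosen, m), drop = FALSE])$aic, 0)
    m_star <- rest[order(trial_aic, rest)[1]]
    if (best$aic - min(trial_aic) < 3) break
    chosen <- c(chosen, m_star)
    best <- fit_binomial_glm(u$y, u$dissim[, chosen, drop = FALSE])
  }
  list(metrics = chosen, fit = best)
}

#' AIC contrast between @optimal and @actual metric variants
#'
#' For each metric computed both ways (aspect ratio, IoU, Hausdorff), fits
#' single-predictor GLMs with each variant and reports
#' `AIC(@optimal) - AIC(@actual)`: negative values favor the
#' rotation-optimized (mental rotation) variant, positive values the
#' presented-orientation variant.
#'
#' @inheritParams evaluate_metrics
#' @return Data frame with one row per paired metric.
#' @export
actual_vs_optimal_contrast <- function(dissim, trials, condition = "all") {
  u <- usable_rows(dissim, trials, condition)
  pairs <- list(aspect_ratio = c("aspect_ratio_sq_diff_actual",
                                 "aspect_ratio_sq_diff_optimal"),
                iou = c("iou_actual", "iou_optimal"),
                hausdorff = c("hausdorff_actual", "hausdorff_optimal"))
  rows <- lapply(names(pairs), function(nm) {
    a <- fit_binomial_glm(u$y, u$dissim[, pairs[[nm]][1], drop = FALSE])$aic
    o <- fit_binomial_glm(u$y, u$dissim[, pairs[[nm]][2], drop = FALSE])$aic
    data.frame(metric = nm, aic_actual = a, aic_optimal = o,
               delta_aic = o - a, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Accuracy as a function of binned dissimilarity
#'
#' On nonmatch trials only, bins the chosen metric into equal-count bins and
#' computes the proportion of correct "different" responses per bin, plus
#' the Pearson correlation between bin centers and proportions.
#'
#' @inheritParams evaluate_metrics
#' @param metric Metric column to bin on.
#' @param n_bins Number of equal-count bins (>= 3).
#' @return List with `bin_center`, `p_correct`, `n_per_bin`, `r`, `p_value`.
#' @export
binned_accuracy_curve <- function(dissim, trials, metric, condition = "all",
                                  n_bins = 10L) {
  if (n_bins < 3) stopf("n_bins must be >= 3")
  u <- usable_rows(dissim, trials, condition)
  nm <- !u$trials$is_match
  v <- u$dissim[[metric]][nm]
  if (is.null(v)) stopf("unknown metric column %s", metric)
  correct <- u$y[nm]                       # "different" is correct on nonmatch
  if (length(unique(v)) < n_bins)
    stopf("metric %s has too few distinct values for %d bins", metric, n_bins)
  qs <- quantile(v, probs = seq(0, 1, length.out = n_bins + 1), type = 7)
  qs[1] <- -Inf; qs[n_bins + 1] <- Inf
  bin <- cut(v, breaks = unique(qs), labels = FALSE, include.lowest = TRUE)
  center <- tapply(v, bin, mean)
  pc <- tapply(correct, bin, mean)
  ct <- suppressWarnings(cor.test(center, pc))
  list(bin_center = as.numeric(center), p_correct = as.numeric(pc),
       n_per_bin = as.numeric(table(bin)), r = unname(ct$estimate),
       p_value = ct$p.value)
}

#' Signal-detection sensitivity
#'
#' `d' = z(hit rate) - z(false-alarm rate)`.
#'
#' @param hit_rate,fa_rate Rates in (0, 1).
#' @export
dprime <- function(hit_rate, fa_rate) qnorm(hit_rate) - qnorm(fa_rate)

#' Per-condition behavior summary
#'
#' Percent correct, hit rate ("same" response on a match trial), false-alarm
#' rate ("same" on a nonmatch trial), d-prime and median RT per condition.
#' Extreme rates (0 or 1) are corrected by the 1/(2N) rule before the
#' z-transform so d-prime stays finite.
#'
#' @param trials Trial table with responses.
#' @return Data frame, one row per condition present.
#' @export
behavior_summary <- function(trials) {
  use <- trials[trials$condition != "warmup" &
                  trials$response %in% c("same", "different"), , drop = FALSE]
  conds <- intersect(c("VV", "HH", "VH", "HV"), unique(use$condition))
  skipped <- setdiff(c("VV", "HH", "VH", "HV"), conds)
  if (length(skipped))
    warning(sprintf("condition(s) with zero trials omitted: %s",
                    paste(skipped, collapse = ", ")))
  rows <- lapply(conds, function(cc) {
    tr <- use[use$condition == cc, , drop = FALSE]
    correct <- ifelse(tr$is_match, tr$response == "same",
                      tr$response == "different")
    nm <- sum(tr$is_match); nn <- sum(!tr$is_match)
    hit <- mean(tr$response[tr$is_match] == "same")
    fa <- mean(tr$response[!tr$is_match] == "same")
    clamp <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
    data.frame(condition = cc, n_trials = nrow(tr),
               percent_correct = 100 * mean(correct),
               hit_rate = hit, false_alarm_rate = fa,
               d_prime = dprime(clamp(hit, nm), clamp(fa, nn)),
               median_rt_ms = if (all(is.na(tr$rt_ms))) NA_real_
                              else median(tr$rt_ms, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
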