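## File formats, run configuration and the end-to-end pipeline.
## All artifacts are plain CSV/JSON; numeric fields are serialized at full
## double precision (%.17g) so read(write(x)) round-trips exactly.

fmt_full <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      v <- sprintf("%.17g", df[[nm]])
      v[is.na(df[[nm]])] <- NA_character_
      df[[nm]] <- v
    }
  }
  df
}

write_csv_full <- function(df, path) {
  write.csv(fmt_full(df), path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

read_csv_checked <- function(path, required, numeric_cols = character()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stopf("%s: missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  for (nm in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (any(is.na(v) & !(is.na(df[[nm]]) | df[[nm]] == "")))
      stopf("%s: non-numeric value in column %s", path, nm)
    df[[nm]] <- v
  }
  df
}

#' Write / read a stimulus shape set
#'
#' The point file has columns `shape_id,point_index,x_mm,y_mm`; the manifest
#' records `shape_id`, `seed`, `n_blobs`, `perimeter_mm`.
#'
#' @param shapes Named list of [shape_outline()]s (with `manifest` attribute,
#'   as from [generate_shape_set()]).
#' @param dir Output directory (created if needed).
#' @return `write_shape_set` returns the directory; `read_shape_set` the
#'   shape list with manifest attribute.
#' @export
write_shape_set <- function(shapes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pts <- do.call(rbind, lapply(shapes, function(s)
    data.frame(shape_id = s$shape_id, point_index = seq_len(nrow(s$points)),
               x_mm = s$points[, 1], y_mm = s$points[, 2],
               stringsAsFactors = FALSE)))
  write_csv_full(pts, file.path(dir, "shapes.csv"))
  man <- attr(shapes, "manifest") %||%
    data.frame(shape_id = vapply(shapes, `[[`, "", "shape_id"),
               seed = NA_integer_, n_blobs = NA_integer_,
               perimeter_mm = vapply(shapes, `[[`, 0, "perimeter_mm"))
  write_csv_full(man, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' @rdname write_shape_set
#' @export
read_shape_set <- function(dir) {
  pts <- read_csv_checked(file.path(dir, "shapes.csv"),
                          c("shape_id", "point_index", "x_mm", "y_mm"),
                          c("point_index", "x_mm", "y_mm"))
  man <- read_csv_checked(file.path(dir, "manifest.csv"),
                          c("shape_id"), c("seed", "n_blobs", "perimeter_mm"))
  ids <- unique(pts$shape_id)
  shapes <- lapply(ids, function(id) {
    p <- pts[pts$shape_id == id, , drop = FALSE]
    p <- p[order(p$point_index), , drop = FALSE]
    shape_outline(cbind(p$x_mm, p$y_mm), shape_id = id, validate = FALSE)
  })
  names(shapes) <- ids
  attr(shapes, "manifest") <- man
  shapes
}

#' Write / read a trial table
#'
#' @param trials Trial data frame (see [generate_block()] for the columns).
#' @param path CSV path.
#' @export
write_trials <- function(trials, path) write_csv_full(trials, path)

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read_csv_checked(path,
    c("trial_id", "block_id", "block_type", "condition", "current_shape_id",
      "prev_shape_id", "current_orientation_deg", "prev_orientation_deg",
      "is_match"),
    c("trial_id", "block_id", "current_orientation_deg",
      "prev_orientation_deg", "orientation_delta", "rt_ms"))
  df$is_match <- as.logical(df$is_match)
  df
}

#' Write / read a dissimilarity table
#'
#' @param dissim A [compute_dissimilarity_table()] result.
#' @param path CSV path.
#' @export
write_dissim <- function(dissim, path) write_csv_full(as.data.frame(dissim), path)

#' @rdname write_dissim
#' @export
read_dissim <- function(path) {
  df <- read_csv_checked(path, c("trial_id", metric_columns(TRUE)),
                         c("trial_id", metric_columns(TRUE)))
  class(df) <- c("dissimilarity_table", "data.frame")
  df
}

#' Write / read a touch-event table
#' @param touches Touch events (`trial_id`, `pad_index`, `onset_ms`,
#'   `duration_ms`).
#' @param path CSV path.
#' @export
write_touches <- function(touches, path) write_csv_full(touches, path)

#' @rdname write_touches
#' @export
read_touches <- function(path) {
  read_csv_checked(path, c("trial_id", "pad_index", "onset_ms", "duration_ms"),
                   c("trial_id", "pad_index", "onset_ms", "duration_ms"))
}

#' Write a metric ranking (sorted by AIC ascending)
#' @param ranking An [evaluate_metrics()] result.
#' @param path CSV path.
#' @export
write_ranking <- function(ranking, path) {
  df <- as.data.frame(ranking)
  write_csv_full(df[order(df$aic, df$metric), , drop = FALSE], path)
}

#' Run configuration for the end-to-end pipeline
#'
#' Bundles the per-module configurations. Every stage seed is derived
#' deterministically from the global `seed`.
#'
#' @param seed Global integer seed.
#' @param out_dir Output directory.
#' @param n_shapes Stimulus pool size.
#' @param generator A [generator_config()] (its `seed` field is overridden).
#' @param metric A [metric_config()].
#' @param observer An [observer_params()].
#' @param touch A [touch_mc_params()].
#' @param gamma Curvature gain of the simulated toucher.
#' @param run_touch Run the touch-baseline stage (the slowest one).
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("shapeback_run_"),
                       n_shapes = 48L,
                       generator = generator_config(),
                       metric = metric_config(),
                       observer = observer_params(
                         beta0 = 0.5,
                         weights = c(curvature_cdf_sse = 2),
                         lapse = 0.05, standardize = TRUE),
                       touch = touch_mc_params(),
                       gamma = 1, run_touch = TRUE) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(metric, "metric_config"),
            inherits(observer, "observer_params"),
            inherits(touch, "touch_mc_params"))
  if (n_shapes < 48) stopf("n_shapes must be >= 48 for the session design")
  generator$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_shapes = as.integer(n_shapes), generator = generator,
                 metric = metric, observer = observer, touch = touch,
                 gamma = gamma, run_touch = run_touch),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Generate shapes, simulate a session and observer, compute the
#' dissimilarity table, rank metrics for every condition, and (optionally)
#' run the Monte Carlo touch analysis. All artifacts and a manifest (inputs,
#' stage seeds, output hashes) are written under `config$out_dir`; a fixed
#' seed reproduces identical files.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stopf("pipeline stage '%s' failed (seed %d): %s", name, config$seed,
            conditionMessage(e)))
  }
  shapes <- stage("generate-shapes", function()
    generate_shape_set(config$n_shapes, config$generator))
  stage("write-shapes", function()
    write_shape_set(shapes, file.path(config$out_dir, "shapes")))
  trials <- stage("simulate-session", function()
    generate_session(names(shapes), seed = config$seed))
  dissim <- stage("compute-metrics", function()
    compute_dissimilarity_table(trials, shapes, config$metric,
                                seed = config$seed))
  trials <- stage("simulate-observer", function()
    simulate_observer(trials, dissim, config$observer, seed = config$seed))
  stage("write-trials", function()
    write_trials(trials, file.path(config$out_dir, "trials.csv")))
  stage("write-dissim", function()
    write_dissim(dissim, file.path(config$out_dir, "dissimilarities.csv")))
  stage("evaluate-metrics", function() {
    for (cc in c("VV", "HH", "VH", "HV")) {
      rk <- evaluate_metrics(dissim, trials, cc)
      write_ranking(rk, file.path(config$out_dir,
                                  sprintf("ranking_%s.csv", cc)))
    }
    sel <- select_multimetric(dissim, trials, "all")
    jsonlite::write_json(
      list(metrics = sel$metrics,
           aic = sel$fit$aic, log_likelihood = sel$fit$log_likelihood,
           k = sel$fit$k, n_obs = sel$fit$n_obs),
      file.path(config$out_dir, "multimetric.json"),
      auto_unbox = TRUE, digits = NA)
    bs <- behavior_summary(trials)
    write_csv_full(bs, file.path(config$out_dir, "behavior_summary.csv"))
  })
  if (config$run_touch) {
    stage("touch-mc", function() {
      hap_ids <- unique(trials$current_shape_id[trials$current_modality == "H"])
      profs <- lapply(hap_ids, function(id)
        pad_profile(shapes[[id]], config$touch,
                    seed = derive_seed(config$seed, 500L), config$metric))
      names(profs) <- hap_ids
      touches <- simulate_touch_sequences(trials, profs, config$gamma,
                                          seed = config$seed)
      write_touches(touches, file.path(config$out_dir, "touches.csv"))
      enr <- touch_enrichment(touches, trials, profs)
      write_csv_full(enr$pad_stats, file.path(config$out_dir, "pad_stats.csv"))
      jsonlite::write_json(list(r = enr$r, p_value = enr$p_value,
                                gamma = config$gamma),
                           file.path(config$out_dir, "touch_enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  }
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "run_manifest.json"))
  manifest <- list(
    seed = config$seed,
    n_shapes = config$n_shapes,
    gamma = config$gamma,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
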