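# Shared expensive fixtures, generated once per test run and memoised.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

shared_shapes <- function() fixture("shapes48", function()
  generate_shape_set(48, generator_config(seed = 3)))

shared_session <- function() fixture("session", function()
  generate_session(names(shared_shapes()), seed = 7))

shared_dissim <- function() fixture("dissim", function()
  compute_dissimilarity_table(shared_session(), shared_shapes(),
                              fast_metric_config(), seed = 7))

shared_pad_profiles <- function() fixture("pad_profiles4", function() {
  shapes <- shared_shapes()[1:4]
  out <- lapply(shapes, pad_profile,
                params = touch_mc_params(n_samples = 20000), seed = 9)
  names(out) <- names(shapes)
  out
})
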