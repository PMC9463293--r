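# Shared fixtures: small generator configurations and helpers used across
# test files. Everything is generated in code; no stored data.

# Short recordings (0.2 + 1 + 0.2 s) for fast structural tests; any
# default can be overridden.
tiny_gen_cfg <- function(...) {
  defaults <- list(n_models_per_class = 1, lanes_per_model = 2,
                   idle_pre_s = 0.2, contact_s = 1.0, idle_post_s = 0.2,
                   contact_window_s = 0.5, seed = 123)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# Smoke-scale study conditions: 2 tissue models per class (20 recordings).
smoke_gen_cfg <- function(...) {
  do.call(generator_config,
          utils::modifyList(list(n_models_per_class = 2, seed = 11),
                            list(...)))
}

# Fast network training schedule for unit tests.
fast_train_cfg <- function(...) {
  train_config(max_epochs = 5, batch_size = 2048,
               early_stopping_patience = 5, seed = 7, ...)
}

# Permute class labels at the recording level (keeps class counts, breaks
# any feature-label association) and rebuild the per-sample view.
permute_recording_labels <- function(ds, seed) {
  labs <- vapply(ds$recordings, `[[`, "", "class_label")
  new_labs <- stiffsense:::with_seed(seed, sample(labs))
  for (i in seq_along(new_labs))
    ds$recordings[[i]]$class_label <- new_labs[[i]]
  ds$per_sample_view <-
    stiffsense:::build_per_sample_view(ds$recordings,
                                       ds$config$contact_window_s)
  ds
}

# Standardized (x, y) lists for a set of recording ids of a dataset view.
std_xy <- function(view, norm, ids) {
  v <- view[view$recording_id %in% ids, , drop = FALSE]
  list(x = apply_normalizer(norm, v),
       y = factor(v$label, levels = levels(v$label)))
}

expect_prob_matrix <- function(p) {
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-6)
}
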