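test_that("experiment grid produces one row per cell-fold-metric with
           exact fold aggregation and no recording leakage", {
  ds <- generate_dataset(smoke_gen_cfg())
  grid <- run_experiment_grid(ds, classifiers = "rf",
                              filters = c("raw", "bandstop"), seed = 3)
  res <- grid$results
  expect_equal(nrow(res), 2 * 5 * 5)       # filters x folds x metrics
  expect_setequal(unique(res$metric), c("F1", "ACC", "PPV", "TPR", "AUROC"))

  s <- summarize_grid(grid)
  for (i in seq_len(nrow(s))) {
    v <- res$value[res$filter == s$filter[i] & res$metric == s$metric[i] &
                     res$classifier == s$classifier[i]]
    expect_equal(s$mean[i], mean(v), tolerance = 1e-12)
    expect_equal(s$sd[i], stats::sd(v), tolerance = 1e-12)
  }

  for (f in grid$folds) {
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    expect_length(intersect(f$val_ids, f$test_ids), 0)
    expect_length(intersect(f$train_ids, f$val_ids), 0)
  }
  expect_setequal(unlist(lapply(grid$folds, `[[`, "test_ids")),
                  names(ds$recordings))
})

test_that("rerunning the grid with the same seed reproduces forest cells
           bit-identically", {
  ds <- generate_dataset(smoke_gen_cfg())
  g1 <- run_experiment_grid(ds, classifiers = "rf", filters = "raw",
                            seed = 5)
  g2 <- run_experiment_grid(ds, classifiers = "rf", filters = "raw",
                            seed = 5)
  expect_identical(g1$results, g2$results)
})

test_that("CNN-scored test samples are the 63-predecessor subset of the
           samples RF/NN score", {
  cfg <- smoke_gen_cfg()
  ds <- generate_dataset(cfg)
  folds <- make_group_folds(ds, 5, 0.125, seed = 2)
  f <- folds[[1]]
  wte <- windows_from_recordings(ds$recordings[f$test_ids], 64,
                                 cfg$contact_window_s)
  te_view <- ds$per_sample_view[
    ds$per_sample_view$recording_id %in% f$test_ids, ]
  # per recording: targets 63..999 out of samples 0..999
  for (id in f$test_ids) {
    cnn_idx <- wte$target_index[wte$recording_id == id]
    expect_equal(cnn_idx, 63:999)
    expect_equal(sum(te_view$recording_id == id), 1000)
  }
  expect_lt(length(wte$target_index), nrow(te_view))
})

test_that("full study writes reproducible artifacts", {
  out1 <- tempfile("study1_"); out2 <- tempfile("study2_")
  cfg <- study_config(classifiers = "rf", filters = c("raw", "lowpass"),
                      seed = 9, smoke = TRUE)
  r1 <- run_full_study(cfg, out1)
  r2 <- run_full_study(cfg, out2)
  for (fn in c("results_long.csv", "results_summary.csv",
               "filter_response.csv", "run_log.json"))
    expect_true(file.exists(file.path(out1, fn)))
  expect_identical(readLines(file.path(out1, "results_long.csv")),
                   readLines(file.path(out2, "results_long.csv")))
  log <- jsonlite::fromJSON(file.path(out1, "run_log.json"))
  expect_equal(log$n_recordings, 20)
  expect_equal(log$seed, 9)
  # 2 filters x 1 classifier x 5 folds evaluation records
  expect_equal(nrow(r1$grid$results) / 5, 2 * 1 * 5)
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("dataset containers round-trip through the plain-text format", {
  ds <- generate_dataset(tiny_gen_cfg())
  dir <- tempfile("dsio_")
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "per_sample_view.csv")))
  back <- read_dataset(dir)
  expect_equal(names(back$recordings), names(ds$recordings))
  for (id in names(ds$recordings)) {
    expect_equal(back$recordings[[id]]$samples,
                 ds$recordings[[id]]$samples, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(back$recordings[[id]]$phase_bounds,
                 ds$recordings[[id]]$phase_bounds)
    expect_equal(back$recordings[[id]]$class_label,
                 ds$recordings[[id]]$class_label)
  }
  expect_equal(back$per_sample_view$label, ds$per_sample_view$label)
  expect_equal(stiffsense:::psv_features(back$per_sample_view),
               stiffsense:::psv_features(ds$per_sample_view),
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
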