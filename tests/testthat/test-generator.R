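test_that("recording has the configured phase structure and shape", {
  cfg <- generator_config(seed = 3)
  r <- generate_recording(cfg, "soft", "model1", 0)
  expect_equal(ncol(r$samples), 6500)   # (1 + 4.5 + 1) s at 1000 Hz
  expect_equal(nrow(r$samples), 9)
  expect_equal(r$phase_bounds, c(1000, 5500))
  expect_equal(diff(r$phase_bounds) / r$fs, cfg$contact_s)
  expect_true(all(is.finite(r$samples)))

  expect_error(generate_recording(cfg, "rigid", "model1", 0), "class label")
  expect_error(generate_recording(cfg, "soft", "model1", 7), "lane_index")
  expect_error(generator_config(fs = -1), "fs")
  expect_error(generator_config(contact_window_s = 5), "contact_window_s")
  expect_error(generator_config(periodic_noise_fraction = 1.5), "fraction")
})

test_that("contact window extraction obeys bounds", {
  r <- generate_recording(generator_config(seed = 3), "soft", "model1", 0)
  expect_equal(dim(extract_contact_window(r, 1.0)), c(9, 1000))
  expect_equal(dim(extract_contact_window(r, 4.5)), c(9, 4500))
  expect_equal(dim(extract_contact_window(r, 0)), c(9, 0))
  expect_error(extract_contact_window(r, 4.6), "exceeds")
})

test_that("noise-free contact phase sits exactly on the class baseline", {
  cfg <- generator_config(broadband_sigma = 0, periodic_noise_fraction = 0,
                          drift_slope = 0, seed = 5)
  for (cls in c("very_soft", "soft")) {
    r <- generate_recording(cfg, cls, "model1", 1)
    w <- extract_contact_window(r, cfg$contact_s)
    baseline <- stiffsense:::class_baseline(cfg, cls)
    expect_equal(w, matrix(baseline, nrow = 9, ncol = 4500),
                 ignore_attr = TRUE)
    # idle phases use the distinct idle level, not the contact baseline
    expect_equal(unname(r$samples[, 1]), rep(0, 9))
  }
})

test_that("periodic noise dominates the contact-window spectrum", {
  cfg <- generator_config(broadband_sigma = 0, periodic_noise_fraction = 1,
                          drift_slope = 0, seed = 9)
  r <- generate_recording(cfg, "very_soft", "model1", 0)
  expect_true(r$has_periodic_noise)
  w <- extract_contact_window(r, 1.0)
  for (ch in c(1, 5, 9)) {
    spec <- Mod(stats::fft(w[ch, ]))
    nonzero <- spec[2:500]                       # positive frequencies, 1 Hz bins
    peak_hz <- which.max(nonzero)                # bin k <-> k Hz
    expect_lte(abs(peak_hz - cfg$periodic_noise_hz), 1)
  }
})

test_that("dataset bookkeeping, balance and empty case", {
  ds <- generate_dataset(smoke_gen_cfg())
  expect_s3_class(ds, "tissue_dataset")
  expect_length(ds$recordings, 20)
  expect_false(anyDuplicated(names(ds$recordings)) > 0)
  tab <- table(ds$per_sample_view$label)
  expect_equal(unname(c(tab)), c(10000, 10000))
  expect_equal(nrow(ds$per_sample_view),
               20 * round(ds$config$contact_window_s * ds$config$fs))
  expect_named(ds$per_sample_view,
               c(paste0("ch", 0:8), "label", "recording_id"))

  empty <- generate_dataset(generator_config(n_models_per_class = 0))
  expect_length(empty$recordings, 0)
  expect_equal(nrow(empty$per_sample_view), 0)
})

test_that("generation is deterministic and recording-substream stable", {
  cfg <- smoke_gen_cfg()
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$per_sample_view, ds2$per_sample_view)

  # a recording's content does not depend on dataset composition
  solo <- generate_recording(cfg, "soft", "model2", 3)
  expect_identical(solo$samples,
                   ds1$recordings[[solo$recording_id]]$samples)

  # enlarging the dataset leaves previously generated recordings untouched
  big <- generate_dataset(generator_config(n_models_per_class = 3,
                                           seed = 11))
  for (id in names(ds1$recordings))
    expect_identical(big$recordings[[id]]$samples,
                     ds1$recordings[[id]]$samples)
})

test_that("periodic-noise fraction controls the flag and class separation
           scales mean distance monotonically", {
  none <- generate_dataset(smoke_gen_cfg(periodic_noise_fraction = 0))
  all_ <- generate_dataset(smoke_gen_cfg(periodic_noise_fraction = 1))
  expect_false(any(vapply(none$recordings, `[[`, TRUE,
                          "has_periodic_noise")))
  expect_true(all(vapply(all_$recordings, `[[`, TRUE,
                         "has_periodic_noise")))

  dist_for <- function(sep) {
    ds <- generate_dataset(smoke_gen_cfg(class_separation = sep))
    x <- stiffsense:::psv_features(ds$per_sample_view)
    mu <- apply(x, 2, tapply, ds$per_sample_view$label, mean)
    sqrt(sum((mu[1, ] - mu[2, ])^2))
  }
  d <- vapply(c(0.5, 1, 2), dist_for, 0)
  expect_true(all(diff(d) > 0))
})
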