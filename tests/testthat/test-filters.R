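test_that("Butterworth low-pass matches its analytic magnitude response", {
  lp <- design_lowpass(0.75, 3, 1000)
  expect_equal(filter_response(lp, 0), 1.0, tolerance = 1e-9)
  expect_equal(filter_response(lp, 0.75), 1 / sqrt(2), tolerance = 1e-3)

  # third-order rolloff: |H| follows the analog prototype
  # 1/sqrt(1 + (f/fc)^6) within 5% a decade above the cutoff
  f <- c(2, 5, 7.5)
  proto <- 1 / sqrt(1 + (f / 0.75)^6)
  expect_equal(filter_response(lp, f), proto, tolerance = 0.05)

  expect_error(design_lowpass(600, 3, 1000), "fs/2")
  expect_error(design_lowpass(0.75, 0, 1000), "order")
})

test_that("notch has a null at center, unit gain at DC/Nyquist, and the
           specified quality-factor bandwidth", {
  bs <- design_bandstop(1.2, 0.4, 1000)
  expect_lt(filter_response(bs, 1.2), 1e-3)
  expect_equal(filter_response(bs, 0), 1.0, tolerance = 1e-6)
  expect_equal(filter_response(bs, 500), 1.0, tolerance = 1e-6)

  # -3 dB edges bracket the center and span ~ center/Q = 3.0 Hz
  hm <- function(f) filter_response(bs, f) - 1 / sqrt(2)
  lo <- stats::uniroot(hm, c(1e-3, 1.2))$root
  hi <- stats::uniroot(hm, c(1.2, 50))$root
  expect_lt(lo, 1.2); expect_gt(hi, 1.2)
  expect_equal(hi - lo, 1.2 / 0.4, tolerance = 0.02)
})

test_that("both filters are stable and agree with an independent design", {
  lp <- design_lowpass(); bs <- design_bandstop()
  expect_true(filter_is_stable(lp))
  expect_true(filter_is_stable(bs))
  expect_true(all(Mod(filter_poles(lp)) < 1))

  skip_if_not_installed("signal")
  ba <- signal::butter(3, 0.75 / 500, "low")
  f <- seq(0.1, 5, by = 0.1)
  z <- exp(-1i * 2 * pi * f / 1000)
  href <- vapply(z, function(zz)
    abs(sum(ba$b * zz^(0:3)) / sum(ba$a * zz^(0:3))), 0)
  expect_equal(filter_response(lp, f), href, tolerance = 1e-6)
})

test_that("zero-phase application preserves constants and attenuates as
           |H|^2 without delay", {
  lp <- design_lowpass()
  x <- rep(2, 6500)
  expect_lt(max(abs(filtfilt_zero_phase(lp, x) - 2)), 1e-9)

  t <- (0:19999) / 1000
  s <- sin(2 * pi * 1.2 * t)
  mid <- 5000:15000                      # interior, away from edges
  y <- filtfilt_zero_phase(lp, s)
  ratio <- sqrt(mean(y[mid]^2)) / sqrt(mean(s[mid]^2))
  expect_equal(ratio, filter_response(lp, 1.2)^2, tolerance = 0.01)

  bs <- design_bandstop()
  yb <- filtfilt_zero_phase(bs, s)
  expect_lt(sqrt(mean(yb[mid]^2)), 0.01 * sqrt(mean(s[mid]^2)))

  # no group delay: cross-correlation of a slow sinusoid peaks at lag 0
  slow <- sin(2 * pi * 0.2 * t)
  ys <- filtfilt_zero_phase(lp, slow)
  cc <- stats::ccf(ys[mid], slow[mid], lag.max = 200, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("apply_filter acts per channel, keeps metadata, and commutes
           with channel permutation", {
  cfg <- tiny_gen_cfg()
  r <- generate_recording(cfg, "soft", "model1", 0)
  lp <- design_lowpass(0.75, 3, cfg$fs)
  rf <- apply_filter(lp, r)
  expect_equal(dim(rf$samples), dim(r$samples))
  expect_equal(rf$phase_bounds, r$phase_bounds)
  expect_equal(rf$class_label, r$class_label)

  perm <- c(3, 1, 2, 9, 5, 4, 8, 7, 6)
  r_perm <- r; r_perm$samples <- r$samples[perm, ]
  expect_equal(apply_filter(lp, r_perm)$samples, rf$samples[perm, ])

  bad <- r; bad$fs <- 500
  expect_error(apply_filter(lp, bad), "fs")

  ds <- generate_dataset(cfg)
  dsf <- apply_filter(lp, ds)
  expect_equal(nrow(dsf$per_sample_view), nrow(ds$per_sample_view))
  expect_false(isTRUE(all.equal(dsf$per_sample_view$ch0,
                                ds$per_sample_view$ch0)))
})

test_that("filter specs survive a JSON round trip", {
  for (spec in list(design_lowpass(), design_bandstop())) {
    back <- filter_from_json(filter_to_json(spec))
    f <- c(0.1, 0.75, 1.2, 5, 100)
    # JSON carries ~15 significant digits per coefficient
    expect_lt(max(abs(filter_response(back, f) - filter_response(spec, f))),
              1e-9)
    expect_equal(back$kind, spec$kind)
  }
})
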