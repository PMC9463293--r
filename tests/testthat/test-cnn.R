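# Independent naive convolution: direct sum over kernel taps and input
# channels, one output position at a time.
naive_conv1d <- function(x3, w, stride, pad) {
  C_out <- dim(w)[1]; K <- dim(w)[3]
  C_in <- dim(x3)[1]; T_len <- dim(x3)[2]; B <- dim(x3)[3]
  T_out <- (T_len + 2 * pad - K) %/% stride + 1
  y <- array(0, c(C_out, T_out, B))
  for (b in seq_len(B)) for (t in seq_len(T_out)) for (co in seq_len(C_out)) {
    acc <- 0
    for (k in seq_len(K)) {
      ti <- (t - 1) * stride + k - pad
      if (ti >= 1 && ti <= T_len)
        acc <- acc + sum(w[co, , k] * x3[, ti, b])
    }
    y[co, t, b] <- acc
  }
  y
}

test_that("compiled convolution matches the naive oracle for stride 1 and
           2, with and without padding", {
  set.seed(12)
  for (case in list(list(s = 1, pad = 3, K = 7), list(s = 2, pad = 3, K = 7),
                    list(s = 2, pad = 0, K = 1))) {
    C_in <- 5; C_out <- 4; T_len <- 20; B <- 3
    x3 <- array(rnorm(C_in * T_len * B), c(C_in, T_len, B))
    w <- array(rnorm(C_out * C_in * case$K), c(C_out, C_in, case$K))
    xm <- x3; dim(xm) <- c(C_in, T_len * B)
    got <- stiffsense:::conv1d_fw(xm, T_len, B, w, case$s, case$pad)
    want <- naive_conv1d(x3, w, case$s, case$pad)
    dim(want) <- c(C_out, got$T_out * B)
    expect_equal(got$y, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("batch normalization standardizes each channel over time and
           batch", {
  set.seed(13)
  xm <- matrix(rnorm(6 * 400, mean = 2, sd = 3), 6)
  rs <- list(mean = rep(0, 6), var = rep(1, 6))
  out <- stiffsense:::bn_fw(xm, g = rep(1, 6), be = rep(0, 6),
                            train = TRUE, rs = rs)
  expect_equal(unname(rowMeans(out$y)), rep(0, 6), tolerance = 1e-9)
  expect_equal(unname(apply(out$y, 1, function(r)
    mean(r^2))), rep(1, 6), tolerance = 1e-3)   # biased var + eps
})

test_that("window construction follows the 63-predecessor rule", {
  m <- matrix(rnorm(9 * 1000), 9)
  mw <- make_windows(m, 64)
  expect_equal(dim(mw$windows), c(9, 64, 937))
  expect_equal(mw$targets[1], 63)
  expect_equal(mw$targets[937], 999)
  expect_identical(mw$windows[, , 1], m[, 1:64])

  expect_equal(dim(make_windows(m[, 1:64], 64)$windows)[3], 1)
  expect_equal(dim(make_windows(m[, 1:63], 64)$windows)[3], 0)
  expect_length(make_windows(m[, 1:63], 64)$targets, 0)
})

test_that("architecture arithmetic: temporal trace 64-32-16-8, 7 conv
           layers, and config validation", {
  cfg <- cnn_config()
  expect_equal(cnn_forward_trace(cfg), c(64, 32, 16, 8))
  expect_equal(cnn_conv_layer_count(cfg), 7)
  expect_error(cnn_config(kernel = 6), "odd")
  expect_error(cnn_config(window = 4), "downsampling")

  # logits have one row per window and two columns
  init <- stiffsense:::cnn_init_params(cfg, 3L)
  x <- array(rnorm(9 * 64 * 5), c(9, 64, 5))
  fw <- stiffsense:::cnn_forward(init$params, init$rs, x, cfg,
                                 train = FALSE)
  expect_equal(dim(fw$logits), c(5, 2))
  expect_equal(nrow(fw$gap), 64)          # pooled channel count
})

test_that("analytic CNN gradients match finite differences", {
  cfg <- cnn_config(window = 16, stem_channels = 4,
                    block_channels = c(6, 6, 8), kernel = 3, dropout = 0)
  init <- stiffsense:::cnn_init_params(cfg, 3L)
  p <- init$params; rs <- init$rs
  set.seed(14)
  x <- array(rnorm(9 * 16 * 4), c(9, 16, 4))
  y <- rep(1:2, 2)
  fw <- stiffsense:::cnn_forward(p, rs, x, cfg, train = TRUE)
  g <- stiffsense:::cnn_backward(p, fw, stiffsense:::ce_grad(fw$logits, y),
                                 cfg)
  loss_at <- function(pp)
    stiffsense:::ce_loss(
      stiffsense:::cnn_forward(pp, rs, x, cfg, train = TRUE)$logits, y)
  for (nm in names(p)) {
    idx <- sample(length(p[[nm]]), min(3, length(p[[nm]])))
    for (i in idx) {
      eps <- 1e-5; p2 <- p
      p2[[nm]][i] <- p2[[nm]][i] + eps; f1 <- loss_at(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; f0 <- loss_at(p2)
      expect_equal(g[[nm]][i], (f1 - f0) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("window batches carry labels and indices; a 1000-sample recording
           yields 937 aligned predictions", {
  cfg <- tiny_gen_cfg(contact_s = 1.5, contact_window_s = 1.0)
  ds <- generate_dataset(cfg)
  wb <- windows_from_recordings(ds$recordings, 64, 1.0)
  expect_equal(dim(wb$x)[3], 4 * 937)
  expect_equal(unique(table(wb$recording_id)), 937L)
  expect_setequal(unique(wb$target_index), 63:999)
  expect_equal(as.character(wb$y[1]),
               ds$recordings[[wb$recording_id[1]]]$class_label)
})

test_that("short training runs are deterministic and produce aligned
           probabilistic predictions", {
  cfg <- tiny_gen_cfg(contact_s = 1.5, contact_window_s = 0.3,
                      class_separation = 3)
  ds <- generate_dataset(cfg)            # 4 recordings, 300-sample windows
  ids <- names(ds$recordings)
  norm <- fit_normalizer(ds$per_sample_view)
  mk <- function(ids) windows_from_recordings(ds$recordings[ids], 64, 0.3,
                                              norm)
  tr <- mk(ids[c(1, 3)]); va <- mk(ids[2]); te <- mk(ids[4])
  tc <- train_config(max_epochs = 2, batch_size = 256,
                     early_stopping_patience = 2, seed = 21)
  mcfg <- cnn_config()
  m1 <- train_cnn(tr, va, mcfg, tc)
  m2 <- train_cnn(tr, va, mcfg, tc)
  p1 <- predict_proba(m1, te)
  expect_identical(p1, predict_proba(m2, te))
  expect_prob_matrix(p1)
  expect_equal(nrow(p1), 300 - 64 + 1)
  expect_equal(attr(p1, "target_index"), te$target_index)
  expect_equal(attr(p1, "recording_id"), te$recording_id)

  expect_error(train_cnn(tr, list(x = array(0, c(9, 64, 0))), mcfg, tc),
               "validation")
})
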