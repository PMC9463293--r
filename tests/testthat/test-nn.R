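test_that("combined loss reduces to cross-entropy in its limits and
           matches hand arithmetic", {
  set.seed(10)
  logits <- matrix(rnorm(12), 6)
  y <- rep(1:2, 3)
  x <- matrix(rnorm(6 * 9), 6)
  xhat <- x + matrix(rnorm(6 * 9, sd = 0.5), 6)

  ce <- stiffsense:::ce_loss(logits, y)
  expect_equal(combined_loss(logits, y, xhat, x, 0), ce)
  expect_equal(combined_loss(logits, y, x, x, 0.7), ce)

  # uniform 2-class softmax CE = ln 2; unit error in 1 of 9 features
  v <- combined_loss(matrix(c(0, 0), 1), 1L,
                     matrix(c(1, rep(0, 8)), 1), matrix(0, 1, 9), 0.3)
  expect_equal(v, log(2) + 0.3 / 9, tolerance = 1e-6)

  expect_error(combined_loss(logits, y[1:3], xhat, x, 0.3), "dimensions")
  expect_error(combined_loss(logits, y, xhat, x, -1), "alpha")
})

test_that("analytic gradients of the combined loss match finite
           differences", {
  cfg <- ae_classifier_config()
  p <- stiffsense:::nn_init_params(cfg, 7L)
  set.seed(11)
  x <- matrix(rnorm(5 * 9), 5)
  y <- c(1L, 2L, 1L, 2L, 1L)
  fw <- stiffsense:::nn_forward(p, x, cfg, train = FALSE)
  g <- stiffsense:::nn_backward(p, fw, y, cfg)
  loss_at <- function(pp)
    stiffsense:::nn_loss_from_forward(
      stiffsense:::nn_forward(pp, x, cfg, train = FALSE), y, cfg)
  for (nm in names(p)) {
    idx <- sample(length(p[[nm]]), min(4, length(p[[nm]])))
    for (i in idx) {
      eps <- 1e-6; p2 <- p
      p2[[nm]][i] <- p2[[nm]][i] + eps; f1 <- loss_at(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; f0 <- loss_at(p2)
      num <- (f1 - f0) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("the network has the published layer sizes (1284 parameters)", {
  expect_equal(nn_param_count(ae_classifier_config()), 1284)
  # closed form: 9*32+32 + 32*9+9 + 9*32+32 + 32*9+9 + 9*4+4 + 4*2+2
  expect_equal(nn_param_count(ae_classifier_config()),
               (9 * 32 + 32) + (32 * 9 + 9) + (9 * 32 + 32) +
                 (32 * 9 + 9) + (9 * 4 + 4) + (4 * 2 + 2))
})

test_that("training descends, stops on validation, and is deterministic", {
  ds <- generate_dataset(smoke_gen_cfg(class_separation = 3,
                                       periodic_noise_fraction = 0))
  folds <- make_group_folds(ds, 5, 0.125, seed = 2)
  f <- folds[[1]]
  norm <- fit_normalizer(ds$per_sample_view[
    ds$per_sample_view$recording_id %in% f$train_ids, ])
  tr <- std_xy(ds$per_sample_view, norm, f$train_ids)
  va <- std_xy(ds$per_sample_view, norm, f$val_ids)
  te <- std_xy(ds$per_sample_view, norm, f$test_ids)

  nn <- train_ae_nn(tr, va, ae_classifier_config(), fast_train_cfg())
  h <- nn$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_equal(nn$best_val_f1, max(h$val_f1))

  p <- predict_proba(nn, te$x)
  expect_prob_matrix(p)
  expect_gte(compute_metrics(te$y, p)["F1"], 0.95)

  nn2 <- train_ae_nn(tr, va, ae_classifier_config(), fast_train_cfg())
  expect_identical(predict_proba(nn2, te$x), p)

  expect_error(train_ae_nn(tr, list(x = tr$x[0, ], y = tr$y[0]),
                           ae_classifier_config(), fast_train_cfg()),
               "validation")
})
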