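mk_prob <- function(p_pos) {
  cbind(very_soft = p_pos, soft = 1 - p_pos)
}

test_that("perfect and chance predictions give the expected metric values", {
  y <- factor(rep(c("very_soft", "soft"), each = 10),
              levels = c("very_soft", "soft"))
  perfect <- mk_prob(c(rep(0.9, 10), rep(0.1, 10)))
  m <- compute_metrics(y, perfect)
  expect_equal(unname(m), rep(1, 5))

  flat <- mk_prob(rep(0.5, 20))
  m0 <- compute_metrics(y, flat)
  expect_equal(unname(m0["ACC"]), 0.5)
  expect_equal(unname(m0["AUROC"]), 0.5)
})

test_that("hand-built confusion matrix yields macro F1 = ACC = 0.75", {
  # per class: TP 3, FP 1, FN 1, TN 3
  y <- factor(c(rep("very_soft", 4), rep("soft", 4)),
              levels = c("very_soft", "soft"))
  p_pos <- c(0.9, 0.9, 0.9, 0.1, 0.9, 0.1, 0.1, 0.1)
  m <- compute_metrics(y, mk_prob(p_pos))
  expect_equal(unname(m["F1"]), 0.75)
  expect_equal(unname(m["ACC"]), 0.75)
  expect_equal(unname(m["PPV"]), 0.75)
  expect_equal(unname(m["TPR"]), 0.75)
})

test_that("single-class truth yields NA AUROC with a warning", {
  y <- factor(rep("soft", 5), levels = c("very_soft", "soft"))
  expect_warning(m <- compute_metrics(y, mk_prob(runif(5))), "AUROC")
  expect_true(is.na(m["AUROC"]))
})

test_that("rank-based AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  y <- factor(sample(c("very_soft", "soft"), 300, TRUE),
              levels = c("very_soft", "soft"))
  s <- runif(300) + 0.3 * (y == "very_soft")
  m <- compute_metrics(y, mk_prob(pmin(pmax(s, 0), 1)))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = pmin(pmax(s, 0), 1),
    levels = c("soft", "very_soft"), direction = "<", quiet = TRUE)))
  expect_equal(unname(m["AUROC"]), ref, tolerance = 1e-12)
})

test_that("fold aggregation is the arithmetic mean and sd over folds", {
  fm <- rbind(c(F1 = 0.8, ACC = 0.9), c(F1 = 0.6, ACC = 0.7),
              c(F1 = 0.7, ACC = 0.8))
  agg <- aggregate_metrics(fm)
  expect_equal(agg$mean, c(0.7, 0.8), tolerance = 1e-12)
  expect_equal(agg$sd, c(stats::sd(c(0.8, 0.6, 0.7)),
                         stats::sd(c(0.9, 0.7, 0.8))), tolerance = 1e-12)
})
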