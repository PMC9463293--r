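#' Realize a named preprocessing filter
#'
#' @param name One of `"raw"`, `"lowpass"`, `"bandstop"`.
#' @param fs Sampling frequency in Hz.
#' @return A `filter_spec`, or `NULL` for `"raw"`.
#' @export
filter_by_name <- function(name, fs = 1000) {
  switch(name,
         raw = NULL,
         lowpass = design_lowpass(0.75, 3, fs),
         bandstop = design_bandstop(1.2, 0.4, fs),
         stop_config("unknown filter '%s'", name))
}

#' Run the classifier-by-filter experiment grid
#'
#' For every preprocessing filter and every classifier, runs recording-
#' disjoint k-fold cross-validation: per fold, the feature normalizer is
#' fitted on that fold's training recordings only, the classifier is
#' trained (networks use the fold's validation recordings for early
#' stopping; the random forest trains on train plus validation), and the
#' five metrics are computed on the fold's test recordings. CNN metrics are
#' computed on the windows whose targets have 63 predecessors; RF/NN score
#' every test sample.
#'
#' @param dataset A `tissue_dataset`.
#' @param classifiers Subset of `c("rf", "nn", "cnn")`.
#' @param filters Subset of `c("raw", "lowpass", "bandstop")`.
#' @param seed Integer seed controlling fold assignment and per-cell
#'   training seeds.
#' @param k Number of cross-validation folds.
#' @param val_fraction Validation fraction of each fold's non-test
#'   recordings.
#' @param train_cfg A [train_config()] shared by both networks (per-cell
#'   seeds are derived from `seed`).
#' @param nn_cfg,cnn_cfg Model configurations.
#' @param verbose Print per-cell progress.
#' @return Object of class `experiment_grid`: list with `results` (long
#'   data.frame: classifier, filter, fold, metric, value), `folds`,
#'   `histories` (per-cell network training histories), and the
#'   configuration used.
#' @export
run_experiment_grid <- function(dataset,
                                classifiers = c("rf", "nn", "cnn"),
                                filters = c("raw", "lowpass", "bandstop"),
                                seed = 1L, k = 5, val_fraction = 0.125,
                                train_cfg = train_config(),
                                nn_cfg = ae_classifier_config(),
                                cnn_cfg = cnn_config(),
                                verbose = FALSE) {
  stopifnot(inherits(dataset, "tissue_dataset"))
  classifiers <- match.arg(classifiers, c("rf", "nn", "cnn"),
                           several.ok = TRUE)
  folds <- make_group_folds(dataset, k, val_fraction, seed)
  fs <- dataset$config$fs
  cw_s <- dataset$config$contact_window_s

  rows <- list()
  histories <- list()

  for (flt in filters) {
    spec <- filter_by_name(flt, fs)
    fds <- if (is.null(spec)) dataset else apply_filter(spec, dataset)
    view <- fds$per_sample_view

    for (fold in folds) {
      fi <- fold$fold_index
      tr_view <- psv_subset(view, fold$train_ids)
      va_view <- psv_subset(view, fold$val_ids)
      te_view <- psv_subset(view, fold$test_ids)
      norm <- fit_normalizer(tr_view)

      std <- function(v) list(x = apply_normalizer(norm, v),
                              y = factor(v$label, stiffness_classes()))

      for (clf in classifiers) {
        cell_seed <- substream_seed(seed, sprintf("%s/%s/%d", flt, clf, fi))
        if (verbose)
          message(sprintf("[grid] filter=%s fold=%d clf=%s", flt, fi, clf))

        if (clf == "rf") {
          # no validation split for the forest: train on train + val
          trva <- psv_subset(view, c(fold$train_ids, fold$val_ids))
          model <- train_rf(list(x = apply_normalizer(norm, trva),
                                 y = factor(trva$label,
                                            stiffness_classes())),
                            rf_config(seed = cell_seed))
          prob <- predict_proba(model, std(te_view)$x)
          met <- compute_metrics(te_view$label, prob)
        } else if (clf == "nn") {
          tc <- train_cfg; tc$seed <- cell_seed
          model <- train_ae_nn(std(tr_view), std(va_view), nn_cfg, tc)
          prob <- predict_proba(model, std(te_view)$x)
          met <- compute_metrics(te_view$label, prob)
          histories[[sprintf("%s_nn_fold%d", flt, fi)]] <- model$history
        } else {
          tc <- train_cfg; tc$seed <- cell_seed
          wtr <- windows_from_recordings(fds$recordings[fold$train_ids],
                                         cnn_cfg$window, cw_s, norm)
          wva <- windows_from_recordings(fds$recordings[fold$val_ids],
                                         cnn_cfg$window, cw_s, norm)
          wte <- windows_from_recordings(fds$recordings[fold$test_ids],
                                         cnn_cfg$window, cw_s, norm)
          model <- train_cnn(wtr, wva, cnn_cfg, tc)
          prob <- predict_proba(model, wte)
          met <- compute_metrics(wte$y, prob)
          histories[[sprintf("%s_cnn_fold%d", flt, fi)]] <- model$history
        }

        rows[[length(rows) + 1]] <-
          data.frame(classifier = clf, filter = flt, fold = fi,
                     metric = names(met), value = unname(met))
      }
    }
  }

  structure(list(results = do.call(rbind, rows), folds = folds,
                 histories = histories,
                 classifiers = classifiers, filters = filters,
                 seed = seed, k = k),
            class = "experiment_grid")
}

#' Summarize an experiment grid as mean (sd) over folds
#'
#' @param grid An `experiment_grid` (or its long `results` data.frame).
#' @return Data.frame with one row per classifier x filter x metric and
#'   columns `mean`, `sd` (sd over the fold-level metric values).
#' @export
summarize_grid <- function(grid) {
  res <- if (inherits(grid, "experiment_grid")) grid$results else grid
  agg_m <- stats::aggregate(value ~ classifier + filter + metric, res,
                            mean, na.rm = TRUE)
  agg_s <- stats::aggregate(value ~ classifier + filter + metric, res,
                            stats::sd, na.rm = TRUE)
  out <- merge(agg_m, agg_s,
               by = c("classifier", "filter", "metric"),
               suffixes = c("_mean", "_sd"))
  names(out)[names(out) == "value_mean"] <- "mean"
  names(out)[names(out) == "value_sd"] <- "sd"
  out[order(out$filter, out$classifier, out$metric), ]
}

#' @export
print.experiment_grid <- function(x, ...) {
  cat(sprintf("Experiment grid: %s x %s, %d folds\n",
              paste(x$classifiers, collapse = "/"),
              paste(x$filters, collapse = "/"), x$k))
  s <- summarize_grid(x)
  f1 <- s[s$metric == "F1", ]
  for (i in seq_len(nrow(f1)))
    cat(sprintf("  %-8s %-9s F1 %.3f (%.3f)\n", f1$classifier[i],
                f1$filter[i], f1$mean[i], f1$sd[i]))
  invisible(x)
}
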