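#' Recording-disjoint stratified k-fold splits
#'
#' Partitions the dataset's recordings into `k` test folds, stratified by
#' stiffness class at the recording level, and carves a validation subset
#' (for the neural networks' early stopping) out of each fold's remaining
#' recordings — also recording-disjoint and class-stratified. No recording
#' ever contributes samples to more than one of train/validation/test
#' within a fold, so no per-sample leakage across partitions is possible.
#'
#' With 40 recordings and `k = 5` each test fold holds 8 recordings (4 per
#' class) and the default `val_fraction = 0.125` of the 32 remaining
#' recordings gives 4 validation recordings (87.5% / 12.5% train/validation
#' split).
#'
#' @param dataset A `tissue_dataset` (or plain list of `recording`s).
#' @param k Number of folds (>= 2).
#' @param val_fraction Fraction of each fold's non-test recordings held out
#'   for validation, rounded to the nearest whole recording per split.
#' @param seed Integer seed controlling the (deterministic) shuffle.
#' @return List of `k` fold objects, each a list with `fold_index` (0-based),
#'   `train_ids`, `val_ids`, `test_ids`.
#' @export
make_group_folds <- function(dataset, k = 5, val_fraction = 0.125,
                             seed = 1L) {
  recs <- if (inherits(dataset, "tissue_dataset")) dataset$recordings
          else dataset
  if (k < 2) stop_config("k must be >= 2")
  ids <- names(recs)
  cls <- vapply(recs, `[[`, "", "class_label")

  by_class <- split(ids, cls)
  for (cl in names(by_class))
    if (length(by_class[[cl]]) < k)
      stop_config("class '%s' has %d recordings, fewer than k = %d",
                  cl, length(by_class[[cl]]), k)

  with_seed(seed, {
    # deal shuffled ids of each class round-robin over the k test folds
    test_sets <- vector("list", k)
    shuffled <- lapply(by_class, sample)
    for (cl in names(shuffled)) {
      assign_to <- rep_len(seq_len(k), length(shuffled[[cl]]))
      for (f in seq_len(k))
        test_sets[[f]] <- c(test_sets[[f]], shuffled[[cl]][assign_to == f])
    }

    lapply(seq_len(k), function(f) {
      test_ids <- test_sets[[f]]
      rest <- setdiff(ids, test_ids)
      n_val <- round(val_fraction * length(rest))
      # stratified validation pick: proportional per class, shuffled order
      rest_by_class <- split(rest, cls[rest])
      quota <- vapply(rest_by_class, length, 0L)
      take <- round(n_val * quota / sum(quota))
      # fix rounding so the total matches
      while (sum(take) > n_val) take[which.max(take)] <- take[which.max(take)] - 1L
      while (sum(take) < n_val) take[which.min(take)] <- take[which.min(take)] + 1L
      val_ids <- unlist(lapply(names(rest_by_class), function(cl)
        sample(rest_by_class[[cl]])[seq_len(take[[cl]])]), use.names = FALSE)
      list(fold_index = f - 1L,
           train_ids = setdiff(rest, val_ids),
           val_ids = val_ids,
           test_ids = test_ids)
    })
  })
}

# Rows of a per-sample view belonging to a set of recording ids.
psv_subset <- function(view, ids) {
  view[view$recording_id %in% ids, , drop = FALSE]
}
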