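#' Write a dataset to a plain-text directory container
#'
#' Layout: `recordings/<id>.csv` (samples, one column per channel, header
#' `ch0..ch<C-1>`), `recordings/<id>.json` (label, phase bounds, fs, noise
#' flag, provenance ids), `per_sample_view.csv` (flat export with header
#' `ch0..ch8,label,recording_id`), and `dataset.json` (generator config and
#' a content hash of the per-sample view).
#'
#' @param dataset A `tissue_dataset`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tissue_dataset"))
  rec_dir <- file.path(dir, "recordings")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)

  for (r in dataset$recordings) {
    m <- as.data.frame(t(r$samples))
    names(m) <- paste0("ch", seq_len(nrow(r$samples)) - 1)
    utils::write.csv(m, file.path(rec_dir, paste0(r$recording_id, ".csv")),
                     row.names = FALSE)
    meta <- r[setdiff(names(r), "samples")]
    writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                             digits = NA)),
               file.path(rec_dir, paste0(r$recording_id, ".json")))
  }

  utils::write.csv(dataset$per_sample_view,
                   file.path(dir, "per_sample_view.csv"),
                   row.names = FALSE)

  cfg <- unclass(dataset$config)
  cfg$class_offsets <- list(values = as.vector(dataset$config$class_offsets),
                            classes = rownames(dataset$config$class_offsets))
  writeLines(as.character(jsonlite::toJSON(
    list(config = cfg, hash = content_hash(dataset$per_sample_view)),
    auto_unbox = TRUE, digits = NA)), file.path(dir, "dataset.json"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the container.
#' @return A `tissue_dataset`.
#' @export
read_dataset <- function(dir) {
  doc <- jsonlite::fromJSON(file.path(dir, "dataset.json"),
                            simplifyVector = TRUE)
  cfg <- doc$config
  co <- matrix(cfg$class_offsets$values, nrow = 2,
               dimnames = list(cfg$class_offsets$classes, NULL))
  cfg$class_offsets <- co
  config <- do.call(generator_config,
                    cfg[names(cfg) %in% names(formals(generator_config))])

  meta_files <- list.files(file.path(dir, "recordings"),
                           pattern = "\\.json$", full.names = TRUE)
  recs <- list()
  for (mf in meta_files) {
    meta <- jsonlite::fromJSON(mf, simplifyVector = TRUE)
    m <- utils::read.csv(sub("\\.json$", ".csv", mf))
    r <- structure(list(
      recording_id = meta$recording_id,
      tissue_model_id = meta$tissue_model_id,
      lane_index = as.integer(meta$lane_index),
      class_label = meta$class_label,
      samples = t(as.matrix(m)),
      phase_bounds = as.integer(meta$phase_bounds),
      fs = meta$fs,
      has_periodic_noise = isTRUE(meta$has_periodic_noise)
    ), class = "recording")
    recs[[r$recording_id]] <- r
  }
  # keep generation order: class, then model, then lane
  ord <- order(match(vapply(recs, `[[`, "", "class_label"),
                     stiffness_classes()),
               vapply(recs, `[[`, "", "tissue_model_id"),
               vapply(recs, `[[`, 0L, "lane_index"))
  recs <- recs[ord]

  structure(list(recordings = recs,
                 per_sample_view = build_per_sample_view(
                   recs, config$contact_window_s),
                 config = config),
            class = "tissue_dataset")
}
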