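#' Configuration for the synthetic recording generator
#'
#' Describes the acquisition protocol and signal statistics emulated by
#' [generate_dataset()]. The defaults mirror the laboratory protocol the
#' pipeline targets: 9 electrical channels sampled at 1000 Hz, recordings
#' with an initial idle phase, a 4.5 s tissue-contact phase and a final idle
#' phase, four tissue models per stiffness class traversed in five lanes
#' each (40 recordings), and analysis restricted to the first second of
#' contact (1000 measurement points per recording).
#'
#' Two stiffness classes are generated, `very_soft` (meningioma-like) and
#' `soft` (healthy-brain-like), differing in their per-channel contact
#' baselines. A fraction of recordings additionally carries a superimposed
#' periodic oscillation near 1.2 Hz emulating irrigation-related noise; it
#' is applied as a common-mode component across all channels, so it
#' contaminates the class-informative direction of the feature space.
#'
#' @param fs Sampling frequency in Hz.
#' @param n_channels Number of electrical feature channels.
#' @param n_models_per_class Tissue models per stiffness class.
#' @param lanes_per_model Traversal lanes (= recordings) per tissue model.
#' @param idle_pre_s,contact_s,idle_post_s Phase durations in seconds.
#' @param contact_window_s Analysed prefix of the contact phase in seconds.
#' @param class_offsets Numeric matrix (2 x n_channels, rownames
#'   `very_soft`/`soft`) of per-class, per-channel contact baselines in
#'   arbitrary signal units. Default: common level 1.0 with a symmetric
#'   between-class split of total Euclidean distance 1 spread evenly over
#'   channels.
#' @param class_separation Scalar scaling of the between-class offset
#'   distance about the class midpoint (1 keeps `class_offsets` as given, 0
#'   collapses the classes).
#' @param drift_slope Slow linear drift during contact, signal units per
#'   second, modelling the continuous descent of the instrument into the
#'   tissue.
#' @param periodic_noise_hz Frequency of the superimposed periodic noise.
#' @param periodic_noise_amplitude Amplitude of that oscillation (signal
#'   units, common-mode across channels).
#' @param periodic_noise_fraction Fraction of recordings carrying the
#'   periodic noise (each recording flips its own deterministic coin).
#' @param broadband_sigma Standard deviation of i.i.d. Gaussian measurement
#'   noise added to every sample.
#' @param seed Integer seed; every recording derives an independent RNG
#'   substream from `(seed, recording_id)`.
#'
#' @return An object of class `generator_config` (a validated list).
#' @seealso [generate_dataset()], [generate_recording()]
#' @export
generator_config <- function(fs = 1000,
                             n_channels = 9,
                             n_models_per_class = 4,
                             lanes_per_model = 5,
                             idle_pre_s = 1.0,
                             contact_s = 4.5,
                             idle_post_s = 1.0,
                             contact_window_s = 1.0,
                             class_offsets = NULL,
                             class_separation = 1.0,
                             drift_slope = 0.05,
                             periodic_noise_hz = 1.2,
                             periodic_noise_amplitude = 0.5,
                             periodic_noise_fraction = 0.5,
                             broadband_sigma = 0.3,
                             seed = 1L) {
  if (fs <= 0) stop_config("fs must be positive (got %g)", fs)
  if (n_channels < 1) stop_config("n_channels must be >= 1")
  if (idle_pre_s <= 0 || contact_s <= 0 || idle_post_s <= 0)
    stop_config("all phase durations must be positive")
  if (contact_window_s < 0 || contact_window_s > contact_s)
    stop_config("contact_window_s must lie in [0, contact_s]")
  if (periodic_noise_fraction < 0 || periodic_noise_fraction > 1)
    stop_config("periodic_noise_fraction must lie in [0, 1]")
  if (fs <= 2 * periodic_noise_hz)
    stop_config("fs must exceed twice periodic_noise_hz")
  if (n_models_per_class < 0 || lanes_per_model < 0)
    stop_config("model and lane counts must be non-negative")
  if (broadband_sigma < 0) stop_config("broadband_sigma must be >= 0")

  if (is.null(class_offsets)) {
    half <- 0.5 / sqrt(n_channels)
    class_offsets <- rbind(
      very_soft = rep(1 + half, n_channels),
      soft      = rep(1 - half, n_channels)
    )
  }
  class_offsets <- as.matrix(class_offsets)
  if (nrow(class_offsets) != 2 || ncol(class_offsets) != n_channels)
    stop_config("class_offsets must be a 2 x n_channels matrix")
  if (is.null(rownames(class_offsets)))
    rownames(class_offsets) <- c("very_soft", "soft")

  cfg <- list(
    fs = fs, n_channels = n_channels,
    n_models_per_class = n_models_per_class,
    lanes_per_model = lanes_per_model,
    idle_pre_s = idle_pre_s, contact_s = contact_s,
    idle_post_s = idle_post_s,
    contact_window_s = contact_window_s,
    class_offsets = class_offsets,
    class_separation = class_separation,
    drift_slope = drift_slope,
    periodic_noise_hz = periodic_noise_hz,
    periodic_noise_amplitude = periodic_noise_amplitude,
    periodic_noise_fraction = periodic_noise_fraction,
    broadband_sigma = broadband_sigma,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic aspirator-recording generator\n")
  cat(sprintf("  %d channels @ %g Hz; phases %g + %g + %g s (window %g s)\n",
              x$n_channels, x$fs, x$idle_pre_s, x$contact_s, x$idle_post_s,
              x$contact_window_s))
  cat(sprintf("  %d models/class x %d lanes = %d recordings\n",
              x$n_models_per_class, x$lanes_per_model,
              2 * x$n_models_per_class * x$lanes_per_model))
  cat(sprintf("  separation %g, sigma %g, periodic %g Hz (amp %g, frac %g)\n",
              x$class_separation, x$broadband_sigma, x$periodic_noise_hz,
              x$periodic_noise_amplitude, x$periodic_noise_fraction))
  invisible(x)
}

stiffness_classes <- function() c("very_soft", "soft")

# Effective per-channel contact baseline for one class: midpoint of the two
# class offsets plus the class half-offset scaled by class_separation.
class_baseline <- function(config, class_label) {
  mid <- colMeans(config$class_offsets)
  mid + config$class_separation *
    (config$class_offsets[class_label, ] - mid)
}

#' Generate one synthetic recording
#'
#' Synthesizes the multichannel electrical time series of a single traversal
#' lane: an idle baseline before and after contact, a class-dependent contact
#' baseline with slow linear drift, an optional common-mode sinusoid at the
#' configured periodic-noise frequency (each recording flips a deterministic
#' coin with probability `periodic_noise_fraction`), and broadband Gaussian
#' measurement noise.
#'
#' All randomness is drawn from an RNG substream derived from
#' `(config$seed, recording_id)`, so a recording's content does not depend on
#' how many other recordings are generated around it.
#'
#' @param config A [generator_config()].
#' @param class_label `"very_soft"` or `"soft"`.
#' @param tissue_model_id String identifying the emulated tissue model.
#' @param lane_index Integer lane index, `0 <= lane_index < lanes_per_model`.
#'
#' @return An object of class `recording`: a list with `recording_id`,
#'   `tissue_model_id`, `lane_index`, `class_label`, `samples` (numeric
#'   matrix n_channels x total_samples), `phase_bounds` (0-based half-open
#'   `[contact_start, contact_end)` sample indices), `fs`, and
#'   `has_periodic_noise`.
#' @export
generate_recording <- function(config, class_label, tissue_model_id,
                               lane_index) {
  stopifnot(inherits(config, "generator_config"))
  if (!class_label %in% stiffness_classes())
    stop_config("unknown class label '%s'", class_label)
  if (lane_index < 0 || lane_index >= config$lanes_per_model)
    stop_config("lane_index %d out of range [0, %d)",
                lane_index, config$lanes_per_model)

  fs <- config$fs
  n_pre <- round(config$idle_pre_s * fs)
  n_contact <- round(config$contact_s * fs)
  n_post <- round(config$idle_post_s * fs)
  n_total <- n_pre + n_contact + n_post
  C <- config$n_channels

  recording_id <- sprintf("%s_%s_lane%d", class_label, tissue_model_id,
                          lane_index)
  rec_seed <- substream_seed(config$seed, recording_id)

  rec <- with_seed(rec_seed, {
    has_noise <- stats::runif(1) < config$periodic_noise_fraction
    noise_phase <- stats::runif(1, 0, 2 * pi)

    baseline <- class_baseline(config, class_label)
    x <- matrix(0, nrow = C, ncol = n_total)

    # contact phase: class baseline + linear drift (instrument descends)
    t_rel <- (seq_len(n_contact) - 1) / fs
    contact_cols <- n_pre + seq_len(n_contact)
    x[, contact_cols] <- baseline +
      matrix(config$drift_slope * t_rel, nrow = C, ncol = n_contact,
             byrow = TRUE)

    # common-mode periodic (irrigation-like) component over the whole record
    if (has_noise && config$periodic_noise_amplitude != 0) {
      t_all <- (seq_len(n_total) - 1) / fs
      osc <- config$periodic_noise_amplitude *
        sin(2 * pi * config$periodic_noise_hz * t_all + noise_phase)
      x <- x + matrix(osc, nrow = C, ncol = n_total, byrow = TRUE)
    }

    if (config$broadband_sigma > 0) {
      x <- x + matrix(stats::rnorm(C * n_total, sd = config$broadband_sigma),
                      nrow = C)
    }

    structure(list(
      recording_id = recording_id,
      tissue_model_id = tissue_model_id,
      lane_index = as.integer(lane_index),
      class_label = class_label,
      samples = x,
      phase_bounds = c(n_pre, n_pre + n_contact),
      fs = fs,
      has_periodic_noise = has_noise
    ), class = "recording")
  })
  rec
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("Recording %s: %d ch x %d samples @ %g Hz, class %s\n",
              x$recording_id, nrow(x$samples), ncol(x$samples), x$fs,
              x$class_label))
  cat(sprintf("  contact [%d, %d), periodic noise: %s\n",
              x$phase_bounds[1], x$phase_bounds[2], x$has_periodic_noise))
  invisible(x)
}

#' Extract the analysed prefix of the contact phase
#'
#' @param recording A `recording`.
#' @param window_s Window length in seconds from contact onset; must not
#'   exceed the contact-phase duration.
#' @return Numeric matrix n_channels x `round(window_s * fs)`.
#' @export
extract_contact_window <- function(recording, window_s) {
  stopifnot(inherits(recording, "recording"))
  n <- round(window_s * recording$fs)
  cs <- recording$phase_bounds[1]
  ce <- recording$phase_bounds[2]
  if (n < 0 || cs + n > ce)
    stop_config("window of %g s exceeds contact phase of %g s",
                window_s, (ce - cs) / recording$fs)
  recording$samples[, cs + seq_len(n), drop = FALSE]
}

# Flattened per-sample table of contact-window samples: one row per
# measurement point, columns ch0..ch<C-1>, label, recording_id.
build_per_sample_view <- function(recordings, contact_window_s) {
  if (length(recordings) == 0) {
    C <- 0
    df <- data.frame(label = factor(character(), stiffness_classes()),
                     recording_id = character())
    return(df)
  }
  C <- nrow(recordings[[1]]$samples)
  blocks <- lapply(recordings, function(r) {
    w <- extract_contact_window(r, contact_window_s)
    d <- as.data.frame(t(w))
    names(d) <- paste0("ch", seq_len(C) - 1)
    d$label <- r$class_label
    d$recording_id <- r$recording_id
    d
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out$label <- factor(out$label, levels = stiffness_classes())
  out
}

#' Generate a full synthetic dataset
#'
#' Produces `n_models_per_class * lanes_per_model` recordings per stiffness
#' class (40 under the defaults) and the flattened per-sample view of their
#' contact windows (40,000 measurement points under the defaults, 20,000 per
#' class).
#'
#' @param config A [generator_config()].
#' @return Object of class `tissue_dataset`: list with `recordings` (named
#'   list of `recording` objects), `per_sample_view` (data.frame with columns
#'   `ch0..ch<C-1>`, `label`, `recording_id`), and `config`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  recs <- list()
  for (cls in stiffness_classes()) {
    for (m in seq_len(config$n_models_per_class)) {
      model_id <- sprintf("model%d", m)
      for (lane in seq_len(config$lanes_per_model) - 1) {
        r <- generate_recording(config, cls, model_id, lane)
        recs[[r$recording_id]] <- r
      }
    }
  }
  if (anyDuplicated(names(recs)))
    stop_config("recording ids are not unique")
  structure(list(
    recordings = recs,
    per_sample_view = build_per_sample_view(recs, config$contact_window_s),
    config = config
  ), class = "tissue_dataset")
}

#' @export
print.tissue_dataset <- function(x, ...) {
  tab <- table(vapply(x$recordings, `[[`, "", "class_label"))
  cat(sprintf("Tissue dataset: %d recordings (%s); %d per-sample rows\n",
              length(x$recordings),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nrow(x$per_sample_view)))
  invisible(x)
}

# Numeric feature matrix (rows = samples) from a per-sample view.
psv_features <- function(view) {
  as.matrix(view[, grep("^ch", names(view)), drop = FALSE])
}
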