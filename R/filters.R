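#' Digital noise-removal filters
#'
#' The pipeline removes a low-frequency periodic disturbance (irrigation
#' noise near 1.2 Hz) from the recorded electrical signals with one of two
#' filters: a third-order Butterworth low-pass with cutoff 0.75 Hz, or a
#' second-order notch (band-stop) centred at 1.2 Hz with quality factor 0.4.
#' At a sampling rate of 1000 Hz these cutoffs sit at a normalized frequency
#' of ~1e-3, where a single transfer-function (b, a) realization loses
#' precision to coefficient cancellation; filters are therefore realized as
#' cascaded first/second-order sections designed directly from the analytic
#' pole locations via the bilinear transform.
#'
#' @name filters
NULL

# ---- design ----------------------------------------------------------------

# One section: list(b = c(b0,b1,b2), a = c(1,a1,a2)); first-order sections
# carry b2 = a2 = 0.
section_gain <- function(sec, z) {
  (sec$b[1] + sec$b[2] / z + sec$b[3] / z^2) /
    (sec$a[1] + sec$a[2] / z + sec$a[3] / z^2)
}

#' Design a Butterworth low-pass filter
#'
#' Builds a stable digital Butterworth low-pass of the given order as a
#' cascade of biquad (and, for odd orders, one first-order) sections, with
#' unit DC gain and the -3 dB point at `cutoff_hz`. Analog prototype poles
#' are placed on the Butterworth circle at the prewarped cutoff and mapped
#' with the bilinear transform; each section is gain-normalized at DC.
#'
#' @param cutoff_hz Cutoff (-3 dB) frequency in Hz, `0 < cutoff_hz < fs/2`.
#' @param order Filter order (>= 1).
#' @param fs Sampling frequency in Hz.
#' @return A `filter_spec` object.
#' @export
design_lowpass <- function(cutoff_hz = 0.75, order = 3, fs = 1000) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    stop_config("cutoff must lie strictly between 0 and fs/2")
  if (order < 1) stop_config("order must be >= 1")

  warped <- 2 * fs * tan(pi * cutoff_hz / fs)   # prewarped analog cutoff
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  poles_a <- warped * exp(1i * theta)           # analog Butterworth poles

  # pair conjugate poles into biquads; odd order leaves one real pole
  secs <- list()
  used <- rep(FALSE, order)
  for (i in k) {
    if (used[i]) next
    p <- poles_a[i]
    if (abs(Im(p)) < 1e-9 * abs(p)) {           # real pole -> 1st order
      zp <- (2 * fs + Re(p)) / (2 * fs - Re(p)) # bilinear
      a <- c(1, -zp, 0)
      b <- c(1, 1, 0)                           # zero at z = -1
      used[i] <- TRUE
    } else {                                    # conjugate pair -> biquad
      j <- which(!used & abs(poles_a - Conj(p)) <
                   1e-6 * abs(p))[1]
      used[c(i, j)] <- TRUE
      zp <- (2 * fs + p) / (2 * fs - p)
      a <- c(1, -2 * Re(zp), abs(zp)^2)
      b <- c(1, 2, 1)                           # double zero at z = -1
    }
    g <- sum(a) / sum(b)                        # unit gain at DC (z = 1)
    secs[[length(secs) + 1]] <- list(b = b * g, a = a)
  }

  new_filter_spec(kind = "lowpass_butterworth", sections = secs, fs = fs,
                  params = list(cutoff_hz = cutoff_hz, order = order))
}

#' Design a notch (band-stop) filter
#'
#' Second-order IIR notch with zeros on the unit circle at the centre
#' frequency: unit gain at DC and Nyquist, a spectral null at `center_hz`,
#' and a -3 dB bandwidth of approximately `center_hz / quality_factor`.
#'
#' @param center_hz Frequency to remove, in Hz.
#' @param quality_factor Centre frequency divided by -3 dB bandwidth; small
#'   values give a wide stopband.
#' @param fs Sampling frequency in Hz.
#' @return A `filter_spec` object.
#' @export
design_bandstop <- function(center_hz = 1.2, quality_factor = 0.4,
                            fs = 1000) {
  if (center_hz <= 0 || center_hz >= fs / 2)
    stop_config("center frequency must lie strictly between 0 and fs/2")
  if (quality_factor <= 0) stop_config("quality_factor must be > 0")

  w0 <- 2 * pi * center_hz / fs
  alpha <- sin(w0) / (2 * quality_factor)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1]; a <- a / a[1]

  new_filter_spec(kind = "bandstop_notch",
                  sections = list(list(b = b, a = a)), fs = fs,
                  params = list(center_hz = center_hz,
                                quality_factor = quality_factor))
}

new_filter_spec <- function(kind, sections, fs, params) {
  spec <- c(list(kind = kind, fs = fs, sections = sections), params)
  class(spec) <- "filter_spec"
  if (!filter_is_stable(spec))
    stop_config("designed filter is unstable")   # should be unreachable
  spec
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("%s @ fs %g Hz, %d section(s)\n", x$kind, x$fs,
              length(x$sections)))
  invisible(x)
}

#' Poles of a realized filter
#'
#' @param spec A `filter_spec`.
#' @return Complex vector of all section poles.
#' @export
filter_poles <- function(spec) {
  unlist(lapply(spec$sections, function(s) {
    a <- s$a
    if (abs(a[3]) < .Machine$double.eps) -a[2] else
      polyroot(rev(a))
  }))
}

#' Is every pole strictly inside the unit circle?
#' @param spec A `filter_spec`.
#' @export
filter_is_stable <- function(spec) all(Mod(filter_poles(spec)) < 1)

#' Magnitude response of a realized filter
#'
#' Evaluates the cascade's transfer function on a frequency grid.
#'
#' @param spec A `filter_spec`.
#' @param f_hz Numeric vector of frequencies in Hz.
#' @return Numeric vector `|H(f)|`.
#' @export
filter_response <- function(spec, f_hz) {
  z <- exp(1i * 2 * pi * f_hz / spec$fs)
  h <- rep(1 + 0i, length(z))
  for (sec in spec$sections) h <- h * section_gain(sec, z)
  Mod(h)
}

#' Serialize a filter specification to JSON
#'
#' Round-trippable provenance record of kind, parameters and realized
#' section coefficients.
#'
#' @param spec A `filter_spec`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
filter_to_json <- function(spec, path = NULL) {
  doc <- list(kind = spec$kind, fs = spec$fs,
              params = spec[setdiff(names(spec),
                                    c("kind", "fs", "sections"))],
              sections = lapply(spec$sections, function(s)
                list(b = s$b, a = s$a)))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname filter_to_json
#' @param json JSON string or file path produced by [filter_to_json()].
#' @export
filter_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  # jsonlite simplifies the section list to a data.frame of list-columns
  sections <- lapply(seq_along(doc$sections$b), function(i)
    list(b = doc$sections$b[[i]], a = doc$sections$a[[i]]))
  new_filter_spec(doc$kind, sections, doc$fs, as.list(doc$params))
}

# ---- zero-phase application ------------------------------------------------

# Single-pass IIR filtering of one section with steady-state initial
# conditions for input level x0 (system assumed at rest under constant x0
# for t < 0). Vectorized via stats::filter: FIR stage with prepended input
# history, then the recursive stage initialized at the steady-state output.
section_filter_ss <- function(sec, x, x0) {
  b <- sec$b; a <- sec$a
  nb <- 3L
  h0 <- sum(b) / sum(a)
  v <- stats::filter(c(rep(x0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  y <- stats::filter(v, -a[-1], method = "recursive",
                     init = rep(x0 * h0, 2))
  as.numeric(y)
}

#' Zero-phase filtering of a numeric vector
#'
#' Applies the filter cascade forward and then backward (squaring the
#' magnitude response, cancelling the phase). Edges are handled by odd
#' extension around the endpoints with steady-state section initialization,
#' so constant signals pass through unchanged to machine precision.
#'
#' @param spec A `filter_spec`.
#' @param x Numeric vector, longer than the edge padding (6 x number of
#'   section coefficient rows, at least 24 samples).
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt_zero_phase <- function(spec, x) {
  n <- length(x)
  p <- max(24L, 6L * length(spec$sections) * 3L)
  if (n <= p + 1)
    stop_config("signal too short (%d samples) for zero-phase padding %d",
                n, p)
  xe <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  for (sec in spec$sections) xe <- section_filter_ss(sec, xe, xe[1])
  xe <- rev(xe)
  for (sec in spec$sections) xe <- section_filter_ss(sec, xe, xe[1])
  rev(xe)[(p + 1):(p + n)]
}

#' Apply a filter to a recording or dataset
#'
#' Each channel is filtered independently over the full recording
#' (zero-phase, forward-backward) before any contact window is extracted,
#' which keeps edge transients away from the analysed segment. Phase bounds
#' and metadata are unchanged. For a `tissue_dataset` the per-sample view is
#' rebuilt from the filtered recordings.
#'
#' @param spec A `filter_spec`.
#' @param x A `recording` or `tissue_dataset`.
#' @return Object of the same class as `x` with filtered samples.
#' @export
apply_filter <- function(spec, x) UseMethod("apply_filter", x)

#' @export
apply_filter.recording <- function(spec, x) {
  if (!isTRUE(all.equal(spec$fs, x$fs)))
    stop_config("filter fs (%g) does not match recording fs (%g)",
                spec$fs, x$fs)
  x$samples <- t(apply(x$samples, 1, function(ch)
    filtfilt_zero_phase(spec, ch)))
  x
}

#' @export
apply_filter.tissue_dataset <- function(spec, x) {
  x$recordings <- lapply(x$recordings, function(r) apply_filter(spec, r))
  x$per_sample_view <- build_per_sample_view(x$recordings,
                                             x$config$contact_window_s)
  x
}
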