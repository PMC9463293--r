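#' Fit a per-feature standardizer on training samples
#'
#' Computes per-feature mean and standard deviation from the training
#' partition only; applying the result elsewhere (validation/test) therefore
#' carries no information from those partitions. Constant features get their
#' standard deviation floored at 1e-8 with a warning.
#'
#' @param x Numeric matrix (rows = samples) or a per-sample view data.frame
#'   with `ch*` columns.
#' @return Object of class `normalizer` with `mean` and `sd` vectors and the
#'   number of samples used.
#' @export
fit_normalizer <- function(x) {
  if (is.data.frame(x)) x <- psv_features(x)
  if (nrow(x) < 2) stop_config("need at least 2 samples to fit normalizer")
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  if (any(sd < 1e-8)) {
    warning("constant feature(s) detected; flooring std at 1e-8")
    sd <- pmax(sd, 1e-8)
  }
  structure(list(mean = mu, sd = sd, n_fit = nrow(x)),
            class = "normalizer")
}

#' Apply a fitted standardizer
#'
#' @param norm A `normalizer` from [fit_normalizer()].
#' @param x Numeric matrix or per-sample view data.frame; feature count must
#'   match the fit.
#' @return Numeric matrix of standardized features.
#' @export
apply_normalizer <- function(norm, x) {
  stopifnot(inherits(norm, "normalizer"))
  if (is.data.frame(x)) x <- psv_features(x)
  if (ncol(x) != length(norm$mean))
    stop_config("feature count %d does not match normalizer (%d)",
                ncol(x), length(norm$mean))
  sweep(sweep(x, 2, norm$mean), 2, norm$sd, "/")
}

#' Add i.i.d. Gaussian noise to a feature table
#'
#' Training-time input perturbation for the neural network (applied after
#' normalization, never at inference).
#'
#' @param x Numeric matrix.
#' @param sigma Noise standard deviation (>= 0; 0 is the identity).
#' @param seed Optional integer; if given, the perturbation is drawn from a
#'   local RNG stream and the caller's RNG state is untouched.
#' @return Matrix of the same shape.
#' @export
add_gaussian_noise <- function(x, sigma, seed = NULL) {
  if (sigma < 0) stop_config("sigma must be >= 0")
  if (sigma == 0) return(x)
  draw <- function() x + matrix(stats::rnorm(length(x), sd = sigma),
                                nrow = nrow(x))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}
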