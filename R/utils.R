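#' @keywords internal
#' @useDynLib stiffsense, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Deterministic 31-bit string hash (polynomial, base 31, modulo 2^31 - 1).
# Used to derive per-recording RNG substreams from (seed, recording_id) so
# that adding recordings to a dataset never perturbs existing ones.
hash_string <- function(s) {
  codes <- utf8ToInt(s)
  m <- 2147483647
  h <- 0
  for (k in codes) {
    h <- (h * 31 + k) %% m
  }
  h
}

# Substream seed for one recording. Mixes the dataset seed with the id hash;
# result is a valid 32-bit integer seed.
substream_seed <- function(seed, recording_id) {
  m <- 2147483647
  as.integer((seed %% m * 2654435 + hash_string(recording_id)) %% m)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Content hash of an arbitrary R object for provenance logging: two
# position-weighted byte sums over its ASCII serialization, reported as
# 8 hex digits. Vectorized; products stay far below 2^53 so double
# arithmetic is exact.
content_hash <- function(x) {
  v <- as.integer(serialize(x, NULL, ascii = TRUE))
  m <- 2147483647
  w <- (seq_along(v) %% 9973L) + 1L
  h1 <- (sum(as.numeric(v) * w) + length(v)) %% m
  h2 <- sum(as.numeric(v) * rev(w)) %% m
  sprintf("%08x", as.integer((h1 * 65539 + h2) %% m))
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
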