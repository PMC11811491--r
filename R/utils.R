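# Shared internal helpers: argument checks, seed derivation, score binning,
# structured logging.

check_finite <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop(sprintf("`%s` must be non-empty finite numeric", what), call. = FALSE)
  }
  invisible(x)
}

check_scalar <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", what), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must lie in [%s, %s], got %s", what,
                 format(lower), format(upper), format(x)), call. = FALSE)
  }
  invisible(x)
}

#' Derive a reproducible stream seed from a master seed
#'
#' Applies two rounds of a Park-Miller (Lehmer) multiplicative step,
#' `x <- (48271 * x) mod (2^31 - 1)`, to `master + index`. Both rounds are
#' exact in double precision (products stay below 2^53) and the result is
#' always a positive integer below 2^31, so it is a valid [set.seed()] input
#' on every platform. Used to give each simulated child (and each policy
#' replicate) its own independent, reproducible stream.
#'
#' @param master Master seed (single finite number; truncated to integer).
#' @param index Stream index (non-negative integer).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 1)
#' derive_seed(42, 2)
derive_seed <- function(master, index) {
  check_scalar(master, "master")
  check_scalar(index, "index", lower = 0)
  m <- 2147483647
  a <- 48271
  x <- (abs(trunc(master)) + trunc(index)) %% (m - 1) + 1
  x <- (a * x) %% m
  x <- (a * x) %% m
  as.integer(x)
}

#' Discretize a score into uniform bins on [0, 1]
#'
#' Bins are half-open `[lo, hi)` except the final bin, which is closed at 1
#' so that a score of exactly 1 falls in bin `n_bins - 1`. Scores outside
#' [0, 1] are clipped (with a log warning) before binning.
#'
#' @param s Numeric vector of scores.
#' @param n_bins Number of uniform bins (>= 1).
#' @return Integer vector of 0-based bin indices in `[0, n_bins)`.
#' @export
score_bin <- function(s, n_bins = 10L) {
  check_finite(s, "s")
  check_scalar(n_bins, "n_bins", lower = 1)
  if (any(s < 0 | s > 1)) {
    sen_log("warn", "binning", "scores outside [0, 1] clipped before binning")
    s <- pmin(pmax(s, 0), 1)
  }
  as.integer(pmin(floor(s * n_bins), n_bins - 1L))
}

#' Structured log message
#'
#' Emits `[level] component: msg` on the message stream (stderr), so log
#' output never interleaves with data written to stdout or to files.
#'
#' @param level One of "debug", "info", "warn", "error".
#' @param component Short component name.
#' @param msg Message text.
#' @return Invisibly, the formatted line.
#' @export
sen_log <- function(level = "info", component = "senadapt", msg = "") {
  line <- sprintf("[%s] %s: %s", toupper(level), component, msg)
  message(line)
  invisible(line)
}

# Numerically stabilized softmax (max-subtraction); internal.
softmax <- function(e) {
  check_finite(e, "alignment scores")
  w <- exp(e - max(e))
  w / sum(w)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
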