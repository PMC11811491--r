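# Latent interaction-state model: immediate tanh encoding of current cues,
# geometrically decaying contribution of past states, a logistic adaptive
# gate, and isotropic Gaussian noise.

#' Parameters of the latent interaction-state model
#'
#' Holds the encoder (D x M affine map, tanh-squashed), the decay map
#' (D x D matrix `A` and decay rate `rho`), the gate (D x (M + D) affine map,
#' logistic-squashed) and the noise scale. With `init = "random"` entries are
#' drawn `Normal(0, scale^2)` from the current RNG stream.
#'
#' @param M Number of behavioral cues (default 6).
#' @param D Latent dimension (default 4).
#' @param encoder_w,encoder_b Encoder weights (D x M) and bias (D).
#' @param decay_A Decay map matrix (D x D).
#' @param decay_rho Non-negative decay rate.
#' @param gate_w,gate_b Gate weights (D x (M + D)) and bias (D).
#' @param noise_sd Non-negative noise standard deviation (default 0.05).
#' @param init `"zero"` or `"random"`; used for any component not supplied.
#' @param scale SD of random initialization draws.
#' @return An object of class `sen_latent_params`.
#' @export
latent_params <- function(M = 6L, D = 4L,
                          encoder_w = NULL, encoder_b = NULL,
                          decay_A = NULL, decay_rho = 0.5,
                          gate_w = NULL, gate_b = NULL,
                          noise_sd = 0.05,
                          init = c("zero", "random"), scale = 0.5) {
  init <- match.arg(init)
  check_scalar(M, "M", lower = 1); check_scalar(D, "D", lower = 1)
  check_scalar(decay_rho, "decay_rho", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  M <- as.integer(M); D <- as.integer(D)
  rnd <- function(nr, nc = 1L) {
    if (init == "zero") matrix(0, nr, nc) else matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
  }
  if (is.null(encoder_w)) encoder_w <- rnd(D, M)
  if (is.null(encoder_b)) encoder_b <- as.numeric(rnd(D))
  if (is.null(decay_A)) decay_A <- rnd(D, D)
  if (is.null(gate_w)) gate_w <- rnd(D, M + D)
  if (is.null(gate_b)) gate_b <- as.numeric(rnd(D))
  p <- list(M = M, D = D,
            encoder_w = encoder_w, encoder_b = encoder_b,
            decay_A = decay_A, decay_rho = decay_rho,
            gate_w = gate_w, gate_b = gate_b,
            noise_sd = noise_sd)
  validate_latent_params(p)
  structure(p, class = "sen_latent_params")
}

validate_latent_params <- function(p) {
  stopifnot(
    is.matrix(p$encoder_w), all(dim(p$encoder_w) == c(p$D, p$M)),
    length(p$encoder_b) == p$D,
    is.matrix(p$decay_A), all(dim(p$decay_A) == c(p$D, p$D)),
    is.matrix(p$gate_w), all(dim(p$gate_w) == c(p$D, p$M + p$D)),
    length(p$gate_b) == p$D,
    p$decay_rho >= 0, p$noise_sd >= 0)
  check_finite(p$encoder_w, "encoder_w"); check_finite(p$decay_A, "decay_A")
  check_finite(p$gate_w, "gate_w")
  invisible(p)
}

#' @export
print.sen_latent_params <- function(x, ...) {
  cat(sprintf("<sen_latent_params> M = %d, D = %d, rho = %g, noise_sd = %g\n",
              x$M, x$D, x$decay_rho, x$noise_sd))
  invisible(x)
}

#' Immediate encoding of current cues
#'
#' `phi(x) = tanh(W1 x + b1)`: the bounded affine encoding of the current
#' interaction's cue vector into latent space. Components lie in (-1, 1).
#'
#' @param x Cue vector of length M.
#' @param params A [latent_params()].
#' @return Numeric vector of length D.
#' @export
encode_immediate <- function(x, params) {
  stopifnot(inherits(params, "sen_latent_params"))
  check_finite(x, "x")
  if (length(x) != params$M) {
    stop(sprintf("cue vector length %d does not match M = %d",
                 length(x), params$M), call. = FALSE)
  }
  as.numeric(tanh(params$encoder_w %*% x + params$encoder_b))
}

#' Decaying contribution of past latent states
#'
#' Accumulates `sum_{j < i} exp(-rho * (i - j)) * (A z_j)` over the ordered
#' history of past states: contributions shrink geometrically with temporal
#' distance, giving the model a flexible but decaying memory. An empty
#' history contributes the zero vector.
#'
#' @param history Matrix with one row per past state (`(i-1) x D`), ordered
#'   oldest first; `NULL` or a 0-row matrix for no history.
#' @param params A [latent_params()].
#' @return Numeric vector of length D.
#' @export
decay_contribution <- function(history, params) {
  stopifnot(inherits(params, "sen_latent_params"))
  if (is.null(history) || NROW(history) == 0L) return(rep(0, params$D))
  history <- rbind(history)  # accept a single vector
  if (ncol(history) != params$D) {
    stop(sprintf("history has %d columns, expected D = %d",
                 ncol(history), params$D), call. = FALSE)
  }
  check_finite(history, "history")
  n <- nrow(history)
  lag <- (n + 1L) - seq_len(n)          # i - j for j = 1..i-1, i = n + 1
  w <- exp(-params$decay_rho * lag)
  as.numeric(params$decay_A %*% (t(history) %*% w))
}

#' Adaptive gate
#'
#' `Gamma(x, z_prev) = logistic(Wg [x; z_prev] + bg)`: a componentwise gate
#' in (0, 1) that modulates how much of the combined immediate-plus-memory
#' signal passes into the new latent state, as a function of the current
#' interaction context and the previous state.
#'
#' @param x Cue vector of length M.
#' @param z_prev Previous latent state of length D (zero vector at i = 1).
#' @param params A [latent_params()].
#' @return Numeric vector of length D with components in (0, 1).
#' @export
latent_gate <- function(x, z_prev, params) {
  stopifnot(inherits(params, "sen_latent_params"))
  check_finite(x, "x"); check_finite(z_prev, "z_prev")
  if (length(x) != params$M || length(z_prev) != params$D) {
    stop("shape mismatch in gate inputs", call. = FALSE)
  }
  as.numeric(stats::plogis(params$gate_w %*% c(x, z_prev) + params$gate_b))
}

#' One latent-state update
#'
#' Computes `z_i = Gamma(x, z_{i-1}) * (phi(x) + decay) + eps` with
#' `eps ~ Normal(0, noise_sd^2 I)` drawn from the current RNG stream. With
#' `noise_sd = 0` the update is deterministic and equals the gated
#' expression exactly. The initial state is the zero vector: at `i = 1` the
#' gate receives `z_0 = 0` and the decay sum is empty.
#'
#' @param history Matrix of past states (rows ordered oldest first) or NULL.
#' @param x Cue vector of length M.
#' @param params A [latent_params()].
#' @param gate_override Optional fixed gate vector (length D) replacing the
#'   computed gate; a test/analysis hook for compositional checks.
#' @return New latent state, numeric vector of length D.
#' @export
update_latent <- function(history, x, params, gate_override = NULL) {
  stopifnot(inherits(params, "sen_latent_params"))
  D <- params$D
  z_prev <- if (is.null(history) || NROW(history) == 0L) rep(0, D)
            else as.numeric(rbind(history)[NROW(rbind(history)), ])
  g <- if (is.null(gate_override)) latent_gate(x, z_prev, params)
       else check_finite(gate_override, "gate_override")
  if (length(g) != D) stop("gate vector length must be D", call. = FALSE)
  base <- encode_immediate(x, params) + decay_contribution(history, params)
  z <- g * base
  if (params$noise_sd > 0) z <- z + stats::rnorm(D, 0, params$noise_sd)
  as.numeric(z)
}

#' Infer the latent trajectory of a session
#'
#' Runs the deterministic latent-state recursion (noise suppressed) over a
#' session's cue vectors, returning the full state trajectory. This is the
#' bridge from observed session logs to the state-space the transition model
#' is fitted in.
#'
#' @param session A `sen_session` (or any list with a `features` matrix).
#' @param params A [latent_params()].
#' @return An `n x D` matrix of latent states.
#' @export
infer_latent_trajectory <- function(session, params) {
  stopifnot(inherits(params, "sen_latent_params"))
  X <- session$features
  n <- nrow(X)
  p0 <- params
  p0$noise_sd <- 0
  class(p0) <- class(params)
  Z <- matrix(0, n, params$D)
  for (i in seq_len(n)) {
    hist <- if (i == 1L) NULL else Z[seq_len(i - 1L), , drop = FALSE]
    Z[i, ] <- update_latent(hist, X[i, ], p0)
  }
  Z
}
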