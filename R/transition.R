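# Dynamic transition mechanism: one-step latent evolution with a
# context-dependent decay gate, attention modulation in state space,
# smoothness regularization, and least-squares parameter fitting.

#' Parameters of the dynamic transition model
#'
#' The one-step update is
#' `z' = a * (delta * g(z) + (1 - delta) * h(x')) + eps`, where
#' `g = tanh(state_w z + state_b)` (bounded, so the convex combination stays
#' stable), `h = input_w x' + input_b`, `a` is a softmax attention vector in
#' state space computed from the concatenated `(z, x')` context, and `delta`
#' is a logistic novelty gate on the distance of `x'` from the running cue
#' mean.
#'
#' @param D Latent dimension. @param M Number of cues.
#' @param state_w,state_b Past-state map (D x D) and bias (D).
#' @param input_w,input_b New-input map (D x M) and bias (D).
#' @param attn_w,attn_b Attention map (D x (D + M)) and bias (D).
#' @param decay_c0,decay_c1 Decay-gate intercept and (non-negative) slope:
#'   `delta = logistic(c0 - c1 * ||x' - xbar||)`.
#' @param reg_lambda Non-negative smoothness regularization weight.
#' @param noise_sd Non-negative transition noise SD.
#' @param attention_renorm `"none"` applies the softmax weights verbatim
#'   (each < 1, so state magnitude shrinks over long runs); `"max"` divides
#'   by the largest weight (uniform attention becomes all-ones, the exact
#'   degeneracy hook); `"sum_to_D"` rescales weights to sum to D.
#' @param init,scale As in [latent_params()].
#' @return An object of class `sen_transition_params`.
#' @export
transition_params <- function(D = 4L, M = 6L,
                              state_w = NULL, state_b = NULL,
                              input_w = NULL, input_b = NULL,
                              attn_w = NULL, attn_b = NULL,
                              decay_c0 = 0, decay_c1 = 1,
                              reg_lambda = 0, noise_sd = 0,
                              attention_renorm = c("none", "max", "sum_to_D"),
                              init = c("zero", "random"), scale = 0.5) {
  init <- match.arg(init)
  attention_renorm <- match.arg(attention_renorm)
  check_scalar(D, "D", lower = 1); check_scalar(M, "M", lower = 1)
  check_scalar(decay_c1, "decay_c1", lower = 0)
  check_scalar(reg_lambda, "reg_lambda", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  D <- as.integer(D); M <- as.integer(M)
  rnd <- function(nr, nc = 1L) {
    if (init == "zero") matrix(0, nr, nc) else matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
  }
  if (is.null(state_w)) state_w <- rnd(D, D)
  if (is.null(state_b)) state_b <- as.numeric(rnd(D))
  if (is.null(input_w)) input_w <- rnd(D, M)
  if (is.null(input_b)) input_b <- as.numeric(rnd(D))
  if (is.null(attn_w)) attn_w <- rnd(D, D + M)
  if (is.null(attn_b)) attn_b <- as.numeric(rnd(D))
  p <- list(D = D, M = M, state_w = state_w, state_b = state_b,
            input_w = input_w, input_b = input_b,
            attn_w = attn_w, attn_b = attn_b,
            decay_c0 = decay_c0, decay_c1 = decay_c1,
            reg_lambda = reg_lambda, noise_sd = noise_sd,
            attention_renorm = attention_renorm)
  stopifnot(all(dim(p$state_w) == c(D, D)), length(p$state_b) == D,
            all(dim(p$input_w) == c(D, M)), length(p$input_b) == D,
            all(dim(p$attn_w) == c(D, D + M)), length(p$attn_b) == D)
  structure(p, class = "sen_transition_params")
}

#' @export
print.sen_transition_params <- function(x, ...) {
  cat(sprintf(paste0("<sen_transition_params> D = %d, M = %d, ",
                     "reg_lambda = %g, noise_sd = %g, renorm = %s\n"),
              x$D, x$M, x$reg_lambda, x$noise_sd, x$attention_renorm))
  invisible(x)
}

#' Transition attention vector
#'
#' `a = softmax(attn_w [z; x'] + attn_b)` over the D state components:
#' attention lives in state space (the only shape under which it can
#' multiply the length-D transition terms), computed from the concatenated
#' `(D + M)` context. Sums to one; every component in (0, 1).
#'
#' @param z Current latent state (length D).
#' @param x_next Next interaction's cue vector (length M).
#' @param params A [transition_params()].
#' @return Numeric vector of length D on the simplex.
#' @export
transition_attention <- function(z, x_next, params) {
  stopifnot(inherits(params, "sen_transition_params"))
  check_finite(z, "z"); check_finite(x_next, "x_next")
  if (length(z) != params$D || length(x_next) != params$M) {
    stop("shape mismatch in attention inputs", call. = FALSE)
  }
  softmax(as.numeric(params$attn_w %*% c(z, x_next) + params$attn_b))
}

renorm_attention <- function(a, mode) {
  switch(mode,
         none = a,
         max = a / max(a),
         sum_to_D = a * length(a))
}

#' Context-dependent decay gate
#'
#' `delta = logistic(c0 - c1 * ||x' - xbar||_2)`, where `xbar` is the running
#' mean of the cues seen so far. The gate is large (persistence of the
#' previous state) when the new interaction carries little novel
#' information, and decays toward new-input dominance as the interaction
#' departs from the running mean.
#'
#' @param x_next Next cue vector.
#' @param x_mean Running mean of cues seen so far (same length); defaults to
#'   `x_next` (zero novelty).
#' @param params A [transition_params()].
#' @return Scalar in (0, 1).
#' @export
context_decay <- function(x_next, x_mean = NULL, params) {
  stopifnot(inherits(params, "sen_transition_params"))
  check_finite(x_next, "x_next")
  if (is.null(x_mean)) x_mean <- x_next
  check_finite(x_mean, "x_mean")
  d <- sqrt(sum((x_next - x_mean)^2))
  stats::plogis(params$decay_c0 - params$decay_c1 * d)
}

#' One transition step
#'
#' `z' = a * (delta * tanh(state_w z + state_b) +
#' (1 - delta) * (input_w x' + input_b)) + eps`, with noise drawn from the
#' current RNG stream when `noise_sd > 0`. Attention is renormalized per the
#' `attention_renorm` flag in `params`.
#'
#' @param z Current latent state.
#' @param x_next Next cue vector.
#' @param params A [transition_params()].
#' @param x_mean Running cue mean for the decay gate (default: `x_next`).
#' @param delta Optional fixed decay value overriding the gate (analysis /
#'   degeneracy hook).
#' @return New latent state, length D.
#' @export
transition_step <- function(z, x_next, params, x_mean = NULL, delta = NULL) {
  stopifnot(inherits(params, "sen_transition_params"))
  a <- renorm_attention(transition_attention(z, x_next, params),
                        params$attention_renorm)
  if (is.null(delta)) delta <- context_decay(x_next, x_mean, params)
  check_scalar(delta, "delta", lower = 0, upper = 1)
  g <- tanh(as.numeric(params$state_w %*% z + params$state_b))
  h <- as.numeric(params$input_w %*% x_next + params$input_b)
  z_new <- a * (delta * g + (1 - delta) * h)
  if (params$noise_sd > 0) {
    z_new <- z_new + stats::rnorm(params$D, 0, params$noise_sd)
  }
  z_new
}

#' Smoothness penalty of a latent trajectory
#'
#' `Omega = lambda * sum_i ||z_{i+1} - z_i||^2`: penalizes abrupt jumps
#' between consecutive latent states. Zero iff the trajectory is constant
#' (or has a single state).
#'
#' @param trajectory `n x D` matrix of latent states (rows in time order).
#' @param reg_lambda Non-negative weight.
#' @return Non-negative scalar.
#' @export
smoothness_penalty <- function(trajectory, reg_lambda = 1) {
  check_scalar(reg_lambda, "reg_lambda", lower = 0)
  trajectory <- rbind(trajectory)
  check_finite(trajectory, "trajectory")
  if (nrow(trajectory) < 2L) return(0)
  reg_lambda * sum(diff(trajectory)^2)
}

#' Simulate latent trajectories from the transition model
#'
#' Generates sessions from known transition parameters: cue vectors are
#' drawn `Uniform(0, 1)`, the state starts at zero, and each step applies
#' [transition_step()] with the model's own noise. Used for
#' parameter-recovery studies where the generating truth is known.
#'
#' @param params A [transition_params()].
#' @param n_sessions Number of sessions.
#' @param n_steps States per session.
#' @param seed Seed for the whole batch.
#' @return List of sessions, each a list with `Z` (`n_steps x D`) and `X`
#'   (`n_steps x M`, where row i is the cue vector that produced `Z[i, ]`).
#' @export
simulate_transition_trajectories <- function(params, n_sessions, n_steps,
                                             seed) {
  stopifnot(inherits(params, "sen_transition_params"))
  check_scalar(n_sessions, "n_sessions", lower = 1)
  check_scalar(n_steps, "n_steps", lower = 2)
  set.seed(seed)
  lapply(seq_len(n_sessions), function(s) {
    X <- matrix(stats::runif(n_steps * params$M), n_steps, params$M)
    Z <- matrix(0, n_steps, params$D)
    Z[1, ] <- stats::runif(params$D, -0.5, 0.5)
    for (i in seq_len(n_steps - 1L)) {
      x_mean <- colMeans(X[seq_len(i), , drop = FALSE])
      Z[i + 1L, ] <- transition_step(Z[i, ], X[i + 1L, ], params,
                                     x_mean = x_mean)
    }
    list(Z = Z, X = X)
  })
}

# Stack trajectories into the design used by the fitting loss. Attention and
# decay are computed from the data and the fixed (non-fitted) parameters, so
# they enter the loss as known per-transition constants.
build_fit_design <- function(trajectories, params) {
  Zc <- NULL; Zn <- NULL; Xn <- NULL; A <- NULL; Delta <- NULL
  parts <- lapply(trajectories, function(tr) {
    Z <- rbind(tr$Z); X <- rbind(tr$X)
    n <- nrow(Z)
    stopifnot(n >= 2L, nrow(X) == n)
    idx <- seq_len(n - 1L)
    a <- matrix(0, params$D, n - 1L)
    d <- numeric(n - 1L)
    for (i in idx) {
      a[, i] <- renorm_attention(
        transition_attention(Z[i, ], X[i + 1L, ], params),
        params$attention_renorm)
      d[i] <- context_decay(X[i + 1L, ],
                            colMeans(X[seq_len(i), , drop = FALSE]), params)
    }
    list(Zc = t(Z[idx, , drop = FALSE]),
         Zn = t(Z[idx + 1L, , drop = FALSE]),
         Xn = t(X[idx + 1L, , drop = FALSE]),
         A = a, Delta = d)
  })
  list(Zc = do.call(cbind, lapply(parts, `[[`, "Zc")),
       Zn = do.call(cbind, lapply(parts, `[[`, "Zn")),
       Xn = do.call(cbind, lapply(parts, `[[`, "Xn")),
       A = do.call(cbind, lapply(parts, `[[`, "A")),
       Delta = unlist(lapply(parts, `[[`, "Delta")))
}

# theta vector <-> (state_w, state_b, input_w, input_b)
theta_pack <- function(p) {
  c(as.numeric(p$state_w), p$state_b, as.numeric(p$input_w), p$input_b)
}
theta_unpack <- function(theta, D, M) {
  i <- 0L
  state_w <- matrix(theta[i + seq_len(D * D)], D, D); i <- i + D * D
  state_b <- theta[i + seq_len(D)]; i <- i + D
  input_w <- matrix(theta[i + seq_len(D * M)], D, M); i <- i + D * M
  input_b <- theta[i + seq_len(D)]
  list(state_w = state_w, state_b = state_b,
       input_w = input_w, input_b = input_b)
}

# Loss and analytic gradient of the one-step prediction objective:
#   L = (1/T) sum ||z_next - pred||^2 + reg * (1/T) sum ||pred - z_cur||^2
# with pred = A * (Delta * tanh(W4 z + b4) + (1 - Delta) * (W5 x + b5)).
fit_loss_grad <- function(theta, design, D, M, reg, grad = TRUE) {
  th <- theta_unpack(theta, D, M)
  Tn <- ncol(design$Zc)
  DeltaM <- matrix(design$Delta, D, Tn, byrow = TRUE)
  G <- tanh(th$state_w %*% design$Zc + th$state_b)
  H <- th$input_w %*% design$Xn + th$input_b
  Pred <- design$A * (DeltaM * G + (1 - DeltaM) * H)
  R <- design$Zn - Pred
  loss <- sum(R^2) / Tn + reg * sum((Pred - design$Zc)^2) / Tn
  if (!grad) return(list(loss = loss))
  dPred <- (-2 / Tn) * R + (2 * reg / Tn) * (Pred - design$Zc)
  dG <- dPred * design$A * DeltaM * (1 - G^2)
  dH <- dPred * design$A * (1 - DeltaM)
  g <- c(as.numeric(dG %*% t(design$Zc)), rowSums(dG),
         as.numeric(dH %*% t(design$Xn)), rowSums(dH))
  list(loss = loss, grad = g)
}

#' Fit the transition model to observed trajectories
#'
#' Minimizes the mean one-step prediction error plus the smoothness penalty
#' by full-batch gradient descent with backtracking (Armijo) line search;
#' the step length is initialized each iteration by the Barzilai-Borwein
#' spectral rule, which handles the ill-conditioning between the bias
#' directions and the (weakly excited) state-map directions that a fixed
#' step cannot traverse. Only the past-state map (`state_w`, `state_b`)
#' and new-input map (`input_w`, `input_b`) are fitted; attention and
#' decay-gate parameters are taken from `params_init` and held fixed
#' (given the data they contribute known per-transition weights). The loss
#' trace is non-increasing by construction of the line search.
#'
#' @param trajectories List of sessions with `Z` (`n x D` states) and `X`
#'   (`n x M` cues), e.g. from [simulate_transition_trajectories()] or
#'   [infer_latent_trajectory()]. A single session may be passed directly.
#' @param params_init A [transition_params()] providing the initial point
#'   and the fixed attention/decay parameters.
#' @param control List of optimizer settings: `max_iter` (default 5000),
#'   `tol` (relative loss change for convergence, default 1e-8), `step0`
#'   (initial step, default 1), `bt_factor` (step shrink, default 0.5),
#'   `bt_max` (max halvings per iteration, default 40), `armijo`
#'   (sufficient-decrease constant, default 1e-4).
#' @return An object of class `sen_transition_fit`: list with `params`
#'   (fitted [transition_params()]), `loss` (final value), `trace`
#'   (per-iteration loss), `converged`, `iterations`, `degenerate` (TRUE
#'   when the inputs carry no variation).
#' @export
fit_transition <- function(trajectories, params_init, control = list()) {
  stopifnot(inherits(params_init, "sen_transition_params"))
  if (!is.null(trajectories$Z)) trajectories <- list(trajectories)
  if (length(trajectories) == 0L) stop("no trajectories", call. = FALSE)
  ctl <- utils::modifyList(
    list(max_iter = 5000L, tol = 1e-8, step0 = 1, bt_factor = 0.5,
         bt_max = 40L, armijo = 1e-4),
    control)
  D <- params_init$D; M <- params_init$M
  design <- build_fit_design(trajectories, params_init)
  degenerate <- stats::sd(design$Xn) < 1e-12 || stats::sd(design$Zc) < 1e-12
  if (degenerate) {
    sen_log("warn", "transition",
            "degenerate trajectories (no input variation); fit may be unidentifiable")
  }
  reg <- params_init$reg_lambda
  theta <- theta_pack(params_init)
  lg <- fit_loss_grad(theta, design, D, M, reg)
  trace <- lg$loss
  converged <- FALSE
  iter <- 0L
  theta_prev <- NULL
  g_prev <- NULL
  while (iter < ctl$max_iter) {
    iter <- iter + 1L
    g <- lg$grad
    gnorm2 <- sum(g^2)
    if (gnorm2 < 1e-30) { converged <- TRUE; break }
    s <- ctl$step0
    if (!is.null(theta_prev)) {  # Barzilai-Borwein spectral step
      dth <- theta - theta_prev
      dg <- g - g_prev
      denom <- sum(dth * dg)
      if (is.finite(denom) && denom > 0) {
        s <- min(max(sum(dth * dth) / denom, 1e-10), 1e8)
      }
    }
    accepted <- FALSE
    for (bt in seq_len(ctl$bt_max)) {
      cand <- theta - s * g
      cl <- fit_loss_grad(cand, design, D, M, reg, grad = FALSE)$loss
      if (is.finite(cl) && cl <= lg$loss - ctl$armijo * s * gnorm2) {
        accepted <- TRUE
        break
      }
      s <- s * ctl$bt_factor
    }
    if (!accepted) { converged <- TRUE; break }  # no descent direction left
    theta_prev <- theta
    g_prev <- g
    theta <- theta - s * g
    new_lg <- fit_loss_grad(theta, design, D, M, reg)
    trace <- c(trace, new_lg$loss)
    rel <- abs(lg$loss - new_lg$loss) / max(abs(lg$loss), 1e-30)
    lg <- new_lg
    if (rel < ctl$tol) { converged <- TRUE; break }
  }
  th <- theta_unpack(theta, D, M)
  fitted <- params_init
  fitted$state_w <- th$state_w; fitted$state_b <- th$state_b
  fitted$input_w <- th$input_w; fitted$input_b <- th$input_b
  structure(list(params = fitted, loss = lg$loss, trace = trace,
                 converged = converged, iterations = iter,
                 degenerate = degenerate),
            class = "sen_transition_fit")
}

#' @export
print.sen_transition_fit <- function(x, ...) {
  cat(sprintf("<sen_transition_fit> loss = %.6g after %d iterations (%s)\n",
              x$loss, x$iterations,
              if (x$converged) "converged" else "max iterations"))
  invisible(x)
}
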