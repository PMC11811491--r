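# Independent brute-force oracles used across tests. All are deliberately
# naive (explicit loops, no stabilization) so they share no code with the
# implementation paths they check.

oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_mse <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  s / length(a)
}

oracle_dot <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + a[i] * b[i]
  s
}

# Unstabilized exp-normalize; valid for small-magnitude inputs.
oracle_softmax <- function(e) {
  w <- numeric(length(e))
  for (i in seq_along(e)) w[i] <- exp(e[i])
  w / sum(w)
}

oracle_cumulative_reward <- function(r, beta, gamma) {
  i <- length(r)
  s <- 0
  for (k in seq_len(i)) s <- s + beta^(i - k) * r[k]
  gamma * s
}

oracle_final_objective <- function(r, beta, gamma) {
  total <- 0
  for (i in seq_along(r)) {
    inner <- 0
    for (k in seq_len(i)) inner <- inner + beta^(i - k) * r[k]
    total <- total + gamma * inner
  }
  total
}

oracle_discounted_return <- function(r, gamma) {
  i <- length(r)
  s <- 0
  for (t in seq_len(i)) s <- s + gamma^(i - t) * r[t]
  s
}

oracle_decay_contribution <- function(history, A, rho) {
  n <- nrow(history)
  D <- ncol(history)
  out <- numeric(D)
  for (j in seq_len(n)) {
    lag <- (n + 1) - j
    contrib <- as.numeric(A %*% history[j, ])
    for (d in seq_len(D)) out[d] <- out[d] + exp(-rho * lag) * contrib[d]
  }
  out
}

oracle_smoothness <- function(traj, lambda) {
  s <- 0
  for (i in seq_len(nrow(traj) - 1)) {
    s <- s + sum((traj[i + 1, ] - traj[i, ])^2)
  }
  lambda * s
}

# Straight-line single-function restatement of the transition update,
# independent of the package's modular path.
oracle_transition_step <- function(z, x_next, p, x_mean) {
  logits <- as.numeric(p$attn_w %*% c(z, x_next) + p$attn_b)
  a <- exp(logits - max(logits)); a <- a / sum(a)
  a <- switch(p$attention_renorm,
              none = a, max = a / max(a), sum_to_D = a * length(a))
  delta <- 1 / (1 + exp(-(p$decay_c0 -
                            p$decay_c1 * sqrt(sum((x_next - x_mean)^2)))))
  g <- tanh(as.numeric(p$state_w %*% z) + p$state_b)
  h <- as.numeric(p$input_w %*% x_next) + p$input_b
  a * (delta * g + (1 - delta) * h)
}

# Random trained transition truth with entries bounded away from zero, as
# used in parameter-recovery studies.
recovery_truth <- function(D = 2L, M = 2L, noise_sd = 0.02, seed = 31L) {
  set.seed(seed)
  draw <- function(n) sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.3, 1.2)
  transition_params(
    D = D, M = M,
    state_w = matrix(draw(D * D), D, D), state_b = draw(D),
    input_w = matrix(draw(D * M), D, M), input_b = draw(D),
    attn_w = matrix(rnorm(D * (D + M), 0, 0.5), D, D + M),
    attn_b = rnorm(D, 0, 0.5),
    noise_sd = noise_sd, decay_c0 = 0, decay_c1 = 1,
    attention_renorm = "max")
}

expect_session_equal <- function(a, b) {
  expect_identical(a$child_id, b$child_id)
  expect_equal(a$time, b$time)
  expect_equal(a$features, b$features, ignore_attr = TRUE)
  expect_identical(a$intervention, b$intervention)
  expect_equal(a$engagement, b$engagement)
}
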