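# Dynamic transition mechanism: attention, decay gate, one-step update,
# smoothness penalty, least-squares fitting.

test_that("transition attention is a softmax over the state dimensions", {
  p <- transition_params(D = 4, M = 2)
  expect_equal(transition_attention(rnorm(4), runif(2), p), rep(0.25, 4))
  p2 <- transition_params(D = 2, M = 2, attn_b = c(log(2), 0))
  expect_equal(transition_attention(rnorm(2), runif(2), p2), c(2 / 3, 1 / 3))
  set.seed(19)
  p3 <- transition_params(D = 3, M = 4, init = "random")
  for (i in 1:200) {
    z <- rnorm(3); x <- runif(4)
    a <- transition_attention(z, x, p3)
    logits <- as.numeric(p3$attn_w %*% c(z, x) + p3$attn_b)
    expect_equal(a, oracle_softmax(logits), tolerance = 1e-12)
    expect_equal(sum(a), 1, tolerance = 1e-9)
    expect_true(all(a > 0 & a < 1))
  }
  # shift invariance in the bias
  p4 <- p3; p4$attn_b <- p3$attn_b + 7.3
  z <- rnorm(3); x <- runif(4)
  expect_equal(transition_attention(z, x, p4),
               transition_attention(z, x, p3), tolerance = 1e-9)
  expect_error(transition_attention(rnorm(2), runif(4), p3), "shape")
})

test_that("context decay is a logistic novelty gate, decreasing in distance", {
  p0 <- transition_params(D = 2, M = 3, decay_c0 = 0, decay_c1 = 0)
  expect_equal(context_decay(runif(3), runif(3), p0), 0.5)
  psat <- transition_params(D = 2, M = 3, decay_c0 = 50, decay_c1 = 1)
  expect_equal(context_decay(runif(3), runif(3), psat), 1)
  p <- transition_params(D = 2, M = 3, decay_c0 = 0, decay_c1 = 2)
  xbar <- rep(0.5, 3)
  deltas <- sapply(seq(0, 1, length.out = 20), function(d) {
    context_decay(xbar + d, xbar, p)
  })
  expect_true(all(diff(deltas) < 0))
  expect_true(all(deltas > 0 & deltas < 1))
})

test_that("transition_step degenerates to its component maps at delta 0 and 1", {
  set.seed(21)
  p <- transition_params(D = 3, M = 2, init = "random", noise_sd = 0,
                         attention_renorm = "max")
  p$attn_w[] <- 0; p$attn_b[] <- 0  # uniform attention -> all-ones after renorm
  z <- rnorm(3); x <- runif(2)
  expect_equal(transition_step(z, x, p, delta = 1),
               tanh(as.numeric(p$state_w %*% z + p$state_b)))
  expect_equal(transition_step(z, x, p, delta = 0),
               as.numeric(p$input_w %*% x + p$input_b))
})

test_that("transition_step matches the straight-line oracle and is pure at zero noise", {
  set.seed(23)
  for (i in 1:100) {
    renorm <- sample(c("none", "max", "sum_to_D"), 1)
    p <- transition_params(D = 3, M = 2, init = "random", noise_sd = 0,
                           attention_renorm = renorm,
                           decay_c0 = rnorm(1), decay_c1 = runif(1, 0, 2))
    z <- rnorm(3); x <- runif(2); xm <- runif(2)
    got <- transition_step(z, x, p, x_mean = xm)
    expect_equal(got, oracle_transition_step(z, x, p, xm), tolerance = 1e-12)
    expect_identical(got, transition_step(z, x, p, x_mean = xm))
  }
})

test_that("bounded transitions stay finite over long runs", {
  set.seed(25)
  p <- transition_params(D = 4, M = 3, init = "random", noise_sd = 0.05,
                         attention_renorm = "max")
  z <- rnorm(4)
  set.seed(1)
  for (t in 1:10000) z <- transition_step(z, runif(3), p)
  expect_true(all(is.finite(z)))
  expect_lt(max(abs(z)), 50)
})

test_that("smoothness penalty is the weighted sum of squared jumps", {
  expect_equal(smoothness_penalty(matrix(0.3, 5, 2), 3), 0)
  expect_equal(smoothness_penalty(rbind(c(0, 0), c(1, 0)), 2), 2)
  expect_equal(smoothness_penalty(matrix(rnorm(3), 1, 3), 1), 0)
  set.seed(29)
  traj <- matrix(rnorm(30), 10, 3)
  expect_equal(smoothness_penalty(traj, 1.7), oracle_smoothness(traj, 1.7),
               tolerance = 1e-12)
})

test_that("smoothness penalty is reversal-invariant and scales quadratically", {
  set.seed(31)
  traj <- matrix(rnorm(24), 8, 3)
  expect_equal(smoothness_penalty(traj, 1),
               smoothness_penalty(traj[8:1, ], 1))
  expect_equal(smoothness_penalty(3 * traj, 1),
               9 * smoothness_penalty(traj, 1))
})

test_that("analytic fitting gradient matches central finite differences", {
  set.seed(33)
  p <- recovery_truth(D = 2, M = 3, noise_sd = 0.05, seed = 33)
  trajs <- simulate_transition_trajectories(p, 3, 8, seed = 34)
  design <- senadapt:::build_fit_design(trajs, p)
  theta <- senadapt:::theta_pack(p)
  theta <- theta + rnorm(length(theta), 0, 0.1)
  lg <- senadapt:::fit_loss_grad(theta, design, 2, 3, reg = 0.05)
  h <- 1e-6
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    fd <- (senadapt:::fit_loss_grad(tp, design, 2, 3, 0.05, grad = FALSE)$loss -
           senadapt:::fit_loss_grad(tm, design, 2, 3, 0.05, grad = FALSE)$loss) /
      (2 * h)
    expect_equal(lg$grad[k], fd, tolerance = 1e-5)
  }
})

test_that("fitting from the truth on noiseless data is a fixed point", {
  truth <- recovery_truth(D = 2, M = 2, noise_sd = 0, seed = 35)
  trajs <- simulate_transition_trajectories(truth, 5, 20, seed = 36)
  fit <- fit_transition(trajs, truth, control = list(max_iter = 50))
  expect_lt(fit$loss, 1e-20)
  for (nm in c("state_w", "state_b", "input_w", "input_b")) {
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-6)
  }
})

test_that("the fit loss trace is non-increasing and degenerate data warns", {
  truth <- recovery_truth(D = 2, M = 2, noise_sd = 0.05, seed = 37)
  trajs <- simulate_transition_trajectories(truth, 4, 15, seed = 38)
  init <- truth
  init$state_w <- init$state_w * 0; init$input_w <- init$input_w * 0
  fit <- fit_transition(trajs, init, control = list(max_iter = 300))
  expect_true(all(diff(fit$trace) <= 1e-12))
  expect_lte(fit$loss, fit$trace[1])
  # all-identical inputs: converges with the degenerate flag, no crash
  flat <- list(Z = matrix(0.2, 10, 2), X = matrix(0.5, 10, 2))
  expect_message(
    dfit <- fit_transition(list(flat), init, control = list(max_iter = 50)),
    "degenerate")
  expect_true(dfit$degenerate)
  expect_true(all(is.finite(dfit$trace)))
})

test_that("transition params survive a JSON round trip", {
  p <- recovery_truth(D = 3, M = 2, noise_sd = 0.02, seed = 39)
  path <- withr::local_tempfile(fileext = ".json")
  write_params(p, path)
  expect_equal(unclass(read_params(path)), unclass(p))
})
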