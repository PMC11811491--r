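# Finite-MDP abstraction of the engagement dynamics, with an exact
# value-iteration solver. The MDP discretizes the simulator's mean-reverting
# AR(1) engagement process onto score bins with Gaussian transition kernels
# integrated exactly (pnorm differences, boundary mass folded into the edge
# bins), so TD learning can be checked against a closed-form Q*.

#' Finite MDP over engagement score bins
#'
#' States are the `n_bins` uniform score bins (represented by their
#' midpoints); from midpoint `m` under intervention `j` the next engagement
#' is `Normal(carryover * m + (1 - carryover) * baseline + effect_j,
#' noise_sd^2)` with the out-of-range mass clipped into the first/last bin.
#' The reward of `(state, intervention)` is the expected next-step
#' engagement midpoint.
#'
#' @param baseline Mean-reversion level in \[0, 1\].
#' @param carryover AR(1) coefficient in \[0, 1).
#' @param effects Named numeric vector of per-intervention additive effects.
#' @param noise_sd Positive engagement noise SD.
#' @param n_bins Number of score bins.
#' @return An object of class `sen_mdp`: list with transition array `P`
#'   (`n_bins x n_arms x n_bins`), reward matrix `R` (`n_bins x n_arms`),
#'   bin `midpoints`, and the catalog.
#' @export
make_engagement_mdp <- function(baseline = 0.5, carryover = 0.7,
                                effects = c(video_modeling = 0.3,
                                            social_prompt = 0,
                                            reinforcement = 0),
                                noise_sd = 0.1, n_bins = 10L) {
  check_scalar(baseline, "baseline", lower = 0, upper = 1)
  check_scalar(carryover, "carryover", lower = 0, upper = 1)
  check_scalar(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0 for a stochastic MDP",
                          call. = FALSE)
  if (is.null(names(effects))) stop("`effects` must be named", call. = FALSE)
  n_bins <- as.integer(n_bins)
  catalog <- names(effects)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  P <- array(0, dim = c(n_bins, length(catalog), n_bins),
             dimnames = list(NULL, catalog, NULL))
  for (b in seq_len(n_bins)) {
    for (j in seq_along(catalog)) {
      mu <- carryover * mids[b] + (1 - carryover) * baseline + effects[j]
      cdf <- stats::pnorm(edges, mean = mu, sd = noise_sd)
      pr <- diff(cdf)
      pr[1L] <- pr[1L] + cdf[1L]                 # clip mass below 0
      pr[n_bins] <- pr[n_bins] + (1 - cdf[n_bins + 1L])  # clip mass above 1
      P[b, j, ] <- pr
    }
  }
  R <- matrix(0, n_bins, length(catalog), dimnames = list(NULL, catalog))
  for (j in seq_along(catalog)) R[, j] <- P[, j, ] %*% mids
  structure(list(P = P, R = R, midpoints = mids, catalog = catalog,
                 n_bins = n_bins),
            class = "sen_mdp")
}

#' Value iteration on a finite MDP
#'
#' Iterates `Q(b, j) = R(b, j) + gamma * sum_b' P(b, j, b') max_j' Q(b', j')`
#' to the fixed point; the contraction has modulus `gamma`, so the sup-norm
#' error bound at termination is `tol * gamma / (1 - gamma)`.
#'
#' @param mdp A [make_engagement_mdp()].
#' @param discount Discount factor in \[0, 1).
#' @param tol Sup-norm stopping tolerance on successive Q iterates.
#' @param max_iter Iteration cap.
#' @return Optimal Q matrix (`n_bins x n_arms`).
#' @export
value_iteration <- function(mdp, discount = 0.9, tol = 1e-10,
                            max_iter = 100000L) {
  stopifnot(inherits(mdp, "sen_mdp"))
  check_scalar(discount, "discount", lower = 0, upper = 1)
  if (discount >= 1) stop("`discount` must be < 1", call. = FALSE)
  Q <- mdp$R * 0
  for (it in seq_len(max_iter)) {
    V <- apply(Q, 1L, max)
    Qn <- mdp$R
    for (j in seq_along(mdp$catalog)) {
      Qn[, j] <- Qn[, j] + discount * as.numeric(mdp$P[, j, ] %*% V)
    }
    if (max(abs(Qn - Q)) < tol) return(Qn)
    Q <- Qn
  }
  sen_log("warn", "mdp", "value iteration hit max_iter before tolerance")
  Q
}

#' TD(0) learning on a finite MDP
#'
#' Runs epsilon-greedy TD(0) ([td_update()] / [epsilon_greedy()]) on
#' trajectories sampled from the MDP's exact transition tables. Sampling is
#' episodic with exploring starts: every `restart_every` steps the chain
#' restarts from a uniformly drawn bin, so all state-intervention pairs are
#' visited often enough for the whole table to converge (a mean-reverting
#' chain left to itself concentrates near its stationary mode and starves
#' the outlying bins). Rewards are the MDP's expected-next-engagement
#' rewards. Returns the learned Q table re-shaped to match
#' [value_iteration()] output for direct comparison.
#'
#' @param mdp A [make_engagement_mdp()].
#' @param steps Number of TD steps.
#' @param epsilon Exploration probability.
#' @param learn_rate TD learning rate.
#' @param discount Discount factor in \[0, 1).
#' @param seed Seed for the sampled trajectory.
#' @param restart_every Episode length between uniform restarts.
#' @return List with `Q` (matrix `n_bins x n_arms`) and the underlying
#'   `sen_qtable`.
#' @export
td_learn_mdp <- function(mdp, steps = 2e5, epsilon = 0.2, learn_rate = 0.1,
                         discount = 0.9, seed = 1L, restart_every = 10L) {
  stopifnot(inherits(mdp, "sen_mdp"))
  check_scalar(steps, "steps", lower = 1)
  check_scalar(restart_every, "restart_every", lower = 1)
  set.seed(seed)
  q <- q_table(mdp$catalog, n_bins = mdp$n_bins, learn_rate = learn_rate,
               discount = discount, epsilon = epsilon)
  keys <- sprintf("b%d", seq_len(mdp$n_bins) - 1L)
  b <- sample.int(mdp$n_bins, 1L)
  for (t in seq_len(steps)) {
    a <- epsilon_greedy(q, keys[b])
    j <- match(a, mdp$catalog)
    b_next <- sample.int(mdp$n_bins, 1L, prob = mdp$P[b, j, ])
    td_update(q, keys[b], a, mdp$R[b, j], keys[b_next])
    b <- if (t %% restart_every == 0L) sample.int(mdp$n_bins, 1L) else b_next
  }
  Q <- matrix(0, mdp$n_bins, length(mdp$catalog),
              dimnames = list(NULL, mdp$catalog))
  for (i in seq_len(mdp$n_bins)) Q[i, ] <- q_values(q, keys[i])
  list(Q = Q, qtable = q)
}
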