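# Reward stack: immediate, discounted-cumulative, predictive,
# penalty-modified, and final objective. Config keys carry role-prefixed
# names because the source symbols gamma/beta/lambda/delta are reused across
# unrelated roles in the model family; the methods vignette carries the
# symbol map.

#' Reward configuration
#'
#' @param sensitivity_alpha Non-negative sensitivity `alpha` scaling the
#'   observed improvement in the immediate reward `R = s + alpha * (s - s_prev)`.
#' @param scale_gamma Positive scale of the cumulative reward.
#' @param discount_beta Discount in \[0, 1\] emphasizing recent rewards in
#'   the cumulative sum (`beta^(i-k)`).
#' @param penalty_lambda Non-negative flat penalty applied when improvement
#'   falls below threshold.
#' @param improvement_delta Improvement threshold of the penalty indicator
#'   (strict: `delta_s < improvement_delta` incurs the penalty, equality
#'   does not).
#' @return An object of class `sen_reward_config`.
#' @export
reward_config <- function(sensitivity_alpha = 0.25,
                          scale_gamma = 1,
                          discount_beta = 0.9,
                          penalty_lambda = 0.1,
                          improvement_delta = 0.01) {
  check_scalar(sensitivity_alpha, "sensitivity_alpha", lower = 0)
  check_scalar(scale_gamma, "scale_gamma")
  if (scale_gamma <= 0) stop("`scale_gamma` must be > 0", call. = FALSE)
  check_scalar(discount_beta, "discount_beta", lower = 0, upper = 1)
  check_scalar(penalty_lambda, "penalty_lambda", lower = 0)
  check_scalar(improvement_delta, "improvement_delta")
  structure(list(sensitivity_alpha = sensitivity_alpha,
                 scale_gamma = scale_gamma,
                 discount_beta = discount_beta,
                 penalty_lambda = penalty_lambda,
                 improvement_delta = improvement_delta),
            class = "sen_reward_config")
}

#' Immediate reward
#'
#' `R = s + alpha * (s - s_prev)`: the current engagement level plus a
#' sensitivity-scaled bonus for the observed improvement over the previous
#' interaction.
#'
#' @param s Current engagement score.
#' @param s_prev Previous engagement score.
#' @param cfg A [reward_config()].
#' @return Scalar reward.
#' @export
immediate_reward <- function(s, s_prev, cfg = reward_config()) {
  check_scalar(s, "s"); check_scalar(s_prev, "s_prev")
  s + cfg$sensitivity_alpha * (s - s_prev)
}

#' Discounted cumulative reward
#'
#' `R_total = gamma * sum_{k=1}^{i} beta^(i-k) R_k`: recent rewards dominate
#' as `beta` shrinks. At `beta = 0` the convention `0^0 = 1` keeps the most
#' recent reward (only that reward survives, the fully myopic limit).
#'
#' @param rewards Ordered numeric vector `R_1..R_i` (length >= 1).
#' @param cfg A [reward_config()].
#' @return Scalar cumulative reward.
#' @export
cumulative_reward <- function(rewards, cfg = reward_config()) {
  if (length(rewards) == 0L) stop("empty reward history", call. = FALSE)
  check_finite(rewards, "rewards")
  i <- length(rewards)
  w <- cfg$discount_beta^(i - seq_len(i))  # R evaluates 0^0 as 1
  cfg$scale_gamma * sum(w * rewards)
}

#' Binned conditional next-score predictor
#'
#' Empirical estimator of `E[s_{i+1} | s_i, j]`: accumulates observed
#' next-step scores into (score-bin, intervention) cells, sharing the
#' uniform binning of the policy module. Cells with no observations fall
#' back to a martingale prior (predicted next score = current score).
#'
#' @param catalog Character vector of intervention ids.
#' @param n_bins Number of score bins.
#' @return An object of class `sen_reward_predictor`.
#' @export
reward_predictor <- function(catalog, n_bins = 10L) {
  if (length(catalog) == 0L) stop("empty intervention catalog", call. = FALSE)
  n_bins <- as.integer(n_bins)
  dm <- list(NULL, catalog)
  structure(list(catalog = catalog, n_bins = n_bins,
                 sums = matrix(0, n_bins, length(catalog), dimnames = dm),
                 counts = matrix(0L, n_bins, length(catalog), dimnames = dm)),
            class = "sen_reward_predictor")
}

#' Record an observed transition into the predictor
#'
#' @param pred A [reward_predictor()].
#' @param s Score at which intervention was applied.
#' @param intervention Intervention id.
#' @param s_next Observed next-step score.
#' @return The updated predictor.
#' @export
update_predictor <- function(pred, s, intervention, s_next) {
  stopifnot(inherits(pred, "sen_reward_predictor"))
  check_scalar(s_next, "s_next")
  if (!intervention %in% pred$catalog) {
    stop(sprintf("unknown intervention '%s'", intervention), call. = FALSE)
  }
  b <- score_bin(s, pred$n_bins) + 1L
  pred$sums[b, intervention] <- pred$sums[b, intervention] + s_next
  pred$counts[b, intervention] <- pred$counts[b, intervention] + 1L
  pred
}

#' Predictive reward
#'
#' `R_pred = E[s_{i+1} | s_i, j] + alpha * delta_s`, with the conditional
#' expectation taken from the binned empirical predictor; a cold cell
#' predicts `s_i` itself (martingale prior).
#'
#' @param s Current score.
#' @param intervention Intervention id under consideration.
#' @param pred A [reward_predictor()].
#' @param cfg A [reward_config()].
#' @param delta_s Observed recent improvement `s_i - s_{i-1}` (default 0).
#' @return Scalar predicted reward.
#' @export
predicted_reward <- function(s, intervention, pred, cfg = reward_config(),
                             delta_s = 0) {
  stopifnot(inherits(pred, "sen_reward_predictor"))
  check_scalar(s, "s"); check_scalar(delta_s, "delta_s")
  b <- score_bin(s, pred$n_bins) + 1L
  n <- pred$counts[b, intervention]
  expect <- if (n > 0) pred$sums[b, intervention] / n else s
  unname(expect + cfg$sensitivity_alpha * delta_s)
}

#' Penalty-modified reward
#'
#' `R_mod = R - lambda * 1[delta_s < delta]`: interventions whose observed
#' improvement falls strictly below the threshold incur a flat penalty,
#' discouraging strategies with minimal impact. Improvement exactly at the
#' threshold incurs no penalty.
#'
#' @param R Reward to modify.
#' @param delta_s Observed improvement.
#' @param cfg A [reward_config()].
#' @return Scalar modified reward, `<= R`.
#' @export
modified_reward <- function(R, delta_s, cfg = reward_config()) {
  check_scalar(R, "R"); check_scalar(delta_s, "delta_s")
  R - cfg$penalty_lambda * as.numeric(delta_s < cfg$improvement_delta)
}

#' Final cumulative reward objective
#'
#' `R_final = sum_{i=1}^{N} gamma * sum_{k=1}^{i} beta^(i-k) R_mod_k`: the
#' sum over interaction prefixes of the discounted cumulative
#' penalty-modified reward. Note this weights early rewards by a full
#' geometric series (each prefix re-counts them), unlike the standard RL
#' return of [discounted_return()]; both are reported, this one as a
#' session-level diagnostic.
#'
#' @param rewards_mod Ordered numeric vector of penalty-modified rewards.
#' @param cfg A [reward_config()].
#' @return Scalar objective value.
#' @export
final_objective <- function(rewards_mod, cfg = reward_config()) {
  if (length(rewards_mod) == 0L) stop("empty reward history", call. = FALSE)
  check_finite(rewards_mod, "rewards_mod")
  sum(vapply(seq_along(rewards_mod), function(i) {
    cumulative_reward(rewards_mod[seq_len(i)], cfg)
  }, numeric(1)))
}
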