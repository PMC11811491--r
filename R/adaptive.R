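# Closed-loop orchestration: observe -> score -> gate -> select -> act ->
# reward -> TD update, with confidence-based frequency and intensity
# adjustment. This is the adaptive engine that ties the scoring, feedback,
# policy and adjustment modules to the simulator.

#' Run one adaptive intervention session
#'
#' Interleaves, per interaction: cue observation from the child's
#' ground-truth dynamics; attention-based engagement scoring; confidence
#' over the recent score window; a Bernoulli intervention gate with
#' probability from [intervention_probability()]; epsilon-greedy arm
#' selection on the Q table (exploration follows [epsilon_schedule()] on
#' the global step counter unless a fixed `epsilon` is given); the
#' intervention applied at its smoothed, capped intensity; the
#' penalty-modified immediate reward from the next observed score; and a
#' TD(0) update keyed by the discretized score. Steps where the gate stays
#' closed apply no intervention and no Q update.
#'
#' @param profile A [make_child_profile()].
#' @param q A [q_table()] (mutated in place when `update = TRUE`).
#' @param n Number of interactions.
#' @param seed Session seed.
#' @param reward_cfg A [reward_config()].
#' @param adjust A [adjustment_state()] over the same catalog as `q`.
#' @param goal Goal vector for the scoring attention (default all ones).
#' @param epsilon Fixed exploration probability; `NULL` (default) follows
#'   the decay schedule at `global_step`.
#' @param schedule List of [epsilon_schedule()] settings
#'   (`epsilon0`, `decay`, `epsilon_min`).
#' @param global_step Global interaction counter carried across sessions
#'   (for the epsilon schedule).
#' @param update Perform TD and intensity updates? Set `FALSE` for pure
#'   evaluation rollouts.
#' @return List with `session` (a `sen_session` whose `confidence`,
#'   `intensity` and `reward` columns are filled), `q`, `adjust`, and the
#'   advanced `global_step`.
#' @export
run_adaptive_session <- function(profile, q, n = 50L, seed,
                                 reward_cfg = reward_config(),
                                 adjust = adjustment_state(q$catalog),
                                 goal = NULL,
                                 epsilon = NULL,
                                 schedule = list(epsilon0 = 0.3,
                                                 decay = 0.999,
                                                 epsilon_min = 0.05),
                                 global_step = 0L,
                                 update = TRUE) {
  stopifnot(inherits(profile, "sen_child_profile"),
            inherits(q, "sen_qtable"),
            inherits(adjust, "sen_adjustment"),
            identical(sort(q$catalog), sort(adjust$catalog)))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  check_scalar(n, "n", lower = 1)
  n <- as.integer(n)
  if (is.null(goal)) goal <- rep(1, profile$M)
  set.seed(seed)
  X <- matrix(0, n, profile$M)
  interv <- rep(NA_character_, n)
  scores <- numeric(n)
  eng <- numeric(n)
  conf <- numeric(n)
  used_intensity <- rep(NA_real_, n)
  rewards <- rep(NA_real_, n)
  l <- profile$baseline
  n_clipped <- 0L
  K <- adjust$window_size
  for (t in seq_len(n)) {
    if (l < 0 || l > 1) n_clipped <- n_clipped + 1L
    eng[t] <- clip01(l)
    X[t, ] <- observe_cues(l, profile)
    a_t <- attention_weights(alignment_scores(X[t, ], goal))
    scores[t] <- engagement_score(X[t, ], a_t)
    win <- scores[max(1L, t - K + 1L):t]
    conf[t] <- confidence(win)
    p_t <- intervention_probability(conf[t], adjust$p_min, adjust$p_max)
    if (stats::runif(1) < p_t) {
      eps_t <- if (is.null(epsilon)) {
        epsilon_schedule(global_step, schedule$epsilon0, schedule$decay,
                         schedule$epsilon_min)
      } else epsilon
      interv[t] <- epsilon_greedy(q, discretize_state(scores[t],
                                                      n_bins = q$n_bins),
                                  epsilon = eps_t)
      used_intensity[t] <- min(max(
        adjust$smoothed_intensities[[interv[t]]], 0), adjust$phi_max)
    }
    phi <- if (is.na(interv[t])) 1 else used_intensity[t]
    l <- advance_engagement(l, profile, interv[t], phi)
    global_step <- global_step + 1L
    # reward and updates use the *next* observed score
    s_next <- {
      x_next <- profile$cue_loadings * clip01(l)  # noiseless preview score
      a_n <- attention_weights(alignment_scores(clip01(x_next), goal))
      engagement_score(clip01(x_next), a_n)
    }
    if (!is.na(interv[t])) {
      delta_s <- s_next - scores[t]
      r <- immediate_reward(s_next, scores[t], reward_cfg)
      r <- modified_reward(r, delta_s, reward_cfg)
      rewards[t] <- r
      if (update) {
        td_update(q, discretize_state(scores[t], n_bins = q$n_bins),
                  interv[t], r,
                  discretize_state(s_next, n_bins = q$n_bins))
        j <- interv[t]
        adjust$intensities[[j]] <- min(max(intensity_update(
          adjust$intensities[[j]], delta_s, conf[t], adjust$eta), 0),
          adjust$phi_max)
        adjust$smoothed_intensities[[j]] <- smooth_intensity(
          adjust$smoothed_intensities[[j]], adjust$intensities[[j]],
          adjust$smooth_lambda)
      }
    }
  }
  session <- structure(
    list(child_id = profile$child_id, seed = as.integer(seed),
         time = as.numeric(seq_len(n)), features = X,
         intervention = interv, engagement = scores,
         confidence = conf, intensity = used_intensity,
         reward = rewards, n_clipped = n_clipped),
    class = "sen_session")
  list(session = session, q = q, adjust = adjust, global_step = global_step)
}

#' Train the adaptive policy over a cohort
#'
#' Runs [run_adaptive_session()] over `n_sessions` freshly drawn child
#' profiles (cycling through the cohort's children), sharing one Q table
#' and one adjustment state, with the epsilon schedule advancing over the
#' global step counter.
#'
#' @param cfg A [cohort_config()].
#' @param n_sessions Number of training sessions (default: the cohort
#'   size).
#' @param q Optional pre-built [q_table()]. The default training table uses
#'   an optimistic cold start (`default_q = 10`, about the value-scale
#'   ceiling `R_max / (1 - gamma)`) and a Robbins-Monro learning-rate
#'   schedule (`learn_rate = 1`, `visit_decay = 10`), so every arm is tried
#'   until proven worse and per-entry estimates average out the
#'   between-child target noise instead of tracking it.
#' @param reward_cfg,adjust,goal,schedule As in [run_adaptive_session()].
#' @return List with `q`, `adjust`, `sessions` (the training logs) and
#'   `global_step`.
#' @export
train_policy <- function(cfg, n_sessions = cfg$n_children, q = NULL,
                         reward_cfg = reward_config(),
                         adjust = NULL, goal = NULL,
                         schedule = list(epsilon0 = 0.3, decay = 0.999,
                                         epsilon_min = 0.05)) {
  stopifnot(inherits(cfg, "sen_cohort_config"))
  check_scalar(n_sessions, "n_sessions", lower = 1)
  if (is.null(q)) {
    q <- q_table(cfg$catalog, learn_rate = 1, visit_decay = 10,
                 default_q = 10)
  }
  if (is.null(adjust)) adjust <- adjustment_state(cfg$catalog)
  sessions <- vector("list", n_sessions)
  gs <- 0L
  for (i in seq_len(n_sessions)) {
    child <- ((i - 1L) %% cfg$n_children) + 1L
    profile <- make_child_profile(cfg, child)
    out <- run_adaptive_session(
      profile, q, n = cfg$n_interactions,
      seed = derive_seed(cfg$seed, 1000L + i),
      reward_cfg = reward_cfg, adjust = adjust, goal = goal,
      schedule = schedule, global_step = gs, update = TRUE)
    sessions[[i]] <- out$session
    adjust <- out$adjust
    gs <- out$global_step
  }
  list(q = q, adjust = adjust, sessions = sessions, global_step = gs)
}

# Built-in evaluation policies over a profile's catalog.
policy_from_q <- function(q) {
  force(q)
  function(t, engagement, features) {
    greedy_action(q, discretize_state(engagement, n_bins = q$n_bins))
  }
}

policy_random <- function(catalog) {
  force(catalog)
  function(t, engagement, features) catalog[sample.int(length(catalog), 1L)]
}

policy_never <- function() {
  function(t, engagement, features) NA_character_
}

policy_fixed <- function(arm) {
  force(arm)
  function(t, engagement, features) arm
}

#' Evaluate intervention policies on replicate sessions
#'
#' Rolls out each policy on `n_sessions` replicate children (profiles drawn
#' per replicate index, identical across policies so comparisons are
#' paired at the child level; session noise streams differ per policy) and
#' scores each session by the discounted return of the per-step immediate
#' rewards on the true engagement series.
#'
#' @param cfg A [cohort_config()].
#' @param policies Named list of policy functions
#'   `(step, engagement, features) -> id or NA` (see [simulate_session()]);
#'   the names label the output rows.
#' @param n_sessions Replicates per policy.
#' @param discount Discount factor of the per-session return.
#' @param reward_cfg A [reward_config()].
#' @param seed Master evaluation seed.
#' @return List with `summary` (data.frame: `policy`, `mean_return`,
#'   `sd_return`, `n_sessions`) and `returns` (matrix `n_sessions x
#'   n_policies` of per-replicate returns).
#' @export
evaluate_policies <- function(cfg, policies, n_sessions = 100L,
                              discount = 0.9,
                              reward_cfg = reward_config(), seed) {
  stopifnot(inherits(cfg, "sen_cohort_config"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (is.null(names(policies)) || any(names(policies) == "")) {
    stop("`policies` must be a named list", call. = FALSE)
  }
  returns <- matrix(0, n_sessions, length(policies),
                    dimnames = list(NULL, names(policies)))
  eval_seed <- derive_seed(cfg$seed, seed)
  for (r in seq_len(n_sessions)) {
    profile <- make_child_profile(cfg, r)
    for (p in seq_along(policies)) {
      ss <- simulate_session(
        profile, policy = policies[[p]], n = cfg$n_interactions,
        seed = derive_seed(eval_seed, r * length(policies) + p))
      e <- ss$engagement
      rw <- vapply(2:length(e), function(t) {
        immediate_reward(e[t], e[t - 1L], reward_cfg)
      }, numeric(1))
      returns[r, p] <- discounted_return(rw, discount)
    }
  }
  summary <- data.frame(
    policy = names(policies),
    mean_return = colMeans(returns),
    sd_return = apply(returns, 2L, stats::sd),
    n_sessions = n_sessions,
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, returns = returns)
}
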