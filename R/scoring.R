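# Observational layer: skill scores, learning-rate trajectories,
# attention-weighted engagement scoring, and the greedy effectiveness-based
# intervention mapping.

#' Aggregate skill score
#'
#' The overall social-skill score of a series of interactions is the
#' arithmetic mean of the per-interaction scores, giving each skill
#' component equal weight.
#'
#' @param scores Numeric vector of per-interaction scores (length >= 1).
#' @return The mean score.
#' @export
#' @examples
#' skill_score(c(0.2, 0.4, 0.6))
skill_score <- function(scores) {
  if (length(scores) == 0L) {
    stop("no interactions: `scores` is empty", call. = FALSE)
  }
  check_finite(scores, "scores")
  sum(scores) / length(scores)
}

#' Learning-rate trajectory
#'
#' Estimates the rate of skill acquisition over time by forward finite
#' differences of the score series: `g_i = (s_i - s_{i-1}) / (t_i - t_{i-1})`
#' for `i = 2..N`. Positive entries signal progress, negative entries
#' regression. Sessions are discrete event sequences, so the time derivative
#' is discretized as a forward difference.
#'
#' @param scores Numeric vector of scores (length >= 2).
#' @param times Strictly increasing numeric vector of timestamps, same length.
#' @return Numeric vector of length `N - 1` of per-interval rates.
#' @export
#' @examples
#' learning_rate(c(0, 1), c(0, 2))
learning_rate <- function(scores, times) {
  check_finite(scores, "scores")
  check_finite(times, "times")
  if (length(scores) != length(times)) {
    stop("`scores` and `times` must have equal length", call. = FALSE)
  }
  if (length(scores) < 2L) {
    stop("need at least 2 interactions to estimate a learning rate",
         call. = FALSE)
  }
  dt <- diff(times)
  if (any(dt <= 0)) {
    stop("`times` must be strictly increasing (duplicate or reversed timestamps)",
         call. = FALSE)
  }
  diff(scores) / dt
}

#' Alignment scores between cues and a skill goal
#'
#' Computes the per-cue alignment `e_j = x_j * goal_j` between the observed
#' cue intensities and a target social-skill goal vector. The elementwise
#' product is the default alignment kernel: with an all-ones goal it reduces
#' attention to a softmax over raw cue intensities, and goal components
#' up- or down-weight individual cues.
#'
#' @param x Numeric vector of M cue intensities.
#' @param goal Numeric vector of M goal components.
#' @return Numeric vector of M alignment scores.
#' @export
alignment_scores <- function(x, goal) {
  check_finite(x, "x")
  check_finite(goal, "goal")
  if (length(x) != length(goal)) {
    stop(sprintf("cue vector (M = %d) and goal vector (M = %d) lengths differ",
                 length(x), length(goal)), call. = FALSE)
  }
  x * goal
}

#' Attention weights over behavioral cues
#'
#' Normalizes alignment scores into attention weights with a softmax,
#' `a_j = exp(e_j) / sum_k exp(e_k)`, stabilized by max-subtraction. The
#' weights are strictly positive and sum to one, so they can be read as the
#' relative importance of each cue within the interaction.
#'
#' @param e Numeric vector of finite alignment scores (length >= 1).
#' @return An object of class `sen_attention`: a list with `weights`
#'   (softmax weights) and `alignments` (the input scores).
#' @export
#' @examples
#' attention_weights(c(log(2), 0))$weights  # 2/3, 1/3
attention_weights <- function(e) {
  w <- softmax(e)
  structure(list(weights = w, alignments = e), class = "sen_attention")
}

#' @export
print.sen_attention <- function(x, ...) {
  cat("<sen_attention> M =", length(x$weights), "\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' Engagement score of one interaction
#'
#' Aggregates the attended cues into a scalar engagement score
#' `E = sum_j a_j * x_j`. With weights on the simplex the score is a convex
#' combination of the cue intensities, so cues in \[0, 1\] give a score in
#' \[0, 1\].
#'
#' @param x Numeric vector of M cue intensities.
#' @param a Attention weights: either a [attention_weights()] object or a
#'   numeric vector of M weights.
#' @return The scalar engagement score.
#' @export
engagement_score <- function(x, a) {
  if (inherits(a, "sen_attention")) a <- a$weights
  check_finite(x, "x")
  check_finite(a, "a")
  if (length(x) != length(a)) {
    stop("cue vector and weight vector lengths differ", call. = FALSE)
  }
  sum(a * x)
}

#' Mean squared scoring loss
#'
#' Discrepancy between observed and predicted engagement scores,
#' `(1/N) sum (E_i - Ehat_i)^2`. Zero iff the two series are identical.
#'
#' @param observed Numeric vector of observed scores.
#' @param predicted Numeric vector of predicted scores, same length.
#' @return Non-negative scalar loss.
#' @export
scoring_loss <- function(observed, predicted) {
  check_finite(observed, "observed")
  check_finite(predicted, "predicted")
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  mean((observed - predicted)^2)
}

#' Empirical intervention-effectiveness table
#'
#' Accumulates observed post-intervention score changes into score-bin by
#' intervention cells, so that `Effectiveness(j | s)` can be estimated as the
#' empirical mean improvement of intervention `j` in the bin containing `s`.
#' Cells with no observations report an optimistic prior of 0 (cold-start
#' safe: an unexplored intervention is never penalized below "no effect").
#'
#' @param catalog Character vector of intervention ids (non-empty).
#' @param n_bins Number of score bins shared with the policy module.
#' @return An object of class `sen_effectiveness`.
#' @export
effectiveness_table <- function(catalog, n_bins = 10L) {
  if (length(catalog) == 0L) stop("empty intervention catalog", call. = FALSE)
  check_scalar(n_bins, "n_bins", lower = 1)
  n_bins <- as.integer(n_bins)
  dm <- list(NULL, catalog)
  structure(
    list(catalog = catalog, n_bins = n_bins,
         sums = matrix(0, n_bins, length(catalog), dimnames = dm),
         counts = matrix(0L, n_bins, length(catalog), dimnames = dm)),
    class = "sen_effectiveness")
}

#' Record an observed improvement into an effectiveness table
#'
#' @param tab A [effectiveness_table()].
#' @param s_prev Score at which the intervention was applied.
#' @param intervention Intervention id (must be in the catalog).
#' @param delta_s Observed change in score following the intervention.
#' @return The updated table.
#' @export
update_effectiveness <- function(tab, s_prev, intervention, delta_s) {
  stopifnot(inherits(tab, "sen_effectiveness"))
  check_scalar(delta_s, "delta_s")
  if (!intervention %in% tab$catalog) {
    stop(sprintf("unknown intervention '%s'", intervention), call. = FALSE)
  }
  b <- score_bin(s_prev, tab$n_bins) + 1L
  tab$sums[b, intervention] <- tab$sums[b, intervention] + delta_s
  tab$counts[b, intervention] <- tab$counts[b, intervention] + 1L
  tab
}

#' Estimated effectiveness of each intervention at a score
#'
#' @param tab A [effectiveness_table()].
#' @param s Score at which to evaluate.
#' @return Named numeric vector of expected improvements, one per catalog
#'   entry; 0 for unobserved cells.
#' @export
effectiveness_at <- function(tab, s) {
  stopifnot(inherits(tab, "sen_effectiveness"))
  b <- score_bin(s, tab$n_bins) + 1L
  n <- tab$counts[b, ]
  est <- ifelse(n > 0, tab$sums[b, ] / pmax(n, 1L), 0)
  names(est) <- tab$catalog
  est
}

#' Greedy intervention mapping
#'
#' Suggests the intervention with the highest expected improvement at the
#' current score: `h(s) = argmax_j Effectiveness(j | s)`. Ties are broken by
#' the lowest catalog index, so the mapping is deterministic.
#'
#' @param s Current score.
#' @param effectiveness Either a [effectiveness_table()] or a named numeric
#'   vector of per-intervention expected improvements.
#' @return The selected intervention id.
#' @export
#' @examples
#' greedy_intervention(0.5, c(A = 0.1, B = 0.3))
greedy_intervention <- function(s, effectiveness) {
  if (inherits(effectiveness, "sen_effectiveness")) {
    effectiveness <- effectiveness_at(effectiveness, s)
  }
  if (length(effectiveness) == 0L) {
    stop("empty intervention catalog", call. = FALSE)
  }
  check_finite(effectiveness, "effectiveness")
  if (is.null(names(effectiveness))) {
    stop("`effectiveness` must be named by intervention id", call. = FALSE)
  }
  names(effectiveness)[which.max(effectiveness)]
}

#' Feedback update of a score
#'
#' The reinforcement feedback loop carries the observed post-intervention
#' improvement back onto the score: `F(s, h(s)) = s + delta_s`.
#'
#' @param s Current score.
#' @param delta_s Observed improvement (may be negative).
#' @return The updated score.
#' @export
feedback_update <- function(s, delta_s) {
  check_scalar(s, "s")
  check_scalar(delta_s, "delta_s")
  s + delta_s
}

#' Per-session engagement score table
#'
#' Applies attention-based scoring to every interaction of one or more
#' sessions, returning a per-interaction table with the running mean skill
#' score.
#'
#' @param sessions A `sen_session` or list of them (see [simulate_session()]).
#' @param goal Goal vector of length M; default all ones.
#' @return A data.frame with columns `child_id`, `interaction_index`, `time`,
#'   `engagement`, `skill_score_cum`.
#' @export
score_sessions <- function(sessions, goal = NULL) {
  if (inherits(sessions, "sen_session")) sessions <- list(sessions)
  out <- lapply(sessions, function(ss) {
    n <- length(ss$time)
    m <- ncol(ss$features)
    g <- if (is.null(goal)) rep(1, m) else goal
    eng <- vapply(seq_len(n), function(i) {
      x <- ss$features[i, ]
      engagement_score(x, attention_weights(alignment_scores(x, g)))
    }, numeric(1))
    data.frame(child_id = ss$child_id,
               interaction_index = seq_len(n),
               time = ss$time,
               engagement = eng,
               skill_score_cum = cumsum(eng) / seq_len(n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
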