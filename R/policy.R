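# Tabular TD(0) intervention policy: discretized state keys, Q table,
# epsilon-greedy selection, discounted returns, and batch updates.

#' Discretize a (latent state, score) pair into a tabular state key
#'
#' The default key is the uniform score bin only (`"b<k>"`); with
#' `use_sign = TRUE` the sign pattern of the latent state is appended
#' (`"b<k>|+-+-"`), giving up to `2^D` extra context cells. Scores are
#' clipped to \[0, 1\] (with a log warning) and binned half-open with the
#' final bin closed at 1.
#'
#' @param s Engagement/skill score.
#' @param z Optional latent state vector (used only when `use_sign = TRUE`).
#' @param n_bins Number of score bins (default 10).
#' @param use_sign Append the sign pattern of `z`?
#' @return A single character state key.
#' @export
#' @examples
#' discretize_state(0.42)
#' discretize_state(0.42, z = c(0.3, -1), use_sign = TRUE)
discretize_state <- function(s, z = NULL, n_bins = 10L, use_sign = FALSE) {
  b <- score_bin(s, n_bins)
  key <- sprintf("b%d", b)
  if (use_sign) {
    if (is.null(z)) stop("`z` required when `use_sign = TRUE`", call. = FALSE)
    check_finite(z, "z")
    key <- paste0(key, "|", paste(ifelse(z >= 0, "+", "-"), collapse = ""))
  }
  key
}

#' Tabular Q function over (state key, intervention)
#'
#' Backed by an environment so TD updates mutate in place; treat the object
#' by reference. Unvisited states report the cold-start default Q for every
#' intervention.
#'
#' @param catalog Character vector of intervention ids (non-empty).
#' @param n_bins Score bins used by the associated discretization.
#' @param learn_rate TD learning rate `beta` in \[0, 1\].
#' @param discount Discount factor `gamma` in \[0, 1).
#' @param epsilon Exploration probability in \[0, 1\].
#' @param default_q Cold-start Q value.
#' @param visit_decay Optional learning-rate decay horizon `tau`: when set,
#'   the effective rate at the N-th update of an entry is
#'   `learn_rate * tau / (tau + N - 1)` (a Robbins-Monro schedule: at
#'   `learn_rate = 1`, `tau = 1` the entry is the running mean of its
#'   targets, and larger `tau` decays more slowly); `NULL` (default) keeps
#'   the rate constant as in the plain TD rule.
#' @return An object of class `sen_qtable`.
#' @export
q_table <- function(catalog, n_bins = 10L, learn_rate = 0.1, discount = 0.9,
                    epsilon = 0.1, default_q = 0, visit_decay = NULL) {
  if (length(catalog) == 0L) stop("empty intervention catalog", call. = FALSE)
  check_scalar(learn_rate, "learn_rate", lower = 0, upper = 1)
  check_scalar(discount, "discount", lower = 0, upper = 1)
  if (discount >= 1) stop("`discount` must be < 1", call. = FALSE)
  check_scalar(epsilon, "epsilon", lower = 0, upper = 1)
  check_scalar(default_q, "default_q")
  if (!is.null(visit_decay)) check_scalar(visit_decay, "visit_decay", lower = 1)
  q <- new.env(parent = emptyenv())
  q$values <- new.env(parent = emptyenv())
  q$visits <- new.env(parent = emptyenv())
  q$catalog <- catalog
  q$n_bins <- as.integer(n_bins)
  q$learn_rate <- learn_rate
  q$discount <- discount
  q$epsilon <- epsilon
  q$default_q <- default_q
  q$visit_decay <- visit_decay
  class(q) <- "sen_qtable"
  q
}

#' @export
print.sen_qtable <- function(x, ...) {
  cat(sprintf("<sen_qtable> %d arms, %d visited states, beta = %g, gamma = %g\n",
              length(x$catalog), length(ls(x$values)),
              x$learn_rate, x$discount))
  invisible(x)
}

#' Q values at a state
#'
#' @param q A [q_table()].
#' @param state State key from [discretize_state()].
#' @return Named numeric vector of Q values over the catalog.
#' @export
q_values <- function(q, state) {
  stopifnot(inherits(q, "sen_qtable"))
  v <- get0(state, envir = q$values, inherits = FALSE)
  if (is.null(v)) {
    v <- rep(q$default_q, length(q$catalog))
    names(v) <- q$catalog
  }
  v
}

#' One TD(0) update
#'
#' `Q(s, j) <- Q(s, j) + beta * (R + gamma * max_j' Q(s', j') - Q(s, j))`.
#' Only the touched entry changes; the table is mutated in place and also
#' returned.
#'
#' @param q A [q_table()].
#' @param state Current state key.
#' @param action Intervention id taken.
#' @param reward Observed reward (finite).
#' @param next_state Next state key.
#' @return The updated table, invisibly.
#' @export
td_update <- function(q, state, action, reward, next_state) {
  stopifnot(inherits(q, "sen_qtable"))
  check_scalar(reward, "reward")
  if (!action %in% q$catalog) {
    stop(sprintf("unknown intervention '%s'", action), call. = FALSE)
  }
  v <- q_values(q, state)
  target <- reward + q$discount * max(q_values(q, next_state))
  rate <- q$learn_rate
  if (!is.null(q$visit_decay)) {
    key <- paste(state, action, sep = "\r")
    n <- (get0(key, envir = q$visits, inherits = FALSE) %||% 0L) + 1L
    assign(key, n, envir = q$visits)
    rate <- rate * q$visit_decay / (q$visit_decay + n - 1L)
  }
  v[action] <- v[action] + rate * (target - v[action])
  assign(state, v, envir = q$values)
  invisible(q)
}

#' Greedy action at a state
#'
#' Argmax of the Q values, ties broken by the lowest catalog index.
#'
#' @param q A [q_table()].
#' @param state State key.
#' @return Intervention id.
#' @export
greedy_action <- function(q, state) {
  v <- q_values(q, state)
  q$catalog[which.max(v)]
}

#' Epsilon-greedy intervention selection
#'
#' With probability `epsilon`, a uniform draw over the full catalog
#' (including the greedy arm), otherwise the greedy argmax with
#' lowest-index tie-breaking. The greedy arm's total selection probability
#' is therefore `(1 - epsilon) + epsilon / |catalog|`. Uses the current RNG
#' stream; seed with [set.seed()] at the call site for reproducibility.
#'
#' @param q A [q_table()].
#' @param state State key.
#' @param epsilon Exploration probability; defaults to the table's own.
#' @return Intervention id.
#' @export
epsilon_greedy <- function(q, state, epsilon = NULL) {
  stopifnot(inherits(q, "sen_qtable"))
  if (is.null(epsilon)) epsilon <- q$epsilon
  check_scalar(epsilon, "epsilon", lower = 0, upper = 1)
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    q$catalog[sample.int(length(q$catalog), 1L)]
  } else {
    greedy_action(q, state)
  }
}

#' Exploration schedule
#'
#' Exponentially decaying exploration probability
#' `epsilon_t = max(epsilon_min, epsilon0 * decay^t)`.
#'
#' @param step Global interaction counter (0-based).
#' @param epsilon0 Initial exploration probability (default 0.3).
#' @param decay Per-step multiplicative decay (default 0.999).
#' @param epsilon_min Exploration floor (default 0.05).
#' @return Scalar epsilon.
#' @export
epsilon_schedule <- function(step, epsilon0 = 0.3, decay = 0.999,
                             epsilon_min = 0.05) {
  check_scalar(step, "step", lower = 0)
  max(epsilon_min, epsilon0 * decay^step)
}

#' Discounted return of a reward sequence
#'
#' `G = sum_{t=1}^{i} gamma^(i-t) R_t`: the standard discounted cumulative
#' reward, most recent reward undiscounted. At `gamma = 0` only the final
#' reward survives.
#'
#' @param rewards Ordered numeric vector (length >= 1).
#' @param discount Discount factor in \[0, 1\].
#' @return Scalar return.
#' @export
discounted_return <- function(rewards, discount) {
  if (length(rewards) == 0L) stop("empty reward sequence", call. = FALSE)
  check_finite(rewards, "rewards")
  check_scalar(discount, "discount", lower = 0, upper = 1)
  i <- length(rewards)
  sum(discount^(i - seq_len(i)) * rewards)
}

#' Mini-batch TD update
#'
#' Applies [td_update()] sequentially over the rows of a batch, in order;
#' the result equals iterated single updates exactly. An empty batch is a
#' no-op with a log warning.
#'
#' @param q A [q_table()].
#' @param batch A data.frame with columns `state`, `action`, `reward`,
#'   `next_state`.
#' @return The updated table, invisibly.
#' @export
batch_update <- function(q, batch) {
  stopifnot(inherits(q, "sen_qtable"))
  if (NROW(batch) == 0L) {
    sen_log("warn", "policy", "empty batch: no-op")
    return(invisible(q))
  }
  stopifnot(all(c("state", "action", "reward", "next_state") %in% names(batch)))
  for (i in seq_len(nrow(batch))) {
    td_update(q, batch$state[i], batch$action[i], batch$reward[i],
              batch$next_state[i])
  }
  invisible(q)
}

#' Serialize a Q table to JSON
#'
#' Keys are written in deterministic (sorted) order; hyperparameters and
#' catalog travel with the values, so [read_qtable()] reproduces the table
#' exactly.
#'
#' @param q A [q_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qtable <- function(q, path) {
  stopifnot(inherits(q, "sen_qtable"))
  keys <- sort(ls(q$values))
  vals <- lapply(keys, function(k) as.numeric(get(k, envir = q$values)))
  names(vals) <- keys
  doc <- list(schema = "senadapt/qtable/v1",
              catalog = q$catalog, n_bins = q$n_bins,
              learn_rate = q$learn_rate, discount = q$discount,
              epsilon = q$epsilon, default_q = q$default_q,
              values = vals)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a Q table from JSON
#'
#' @param path File written by [write_qtable()].
#' @return A [q_table()].
#' @export
read_qtable <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "senadapt/qtable/v1")) {
    stop("not a senadapt Q-table document", call. = FALSE)
  }
  q <- q_table(doc$catalog, n_bins = doc$n_bins, learn_rate = doc$learn_rate,
               discount = doc$discount, epsilon = doc$epsilon,
               default_q = doc$default_q)
  for (k in names(doc$values)) {
    v <- as.numeric(doc$values[[k]])
    names(v) <- q$catalog
    assign(k, v, envir = q$values)
  }
  q
}
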