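# Tabular TD policy: discretization, TD updates, epsilon-greedy selection,
# returns, batches, closed-loop orchestration.

test_that("score discretization respects bin edges and uniformity", {
  expect_equal(discretize_state(0, n_bins = 5), "b0")
  expect_equal(discretize_state(1, n_bins = 5), "b4")
  expect_equal(discretize_state(0.2, n_bins = 5), "b1")  # left-closed edges
  expect_equal(discretize_state(0.3, z = c(0.2, -4), use_sign = TRUE),
               "b3|+-")
  set.seed(43)
  s <- runif(1e4)
  counts <- table(factor(score_bin(s, 10), levels = 0:9))
  # multinomial: sd per cell = sqrt(n p (1-p))
  expect_true(all(abs(counts - 1000) < 3 * sqrt(1e4 * 0.1 * 0.9)))
  expect_message(expect_equal(discretize_state(1.4), "b9"), "clipped")
})

test_that("td_update applies the one-step TD rule to the touched entry only", {
  q <- q_table(c("A", "B"), learn_rate = 0.5, discount = 0.9)
  td_update(q, "b1", "A", 1, "b2")
  expect_equal(unname(q_values(q, "b1")), c(0.5, 0))
  expect_equal(unname(q_values(q, "b2")), c(0, 0))
  q0 <- q_table(c("A", "B"), learn_rate = 0)
  td_update(q0, "b1", "A", 5, "b2")
  expect_equal(unname(q_values(q0, "b1")), c(0, 0))
})

test_that("td_update converges to the self-loop fixed point R/(1-gamma)", {
  q <- q_table("A", learn_rate = 0.1, discount = 0.5)
  for (i in 1:1e4) td_update(q, "s", "A", 1, "s")
  expect_equal(unname(q_values(q, "s"))[1], 2, tolerance = 0.01)
})

test_that("the visit-decay schedule turns the entry into a running average", {
  # with gamma = 0 and tau = 1, rate_N = 1/N: Q is the mean of the rewards
  q <- q_table("A", learn_rate = 1, discount = 0, visit_decay = 1)
  r <- c(4, 2, 6, 0)
  for (x in r) td_update(q, "s", "A", x, "s2")
  expect_equal(unname(q_values(q, "s"))[1], mean(r))
})

test_that("epsilon_greedy calibrates to (1 - eps) + eps/|I| and is exact at eps 0", {
  q <- q_table(c("A", "B"), epsilon = 0)
  td_update(q, "s", "B", 1, "s")  # make B the greedy arm
  set.seed(45)
  picks <- replicate(200, epsilon_greedy(q, "s"))
  expect_true(all(picks == "B"))
  # eps = 1: uniform over both arms
  set.seed(46)
  picks <- replicate(2e4, epsilon_greedy(q, "s", epsilon = 1))
  pA <- mean(picks == "A")
  expect_lt(abs(pA - 0.5), 4 * sqrt(0.25 / 2e4))
  # eps = 0.3: greedy arm probability 0.85
  set.seed(47)
  picks <- replicate(2e4, epsilon_greedy(q, "s", epsilon = 0.3))
  pB <- mean(picks == "B")
  expect_lt(abs(pB - 0.85), 4 * sqrt(0.85 * 0.15 / 2e4))
  expect_error(epsilon_greedy(q_table("A"), "s", epsilon = 2), "epsilon")
})

test_that("greedy ties break toward the lowest catalog index", {
  q <- q_table(c("A", "B", "C"))
  expect_identical(greedy_action(q, "anywhere"), "A")
})

test_that("discounted_return matches the loop oracle and its limits", {
  expect_equal(discounted_return(c(1, 1, 1), 0.5), 1.75)
  expect_equal(discounted_return(c(3, 7, 2), 0), 2)
  set.seed(43)
  r <- runif(30)
  expect_equal(discounted_return(r, 0.9), oracle_discounted_return(r, 0.9),
               tolerance = 1e-12)
  expect_error(discounted_return(numeric(0), 0.9), "empty")
})

test_that("batch_update equals the sequential fold of td_update", {
  set.seed(47)
  batch <- data.frame(
    state = sprintf("b%d", sample(0:9, 500, replace = TRUE)),
    action = sample(c("A", "B", "C"), 500, replace = TRUE),
    reward = runif(500),
    next_state = sprintf("b%d", sample(0:9, 500, replace = TRUE)),
    stringsAsFactors = FALSE)
  q1 <- q_table(c("A", "B", "C"))
  batch_update(q1, batch)
  q2 <- q_table(c("A", "B", "C"))
  for (i in seq_len(nrow(batch))) {
    td_update(q2, batch$state[i], batch$action[i], batch$reward[i],
              batch$next_state[i])
  }
  for (k in ls(q1$values)) {
    expect_identical(q_values(q1, k), q_values(q2, k))
  }
  expect_message(batch_update(q1, batch[0, ]), "empty batch")
  # disjoint keys: order-independent result
  disjoint <- data.frame(state = sprintf("b%d", 0:9), action = "A",
                         reward = runif(10), next_state = "z",
                         stringsAsFactors = FALSE)
  ref <- q_table("A"); batch_update(ref, disjoint)
  for (shuffle in 1:10) {
    qs <- q_table("A")
    batch_update(qs, disjoint[sample(10), ])
    for (k in ls(ref$values)) expect_equal(q_values(qs, k), q_values(ref, k))
  }
})

test_that("Q values stay bounded by R_max / (1 - gamma) for bounded rewards", {
  set.seed(49)
  q <- q_table(c("A", "B"), learn_rate = 0.5, discount = 0.8)
  rmax <- 2
  for (i in 1:5000) {
    td_update(q, sprintf("b%d", sample(0:4, 1)),
              sample(c("A", "B"), 1), runif(1, 0, rmax),
              sprintf("b%d", sample(0:4, 1)))
  }
  vals <- unlist(lapply(ls(q$values), function(k) q_values(q, k)))
  expect_true(all(vals >= 0 & vals <= rmax / (1 - 0.8) + 1e-9))
})

test_that("epsilon schedule decays exponentially to its floor", {
  expect_equal(epsilon_schedule(0), 0.3)
  expect_equal(epsilon_schedule(1), 0.3 * 0.999)
  expect_equal(epsilon_schedule(1e6), 0.05)
})

test_that("q tables survive a JSON round trip with sorted keys", {
  set.seed(51)
  q <- q_table(c("A", "B"), learn_rate = 0.3, discount = 0.8, epsilon = 0.2,
               default_q = 1)
  for (i in 1:20) {
    td_update(q, sprintf("b%d", sample(0:9, 1)), sample(c("A", "B"), 1),
              runif(1), sprintf("b%d", sample(0:9, 1)))
  }
  path <- withr::local_tempfile(fileext = ".json")
  write_qtable(q, path)
  q2 <- read_qtable(path)
  expect_identical(sort(ls(q$values)), sort(ls(q2$values)))
  for (k in ls(q$values)) expect_equal(q_values(q, k), q_values(q2, k))
  expect_equal(q2$learn_rate, 0.3)
  expect_equal(q2$default_q, 1)
})

test_that("adaptive sessions are reproducible and follow a pre-trained table", {
  cc <- cohort_config(n_children = 3, n_interactions = 25, seed = 53)
  profile <- make_child_profile(cc, 1)
  q <- q_table(cc$catalog)
  # pre-train Q to prefer the known best arm everywhere
  for (b in 0:9) td_update(q, sprintf("b%d", b), cc$best_intervention, 10,
                           sprintf("b%d", b))
  out1 <- run_adaptive_session(profile, q, n = 25, seed = 99, epsilon = 0,
                               update = FALSE)
  out2 <- run_adaptive_session(profile, q, n = 25, seed = 99, epsilon = 0,
                               update = FALSE)
  expect_session_equal(out1$session, out2$session)
  iv <- out1$session$intervention
  expect_gt(sum(!is.na(iv)), 0)
  expect_true(all(iv[!is.na(iv)] == cc$best_intervention))
})

test_that("adaptive sessions fill confidence, intensity and reward columns", {
  cc <- cohort_config(n_children = 1, n_interactions = 20, seed = 55)
  profile <- make_child_profile(cc, 1)
  out <- run_adaptive_session(profile, q_table(cc$catalog), n = 20, seed = 7)
  ss <- out$session
  expect_true(all(ss$confidence > 0 & ss$confidence <= 1))
  it <- !is.na(ss$intervention)
  expect_true(all(!is.na(ss$intensity[it])))
  expect_true(all(!is.na(ss$reward[it])))
  expect_true(all(is.na(ss$reward[!it])))
})
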