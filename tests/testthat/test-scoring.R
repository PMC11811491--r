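# Observational layer: skill scores, learning rates, attention scoring,
# greedy intervention mapping.

test_that("skill_score is the mean and matches the summation oracle", {
  expect_equal(skill_score(c(1, 1, 1)), 1)
  expect_equal(skill_score(c(0.2, 0.4, 0.6)), 0.4)
  set.seed(1)
  s <- runif(100)
  expect_equal(skill_score(s), oracle_mean(s), tolerance = 1e-12)
  expect_error(skill_score(numeric(0)), "no interactions")
})

test_that("learning_rate takes forward differences over time", {
  expect_equal(learning_rate(c(0, 1), c(0, 2)), 0.5)
  expect_equal(learning_rate(rep(0.7, 5), 1:5), rep(0, 4))
  t <- 0:5
  expect_equal(learning_rate(t^2, t), c(1, 3, 5, 7, 9))
  expect_error(learning_rate(c(0, 1), c(1, 1)), "strictly increasing")
  expect_error(learning_rate(1, 1), "at least 2")
  expect_error(learning_rate(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("alignment_scores is the elementwise product with the goal", {
  expect_equal(alignment_scores(rep(1, 4), rep(1, 4)), rep(1, 4))
  expect_equal(alignment_scores(runif(3), rep(0, 3)), rep(0, 3))
  set.seed(3)
  x <- runif(6); g <- runif(6)
  e <- alignment_scores(x, g)
  for (j in seq_along(x)) expect_equal(e[j], x[j] * g[j])
  expect_error(alignment_scores(1:3, 1:4), "lengths differ")
})

test_that("attention weights form a softmax over alignments", {
  expect_equal(attention_weights(rep(0, 4))$weights, rep(0.25, 4))
  expect_equal(attention_weights(c(log(2), 0))$weights, c(2 / 3, 1 / 3))
  expect_error(attention_weights(c(1, NA)), "finite")
})

test_that("attention weights match the naive oracle, normalize, and are shift-invariant", {
  set.seed(42)
  for (i in 1:1000) {
    e <- runif(sample(2:8, 1), -3, 3)
    w <- attention_weights(e)$weights
    expect_equal(w, oracle_softmax(e), tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-9)
    expect_true(all(w > 0 & w < 1))
    shifted <- attention_weights(e + runif(1, -50, 50))$weights
    expect_equal(shifted, w, tolerance = 1e-9)
  }
})

test_that("engagement_score is the attended aggregate, bounded by the cue range", {
  expect_equal(engagement_score(c(2, 4), c(0.5, 0.5)), 3)
  expect_equal(engagement_score(c(0.1, 0.9, 0.4), c(0, 1, 0)), 0.9)
  set.seed(5)
  for (i in 1:50) {
    x <- runif(5)
    a <- attention_weights(runif(5, -2, 2))
    E <- engagement_score(x, a)
    expect_equal(E, oracle_dot(x, a$weights), tolerance = 1e-12)
    expect_gte(E, min(x))
    expect_lte(E, max(x))
  }
  expect_error(engagement_score(1:3, c(0.5, 0.5)), "lengths differ")
})

test_that("scoring_loss is the mean squared discrepancy", {
  expect_equal(scoring_loss(c(0.3, 0.6), c(0.3, 0.6)), 0)
  expect_equal(scoring_loss(c(0, 0), c(1, 1)), 1)
  set.seed(7)
  a <- runif(40); b <- runif(40)
  expect_equal(scoring_loss(a, b), oracle_mse(a, b), tolerance = 1e-12)
  expect_error(scoring_loss(1:3, 1:2), "equal length")
})

test_that("greedy_intervention takes the argmax with lowest-index ties", {
  expect_identical(greedy_intervention(0.5, c(A = 0.1, B = 0.3)), "B")
  expect_identical(greedy_intervention(0.5, c(A = 0.2, B = 0.2)), "A")
  expect_error(greedy_intervention(0.5, numeric(0)), "empty")
})

test_that("greedy_intervention is permutation-covariant up to the tie rule", {
  set.seed(11)
  for (i in 1:20) {
    eff <- runif(4)
    names(eff) <- c("a", "b", "c", "d")
    perm <- sample(4)
    expect_identical(greedy_intervention(0.5, eff),
                     greedy_intervention(0.5, eff[perm]))
  }
})

test_that("effectiveness table identifies a truly effective intervention", {
  # intervention C adds +0.3 to the score change, others nothing
  set.seed(13)
  hits <- 0L
  for (rep in 1:100) {
    tab <- effectiveness_table(c("A", "B", "C"), n_bins = 5)
    for (i in 1:60) {
      j <- sample(c("A", "B", "C"), 1)
      ds <- rnorm(1, 0, 0.05) + if (j == "C") 0.3 else 0
      tab <- update_effectiveness(tab, runif(1), j, ds)
    }
    if (identical(greedy_intervention(runif(1), tab), "C")) hits <- hits + 1L
  }
  expect_gt(hits / 100, 0.95)
})

test_that("effectiveness estimates default to the optimistic zero prior", {
  tab <- effectiveness_table(c("A", "B"), n_bins = 4)
  expect_equal(unname(effectiveness_at(tab, 0.5)), c(0, 0))
  tab <- update_effectiveness(tab, 0.5, "B", -0.2)
  expect_identical(greedy_intervention(0.5, tab), "A")
})

test_that("feedback_update adds the observed improvement", {
  expect_equal(feedback_update(0.5, 0.1), 0.6)
  expect_equal(feedback_update(0.5, 0), 0.5)
  expect_equal(feedback_update(0.5, -0.2), 0.3)
})

test_that("score_sessions emits one scored row per interaction", {
  cc <- cohort_config(n_children = 2, n_interactions = 8, seed = 99)
  cohort <- simulate_cohort(cc)
  tab <- score_sessions(cohort)
  expect_equal(nrow(tab), 16)
  expect_named(tab, c("child_id", "interaction_index", "time", "engagement",
                      "skill_score_cum"))
  expect_true(all(tab$engagement >= 0 & tab$engagement <= 1))
  first <- tab[tab$child_id == tab$child_id[1], ]
  expect_equal(first$skill_score_cum[3], mean(first$engagement[1:3]))
})
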