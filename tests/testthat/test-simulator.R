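# Synthetic cohort generator: determinism, ground-truth dynamics, effect
# recovery, closed-form steady state.

test_that("child profiles are deterministic and respect the config", {
  cc <- cohort_config(n_children = 5, n_interactions = 10, seed = 63)
  p1 <- make_child_profile(cc, 2)
  p2 <- make_child_profile(cc, 2)
  expect_equal(unclass(p1), unclass(p2))
  expect_true(p1$baseline >= 0.3 && p1$baseline <= 0.7)
  expect_true(p1$carryover >= 0.5 && p1$carryover <= 0.9)
  expect_equal(unname(p1$effects[cc$best_intervention]), 0.3)
  expect_true(all(p1$effects[setdiff(cc$catalog, cc$best_intervention)] == 0))
  cc0 <- cohort_config(n_children = 2, n_interactions = 5, best_effect = 0,
                       seed = 64)
  expect_true(all(make_child_profile(cc0, 1)$effects == 0))
})

test_that("profile baselines concentrate around the configured center", {
  cc <- cohort_config(n_children = 1000, n_interactions = 1, seed = 65)
  b <- sapply(1:1000, function(i) make_child_profile(cc, i)$baseline)
  # Uniform(0.3, 0.7): mean 0.5, sd of the mean = 0.4/sqrt(12)/sqrt(1000)
  expect_lt(abs(mean(b) - 0.5), 4 * 0.4 / sqrt(12) / sqrt(1000))
})

test_that("noiseless dynamics hold engagement at the baseline fixed point", {
  cc <- cohort_config(n_children = 1, n_interactions = 20, noise_sd = 0,
                      cue_noise_sd = 0, seed = 67)
  profile <- make_child_profile(cc, 1)
  ss <- simulate_session(profile, NULL, n = 20, seed = 1)
  expect_equal(ss$engagement, rep(profile$baseline, 20))
})

test_that("a single intervention shifts the next step by exactly its effect", {
  cc <- cohort_config(n_children = 1, n_interactions = 6, noise_sd = 0,
                      cue_noise_sd = 0, baseline_range = c(0.4, 0.4),
                      carryover_range = c(0.6, 0.6), seed = 69)
  profile <- make_child_profile(cc, 1)
  once <- function(t, e, x) if (t == 3) cc$best_intervention else NA_character_
  with_iv <- simulate_session(profile, once, n = 6, seed = 2)
  without <- simulate_session(profile, NULL, n = 6, seed = 2)
  expect_equal(with_iv$engagement[4] - without$engagement[4], 0.3)
  expect_equal(with_iv$engagement[1:3], without$engagement[1:3])
  # the shift decays at the carryover rate afterwards
  expect_equal(with_iv$engagement[5] - without$engagement[5], 0.3 * 0.6)
})

test_that("cohorts are reproducible byte-for-byte with distinct child streams", {
  cc <- cohort_config(n_children = 3, n_interactions = 10, seed = 71)
  a <- simulate_cohort(cc)
  b <- simulate_cohort(cc)
  expect_equal(length(a), 3)
  for (i in 1:3) expect_session_equal(a[[i]], b[[i]])
  seeds <- sapply(a, `[[`, "seed")
  expect_equal(length(unique(seeds)), 3)
  expect_false(identical(a[[1]]$engagement, a[[2]]$engagement))
})

test_that("steady-state engagement shift matches the AR(1) closed form", {
  # interior dynamics: small effect, moderate carryover, away from clipping
  cc <- cohort_config(n_children = 300, n_interactions = 60, M = 3,
                      best_effect = 0.05, noise_sd = 0.02,
                      baseline_range = c(0.4, 0.5),
                      carryover_range = c(0.5, 0.6), seed = 73)
  always_best <- function(t, e, x) cc$best_intervention
  with_iv <- simulate_cohort(cc, policy = always_best)
  without <- simulate_cohort(cc)
  # discard burn-in; compare to effect * p / (1 - carryover) per child
  shift_obs <- mean(sapply(seq_len(300), function(i) {
    mean(with_iv[[i]]$engagement[21:60]) - mean(without[[i]]$engagement[21:60])
  }))
  shift_theory <- mean(sapply(seq_len(300), function(i) {
    p <- make_child_profile(cc, i)
    0.05 / (1 - p$carryover)
  }))
  expect_equal(shift_obs, shift_theory, tolerance = 0.1 * shift_theory)
})

test_that("regression on simulated data recovers the configured effects", {
  cc <- cohort_config(n_children = 500, n_interactions = 100, M = 3,
                      best_effect = 0.1, other_effect = 0.02,
                      noise_sd = 0.03,
                      baseline_range = c(0.35, 0.45),
                      carryover_range = c(0.5, 0.6), seed = 75)
  set.seed(76)
  rnd <- function(t, e, x) {
    if (runif(1) < 0.5) sample(cc$catalog, 1) else NA_character_
  }
  cohort <- simulate_cohort(cc, policy = rnd)
  rows <- do.call(rbind, lapply(cohort, function(ss) {
    p <- make_child_profile(cc, as.integer(sub("child_", "", ss$child_id)))
    n <- length(ss$engagement)
    e <- ss$engagement
    # next-step change net of the known mean reversion isolates the effect
    resid <- e[-1] - (p$carryover * e[-n] + (1 - p$carryover) * p$baseline)
    data.frame(resid = resid,
               j = factor(ifelse(is.na(ss$intervention[-n]), "none",
                                 ss$intervention[-n]),
                          levels = c("none", cc$catalog)))
  }))
  fit <- lm(resid ~ j, data = rows)
  est <- coef(fit)
  expect_equal(unname(est[paste0("j", cc$best_intervention)]), 0.1,
               tolerance = 0.1)
  for (other in setdiff(cc$catalog, cc$best_intervention)) {
    expect_equal(unname(est[paste0("j", other)]), 0.02, tolerance = 0.1)
  }
})
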