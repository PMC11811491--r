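# Synthetic cohort generator: children with known mean-reverting AR(1)
# engagement dynamics, additive intervention effects, and cue vectors that
# load linearly on latent engagement. Deliberately simpler than the latent
# state-space model so that fitting and policy tests have an analytically
# tractable ground truth (closed-form AR(1) steady state, known effects).

#' Cohort configuration
#'
#' Defines the study conditions of a simulated cohort: one designated best
#' intervention with an additive next-step engagement effect (default +0.3)
#' and null alternatives, child-level baselines drawn Uniform(0.3, 0.7) and
#' carryover (AR(1) coefficient) Uniform(0.5, 0.9), Gaussian engagement and
#' cue noise. The master seed is mandatory; per-child seeds are derived with
#' [derive_seed()].
#'
#' @param n_children Number of children in the cohort.
#' @param n_interactions Interactions per session.
#' @param M Number of behavioral cues (default 6).
#' @param catalog Character vector of intervention ids.
#' @param best_intervention Id of the effective intervention (must be in the
#'   catalog).
#' @param best_effect Additive next-step engagement effect of the best
#'   intervention (default 0.3).
#' @param other_effect Effect of the remaining interventions (default 0).
#' @param noise_sd Engagement noise SD (default 0.05).
#' @param cue_noise_sd Cue noise SD (default 0.05).
#' @param baseline_range Range of child baselines (default `c(0.3, 0.7)`).
#' @param carryover_range Range of AR(1) coefficients (default `c(0.5, 0.9)`).
#' @param seed Mandatory master seed (integer).
#' @return An object of class `sen_cohort_config`.
#' @export
cohort_config <- function(n_children = 30L, n_interactions = 50L, M = 6L,
                          catalog = c("video_modeling", "social_prompt",
                                      "reinforcement"),
                          best_intervention = "video_modeling",
                          best_effect = 0.3, other_effect = 0,
                          noise_sd = 0.05, cue_noise_sd = 0.05,
                          baseline_range = c(0.3, 0.7),
                          carryover_range = c(0.5, 0.9),
                          seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  check_scalar(seed, "seed")
  check_scalar(n_children, "n_children", lower = 1)
  check_scalar(n_interactions, "n_interactions", lower = 1)
  check_scalar(M, "M", lower = 1)
  if (length(catalog) == 0L) stop("empty intervention catalog", call. = FALSE)
  if (!best_intervention %in% catalog) {
    stop("`best_intervention` must be in the catalog", call. = FALSE)
  }
  check_scalar(best_effect, "best_effect")
  check_scalar(other_effect, "other_effect")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(cue_noise_sd, "cue_noise_sd", lower = 0)
  stopifnot(length(baseline_range) == 2L, length(carryover_range) == 2L,
            baseline_range[1] <= baseline_range[2],
            carryover_range[1] <= carryover_range[2],
            baseline_range[1] >= 0, baseline_range[2] <= 1,
            carryover_range[1] >= 0, carryover_range[2] < 1)
  structure(list(n_children = as.integer(n_children),
                 n_interactions = as.integer(n_interactions),
                 M = as.integer(M), catalog = catalog,
                 best_intervention = best_intervention,
                 best_effect = best_effect, other_effect = other_effect,
                 noise_sd = noise_sd, cue_noise_sd = cue_noise_sd,
                 baseline_range = baseline_range,
                 carryover_range = carryover_range,
                 seed = as.integer(seed)),
            class = "sen_cohort_config")
}

#' Ground-truth profile of one simulated child
#'
#' Draws baseline engagement, carryover, cue loadings (Uniform(0.5, 1.5),
#' so cues track latent engagement with child-specific gain), and the
#' per-intervention effect vector (the configured best/other effects).
#' Deterministic given `(cfg, child_index)`: the profile stream is seeded
#' with `derive_seed(cfg$seed, 2 * child_index - 1)`.
#'
#' @param cfg A [cohort_config()].
#' @param child_index 1-based child index within the cohort.
#' @return An object of class `sen_child_profile`.
#' @export
make_child_profile <- function(cfg, child_index = 1L) {
  stopifnot(inherits(cfg, "sen_cohort_config"))
  check_scalar(child_index, "child_index", lower = 1)
  set.seed(derive_seed(cfg$seed, 2 * child_index - 1))
  effects <- rep(cfg$other_effect, length(cfg$catalog))
  names(effects) <- cfg$catalog
  effects[cfg$best_intervention] <- cfg$best_effect
  structure(list(
    child_id = sprintf("child_%03d", as.integer(child_index)),
    baseline = stats::runif(1, cfg$baseline_range[1], cfg$baseline_range[2]),
    carryover = stats::runif(1, cfg$carryover_range[1], cfg$carryover_range[2]),
    effects = effects,
    cue_loadings = stats::runif(cfg$M, 0.5, 1.5),
    noise_sd = cfg$noise_sd, cue_noise_sd = cfg$cue_noise_sd,
    M = cfg$M, catalog = cfg$catalog),
    class = "sen_child_profile")
}

#' @export
print.sen_child_profile <- function(x, ...) {
  cat(sprintf("<sen_child_profile> %s: baseline %.3f, carryover %.3f\n",
              x$child_id, x$baseline, x$carryover))
  invisible(x)
}

# One step of the ground-truth engagement dynamics; shared by the open-loop
# simulator and the adaptive closed loop so the two can never diverge.
advance_engagement <- function(l, profile, intervention = NA_character_,
                               intensity = 1) {
  eff <- 0
  if (!is.na(intervention)) {
    eff <- profile$effects[[intervention]] * intensity
  }
  profile$carryover * l + (1 - profile$carryover) * profile$baseline + eff +
    (if (profile$noise_sd > 0) stats::rnorm(1, 0, profile$noise_sd) else 0)
}

# Cue vector observed at latent engagement l.
observe_cues <- function(l, profile) {
  x <- profile$cue_loadings * l
  if (profile$cue_noise_sd > 0) {
    x <- x + stats::rnorm(profile$M, 0, profile$cue_noise_sd)
  }
  clip01(x)
}

#' Simulate one child session
#'
#' Generates `n` interaction records from the ground-truth dynamics
#' `l_{t+1} = carryover * l_t + (1 - carryover) * baseline +
#' effect(j_t) * intensity(j_t) + Normal(0, noise_sd^2)`, with observed
#' engagement `E_t = clip(l_t, 0, 1)` and cues
#' `X_t = clip(loadings * l_t + cue noise, 0, 1)`. The latent level starts
#' at the child's baseline. Clip events on the engagement series are
#' counted in `n_clipped`.
#'
#' @param profile A [make_child_profile()].
#' @param policy `NULL` (never intervene) or a function
#'   `(step, engagement, features) -> intervention id or NA`.
#' @param n Number of interactions.
#' @param seed Session seed.
#' @param intensity Named per-intervention intensity multipliers (default
#'   all 1).
#' @return An object of class `sen_session`: list with `child_id`, `seed`,
#'   `time` (1..n), `features` (`n x M`), `intervention` (character, NA for
#'   none), `engagement`, `confidence`/`intensity`/`reward` (NA here;
#'   filled by the adaptive loop), `n_clipped`.
#' @export
simulate_session <- function(profile, policy = NULL, n = 50L, seed,
                             intensity = NULL) {
  stopifnot(inherits(profile, "sen_child_profile"))
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  check_scalar(n, "n", lower = 1)
  n <- as.integer(n)
  if (is.null(intensity)) {
    intensity <- rep(1, length(profile$catalog))
    names(intensity) <- profile$catalog
  }
  set.seed(seed)
  X <- matrix(0, n, profile$M)
  interv <- rep(NA_character_, n)
  eng <- numeric(n)
  l <- profile$baseline
  n_clipped <- 0L
  for (t in seq_len(n)) {
    if (l < 0 || l > 1) n_clipped <- n_clipped + 1L
    eng[t] <- clip01(l)
    X[t, ] <- observe_cues(l, profile)
    if (!is.null(policy)) {
      j <- policy(t, eng[t], X[t, ])
      if (!is.null(j) && !is.na(j)) interv[t] <- j
    }
    phi <- if (is.na(interv[t])) 1 else intensity[[interv[t]]]
    l <- advance_engagement(l, profile, interv[t], phi)
  }
  if (n_clipped > 0L) {
    sen_log("debug", "simulator",
            sprintf("%s: %d engagement values clipped to [0, 1]",
                    profile$child_id, n_clipped))
  }
  structure(list(child_id = profile$child_id, seed = as.integer(seed),
                 time = as.numeric(seq_len(n)), features = X,
                 intervention = interv, engagement = eng,
                 confidence = rep(NA_real_, n),
                 intensity = rep(NA_real_, n),
                 reward = rep(NA_real_, n),
                 n_clipped = n_clipped),
            class = "sen_session")
}

#' @export
print.sen_session <- function(x, ...) {
  cat(sprintf("<sen_session> %s: %d interactions, %d intervened, mean E = %.3f\n",
              x$child_id, length(x$time), sum(!is.na(x$intervention)),
              mean(x$engagement)))
  invisible(x)
}

#' Simulate a cohort of child sessions
#'
#' One session per child; child profiles and session noise streams use
#' seeds derived from the master seed (odd indices for profiles, even for
#' sessions), so the whole cohort is reproducible byte-for-byte and
#' sessions are independent across children.
#'
#' @param cfg A [cohort_config()].
#' @param policy As in [simulate_session()].
#' @param intensity As in [simulate_session()].
#' @return A list of `sen_session` objects with class `sen_cohort`; the
#'   config is attached as attribute `config`.
#' @export
simulate_cohort <- function(cfg, policy = NULL, intensity = NULL) {
  stopifnot(inherits(cfg, "sen_cohort_config"))
  sessions <- lapply(seq_len(cfg$n_children), function(i) {
    profile <- make_child_profile(cfg, i)
    simulate_session(profile, policy = policy, n = cfg$n_interactions,
                     seed = derive_seed(cfg$seed, 2 * i),
                     intensity = intensity)
  })
  structure(sessions, class = "sen_cohort", config = cfg)
}
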