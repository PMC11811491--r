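# Run configuration: a flat-sectioned YAML document with validated keys,
# documented defaults, and a mandatory master seed.

config_defaults <- function() {
  list(
    model = list(D = 4L, M = 6L, decay_rho = 0.5, latent_noise_sd = 0.05,
                 fit_max_iter = 5000L, fit_tol = 1e-8),
    reward = list(sensitivity_alpha = 0.25, scale_gamma = 1,
                  discount_beta = 0.9, penalty_lambda = 0.1,
                  improvement_delta = 0.01),
    policy = list(n_bins = 10L, learn_rate = 1, discount = 0.9,
                  epsilon0 = 0.3, epsilon_decay = 0.999, epsilon_min = 0.05,
                  default_q = 10, visit_decay = 10),
    adjustment = list(window = 5L, eta = 0.1, smooth_lambda = 0.8,
                      p_min = 0.2, p_max = 0.9, phi_max = 2),
    simulator = list(n_children = 30L, n_interactions = 50L,
                     catalog = c("video_modeling", "social_prompt",
                                 "reinforcement"),
                     best_intervention = "video_modeling",
                     best_effect = 0.3, other_effect = 0,
                     noise_sd = 0.05, cue_noise_sd = 0.05,
                     baseline_min = 0.3, baseline_max = 0.7,
                     carryover_min = 0.5, carryover_max = 0.9))
}

config_ranges <- function() {
  # key -> c(lower, upper); checked after defaults are merged
  list(
    "reward.sensitivity_alpha" = c(0, Inf),
    "reward.discount_beta" = c(0, 1),
    "reward.penalty_lambda" = c(0, Inf),
    "policy.n_bins" = c(1, Inf),
    "policy.learn_rate" = c(0, 1),
    "policy.visit_decay" = c(1, Inf),
    "policy.discount" = c(0, 1),
    "policy.epsilon0" = c(0, 1),
    "policy.epsilon_decay" = c(0, 1),
    "policy.epsilon_min" = c(0, 1),
    "adjustment.window" = c(1, Inf),
    "adjustment.eta" = c(0, Inf),
    "adjustment.smooth_lambda" = c(0, 1),
    "adjustment.p_min" = c(0, 1),
    "adjustment.p_max" = c(0, 1),
    "adjustment.phi_max" = c(0, Inf),
    "simulator.n_children" = c(1, Inf),
    "simulator.n_interactions" = c(1, Inf),
    "simulator.noise_sd" = c(0, Inf),
    "simulator.cue_noise_sd" = c(0, Inf),
    "simulator.baseline_min" = c(0, 1),
    "simulator.baseline_max" = c(0, 1),
    "simulator.carryover_min" = c(0, 1),
    "simulator.carryover_max" = c(0, 1),
    "model.D" = c(1, Inf),
    "model.M" = c(1, Inf),
    "model.decay_rho" = c(0, Inf),
    "model.latent_noise_sd" = c(0, Inf))
}

#' Default run configuration
#'
#' The fully populated configuration with every documented default applied.
#'
#' @param seed Mandatory master seed.
#' @return A validated configuration list of class `sen_config`.
#' @export
default_config <- function(seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  validate_config(c(config_defaults(), list(seed = as.integer(seed))))
}

#' Validate a configuration list
#'
#' Rejects unknown keys (naming them section.key), checks every documented
#' range, and requires a seed. Returns the effective configuration with
#' defaults merged in.
#'
#' @param cfg A (possibly partial) configuration list.
#' @return The effective configuration, class `sen_config`.
#' @export
validate_config <- function(cfg) {
  defaults <- config_defaults()
  known_sections <- c(names(defaults), "seed")
  unknown <- setdiff(names(cfg), known_sections)
  if (length(unknown)) {
    stop(sprintf("unknown config key: %s", unknown[1L]), call. = FALSE)
  }
  if (is.null(cfg$seed)) stop("missing mandatory key: seed", call. = FALSE)
  check_scalar(cfg$seed, "seed")
  out <- list(seed = as.integer(cfg$seed))
  for (sec in names(defaults)) {
    given <- cfg[[sec]]
    if (!is.null(given)) {
      bad <- setdiff(names(given), names(defaults[[sec]]))
      if (length(bad)) {
        stop(sprintf("unknown config key: %s.%s", sec, bad[1L]),
             call. = FALSE)
      }
    }
    out[[sec]] <- utils::modifyList(defaults[[sec]], as.list(given %||% list()))
  }
  for (key in names(config_ranges())) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    val <- out[[parts[1L]]][[parts[2L]]]
    rng <- config_ranges()[[key]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val) ||
        val < rng[1L] || val > rng[2L]) {
      stop(sprintf("config value out of range for %s (allowed [%s, %s])",
                   key, format(rng[1L]), format(rng[2L])), call. = FALSE)
    }
  }
  if (out$adjustment$p_min > out$adjustment$p_max) {
    stop("config value out of range for adjustment.p_min (must be <= p_max)",
         call. = FALSE)
  }
  if (!out$simulator$best_intervention %in% out$simulator$catalog) {
    stop("config value out of range for simulator.best_intervention (not in catalog)",
         call. = FALSE)
  }
  structure(out, class = "sen_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and validate a YAML run configuration
#'
#' Applies the documented defaults to any key not present, validates ranges
#' and key names, and returns the effective configuration. Use
#' [write_config()] to echo the effective configuration next to a run's
#' outputs; the echoed file reloads to an identical configuration.
#'
#' @param path YAML file path.
#' @return The effective configuration, class `sen_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' Write an effective configuration to YAML
#'
#' @param cfg A `sen_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sen_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Cohort configuration from a run configuration
#'
#' @param cfg A `sen_config`.
#' @return The corresponding [cohort_config()].
#' @export
cohort_config_from <- function(cfg) {
  stopifnot(inherits(cfg, "sen_config"))
  s <- cfg$simulator
  cohort_config(n_children = s$n_children,
                n_interactions = s$n_interactions,
                M = cfg$model$M, catalog = s$catalog,
                best_intervention = s$best_intervention,
                best_effect = s$best_effect, other_effect = s$other_effect,
                noise_sd = s$noise_sd, cue_noise_sd = s$cue_noise_sd,
                baseline_range = c(s$baseline_min, s$baseline_max),
                carryover_range = c(s$carryover_min, s$carryover_max),
                seed = cfg$seed)
}
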