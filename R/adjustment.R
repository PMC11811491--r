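# Confidence-based modulation of intervention frequency and intensity with
# exponential smoothing.

#' Adjustment parameters and state
#'
#' Per-intervention intensities start at 1 (the simulator's ground-truth
#' effect size unscaled); the frequency gate maps confidence onto an
#' intervention probability in `[p_min, p_max]`.
#'
#' @param catalog Character vector of intervention ids.
#' @param window_size Rolling window K for the confidence score (default 5).
#' @param eta Non-negative intensity adjustment factor (default 0.1).
#' @param smooth_lambda Smoothing factor in \[0, 1\] (default 0.8; 0 = no
#'   smoothing, 1 = fully inert).
#' @param p_min,p_max Intervention probability bounds (default 0.2, 0.9).
#' @param phi_max Intensity cap (default 2); intensities are clamped to
#'   `[0, phi_max]` where they scale effects.
#' @return An object of class `sen_adjustment`.
#' @export
adjustment_state <- function(catalog, window_size = 5L, eta = 0.1,
                             smooth_lambda = 0.8, p_min = 0.2, p_max = 0.9,
                             phi_max = 2) {
  if (length(catalog) == 0L) stop("empty intervention catalog", call. = FALSE)
  check_scalar(window_size, "window_size", lower = 1)
  check_scalar(eta, "eta", lower = 0)
  check_scalar(smooth_lambda, "smooth_lambda", lower = 0, upper = 1)
  check_scalar(p_min, "p_min", lower = 0, upper = 1)
  check_scalar(p_max, "p_max", lower = 0, upper = 1)
  if (p_min > p_max) stop("`p_min` must be <= `p_max`", call. = FALSE)
  check_scalar(phi_max, "phi_max", lower = 0)
  phi <- rep(1, length(catalog)); names(phi) <- catalog
  structure(list(catalog = catalog, window_size = as.integer(window_size),
                 eta = eta, smooth_lambda = smooth_lambda,
                 p_min = p_min, p_max = p_max, phi_max = phi_max,
                 intensities = phi, smoothed_intensities = phi),
            class = "sen_adjustment")
}

#' Confidence score of an engagement window
#'
#' `c = exp(-(1/K) sum_k (E_k - Ebar)^2)`: the exponentiated negative
#' (population) variance of the last K engagement scores. Equals 1 exactly
#' on a constant window and decays toward 0 as engagement fluctuates. Early
#' in a session, when fewer than K observations exist, the window is all
#' available observations and K is the actual count.
#'
#' @param window Numeric vector of recent engagement scores (length >= 1).
#' @return Scalar confidence in (0, 1\].
#' @export
#' @examples
#' confidence(c(0.5, 0.5, 0.5))  # 1
#' confidence(c(0, 2))           # exp(-1)
confidence <- function(window) {
  if (length(window) == 0L) stop("empty engagement window", call. = FALSE)
  check_finite(window, "window")
  exp(-mean((window - mean(window))^2))
}

#' Confidence-weighted intensity update
#'
#' `phi(j) <- phi(j) + eta * c * delta_E`: the intensity of the applied
#' intervention moves with the observed engagement change, scaled by the
#' adjustment factor and by confidence — in stable periods (high c) the
#' intensity tracks engagement changes fully; in volatile periods the
#' response is damped in proportion. With `c = 1` this is the unweighted
#' responsiveness update.
#'
#' @param phi Current intensity of the intervention.
#' @param delta_E Engagement change following the intervention.
#' @param c_i Confidence score in (0, 1\].
#' @param eta Non-negative adjustment factor.
#' @return Updated intensity (uncapped; callers clamp to `[0, phi_max]`
#'   where the intensity scales effects).
#' @export
intensity_update <- function(phi, delta_E, c_i, eta) {
  check_scalar(phi, "phi"); check_scalar(delta_E, "delta_E")
  check_scalar(c_i, "c_i", lower = 0, upper = 1)
  check_scalar(eta, "eta", lower = 0)
  phi + eta * c_i * delta_E
}

#' Exponentially smoothed intensity
#'
#' `phi_smooth <- lambda * phi_smooth + (1 - lambda) * phi`: prevents abrupt
#' shifts in delivered intensity; under a constant raw intensity the
#' smoothed value converges geometrically with modulus `lambda`.
#'
#' @param smoothed Current smoothed intensity.
#' @param raw New raw intensity.
#' @param smooth_lambda Smoothing factor in \[0, 1\].
#' @return Updated smoothed intensity.
#' @export
smooth_intensity <- function(smoothed, raw, smooth_lambda) {
  check_scalar(smoothed, "smoothed"); check_scalar(raw, "raw")
  check_scalar(smooth_lambda, "smooth_lambda", lower = 0, upper = 1)
  smooth_lambda * smoothed + (1 - smooth_lambda) * raw
}

#' Confidence-based intervention probability
#'
#' `p = p_min + (p_max - p_min) * (1 - c)`: high confidence (stable
#' engagement) reduces intervention frequency toward `p_min`; low confidence
#' raises it toward `p_max`. Applied per interaction as the probability
#' that the policy intervenes at all.
#'
#' @param c_i Confidence score in (0, 1\].
#' @param p_min,p_max Probability bounds.
#' @return Scalar probability in `[p_min, p_max]`.
#' @export
intervention_probability <- function(c_i, p_min = 0.2, p_max = 0.9) {
  check_scalar(c_i, "c_i", lower = 0, upper = 1)
  check_scalar(p_min, "p_min", lower = 0, upper = 1)
  check_scalar(p_max, "p_max", lower = 0, upper = 1)
  if (p_min > p_max) stop("`p_min` must be <= `p_max`", call. = FALSE)
  p_min + (p_max - p_min) * (1 - c_i)
}
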