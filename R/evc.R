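#' Attentional control policy
#'
#' The pair of non-negative attention intensities applied to the motion
#' (`am`) and color (`ac`) attributes.  They multiply the bottom-up
#' coherence of each attribute in the drift rate (see [drift_rate()]) and
#' each incurs an exponential cost (see [control_cost()]).
#'
#' @param am,ac Attention intensities, `>= 0`.
#' @return An object of class `control_policy`.
#' @examples
#' control_policy(0.69, 0.18)
#' @export
control_policy <- function(am, ac) {
  stopifnot(is.numeric(am), is.numeric(ac), length(am) == 1L, length(ac) == 1L)
  if (am < 0 || ac < 0) abort("attention intensities must be >= 0.")
  structure(list(am = am, ac = ac), class = "control_policy")
}

#' @export
print.control_policy <- function(x, ...) {
  cat(sprintf("<control_policy> Am = %.3g, Ac = %.3g\n", x$am, x$ac))
  invisible(x)
}

check_policy <- function(policy) {
  if (!inherits(policy, "control_policy")) {
    abort("`policy` must be created by `control_policy()`.")
  }
  policy
}

#' Attention-weighted drift rate
#'
#' The net rate of evidence accumulation on a trial is the
#' attention-weighted sum of the signed coherences of the two attributes:
#' `am * cm + ac * cc`.
#'
#' @param policy A [control_policy()].
#' @param signed_cm,signed_cc Signed motion and color coherences (sign
#'   encodes which response the attribute supports); vectorized.
#' @return Drift rate vector.
#' @examples
#' drift_rate(control_policy(1, 1), 0.3, 0.3)  # 0.6
#' @export
drift_rate <- function(policy, signed_cm, signed_cc) {
  check_policy(policy)
  policy$am * signed_cm + policy$ac * signed_cc
}

#' Exponential cost of an attentional intensity
#'
#' `Cost(signal) = exp(k * intensity)`.  With `k = 0` every intensity costs
#' 1, removing any penalty on control.
#'
#' @param intensity Attention intensity, `>= 0`; vectorized.
#' @param k Cost exponent.
#' @return Cost vector.
#' @examples
#' control_cost(1, 2)  # e^2
#' @export
control_cost <- function(intensity, k) {
  if (any(intensity < 0)) abort("`intensity` must be >= 0.")
  exp(k * intensity)
}

#' Canonical simulated trial set
#'
#' The 32 distinct trial types of the factorial design: 4 motion x 4 color
#' ordinal levels crossed with congruent/incongruent, weighted equally
#' (matching the balanced experimental design).
#'
#' @return A 32-row tibble with `motion_level`, `color_level`, `congruent`.
#' @export
evc_trial_types <- function() {
  tidyr::expand_grid(motion_level = 1:4, color_level = 1:4,
                     congruent = c(TRUE, FALSE))
}

#' Configuration for an EVC policy optimization
#'
#' Bundles the rewards, cost exponent, policy grid, diffusion parameters,
#' coherence magnitudes and trial set over which the Expected Value of
#' Control surface is evaluated.  Defaults are the published simulation
#' constants: rewards 7.5/7.5 (epoch 1; use 10/5 for the unequal epochs and
#' 8.5/6.5 for the intrinsic-reward variant), `k = 2`, grid 0..2 in steps
#' of 0.01, coherence magnitudes 0.3, 0.53, 0.77, 1.0.
#'
#' @param reward_m,reward_c Reward for a motion-/color-correct response
#'   (abstract units).
#' @param k Control cost exponent (see [control_cost()]).
#' @param grid_lo,grid_hi,grid_step Policy grid specification; requires
#'   `grid_lo < grid_hi` and `grid_step > 0`.
#' @param ddm A [ddm_params()] object.
#' @param coherence_values Coherence magnitudes for ordinal levels 1-4,
#'   each in (0, 1].
#' @param trials Trial-type tibble (default [evc_trial_types()]), weighted
#'   equally.
#' @param aggregate `"mean"`: EVC is the mean over trials of the per-trial
#'   reward rate `EV_t / RT_t`, minus the policy cost (the default);
#'   `"session"`: total expected reward over total expected time,
#'   `sum(EV_t) / sum(RT_t)`, minus the cost.
#' @return An object of class `evc_config`.
#' @export
evc_config <- function(reward_m = 7.5, reward_c = 7.5, k = 2,
                       grid_lo = 0, grid_hi = 2, grid_step = 0.01,
                       ddm = ddm_params(),
                       coherence_values = c(0.3, 0.53, 0.77, 1.0),
                       trials = evc_trial_types(),
                       aggregate = c("mean", "session")) {
  aggregate <- match.arg(aggregate)
  check_ddm(ddm)
  if (grid_step <= 0) abort("`grid_step` must be > 0.")
  if (grid_lo >= grid_hi) abort("degenerate grid: `grid_lo` must be < `grid_hi`.")
  if (grid_lo < 0) abort("`grid_lo` must be >= 0.")
  stopifnot(length(coherence_values) == 4L)
  if (any(coherence_values <= 0) || any(coherence_values > 1)) {
    abort("`coherence_values` must lie in (0, 1].")
  }
  if (is.null(trials) || nrow(trials) == 0L) abort("`trials` must be non-empty.")
  structure(
    list(reward_m = reward_m, reward_c = reward_c, k = k,
         grid_lo = grid_lo, grid_hi = grid_hi, grid_step = grid_step,
         ddm = ddm, coherence_values = coherence_values, trials = trials,
         aggregate = aggregate),
    class = "evc_config"
  )
}

check_evc_config <- function(config) {
  if (!inherits(config, "evc_config")) {
    abort("`config` must be created by `evc_config()`.")
  }
  config
}

# Vectorized EVC evaluation over policies (am, ac vectors of equal length).
evc_evaluate <- function(am, ac, config) {
  cfg <- check_evc_config(config)
  tt <- cfg$trials
  cm <- cfg$coherence_values[tt$motion_level]
  cc <- cfg$coherence_values[tt$color_level]
  sgn <- ifelse(tt$congruent, 1, -1)
  n_pol <- length(am)
  rate_sum <- numeric(n_pol)
  ev_sum <- numeric(n_pol)
  rt_sum <- numeric(n_pol)
  for (i in seq_len(nrow(tt))) {
    v <- am * cm[i] + sgn[i] * ac * cc[i]
    p <- ddm_choice_probability(v, cfg$ddm)
    p_c <- if (tt$congruent[i]) p else 1 - p
    ev <- p * cfg$reward_m + p_c * cfg$reward_c
    rt <- ddm_mean_decision_time(v, cfg$ddm) + cfg$ddm$non_decision_time
    rate_sum <- rate_sum + ev / rt
    ev_sum <- ev_sum + ev
    rt_sum <- rt_sum + rt
  }
  rate <- if (cfg$aggregate == "mean") rate_sum / nrow(tt) else ev_sum / rt_sum
  cost <- control_cost(am, cfg$k) + control_cost(ac, cfg$k)
  tibble::tibble(am = am, ac = ac, reward_rate = rate,
                 total_cost = cost, evc = rate - cost)
}

#' Expected value of one trial under a policy
#'
#' `EV_t = Pr(Mcorrect) * reward_m + Pr(Ccorrect) * reward_c`, with the
#' outcome probabilities from [trial_outcome_probabilities()].
#'
#' @inheritParams trial_outcome_probabilities
#' @param reward_m,reward_c Rewards for a correct motion/color response.
#' @return `trials` with added columns (including `expected_value`).
#' @export
expected_value <- function(trials, policy, reward_m, reward_c,
                           params = ddm_params(),
                           coherence_values = c(0.3, 0.53, 0.77, 1.0)) {
  out <- trial_outcome_probabilities(trials, policy, params, coherence_values)
  dplyr::mutate(out,
    expected_value = .data$p_motion_correct * reward_m +
      .data$p_color_correct * reward_c)
}

#' Expected value of control for one policy
#'
#' The expected reward rate over the configured trial set, discounted by
#' the summed exponential costs of the two attentional intensities.
#'
#' @param policy A [control_policy()].
#' @param config An [evc_config()].
#' @return Scalar EVC.
#' @export
evc_of_policy <- function(policy, config = evc_config()) {
  check_policy(policy)
  evc_evaluate(policy$am, policy$ac, config)$evc
}

#' Grid-search optimization of the attentional policy
#'
#' Evaluates EVC exhaustively on the configured (am, ac) grid and returns
#' the full surface together with the maximizing policy.  Ties are broken
#' deterministically in favour of the smallest `am`, then the smallest
#' `ac`.
#'
#' @param config An [evc_config()].
#' @return An object of class `evc_policy` with elements `grid` (tibble of
#'   `am`, `ac`, `reward_rate`, `total_cost`, `evc`), `optimum` (one-row
#'   tibble) and `config`.  Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' fit <- optimize_policy(evc_config(reward_m = 10, reward_c = 5))
#' glance(fit)
#' }
#' @export
optimize_policy <- function(config = evc_config()) {
  cfg <- check_evc_config(config)
  g <- seq(cfg$grid_lo, cfg$grid_hi, by = cfg$grid_step)
  pol <- tidyr::expand_grid(am = g, ac = g)
  grid <- evc_evaluate(pol$am, pol$ac, cfg)
  best <- dplyr::arrange(grid, dplyr::desc(.data$evc), .data$am, .data$ac)[1, ]
  structure(list(grid = grid, optimum = best, config = cfg),
            class = "evc_policy")
}

#' @export
print.evc_policy <- function(x, ...) {
  cat(sprintf(
    "<evc_policy> %d policies evaluated; optimum Am = %.3g, Ac = %.3g, EVC = %.4g\n",
    nrow(x$grid), x$optimum$am, x$optimum$ac, x$optimum$evc))
  invisible(x)
}

#' @rdname optimize_policy
#' @param x An `evc_policy` object.
#' @param ... Unused.
#' @method tidy evc_policy
#' @export
tidy.evc_policy <- function(x, ...) x$grid

#' @rdname optimize_policy
#' @method glance evc_policy
#' @export
glance.evc_policy <- function(x, ...) {
  dplyr::transmute(x$optimum,
    am = .data$am, ac = .data$ac, evc = .data$evc,
    reward_rate = .data$reward_rate, total_cost = .data$total_cost,
    reward_m = x$config$reward_m, reward_c = x$config$reward_c,
    k = x$config$k, n_policies = nrow(x$grid))
}

#' @rdname optimize_policy
#' @param object An `evc_policy` object.
#' @method autoplot evc_policy
#' @export
autoplot.evc_policy <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$am, y = .data$ac, fill = .data$evc)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = object$optimum, colour = "white", size = 2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "attention to motion (Am)",
                  y = "attention to color (Ac)", fill = "EVC",
                  title = sprintf("EVC surface (rewards %.3g/%.3g, k = %.3g)",
                                  object$config$reward_m,
                                  object$config$reward_c, object$config$k))
}
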