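#' Drift-diffusion model parameters
#'
#' A single accumulator with symmetric absorbing boundaries at `+boundary`
#' and `-boundary`, diffusion standard deviation `noise` per unit time,
#' starting point `starting_point` (evidence units, strictly inside the
#' boundaries) and a fixed `non_decision_time` added to the first-passage
#' time to give the response time.  Defaults are the simulation constants
#' used throughout: boundary 0.45, noise 0.5, non-decision time 0.2 s,
#' start 0.
#'
#' @param boundary Boundary separation from the start axis, `a > 0`.
#' @param noise Diffusion coefficient (SD per unit time), `sigma > 0`.
#' @param non_decision_time Seconds, `t0 >= 0`.
#' @param starting_point Evidence units, `|z| < a`.
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params()
#' @export
ddm_params <- function(boundary = 0.45, noise = 0.5, non_decision_time = 0.2,
                       starting_point = 0) {
  stopifnot(is.numeric(boundary), is.numeric(noise),
            is.numeric(non_decision_time), is.numeric(starting_point))
  if (boundary <= 0) abort("`boundary` must be > 0.")
  if (noise <= 0) abort("`noise` must be > 0.")
  if (non_decision_time < 0) abort("`non_decision_time` must be >= 0.")
  if (abs(starting_point) >= boundary) {
    abort("`starting_point` must lie strictly between the boundaries.")
  }
  structure(
    list(boundary = boundary, noise = noise,
         non_decision_time = non_decision_time,
         starting_point = starting_point),
    class = "ddm_params"
  )
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "<ddm_params> boundary %.3g, noise %.3g, t0 %.3g s, start %.3g\n",
    x$boundary, x$noise, x$non_decision_time, x$starting_point))
  invisible(x)
}

check_ddm <- function(params) {
  if (!inherits(params, "ddm_params")) {
    abort("`params` must be created by `ddm_params()`.")
  }
  params
}

#' Probability of absorbing at the upper boundary
#'
#' Closed-form first-passage probability for constant drift between two
#' absorbing boundaries.  For a zero starting point this reduces to the
#' logistic `1 / (1 + exp(-2 * drift * a / sigma^2))`; the general
#' expression uses the boundaries mapped to `[0, 2a]` with start `a + z`.
#' Continuous at zero drift, where it equals `(a + z) / 2a`.
#'
#' @param drift Drift rate(s), evidence units per second.
#' @param params A [ddm_params()] object.
#' @return Probability vector, one per drift.
#' @examples
#' ddm_choice_probability(0)               # 0.5
#' ddm_choice_probability(c(-1, 1))        # sums to 1
#' @export
ddm_choice_probability <- function(drift, params = ddm_params()) {
  check_ddm(params)
  a2 <- 2 * params$boundary
  w <- params$boundary + params$starting_point
  s2 <- params$noise^2
  out <- numeric(length(drift))
  small <- abs(drift) < 1e-8
  out[small] <- w / a2
  v <- drift[!small]
  if (length(v)) {
    out[!small] <- expm1(-2 * v * w / s2) / expm1(-2 * v * a2 / s2)
  }
  out
}

#' Mean decision time (first-passage time)
#'
#' Closed-form unconditional mean first-passage time for constant drift
#' between two absorbing boundaries.  For a zero starting point this is
#' `(a / drift) * tanh(a * drift / sigma^2)`, with limit `a^2 / sigma^2`
#' at zero drift; it is even in drift and strictly decreasing in |drift|.
#'
#' @inheritParams ddm_choice_probability
#' @return Mean decision time(s) in seconds (excludes non-decision time).
#' @examples
#' ddm_mean_decision_time(0)   # 0.81 s at the default parameters
#' @export
ddm_mean_decision_time <- function(drift, params = ddm_params()) {
  check_ddm(params)
  a2 <- 2 * params$boundary
  w <- params$boundary + params$starting_point
  s2 <- params$noise^2
  out <- numeric(length(drift))
  small <- abs(drift) < 1e-8
  out[small] <- w * (a2 - w) / s2
  v <- drift[!small]
  if (length(v)) {
    p_up <- expm1(-2 * v * w / s2) / expm1(-2 * v * a2 / s2)
    out[!small] <- (a2 * p_up - w) / v
  }
  out
}

#' Closed-form first-passage summary
#'
#' @inheritParams ddm_choice_probability
#' @return A tibble with `drift`, `p_upper`, `mean_decision_time` and
#'   `mean_rt` (`= mean_decision_time + t0`).
#' @export
ddm_first_passage <- function(drift, params = ddm_params()) {
  check_ddm(params)
  tibble::tibble(
    drift = drift,
    p_upper = ddm_choice_probability(drift, params),
    mean_decision_time = ddm_mean_decision_time(drift, params),
    mean_rt = .data$mean_decision_time + params$non_decision_time
  )
}

#' Monte-Carlo first-passage sampler
#'
#' Euler-Maruyama simulation of the diffusion with a Brownian-bridge
#' within-step crossing test: after each step that leaves the path inside
#' the boundaries, the path is additionally absorbed with the exact bridge
#' probability `exp(-2 (a - x0)(a - x1) / (sigma^2 dt))` of having crossed
#' between the endpoints (and likewise for the lower boundary).  Without
#' this correction the discrete-time walk systematically overshoots its
#' absorption time by O(sqrt(dt)).  Serves as the in-package stochastic
#' oracle for the closed forms.
#'
#' @param drift Drift rate (scalar).
#' @param params A [ddm_params()] object.
#' @param n Number of paths (>= 1).
#' @param dt Step size in seconds; values above 0.01 s trigger a warning.
#' @param seed Integer seed.
#' @param max_time Censoring horizon in seconds; paths still inside the
#'   boundaries at `max_time` are returned with `boundary = NA`.
#' @return A tibble with one row per path: `boundary` (`"upper"`/`"lower"`
#'   or `NA` if censored), `decision_time` and `rt`
#'   (`= decision_time + t0`).
#' @examples
#' sim <- simulate_first_passage(0.6, n = 1000, seed = 1)
#' mean(sim$boundary == "upper")
#' @export
simulate_first_passage <- function(drift, params = ddm_params(), n = 1000L,
                                   dt = 0.001, seed = 1L, max_time = 20) {
  check_ddm(params)
  stopifnot(length(drift) == 1L, n >= 1, dt > 0)
  if (dt > 0.01) {
    warn("`dt` > 0.01 s: discretization error may be appreciable.")
  }
  a <- params$boundary
  s <- params$noise
  withr::with_seed(seed, {
    x <- rep(params$starting_point, n)
    t_abs <- rep(NA_real_, n)
    up <- rep(NA, n)
    active <- seq_len(n)
    sdt <- s * sqrt(dt)
    v2 <- s^2 * dt
    t <- 0
    while (length(active) && t < max_time) {
      t <- t + dt
      x0 <- x[active]
      x1 <- x0 + drift * dt + sdt * rnorm(length(active))
      hit_up <- x1 >= a
      hit_dn <- x1 <= -a
      inter <- !hit_up & !hit_dn
      if (any(inter)) {
        pu <- exp(-2 * (a - x0[inter]) * (a - x1[inter]) / v2)
        pd <- exp(-2 * (a + x0[inter]) * (a + x1[inter]) / v2)
        u <- runif(sum(inter))
        bu <- u < pu
        bd <- !bu & (u < pu + pd)
        hit_up[inter][bu] <- TRUE
        hit_dn[inter][bd] <- TRUE
      }
      hit <- hit_up | hit_dn
      idx <- active[hit]
      t_abs[idx] <- t
      up[idx] <- hit_up[hit]
      x[active] <- x1
      active <- active[!hit]
    }
  })
  tibble::tibble(
    boundary = dplyr::case_when(is.na(up) ~ NA_character_,
                                up ~ "upper", TRUE ~ "lower"),
    decision_time = t_abs,
    rt = t_abs + params$non_decision_time
  )
}

#' Per-trial outcome probabilities under an attentional policy
#'
#' For each trial the net drift toward the boundary mapped to the
#' motion-correct response is `am * cm + ac * cc` on congruent trials and
#' `am * cm - ac * cc` on incongruent trials, where `cm`, `cc` are the
#' simulated coherence magnitudes for the trial's ordinal levels.  The
#' probability of a motion-correct response is the closed-form absorption
#' probability at that boundary; the color-correct probability equals it on
#' congruent trials and its complement on incongruent trials.
#'
#' @param trials Design tibble with `motion_level`, `color_level`,
#'   `congruent` (e.g. from [generate_epoch()]).
#' @param policy A [control_policy()].
#' @param params A [ddm_params()] object.
#' @param coherence_values Coherence magnitudes for ordinal levels 1-4;
#'   default the simulation values 0.3, 0.53, 0.77, 1.0.
#' @return `trials` with added columns `drift_motion` (net drift toward the
#'   motion-correct boundary), `p_motion_correct`, `p_color_correct` and
#'   `mean_rt`.
#' @export
trial_outcome_probabilities <- function(trials, policy,
                                        params = ddm_params(),
                                        coherence_values = c(0.3, 0.53, 0.77, 1.0)) {
  check_policy(policy)
  check_ddm(params)
  stopifnot(length(coherence_values) == 4L, all(coherence_values > 0),
            all(coherence_values <= 1))
  cm <- coherence_values[trials$motion_level]
  cc <- coherence_values[trials$color_level]
  sgn <- ifelse(trials$congruent, 1, -1)
  v <- policy$am * cm + sgn * policy$ac * cc
  p <- ddm_choice_probability(v, params)
  dplyr::mutate(trials,
    drift_motion = v,
    p_motion_correct = p,
    p_color_correct = ifelse(trials$congruent, p, 1 - p),
    mean_rt = ddm_mean_decision_time(v, params) + params$non_decision_time
  )
}
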