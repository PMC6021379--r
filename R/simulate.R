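#' Configuration of a simulated task participant
#'
#' A participant is a two-attribute diffusion agent: on each trial the
#' drift toward the boundary of the right-hand response is the
#' attention-weighted sum of the signed coherence magnitudes of the two
#' attributes, and the choice/RT are a single sampled first passage.
#' Attention follows the epoch's reward structure: `attn_equal` on both
#' attributes in epoch 1, and `attn_high`/`attn_low` on the high-/
#' low-reward attribute in epochs 2-3.  Defaults are the EVC-optimal
#' intensities under the standard simulation constants (epoch 1 symmetric
#' optimum 0.50/0.50; unequal-reward optimum 0.69/0.18 for rewards 10/5 at
#' `k = 2`; see [optimize_policy()]).
#'
#' Responses lapse (uniform random choice, uniform RT) with probability
#' `lapse_rate`; first passages later than `deadline` are recorded as
#' misses.  `gain_sd` adds trialwise lognormal variability (unit mean) to
#' the attention paid to the low-reward attribute, representing
#' spontaneous fluctuation of the attentional policy; it is the generative
#' hook for analyses linking trialwise neural activity to the influence of
#' the low-reward attribute.
#'
#' @param attn_equal Attention per attribute in the equal-reward epoch.
#' @param attn_high,attn_low Attention to the high-/low-reward attribute in
#'   unequal-reward epochs.
#' @param ddm A [ddm_params()] object.
#' @param lapse_rate Probability of a lapse trial, in `[0, 0.2]`.
#' @param deadline Response deadline in seconds.
#' @param gain_sd Lognormal SD of the trialwise low-reward attention gain.
#' @param coherence_values Coherence magnitudes for ordinal levels 1-4.
#' @param dt Euler step for the first-passage sampler.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(attn_equal = 0.50, attn_high = 0.69, attn_low = 0.18,
                         ddm = ddm_params(), lapse_rate = 0.02, deadline = 3,
                         gain_sd = 0, coherence_values = c(0.3, 0.53, 0.77, 1.0),
                         dt = 0.001) {
  check_ddm(ddm)
  stopifnot(attn_equal >= 0, attn_high >= 0, attn_low >= 0, gain_sd >= 0,
            dt > 0, length(coherence_values) == 4L)
  if (deadline <= 0) abort("`deadline` must be > 0.")
  if (lapse_rate < 0 || lapse_rate > 0.2) {
    abort("`lapse_rate` must lie in [0, 0.2].")
  }
  structure(as.list(environment()), class = "agent_config")
}

#' @export
print.agent_config <- function(x, ...) {
  cat(sprintf(
    "<agent_config> attention %.2f (equal) / %.2f:%.2f (high:low), lapse %.2f, deadline %g s\n",
    x$attn_equal, x$attn_high, x$attn_low, x$lapse_rate, x$deadline))
  invisible(x)
}

# One first-passage sample per trial, all trials stepped in parallel.
# Returns decision time (NA if not absorbed by the horizon) and boundary.
sample_first_passages <- function(drift, params, dt, horizon) {
  n <- length(drift)
  a <- params$boundary
  s <- params$noise
  x <- rep(params$starting_point, n)
  t_abs <- rep(NA_real_, n)
  up <- rep(NA, n)
  active <- seq_len(n)
  sdt <- s * sqrt(dt)
  v2 <- s^2 * dt
  t <- 0
  while (length(active) && t < horizon) {
    t <- t + dt
    x0 <- x[active]
    x1 <- x0 + drift[active] * dt + sdt * rnorm(length(active))
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
  list(decision_time = t_abs, upper = up)
}

#' Simulate one participant's behavior over a task design
#'
#' For every trial the net drift toward the "R" boundary is
#' `a_m * s_m + a_c * s_c`, where `s_m`, `s_c` are the attributes' signed
#' coherence magnitudes (positive when the attribute's correct response is
#' "R") and the attention intensities follow the epoch's reward structure.
#' Choice and decision time are one Monte-Carlo first passage; first
#' passages whose RT (decision time + non-decision time) exceeds the
#' deadline are misses.  Correctness is recorded per attribute and the
#' trial reward is the sum over correctly discriminated attributes.
#'
#' @param design A design tibble from [generate_session()] or
#'   [generate_epoch()].
#' @param agent An [agent_config()].
#' @param seed Integer seed.
#' @return `design` with added columns `choice` (`"L"`, `"R"` or
#'   `"missed"`), `rt`, `missed`, `lapsed`, `correct_motion`,
#'   `correct_color`, `reward`, `attn_motion`, `attn_color`,
#'   `attn_gain_low`.
#' @examples
#' \donttest{
#' rec <- simulate_participant(generate_session(seed = 1), agent_config(),
#'                             seed = 1)
#' mean(rec$missed)
#' }
#' @export
simulate_participant <- function(design, agent = agent_config(), seed = 1L) {
  stopifnot(inherits(agent, "agent_config"), nrow(design) > 0)
  n <- nrow(design)
  high_is_motion <- design$high_reward_attribute == "motion"
  equal <- design$high_reward_attribute == "equal"

  withr::with_seed(seed, {
    gain <- if (agent$gain_sd > 0) {
      exp(rnorm(n, -agent$gain_sd^2 / 2, agent$gain_sd))
    } else rep(1, n)
    attn_motion <- ifelse(equal, agent$attn_equal,
                          ifelse(high_is_motion, agent$attn_high,
                                 agent$attn_low * gain))
    attn_color <- ifelse(equal, agent$attn_equal,
                         ifelse(high_is_motion, agent$attn_low * gain,
                                agent$attn_high))
    sm <- ifelse(design$motion_correct == "R", 1, -1) *
      agent$coherence_values[design$motion_level]
    sc <- ifelse(design$color_correct == "R", 1, -1) *
      agent$coherence_values[design$color_level]
    v <- attn_motion * sm + attn_color * sc

    horizon <- agent$deadline - agent$ddm$non_decision_time
    fp <- sample_first_passages(v, agent$ddm, agent$dt, horizon)
    rt <- fp$decision_time + agent$ddm$non_decision_time
    choice <- dplyr::case_when(is.na(fp$upper) ~ "missed",
                               fp$upper ~ "R", TRUE ~ "L")
    # lapses override the accumulator
    lapsed <- runif(n) < agent$lapse_rate
    lap_choice <- sample(c("L", "R"), n, replace = TRUE)
    lap_rt <- runif(n, agent$ddm$non_decision_time, agent$deadline)
    choice[lapsed] <- lap_choice[lapsed]
    rt[lapsed] <- lap_rt[lapsed]
  })

  missed <- choice == "missed"
  rt[missed] <- NA_real_
  correct_motion <- !missed & choice == design$motion_correct
  correct_color <- !missed & choice == design$color_correct
  dplyr::mutate(design,
    choice = choice, rt = rt, missed = missed, lapsed = lapsed,
    correct_motion = correct_motion, correct_color = correct_color,
    reward = correct_motion * design$reward_motion +
      correct_color * design$reward_color,
    attn_motion = attn_motion, attn_color = attn_color,
    attn_gain_low = ifelse(equal, 1, gain)
  )
}

#' Simulate a cohort of participants
#'
#' Each participant gets a fresh session design (high-reward attribute in
#' epoch 2 alternating across participants, mirroring counterbalancing) and
#' their own behavioral simulation.  Between-participant variability is
#' introduced as independent lognormal scaling (unit median, SD
#' `attn_sd` on the log scale) of the three attention intensities.
#'
#' @param n_participants Cohort size (the study's n is 34).
#' @param agent Baseline [agent_config()].
#' @param attn_sd Log-scale SD of between-participant attention scaling.
#' @param seed Master seed; per-participant seeds are derived via
#'   [derive_seed()].
#' @return A tibble of behavioral records with a `participant` column,
#'   plus `attn_scale_high`/`attn_scale_low`/`attn_scale_equal` recording
#'   each participant's true attention multipliers.
#' @export
simulate_cohort <- function(n_participants = 34, agent = agent_config(),
                            attn_sd = 0.1, seed = 1L) {
  stopifnot(n_participants >= 1, attn_sd >= 0)
  purrr::map_dfr(seq_len(n_participants), function(i) {
    s_design <- derive_seed(seed, paste0("design", i))
    s_scale <- derive_seed(seed, paste0("attn", i))
    s_behav <- derive_seed(seed, paste0("behavior", i))
    high_first <- if (i %% 2 == 1) "motion" else "color"
    design <- generate_session(high_first, seed = s_design)
    sc <- withr::with_seed(s_scale, exp(rnorm(3, 0, attn_sd)))
    agent_i <- agent
    agent_i$attn_equal <- agent$attn_equal * sc[1]
    agent_i$attn_high <- agent$attn_high * sc[2]
    agent_i$attn_low <- agent$attn_low * sc[3]
    rec <- simulate_participant(design, agent_i, seed = s_behav)
    dplyr::mutate(rec, participant = i,
                  attn_scale_equal = sc[1], attn_scale_high = sc[2],
                  attn_scale_low = sc[3], .before = 1L)
  })
}
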