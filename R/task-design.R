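#' Per-attribute coherence level multipliers
#'
#' Coherence levels 1-4 are fixed multiples of the individually calibrated
#' threshold coherence.  Motion uses 50/95/140/185% of threshold; color uses
#' 50/105/160/215% (the wider spacing compensates for flatter choice
#' sensitivity to color found in piloting).
#'
#' @param attribute `"motion"` or `"color"`.
#' @return Numeric vector of four ascending multipliers.
#' @export
ladder_multipliers <- function(attribute = c("motion", "color")) {
  attribute <- match.arg(attribute)
  switch(attribute,
    motion = c(0.50, 0.95, 1.40, 1.85),
    color  = c(0.50, 1.05, 1.60, 2.15)
  )
}

#' Build the four-level coherence ladder for one attribute
#'
#' Scales the calibrated threshold coherence (the staircase output, in
#' percent) by the attribute-specific multipliers to produce the four
#' per-trial coherence levels, from most difficult (level 1) to easiest
#' (level 4).  E.g. a 10% calibrated motion threshold yields levels
#' 5, 9.5, 14 and 18.5% coherence.
#'
#' @param threshold Calibrated threshold coherence, in percent (>= 0).
#' @param attribute `"motion"` or `"color"`.
#' @return A tibble with columns `attribute`, `level` (1-4), `multiplier`
#'   and `coherence` (percent), coherence strictly ascending for positive
#'   thresholds.
#' @examples
#' coherence_ladder(10, "motion")
#' @export
coherence_ladder <- function(threshold, attribute = c("motion", "color")) {
  attribute <- match.arg(attribute)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold)) {
    abort("`threshold` must be a single number.")
  }
  if (threshold < 0) {
    abort("`threshold` must be a non-negative coherence (in percent).")
  }
  mult <- ladder_multipliers(attribute)
  tibble::tibble(
    attribute = attribute,
    level = 1:4,
    multiplier = mult,
    coherence = threshold * mult
  )
}

#' Reward schedule for one epoch
#'
#' Epoch 1 rewards both attributes equally at $0.15 per correct
#' discrimination.  In epoch 2 one attribute pays $0.20 and the other
#' $0.10; in epoch 3 the assignment is reversed.
#'
#' @param epoch Epoch index, 1, 2 or 3.
#' @param high_first Which attribute is the high-reward one in epoch 2
#'   (`"motion"` or `"color"`); counterbalanced across participants.
#' @return One-row tibble with `epoch`, `reward_motion`, `reward_color`
#'   (dollars/trial) and `high_reward_attribute`
#'   (`"motion"`, `"color"` or `"equal"`).
#' @examples
#' reward_schedule(2, "motion")
#' @export
reward_schedule <- function(epoch, high_first = c("motion", "color")) {
  high_first <- match.arg(high_first)
  if (!is.numeric(epoch) || length(epoch) != 1L || !epoch %in% 1:3) {
    abort("`epoch` must be 1, 2 or 3.")
  }
  if (epoch == 1) {
    return(tibble::tibble(epoch = 1L, reward_motion = 0.15,
                          reward_color = 0.15,
                          high_reward_attribute = "equal"))
  }
  high <- if (epoch == 2) high_first else setdiff(c("motion", "color"), high_first)
  tibble::tibble(
    epoch = as.integer(epoch),
    reward_motion = if (high == "motion") 0.20 else 0.10,
    reward_color = if (high == "color") 0.20 else 0.10,
    high_reward_attribute = high
  )
}

#' Generate the 192-trial factorial design for one epoch
#'
#' The 4 motion x 4 color coherence grid is fully crossed and balanced: each
#' of the 16 cells appears 12 times per epoch, split into 6 congruent trials
#' (both attributes map to the same response) and 6 incongruent, with
#' left/right correct responses balanced within each half.  Trials are
#' shuffled with the given seed and split into 4 blocks of 48.  Inter-trial
#' intervals are drawn uniformly on [1.2, 7.2] s; each trial ends with a
#' fixed 0.5 s preparatory cue (metadata only).
#'
#' @param epoch Epoch index 1-3.
#' @param high_first High-reward attribute in epoch 2 (see
#'   [reward_schedule()]).
#' @param seed Integer seed for the trial-order shuffle and ITI draw.
#' @return A tibble of 192 rows with columns `index`, `epoch`, `block`,
#'   `motion_level`, `color_level`, `motion_correct`, `color_correct`
#'   (`"L"`/`"R"`), `congruent`, `iti`, `cue` plus the epoch's reward
#'   schedule columns.
#' @examples
#' design <- generate_epoch(1, seed = 1)
#' dplyr::count(design, motion_level, color_level)
#' @export
generate_epoch <- function(epoch, high_first = c("motion", "color"), seed = 1L) {
  high_first <- match.arg(high_first)
  sched <- reward_schedule(epoch, high_first)

  cells <- tidyr::expand_grid(
    motion_level = 1:4,
    color_level = 1:4,
    congruent = c(TRUE, FALSE),
    motion_correct = c("L", "R"),
    rep = 1:3
  )
  cells$color_correct <- ifelse(cells$congruent, cells$motion_correct,
                                ifelse(cells$motion_correct == "L", "R", "L"))

  withr::with_seed(seed, {
    ord <- sample.int(nrow(cells))
    iti <- runif(nrow(cells), 1.2, 7.2)
  })
  trials <- cells[ord, c("motion_level", "color_level", "motion_correct",
                         "color_correct", "congruent")]
  n <- nrow(trials)
  trials <- dplyr::mutate(trials,
    index = seq_len(n),
    epoch = as.integer(epoch),
    block = as.integer(ceiling(.data$index / 48)),
    iti = iti,
    cue = 0.5
  )
  trials <- dplyr::cross_join(trials, sched[, -1L])
  dplyr::select(trials, "index", "epoch", "block", "motion_level",
                "color_level", "motion_correct", "color_correct",
                "congruent", "iti", "cue", dplyr::everything())
}

#' Generate a full three-epoch session
#'
#' Binds the three epochs (equal rewards, then the two unequal-reward
#' epochs with the assignment reversed between them), with per-epoch seeds
#' derived from the session seed, and a session-wide trial counter.
#'
#' @inheritParams generate_epoch
#' @return A 576-row tibble as in [generate_epoch()], plus `trial`
#'   (session-wide index).
#' @export
generate_session <- function(high_first = c("motion", "color"), seed = 1L) {
  high_first <- match.arg(high_first)
  out <- purrr::map(1:3, function(e) {
    generate_epoch(e, high_first, seed = derive_seed(seed, paste0("epoch", e)))
  })
  out <- dplyr::bind_rows(out)
  dplyr::mutate(out, trial = dplyr::row_number(), .before = 1L)
}

#' Signed coherence of an attribute relative to a reference response
#'
#' The analysis coding for evidence strength: the ordinal coherence level
#' (1-4) signed positive when the attribute's correct response matches the
#' reference response and negative otherwise, so values span -4..+4 with no
#' zero.
#'
#' @param level Ordinal coherence level(s), 1-4.
#' @param correct_response The attribute's correct response(s), `"L"`/`"R"`.
#' @param reference The reference response (`"L"` or `"R"`), e.g. the
#'   response actually chosen, or a fixed response for response-frame
#'   regressions.  Recycled against `level`.
#' @return Integer vector of signed levels.
#' @examples
#' signed_coherence(3, "R", "R")   # +3
#' signed_coherence(3, "L", "R")   # -3
#' @export
signed_coherence <- function(level, correct_response, reference = "R") {
  if (!all(reference %in% c("L", "R"))) {
    abort("`reference` must be \"L\" or \"R\".")
  }
  if (!all(correct_response %in% c("L", "R"))) {
    abort("`correct_response` must be \"L\" or \"R\".")
  }
  if (!all(level %in% 1:4)) {
    abort("`level` must be an ordinal coherence level in 1..4.")
  }
  as.integer(ifelse(correct_response == reference, level, -level))
}

# Map motion/color columns into the high/low-reward frame.  In epoch 1
# (equal rewards) "high" falls back to motion by convention; reward-frame
# analyses are meant for the unequal epochs.
reward_frame <- function(trials) {
  high_is_motion <- trials$high_reward_attribute != "color"
  dplyr::mutate(trials,
    high_level = ifelse(high_is_motion, .data$motion_level, .data$color_level),
    low_level = ifelse(high_is_motion, .data$color_level, .data$motion_level),
    high_correct = ifelse(high_is_motion, .data$motion_correct, .data$color_correct),
    low_correct = ifelse(high_is_motion, .data$color_correct, .data$motion_correct),
    reward_high = pmax(.data$reward_motion, .data$reward_color),
    reward_low = pmin(.data$reward_motion, .data$reward_color)
  )
}
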