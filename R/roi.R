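#' Design variables for trialwise encoding models
#'
#' Builds, from behavioral records, the per-trial regressors the encoding
#' analyses use, all in the reward frame (high/low-reward attribute; in the
#' equal-reward epoch "high" falls back to motion by convention):
#'
#' * `signed_high`, `signed_low` — ordinal coherence (1-4) signed toward
#'   the **chosen** response (0 on missed trials, which the analyses
#'   exclude unless a miss regressor is requested);
#' * `unsigned_high`, `unsigned_low` — ordinal coherence 1-4;
#' * `congruent` — 1 when both attributes map to the same response;
#' * `error_high` — 1 when the response was wrong for the high-reward
#'   attribute (0 on misses);
#' * `miss` — 1 on missed trials;
#' * `lag_signed_high` — previous trial's `signed_high`, 0 on each epoch's
#'   first trial;
#' * `attn_gain_low` — the generator's trialwise low-reward attention gain,
#'   centred at 0 (identically 0 unless the agent was simulated with
#'   `gain_sd > 0`).
#'
#' @param records Behavioral records for a single participant, in trial
#'   order (from [simulate_participant()]).
#' @return A tibble of design variables aligned to `records`.
#' @export
encoding_design <- function(records) {
  rec <- reward_frame(records)
  chosen <- ifelse(rec$missed, NA_character_, rec$choice)
  signed_high <- ifelse(rec$missed, 0L,
                        signed_coherence(rec$high_level,
                                         rec$high_correct,
                                         ifelse(rec$missed, "R", chosen)))
  signed_low <- ifelse(rec$missed, 0L,
                       signed_coherence(rec$low_level,
                                        rec$low_correct,
                                        ifelse(rec$missed, "R", chosen)))
  out <- tibble::tibble(
    signed_high = as.numeric(signed_high),
    signed_low = as.numeric(signed_low),
    unsigned_high = as.numeric(rec$high_level),
    unsigned_low = as.numeric(rec$low_level),
    congruent = as.numeric(rec$congruent),
    error_high = as.numeric(!rec$missed & rec$choice != rec$high_correct),
    miss = as.numeric(rec$missed),
    attn_gain_low = if ("attn_gain_low" %in% names(rec)) {
      rec$attn_gain_low - 1
    } else 0
  )
  first_of_epoch <- c(TRUE, diff(rec$epoch) != 0)
  out$lag_signed_high <- dplyr::lag(out$signed_high, default = 0)
  out$lag_signed_high[first_of_epoch] <- 0
  out
}

#' Encoding weights
#'
#' The design variables an [encoding_spec()] may weight.
#' @return Character vector of variable names.
#' @export
encoding_variables <- function() {
  c("signed_high", "signed_low", "unsigned_high", "unsigned_low",
    "congruent", "error_high", "miss", "lag_signed_high", "attn_gain_low")
}

#' Specify a linear-Gaussian generator for one region's beta series
#'
#' Trialwise activity for the region is
#' `beta_t = sum_j w_j x_jt + N(0, noise_sd)`, with `x` the design
#' variables of [encoding_design()].  This is an explicitly assumed
#' generative form: it reproduces the *regression structure* of trialwise
#' region-of-interest beta series, not any hemodynamic process.
#'
#' @param region Region label.
#' @param weights Named numeric vector; names must be a subset of
#'   [encoding_variables()].
#' @param noise_sd Gaussian noise SD (>= 0).
#' @return An object of class `encoding_spec`.
#' @examples
#' encoding_spec("vmpfc", c(signed_high = 0.4, signed_low = 0.2))
#' @export
encoding_spec <- function(region, weights, noise_sd = 1) {
  stopifnot(is.character(region), length(region) == 1L,
            is.numeric(weights), !is.null(names(weights)))
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  bad <- setdiff(names(weights), encoding_variables())
  if (length(bad)) {
    abort(sprintf("unknown design variable(s): %s", paste(bad, collapse = ", ")))
  }
  structure(list(region = region, weights = weights, noise_sd = noise_sd),
            class = "encoding_spec")
}

#' @export
print.encoding_spec <- function(x, ...) {
  cat(sprintf("<encoding_spec> %s: %s; noise_sd %.3g\n", x$region,
              paste(sprintf("%s=%.3g", names(x$weights), x$weights),
                    collapse = ", "),
              x$noise_sd))
  invisible(x)
}

#' Generate a synthetic trialwise beta series for a region
#'
#' Applies the [encoding_spec()]'s linear-Gaussian model to the design
#' variables of each participant's records.  One beta per trial, including
#' missed trials (downstream fits drop them unless a miss regressor is
#' requested).
#'
#' @param records Behavioral records (one or more participants; a
#'   `participant` column groups them, otherwise a single participant is
#'   assumed).
#' @param spec An [encoding_spec()].
#' @param seed Integer seed; per-participant noise streams are derived
#'   from it and the region label.
#' @return A tibble with `participant`, `region`, `trial`, `beta`.
#' @export
generate_roi_betas <- function(records, spec, seed = 1L) {
  stopifnot(inherits(spec, "encoding_spec"))
  if (!"participant" %in% names(records)) {
    records <- dplyr::mutate(records, participant = 1L)
  }
  if (!"trial" %in% names(records)) {
    records <- dplyr::mutate(records, trial = dplyr::row_number())
  }
  purrr::map_dfr(split(records, records$participant), function(rec) {
    x <- encoding_design(rec)
    mu <- as.matrix(x[, names(spec$weights), drop = FALSE]) %*% spec$weights
    p <- rec$participant[1]
    noise <- withr::with_seed(
      derive_seed(seed, paste0(spec$region, "-", p)),
      rnorm(nrow(rec), 0, spec$noise_sd))
    tibble::tibble(participant = p, region = spec$region,
                   trial = rec$trial, beta = as.numeric(mu) + noise)
  })
}

#' Preset encoding generators
#'
#' A set of named [encoding_spec()]s emulating the qualitative encoding
#' patterns the analyses are designed to recover:
#'
#' * `vmpfc` — positive signed-coherence weights in a 2:1 (high:low) ratio,
#'   mirroring reward-proportional evidence coding, plus a positive
#'   congruence and lag-1 high-reward evidence response;
#' * `dacc` — negative signed-coherence weights in a 4:1 (high:low) ratio,
#'   twice the reward ratio (attention-proportional, response-level
#'   coding), plus error and miss responses;
#' * `dacc_caudal1`, `dacc_caudal2` — negative unsigned high-reward
#'   coherence weight (response-level uncertainty);
#' * `dacc_rostral1`, `dacc_rostral2` — positive unsigned low-reward
#'   coherence weight and a weak negative unsigned high-reward weight
#'   (attention-level uncertainty), plus a positive loading on the
#'   trialwise low-reward attention gain.
#'
#' Weight magnitudes are chosen so each region's primary effect is
#' estimable within a single synthetic participant (about 5 within-
#' participant standard errors at the default 384 unequal-reward trials
#' and `noise_sd = 1`); they preserve the sign and ratio structure of the
#' reported group effects rather than their absolute (much smaller)
#' group-level magnitudes.
#'
#' @param noise_sd Noise SD applied to every preset.
#' @return Named list of `encoding_spec`s.
#' @export
encoding_presets <- function(noise_sd = 1) {
  list(
    vmpfc = encoding_spec("vmpfc",
      c(signed_high = 0.4, signed_low = 0.2, congruent = 0.1,
        lag_signed_high = 0.2), noise_sd),
    dacc = encoding_spec("dacc",
      c(signed_high = -0.44, signed_low = -0.11, error_high = 0.5,
        miss = 0.8), noise_sd),
    dacc_caudal1 = encoding_spec("dacc_caudal1",
      c(unsigned_high = -0.25, error_high = 0.45, miss = 0.8), noise_sd),
    dacc_caudal2 = encoding_spec("dacc_caudal2",
      c(unsigned_high = -0.25, error_high = 0.45, miss = 0.8), noise_sd),
    dacc_rostral1 = encoding_spec("dacc_rostral1",
      c(unsigned_low = 0.25, unsigned_high = -0.08, error_high = 0.45,
        miss = 0.45, attn_gain_low = 1), noise_sd),
    dacc_rostral2 = encoding_spec("dacc_rostral2",
      c(unsigned_low = 0.25, unsigned_high = -0.08, error_high = 0.45,
        miss = 0.45, attn_gain_low = 1), noise_sd)
  )
}
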