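#' Psychometric observer model for calibration
#'
#' A stand-in for the human observer calibrated by the staircase: accuracy
#' is `guess_rate + (1 - guess_rate - lapse_rate) * F(coherence)` with `F` a
#' logistic in coherence, midpoint `c50` and scale `slope` (both percent
#' coherence).  Accuracy is near chance at zero coherence and saturates at
#' `1 - lapse_rate`.
#'
#' Defaults (`c50` 15%, `slope` 6%, 1% lapses) describe an observer whose
#' threshold sits in the plausible human range for these stimuli and whose
#' psychometric function is smooth at the scale of the staircase step: one
#' 1.5% step moves accuracy by about 3 percentage points near threshold.
#'
#' @param c50 Logistic midpoint, percent coherence.
#' @param slope Logistic scale, percent coherence.
#' @param guess_rate Chance performance level (0.5 for two responses).
#' @param lapse_rate Probability of an attention lapse (caps accuracy at
#'   `1 - lapse_rate`).
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(c50 = 15, slope = 6, guess_rate = 0.5,
                           lapse_rate = 0.01) {
  stopifnot(c50 >= 0, slope > 0, guess_rate >= 0, guess_rate < 1,
            lapse_rate >= 0, lapse_rate < 0.5)
  structure(list(c50 = c50, slope = slope, guess_rate = guess_rate,
                 lapse_rate = lapse_rate),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf("<observer_model> c50 %.3g%%, slope %.3g%%, guess %.2f, lapse %.3f\n",
              x$c50, x$slope, x$guess_rate, x$lapse_rate))
  invisible(x)
}

#' True accuracy of an observer at a coherence
#'
#' @param observer An [observer_model()].
#' @param coherence Coherence(s) in percent, `>= 0`.
#' @return Probability of a correct response.
#' @export
observer_accuracy <- function(observer, coherence) {
  stopifnot(inherits(observer, "observer_model"))
  if (any(coherence < 0)) abort("`coherence` must be >= 0.")
  f <- 1 / (1 + exp(-(coherence - observer$c50) / observer$slope))
  observer$guess_rate + (1 - observer$guess_rate - observer$lapse_rate) * f
}

#' Draw Bernoulli responses from an observer
#'
#' Uses the current RNG stream; seed via `withr::with_seed()` or the
#' caller ([run_staircase()] seeds its own stream).
#'
#' @inheritParams observer_accuracy
#' @return Logical vector of correct/incorrect responses.
#' @export
observer_response <- function(observer, coherence) {
  runif(length(coherence)) < observer_accuracy(observer, coherence)
}
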