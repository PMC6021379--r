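#' Configuration of the 3-down/1-up calibration staircase
#'
#' Coherence decreases by `step` after every `down_count` consecutive
#' correct trials and increases by `step` after every error (never below
#' zero).  The running threshold estimate is the mean coherence over the
#' last `estimate_window` trials.  The staircase stops at the first trial
#' where all four criteria hold: (1) at least `min_trials` trials have
#' passed; (2) the running estimate is below `max_threshold`; (3) the
#' running estimate is no more than `drift_tolerance` above the lowest
#' running estimate over the previous `drift_window` trials (or as many as
#' completed); (4) a non-parametric correlation of coherence against trial
#' index over the last `trend_window` trials has two-tailed
#' `p > trend_alpha` (no linear trend).
#'
#' @param start_coherence Starting coherence in percent (40 for motion
#'   blocks, 33 for color).
#' @param step Staircase step, percent coherence.
#' @param down_count Consecutive correct responses required to step down.
#' @param min_trials Minimum number of trials before stopping.
#' @param max_threshold Running estimate must fall below this (percent).
#' @param drift_tolerance Maximum allowed excess (percent) of the current
#'   estimate over the windowed minimum estimate (four steps = 6%).
#' @param drift_window Look-back window (trials) for the minimum estimate.
#' @param trend_window Trials entering the trend test.
#' @param trend_alpha Two-tailed p-value that the trend test must exceed.
#' @param trend_method `"spearman"` (default) or `"kendall"`.
#' @param estimate_window Trials averaged for the threshold estimate.
#' @param max_trials Hard cap; exceeding it raises a non-convergence error.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(start_coherence = 40, step = 1.5, down_count = 3,
                             min_trials = 300, max_threshold = 30,
                             drift_tolerance = 6, drift_window = 400,
                             trend_window = 15, trend_alpha = 0.10,
                             trend_method = c("spearman", "kendall"),
                             estimate_window = 12, max_trials = 5000) {
  trend_method <- match.arg(trend_method)
  stopifnot(start_coherence > 0, step > 0, down_count >= 1, min_trials >= 1,
            max_threshold > 0, drift_tolerance > 0, drift_window >= 1,
            trend_window >= 3, estimate_window >= 1,
            max_trials >= min_trials)
  if (trend_alpha <= 0 || trend_alpha >= 1) {
    abort("`trend_alpha` must lie in (0, 1).")
  }
  structure(as.list(environment()), class = "staircase_config")
}

#' Initialize a staircase state
#'
#' @param config A [staircase_config()].
#' @return An object of class `staircase_state` with fields `coherence`
#'   (per-trial presented levels), `correct` (responses so far),
#'   `consecutive_correct` and `current_coherence` (level for the next
#'   trial).
#' @export
staircase_state <- function(config = staircase_config()) {
  structure(
    list(coherence = numeric(0), correct = logical(0),
         consecutive_correct = 0L,
         current_coherence = config$start_coherence),
    class = "staircase_state"
  )
}

#' Advance the staircase by one trial
#'
#' Records the presented coherence and the response, then applies the
#' 3-down/1-up update: an error raises coherence by one step and resets
#' the streak; a third consecutive correct response lowers it by one step
#' (floored at 0) and resets the streak; otherwise the streak increments.
#'
#' @param state A [staircase_state()].
#' @param correct Logical: was the response correct?
#' @param config A [staircase_config()].
#' @return The updated state.
#' @export
staircase_step <- function(state, correct, config = staircase_config()) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  state$coherence <- c(state$coherence, state$current_coherence)
  state$correct <- c(state$correct, correct)
  if (!correct) {
    state$current_coherence <- state$current_coherence + config$step
    state$consecutive_correct <- 0L
  } else {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= config$down_count) {
      state$current_coherence <- max(state$current_coherence - config$step, 0)
      state$consecutive_correct <- 0L
    }
  }
  state
}

#' Threshold estimate from a staircase history
#'
#' Arithmetic mean of the presented coherences over the last `window`
#' trials.
#'
#' @param state A [staircase_state()] (or any object with a numeric
#'   `coherence` history field).
#' @param window Number of trailing trials to average.
#' @return Threshold estimate in percent coherence.
#' @export
threshold_estimate <- function(state, window = 12) {
  h <- state$coherence
  if (length(h) < window) {
    abort(sprintf("need at least %d trials for a threshold estimate (have %d).",
                  window, length(h)))
  }
  mean(tail(h, window))
}

# Rolling estimate series: mean of each trailing `window` trials, NA until
# enough history exists.
rolling_estimates <- function(coherence, window) {
  n <- length(coherence)
  if (n < window) return(rep(NA_real_, n))
  cs <- cumsum(coherence)
  out <- rep(NA_real_, n)
  out[window:n] <- (cs[window:n] - c(0, cs)[ (window:n) - window + 1L]) / window
  out
}

trend_p_value <- function(coherence, config) {
  w <- tail(coherence, config$trend_window)
  if (length(unique(w)) < 2L) return(1)  # flat history: no trend
  ct <- suppressWarnings(
    cor.test(w, seq_along(w), method = config$trend_method, exact = FALSE))
  if (is.na(ct$p.value)) 1 else ct$p.value
}

#' Evaluate the four staircase termination criteria
#'
#' @param state A [staircase_state()].
#' @param config A [staircase_config()].
#' @return A list with `stop` (all four criteria hold) and `criteria`, a
#'   named logical vector (`min_trials`, `below_max`, `near_minimum`,
#'   `no_trend`).
#' @export
termination_check <- function(state, config = staircase_config()) {
  h <- state$coherence
  n <- length(h)
  crit <- c(min_trials = FALSE, below_max = FALSE, near_minimum = FALSE,
            no_trend = FALSE)
  crit["min_trials"] <- n >= config$min_trials
  if (n >= config$estimate_window) {
    est_series <- rolling_estimates(h, config$estimate_window)
    est <- est_series[n]
    crit["below_max"] <- est < config$max_threshold
    lo <- max(1L, n - config$drift_window + 1L)
    win_min <- min(est_series[lo:n], na.rm = TRUE)
    crit["near_minimum"] <- est <= win_min + config$drift_tolerance
  }
  if (n >= config$trend_window) {
    crit["no_trend"] <- trend_p_value(h, config) > config$trend_alpha
  }
  list(stop = all(crit), criteria = crit)
}

#' Run a calibration staircase against a simulated observer
#'
#' Iterates [staircase_step()] with Bernoulli responses from the observer's
#' psychometric function until [termination_check()] passes, then returns
#' the threshold estimate (mean of the last 12 presented coherences by
#' default).
#'
#' @param observer An [observer_model()].
#' @param config A [staircase_config()].
#' @param seed Integer seed for the observer's responses.
#' @return An object of class `staircase_fit` with elements `threshold`,
#'   `trials` (tibble: `trial`, `coherence`, `correct`, `estimate`),
#'   `criteria` (flags at stopping), `n_trials`, `observer`, `config`.
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' fit <- run_staircase(observer_model(), seed = 1)
#' glance(fit)
#' @export
run_staircase <- function(observer, config = staircase_config(), seed = 1L) {
  stopifnot(inherits(observer, "observer_model"))
  # flat vectors rather than the list state, for speed; semantics identical
  withr::with_seed(seed, {
    coh <- numeric(config$max_trials)
    corr <- logical(config$max_trials)
    cur <- config$start_coherence
    streak <- 0L
    ests <- rep(NA_real_, config$max_trials)
    csum <- 0
    stopped <- FALSE
    crit <- NULL
    w <- config$estimate_window
    for (i in seq_len(config$max_trials)) {
      coh[i] <- cur
      corr[i] <- runif(1) < observer_accuracy(observer, cur)
      if (!corr[i]) {
        cur <- cur + config$step
        streak <- 0L
      } else {
        streak <- streak + 1L
        if (streak >= config$down_count) {
          cur <- max(cur - config$step, 0)
          streak <- 0L
        }
      }
      if (i >= w) ests[i] <- mean(coh[(i - w + 1L):i])
      if (i >= config$min_trials) {
        est <- ests[i]
        lo <- max(1L, i - config$drift_window + 1L)
        win_min <- suppressWarnings(min(ests[lo:i], na.rm = TRUE))
        crit <- c(
          min_trials = TRUE,
          below_max = est < config$max_threshold,
          near_minimum = est <= win_min + config$drift_tolerance,
          no_trend = trend_p_value(coh[1:i], config) > config$trend_alpha
        )
        if (all(crit)) {
          stopped <- TRUE
          n <- i
          break
        }
      }
    }
  })
  if (!stopped) {
    abort(sprintf(
      "staircase failed to satisfy its termination criteria within %d trials.",
      config$max_trials))
  }
  trials <- tibble::tibble(trial = 1:n, coherence = coh[1:n],
                           correct = corr[1:n], estimate = ests[1:n])
  structure(
    list(threshold = ests[n], trials = trials, criteria = crit,
         n_trials = n, observer = observer, config = config, seed = seed),
    class = "staircase_fit"
  )
}

#' @export
print.staircase_fit <- function(x, ...) {
  cat(sprintf("<staircase_fit> threshold %.2f%% after %d trials\n",
              x$threshold, x$n_trials))
  invisible(x)
}

#' @rdname run_staircase
#' @param x,object A `staircase_fit` object.
#' @param ... Unused.
#' @method tidy staircase_fit
#' @export
tidy.staircase_fit <- function(x, ...) x$trials

#' @rdname run_staircase
#' @method glance staircase_fit
#' @export
glance.staircase_fit <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold,
    n_trials = x$n_trials,
    accuracy_at_threshold = observer_accuracy(x$observer, x$threshold),
    prop_correct = mean(x$trials$correct)
  )
}

#' @rdname run_staircase
#' @method autoplot staircase_fit
#' @export
autoplot.staircase_fit <- function(object, ...) {
  ggplot2::ggplot(object$trials, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$coherence), colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate), colour = "firebrick",
                       na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "trial", y = "coherence (%)",
                  title = sprintf("3-down/1-up staircase: threshold %.2f%%",
                                  object$threshold))
}
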