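#' Add signed ordinal coherence columns to records
#'
#' @param records Behavioral records.
#' @param frame `"reward"` (high/low-reward attributes) or `"motion_color"`.
#' @param reference `"chosen"` (sign toward the response actually made;
#'   missed trials get NA) or a fixed response `"L"`/`"R"`.
#' @return `records` with `s1`/`s2` columns (`signed_high`/`signed_low` or
#'   `signed_motion`/`signed_color` naming).
#' @keywords internal
signed_columns <- function(records, frame = c("reward", "motion_color"),
                           reference = "R") {
  frame <- match.arg(frame)
  rec <- reward_frame(records)
  ref <- if (identical(reference, "chosen")) {
    ifelse(rec$missed, "R", rec$choice)  # placeholder on misses; NA'd below
  } else {
    if (!reference %in% c("L", "R")) abort("`reference` must be \"L\", \"R\" or \"chosen\".")
    rep(reference, nrow(rec))
  }
  if (frame == "reward") {
    rec$s1 <- signed_coherence(rec$high_level, rec$high_correct, ref)
    rec$s2 <- signed_coherence(rec$low_level, rec$low_correct, ref)
  } else {
    rec$s1 <- signed_coherence(rec$motion_level, rec$motion_correct, ref)
    rec$s2 <- signed_coherence(rec$color_level, rec$color_correct, ref)
  }
  if (identical(reference, "chosen")) {
    rec$s1[rec$missed] <- NA_integer_
    rec$s2[rec$missed] <- NA_integer_
  }
  rec
}

coef_tibble <- function(fit, labels = NULL) {
  s <- summary(fit)$coefficients
  out <- tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, ncol(s)])
  )
  if (!is.null(labels)) out$term <- dplyr::recode(out$term, !!!labels)
  out
}

#' Logistic regression of choice on the two signed coherences
#'
#' Per-participant first stage of the choice analysis: the right-hand
#' response is regressed on the signed ordinal coherences (-4..+4, sign
#' toward "R") of the two attributes, in either the reward frame
#' (`b_high`, `b_low`; unequal-reward epochs) or the motion/color frame
#' (`b_motion`, `b_color`).  Missed trials are excluded.  Complete
#' separation is flagged with a warning rather than an error.
#'
#' @param records One participant's behavioral records.
#' @param frame `"reward"` or `"motion_color"`.
#' @param reference Response predicted and used to sign coherence
#'   (`"L"` or `"R"`).
#' @return An object of class `choice_fit`; [tidy()] gives the coefficient
#'   table, [glance()] the fit summary.
#' @export
fit_choice_model <- function(records, frame = c("reward", "motion_color"),
                             reference = "R") {
  frame <- match.arg(frame)
  rec <- signed_columns(records, frame, reference)
  rec <- dplyr::filter(rec, !.data$missed)
  if (length(unique(rec$choice)) < 2L) {
    abort("degenerate design: fewer than 2 distinct choices present.")
  }
  rec$y <- as.integer(rec$choice == reference)
  fit <- glm(y ~ s1 + s2, family = binomial(), data = rec)
  separated <- any(fit$fitted.values > 1 - 1e-8) ||
    any(fit$fitted.values < 1e-8) || !fit$converged
  if (separated) {
    warn("possible complete separation: coefficients may be unstable.")
  }
  labels <- if (frame == "reward") {
    c(s1 = "b_high", s2 = "b_low")
  } else {
    c(s1 = "b_motion", s2 = "b_color")
  }
  structure(
    list(coefficients = coef_tibble(fit, labels), fit = fit,
         frame = frame, reference = reference, n = nrow(rec),
         separated = separated),
    class = "choice_fit"
  )
}

#' @export
print.choice_fit <- function(x, ...) {
  cat(sprintf("<choice_fit> frame %s, %d trials\n", x$frame, x$n))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_choice_model
#' @param x,object A `choice_fit`.
#' @param ... Unused.
#' @method tidy choice_fit
#' @export
tidy.choice_fit <- function(x, ...) x$coefficients

#' @rdname fit_choice_model
#' @method glance choice_fit
#' @export
glance.choice_fit <- function(x, ...) {
  tibble::tibble(n = x$n, frame = x$frame, separated = x$separated,
                 deviance = x$fit$deviance, df.residual = x$fit$df.residual)
}

#' Linear regression of log RT on chosen-response evidence
#'
#' Response times are log-transformed; the predictors are the two signed
#' ordinal coherences in the chosen-response frame (how much each
#' attribute supported the response actually made).  Faster responses with
#' more supporting evidence appear as negative coefficients.  Missed
#' trials are excluded.
#'
#' @inheritParams fit_choice_model
#' @return An object of class `rt_fit` (same interface as `choice_fit`).
#' @export
fit_rt_model <- function(records, frame = c("reward", "motion_color")) {
  frame <- match.arg(frame)
  rec <- signed_columns(records, frame, reference = "chosen")
  rec <- dplyr::filter(rec, !.data$missed, .data$rt > 0)
  if (nrow(rec) == 0L) abort("no usable (non-missed) trials.")
  fit <- lm(log(rt) ~ s1 + s2, data = rec)
  labels <- if (frame == "reward") {
    c(s1 = "b_high", s2 = "b_low")
  } else {
    c(s1 = "b_motion", s2 = "b_color")
  }
  structure(
    list(coefficients = coef_tibble(fit, labels), fit = fit,
         frame = frame, n = nrow(rec)),
    class = "rt_fit"
  )
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("<rt_fit> frame %s, %d trials\n", x$frame, x$n))
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_rt_model
#' @param x,object An `rt_fit`.
#' @param ... Unused.
#' @method tidy rt_fit
#' @export
tidy.rt_fit <- function(x, ...) x$coefficients

#' @rdname fit_rt_model
#' @method glance rt_fit
#' @export
glance.rt_fit <- function(x, ...) {
  tibble::tibble(n = x$n, frame = x$frame,
                 sigma = summary(x$fit)$sigma,
                 r.squared = summary(x$fit)$r.squared)
}

#' Empirical psychometric table
#'
#' Proportion of reference-response choices at each signed high-reward
#' coherence level (-4..-1, +1..+4, response frame), with exact binomial
#' confidence intervals.  Levels with no observations are reported as
#' missing rows, not errors.
#'
#' @param records Behavioral records (missed trials excluded internally).
#' @param reference Reference response, default `"R"`.
#' @param conf.level Confidence level for the binomial intervals.
#' @return A tibble with `signed_high`, `n`, `k`, `p`, `conf.low`,
#'   `conf.high`.
#' @export
psychometric_table <- function(records, reference = "R", conf.level = 0.95) {
  rec <- signed_columns(records, "reward", reference)
  rec <- dplyr::filter(rec, !.data$missed)
  lvls <- setdiff(-4:4, 0)
  purrr::map_dfr(lvls, function(l) {
    sub <- rec[rec$s1 == l, ]
    n <- nrow(sub)
    if (n == 0L) {
      return(tibble::tibble(signed_high = l, n = 0L, k = NA_integer_,
                            p = NA_real_, conf.low = NA_real_,
                            conf.high = NA_real_))
    }
    k <- sum(sub$choice == reference)
    bt <- binom.test(k, n, conf.level = conf.level)
    tibble::tibble(signed_high = l, n = n, k = k, p = k / n,
                   conf.low = bt$conf.int[1], conf.high = bt$conf.int[2])
  })
}

#' Plot a psychometric table
#'
#' @param table Output of [psychometric_table()].
#' @return A ggplot.
#' @export
plot_psychometric <- function(table) {
  ggplot2::ggplot(dplyr::filter(table, !is.na(.data$p)),
                  ggplot2::aes(x = .data$signed_high, y = .data$p)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "signed high-reward coherence (ordinal)",
                  y = "P(reference response)")
}

#' Trial-history (lagged evidence) models
#'
#' Tests whether performance on the high-reward attribute improves after
#' trials with strong evidence for the previously chosen response:
#' logistic regression of high-reward accuracy, and linear regression of
#' log RT, on the previous trial's chosen-frame signed high-reward
#' coherence (zeroed at each epoch's first trial), controlling for the
#' current trial's unsigned coherences.  Missed trials are excluded as
#' outcomes but still contribute a zero lag feature.
#'
#' @param records One participant's behavioral records, in trial order.
#' @return A tibble of coefficients for both models (`model` column:
#'   `"accuracy"`, `"log_rt"`).
#' @export
trial_history_model <- function(records) {
  rec <- reward_frame(records)
  if (min(table(rec$epoch)) < 2L) abort("need at least 2 trials per epoch.")
  x <- encoding_design(records)
  rec$lag_signed_high <- x$lag_signed_high
  rec$unsigned_high <- x$unsigned_high
  rec$unsigned_low <- x$unsigned_low
  rec$correct_high <- as.integer(!rec$missed & rec$choice == rec$high_correct)
  use <- !rec$missed
  acc <- glm(correct_high ~ unsigned_high + unsigned_low + lag_signed_high,
             family = binomial(), data = rec[use, ])
  rtm <- lm(log(rt) ~ unsigned_high + unsigned_low + lag_signed_high,
            data = rec[use & !is.na(rec$rt), ])
  dplyr::bind_rows(
    dplyr::mutate(coef_tibble(acc), model = "accuracy"),
    dplyr::mutate(coef_tibble(rtm), model = "log_rt")
  )
}

#' Per-participant fits across a cohort
#'
#' Maps a single-participant fitter over the cohort and stacks the
#' coefficient tables — the first stage of the two-stage group analysis.
#'
#' @param records Cohort records with a `participant` column.
#' @param fitter A function of one participant's records returning an
#'   object with a [tidy()] method or a coefficient tibble.
#' @param ... Passed to `fitter`.
#' @return Tibble of per-participant coefficients (`participant`, `term`,
#'   `estimate`, `std.error`, ...).
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(4, seed = 1)
#' fits <- cohort_fits(cohort, fit_choice_model, frame = "reward")
#' group_coefficient_tests(fits)
#' }
#' @export
cohort_fits <- function(records, fitter, ...) {
  stopifnot("participant" %in% names(records))
  purrr::map_dfr(split(records, records$participant), function(rec) {
    out <- fitter(rec, ...)
    tbl <- if (tibble::is_tibble(out)) out else tidy(out)
    dplyr::mutate(tbl, participant = rec$participant[1], .before = 1L)
  })
}

#' Group-level tests on per-participant coefficients
#'
#' Second stage of the two-stage analysis: a two-tailed one-sample t-test
#' of each term's per-participant estimates against `mu` (default 0).
#'
#' @param fits Per-participant coefficient tibble (from [cohort_fits()]).
#' @param mu Null value.
#' @return A tibble with one row per term (and per `model`/`region` group
#'   if present): `mean`, `sd`, `n`, `statistic`, `p.value`, `conf.low`,
#'   `conf.high`.
#' @export
group_coefficient_tests <- function(fits, mu = 0) {
  grp <- intersect(c("model", "region", "term"), names(fits))
  dplyr::summarise(
    dplyr::group_by(fits, dplyr::across(dplyr::all_of(grp))),
    mean = mean(.data$estimate),
    sd = sd(.data$estimate),
    n = dplyr::n(),
    statistic = tryCatch(t.test(.data$estimate, mu = mu)$statistic,
                         error = function(e) NA_real_),
    p.value = tryCatch(t.test(.data$estimate, mu = mu)$p.value,
                       error = function(e) NA_real_),
    conf.low = .data$mean - stats::qt(0.975, .data$n - 1) * .data$sd / sqrt(.data$n),
    conf.high = .data$mean + stats::qt(0.975, .data$n - 1) * .data$sd / sqrt(.data$n),
    .groups = "drop"
  )
}
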