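#' Hyperbolic-arcsine transform of beta series
#'
#' Trialwise beta estimates are arcsinh-transformed before regression to
#' reduce kurtosis; the map is odd, strictly increasing and
#' order-preserving.
#'
#' @param betas Numeric vector, or a tibble with a `beta` column.
#' @return Same shape as the input, transformed.
#' @examples
#' transform_betas(c(0, 1))   # 0, log(1 + sqrt(2))
#' @export
transform_betas <- function(betas) {
  if (is.numeric(betas)) return(asinh(betas))
  stopifnot("beta" %in% names(betas))
  dplyr::mutate(betas, beta = asinh(.data$beta))
}

# Nuisance columns: per-block intercepts and per-block linear trends,
# mirroring first-level GLM practice.
nuisance_matrix <- function(rec) {
  blk <- interaction(rec$epoch, rec$block, drop = TRUE)
  x <- model.matrix(~ 0 + blk)
  trend <- scale(stats::ave(seq_len(nrow(rec)), blk, FUN = seq_along),
                 scale = FALSE)
  tr <- x * as.numeric(trend)
  colnames(tr) <- paste0(colnames(x), "_trend")
  cbind(x, tr)
}

#' Fit trialwise encoding models
#'
#' Per participant and region: ordinary least squares of the
#' arcsinh-transformed beta series on the requested design variables (see
#' [encoding_design()]) plus per-block intercepts and linear trends as
#' nuisance terms.  Missed trials are excluded unless `"miss"` is among the
#' requested variables, in which case all trials enter and the miss
#' indicator is estimated.  A rank-deficient design is an error naming the
#' collinear columns.
#'
#' @param betas Beta-series tibble (`participant`, `region`, `trial`,
#'   `beta`), e.g. from [generate_roi_betas()]; multiple regions may be
#'   stacked.
#' @param records Cohort behavioral records aligned by `participant` and
#'   `trial`.
#' @param variables Design variables to estimate (subset of
#'   [encoding_variables()]).
#' @param transform Apply [transform_betas()] first (default TRUE).
#' @return An object of class `encoding_fits`: a per-participant/region
#'   coefficient tibble (`participant`, `region`, `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`), nuisance terms dropped.
#'   [tidy()] returns the table; [glance()] the group-level t-tests.
#' @export
fit_encoding_model <- function(betas, records,
                               variables = c("signed_high", "signed_low"),
                               transform = TRUE) {
  stopifnot(all(variables %in% encoding_variables()))
  if (!"participant" %in% names(records)) {
    records <- dplyr::mutate(records, participant = 1L)
  }
  if (transform) betas <- transform_betas(betas)
  keys <- dplyr::distinct(betas, .data$participant, .data$region)
  out <- purrr::pmap_dfr(keys, function(participant, region) {
    rec <- records[records$participant == participant, ]
    b <- betas[betas$participant == participant & betas$region == region, ]
    stopifnot(nrow(b) == nrow(rec))
    b <- b[match(rec$trial, b$trial), ]
    x <- encoding_design(rec)
    keep <- if ("miss" %in% variables) rep(TRUE, nrow(rec)) else !rec$missed
    xm <- cbind(as.matrix(x[keep, variables, drop = FALSE]),
                nuisance_matrix(rec[keep, ]))
    qx <- qr(xm)
    if (qx$rank < ncol(xm)) {
      dropped <- colnames(xm)[qx$pivot[(qx$rank + 1):ncol(xm)]]
      abort(sprintf("rank-deficient encoding design; collinear column(s): %s",
                    paste(dropped, collapse = ", ")))
    }
    fit <- lm(b$beta[keep] ~ 0 + xm)
    tbl <- coef_tibble(fit)
    tbl$term <- sub("^xm", "", tbl$term)
    tbl <- tbl[tbl$term %in% variables, ]
    dplyr::mutate(tbl, participant = participant, region = region,
                  .before = 1L)
  })
  structure(list(coefficients = out, variables = variables),
            class = "encoding_fits")
}

#' @export
print.encoding_fits <- function(x, ...) {
  cat(sprintf("<encoding_fits> %d participant x region fits of [%s]\n",
              nrow(dplyr::distinct(x$coefficients, .data$participant,
                                   .data$region)),
              paste(x$variables, collapse = ", ")))
  invisible(x)
}

#' @rdname fit_encoding_model
#' @param x,object An `encoding_fits` object.
#' @param ... Unused.
#' @method tidy encoding_fits
#' @export
tidy.encoding_fits <- function(x, ...) x$coefficients

#' @rdname fit_encoding_model
#' @method glance encoding_fits
#' @export
glance.encoding_fits <- function(x, ...) {
  group_coefficient_tests(x$coefficients)
}

#' Test the high:low encoding-weight ratio against a reference
#'
#' Computes each participant's ratio of signed high- to signed low-reward
#' coefficients in one region and t-tests the cohort's ratios against the
#' reward ratio (2 by default).  Participants whose low-reward coefficient
#' is smaller in magnitude than `floor` times its standard error are
#' excluded (unstable denominators) and counted.
#'
#' @param fits An [fit_encoding_model()] result containing `signed_high`
#'   and `signed_low` terms.
#' @param region Region label to test.
#' @param reference Null ratio (default 2, the reward ratio).
#' @param floor Stability floor multiplier on the denominator's SE.
#' @return A list of class `ratio_test`: `ratios` (per-participant tibble),
#'   `mean_ratio`, `statistic`, `p.value`, `n`, `n_excluded`, `reference`.
#' @export
attribute_weight_ratio <- function(fits, region, reference = 2, floor = 0.1) {
  stopifnot(inherits(fits, "encoding_fits"))
  tbl <- fits$coefficients
  if (!all(c("signed_high", "signed_low") %in% tbl$term)) {
    abort("fits must include `signed_high` and `signed_low` terms.")
  }
  wide <- tidyr::pivot_wider(
    dplyr::filter(tbl, .data$region == !!region,
                  .data$term %in% c("signed_high", "signed_low")),
    id_cols = "participant", names_from = "term",
    values_from = c("estimate", "std.error"))
  stable <- abs(wide$estimate_signed_low) >= floor * wide$std.error_signed_low
  ratios <- dplyr::mutate(wide[stable, ],
                          ratio = .data$estimate_signed_high /
                            .data$estimate_signed_low)
  if (nrow(ratios) < 2L) {
    abort("fewer than 2 participants with a stable low-reward coefficient.")
  }
  if (sd(ratios$ratio) < 1e-12) {
    # degenerate (e.g. noiseless) cohorts: all ratios identical
    on_ref <- abs(mean(ratios$ratio) - reference) < 1e-12
    tt <- list(statistic = if (on_ref) 0 else sign(mean(ratios$ratio) -
                                                     reference) * Inf,
               p.value = if (on_ref) 1 else 0)
  } else {
    tt <- t.test(ratios$ratio, mu = reference)
  }
  structure(
    list(ratios = ratios, region = region,
         mean_ratio = mean(ratios$ratio),
         statistic = unname(tt$statistic), p.value = tt$p.value,
         n = nrow(ratios), n_excluded = sum(!stable), reference = reference),
    class = "ratio_test"
  )
}

#' @export
print.ratio_test <- function(x, ...) {
  cat(sprintf(
    "<ratio_test> %s: mean high:low ratio %.3f vs %.3g (t = %.2f, p = %.3g, n = %d, excluded %d)\n",
    x$region, x$mean_ratio, x$reference, x$statistic, x$p.value, x$n,
    x$n_excluded))
  invisible(x)
}

#' Paired comparison of two regions' weight ratios
#'
#' @inheritParams attribute_weight_ratio
#' @param region1,region2 Regions to compare.
#' @return Tibble with the paired t-test of region1 - region2 ratios.
#' @export
paired_ratio_test <- function(fits, region1, region2, floor = 0.1) {
  r1 <- attribute_weight_ratio(fits, region1, floor = floor)$ratios
  r2 <- attribute_weight_ratio(fits, region2, floor = floor)$ratios
  both <- dplyr::inner_join(r1[, c("participant", "ratio")],
                            r2[, c("participant", "ratio")],
                            by = "participant", suffix = c("_1", "_2"))
  tt <- t.test(both$ratio_1, both$ratio_2, paired = TRUE)
  tibble::tibble(region1 = region1, region2 = region2,
                 mean_difference = mean(both$ratio_1 - both$ratio_2),
                 statistic = unname(tt$statistic), p.value = tt$p.value,
                 n = nrow(both))
}

#' Rostral vs caudal coherence-encoding interaction
#'
#' Tests the double dissociation along the rostrocaudal axis: per
#' participant, unsigned high- and low-reward coherence coefficients are
#' averaged within the rostral and within the caudal ROI group; the
#' contrasts reported are the group differences for each coherence type
#' and their interaction (rostral-minus-caudal difference for low- minus
#' high-reward coherence), each with a one-sample t-test across
#' participants.
#'
#' @param fits An [fit_encoding_model()] result containing `unsigned_high`
#'   and `unsigned_low` terms for the listed regions.
#' @param rostral,caudal Character vectors of region labels (>= 1 each;
#'   the axis analyses use 2 + 2).
#' @return A tibble with rows `low_rostral_minus_caudal`,
#'   `high_rostral_minus_caudal` and `interaction`, each with `mean`,
#'   `statistic`, `p.value`, `n`.
#' @export
rostrocaudal_interaction <- function(fits, rostral, caudal) {
  stopifnot(inherits(fits, "encoding_fits"))
  tbl <- dplyr::filter(fits$coefficients,
                       .data$term %in% c("unsigned_high", "unsigned_low"),
                       .data$region %in% c(rostral, caudal))
  if (!any(tbl$region %in% rostral) || !any(tbl$region %in% caudal)) {
    abort("both ROI groups must be present in the fits.")
  }
  tbl$roi_group <- ifelse(tbl$region %in% rostral, "rostral", "caudal")
  per <- dplyr::summarise(
    dplyr::group_by(tbl, .data$participant, .data$roi_group, .data$term),
    estimate = mean(.data$estimate), .groups = "drop")
  wide <- tidyr::pivot_wider(per, names_from = c("roi_group", "term"),
                             values_from = "estimate")
  d_low <- wide$rostral_unsigned_low - wide$caudal_unsigned_low
  d_high <- wide$rostral_unsigned_high - wide$caudal_unsigned_high
  contrasts <- list(
    low_rostral_minus_caudal = d_low,
    high_rostral_minus_caudal = d_high,
    interaction = d_low - d_high
  )
  purrr::imap_dfr(contrasts, function(v, nm) {
    tt <- t.test(v)
    tibble::tibble(contrast = nm, mean = mean(v),
                   statistic = unname(tt$statistic), p.value = tt$p.value,
                   n = length(v))
  })
}

#' Cross-participant neural-behavioral coupling
#'
#' Regresses each participant's behavioral sensitivity (e.g. the choice
#' coefficient on signed high-reward coherence) on their neural
#' sensitivity in a region (e.g. the encoding coefficient for the same
#' variable).
#'
#' @param neural_fits Per-participant neural coefficients (tibble from
#'   [tidy()] on an [fit_encoding_model()] result, or the object itself).
#' @param behavioral_fits Per-participant behavioral coefficients (from
#'   [cohort_fits()]).
#' @param region Region whose coefficients enter the regression.
#' @param neural_term,behavioral_term Coefficient names to couple.
#' @return Tidy coefficient tibble of the cross-participant regression
#'   (slope row named `neural`).
#' @export
neural_behavior_coupling <- function(neural_fits, behavioral_fits, region,
                                     neural_term = "signed_high",
                                     behavioral_term = "b_high") {
  if (inherits(neural_fits, "encoding_fits")) {
    neural_fits <- neural_fits$coefficients
  }
  nn <- dplyr::filter(neural_fits, .data$region == !!region,
                      .data$term == neural_term)
  bb <- dplyr::filter(behavioral_fits, .data$term == behavioral_term)
  both <- dplyr::inner_join(
    dplyr::select(nn, "participant", neural = "estimate"),
    dplyr::select(bb, "participant", behavior = "estimate"),
    by = "participant")
  if (nrow(both) < 3L) abort("need at least 3 participants in common.")
  coef_tibble(lm(behavior ~ neural, data = both))
}

#' Does rostral activity gate the low-reward attribute's influence?
#'
#' Per participant, logistic regression of low-reward-attribute
#' correctness on (z-scored) rostral region activity, the unsigned
#' low-reward coherence, and their interaction; group-level t-tests across
#' participants.  A positive interaction means that on high-activity
#' trials the participant was more likely to respond correctly to a
#' high-coherence low-reward attribute.  Missed trials are excluded.
#'
#' @param records Cohort behavioral records.
#' @param betas Beta series for the (rostral) region to test, same
#'   participants.
#' @param transform Apply [transform_betas()] first.
#' @return A list of class `choice_interaction`: per-participant
#'   coefficients and group tests; the interaction row is named
#'   `activity:unsigned_low`.
#' @export
choice_interaction_model <- function(records, betas, transform = TRUE) {
  if (!"participant" %in% names(records)) {
    records <- dplyr::mutate(records, participant = 1L)
  }
  if (transform) betas <- transform_betas(betas)
  per <- purrr::map_dfr(split(records, records$participant), function(rec) {
    b <- betas[betas$participant == rec$participant[1], ]
    stopifnot(nrow(b) == nrow(rec))
    b <- b[match(rec$trial, b$trial), ]
    rec <- reward_frame(rec)
    rec$activity <- as.numeric(scale(b$beta))
    rec$unsigned_low <- rec$low_level
    rec$correct_low <- as.integer(!rec$missed & rec$choice == rec$low_correct)
    rec <- rec[!rec$missed, ]
    if (length(unique(rec$correct_low)) < 2L) {
      abort("degenerate outcome: low-reward correctness does not vary.")
    }
    fit <- glm(correct_low ~ activity * unsigned_low, family = binomial(),
               data = rec)
    dplyr::mutate(coef_tibble(fit), participant = rec$participant[1],
                  .before = 1L)
  })
  structure(list(coefficients = per,
                 group = group_coefficient_tests(per)),
            class = "choice_interaction")
}

#' @export
print.choice_interaction <- function(x, ...) {
  cat("<choice_interaction> group-level tests:\n")
  print(x$group)
  invisible(x)
}

#' @rdname choice_interaction_model
#' @param x An `choice_interaction` object.
#' @param ... Unused.
#' @method tidy choice_interaction
#' @export
tidy.choice_interaction <- function(x, ...) x$coefficients

#' @rdname choice_interaction_model
#' @method glance choice_interaction
#' @export
glance.choice_interaction <- function(x, ...) x$group
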