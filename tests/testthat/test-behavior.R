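test_that("choice coefficients recover the generating population values", {
  # one participant, large trial count: estimates within 3 SE of the
  # population coefficients computed by the closed-form oracle
  agent <- agent_config(lapse_rate = 0.02)
  design <- dplyr::bind_rows(purrr::map(1:4, function(i) {
    dplyr::filter(generate_session("motion", seed = 100 + i), epoch == 2)
  }))
  design$trial <- seq_len(nrow(design))
  rec <- simulate_participant(design, agent, seed = 51)
  fit <- fit_choice_model(rec, frame = "reward")
  est <- tidy(fit)
  truth <- oracle_choice_coefs(agent$attn_high, agent$attn_low,
                               lapse = agent$lapse_rate)
  expect_lt(abs(est$estimate[est$term == "b_high"] - truth[["s_high"]]),
            3 * est$std.error[est$term == "b_high"])
  expect_lt(abs(est$estimate[est$term == "b_low"] - truth[["s_low"]]),
            3 * est$std.error[est$term == "b_low"])
  expect_equal(glance(fit)$n, sum(!rec$missed))
})

test_that("an ignored attribute has a null choice coefficient", {
  design <- dplyr::filter(generate_session("motion", seed = 61), epoch == 2)
  rec <- simulate_participant(
    design, agent_config(attn_high = 0.8, attn_low = 0), seed = 52)
  est <- tidy(fit_choice_model(rec, frame = "reward"))
  expect_lt(abs(est$estimate[est$term == "b_low"]),
            3 * est$std.error[est$term == "b_low"])
})

test_that("the fit is equivariant under reflection of the response axis", {
  # re-referencing from R to L flips both the outcome and the predictor
  # signs: slopes are invariant, the intercept changes sign
  co <- make_unequal_cohort(n = 1, seed = 62)
  eR <- tidy(fit_choice_model(co, "reward", reference = "R"))
  eL <- tidy(fit_choice_model(co, "reward", reference = "L"))
  expect_equal(eR$estimate[eR$term == "(Intercept)"],
               -eL$estimate[eL$term == "(Intercept)"], tolerance = 1e-6)
  expect_equal(eR$estimate[eR$term != "(Intercept)"],
               eL$estimate[eL$term != "(Intercept)"], tolerance = 1e-6)
  # flipping the outcome coding alone flips every coefficient: refit with
  # the choices relabelled
  flipped <- dplyr::mutate(co, choice = dplyr::recode(choice, R = "L",
                                                      L = "R"))
  ef <- tidy(fit_choice_model(flipped, "reward", reference = "R"))
  expect_equal(ef$estimate, -eR$estimate, tolerance = 1e-6)
})

test_that("reward and attribute frames coincide up to relabeling", {
  # epoch-2 data with motion as the high-reward attribute: the reward-frame
  # fit is the motion/color fit with renamed terms
  design <- dplyr::filter(generate_session("motion", seed = 63), epoch == 2)
  rec <- simulate_participant(design, agent_config(), seed = 53)
  rew <- tidy(fit_choice_model(rec, "reward"))
  mc <- tidy(fit_choice_model(rec, "motion_color"))
  expect_equal(rew$estimate[rew$term == "b_high"],
               mc$estimate[mc$term == "b_motion"])
  expect_equal(rew$estimate[rew$term == "b_low"],
               mc$estimate[mc$term == "b_color"])
})

test_that("log-RT regressions show faster responses with more evidence", {
  co <- make_unequal_cohort(n = 8, seed = 64)
  fits <- cohort_fits(co, fit_rt_model, frame = "reward")
  grp <- group_coefficient_tests(fits)
  b_high <- grp[grp$term == "b_high", ]
  b_low <- grp[grp$term == "b_low", ]
  expect_lt(b_high$mean, 0)
  expect_lt(b_low$mean, 0)
  expect_lt(b_high$p.value, 0.05)
  # missed trials never enter the fit
  one <- dplyr::filter(co, .data$participant == 1)
  expect_equal(glance(fit_rt_model(one))$n, sum(!one$missed))
})

test_that("shuffled coherence labels yield null RT coefficients", {
  co <- make_unequal_cohort(n = 1, seed = 65)
  shuffled <- co
  set.seed(99)
  idx <- sample(nrow(co))
  lvl_cols <- c("motion_level", "color_level", "motion_correct",
                "color_correct", "congruent")
  shuffled[lvl_cols] <- co[idx, lvl_cols]
  est <- tidy(fit_rt_model(shuffled, "reward"))
  expect_true(all(abs(est$estimate[est$term != "(Intercept)"]) <
                    3 * est$std.error[est$term != "(Intercept)"]))
})

test_that("psychometric tables are symmetric and span the signed levels", {
  co <- make_unequal_cohort(n = 8, seed = 66)
  tab <- psychometric_table(co)
  expect_equal(tab$signed_high, setdiff(-4:4, 0))
  expect_true(all(tab$n > 0))
  # generator is left/right symmetric: P(+k) ~ 1 - P(-k)
  for (k in 1:4) {
    p_pos <- tab$p[tab$signed_high == k]
    p_neg <- tab$p[tab$signed_high == -k]
    se <- sqrt(p_pos * (1 - p_pos) / tab$n[tab$signed_high == k] +
                 p_neg * (1 - p_neg) / tab$n[tab$signed_high == -k])
    expect_lt(abs(p_pos - (1 - p_neg)), 4 * se + 0.02)
  }
  # strong evidence for the high-reward attribute approaches ceiling
  expect_gt(tab$p[tab$signed_high == 4], 0.85)
  # monotone increasing for a strongly weighted cohort
  expect_true(all(diff(tab$p) > -0.05))
})

test_that("a level bin with no observations is reported as missing", {
  co <- make_unequal_cohort(n = 1, seed = 67)
  sub <- dplyr::filter(
    evcddm:::signed_columns(co, "reward", "R"), .data$s1 != 4)
  tab <- psychometric_table(sub)
  expect_true(is.na(tab$p[tab$signed_high == 4]))
  expect_equal(tab$n[tab$signed_high == 4], 0L)
})

test_that("trial-history lag features match hand-computed bookkeeping", {
  co <- simulate_cohort(1, seed = 68)
  x <- encoding_design(co)
  # hand-compute the lag on a 3-trial window inside an epoch
  i <- 10:12
  expect_equal(x$lag_signed_high[i], x$signed_high[i - 1])
  th <- trial_history_model(co)
  expect_true(all(c("accuracy", "log_rt") %in% th$model))
  # a memoryless agent: lag coefficient null at the group level
  co8 <- simulate_cohort(6, seed = 69)
  lags <- cohort_fits(co8, trial_history_model)
  grp <- group_coefficient_tests(
    dplyr::filter(lags, .data$term == "lag_signed_high"))
  expect_true(all(grp$p.value > 0.01))
})

test_that("group recovery orders b_high above b_low with asymmetric policies", {
  co <- make_unequal_cohort(n = 8, seed = 70)
  fits <- cohort_fits(co, fit_choice_model, frame = "reward")
  wide <- tidyr::pivot_wider(
    dplyr::filter(fits, .data$term %in% c("b_high", "b_low")),
    id_cols = "participant", names_from = "term", values_from = "estimate")
  tt <- t.test(wide$b_high, wide$b_low, paired = TRUE)
  expect_gt(mean(wide$b_high - wide$b_low), 0)
  expect_lt(tt$p.value, 0.05)
})

test_that("degenerate designs are rejected with clear errors", {
  co <- make_unequal_cohort(n = 1, seed = 71)
  one_choice <- dplyr::mutate(co, choice = "R", missed = FALSE, rt = 1)
  expect_error(fit_choice_model(one_choice), "degenerate")
  all_missed <- dplyr::mutate(co, missed = TRUE, choice = "missed",
                              rt = NA_real_)
  expect_error(fit_rt_model(all_missed), "no usable")
})
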