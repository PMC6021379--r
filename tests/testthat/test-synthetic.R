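test_that("observer accuracy has chance floor, saturation and midpoint", {
  obs <- observer_model(c50 = 15, slope = 4, lapse_rate = 0.02)
  expect_equal(observer_accuracy(observer_model(c50 = 40, slope = 1,
                                                lapse_rate = 0), 0),
               0.5, tolerance = 1e-10)
  expect_equal(observer_accuracy(obs, 1e6), 0.98)
  # logistic midpoint: halfway between floor and ceiling
  expect_equal(observer_accuracy(obs, 15), (0.5 + 0.98) / 2)
  expect_true(all(diff(observer_accuracy(obs, seq(0, 60, 2))) > 0))
  expect_error(observer_accuracy(obs, -3), "coherence")
})

test_that("simulated participants are reproducible and respect the deadline", {
  design <- generate_session(seed = 3)
  agent <- agent_config()
  r1 <- simulate_participant(design, agent, seed = 5)
  r2 <- simulate_participant(design, agent, seed = 5)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 576)
  expect_true(all(is.na(r1$rt[r1$missed])))
  expect_true(all(r1$rt[!r1$missed] <= agent$deadline + 1e-12))
  expect_true(all(r1$rt[!r1$missed] >= agent$ddm$non_decision_time))
  # reward bookkeeping: sum of attribute payouts actually earned
  expect_equal(r1$reward,
               r1$correct_motion * r1$reward_motion +
                 r1$correct_color * r1$reward_color)
  expect_true(all(r1$reward[r1$missed] == 0))
})

test_that("attention drives accuracy in the expected directions", {
  design <- dplyr::filter(generate_session(seed = 8), epoch == 2)
  # overwhelming motion attention: near-perfect motion accuracy
  strong <- simulate_participant(
    design, agent_config(attn_high = 8, attn_low = 0, lapse_rate = 0),
    seed = 2)
  expect_gt(mean(strong$correct_motion[!strong$missed]), 0.95)
  # no color attention: choice is carried entirely by motion evidence,
  # which is orthogonal to color, so overall color accuracy sits at
  # chance (and tracks motion errors on incongruent trials)
  ok <- strong[!strong$missed, ]
  expect_lt(abs(mean(ok$correct_color) - 0.5), 3 * 0.5 / sqrt(nrow(ok)))
  inc <- ok[!ok$congruent, ]
  expect_lt(mean(inc$correct_color), 0.05)
  # motion accuracy rises monotonically with motion attention
  accs <- vapply(c(0.2, 0.6, 1.4), function(a) {
    r <- simulate_participant(
      design, agent_config(attn_high = a, attn_low = 0.18, lapse_rate = 0),
      seed = 31)
    mean(r$correct_motion[!r$missed])
  }, numeric(1))
  expect_true(all(diff(accs) > 0))
})

test_that("miss rate grows with the boundary at a fixed deadline", {
  design <- dplyr::filter(generate_session(seed = 9), epoch == 2)
  rates <- vapply(c(0.45, 1.2, 2), function(a) {
    r <- simulate_participant(
      design, agent_config(ddm = ddm_params(boundary = a), lapse_rate = 0),
      seed = 13)
    mean(r$missed)
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("noiseless beta series recover the generating weights exactly", {
  co <- make_unequal_cohort(n = 1, seed = 21)
  spec <- encoding_spec("toy", c(signed_high = 2, signed_low = 1),
                        noise_sd = 0)
  b <- generate_roi_betas(co, spec, seed = 1)
  expect_equal(nrow(b), nrow(co))
  fits <- suppressWarnings(  # lm warns on the perfect (noiseless) fit
    fit_encoding_model(b, co, c("signed_high", "signed_low"),
                       transform = FALSE))
  est <- tidy(fits)
  expect_equal(est$estimate[est$term == "signed_high"], 2, tolerance = 1e-10)
  expect_equal(est$estimate[est$term == "signed_low"], 1, tolerance = 1e-10)
  # ratio recovered exactly
  expect_equal(est$estimate[est$term == "signed_high"] /
                 est$estimate[est$term == "signed_low"], 2,
               tolerance = 1e-10)
})

test_that("positive signed weights imply a positive congruence contrast", {
  co <- make_unequal_cohort(n = 1, seed = 22)
  spec <- encoding_spec("toy", c(signed_high = 1, signed_low = 0.5),
                        noise_sd = 0)
  b <- generate_roi_betas(co, spec, seed = 1)
  joined <- dplyr::left_join(co, b, by = c("participant", "trial"))
  ok <- !joined$missed
  expect_gt(mean(joined$beta[ok & joined$congruent]),
            mean(joined$beta[ok & !joined$congruent]))
})

test_that("beta generation is reproducible with documented substreams", {
  co <- make_unequal_cohort(n = 2, seed = 23)
  spec <- encoding_presets()$vmpfc
  expect_identical(generate_roi_betas(co, spec, seed = 4),
                   generate_roi_betas(co, spec, seed = 4))
  expect_false(identical(generate_roi_betas(co, spec, seed = 4)$beta,
                         generate_roi_betas(co, spec, seed = 5)$beta))
  expect_error(encoding_spec("x", c(not_a_variable = 1)), "unknown design")
})

test_that("lag features are zeroed at epoch starts and shifted otherwise", {
  co <- simulate_cohort(1, seed = 24)
  x <- encoding_design(co)
  starts <- which(c(TRUE, diff(co$epoch) != 0))
  expect_equal(x$lag_signed_high[starts], rep(0, 3))
  inner <- setdiff(seq_len(nrow(co)), starts)
  expect_equal(x$lag_signed_high[inner], x$signed_high[inner - 1])
})
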