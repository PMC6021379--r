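test_that("the arcsinh transform has the expected values and monotonicity", {
  expect_equal(transform_betas(0), 0)
  expect_equal(transform_betas(1), log(1 + sqrt(2)))
  x <- sort(rnorm(50, sd = 5))
  expect_true(all(diff(transform_betas(x)) > 0))
  expect_equal(transform_betas(-x), -transform_betas(x))
  tb <- transform_betas(tibble::tibble(beta = c(0, 1)))
  expect_equal(tb$beta, c(0, log(1 + sqrt(2))))
})

test_that("encoding fits recover generating weights under noise", {
  co <- make_unequal_cohort(n = 4, seed = 81)
  spec <- encoding_spec("roi", c(signed_high = 0.4, signed_low = 0.2),
                        noise_sd = 1)
  b <- generate_roi_betas(co, spec, seed = 2)
  fits <- fit_encoding_model(b, co, c("signed_high", "signed_low"),
                             transform = FALSE)
  est <- tidy(fits)
  # every estimate within a gross-error bound, and no group-level bias
  for (tm in c("signed_high", "signed_low")) {
    truth <- c(signed_high = 0.4, signed_low = 0.2)[[tm]]
    sub <- est[est$term == tm, ]
    expect_true(all(abs(sub$estimate - truth) < 4 * sub$std.error))
    expect_lt(abs(mean(sub$estimate - truth)) /
                (sd(sub$estimate) / sqrt(nrow(sub))), 3)
  }
  # a variable the generator never used is null
  fits2 <- fit_encoding_model(b, co, c("signed_high", "signed_low",
                                       "unsigned_low"), transform = FALSE)
  e2 <- tidy(fits2)
  expect_true(all(abs(e2$estimate[e2$term == "unsigned_low"]) <
                    4 * e2$std.error[e2$term == "unsigned_low"]))
})

test_that("a constant offset is absorbed by the block intercepts", {
  co <- make_unequal_cohort(n = 1, seed = 82)
  spec <- encoding_spec("roi", c(signed_high = 0.3), noise_sd = 0.5)
  b <- generate_roi_betas(co, spec, seed = 3)
  f1 <- tidy(fit_encoding_model(b, co, "signed_high", transform = FALSE))
  b2 <- dplyr::mutate(b, beta = beta + 7)
  f2 <- tidy(fit_encoding_model(b2, co, "signed_high", transform = FALSE))
  expect_equal(f1$estimate[f1$term == "signed_high"],
               f2$estimate[f2$term == "signed_high"], tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  co <- dplyr::filter(make_unequal_cohort(n = 1, seed = 83), !.data$missed)
  b <- generate_roi_betas(co, encoding_spec("roi", c(signed_high = 1)),
                          seed = 1)
  # no missed trials left, so the requested miss indicator is all-zero
  expect_error(fit_encoding_model(b, co, c("signed_high", "miss")),
               "collinear.*miss")
})

test_that("the weight-ratio test tracks its generator", {
  co <- make_unequal_cohort(n = 10, seed = 84)
  # vmPFC-like generator: ratio 2, test should not reject
  b <- generate_roi_betas(co, encoding_presets()$vmpfc, seed = 5)
  fits <- fit_encoding_model(b, co, c("signed_high", "signed_low"))
  rt <- attribute_weight_ratio(fits, "vmpfc")
  expect_lt(abs(rt$mean_ratio - 2), 0.5)
  # dACC-like generator: 4:1 negative weights; the test rejects ratio 2
  bd <- generate_roi_betas(co, encoding_presets()$dacc, seed = 6)
  fd <- fit_encoding_model(bd, co, c("signed_high", "signed_low"))
  rd <- attribute_weight_ratio(fd, "dacc")
  expect_lt(rd$p.value, 0.05)
  expect_gt(rd$mean_ratio, 2.5)
  # the two regions differ in a paired comparison
  both <- fit_encoding_model(dplyr::bind_rows(b, bd), co,
                             c("signed_high", "signed_low"))
  pr <- paired_ratio_test(both, "dacc", "vmpfc")
  expect_lt(pr$p.value, 0.05)
})

test_that("the stability floor excludes near-zero denominators", {
  tbl <- tibble::tibble(
    participant = rep(1:4, each = 2),
    region = "r",
    term = rep(c("signed_high", "signed_low"), 4),
    estimate = c(2, 1, 2, 1, 2, 1e-6, 2, 1),
    std.error = 0.1, statistic = 1, p.value = 0.5
  )
  fits <- structure(list(coefficients = tbl,
                         variables = c("signed_high", "signed_low")),
                    class = "encoding_fits")
  rt <- attribute_weight_ratio(fits, "r", floor = 0.1)
  expect_equal(rt$n_excluded, 1)
  expect_equal(rt$n, 3)
  expect_equal(rt$mean_ratio, 2)
})

test_that("rostrocaudal contrasts recover the generating dissociation", {
  co <- make_unequal_cohort(n = 8, seed = 85)
  pres <- encoding_presets()
  b <- purrr::map_dfr(pres[c("dacc_caudal1", "dacc_caudal2",
                             "dacc_rostral1", "dacc_rostral2")],
                      generate_roi_betas, records = co, seed = 7)
  fits <- fit_encoding_model(b, co, c("unsigned_high", "unsigned_low"))
  res <- rostrocaudal_interaction(
    fits, rostral = c("dacc_rostral1", "dacc_rostral2"),
    caudal = c("dacc_caudal1", "dacc_caudal2"))
  low <- res[res$contrast == "low_rostral_minus_caudal", ]
  high <- res[res$contrast == "high_rostral_minus_caudal", ]
  inter <- res[res$contrast == "interaction", ]
  expect_gt(low$mean, 0)
  expect_lt(low$p.value, 0.05)
  expect_gt(high$mean, 0)   # caudal more negative than rostral
  expect_lt(high$p.value, 0.05)
  expect_lt(inter$p.value, 0.05)
  # swapping the group labels flips the contrast signs
  swapped <- rostrocaudal_interaction(
    fits, rostral = c("dacc_caudal1", "dacc_caudal2"),
    caudal = c("dacc_rostral1", "dacc_rostral2"))
  expect_equal(swapped$mean, -res$mean)
  # identical encodings in every ROI: null interaction
  b0 <- purrr::map_dfr(c("r1", "r2", "c1", "c2"), function(nm) {
    generate_roi_betas(co, encoding_spec(nm, c(unsigned_high = -0.25)),
                       seed = 8)
  })
  f0 <- fit_encoding_model(b0, co, c("unsigned_high", "unsigned_low"))
  res0 <- rostrocaudal_interaction(f0, rostral = c("r1", "r2"),
                                   caudal = c("c1", "c2"))
  expect_true(all(res0$p.value > 0.05))
  expect_error(rostrocaudal_interaction(f0, rostral = "absent",
                                        caudal = "c1"), "ROI group")
})

test_that("cross-participant coupling detects a shared attention factor", {
  # participants vary in attention; the region's encoding weight is
  # proportional to each participant's attention scale
  set.seed(101)
  co <- simulate_cohort(12, agent_config(), attn_sd = 0.35, seed = 91)
  co <- dplyr::filter(co, .data$epoch > 1)
  b <- purrr::map_dfr(split(co, co$participant), function(rec) {
    w <- -0.4 * rec$attn_scale_high[1]
    generate_roi_betas(rec, encoding_spec(
      "dacc", c(signed_high = w), noise_sd = 1), seed = 92)
  })
  nf <- fit_encoding_model(b, co, c("signed_high", "signed_low"))
  bf <- cohort_fits(co, fit_choice_model, frame = "reward")
  cp <- neural_behavior_coupling(nf, bf, "dacc")
  slope <- cp[cp$term == "neural", ]
  expect_lt(slope$estimate, 0)   # stronger (more negative) encoding with
  expect_lt(slope$p.value, 0.05) # higher behavioral sensitivity
  # independent generators: null slope
  b0 <- generate_roi_betas(co, encoding_spec("dacc", c(congruent = 0.2),
                                             noise_sd = 1), seed = 93)
  nf0 <- fit_encoding_model(b0, co, c("signed_high", "signed_low"))
  cp0 <- neural_behavior_coupling(nf0, bf, "dacc")
  expect_gt(cp0$p.value[cp0$term == "neural"], 0.05)
})

test_that("rostral activity gating is recovered as a choice interaction", {
  # the agent's low-reward attention fluctuates trialwise; the rostral
  # series loads on that gain, so high activity predicts following a
  # high-coherence low-reward attribute
  co <- simulate_cohort(10, agent_config(gain_sd = 0.8), seed = 94)
  co <- dplyr::filter(co, .data$epoch > 1)
  b <- generate_roi_betas(
    co, encoding_spec("rostral", c(unsigned_low = 0.25, attn_gain_low = 2),
                      noise_sd = 0.5), seed = 95)
  ci <- choice_interaction_model(co, b)
  inter <- ci$group[ci$group$term == "activity:unsigned_low", ]
  expect_gt(inter$mean, 0)
  expect_lt(inter$p.value, 0.05)
  # activity independent of behavior: null interaction, and a permutation
  # oracle on one participant confirms the observed statistic is typical
  b0 <- generate_roi_betas(
    co, encoding_spec("rostral", c(unsigned_low = 0.25), noise_sd = 0.5),
    seed = 96)
  ci0 <- choice_interaction_model(co, b0)
  expect_gt(ci0$group$p.value[ci0$group$term == "activity:unsigned_low"],
            0.05)
  one <- dplyr::filter(co, .data$participant == 1, !.data$missed)
  bone <- dplyr::semi_join(dplyr::filter(b0, .data$participant == 1),
                           one, by = "trial")
  rec <- evcddm:::reward_frame(one)
  rec$activity <- as.numeric(scale(asinh(bone$beta[match(rec$trial, bone$trial)])))
  rec$unsigned_low <- rec$low_level
  rec$correct_low <- as.integer(rec$choice == rec$low_correct)
  obs <- coef(glm(correct_low ~ activity * unsigned_low, binomial(),
                  data = rec))[["activity:unsigned_low"]]
  set.seed(97)
  perm <- replicate(1000, {
    rec$activity <- rec$activity[sample(nrow(rec))]
    coef(glm(correct_low ~ activity * unsigned_low, binomial(),
             data = rec))[["activity:unsigned_low"]]
  })
  p_perm <- mean(abs(perm) >= abs(obs))
  expect_gt(p_perm, 0.05)
})
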