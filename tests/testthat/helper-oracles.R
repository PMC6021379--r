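# Independent oracles used across the suite.  Written from first
# principles so they do not share code paths with the package internals.

# Upper-boundary absorption probability for symmetric bounds +/-a, start 0.
oracle_p_upper <- function(v, a = 0.45, sigma = 0.5) {
  ifelse(abs(v) < 1e-12, 0.5, 1 / (1 + exp(-2 * v * a / sigma^2)))
}

# Unconditional mean first-passage time, same geometry.
oracle_mdt <- function(v, a = 0.45, sigma = 0.5) {
  ifelse(abs(v) < 1e-12, a^2 / sigma^2, (a / v) * tanh(a * v / sigma^2))
}

# Population coefficients of the choice logistic regression: the estimand
# of glm(choice ~ signed_high + signed_low) for an agent with attention
# (a_high, a_low), computed from exact cell probabilities on the balanced
# 64-cell design (4 x 4 levels x relative sign x absolute sign), with the
# lapse mixture included.  Deadline censoring is ignored (miss rates at
# the default parameters are < 2%).
oracle_choice_coefs <- function(a_high, a_low, lapse = 0.02,
                                mags = c(0.3, 0.53, 0.77, 1.0),
                                a = 0.45, sigma = 0.5) {
  cells <- expand.grid(h = 1:4, l = 1:4, sh = c(-1, 1), sl = c(-1, 1))
  cells$s_high <- cells$sh * cells$h
  cells$s_low <- cells$sl * cells$l
  v <- a_high * cells$sh * mags[cells$h] + a_low * cells$sl * mags[cells$l]
  p <- lapse / 2 + (1 - lapse) * oracle_p_upper(v, a, sigma)
  fit <- suppressWarnings(
    glm(p ~ s_high + s_low, family = binomial(),
        weights = rep(1000, nrow(cells)), data = cells))
  coef(fit)[c("s_high", "s_low")]
}

# Brute-force EVC for a single policy: explicit per-trial loop with plain
# formulas (no vectorization, no shared helpers).
oracle_evc <- function(am, ac, reward_m, reward_c, k,
                       mags = c(0.3, 0.53, 0.77, 1.0),
                       a = 0.45, sigma = 0.5, t0 = 0.2) {
  total <- 0
  n <- 0
  for (h in 1:4) for (l in 1:4) for (cong in c(TRUE, FALSE)) {
    v <- am * mags[h] + (if (cong) 1 else -1) * ac * mags[l]
    p_m <- oracle_p_upper(v, a, sigma)
    p_c <- if (cong) p_m else 1 - p_m
    ev <- p_m * reward_m + p_c * reward_c
    rt <- oracle_mdt(v, a, sigma) + t0
    total <- total + ev / rt
    n <- n + 1
  }
  total / n - (exp(k * am) + exp(k * ac))
}

# Small standard cohort fixtures (built once per test run).
make_unequal_cohort <- function(n = 6, seed = 42, agent = agent_config(),
                                attn_sd = 0.1) {
  co <- simulate_cohort(n, agent, attn_sd = attn_sd, seed = seed)
  dplyr::filter(co, .data$epoch > 1)
}
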