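test_that("lasso recovers strong true predictors and respects the 1-SE rule", {
  hits <- vapply(1:10, function(s) {
    beh <- small_behavior(seed = 300 + s, n_sessions = 2, trials = 200,
                          agent = agent_params(trial_drift_sd = 0,
                                               session_drift_sd = 0))
    X <- build_regressors(beh$trials)
    # bids built from 3 known columns plus noise, independent of the rest
    set.seed(s)
    y <- 0.4 * X$reward_value + 0.3 * X$starting_bid +
      0.3 * X$competing_bid_same_lag1 + rnorm(nrow(X), 0, 0.05)
    sel <- lasso_select(X, y = y, seed = s)
    expect_gte(sel$lambda_1se, sel$lambda_min)
    all(c("reward_value", "starting_bid", "competing_bid_same_lag1") %in%
          sel$selected)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("lasso selects nothing when the response is pure noise", {
  empty <- vapply(1:10, function(s) {
    beh <- small_behavior(seed = 400 + s, n_sessions = 2, trials = 200)
    X <- build_regressors(beh$trials)
    set.seed(s)
    y <- rnorm(nrow(X))
    length(lasso_select(X, y = y, seed = s)$selected) == 0L
  }, TRUE)
  expect_gt(mean(empty), 0.5)
})

test_that("mixed models have the specified fixed/random structure", {
  beh <- small_behavior(seed = 17, n_sessions = 3, trials = 150)
  m1 <- suppressMessages(fit_mixed_model(beh$trials, 1))
  m2 <- suppressMessages(fit_mixed_model(beh$trials, 2))
  m3 <- suppressMessages(fit_mixed_model(beh$trials, 3))
  expect_true("RewardMagnitude" %in% m1$fixed$term)
  expect_false("RewardMagnitude" %in% m2$fixed$term)
  expect_setequal(
    setdiff(m3$fixed$term, "(Intercept)"),
    c("StartingBid", "TotalLiquid", "PreviousCompetingBid",
      "PreviousWinStreak", "PreviousLoseStreak"))
  expect_true(all(c("RewardMagnitude", "PreviousResult") %in%
                    names(lme4::ranef(m3$fit))))
  expect_error(fit_mixed_model(beh$trials, 4), "model_id")
})

test_that("mixed model recovers the sign of an injected satiety effect", {
  ag <- agent_params(w_total_liquid = 0.3, trial_drift_sd = 0.01,
                     session_drift_sd = 0.02, bid_noise_sd = 0.05)
  cfg <- monkey_v_config(n_sessions = 10, trials_per_session = 500,
                         agent = ag)
  beh <- simulate_behavior(cfg, seed = 55)
  m2 <- suppressMessages(fit_mixed_model(beh$trials, 2))
  row <- m2$fixed[m2$fixed$term == "TotalLiquid", ]
  expect_gt(row$estimate, 0)
  expect_gt(row$ci_lo, 0)  # CI excludes zero
})

test_that("rank-order check behaves on ordered, shuffled and default bids", {
  beh <- small_behavior(seed = 23, agent = deterministic_agent())
  ro <- rank_order_check(beh$trials)
  expect_equal(ro$pooled$rho, 1)
  # shuffling bids across magnitudes kills the correlation
  rhos <- vapply(1:30, function(s) {
    tr <- beh$trials
    set.seed(s)
    tr$bid <- sample(tr$bid)
    rank_order_check(tr, per_session = FALSE)$pooled$rho
  }, 0)
  expect_lt(median(abs(rhos)), 0.1)
  # default generator: sessions overwhelmingly significant
  beh2 <- small_behavior(seed = 24, n_sessions = 6, trials = 150)
  expect_gte(rank_order_check(beh2$trials)$frac_significant, 0.9)
})

test_that("bid coherence is perfect under shared drift with no noise", {
  ag <- agent_params(trial_drift_sd = 0.03, session_drift_sd = 0,
                     bid_noise_sd = 0, w_starting_bid = 0, w_total_liquid = 0,
                     w_prev_computer_bid = 0, w_prev_result = 0,
                     w_win_streak = 0, w_lose_streak = 0, fail_prob = 0,
                     base_values = c(0.3, 0.5, 0.7))
  beh <- small_behavior(seed = 61, n_sessions = 2, trials = 120, agent = ag)
  co <- bid_coherence(beh$trials)
  # identical latent path, monotone mapping: interpolation (each magnitude is
  # sampled on its own trials) is the only loss, so rho is high but below 1
  expect_true(all(co$within$median_rho > 0.8))
})

test_that("coherence is near zero for independent per-magnitude values", {
  meds <- vapply(1:15, function(s) {
    beh <- simulate_behavior(study_scenario("independent", n_sessions = 2),
                             seed = 500 + s)
    co <- suppressMessages(bid_coherence(beh$trials))
    median(co$within$median_rho)
  }, 0)
  expect_lt(abs(median(meds)), 0.1)
})

test_that("coherence is invariant to strictly monotone bid transforms", {
  beh <- small_behavior(seed = 71, n_sessions = 1, trials = 120)
  co1 <- bid_coherence(beh$trials)
  tr <- beh$trials
  tr$bid <- tr$bid^3          # strictly monotone on [0, 1]
  co2 <- bid_coherence(tr)
  expect_equal(co1$within$median_rho, co2$within$median_rho, tolerance = 0.05)
})
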