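test_that("deterministic agent bids exactly its base values", {
  beh <- small_behavior(seed = 3, agent = deterministic_agent())
  tr <- beh$trials
  base <- c(low = 0.2, mid = 0.5, high = 0.8)
  expect_equal(tr$bid, unname(base[as.character(tr$magnitude_level)]))
})

test_that("simulation is fully reproducible under a fixed seed", {
  b1 <- small_behavior(seed = 11)
  b2 <- small_behavior(seed = 11)
  expect_identical(b1$trials, b2$trials)
  expect_identical(b1$latent, b2$latent)
  b3 <- small_behavior(seed = 12)
  expect_false(identical(b1$trials$bid, b3$trials$bid))
})

test_that("mean bids are ordered by reward magnitude across seeds", {
  ordered <- vapply(1:40, function(s) {
    beh <- small_behavior(seed = s, n_sessions = 2, trials = 120)
    ok <- beh$trials$result != "failed"
    mb <- tapply(beh$trials$bid[ok], beh$trials$magnitude_level[ok], mean)
    mb[["high"]] > mb[["mid"]] && mb[["mid"]] > mb[["low"]]
  }, TRUE)
  expect_gte(mean(ordered), 0.95)
})

test_that("auction outcomes inside simulated trials respect the payoff rules", {
  tr <- small_behavior(seed = 5)$trials
  ok <- tr[tr$result != "failed", ]
  win <- ok[ok$result == "win", ]
  expect_true(all(win$bid >= win$computer_bid))
  expect_equal(win$water_ml, 1.2 - win$computer_bid * 1.2)
  expect_equal(win$juice_ml, win$magnitude_ml)
  lose <- ok[ok$result == "lose", ]
  expect_true(all(lose$bid < lose$computer_bid))
  expect_true(all(lose$water_ml == 1.2 & lose$juice_ml == 0))
  # event times follow the task order, fractal 0.5 s after trial start
  expect_equal(tr$t_fractal - tr$t_trial_start, rep(0.5, nrow(tr)))
  tmat <- as.matrix(tr[, c("t_trial_start", "t_fractal", "t_bidspace",
                           "t_bid_stable", "t_reveal", "t_juice", "t_water")])
  expect_true(all(apply(tmat, 1, function(r) all(diff(r) > 0))))
})

test_that("history weights shape bids in the expected direction", {
  # strong previous-result effect recovered by regression on the trial table
  ag <- agent_params(w_prev_result = 0.1, trial_drift_sd = 0,
                     session_drift_sd = 0, bid_noise_sd = 0.03)
  beh <- small_behavior(seed = 21, n_sessions = 3, trials = 250, agent = ag)
  X <- build_regressors(beh$trials)
  fit <- lm(bid ~ prev_result_same_magnitude + reward_value, data = X)
  co <- summary(fit)$coefficients
  expect_gt(co["prev_result_same_magnitude", "Estimate"], 0)
  expect_lt(co["prev_result_same_magnitude", "Pr(>|t|)"], 0.05)
})

test_that("spike counts in the pre-event window match the baseline rate", {
  beh <- small_behavior(seed = 31, n_sessions = 1, trials = 200)
  nm <- neuron_model(baseline_rate = 6, coding_target = "none",
                     attentional = list(latency_ms = 90, duration_ms = 90,
                                        amplitude_hz = 0))
  r <- simulate_neuron(nm, beh$trials, seed = 32)
  pre <- windowed_response(r, list(start_ms = -500, end_ms = 0))
  se <- sd(pre) / sqrt(length(pre))
  expect_lt(abs(mean(pre) - 6), 3 * se)
  # whole raster is homogeneous Poisson at baseline: overall mean too
  allr <- windowed_response(r, list(start_ms = -500, end_ms = 1000))
  expect_lt(abs(mean(allr) - 6), 3 * sd(allr) / sqrt(length(allr)))
})

test_that("zero prediction error leaves the value window at baseline", {
  beh <- small_behavior(seed = 41, n_sessions = 1, trials = 150,
                        agent = deterministic_agent(c(0.3, 0.5, 0.7)))
  tr <- beh$trials[beh$trials$magnitude_level == "mid", ]
  nm <- neuron_model(baseline_rate = 5, coding_target = "bid")
  # every bid equals 0.5 = mean_prediction: no prediction error
  r <- simulate_neuron(nm, tr, mean_prediction = 0.5, seed = 42)
  val <- windowed_response(r, analysis_window(180, 340))
  se <- sd(val) / sqrt(length(val))
  expect_lt(abs(mean(val) - 5), 3 * se)
})

test_that("generate_dataset writes a deterministic, readable dataset", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  cfgs <- list(monkey_v_config(n_sessions = 1, trials_per_session = 60))
  generate_dataset(d1, cfgs, n_bid = 2, seed = 5)
  generate_dataset(d2, cfgs, n_bid = 2, seed = 5)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_true("manifest.json" %in% files)
  rep <- validate_inputs(file.path(d1, "trials_V.tsv"),
                         file.path(d1, grep("^raster", files, value = TRUE)))
  expect_true(rep$ok)
})
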