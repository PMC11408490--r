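test_that("dopamine classification applies the canonical screening criteria", {
  beh <- small_behavior(seed = 201, n_sessions = 1, trials = 100)
  # wide waveform, low baseline, strong event response -> dopamine
  r <- simulate_neuron(neuron_model(baseline_rate = 4,
                                    waveform_width_ms = 2.5,
                                    coding_target = "bid"),
                       beh$trials, seed = 1)
  expect_true(classify_dopamine(r)$is_dopamine)
  # narrow waveform excludes regardless of response
  expect_false(classify_dopamine(r, waveform_width_ms = 1.0)$is_dopamine)
  # high baseline excludes
  r2 <- simulate_neuron(neuron_model(baseline_rate = 25,
                                     coding_target = "bid"),
                        beh$trials, seed = 2)
  expect_false(classify_dopamine(r2)$is_dopamine)
  # unresponsive flat neuron excludes
  r3 <- simulate_neuron(neuron_model(baseline_rate = 5,
                                     coding_target = "none",
                                     attentional = list(latency_ms = 90,
                                                        duration_ms = 90,
                                                        amplitude_hz = 0)),
                        beh$trials, seed = 3)
  expect_false(classify_dopamine(r3)$is_dopamine)
  expect_warning(cl <- classify_dopamine(r, waveform_width_ms = NA),
                 "waveform")
  expect_false(cl$is_dopamine)
})

test_that("responsive dopamine-like populations classify as dopamine", {
  frac <- vapply(1:20, function(s) {
    beh <- small_behavior(seed = 600 + s, n_sessions = 1, trials = 100)
    pop <- simulate_population(beh, n_bid = 4, seed = 700 + s)
    mean(vapply(pop$rasters,
                function(r) classify_dopamine(r)$is_dopamine, TRUE))
  }, 0)
  expect_gte(mean(frac), 0.95)
})

test_that("value-window detection recovers the injected window", {
  # generator injects a 180-340 ms value component
  hits <- vapply(1:10, function(s) {
    beh <- small_behavior(seed = 800 + s, n_sessions = 2, trials = 150)
    pop <- simulate_population(beh, n_bid = 12, seed = 900 + s)
    det <- detect_value_window(population_traces(pop, "low"),
                               population_traces(pop, "high"))
    det$status == "ok" &&
      abs(det$start_ms - 180) <= 20 && abs(det$end_ms - 340) <= 20
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("window detection fails explicitly on degenerate populations", {
  beh <- small_behavior(seed = 211, n_sessions = 1, trials = 120)
  # flat population: never leaves baseline
  flat <- neuron_model(baseline_rate = 5, coding_target = "none",
                       attentional = list(latency_ms = 90, duration_ms = 90,
                                          amplitude_hz = 0))
  pop <- simulate_population(beh, n_bid = 0, n_none = 12, model = flat,
                             seed = 212)
  det <- detect_value_window(population_traces(pop, "low"),
                             population_traces(pop, "high"))
  expect_false(det$status == "ok" && det$end_ms - det$start_ms > 40)
  # attentional-only population: start found, but no sustained value signal
  att <- neuron_model(baseline_rate = 5, coding_target = "none")
  pop2 <- simulate_population(beh, n_bid = 0, n_none = 12, model = att,
                              seed = 213)
  det2 <- detect_value_window(population_traces(pop2, "low"),
                              population_traces(pop2, "high"))
  expect_true(det2$status != "ok" ||
                det2$end_ms - det2$start_ms <= 20)
})

test_that("windowed responses and z-normalization follow their definitions", {
  beh <- small_behavior(seed = 221, n_sessions = 1, trials = 60)
  r <- simulate_neuron(neuron_model(), beh$trials, seed = 5)
  # 9 spikes in a 180 ms window = 50 Hz: plant the counts directly
  r$counts[1, ] <- 0L
  r$counts[1, which(r$times_ms == 200) + seq_len(9)] <- 1L
  expect_equal(windowed_response(r, list(start_ms = 180, end_ms = 360))[1], 50)
  # z-scores are mean 0, sd 1 per neuron
  rt <- response_table(list(r), analysis_window(180, 340))
  expect_equal(mean(rt$z), 0, tolerance = 1e-12)
  expect_equal(sd(rt$z), 1, tolerance = 1e-12)
  # constant responses cannot be z-scored: exclusion path
  rc <- r
  rc$counts[] <- 1L
  expect_warning(rt2 <- response_table(list(rc), analysis_window(180, 340)),
                 "zero response variance")
  expect_null(rt2)
})

test_that("bid regression matches its closed-form cases and bins consistently", {
  bids <- seq(0.02, 0.98, length.out = 50)
  fit <- suppressWarnings(bid_regression(2 * bids, bids))  # exact fit
  expect_equal(fit$beta1, 2, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  # binned slope agrees in sign with unbinned on monotone data
  set.seed(9)
  resp <- 1.5 * bids + rnorm(50, 0, 0.3)
  fb <- bid_regression(resp, bids, n_bins = 10)
  expect_equal(sign(fb$beta1), sign(bid_regression(resp, bids)$beta1))
  expect_error(bid_regression(resp, rep(0.5, 50)), "variance")
})

test_that("bid-coding neurons yield significant positive slopes at 200 trials", {
  power <- vapply(1:20, function(s) {
    beh <- small_behavior(seed = 1000 + s, n_sessions = 1, trials = 200)
    r <- simulate_neuron(neuron_model(coding_target = "bid"), beh$trials,
                         seed = 1100 + s)
    rt <- response_table(list(r), analysis_window(180, 340))
    fit <- bid_regression(rt$z, rt$bid)
    fit$p < 0.05 && fit$beta1 > 0
  }, TRUE)
  expect_gte(mean(power), 0.9)
})

test_that("bid-encoding selection excludes negative-gain neurons", {
  beh <- small_behavior(seed = 231, n_sessions = 1, trials = 200)
  neg <- neuron_model(baseline_rate = 10, coding_target = "bid")
  neg$value_component$gain_hz <- -25
  r <- simulate_neuron(neg, beh$trials, seed = 6)
  rt <- response_table(list(r), analysis_window(180, 340))
  sel <- select_bid_encoding(rt)
  expect_lt(sel$beta1, 0)
  expect_false(sel$selected)
})

test_that("bid binning schemes produce the documented partitions", {
  set.seed(3)
  bids <- runif(2000)
  lab <- bin_bids(bids, "tenths")
  expect_true(all(abs(table(lab) / 2000 - 0.1) < 0.03))
  expect_equal(bin_bids(0.95, "tenths"), 10L)
  expect_equal(bin_bids(1.0, "tenths"), 10L)
  # skew-corrected terciles hold equal counts within each magnitude
  skewed <- c(rbeta(300, 5, 1), rbeta(300, 1, 5))
  mag <- rep(c("high", "low"), each = 300)
  lab3 <- bin_bids(skewed, "terciles_skew_corrected", magnitude_level = mag)
  for (k in c("low", "high"))
    expect_true(all(abs(table(lab3[mag == k]) - 100) <= 1))
  expect_message(bin_bids(c(0.05, 0.95), "quintiles"), "empty")
})

test_that("matched-bid comparison discriminates bid from magnitude coding", {
  # identical responses in both groups: difference 0, p = 1
  beh <- small_behavior(seed = 241, n_sessions = 1, trials = 200,
                        agent = agent_params(base_values = c(0.45, 0.5,
                                                             0.55)))
  r <- simulate_neuron(neuron_model(coding_target = "none"), beh$trials,
                       seed = 7)
  rt <- response_table(list(r), analysis_window(180, 340))
  rt$z <- 0.5  # constant: matched differences all zero
  mb <- suppressMessages(matched_bid_comparison(rt))
  run <- !is.na(mb$p)
  expect_true(any(run))
  expect_true(all(mb$p[run] == 1))
  expect_true(all(mb$mean_diff[run] == 0))

  # magnitude-coding population in the overlap scenario: low-vs-high detected
  beh2 <- simulate_behavior(study_scenario("overlap"), seed = 243)
  popm <- simulate_population(beh2, n_bid = 0, n_magnitude = 10, seed = 244)
  rtm <- response_table(popm, analysis_window(180, 340))
  mbm <- suppressMessages(matched_bid_comparison(rtm))
  lvh <- mbm[mbm$pair == "low-vs-high", ]
  expect_gte(lvh$n_matches, 30)
  expect_lt(lvh$p, 0.05)
  expect_gt(lvh$mean_diff, 0)
})

test_that("movement controls stay at chance unless responses follow movement", {
  beh <- small_behavior(seed = 251, n_sessions = 2, trials = 150)
  pop <- simulate_population(beh, n_bid = 10, seed = 252)
  rt <- response_table(pop, analysis_window(180, 340))
  mv <- movement_control_regressions(rt)
  expect_true(all(!mv$exceeds_chance))
  # positive control: responses built from velocity
  rt2 <- rt
  set.seed(1)
  rt2$z <- 0.8 * rt2$velocity + rnorm(nrow(rt2), 0, 0.5)
  mv2 <- movement_control_regressions(rt2)
  expect_true(mv2$exceeds_chance[mv2$covariate == "velocity"])
})
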