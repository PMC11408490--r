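test_that("pseudo-population has the balanced shape and excludes sparse neurons", {
  rt <- linear_response_table(n_neurons = 6, n_trials = 200, noise_sd = 0.1)
  pp <- build_pseudopopulation(rt, seed = 1)
  expect_equal(dim(pp$x), c(6, 10, 10))
  expect_equal(length(pp$excluded), 0)
  # remove a neuron's top-tenth trials: it must be excluded by name
  rt2 <- rt[!(rt$neuron_id == "lin01" & rt$bid > 0.9), ]
  class(rt2) <- class(rt)
  expect_message(pp2 <- build_pseudopopulation(rt2, seed = 1), "lin01")
  expect_equal(length(pp2$neuron_ids), 5)
  # determinism: same seed, identical arrays
  pp3 <- build_pseudopopulation(rt, seed = 1)
  expect_identical(pp$x, pp3$x)
  expect_false(identical(pp$x, build_pseudopopulation(rt, seed = 2)$x))
})

test_that("a noiseless linear population decodes almost perfectly", {
  rt <- linear_response_table(n_neurons = 4, noise_sd = 0)
  pp <- build_pseudopopulation(rt, seed = 2)
  r2 <- svr_decode(pp, seed = 3)
  expect_gte(mean(r2), 0.99)
})

test_that("decoding is reproducible and improves with more coding neurons", {
  rt <- linear_response_table(n_neurons = 20, noise_sd = 1.2, seed = 4)
  pp <- build_pseudopopulation(rt, seed = 5)
  expect_identical(svr_decode(pp, seed = 6), svr_decode(pp, seed = 6))
  dc <- decoding_curve(pp, "random", n_neurons = c(1, 20),
                       n_iterations = 40, seed = 7)
  expect_gt(dc$curve$mean_r2[2], dc$curve$mean_r2[1])
  # single-iteration fixed-seed curve is exactly reproducible
  one <- decoding_curve(pp, "random", n_neurons = 5, n_iterations = 1,
                        seed = 8)
  two <- decoding_curve(pp, "random", n_neurons = 5, n_iterations = 1,
                        seed = 8)
  expect_identical(one$iterations, two$iterations)
})

test_that("shuffled control sits at chance and clamps to 0% accuracy", {
  rt <- linear_response_table(n_neurons = 10, noise_sd = 0.5, seed = 9)
  pp <- build_pseudopopulation(rt, seed = 10)
  sc <- shuffled_control(pp, ordering = "random", n_neurons = 10,
                         n_iterations = 60, seed = 11)
  expect_lt(abs(sc$curve$mean_r2), 0.1)
  expect_equal(sc$curve$accuracy_pct, decode_accuracy(sc$curve$mean_r2))
  expect_equal(decode_accuracy(-0.5), 0)
  expect_equal(decode_accuracy(0.6), 60)
  # shuffle of a shuffle: two independent shuffles are indistinguishable
  sc2 <- shuffled_control(pp, ordering = "random", n_neurons = 10,
                          n_iterations = 60, seed = 12)
  p <- wilcox.test(sc$iterations[1, ], sc2$iterations[1, ])$p.value
  expect_gt(p, 0.01)
})

test_that("real decoding beats its shuffled control on a coding population", {
  rt <- linear_response_table(n_neurons = 10, noise_sd = 0.8, seed = 13)
  pp <- build_pseudopopulation(rt, seed = 14)
  real <- decoding_curve(pp, "random", n_neurons = c(5, 10),
                         n_iterations = 40, seed = 15)
  shuf <- shuffled_control(pp, ordering = "random", n_neurons = c(5, 10),
                           n_iterations = 40, seed = 15)
  cmp <- compare_real_vs_shuffled(real, shuf)
  expect_true(all(cmp$p < 0.01))
})

test_that("neuron orderings bracket the random curve", {
  # heterogeneous population: strong and weak coders
  rt <- do.call(rbind, lapply(1:12, function(i) {
    d <- linear_response_table(n_neurons = 1,
                               noise_sd = if (i <= 4) 0.15 else 3,
                               seed = 20 + i)
    d$neuron_id <- sprintf("mix%02d", i)
    d
  }))
  class(rt) <- c("response_table", "data.frame")
  pp <- build_pseudopopulation(rt, seed = 30)
  ranking <- setNames(vapply(split(rt, rt$neuron_id), function(d)
    bid_regression(d$z, d$bid)$r2, 0), unique(rt$neuron_id))
  counts <- c(2, 4, 8)
  best <- decoding_curve(pp, "best_first", ranking, counts,
                         n_iterations = 25, seed = 31)
  worst <- decoding_curve(pp, "worst_first", ranking, counts,
                          n_iterations = 25, seed = 31)
  rand <- decoding_curve(pp, "random", n_neurons = counts,
                         n_iterations = 25, seed = 31)
  expect_true(all(best$curve$mean_r2 >= rand$curve$mean_r2 - 0.02))
  expect_true(all(rand$curve$mean_r2 >= worst$curve$mean_r2 - 0.02))
})

test_that("decoding is invariant to per-neuron affine rescaling of raw rates", {
  beh <- small_behavior(seed = 271, n_sessions = 1, trials = 800,
                        agent = study_scenario("decoding")$agent)
  pop <- simulate_population(beh, n_bid = 5, seed = 272)
  rt1 <- response_table(pop, analysis_window(180, 340))
  # an affine gain/offset change of each neuron's raw rates is absorbed by
  # the per-neuron z-scoring, so the decoder sees identical features
  rt2 <- rt1
  rt2$rate_hz <- 3.7 * rt2$rate_hz + 11
  rt2$z <- ave(rt2$rate_hz, rt2$neuron_id,
               FUN = function(x) (x - mean(x)) / sd(x))
  expect_equal(rt2$z, rt1$z, tolerance = 1e-10)
  pp1 <- build_pseudopopulation(rt1, seed = 273)
  pp2 <- build_pseudopopulation(rt2, seed = 273)
  expect_equal(svr_decode(pp1, seed = 274), svr_decode(pp2, seed = 274),
               tolerance = 1e-8)
})
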