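test_that("auction resolution follows the second-price payoff rules", {
  cfg <- auction_config()
  # tie wins: bid equal to the computer bid
  out <- resolve_auction(0.5, 0.5, magnitude = 1.0, cfg)
  expect_true(out$won)
  expect_equal(out$juice_delivered, 1.0)
  expect_equal(out$water_delivered, 1.2 - 0.5 * 1.2)
  # loss delivers the full budget and no juice
  out <- resolve_auction(0.0, 0.3, magnitude = 1.0, cfg)
  expect_false(out$won)
  expect_equal(out$water_delivered, 1.2)
  expect_equal(out$juice_delivered, 0)
  # winning at a high computer bid costs nearly the whole budget
  out <- resolve_auction(1.0, 0.99, magnitude = 1.0, cfg)
  expect_true(out$won)
  expect_equal(out$price_paid, 1.188)
  expect_equal(out$water_delivered, 0.012)
  # domain checks
  expect_error(resolve_auction(1.2, 0.5, 1.0, cfg), "\\[0, 1\\]")
  expect_error(resolve_auction(0.5, -0.1, 1.0, cfg), "\\[0, 1\\]")
})

test_that("expected payoff matches the analytic form and quadrature", {
  cfg <- auction_config()
  # never winning yields the full budget
  expect_equal(expected_payoff(0, 0.6, cfg), 1.2)
  # closed form against numerical quadrature of the uniform-opponent payoff
  for (v in c(0.2, 0.6, 1.0)) {
    for (b in c(0.1, 0.4, 0.5, 0.9)) {
      quad <- integrate(function(c_ml) {
        ifelse(b * cfg$budget >= c_ml, v + cfg$budget - c_ml, cfg$budget) /
          cfg$budget
      }, 0, cfg$budget, rel.tol = 1e-10)$value
      expect_equal(expected_payoff(b, v, cfg), quad, tolerance = 1e-8)
    }
  }
})

test_that("truthful bidding maximizes expected payoff (incentive compatibility)", {
  cfg <- auction_config()
  chk <- incentive_compatibility_check(seq(0.1, 1.1, by = 0.1), cfg)
  # grid argmax within one grid step of the analytic optimum
  expect_true(all(chk$argmax_abs_err <= 1e-3 + 1e-12))
  # optimum payoff equals budget + v^2/(2 budget) to 1e-6 relative error
  expect_true(all(chk$max_rel_err < 1e-6))
  # over- and underbidding strictly cost, beyond one grid step
  grid <- seq(0, 1, by = 1e-3)
  for (v in c(0.3, 0.6, 0.9)) {
    pay <- expected_payoff(grid, v, cfg)
    bstar <- optimal_bid(v, cfg)
    off <- abs(grid - bstar) > 1e-3
    expect_true(all(pay[off] < expected_payoff(bstar, v, cfg)))
  }
})

test_that("optimal bid equals value over budget, clamped to the bid space", {
  cfg <- auction_config()
  expect_equal(optimal_bid(0.6, cfg), 0.5)
  expect_equal(optimal_bid(1.5, cfg), 1.0)
  expect_error(optimal_bid(-0.2, cfg), "non-negative")
})

test_that("Monte-Carlo payoff agrees with the closed form within 3 SE", {
  cfg <- auction_config()
  for (v in c(0.3, 0.9)) {
    b <- optimal_bid(v, cfg)
    mc <- simulate_payoff(b, v, cfg, n = 1e5, seed = 7)
    closed <- cfg$budget + v^2 / (2 * cfg$budget)
    expect_lt(abs(mc$mean - closed), 3 * mc$se)
  }
})
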