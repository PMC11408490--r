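#' BDM auction configuration
#'
#' The Becker-DeGroot-Marschak (BDM) mechanism used here is a second-price
#' sealed-bid auction against a computer opponent whose bid is drawn uniformly
#' over the bid space. The bidder pays from a water budget that is refilled on
#' every trial; the bid expresses how much of that budget the bidder is willing
#' to forgo for the juice on offer.
#'
#' Bids are represented internally as fractions of the budget in `[0, 1]`;
#' conversion to ml happens only at I/O boundaries, which keeps the mechanism
#' free of unit-scaling bugs.
#'
#' @param budget water budget per trial in ml (default 1.2).
#' @return an object of class `auction_config`.
#' @examples
#' cfg <- auction_config()
#' resolve_auction(0.5, 0.3, magnitude = 1.0, cfg)
#' @export
auction_config <- function(budget = 1.2) {
  if (!is.numeric(budget) || length(budget) != 1L || !is.finite(budget) ||
      budget <= 0)
    stop_domain("`budget` must be a single positive number (ml)")
  structure(list(budget = budget), class = "auction_config")
}

#' @export
print.auction_config <- function(x, ...) {
  cat("BDM auction: budget", x$budget, "ml; computer bid ~ Uniform[0, budget]\n")
  invisible(x)
}

check_bid_fraction <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1))
    stop_domain("`", what, "` must lie in [0, 1] (fraction of budget)")
  x
}

#' Resolve one BDM auction trial
#'
#' The bidder wins when its bid equals or exceeds the computer bid (ties win).
#' On a win, the juice on offer is delivered and the water payout is the budget
#' minus the computer bid (second-price rule: the price paid is the opponent's
#' bid, not one's own). On a loss, the full water budget is delivered and no
#' juice.
#'
#' @param bid bidder's bid as a fraction of budget in `[0, 1]`.
#' @param computer_bid computer opponent's bid, same units.
#' @param magnitude juice volume on offer (ml).
#' @param cfg an [auction_config()].
#' @return an object of class `auction_outcome`: list with `won`,
#'   `juice_delivered` (ml), `water_delivered` (ml) and `price_paid` (ml).
#' @export
resolve_auction <- function(bid, computer_bid, magnitude,
                            cfg = auction_config()) {
  check_bid_fraction(bid, "bid")
  check_bid_fraction(computer_bid, "computer_bid")
  stopifnot(is.numeric(magnitude), magnitude >= 0)
  won <- bid >= computer_bid
  price <- ifelse(won, computer_bid * cfg$budget, 0)
  structure(list(
    won = won,
    juice_delivered = ifelse(won, magnitude, 0),
    water_delivered = cfg$budget - price,
    price_paid = price
  ), class = "auction_outcome")
}

#' Expected total payoff of a BDM bid
#'
#' For a bidder who values the juice at `true_value` (in ml-water-equivalent
#' units) and faces a uniform opponent on `[0, budget]`, the expected payoff of
#' bidding `b` (fraction of budget, i.e. `bB = b * budget` ml) is
#' \deqn{E[payoff] = B + (v \cdot bB - bB^2/2) / B}
#' obtained by integrating the win branch `v + B - c` over opponent bids
#' `c < bB` and the loss branch `B` over `c > bB`. The maximum is at
#' `bB = v`, i.e. truthful bidding, with value `B + v^2 / (2B)` — the
#' incentive-compatibility property of the mechanism.
#'
#' @param bid bid as fraction of budget; vectorized.
#' @param true_value subjective value of the juice in ml-water-equivalent.
#' @param cfg an [auction_config()].
#' @return expected payoff in ml-water-equivalent units.
#' @seealso [optimal_bid()], [incentive_compatibility_check()]
#' @export
expected_payoff <- function(bid, true_value, cfg = auction_config()) {
  check_bid_fraction(bid, "bid")
  if (!is.numeric(true_value) || any(true_value < 0))
    stop_domain("`true_value` must be non-negative")
  B <- cfg$budget
  bB <- bid * B
  B + (true_value * bB - bB^2 / 2) / B
}

#' Optimal BDM bid for a given subjective value
#'
#' Under the uniform-opponent second-price rules the payoff-maximizing bid
#' equals the subjective value itself; values above the budget clamp to the
#' top of the bid space.
#'
#' @param true_value subjective value in ml-water-equivalent (non-negative).
#' @param cfg an [auction_config()].
#' @return optimal bid as a fraction of budget.
#' @export
optimal_bid <- function(true_value, cfg = auction_config()) {
  if (!is.numeric(true_value) || anyNA(true_value) || any(true_value < 0))
    stop_domain("`true_value` must be non-negative")
  pmin(true_value / cfg$budget, 1)
}

#' Numeric incentive-compatibility check
#'
#' Grid-searches the expected payoff over bids (step `grid_step` in bid-space
#' fractions) for each value in `values` and compares the numeric argmax and
#' maximum with the analytic optimum `b* = v / budget` and
#' `E*[payoff] = budget + v^2 / (2 budget)`.
#'
#' @param values subjective values (ml-water-equivalent) to check.
#' @param cfg an [auction_config()].
#' @param grid_step bid grid step (default 1e-3).
#' @return data.frame with one row per value: numeric argmax, analytic optimum,
#'   their absolute difference, numeric and analytic maxima and the relative
#'   error between them.
#' @export
incentive_compatibility_check <- function(values, cfg = auction_config(),
                                          grid_step = 1e-3) {
  grid <- seq(0, 1, by = grid_step)
  out <- lapply(values, function(v) {
    payoff <- expected_payoff(grid, v, cfg)
    i <- which.max(payoff)
    analytic_max <- cfg$budget + v^2 / (2 * cfg$budget)
    data.frame(
      value = v,
      argmax_bid = grid[i],
      optimal_bid = optimal_bid(v, cfg),
      argmax_abs_err = abs(grid[i] - optimal_bid(v, cfg)),
      max_payoff = payoff[i],
      analytic_max = analytic_max,
      max_rel_err = abs(payoff[i] - analytic_max) / analytic_max
    )
  })
  do.call(rbind, out)
}

#' Monte-Carlo estimate of the expected BDM payoff
#'
#' Simulates `n` auctions against uniform computer bids and averages the total
#' payoff (juice value plus water delivered). Used as an independent numeric
#' check of [expected_payoff()].
#'
#' @param bid bid as fraction of budget.
#' @param true_value subjective value (ml-water-equivalent).
#' @param cfg an [auction_config()].
#' @param n number of simulated auctions.
#' @param seed RNG seed.
#' @return list with `mean`, `se` and `n`.
#' @export
simulate_payoff <- function(bid, true_value, cfg = auction_config(),
                            n = 1e5, seed = 1L) {
  check_bid_fraction(bid, "bid")
  with_seed(seed, {
    comp <- runif(n)
    won <- bid >= comp
    payoff <- ifelse(won,
                     true_value + cfg$budget - comp * cfg$budget,
                     cfg$budget)
    list(mean = mean(payoff), se = stats::sd(payoff) / sqrt(n), n = n)
  })
}
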