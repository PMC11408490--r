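#' Bidding-agent parameters
#'
#' The synthetic bidder carries a latent subjective-value process shared across
#' reward magnitudes: a per-session offset plus a within-session AR(1) scalar,
#' both in bid-space units. On each trial the bid is the magnitude's base value
#' plus the latent value plus weighted outcome-history terms plus independent
#' noise, clipped to `[0, 1]`. The shared latent process is what makes bids for
#' different magnitudes co-fluctuate (bid coherence); setting
#' `shared_drift = FALSE` gives each magnitude its own independent latent
#' process, which removes coherence while leaving marginal bid distributions
#' unchanged.
#'
#' History terms (all computed over non-failed trials): the starting cursor
#' position and previous cumulative liquid are centered at 0.5 before
#' weighting; the previous same-magnitude computer bid is centered at its
#' uniform mean 0.5; the previous same-magnitude result is coded +1 (win) /
#' -1 (lose) / 0 (none yet); win/lose streaks are raw counts of consecutive
#' same-magnitude wins/losses.
#'
#' @param base_values latent value per magnitude level (bid-space units,
#'   increasing). The defaults spread the three levels over the bid space, as
#'   in a task whose reward range is calibrated so the full bid range is used.
#' @param ar_phi AR(1) coefficient of the within-session latent value.
#' @param trial_drift_sd innovation sd of the AR(1) process.
#' @param session_drift_sd sd of the per-session latent offset.
#' @param bid_noise_sd sd of independent per-trial bid noise.
#' @param shared_drift logical; share one latent process across magnitudes?
#' @param w_starting_bid,w_total_liquid,w_prev_computer_bid,w_prev_result,w_win_streak,w_lose_streak
#'   history-effect weights (bid-space units per unit regressor).
#' @param fail_prob probability a trial fails (no stable bid); failed trials
#'   deliver nothing and are excluded from analyses.
#' @return object of class `agent_params`.
#' @export
agent_params <- function(base_values = c(0.2, 0.5, 0.8),
                         ar_phi = 0.97,
                         trial_drift_sd = 0.025,
                         session_drift_sd = 0.10,
                         bid_noise_sd = 0.05,
                         shared_drift = TRUE,
                         w_starting_bid = -0.05,
                         w_total_liquid = 0.10,
                         w_prev_computer_bid = 0.05,
                         w_prev_result = 0.03,
                         w_win_streak = 0.02,
                         w_lose_streak = -0.01,
                         fail_prob = 0.02) {
  stopifnot(length(base_values) == 3L, all(diff(base_values) > 0),
            ar_phi >= 0, ar_phi < 1, trial_drift_sd >= 0,
            session_drift_sd >= 0, bid_noise_sd >= 0,
            fail_prob >= 0, fail_prob < 1)
  structure(as.list(environment()), class = "agent_params")
}

#' Subject configuration for synthetic sessions
#'
#' @param name subject label.
#' @param magnitudes three strictly increasing juice volumes (ml).
#' @param budget water budget per trial (ml).
#' @param n_sessions number of sessions to simulate.
#' @param trials_per_session trials per session.
#' @param agent an [agent_params()] object.
#' @return object of class `subject_config`.
#' @examples
#' cfg <- monkey_v_config(n_sessions = 2, trials_per_session = 50)
#' beh <- simulate_behavior(cfg, seed = 1)
#' head(beh$trials)
#' @export
subject_config <- function(name,
                           magnitudes,
                           budget = 1.2,
                           n_sessions = 10L,
                           trials_per_session = 200L,
                           agent = agent_params()) {
  stopifnot(length(magnitudes) == 3L, all(diff(magnitudes) > 0),
            all(magnitudes > 0), n_sessions >= 1, trials_per_session >= 1,
            inherits(agent, "agent_params"))
  structure(list(name = name, magnitudes = magnitudes, budget = budget,
                 n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 agent = agent),
            class = "subject_config")
}

#' @rdname subject_config
#' @param ... passed on to [subject_config()].
#' @export
monkey_v_config <- function(...) {
  subject_config(name = "V", magnitudes = c(0.3, 1.0, 1.7), ...)
}

#' @rdname subject_config
#' @export
monkey_u_config <- function(...) {
  subject_config(name = "U", magnitudes = c(0.2, 0.45, 0.7), ...)
}

MAG_LEVELS <- c("low", "mid", "high")

#' Named study scenarios for the synthetic generator
#'
#' Fixed generator conditions used by the package's analyses and checks, each
#' emulating a different aspect of the task's behavioral structure:
#'
#' * `"default"`: the standard conditions — three base values spread over the
#'   bid space, slow shared AR(1) value drift plus day-to-day offsets.
#' * `"decoding"`: long sessions (800 trials) with a faster-mixing,
#'   larger-amplitude shared value drift, so every neuron's session
#'   represents the full bid range and the 10-trials-per-bid-tenth balance
#'   requirement of the pseudo-population protocol is met.
#' * `"overlap"`: closely spaced base values (0.4/0.5/0.6), giving heavily
#'   overlapping bid distributions across magnitudes — the regime in which
#'   matched-bid comparisons across all three magnitude pairs have matches.
#' * `"coherent"`: shared value drift dominating the independent bid noise
#'   (drift sd well above noise sd), the signal-dominant condition for
#'   within-session bid-coherence checks.
#' * `"independent"`: no value drift at all — bids are base values plus
#'   independent per-trial noise, the null condition for bid-coherence
#'   calibration (a slowly drifting value process, even an independent one,
#'   produces spurious finite-sample rank correlations).
#'
#' @param name scenario name.
#' @param n_sessions,trials_per_session optional overrides.
#' @param ... passed to [monkey_v_config()].
#' @return a [subject_config()].
#' @export
study_scenario <- function(name = c("default", "decoding", "overlap",
                                    "coherent", "independent"),
                           n_sessions = NULL, trials_per_session = NULL,
                           ...) {
  name <- match.arg(name)
  spec <- switch(name,
    default = list(agent = agent_params(), n_sessions = 10L,
                   trials_per_session = 200L),
    decoding = list(agent = agent_params(ar_phi = 0.9,
                                         trial_drift_sd = 0.09,
                                         session_drift_sd = 0.05,
                                         bid_noise_sd = 0.08),
                    n_sessions = 4L, trials_per_session = 800L),
    overlap = list(agent = agent_params(base_values = c(0.4, 0.5, 0.6)),
                   n_sessions = 2L, trials_per_session = 300L),
    coherent = list(agent = agent_params(base_values = c(0.3, 0.5, 0.7),
                                         ar_phi = 0.9,
                                         trial_drift_sd = 0.07,
                                         session_drift_sd = 0,
                                         bid_noise_sd = 0.03),
                    n_sessions = 4L, trials_per_session = 150L),
    independent = list(agent = agent_params(shared_drift = FALSE,
                                            trial_drift_sd = 0,
                                            session_drift_sd = 0,
                                            bid_noise_sd = 0.08,
                                            w_starting_bid = 0,
                                            w_total_liquid = 0,
                                            w_prev_computer_bid = 0,
                                            w_prev_result = 0,
                                            w_win_streak = 0,
                                            w_lose_streak = 0),
                       n_sessions = 10L, trials_per_session = 200L))
  monkey_v_config(agent = spec$agent,
                  n_sessions = n_sessions %||% spec$n_sessions,
                  trials_per_session = trials_per_session %||%
                    spec$trials_per_session, ...)
}

#' Simulate BDM bidding sessions
#'
#' Generates seeded synthetic sessions of the BDM task: magnitudes interleaved
#' pseudo-randomly, bids driven by the agent's latent value plus history
#' effects, auctions resolved by [resolve_auction()], streaks and cumulative
#' liquid tracked per trial, and task event times laid out in the task's fixed
#' order (fractal appears 0.5 s after trial start).
#'
#' @param cfg a [subject_config()].
#' @param seed integer seed; a fixed seed gives an identical dataset.
#' @return list of class `bdm_behavior` with elements `trials` (data.frame,
#'   one row per trial) and `latent` (data.frame of the latent value
#'   trajectory; one column per magnitude when drift is not shared), plus the
#'   generating `cfg` and `seed`.
#' @export
simulate_behavior <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "subject_config"))
  ag <- cfg$agent
  acfg <- auction_config(cfg$budget)
  with_seed(seed, {
    rows <- vector("list", cfg$n_sessions)
    latents <- vector("list", cfg$n_sessions)
    stat_sd <- if (ag$ar_phi < 1) ag$trial_drift_sd / sqrt(1 - ag$ar_phi^2) else
      ag$trial_drift_sd
    for (s in seq_len(cfg$n_sessions)) {
      nt <- cfg$trials_per_session
      n_proc <- if (ag$shared_drift) 1L else 3L
      sess_off <- rnorm(n_proc, 0, ag$session_drift_sd)
      v <- matrix(0, nt, n_proc)
      v[1, ] <- rnorm(n_proc, 0, stat_sd)
      if (nt > 1) for (t in 2:nt)
        v[t, ] <- ag$ar_phi * v[t - 1, ] + rnorm(n_proc, 0, ag$trial_drift_sd)

      lev <- sample.int(3L, nt, replace = TRUE)
      start_bid <- runif(nt)
      fail <- runif(nt) < ag$fail_prob
      noise <- rnorm(nt, 0, ag$bid_noise_sd)

      cum_liquid <- 0          # ml delivered before current trial
      prev_cb <- rep(NA_real_, 3L)   # last computer bid per magnitude
      prev_res <- rep(0, 3L)         # +1 win / -1 lose per magnitude
      wstreak <- integer(3L)
      lstreak <- integer(3L)
      t_clock <- 0

      bid <- computer_bid <- juice <- water <- numeric(nt)
      result <- character(nt)
      rec_ws <- rec_ls <- integer(nt)
      rec_cum <- numeric(nt)
      rec_prev_cb <- rec_prev_res <- numeric(nt)
      tt <- matrix(NA_real_, nt, 7)

      for (t in seq_len(nt)) {
        k <- lev[t]
        rec_cum[t] <- cum_liquid
        rec_ws[t] <- wstreak[k]; rec_ls[t] <- lstreak[k]
        rec_prev_cb[t] <- prev_cb[k]; rec_prev_res[t] <- prev_res[k]

        liquid_frac <- cum_liquid / (cfg$budget * nt)
        hist_term <-
          ag$w_starting_bid * (start_bid[t] - 0.5) +
          ag$w_total_liquid * (liquid_frac - 0.5) +
          ag$w_prev_computer_bid *
            (if (is.na(prev_cb[k])) 0 else prev_cb[k] - 0.5) +
          ag$w_prev_result * prev_res[k] +
          ag$w_win_streak * wstreak[k] +
          ag$w_lose_streak * lstreak[k]
        vk <- if (ag$shared_drift) v[t, 1] else v[t, k]
        sk <- if (ag$shared_drift) sess_off[1] else sess_off[k]

        # event times: fixed task sequence; trial start 0.5 s before fractal
        tt[t, ] <- t_clock + c(0, 0.5, 1.5, 3.0, 3.5, 4.5, 6.0)
        t_clock <- t_clock + 8

        if (fail[t]) {
          bid[t] <- NA_real_; computer_bid[t] <- NA_real_
          juice[t] <- 0; water[t] <- 0
          result[t] <- "failed"
          next
        }
        bid[t] <- clip01(ag$base_values[k] + sk + vk + hist_term + noise[t])
        computer_bid[t] <- runif(1)
        out <- resolve_auction(bid[t], computer_bid[t], cfg$magnitudes[k], acfg)
        juice[t] <- out$juice_delivered
        water[t] <- out$water_delivered
        result[t] <- if (out$won) "win" else "lose"
        cum_liquid <- cum_liquid + juice[t] + water[t]
        prev_cb[k] <- computer_bid[t]
        if (out$won) {
          prev_res[k] <- 1; wstreak[k] <- wstreak[k] + 1L; lstreak[k] <- 0L
        } else {
          prev_res[k] <- -1; lstreak[k] <- lstreak[k] + 1L; wstreak[k] <- 0L
        }
      }

      rows[[s]] <- data.frame(
        session_id = s,
        trial_index = seq_len(nt),
        magnitude_level = factor(MAG_LEVELS[lev], levels = MAG_LEVELS),
        magnitude_ml = cfg$magnitudes[lev],
        starting_bid = start_bid,
        bid = bid,
        computer_bid = computer_bid,
        result = result,
        juice_ml = juice,
        water_ml = water,
        cumulative_liquid_ml = rec_cum,
        win_streak = rec_ws,
        lose_streak = rec_ls,
        prev_computer_bid_same = rec_prev_cb,
        prev_result_same = rec_prev_res,
        day_of_week = ((s - 1L) %% 5L) + 1L,
        velocity = rnorm(nt),
        absement = rnorm(nt),
        t_trial_start = tt[, 1], t_fractal = tt[, 2], t_bidspace = tt[, 3],
        t_bid_stable = tt[, 4], t_reveal = tt[, 5], t_juice = tt[, 6],
        t_water = tt[, 7]
      )
      lat <- data.frame(session_id = s, trial_index = seq_len(nt))
      if (ag$shared_drift) {
        lat$latent <- sess_off[1] + v[, 1]
      } else {
        lat$latent_low <- sess_off[1] + v[, 1]
        lat$latent_mid <- sess_off[2] + v[, 2]
        lat$latent_high <- sess_off[3] + v[, 3]
      }
      latents[[s]] <- lat
    }
    structure(list(trials = do.call(rbind, rows),
                   latent = do.call(rbind, latents),
                   cfg = cfg, seed = seed),
              class = "bdm_behavior")
  })
}

#' @export
print.bdm_behavior <- function(x, ...) {
  tr <- x$trials
  ok <- tr$result != "failed"
  cat("Synthetic BDM behavior: subject", x$cfg$name, "-",
      length(unique(tr$session_id)), "sessions,", nrow(tr), "trials",
      sprintf("(%.1f%% failed)\n", 100 * mean(!ok)))
  mb <- tapply(tr$bid[ok], tr$magnitude_level[ok], mean)
  cat("Mean bid by magnitude: ",
      paste(sprintf("%s=%.3f", names(mb), mb), collapse = ", "), "\n")
  invisible(x)
}
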