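# Shared fixtures, built in code.

# small behavioral dataset used by several tests
small_behavior <- function(seed = 1, n_sessions = 2, trials = 150,
                           agent = agent_params()) {
  cfg <- monkey_v_config(n_sessions = n_sessions,
                         trials_per_session = trials, agent = agent)
  simulate_behavior(cfg, seed = seed)
}

# agent with every stochastic and history term switched off
deterministic_agent <- function(base_values = c(0.2, 0.5, 0.8)) {
  agent_params(base_values = base_values, trial_drift_sd = 0,
               session_drift_sd = 0, bid_noise_sd = 0,
               w_starting_bid = 0, w_total_liquid = 0,
               w_prev_computer_bid = 0, w_prev_result = 0,
               w_win_streak = 0, w_lose_streak = 0, fail_prob = 0)
}

# brute-force regressor recomputation: for each analysis row, rescan the raw
# session history from the top. Independent of build_regressors' single-pass
# bookkeeping.
naive_regressors <- function(trials) {
  rows <- list()
  for (sess in unique(trials$session_id)) {
    tr <- trials[trials$session_id == sess, ]
    tr <- tr[order(tr$trial_index), ]
    for (t in seq_len(nrow(tr))) {
      if (tr$result[t] == "failed") next
      past <- if (t > 1) tr[1:(t - 1), ] else tr[0, ]
      ok <- past[past$result != "failed", ]
      same <- ok[ok$magnitude_level == as.character(tr$magnitude_level[t]), ]
      v <- c(reward_value = tr$magnitude_ml[t],
             starting_bid = tr$starting_bid[t],
             prev_total_liquid = sum(ok$juice_ml + ok$water_ml),
             day_of_week = tr$day_of_week[t],
             session_number = sess,
             prev_trial_failed = if (t == 1) NA else
               as.numeric(tr$result[t - 1] == "failed"),
             prev_trial_result = if (nrow(ok)) {
               if (ok$result[nrow(ok)] == "win") 1 else -1
             } else NA,
             prev_result_same_magnitude = if (nrow(same)) {
               if (same$result[nrow(same)] == "win") 1 else -1
             } else NA,
             trial_number = tr$trial_index[t])
      for (l in c(1, 2, 3, 5, 7))
        v[paste0("competing_bid_lag", l)] <-
          if (nrow(ok) >= l) ok$computer_bid[nrow(ok) - l + 1] else NA
      for (l in 1:10)
        v[paste0("competing_bid_same_lag", l)] <-
          if (nrow(same) >= l) same$computer_bid[nrow(same) - l + 1] else NA
      for (w in 2:6)
        v[paste0("competing_bid_same_mean", w)] <-
          if (nrow(same) >= w)
            mean(same$computer_bid[(nrow(same) - w + 1):nrow(same)]) else NA
      # streaks: scan same-magnitude results backwards
      ws <- 0L; ls <- 0L
      if (nrow(same)) {
        r <- rev(same$result)
        if (r[1] == "win") while (ws < length(r) && r[ws + 1] == "win")
          ws <- ws + 1L
        if (r[1] == "lose") while (ls < length(r) && r[ls + 1] == "lose")
          ls <- ls + 1L
      }
      v["win_streak"] <- ws
      v["lose_streak"] <- ls
      rows[[length(rows) + 1L]] <- v
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  out[, regressor_names()]
}

# hand-built response table for decoding tests: neurons with exact linear
# z = slope * bid (+ optional noise), uniform bids covering all tenths
linear_response_table <- function(n_neurons = 5, n_trials = 200,
                                  noise_sd = 0, seed = 1) {
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(n_neurons), function(i) {
    bid <- (seq_len(n_trials) - 0.5) / n_trials  # covers every tenth
    z <- bid + rnorm(n_trials, 0, noise_sd)
    data.frame(neuron_id = sprintf("lin%02d", i), session_id = 1,
               trial_index = seq_len(n_trials),
               rate_hz = 10 * z, z = as.numeric(scale(z)), bid = bid,
               magnitude_level = factor("mid", levels = c("low", "mid",
                                                          "high")),
               velocity = rnorm(n_trials), absement = rnorm(n_trials))
  }))
  class(out) <- c("response_table", "data.frame")
  out
}
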