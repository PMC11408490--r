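#' Names of the 31 candidate bid regressors
#'
#' The candidate set spans reward value, the starting cursor position, prior
#' liquid intake, calendar/session/trial indices, the previous trial's fate,
#' competing-bid history both overall (lags 1, 2, 3, 5, 7) and within the same
#' reward magnitude (lags 1-10 and running means over the last 2-6
#' same-magnitude trials), and same-magnitude win/lose streaks.
#'
#' @return character vector of length 31.
#' @export
regressor_names <- function() {
  c("reward_value", "starting_bid", "prev_total_liquid", "day_of_week",
    "session_number", "prev_trial_failed", "prev_trial_result",
    "prev_result_same_magnitude", "trial_number",
    paste0("competing_bid_lag", c(1, 2, 3, 5, 7)),
    paste0("competing_bid_same_lag", 1:10),
    paste0("competing_bid_same_mean", 2:6),
    "win_streak", "lose_streak")
}

#' Build the candidate regressor matrix from a trial table
#'
#' Computes, for every non-failed trial, the 31 candidate variables used for
#' lasso variable selection and the mixed-effects bid models. Lagged
#' competing-bid variables are computed over the session's non-failed trials
#' (a competing bid only exists once a bid was placed); same-magnitude lags
#' run over the subsequence of non-failed trials sharing the trial's magnitude
#' level. Lags that reach before the session start are `NA` and those rows are
#' dropped listwise at fit time, never imputed. Win/lose streaks count
#' consecutive same-magnitude wins/losses entering the trial and reset at
#' session boundaries.
#'
#' @param trials trial data.frame with columns `session_id`, `trial_index`,
#'   `magnitude_level`, `magnitude_ml`, `starting_bid`, `bid`, `computer_bid`,
#'   `result`, `juice_ml`, `water_ml`, `day_of_week` (trials sorted by session
#'   then trial index).
#' @return data.frame of class `regressor_matrix`: `session_id`,
#'   `trial_index`, the response `bid`, and the 31 columns of
#'   [regressor_names()]. `prev_trial_result` and `prev_result_same_magnitude`
#'   are coded +1 win / -1 lose / `NA` none; `prev_trial_failed` is 0/1.
#' @export
build_regressors <- function(trials) {
  need <- c("session_id", "trial_index", "magnitude_level", "magnitude_ml",
            "starting_bid", "bid", "computer_bid", "result", "juice_ml",
            "water_ml", "day_of_week")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop_domain("trial table lacks columns: ", paste(miss, collapse = ", "))
  out <- vector("list", length(unique(trials$session_id)))
  si <- 0L
  for (sess in unique(trials$session_id)) {
    si <- si + 1L
    tr <- trials[trials$session_id == sess, , drop = FALSE]
    tr <- tr[order(tr$trial_index), , drop = FALSE]
    nt <- nrow(tr)
    failed <- tr$result == "failed"
    delivered <- ifelse(failed, 0, tr$juice_ml + tr$water_ml)
    prev_liquid <- c(0, cumsum(delivered))[seq_len(nt)]

    # histories over non-failed trials
    cb_hist <- numeric(0)            # all competing bids so far
    res_hist <- numeric(0)           # +1/-1 results so far
    cb_same <- list(low = numeric(0), mid = numeric(0), high = numeric(0))
    res_same <- list(low = numeric(0), mid = numeric(0), high = numeric(0))
    ws <- c(low = 0L, mid = 0L, high = 0L)
    ls <- c(low = 0L, mid = 0L, high = 0L)

    m <- matrix(NA_real_, nt, 31,
                dimnames = list(NULL, regressor_names()))
    for (t in seq_len(nt)) {
      k <- as.character(tr$magnitude_level[t])
      m[t, "reward_value"] <- tr$magnitude_ml[t]
      m[t, "starting_bid"] <- tr$starting_bid[t]
      m[t, "prev_total_liquid"] <- prev_liquid[t]
      m[t, "day_of_week"] <- tr$day_of_week[t]
      m[t, "session_number"] <- sess
      m[t, "prev_trial_failed"] <- if (t == 1) NA else as.numeric(failed[t - 1])
      m[t, "prev_trial_result"] <-
        if (length(res_hist)) res_hist[length(res_hist)] else NA
      rs <- res_same[[k]]
      m[t, "prev_result_same_magnitude"] <-
        if (length(rs)) rs[length(rs)] else NA
      m[t, "trial_number"] <- tr$trial_index[t]
      for (l in c(1, 2, 3, 5, 7))
        if (length(cb_hist) >= l)
          m[t, paste0("competing_bid_lag", l)] <-
            cb_hist[length(cb_hist) - l + 1]
      cs <- cb_same[[k]]
      for (l in 1:10)
        if (length(cs) >= l)
          m[t, paste0("competing_bid_same_lag", l)] <-
            cs[length(cs) - l + 1]
      for (w in 2:6)
        if (length(cs) >= w)
          m[t, paste0("competing_bid_same_mean", w)] <-
            mean(cs[(length(cs) - w + 1):length(cs)])
      m[t, "win_streak"] <- ws[[k]]
      m[t, "lose_streak"] <- ls[[k]]

      if (!failed[t]) {
        cb_hist <- c(cb_hist, tr$computer_bid[t])
        won <- tr$result[t] == "win"
        res_hist <- c(res_hist, if (won) 1 else -1)
        cb_same[[k]] <- c(cb_same[[k]], tr$computer_bid[t])
        res_same[[k]] <- c(res_same[[k]], if (won) 1 else -1)
        if (won) { ws[[k]] <- ws[[k]] + 1L; ls[[k]] <- 0L }
        else     { ls[[k]] <- ls[[k]] + 1L; ws[[k]] <- 0L }
      }
    }
    keep <- !failed
    out[[si]] <- cbind(
      data.frame(session_id = sess, trial_index = tr$trial_index[keep],
                 bid = tr$bid[keep]),
      as.data.frame(m[keep, , drop = FALSE]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("regressor_matrix", "data.frame")
  res
}
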