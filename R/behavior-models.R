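#' Lasso variable selection with the one-standard-error rule
#'
#' Cross-validated lasso regression of bids on the 31 candidate regressors.
#' The regularization strength is chosen by the 1-SE rule: the largest lambda
#' whose cross-validated mean-squared error lies within one standard error of
#' the minimum, which favors the sparsest model statistically indistinguishable
#' from the best. Day of week enters as one-hot dummies; selecting any dummy
#' counts as selecting the variable. Rows with any missing lag are dropped
#' listwise; constant columns are dropped with a warning before fitting.
#'
#' @param X a `regressor_matrix` from [build_regressors()].
#' @param y response; defaults to `X$bid`.
#' @param n_folds number of CV folds (default 20; any value the data support,
#'   including very large ones, is accepted).
#' @param seed RNG seed for the fold assignment.
#' @return object of class `lasso_selection`: `selected` (variable names with
#'   nonzero coefficient at `lambda_1se`), `coef_1se`, `lambda_1se`,
#'   `lambda_min`, `cv` (the `cv.glmnet` object), `n_used`, `dropped`.
#' @export
lasso_select <- function(X, y = NULL, n_folds = 20L, seed = 1L) {
  stopifnot(inherits(X, "regressor_matrix"))
  y <- y %||% X$bid
  vars <- regressor_names()
  df <- as.data.frame(X)[, vars]
  df$day_of_week <- factor(df$day_of_week)
  keep <- stats::complete.cases(df) & !is.na(y)
  df <- df[keep, , drop = FALSE]
  y <- y[keep]
  if (nrow(df) < 2L * n_folds)
    stop_domain("too few complete rows (", nrow(df), ") for ", n_folds,
                "-fold cross-validation")
  const <- vapply(df, function(col) length(unique(col)) < 2L, TRUE)
  dropped <- names(df)[const]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "))
    df <- df[, !const, drop = FALSE]
  }
  mm <- stats::model.matrix(~ . - 1, data = df)
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(n_folds), nrow(mm)))
    cv <- glmnet::cv.glmnet(mm, y, foldid = foldid, standardize = TRUE)
    co <- stats::coef(cv, s = "lambda.1se")
    nz <- rownames(co)[as.vector(co != 0)]
    nz <- setdiff(nz, "(Intercept)")
    # map one-hot dummies back to their source variable
    sel <- unique(vapply(nz, function(nm) {
      if (grepl("^day_of_week", nm)) "day_of_week" else nm
    }, ""))
    structure(list(selected = sel, coef_1se = co,
                   lambda_1se = cv$lambda.1se, lambda_min = cv$lambda.min,
                   cv = cv, n_used = nrow(mm), dropped = dropped),
              class = "lasso_selection")
  })
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat("Lasso (1-SE rule): lambda_1se =", signif(x$lambda_1se, 4),
      ">= lambda_min =", signif(x$lambda_min, 4), "; n =", x$n_used, "\n")
  cat("Selected (", length(x$selected), "): ",
      paste(x$selected, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# map trial table to the named model variables of the three bid models
mixed_model_frame <- function(trials) {
  X <- build_regressors(trials)
  data.frame(
    Bid = X$bid,
    RewardMagnitude = X$reward_value,
    StartingBid = X$starting_bid,
    TotalLiquid = X$prev_total_liquid,
    PreviousCompetingBid = X$competing_bid_same_lag1,
    PreviousResult = X$prev_result_same_magnitude,
    PreviousWinStreak = X$win_streak,
    PreviousLoseStreak = X$lose_streak,
    TrialNumber = factor(X$trial_index),
    SessionNumber = factor(X$session_id)
  )
}

MIXED_FORMULAS <- list(
  `1` = Bid ~ RewardMagnitude + StartingBid + TotalLiquid +
    PreviousCompetingBid + PreviousResult +
    (1 | TrialNumber) + (1 | SessionNumber),
  `2` = Bid ~ StartingBid + TotalLiquid + PreviousCompetingBid +
    PreviousResult + (1 | RewardMagnitude) +
    (1 | TrialNumber) + (1 | SessionNumber),
  `3` = Bid ~ StartingBid + TotalLiquid + PreviousCompetingBid +
    PreviousWinStreak + PreviousLoseStreak + (1 | RewardMagnitude) +
    (1 | TrialNumber) + (1 | SessionNumber) + (1 | PreviousResult)
)

#' Fit one of the three mixed-effects bid models
#'
#' Model 1 regresses bids on reward magnitude, starting bid, previous total
#' liquid, the previous same-magnitude competing bid and the previous
#' same-magnitude result, with random intercepts grouped by trial number and
#' session number (removing trial-progression and between-day variability from
#' the fixed effects). Model 2 additionally moves reward magnitude into the
#' random intercepts, isolating the non-magnitude drivers of bidding. Model 3
#' replaces the previous result by win/lose streak counts in the fixed effects
#' and moves the previous result to the random intercepts, because streaks and
#' the previous result are collinear.
#'
#' @param trials trial data.frame (see [build_regressors()]).
#' @param model_id 1, 2 or 3.
#' @return object of class `bdm_mixed_model`: `fixed` (data.frame with
#'   estimate, 95% Wald CI, Satterthwaite p per fixed effect), `adj_r2`
#'   (squared correlation of fitted and observed bids, adjusted for the number
#'   of fixed effects), `fit` (the `lmerModLmerTest` object), `n`,
#'   `converged`, `model_id`.
#' @export
fit_mixed_model <- function(trials, model_id = 1L) {
  model_id <- as.character(model_id)
  if (!model_id %in% names(MIXED_FORMULAS))
    stop_domain("`model_id` must be 1, 2 or 3")
  df <- mixed_model_frame(trials)
  if (model_id == "3") df$PreviousResult <- factor(df$PreviousResult)
  vars <- all.vars(MIXED_FORMULAS[[model_id]])
  df <- df[stats::complete.cases(df[, vars]), , drop = FALSE]
  msgs <- character(0)
  fit <- withCallingHandlers(
    lmerTest::lmer(MIXED_FORMULAS[[model_id]], data = df,
                   control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  conv_msgs <- fit@optinfo$conv$lme4$messages %||% character(0)
  singular <- lme4::isSingular(fit)
  conv_msgs <- conv_msgs[!grepl("singular", conv_msgs, ignore.case = TRUE)]
  conv <- length(conv_msgs) == 0L
  if (singular)
    message("mixed model ", model_id,
            ": singular fit (some random-effect variance is zero)")
  if (!conv)
    warning("mixed model ", model_id, " convergence issues: ",
            paste(conv_msgs, collapse = "; "))
  sm <- summary(fit)$coefficients
  ci <- tryCatch(stats::confint(fit, parm = "beta_", method = "Wald"),
                 error = function(e) matrix(NA, nrow(sm), 2))
  fixed <- data.frame(term = rownames(sm),
                      estimate = sm[, "Estimate"],
                      ci_lo = ci[, 1], ci_hi = ci[, 2],
                      p = sm[, "Pr(>|t|)"], row.names = NULL)
  r2 <- stats::cor(stats::fitted(fit), df$Bid)^2
  k <- nrow(sm) - 1L
  adj_r2 <- 1 - (1 - r2) * (nrow(df) - 1) / (nrow(df) - k - 1)
  structure(list(model_id = as.integer(model_id), fixed = fixed,
                 adj_r2 = adj_r2, fit = fit, n = nrow(df),
                 converged = conv, singular = singular, messages = msgs),
            class = "bdm_mixed_model")
}

#' @export
print.bdm_mixed_model <- function(x, digits = 3, ...) {
  cat("Mixed-effects bid model", x$model_id,
      sprintf("(n = %d, adj. R^2 = %.2f%s)\n", x$n, x$adj_r2,
              if (x$converged) "" else ", DID NOT CONVERGE"))
  f <- x$fixed
  f$estimate <- signif(f$estimate, digits)
  f$ci_lo <- signif(f$ci_lo, digits); f$ci_hi <- signif(f$ci_hi, digits)
  f$p <- signif(f$p, 2)
  print(f, row.names = FALSE)
  invisible(x)
}

#' @export
coef.bdm_mixed_model <- function(object, ...) {
  stats::setNames(object$fixed$estimate, object$fixed$term)
}

#' Rank-order check of bids against reward magnitude
#'
#' Spearman rank correlation of bids with juice magnitude, pooled over all
#' trials and (optionally) per session, with the fraction of sessions showing
#' a significant positive correlation. Sessions with a single magnitude level
#' are excluded with a warning.
#'
#' @param trials trial data.frame.
#' @param per_session also compute per-session correlations?
#' @return object of class `rank_order_check`: `pooled` (rho, r2, p, n),
#'   `per_session` (data.frame or NULL), `frac_significant`.
#' @export
rank_order_check <- function(trials, per_session = TRUE) {
  tr <- trials[trials$result != "failed" & !is.na(trials$bid), ]
  if (length(unique(tr$magnitude_ml)) < 2L)
    stop_domain("need at least two magnitude levels")
  ct <- suppressWarnings(
    stats::cor.test(tr$bid, tr$magnitude_ml, method = "spearman"))
  pooled <- list(rho = unname(ct$estimate), r2 = unname(ct$estimate)^2,
                 p = ct$p.value, n = nrow(tr))
  per <- NULL
  frac <- NA_real_
  if (per_session) {
    res <- lapply(split(tr, tr$session_id), function(s) {
      if (length(unique(s$magnitude_ml)) < 2L) {
        warning("session ", s$session_id[1],
                " has a single magnitude level; excluded")
        return(NULL)
      }
      ct <- suppressWarnings(
        stats::cor.test(s$bid, s$magnitude_ml, method = "spearman"))
      data.frame(session_id = s$session_id[1], rho = unname(ct$estimate),
                 p = ct$p.value, n = nrow(s))
    })
    per <- do.call(rbind, res)
    frac <- mean(per$p < 0.05 & per$rho > 0)
  }
  structure(list(pooled = pooled, per_session = per,
                 frac_significant = frac),
            class = "rank_order_check")
}

#' @export
print.rank_order_check <- function(x, ...) {
  cat(sprintf("Bids vs magnitude: pooled Spearman rho = %.2f (R^2 = %.2f, p = %.2g, n = %d)\n",
              x$pooled$rho, x$pooled$r2, x$pooled$p, x$pooled$n))
  if (!is.null(x$per_session))
    cat(sprintf("Per session: %.0f%% of %d sessions significant (mean rho = %.2f)\n",
                100 * x$frac_significant, nrow(x$per_session),
                mean(x$per_session$rho)))
  invisible(x)
}

#' Bid coherence across reward magnitudes
#'
#' If bids track a common underlying value signal, bids for the three
#' magnitudes should co-fluctuate. Within each session, the bids of each
#' magnitude are placed at their trial indices and linearly interpolated onto
#' the full session trial grid, giving three equally populated vectors that
#' retain trial-by-trial temporal order; these are rank-correlated pairwise
#' (low:mid, mid:high, low:high). Because interpolation fills trials where a
#' magnitude was absent, the resulting rho is a lower bound on the true
#' coherence. Between-session (day-to-day) coherence rank-correlates the
#' per-session mean bids across magnitudes.
#'
#' @param trials trial data.frame.
#' @param min_per_magnitude minimum non-failed trials per magnitude for a
#'   session to enter the within-session analysis (default 5).
#' @return object of class `bid_coherence`: `per_session` (session x pairing
#'   rho and p), `within` (per pairing: median rho across sessions and a
#'   sign-rank p of the session rhos against 0), `between` (per pairing rho
#'   and p across session means), `skipped` sessions.
#' @export
bid_coherence <- function(trials, min_per_magnitude = 5L) {
  tr <- trials[trials$result != "failed" & !is.na(trials$bid), ]
  pairings <- list(c("low", "mid"), c("mid", "high"), c("low", "high"))
  pair_lab <- c("L:M", "M:H", "L:H")
  per <- list(); skipped <- integer(0)
  for (s in unique(tr$session_id)) {
    ss <- tr[tr$session_id == s, ]
    counts <- table(factor(ss$magnitude_level, levels = MAG_LEVELS))
    if (any(counts < min_per_magnitude)) {
      message("bid_coherence: skipping session ", s,
              " (fewer than ", min_per_magnitude, " trials in a magnitude)")
      skipped <- c(skipped, s)
      next
    }
    grid <- sort(unique(ss$trial_index))
    interp <- lapply(MAG_LEVELS, function(k) {
      sk <- ss[ss$magnitude_level == k, ]
      stats::approx(sk$trial_index, sk$bid, xout = grid, rule = 2)$y
    })
    names(interp) <- MAG_LEVELS
    for (i in seq_along(pairings)) {
      a <- interp[[pairings[[i]][1]]]; b <- interp[[pairings[[i]][2]]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        message("bid_coherence: session ", s, " pairing ", pair_lab[i],
                " has a constant interpolated bid vector; rho undefined")
        per[[length(per) + 1L]] <-
          data.frame(session_id = s, pairing = pair_lab[i],
                     rho = NA_real_, p = NA_real_)
        next
      }
      ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
      per[[length(per) + 1L]] <-
        data.frame(session_id = s, pairing = pair_lab[i],
                   rho = unname(ct$estimate), p = ct$p.value)
    }
  }
  per <- if (length(per)) do.call(rbind, per) else NULL
  within <- NULL
  if (!is.null(per)) {
    within <- do.call(rbind, lapply(pair_lab, function(pl) {
      rhos <- per$rho[per$pairing == pl]
      rhos <- rhos[!is.na(rhos)]
      p <- if (length(rhos) >= 4)
        suppressWarnings(stats::wilcox.test(rhos, mu = 0)$p.value)
      else per$p[per$pairing == pl][1]
      data.frame(pairing = pl,
                 median_rho = if (length(rhos)) stats::median(rhos)
                              else NA_real_,
                 p = p, n_sessions = length(rhos))
    }))
  }
  between <- NULL
  means <- tapply(tr$bid, list(tr$session_id, tr$magnitude_level), mean)
  if (!is.null(dim(means)) && nrow(means) >= 4) {
    between <- do.call(rbind, lapply(seq_along(pairings), function(i) {
      a <- means[, pairings[[i]][1]]; b <- means[, pairings[[i]][2]]
      ok <- stats::complete.cases(a, b)
      ct <- suppressWarnings(stats::cor.test(a[ok], b[ok],
                                             method = "spearman"))
      data.frame(pairing = pair_lab[i], rho = unname(ct$estimate),
                 p = ct$p.value, n_sessions = sum(ok))
    }))
  }
  structure(list(per_session = per, within = within, between = between,
                 skipped = skipped),
            class = "bid_coherence")
}

#' @export
print.bid_coherence <- function(x, ...) {
  cat("Within-session bid coherence (median rho across sessions):\n")
  if (!is.null(x$within)) print(x$within, row.names = FALSE)
  if (!is.null(x$between)) {
    cat("Between-session coherence (session means):\n")
    print(x$between, row.names = FALSE)
  }
  invisible(x)
}
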