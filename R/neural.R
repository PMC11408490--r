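#' Analysis window constructor
#'
#' A post-fractal-onset analysis window in ms. The start is rounded to the
#' nearest 20 ms, matching the resolution at which value windows are detected.
#'
#' @param start_ms,end_ms window bounds, `0 < start < end <= 500`.
#' @return object of class `analysis_window`.
#' @export
analysis_window <- function(start_ms, end_ms) {
  start_ms <- 20 * round(start_ms / 20)
  if (!(start_ms > 0 && start_ms < end_ms && end_ms <= 500))
    stop_domain("need 0 < start < end <= 500 ms (start rounds to 20 ms)")
  structure(list(start_ms = start_ms, end_ms = end_ms),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat("Analysis window:", x$start_ms, "-", x$end_ms, "ms post fractal onset\n")
  invisible(x)
}

#' Windowed firing rate per trial
#'
#' Spike count inside the window divided by window length, in Hz.
#'
#' @param raster a `spike_raster`.
#' @param window an [analysis_window()] or `list(start_ms, end_ms)`; may also
#'   reach into the pre-event baseline (negative times).
#' @return numeric vector, one rate (Hz) per trial.
#' @export
windowed_response <- function(raster, window) {
  stopifnot(inherits(raster, "spike_raster"))
  sel <- raster$times_ms >= window$start_ms & raster$times_ms < window$end_ms
  if (!any(sel)) stop_domain("window lies outside the raster span")
  rowSums(raster$counts[, sel, drop = FALSE]) /
    ((window$end_ms - window$start_ms) / 1000)
}

#' Per-trial response table for a neuron population
#'
#' Computes, for each neuron and trial, the raw windowed rate and the
#' z-normalized rate (z per neuron across its trials, so neurons with
#' different dynamic ranges are comparable at the population level), together
#' with the trial's bid, magnitude level and movement covariates. Neurons with
#' zero response variance cannot be z-scored and are excluded with a warning.
#'
#' @param population a `neuron_population` (or list of `spike_raster`s).
#' @param window an [analysis_window()].
#' @return data.frame of class `response_table`: `neuron_id`, `session_id`,
#'   `trial_index`, `rate_hz`, `z`, `bid`, `magnitude_level`, `velocity`,
#'   `absement`.
#' @export
response_table <- function(population, window) {
  rasters <- if (inherits(population, "neuron_population"))
    population$rasters else population
  out <- lapply(rasters, function(r) {
    rate <- windowed_response(r, window)
    s <- stats::sd(rate)
    if (!is.finite(s) || s == 0) {
      warning("neuron ", r$neuron_id,
              " has zero response variance; excluded from z-normalization")
      return(NULL)
    }
    data.frame(neuron_id = r$neuron_id,
               session_id = r$trials$session_id,
               trial_index = r$trials$trial_index,
               rate_hz = rate,
               z = (rate - mean(rate)) / s,
               bid = r$trials$bid,
               magnitude_level = r$trials$magnitude_level,
               velocity = r$trials$velocity,
               absement = r$trials$absement)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  class(res) <- c("response_table", "data.frame")
  res
}

#' Classify a neuron as dopamine-like
#'
#' Canonical screening criteria: wide extracellular impulse waveform
#' (> 1.8 ms), low baseline rate (< 10 Hz), and a significant response to at
#' least one task event (per-trial rate in the 0-200 ms post-event window
#' against the per-trial pre-event baseline rate; paired two-sided Wilcoxon,
#' p < 0.05).
#'
#' @param raster a `spike_raster`.
#' @param waveform_width_ms impulse width; defaults to the raster's model
#'   metadata. Missing width classifies the neuron non-dopamine with a
#'   warning.
#' @param event_onsets_ms onsets (ms, relative to the raster alignment) of the
#'   task events to screen; default the aligned fractal onset at 0.
#' @param baseline_ms baseline window (default the 500 ms before the event).
#' @return list of class `dopamine_classification`: `is_dopamine`, `width_ms`,
#'   `baseline_hz`, `event_p` (per event), `criteria` (logical vector).
#' @export
classify_dopamine <- function(raster, waveform_width_ms = NULL,
                              event_onsets_ms = 0,
                              baseline_ms = c(-500, 0)) {
  stopifnot(inherits(raster, "spike_raster"))
  if (nrow(raster$counts) < 20L)
    stop_domain("need at least 20 trials to classify")
  width <- waveform_width_ms %||% raster$model$waveform_width_ms
  base <- windowed_response(raster, list(start_ms = baseline_ms[1],
                                         end_ms = baseline_ms[2]))
  baseline_hz <- mean(base)
  event_p <- vapply(event_onsets_ms, function(on) {
    resp <- windowed_response(raster, list(start_ms = on, end_ms = on + 200))
    suppressWarnings(stats::wilcox.test(resp, base, paired = TRUE)$p.value)
  }, 0)
  if (is.null(width) || is.na(width)) {
    warning("neuron ", raster$neuron_id,
            ": missing waveform width; classified non-dopamine")
    crit <- c(wide_waveform = FALSE, low_baseline = baseline_hz < 10,
              event_responsive = any(event_p < 0.05, na.rm = TRUE))
  } else {
    crit <- c(wide_waveform = width > 1.8, low_baseline = baseline_hz < 10,
              event_responsive = any(event_p < 0.05, na.rm = TRUE))
  }
  structure(list(is_dopamine = all(crit), width_ms = width,
                 baseline_hz = baseline_hz, event_p = event_p,
                 criteria = crit),
            class = "dopamine_classification")
}

#' @export
print.dopamine_classification <- function(x, ...) {
  cat(sprintf("%s (width %.1f ms, baseline %.1f Hz, min event p = %.3g)\n",
              if (x$is_dopamine) "dopamine-like" else "non-dopamine",
              x$width_ms %||% NA, x$baseline_hz, min(x$event_p)))
  invisible(x)
}

#' Population z-scored PSTH traces per neuron
#'
#' For each neuron, the trial-averaged 1 ms firing-rate trace over the trials
#' of one magnitude level, z-scored against the mean and sd of that neuron's
#' trace over the pre-event baseline period.
#'
#' @param population a `neuron_population` or list of rasters.
#' @param level magnitude level (`"low"`, `"mid"`, `"high"`) or `NULL` for all
#'   trials.
#' @param baseline_ms baseline period (default `c(-500, 0)`).
#' @return list with `z` (neurons x time matrix) and `times_ms`.
#' @export
population_traces <- function(population, level = NULL,
                              baseline_ms = c(-500, 0)) {
  rasters <- if (inherits(population, "neuron_population"))
    population$rasters else population
  times <- rasters[[1]]$times_ms
  bsel <- times >= baseline_ms[1] & times < baseline_ms[2]
  z <- t(vapply(rasters, function(r) {
    keep <- if (is.null(level)) rep(TRUE, nrow(r$counts)) else
      r$trials$magnitude_level == level
    trace <- colMeans(r$counts[keep, , drop = FALSE]) * 1000  # Hz
    m <- mean(trace[bsel]); s <- stats::sd(trace[bsel])
    if (s == 0) s <- 1
    (trace - m) / s
  }, numeric(length(times))))
  list(z = z, times_ms = times)
}

#' Detect the value-response analysis window
#'
#' Two-component dopamine-like responses start with a value-independent
#' excitation; the value window must exclude it. The window start is found on
#' the lowest-magnitude population trace, which carries a negative prediction
#' error in its value component but an unchanged positive initial component:
#' the start is the first time after the initial component's peak at which the
#' (smoothed) population-average trace returns to the baseline mean, rounded
#' to the nearest 20 ms. The window end is found on the highest-magnitude
#' trace, which carries a well-defined positive prediction error: 20 ms bins
#' between 0 and 500 ms are tested across neurons against zero (two-sided
#' Wilcoxon sign-rank, p < 0.05, Bonferroni-Holm corrected over bins) and the
#' end is the first bin at or after the start at which the signal is no longer
#' significant.
#'
#' @param traces_low,traces_high outputs of [population_traces()] for the
#'   lowest and highest magnitude. The sign-rank's smallest attainable p is
#'   `2^(1-n)` for `n` neurons, so after Holm correction over the 25 bins at
#'   least 12 neurons are needed for any bin to reach significance; smaller
#'   populations always yield a degenerate (zero-length) window.
#' @param smooth_ms moving-average width used only for the start detection.
#' @param alpha significance level for the end detection.
#' @return list of class `value_window_detection`: `status` (`"ok"`,
#'   `"no_baseline_return"` or `"degenerate"`), `window` (an
#'   [analysis_window()] when status is `"ok"`), `start_ms`, `end_ms`,
#'   `bin_p` (Holm-corrected p per 20 ms bin).
#' @export
detect_value_window <- function(traces_low, traces_high, smooth_ms = 20,
                                alpha = 0.05) {
  if (nrow(traces_low$z) < 12L)
    warning("fewer than 12 neurons: the Holm-corrected sign-rank cannot ",
            "reach significance and the detected window will be degenerate")
  times <- traces_low$times_ms
  post <- times >= 0 & times < 500
  avg_low <- moving_average(colMeans(traces_low$z), smooth_ms)[post]
  t_post <- times[post]
  peak <- which.max(avg_low)
  below <- which(avg_low <= 0 & seq_along(avg_low) > peak)
  if (!length(below))
    return(structure(list(status = "no_baseline_return", window = NULL,
                          start_ms = NA_real_, end_ms = NA_real_,
                          bin_p = NULL),
                     class = "value_window_detection"))
  start_ms <- 20 * round(t_post[below[1]] / 20)

  edges <- seq(0, 480, by = 20)
  zh <- traces_high$z
  t_all <- traces_high$times_ms
  raw_p <- vapply(edges, function(e) {
    sel <- t_all >= e & t_all < e + 20
    v <- rowMeans(zh[, sel, drop = FALSE])
    if (all(v == 0)) return(1)
    suppressWarnings(stats::wilcox.test(v, mu = 0)$p.value)
  }, 0)
  bin_p <- stats::p.adjust(raw_p, method = "holm")
  cand <- which(edges >= start_ms & bin_p >= alpha)
  if (!length(cand) && start_ms < 500) {
    end_ms <- 500  # significant through the whole test range
  } else if (!length(cand)) {
    end_ms <- NA_real_
  } else {
    end_ms <- edges[cand[1]]
  }
  status <- if (is.na(end_ms) || end_ms <= start_ms) "degenerate" else "ok"
  window <- if (status == "ok") analysis_window(start_ms, end_ms) else NULL
  structure(list(status = status, window = window, start_ms = start_ms,
                 end_ms = end_ms, bin_p = stats::setNames(bin_p, edges)),
            class = "value_window_detection")
}

#' @export
print.value_window_detection <- function(x, ...) {
  if (x$status == "ok")
    cat("Value window detected:", x$start_ms, "-", x$end_ms, "ms\n")
  else cat("Value window detection failed:", x$status, "\n")
  invisible(x)
}

#' Linear regression of neuronal responses on bids
#'
#' Ordinary least squares of the windowed (optionally z-normalized) response
#' on the monkey's bid, `y = b0 + b1 * bid`. With `n_bins`, responses are
#' first averaged within equal-width bid bins spanning `[0, 1]` and the
#' regression runs on the bin means against bin-mean bids, which stabilizes
#' estimates when single-trial responses are noisy.
#'
#' @param responses numeric response vector (Hz or z units).
#' @param bids bids in `[0, 1]`, same length.
#' @param n_bins optional number of equal-width bid bins.
#' @return object of class `bid_regression`: `beta0`, `beta1`, `r2`, `p`,
#'   `n`, `n_bins`.
#' @export
bid_regression <- function(responses, bids, n_bins = NULL) {
  ok <- stats::complete.cases(responses, bids)
  responses <- responses[ok]; bids <- bids[ok]
  if (stats::sd(bids) == 0) stop_domain("all bids identical: no variance")
  if (!is.null(n_bins)) {
    lab <- bin_bids(bids, scheme = "equal_width", n_bins = n_bins)
    responses <- as.numeric(tapply(responses, lab, mean))
    bids <- as.numeric(tapply(bids, lab, mean))
    keep <- !is.na(responses)
    responses <- responses[keep]; bids <- bids[keep]
    if (length(bids) < 3L) stop_domain("need at least 3 non-empty bid bins")
  } else if (length(bids) < 10L) {
    stop_domain("need at least 10 observations for the unbinned regression")
  }
  fit <- stats::lm(responses ~ bids)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
  structure(list(beta0 = unname(stats::coef(fit)[1]),
                 beta1 = unname(stats::coef(fit)[2]),
                 r2 = sm$r.squared, p = p, n = length(bids),
                 n_bins = n_bins, fit = fit),
            class = "bid_regression")
}

#' @export
print.bid_regression <- function(x, ...) {
  cat(sprintf("Response ~ bid: beta1 = %.3f, R^2 = %.3f, p = %.3g (n = %d%s)\n",
              x$beta1, x$r2, x$p, x$n,
              if (is.null(x$n_bins)) "" else paste0(", ", x$n_bins, " bins")))
  invisible(x)
}

#' @export
coef.bid_regression <- function(object, ...) {
  c(beta0 = object$beta0, beta1 = object$beta1)
}

#' Select bid-encoding neurons
#'
#' Runs the response-on-bid regression per neuron on z-normalized responses
#' and selects neurons whose value-component response correlates positively
#' and significantly (p < 0.05) with the bids.
#'
#' @param rt a `response_table`.
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per neuron: `neuron_id`, `beta1`, `r2`,
#'   `p`, `selected`.
#' @export
select_bid_encoding <- function(rt, alpha = 0.05) {
  stopifnot(inherits(rt, "response_table"))
  res <- lapply(split(rt, rt$neuron_id), function(d) {
    br <- bid_regression(d$z, d$bid)
    data.frame(neuron_id = d$neuron_id[1], beta1 = br$beta1, r2 = br$r2,
               p = br$p)
  })
  out <- do.call(rbind, res)
  out$selected <- out$p < alpha & out$beta1 > 0
  rownames(out) <- NULL
  out
}

#' Discretize bids into bins
#'
#' Equal-width schemes split `[0, 1]` into 10 (`"tenths"`), 5
#' (`"quintiles"`) or 25 (`"bins25"`) bins (or `n_bins` with
#' `"equal_width"`). `"terciles_skew_corrected"` assigns equal-count
#' (quantile) terciles within each magnitude level, correcting for the
#' skewness of each magnitude's bid distribution.
#'
#' @param bids bids in `[0, 1]`.
#' @param scheme binning scheme.
#' @param magnitude_level required for `"terciles_skew_corrected"`.
#' @param n_bins bin count for `scheme = "equal_width"`.
#' @return integer bin labels (1 = lowest). Empty equal-width bins are
#'   reported with a message.
#' @export
bin_bids <- function(bids, scheme = c("tenths", "quintiles",
                                      "terciles_skew_corrected", "bins25",
                                      "equal_width"),
                     magnitude_level = NULL, n_bins = NULL) {
  scheme <- match.arg(scheme)
  check_bid_fraction(bids[!is.na(bids)], "bids")
  if (scheme == "terciles_skew_corrected") {
    if (is.null(magnitude_level))
      stop_domain("`magnitude_level` required for skew-corrected terciles")
    lab <- integer(length(bids))
    for (k in unique(magnitude_level)) {
      sel <- magnitude_level == k
      r <- rank(bids[sel], ties.method = "first")
      lab[sel] <- as.integer(ceiling(3 * r / sum(sel)))
    }
    return(lab)
  }
  nb <- switch(scheme, tenths = 10L, quintiles = 5L, bins25 = 25L,
               equal_width = as.integer(n_bins %||%
                               stop_domain("`n_bins` required")))
  lab <- pmin(nb, as.integer(floor(bids * nb)) + 1L)
  empty <- setdiff(seq_len(nb), unique(lab[!is.na(lab)]))
  if (length(empty))
    message("bin_bids: empty bin(s) ", paste(empty, collapse = ", "))
  lab
}

# greedy one-to-one nearest-bid matching between two groups, within tolerance
greedy_bid_match <- function(bids_a, bids_b, tolerance) {
  if (!length(bids_a) || !length(bids_b)) return(NULL)
  d <- abs(outer(bids_a, bids_b, "-"))
  cand <- which(d <= tolerance, arr.ind = TRUE)
  if (!nrow(cand)) return(NULL)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_a <- logical(length(bids_a)); used_b <- logical(length(bids_b))
  keep <- matrix(0L, 0, 2)
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1]; b <- cand[i, 2]
    if (!used_a[a] && !used_b[b]) {
      keep <- rbind(keep, c(a, b))
      used_a[a] <- TRUE; used_b[b] <- TRUE
    }
  }
  keep
}

#' Matched-bid comparison of responses across reward magnitudes
#'
#' If neurons encode the bid (subjective value) rather than the displayed
#' reward magnitude, trials with similar bids but different magnitudes should
#' evoke similar responses. For each magnitude pair (low vs mid, mid vs high,
#' low vs high), bids within `tolerance` of one another are matched one-to-one
#' (greedy nearest-bid matching within each session and neuron), response
#' differences (higher magnitude minus lower) are pooled across neurons, and a
#' paired two-sided Wilcoxon sign-rank test is applied. Before testing, a
#' comparison whose matched bid distributions differ significantly (two-sided
#' rank-sum, p < 0.05) is eliminated, since a bid mismatch would confound the
#' response comparison.
#'
#' @param rt a `response_table` (z-normalized responses are compared).
#' @param tolerance maximum bid difference for a match (default 0.05, i.e. 5%
#'   of the bid space).
#' @param min_pairs minimum pooled matches to run the test (default 5).
#' @return data.frame of class `matched_bid_comparison`: per pair,
#'   `n_matches`, `bid_dist_p`, `eliminated`, `mean_diff`, `p`.
#' @export
matched_bid_comparison <- function(rt, tolerance = 0.05, min_pairs = 5L) {
  stopifnot(inherits(rt, "response_table"))
  pairs <- list(`low-vs-mid` = c("low", "mid"),
                `mid-vs-high` = c("mid", "high"),
                `low-vs-high` = c("low", "high"))
  out <- lapply(names(pairs), function(pl) {
    lo_lev <- pairs[[pl]][1]; hi_lev <- pairs[[pl]][2]
    diffs <- numeric(0); bids_lo <- numeric(0); bids_hi <- numeric(0)
    for (grp in split(rt, list(rt$neuron_id, rt$session_id), drop = TRUE)) {
      a <- grp[grp$magnitude_level == lo_lev & !is.na(grp$bid), ]
      b <- grp[grp$magnitude_level == hi_lev & !is.na(grp$bid), ]
      mm <- greedy_bid_match(a$bid, b$bid, tolerance)
      if (is.null(mm) || !nrow(mm)) next
      diffs <- c(diffs, b$z[mm[, 2]] - a$z[mm[, 1]])
      bids_lo <- c(bids_lo, a$bid[mm[, 1]])
      bids_hi <- c(bids_hi, b$bid[mm[, 2]])
    }
    if (length(diffs) < min_pairs) {
      message("matched_bid_comparison: ", pl, " skipped (",
              length(diffs), " matches)")
      return(data.frame(pair = pl, n_matches = length(diffs),
                        bid_dist_p = NA_real_, eliminated = NA,
                        mean_diff = NA_real_, p = NA_real_))
    }
    bp <- suppressWarnings(stats::wilcox.test(bids_lo, bids_hi)$p.value)
    if (bp < 0.05) {
      message("matched_bid_comparison: ", pl,
              " eliminated (matched bid distributions differ, p = ",
              signif(bp, 3), ")")
      return(data.frame(pair = pl, n_matches = length(diffs),
                        bid_dist_p = bp, eliminated = TRUE,
                        mean_diff = mean(diffs), p = NA_real_))
    }
    p <- if (all(diffs == 0)) 1 else
      suppressWarnings(stats::wilcox.test(diffs, mu = 0)$p.value)
    data.frame(pair = pl, n_matches = length(diffs), bid_dist_p = bp,
               eliminated = FALSE, mean_diff = mean(diffs), p = p)
  })
  res <- do.call(rbind, out)
  class(res) <- c("matched_bid_comparison", "data.frame")
  res
}

#' Movement-parameter control regressions
#'
#' Bidding involves an arm movement, so an apparent bid signal could in
#' principle reflect movement. For each movement covariate (velocity,
#' absement, and their unsigned magnitudes), the response-on-covariate
#' regression is run per neuron and the number of significant neurons
#' (p < 0.05) is compared against the 5% chance level with a one-sided
#' binomial test.
#'
#' @param rt a `response_table`.
#' @param covariates base covariate columns (unsigned variants are added).
#' @param alpha per-neuron significance level.
#' @return data.frame: per covariate, `n_significant`, `n_neurons`,
#'   `fraction`, `binom_p` (one-sided, against 5%), `exceeds_chance`.
#' @export
movement_control_regressions <- function(rt,
                                         covariates = c("velocity",
                                                        "absement"),
                                         alpha = 0.05) {
  stopifnot(inherits(rt, "response_table"))
  covs <- c(covariates, paste0("unsigned_", covariates))
  res <- lapply(covs, function(cv) {
    base <- sub("^unsigned_", "", cv)
    sig <- vapply(split(rt, rt$neuron_id), function(d) {
      x <- d[[base]]
      if (startsWith(cv, "unsigned_")) x <- abs(x)
      if (stats::sd(x) == 0) return(FALSE)
      sm <- summary(stats::lm(d$z ~ x))$coefficients
      nrow(sm) > 1 && sm[2, 4] < alpha
    }, TRUE)
    n <- length(sig); k <- sum(sig)
    bp <- stats::binom.test(k, n, 0.05, alternative = "greater")$p.value
    data.frame(covariate = cv, n_significant = k, n_neurons = n,
               fraction = k / n, binom_p = bp, exceeds_chance = bp < 0.05)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
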