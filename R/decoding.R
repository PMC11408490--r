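#' Build a balanced pseudo-population for decoding
#'
#' Neurons recorded in different sessions are combined into pseudo-trials:
#' bids are discretized into `n_bins` equal-width, non-overlapping ranges
#' spanning the bid space, and for each neuron `trials_per_bin` trials are
#' drawn at random without replacement from each bin, giving
#' `n_bins * trials_per_bin` pseudo-trials (100 by default). Neurons lacking
#' `trials_per_bin` trials in any bin cannot be balanced and are excluded with
#' a named log entry.
#'
#' @param rt a `response_table` (z-normalized responses are used as decoder
#'   features).
#' @param n_bins number of bid bins (default 10).
#' @param trials_per_bin trials sampled per neuron per bin (default 10).
#' @param seed RNG seed; the same seed reproduces the identical array.
#' @return object of class `pseudo_population`: `x` (neurons x bins x trials
#'   z-rate array for the initial draw), `bids` (matching actual-bid array),
#'   `pools` (per neuron, per bin, the full candidate trial pools),
#'   `bin_mids`, `neuron_ids`, `excluded`, `n_bins`, `trials_per_bin`.
#' @export
build_pseudopopulation <- function(rt, n_bins = 10L, trials_per_bin = 10L,
                                   seed = 1L) {
  stopifnot(inherits(rt, "response_table"))
  check_bid_fraction(rt$bid[!is.na(rt$bid)], "bids")
  ids <- unique(rt$neuron_id)
  pools <- list(); excluded <- character(0)
  for (id in ids) {
    d <- rt[rt$neuron_id == id & !is.na(rt$bid), ]
    lab <- pmin(n_bins, floor(d$bid * n_bins) + 1L)
    pb <- lapply(seq_len(n_bins), function(b)
      list(z = d$z[lab == b], bid = d$bid[lab == b]))
    if (any(vapply(pb, function(p) length(p$z), 0L) < trials_per_bin)) {
      message("build_pseudopopulation: excluding neuron ", id,
              " (fewer than ", trials_per_bin, " trials in some bid bin)")
      excluded <- c(excluded, id)
      next
    }
    pools[[id]] <- pb
  }
  if (!length(pools))
    stop_domain("no neuron has ", trials_per_bin,
                " trials in every of the ", n_bins, " bid bins")
  pp <- structure(list(pools = pools, neuron_ids = names(pools),
                       excluded = excluded, n_bins = as.integer(n_bins),
                       trials_per_bin = as.integer(trials_per_bin),
                       bin_mids = (seq_len(n_bins) - 0.5) / n_bins),
                  class = "pseudo_population")
  draw <- sample_pseudotrials(pp, seed)
  pp$x <- draw$x
  pp$bids <- draw$bids
  pp
}

#' @export
print.pseudo_population <- function(x, ...) {
  cat("Pseudo-population:", length(x$neuron_ids), "neurons x", x$n_bins,
      "bid bins x", x$trials_per_bin, "trials",
      if (length(x$excluded)) paste0(" (", length(x$excluded),
                                     " neurons excluded)") else "", "\n")
  invisible(x)
}

# fresh balanced draw: arrays [neurons, bins, trials_per_bin]
sample_pseudotrials <- function(pp, seed) {
  n <- length(pp$pools)
  with_seed(seed, {
    x <- array(0, c(n, pp$n_bins, pp$trials_per_bin))
    bids <- array(0, c(n, pp$n_bins, pp$trials_per_bin))
    for (i in seq_len(n)) for (b in seq_len(pp$n_bins)) {
      pool <- pp$pools[[i]][[b]]
      idx <- sample.int(length(pool$z), pp$trials_per_bin)
      x[i, b, ] <- pool$z[idx]
      bids[i, b, ] <- pool$bid[idx]
    }
    list(x = x, bids = bids)
  })
}

# one 5-fold CV on an already-drawn array; returns 5 test-set R^2 values.
# Fold k holds out pseudo-trials {2k-1, 2k} of every bin (2 x n_bins test,
# 8 x n_bins train), a deterministic rotation of the stratified assignment.
decode_cv <- function(x, bids, neuron_idx, target = c("midpoint", "raw"),
                      bin_mids, shuffle = c("none", "global", "within_bin"),
                      shuffle_seed = NULL) {
  target <- match.arg(target)
  shuffle <- match.arg(shuffle)
  nb <- dim(x)[2]; tpb <- dim(x)[3]
  feats <- matrix(0, nb * tpb, length(neuron_idx))
  y <- numeric(nb * tpb)
  bin_of <- integer(nb * tpb)
  trial_of <- integer(nb * tpb)
  r <- 0L
  for (b in seq_len(nb)) for (t in seq_len(tpb)) {
    r <- r + 1L
    feats[r, ] <- x[neuron_idx, b, t]
    y[r] <- if (target == "midpoint") bin_mids[b] else
      mean(bids[neuron_idx, b, t])
    bin_of[r] <- b; trial_of[r] <- t
  }
  if (shuffle != "none") {
    perm <- with_seed(shuffle_seed %||% 0L, {
      if (shuffle == "global") sample.int(length(y)) else {
        p <- seq_along(y)
        for (b in seq_len(nb)) {
          sel <- which(bin_of == b)
          p[sel] <- sel[sample.int(length(sel))]
        }
        p
      }
    })
    y <- y[perm]
  }
  n_folds <- tpb %/% 2L
  vapply(seq_len(n_folds), function(k) {
    test <- trial_of %in% c(2L * k - 1L, 2L * k)
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L)
      stop_domain("fewer than 2 distinct training targets")
    fit <- e1071::svm(feats[!test, , drop = FALSE], ytr,
                      type = "eps-regression", kernel = "linear",
                      scale = FALSE)
    pred <- stats::predict(fit, feats[test, , drop = FALSE])
    yt <- y[test]
    # signed explained variance: squared Pearson correlation of predicted vs
    # actual targets, carrying the sign of the correlation. Chance-level
    # decoding is symmetric around zero and below-chance (anticorrelated)
    # predictions read negative; constant predictions read 0.
    r <- suppressWarnings(stats::cor(pred, yt))
    if (is.na(r)) 0 else sign(r) * r^2
  }, 0)
}

#' Decode bids from a pseudo-population with linear SVR
#'
#' Draws a fresh balanced set of pseudo-trials, then trains a linear
#' epsilon-insensitive support vector regression on 80% of the pseudo-trials
#' (8 trials per bid bin) and tests on the held-out 20% (2 per bin), rotating
#' the held-out pairs deterministically across 5 folds. Performance is the
#' coefficient of determination (explained variance) of predicted versus
#' actual bid targets on the test set; negative values (test predictions
#' worse than the test mean) are reported raw.
#'
#' @param pp a `pseudo_population`.
#' @param n_neurons how many neurons to use (default all); the first
#'   `n_neurons` in `neuron_idx` order.
#' @param neuron_idx integer indices of the neurons to use, in order; default
#'   the population order.
#' @param seed RNG seed for the pseudo-trial draw.
#' @param target regression target: bid-bin midpoint (default) or the mean
#'   raw bid of the pooled trials.
#' @param shuffle `"none"`, `"global"` (permute targets across all
#'   pseudo-trials before training; the shuffled control) or `"within_bin"`.
#' @return numeric vector of 5 per-fold test R-squared values.
#' @export
svr_decode <- function(pp, n_neurons = NULL, neuron_idx = NULL, seed = 1L,
                       target = "midpoint", shuffle = "none") {
  stopifnot(inherits(pp, "pseudo_population"))
  idx <- neuron_idx %||% seq_along(pp$neuron_ids)
  if (!is.null(n_neurons)) {
    if (n_neurons > length(idx))
      stop_domain("n_neurons exceeds available neurons")
    idx <- idx[seq_len(n_neurons)]
  }
  draw <- sample_pseudotrials(pp, seed)
  decode_cv(draw$x, draw$bids, idx, target = target, bin_mids = pp$bin_mids,
            shuffle = shuffle, shuffle_seed = seed + 1L)
}

#' Decoding accuracy from iteration-mean explained variance
#'
#' Headline accuracy in percent: the iteration-mean R-squared clamped below at
#' zero (a shuffled control whose raw mean R-squared is negative reads as 0%
#' accuracy) and scaled to percent.
#'
#' @param mean_r2 mean R-squared value(s).
#' @return accuracy in percent.
#' @export
decode_accuracy <- function(mean_r2) 100 * pmax(0, mean_r2)

#' Decoding curve: accuracy versus neuron count
#'
#' For each neuron count, repeats `n_iterations` times: draw a fresh balanced
#' pseudo-trial set, pick neurons according to the ordering scheme, run the
#' 5-fold SVR protocol, and record the fold-mean R-squared. Ordering
#' `"best_first"` adds neurons from highest to lowest per-neuron bid
#' correlation (upper bound on accuracy), `"worst_first"` the reverse (lower
#' bound), `"random"` draws a fresh random subset each iteration (the typical
#' neuron).
#'
#' @param pp a `pseudo_population`.
#' @param ordering `"random"`, `"best_first"` or `"worst_first"`.
#' @param ranking named numeric vector (per-neuron explained variance from
#'   [select_bid_encoding()], names = neuron ids); required for the ordered
#'   modes.
#' @param n_neurons vector of neuron counts; default `1:length(neurons)`.
#' @param n_iterations iterations per count (default 300).
#' @param seed master seed.
#' @param target,shuffle passed to the decoder (see [svr_decode()]).
#' @return object of class `decoding_curve`: `curve` (data.frame with
#'   `ordering`, `n_neurons`, `mean_r2`, `se_r2`, `accuracy_pct`) and
#'   `iterations` (counts x iterations matrix of fold-mean R-squared).
#' @export
decoding_curve <- function(pp, ordering = c("random", "best_first",
                                            "worst_first"),
                           ranking = NULL, n_neurons = NULL,
                           n_iterations = 300L, seed = 1L,
                           target = "midpoint", shuffle = "none") {
  ordering <- match.arg(ordering)
  stopifnot(inherits(pp, "pseudo_population"))
  n_avail <- length(pp$neuron_ids)
  counts <- n_neurons %||% seq_len(n_avail)
  if (max(counts) > n_avail) stop_domain("n_neurons exceeds available neurons")
  base_order <- seq_len(n_avail)
  if (ordering != "random") {
    if (is.null(ranking)) stop_domain("`ranking` required for ordered modes")
    r <- ranking[pp$neuron_ids]
    if (anyNA(r)) stop_domain("ranking lacks some population neurons")
    base_order <- order(r, decreasing = (ordering == "best_first"))
  }
  iters <- matrix(NA_real_, length(counts), n_iterations,
                  dimnames = list(paste0("n", counts), NULL))
  for (ci in seq_along(counts)) {
    n <- counts[ci]
    for (it in seq_len(n_iterations)) {
      it_seed <- derive_seed(seed, sprintf("%s-%d-%d", ordering, n, it))
      idx <- if (ordering == "random")
        with_seed(it_seed + 1L, sample(base_order, n))
      else base_order[seq_len(n)]
      r2 <- svr_decode(pp, neuron_idx = idx, seed = it_seed,
                       target = target, shuffle = shuffle)
      iters[ci, it] <- mean(r2)
    }
  }
  curve <- data.frame(ordering = ordering, n_neurons = counts,
                      mean_r2 = rowMeans(iters),
                      se_r2 = apply(iters, 1, stats::sd) /
                        sqrt(n_iterations))
  curve$accuracy_pct <- decode_accuracy(curve$mean_r2)
  structure(list(curve = curve, iterations = iters, ordering = ordering,
                 shuffle = shuffle, n_iterations = n_iterations,
                 seed = seed),
            class = "decoding_curve")
}

#' @export
print.decoding_curve <- function(x, ...) {
  cat("Decoding curve (", x$ordering,
      if (x$shuffle != "none") ", shuffled" else "", ", ",
      x$n_iterations, " iterations):\n", sep = "")
  print(transform(x$curve, mean_r2 = signif(mean_r2, 3),
                  se_r2 = signif(se_r2, 2),
                  accuracy_pct = round(accuracy_pct, 1)),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.decoding_curve <- function(x, ylim = NULL, col = "navy", add = FALSE,
                                ...) {
  cv <- x$curve
  ylim <- ylim %||% range(c(cv$mean_r2 - cv$se_r2, cv$mean_r2 + cv$se_r2, 0))
  if (!add)
    graphics::plot(cv$n_neurons, cv$mean_r2, type = "n", ylim = ylim,
                   xlab = "Number of neurons",
                   ylab = expression(R^2 ~ "(decoded vs actual bids)"), ...)
  graphics::lines(cv$n_neurons, cv$mean_r2, col = col, lwd = 2)
  graphics::arrows(cv$n_neurons, cv$mean_r2 - cv$se_r2,
                   cv$n_neurons, cv$mean_r2 + cv$se_r2,
                   angle = 90, code = 3, length = 0.02, col = col)
  invisible(x)
}

#' Shuffled-control decoding curve
#'
#' Runs [decoding_curve()] with the response-bid pairing broken by a global
#' permutation of the targets before training. The resulting accuracy is the
#' chance floor of the protocol.
#'
#' @inheritParams decoding_curve
#' @param ... passed to [decoding_curve()].
#' @return a `decoding_curve` (with `shuffle = "global"`).
#' @export
shuffled_control <- function(pp, ...) {
  decoding_curve(pp, shuffle = "global", ...)
}

#' Standard shuffled-decoding chance benchmark
#'
#' Runs the full chance-level protocol end to end: simulate the `"decoding"`
#' study scenario, fit 20 bid-coding neurons (30 candidates are simulated and
#' the first 20 that satisfy the 10-trials-per-bid-tenth balance requirement
#' are used), build the 10-bin x 10-trial pseudo-population, break the
#' response-bid pairing by a global permutation of the targets, and run the
#' 5-fold linear-SVR protocol for `n_iterations` fresh resamples. Reports the
#' raw iteration-mean explained variance and the clamped accuracy in percent.
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param n_neurons population size (default 20).
#' @param n_iterations resampling iterations (default 300).
#' @param shuffle set `"none"` to run the same protocol without shuffling.
#' @return list: `mean_r2`, `accuracy_pct`, `n_iterations`, `n_neurons`,
#'   `curve` (the underlying `decoding_curve`).
#' @export
shuffled_decoding_control <- function(seed = 1L, n_neurons = 20L,
                                      n_iterations = 300L,
                                      shuffle = "global") {
  beh <- simulate_behavior(study_scenario("decoding"),
                           seed = derive_seed(seed, "beh"))
  # simulate candidate neurons in batches until n_neurons satisfy the
  # 10-trials-per-bid-tenth balance requirement (recording continues until
  # enough includable neurons are collected)
  rt <- NULL
  batch <- 0L
  repeat {
    batch <- batch + 1L
    pop <- simulate_population(beh, n_bid = n_neurons + 10L, n_none = 0L,
                               seed = derive_seed(seed,
                                                  paste0("pop", batch)))
    rtb <- response_table(pop, analysis_window(180, 340))
    rtb$neuron_id <- paste0("b", batch, "_", rtb$neuron_id)
    rt <- if (is.null(rt)) rtb else rbind(rt, rtb)
    class(rt) <- c("response_table", "data.frame")
    pp <- suppressMessages(
      build_pseudopopulation(rt, seed = derive_seed(seed, "pp")))
    if (length(pp$neuron_ids) >= n_neurons) break
    if (batch >= 5L)
      stop_domain("only ", length(pp$neuron_ids),
                  " neurons satisfy the balance requirement")
  }
  dc <- decoding_curve(pp, "random", n_neurons = n_neurons,
                       n_iterations = n_iterations,
                       seed = derive_seed(seed, "decode"),
                       shuffle = shuffle)
  list(mean_r2 = dc$curve$mean_r2, accuracy_pct = dc$curve$accuracy_pct,
       n_iterations = n_iterations, n_neurons = n_neurons, curve = dc)
}

#' Compare real against shuffled decoding
#'
#' Two-sided Wilcoxon rank-sum test of the iteration-level R-squared
#' distributions, real versus shuffled, at each matched neuron count.
#'
#' @param real,shuffled `decoding_curve` objects with matching neuron counts.
#' @return data.frame: `n_neurons`, `p`, `real_mean_r2`, `shuffled_mean_r2`.
#' @export
compare_real_vs_shuffled <- function(real, shuffled) {
  stopifnot(inherits(real, "decoding_curve"),
            inherits(shuffled, "decoding_curve"),
            identical(real$curve$n_neurons, shuffled$curve$n_neurons))
  out <- lapply(seq_len(nrow(real$curve)), function(i) {
    p <- suppressWarnings(stats::wilcox.test(real$iterations[i, ],
                                             shuffled$iterations[i, ])$p.value)
    data.frame(n_neurons = real$curve$n_neurons[i], p = p,
               real_mean_r2 = real$curve$mean_r2[i],
               shuffled_mean_r2 = shuffled$curve$mean_r2[i])
  })
  do.call(rbind, out)
}
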