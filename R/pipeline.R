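#' Run configuration for an end-to-end pipeline run
#'
#' Bundles everything a full run needs: the subject configuration, neuron
#' counts, analysis toggles, the decoding protocol size and a single master
#' seed from which every stochastic stage derives its own seed (full-run
#' determinism). The default `profile = "smoke"` uses 30 decoding iterations
#' and 10 neurons for fast checks; `profile = "full"` uses the complete
#' 300-iteration protocol.
#'
#' @param subject a [subject_config()].
#' @param n_bid,n_magnitude,n_none neuron counts.
#' @param window `NULL` to auto-detect the value window, or an
#'   [analysis_window()] override.
#' @param profile `"smoke"` or `"full"`.
#' @param n_iterations decoding iterations (overrides the profile).
#' @param decode_counts neuron counts for the decoding curve (default a
#'   spread up to the population size).
#' @param seed master seed.
#' @param out_dir output directory, or `NULL` to skip file output.
#' @return object of class `run_config`.
#' @export
run_config <- function(subject = monkey_v_config(),
                       n_bid = 10L, n_magnitude = 0L, n_none = 5L,
                       window = NULL,
                       profile = c("smoke", "full"),
                       n_iterations = NULL,
                       decode_counts = NULL,
                       seed = 1L,
                       out_dir = NULL) {
  profile <- match.arg(profile)
  n_iterations <- n_iterations %||% switch(profile, smoke = 30L, full = 300L)
  structure(list(subject = subject, n_bid = n_bid,
                 n_magnitude = n_magnitude, n_none = n_none,
                 window = window, profile = profile,
                 n_iterations = as.integer(n_iterations),
                 decode_counts = decode_counts, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with fields matching [run_config()] arguments;
#'   `subject` is a list of [subject_config()] arguments and
#'   `subject$agent` of [agent_params()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  agent <- do.call(agent_params, as.list(j$subject$agent %||% list()))
  sargs <- j$subject[setdiff(names(j$subject), "agent")]
  subject <- do.call(subject_config, c(sargs, list(agent = agent)))
  win <- if (!is.null(j$window))
    analysis_window(j$window$start_ms, j$window$end_ms)
  args <- j[setdiff(names(j), c("subject", "window"))]
  do.call(run_config, c(list(subject = subject, window = win), args))
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] done in %.1f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' Generate -> behavior -> neural -> decode -> report. Generates synthetic
#' sessions and rasters, runs the behavioral value models (lasso selection,
#' the three mixed-effects models, rank-order and coherence checks), the
#' neuronal analyses (dopamine-like classification, value-window detection,
#' bid-encoding selection, matched-bid comparisons, movement controls) and
#' the pseudo-population SVR decoding with shuffled control, and assembles a
#' single report. With `out_dir` set, stage outputs are written as TSV/JSON
#' plus a manifest with every derived seed and package version.
#'
#' With zero neurons configured, the neural and decoding stages are skipped
#' with a notice and the behavioral results are still produced.
#'
#' @param cfg a [run_config()].
#' @return list of class `bdm_run_report` with elements `behavior`,
#'   `neural`, `decoding` and `manifest`.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  seeds <- list(behavior = derive_seed(cfg$seed, "behavior"),
                population = derive_seed(cfg$seed, "population"),
                pseudopop = derive_seed(cfg$seed, "pseudopop"),
                lasso = derive_seed(cfg$seed, "lasso"),
                decode = derive_seed(cfg$seed, "decode"))
  n_neurons <- cfg$n_bid + cfg$n_magnitude + cfg$n_none

  beh <- stage("generate", simulate_behavior(cfg$subject,
                                             seed = seeds$behavior))

  behavior <- stage("behavior", {
    X <- build_regressors(beh$trials)
    las <- lasso_select(X, seed = seeds$lasso)
    mm <- lapply(1:3, function(i) fit_mixed_model(beh$trials, i))
    list(lasso = las,
         mixed = mm,
         rank_order = rank_order_check(beh$trials),
         coherence = bid_coherence(beh$trials))
  })

  neural <- NULL; decoding <- NULL
  if (n_neurons == 0L) {
    message("no neurons configured; skipping neural and decoding stages")
  } else {
    pop <- stage("simulate-neurons",
                 simulate_population(beh, cfg$n_bid, cfg$n_magnitude,
                                     cfg$n_none, seed = seeds$population))
    neural <- stage("neural", {
      cls <- lapply(pop$rasters, classify_dopamine)
      detection <- NULL
      win <- cfg$window
      if (is.null(win)) {
        detection <- detect_value_window(
          population_traces(pop, "low"), population_traces(pop, "high"))
        if (detection$status != "ok")
          stop("value-window detection failed (", detection$status,
               "); supply `window` explicitly")
        win <- detection$window
      }
      rt <- response_table(pop, win)
      enc <- select_bid_encoding(rt)
      list(classification = data.frame(
             neuron_id = vapply(pop$rasters, `[[`, "", "neuron_id"),
             is_dopamine = vapply(cls, `[[`, TRUE, "is_dopamine")),
           window = win, detection = detection, responses = rt,
           encoding = enc,
           matched_bids = matched_bid_comparison(rt),
           movement = movement_control_regressions(rt))
    })
    decoding <- stage("decode", {
      rt <- neural$responses
      enc_ids <- neural$encoding$neuron_id[neural$encoding$selected]
      rt_enc <- rt[rt$neuron_id %in% enc_ids, ]
      class(rt_enc) <- class(rt)
      if (length(unique(rt_enc$neuron_id)) < 2L) {
        message("fewer than 2 bid-encoding neurons; decoding skipped")
        NULL
      } else {
        pp <- build_pseudopopulation(rt_enc, seed = seeds$pseudopop)
        n_avail <- length(pp$neuron_ids)
        counts <- cfg$decode_counts %||%
          unique(pmin(n_avail, c(1, 2, 5, 10, 15, 20)))
        ranking <- stats::setNames(neural$encoding$r2,
                                   neural$encoding$neuron_id)
        real <- decoding_curve(pp, "random", n_neurons = counts,
                               n_iterations = cfg$n_iterations,
                               seed = seeds$decode)
        shuf <- shuffled_control(pp, ordering = "random",
                                 n_neurons = counts,
                                 n_iterations = cfg$n_iterations,
                                 seed = seeds$decode)
        list(pseudopopulation = pp, real = real, shuffled = shuf,
             ranking = ranking,
             comparison = compare_real_vs_shuffled(real, shuf))
      }
    })
  }

  manifest <- list(seed = cfg$seed, derived_seeds = seeds,
                   profile = cfg$profile,
                   n_iterations = cfg$n_iterations,
                   package_version =
                     as.character(utils::packageVersion("bdmvalue")))
  report <- structure(list(behavior = behavior, neural = neural,
                           decoding = decoding, manifest = manifest,
                           trials = beh$trials),
                      class = "bdm_run_report")
  if (!is.null(cfg$out_dir)) write_run_report(report, cfg$out_dir)
  report
}

#' @export
print.bdm_run_report <- function(x, ...) {
  cat("BDM pipeline run (seed", x$manifest$seed, ")\n\n")
  print(x$behavior$rank_order)
  cat("Lasso-selected variables:",
      paste(x$behavior$lasso$selected, collapse = ", "), "\n")
  if (!is.null(x$neural)) {
    cat(sprintf("\nNeurons: %d/%d dopamine-like; %d bid-encoding; window %d-%d ms\n",
                sum(x$neural$classification$is_dopamine),
                nrow(x$neural$classification),
                sum(x$neural$encoding$selected),
                x$neural$window$start_ms, x$neural$window$end_ms))
  }
  if (!is.null(x$decoding)) {
    top <- x$decoding$real$curve[nrow(x$decoding$real$curve), ]
    cat(sprintf("Decoding: %.0f%% accuracy at %d neurons (shuffled: %.0f%%)\n",
                top$accuracy_pct, top$n_neurons,
                x$decoding$shuffled$curve$accuracy_pct[
                  nrow(x$decoding$shuffled$curve)]))
  }
  invisible(x)
}

# serialize the report to TSV/JSON stage outputs plus a JSON summary
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$trials, file.path(out_dir, "trials.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    manifest = report$manifest,
    lasso_selected = report$behavior$lasso$selected,
    mixed_models = lapply(report$behavior$mixed, function(m)
      list(model_id = m$model_id, adj_r2 = m$adj_r2, n = m$n,
           converged = m$converged, fixed = m$fixed)),
    rank_order = report$behavior$rank_order$pooled,
    coherence = report$behavior$coherence$within)
  if (!is.null(report$neural)) {
    utils::write.table(report$neural$responses,
                       file.path(out_dir, "responses.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$neural$encoding,
                       file.path(out_dir, "bid_encoding.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$window <- unclass(report$neural$window)
    summary$n_dopamine <- sum(report$neural$classification$is_dopamine)
    summary$n_bid_encoding <- sum(report$neural$encoding$selected)
    summary$matched_bids <- report$neural$matched_bids
    summary$movement <- report$neural$movement
  }
  if (!is.null(report$decoding)) {
    utils::write.table(rbind(report$decoding$real$curve,
                             transform(report$decoding$shuffled$curve,
                                       ordering = "random-shuffled")),
                       file.path(out_dir, "decoding_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$decoding <- list(real = report$decoding$real$curve,
                             shuffled = report$decoding$shuffled$curve,
                             comparison = report$decoding$comparison)
  }
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Validate on-disk input files
#'
#' Checks a trial table (and optionally raster files) against the expected
#' column dictionary, unit ranges (bids and computer bids in `[0, 1]`,
#' volumes non-negative) and task event-time ordering. Raster lines must be
#' `trial_id<TAB>comma-separated spike times (ms)` with times inside the
#' raster span.
#'
#' @param trials_path path to a trial TSV.
#' @param raster_paths optional character vector of raster TSV paths.
#' @return list of class `schema_report`: `ok` (logical) and `problems`
#'   (character vector).
#' @export
validate_inputs <- function(trials_path, raster_paths = NULL) {
  problems <- character(0)
  tr <- tryCatch(utils::read.delim(trials_path),
                 error = function(e) {
                   problems <<- c(problems,
                                  paste("cannot read trial table:",
                                        conditionMessage(e)))
                   NULL
                 })
  if (!is.null(tr)) {
    need <- c("session_id", "trial_index", "magnitude_level", "magnitude_ml",
              "starting_bid", "bid", "computer_bid", "result", "juice_ml",
              "water_ml", "day_of_week")
    miss <- setdiff(need, names(tr))
    if (length(miss))
      problems <- c(problems, paste("missing trial columns:",
                                    paste(miss, collapse = ", ")))
    ok_rows <- !is.na(tr$bid)
    if (any(tr$bid[ok_rows] < 0 | tr$bid[ok_rows] > 1, na.rm = TRUE))
      problems <- c(problems, "bids outside [0, 1]")
    if (!is.null(tr$computer_bid) &&
        any(tr$computer_bid < 0 | tr$computer_bid > 1, na.rm = TRUE))
      problems <- c(problems, "computer bids outside [0, 1]")
    if (!is.null(tr$juice_ml) && any(tr$juice_ml < 0, na.rm = TRUE))
      problems <- c(problems, "negative juice volumes")
    tcols <- c("t_trial_start", "t_fractal", "t_bidspace", "t_bid_stable",
               "t_reveal")
    if (all(tcols %in% names(tr))) {
      tm <- as.matrix(tr[, tcols])
      if (any(apply(tm, 1, function(r) any(diff(r) <= 0)), na.rm = TRUE))
        problems <- c(problems, "event times out of task order")
    }
  }
  for (rp in raster_paths %||% character(0)) {
    lines <- tryCatch(readLines(rp), error = function(e) NULL)
    if (is.null(lines)) {
      problems <- c(problems, paste("cannot read raster:", rp))
      next
    }
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(parts, function(p) {
      if (length(p) < 1L) return(TRUE)
      if (length(p) == 1L || !nzchar(p[2])) return(FALSE)  # silent trial
      t <- suppressWarnings(as.numeric(strsplit(p[2], ",")[[1]]))
      anyNA(t) || any(t < RASTER_SPAN[1] | t >= RASTER_SPAN[2])
    }, TRUE)
    if (any(bad))
      problems <- c(problems,
                    paste0(rp, ": malformed/out-of-span spike times on ",
                           sum(bad), " line(s)"))
  }
  structure(list(ok = length(problems) == 0L, problems = problems),
            class = "schema_report")
}

#' @export
print.schema_report <- function(x, ...) {
  if (x$ok) cat("inputs valid\n")
  else cat("input problems:\n", paste("-", x$problems, collapse = "\n"), "\n")
  invisible(x)
}
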