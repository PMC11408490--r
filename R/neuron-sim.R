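#' Dopamine-like neuron model
#'
#' Generative model of the canonical two-component phasic response of midbrain
#' dopamine neurons to a reward-predicting cue: a short value-independent
#' "attentional" excitation reflecting stimulus detection, followed by a
#' "value" component whose rate encodes the reward prediction error of the
#' trial's signal relative to the mean prediction carried by the preceding
#' trial-start cue. Negative prediction errors depress the rate, floored at
#' 0 Hz; spike counts are Poisson in 1 ms bins.
#'
#' @param baseline_rate baseline firing rate in Hz (dopamine-like: < 10).
#' @param waveform_width_ms extracellular impulse width in ms (dopamine-like:
#'   > 1.8).
#' @param attentional list with `latency_ms`, `duration_ms`, `amplitude_hz`
#'   for the first, value-independent component.
#' @param value_component list with `latency_ms`, `duration_ms`, `gain_hz`
#'   (Hz per unit prediction error in bid-space units) for the second
#'   component.
#' @param coding_target `"bid"` (rate follows the trial's upcoming bid),
#'   `"magnitude"` (rate follows the magnitude level's mean value) or
#'   `"none"` (no value signal).
#' @return object of class `neuron_model`.
#' @export
neuron_model <- function(baseline_rate = 5,
                         waveform_width_ms = 2.5,
                         attentional = list(latency_ms = 90, duration_ms = 90,
                                            amplitude_hz = 12),
                         value_component = list(latency_ms = 180,
                                                duration_ms = 160,
                                                gain_hz = 25),
                         coding_target = c("bid", "magnitude", "none")) {
  coding_target <- match.arg(coding_target)
  stopifnot(baseline_rate >= 0, waveform_width_ms > 0,
            value_component$latency_ms >=
              attentional$latency_ms + attentional$duration_ms)
  structure(list(baseline_rate = baseline_rate,
                 waveform_width_ms = waveform_width_ms,
                 attentional = attentional,
                 value_component = value_component,
                 coding_target = coding_target),
            class = "neuron_model")
}

RASTER_SPAN <- c(-500L, 1000L)  # ms around fractal onset, 1 ms bins

# the per-trial value signal a neuron responds to, in bid-space units
neuron_signal <- function(model, trials) {
  switch(model$coding_target,
    bid = trials$bid,
    magnitude = {
      # magnitude coder: responds to the level's mean subjective value
      m <- tapply(trials$bid, trials$magnitude_level, mean)
      as.numeric(m[as.character(trials$magnitude_level)])
    },
    none = rep(0, nrow(trials))
  )
}

#' Simulate a spike raster for one neuron
#'
#' Produces 1 ms-binned Poisson spike counts from `-500` to `+1000` ms around
#' fractal onset for every non-failed trial in `trials`. Inside the value
#' window the rate is `baseline + gain * (signal - mean_prediction)`; the
#' prediction error is referenced to `mean_prediction`, the across-trial mean
#' value at the trial-start cue.
#'
#' @param model a [neuron_model()].
#' @param trials trial data.frame from [simulate_behavior()] (one session or a
#'   subset; failed trials are dropped).
#' @param mean_prediction prediction baseline in bid-space units; defaults to
#'   the mean of the neuron's signal across the supplied trials.
#' @param seed integer seed.
#' @param neuron_id identifier stored in the raster.
#' @return object of class `spike_raster`: list with `counts` (trials x 1500
#'   integer matrix), `times_ms` (bin left edges), `trials` (the trial rows
#'   used), `model`, `mean_prediction`, `neuron_id`.
#' @export
simulate_neuron <- function(model, trials, mean_prediction = NULL, seed = 1L,
                            neuron_id = "n1") {
  stopifnot(inherits(model, "neuron_model"), is.data.frame(trials))
  trials <- trials[trials$result != "failed" & !is.na(trials$bid), ,
                   drop = FALSE]
  sig <- neuron_signal(model, trials)
  if (is.null(mean_prediction)) mean_prediction <- mean(sig)
  times <- seq(RASTER_SPAN[1], RASTER_SPAN[2] - 1L)
  nt <- nrow(trials); nb <- length(times)
  att <- model$attentional; val <- model$value_component
  in_att <- times >= att$latency_ms & times < att$latency_ms + att$duration_ms
  in_val <- times >= val$latency_ms & times < val$latency_ms + val$duration_ms
  with_seed(seed, {
    counts <- matrix(0L, nt, nb)
    base_prof <- rep(model$baseline_rate, nb)
    base_prof[in_att] <- base_prof[in_att] + att$amplitude_hz
    for (i in seq_len(nt)) {
      rate <- base_prof
      pe <- sig[i] - mean_prediction
      rate[in_val] <- rate[in_val] + val$gain_hz * pe
      rate <- pmax(rate, 0)
      counts[i, ] <- rpois(nb, rate / 1000)
    }
    structure(list(counts = counts, times_ms = times, trials = trials,
                   model = model, mean_prediction = mean_prediction,
                   neuron_id = neuron_id),
              class = "spike_raster")
  })
}

#' @export
print.spike_raster <- function(x, ...) {
  cat("Spike raster", x$neuron_id, ":", nrow(x$counts), "trials x",
      ncol(x$counts), "1-ms bins;",
      sprintf("coding=%s, baseline=%.1f Hz\n",
              x$model$coding_target, x$model$baseline_rate))
  invisible(x)
}

#' Simulate a population of neurons over behavioral sessions
#'
#' Assigns each neuron to one session (cycling through sessions) and simulates
#' its raster on that session's trials. Per-neuron value gains are jittered
#' multiplicatively to create the encoding heterogeneity that neuron-ordering
#' analyses rely on.
#'
#' @param behavior a `bdm_behavior` object.
#' @param n_bid,n_magnitude,n_none neuron counts per coding target.
#' @param model template [neuron_model()].
#' @param gain_jitter range of the multiplicative gain factor, drawn uniformly
#'   per neuron; `c(1, 1)` disables jitter.
#' @param seed integer seed.
#' @return list of class `neuron_population`: `rasters` (list of
#'   `spike_raster`) and `truth` (data.frame of per-neuron ground truth).
#' @export
simulate_population <- function(behavior, n_bid = 20L, n_magnitude = 0L,
                                n_none = 0L, model = neuron_model(),
                                gain_jitter = c(0.5, 1.5), seed = 1L) {
  stopifnot(inherits(behavior, "bdm_behavior"))
  targets <- rep(c("bid", "magnitude", "none"),
                 times = c(n_bid, n_magnitude, n_none))
  n <- length(targets)
  sessions <- sort(unique(behavior$trials$session_id))
  with_seed(seed, {
    gains <- runif(n, gain_jitter[1], gain_jitter[2]) *
      model$value_component$gain_hz
    seeds <- sample.int(2^30, n)
    rasters <- vector("list", n)
    for (i in seq_len(n)) {
      m <- model
      m$coding_target <- targets[i]
      m$value_component$gain_hz <- gains[i]
      sess <- sessions[((i - 1L) %% length(sessions)) + 1L]
      tr <- behavior$trials[behavior$trials$session_id == sess, ]
      rasters[[i]] <- simulate_neuron(m, tr, seed = seeds[i],
                                      neuron_id = sprintf("n%03d", i))
    }
    truth <- data.frame(neuron_id = vapply(rasters, `[[`, "", "neuron_id"),
                        coding_target = targets, gain_hz = gains,
                        session_id = sessions[((seq_len(n) - 1L) %%
                                                 length(sessions)) + 1L],
                        baseline_rate = model$baseline_rate,
                        waveform_width_ms = model$waveform_width_ms)
    structure(list(rasters = rasters, truth = truth, seed = seed),
              class = "neuron_population")
  })
}

#' @export
print.neuron_population <- function(x, ...) {
  cat("Neuron population:", length(x$rasters), "neurons (",
      paste(names(table(x$truth$coding_target)),
            table(x$truth$coding_target), collapse = ", "), ")\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes, for each configured subject, a TSV trial table, one TSV raster per
#' neuron (`trial_id<TAB>comma-separated spike times in ms relative to fractal
#' onset`) and a JSON ground-truth manifest with all generating parameters.
#' Output is byte-identical across runs at a fixed seed.
#'
#' @param out_dir output directory (created if missing).
#' @param subjects list of [subject_config()] objects.
#' @param n_bid,n_magnitude,n_none neuron counts per subject and coding target.
#' @param model template [neuron_model()].
#' @param seed master seed.
#' @return invisibly, the manifest list.
#' @export
generate_dataset <- function(out_dir, subjects = list(monkey_v_config(),
                                                      monkey_u_config()),
                             n_bid = 10L, n_magnitude = 0L, n_none = 0L,
                             model = neuron_model(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, subjects = list())
  for (cfg in subjects) {
    beh <- simulate_behavior(cfg, seed = derive_seed(seed,
                                                     paste0("beh-", cfg$name)))
    pop <- simulate_population(beh, n_bid, n_magnitude, n_none, model,
                               seed = derive_seed(seed,
                                                  paste0("pop-", cfg$name)))
    tt_path <- file.path(out_dir, sprintf("trials_%s.tsv", cfg$name))
    ok <- tryCatch({
      utils::write.table(beh$trials, tt_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("failed writing trial table at ", tt_path, ": ",
           conditionMessage(ok))
    for (r in pop$rasters) {
      lines <- vapply(seq_len(nrow(r$counts)), function(i) {
        spikes <- r$times_ms[r$counts[i, ] > 0]
        # repeat times for bins with >1 spike
        spikes <- rep(spikes, r$counts[i, r$counts[i, ] > 0])
        paste0(r$trials$trial_index[i], "\t",
               paste(spikes, collapse = ","))
      }, "")
      writeLines(lines, file.path(out_dir,
                                  sprintf("raster_%s_%s.tsv", cfg$name,
                                          r$neuron_id)))
    }
    manifest$subjects[[cfg$name]] <- list(
      config = unclass_config(cfg),
      behavior_seed = derive_seed(seed, paste0("beh-", cfg$name)),
      population_seed = derive_seed(seed, paste0("pop-", cfg$name)),
      neurons = pop$truth)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$agent <- unclass(out$agent)
  out
}
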