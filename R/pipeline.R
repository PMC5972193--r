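#' Default pipeline configuration
#'
#' One nested list with a section per stage (`task`, `agent`, `lfp`,
#' `preproc`, `spectral`, `discriminant`, `contrasts`) plus the run seed and
#' output directory. The defaults reproduce the analysis-chain parameters
#' used throughout the package: 512 Hz, -4000..+2000 ms feedback-locked
#' epochs, -2000..0 ms baseline, 50 ms discriminant windows from -200 to
#' 600 ms in 10 ms steps, 1000 label randomizations at alpha = 0.01.
#' `discriminant$bootstrap_step_ms` subsamples the window grid used for the
#' bootstrap null only.
#'
#' @return Nested configuration list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = NULL,
    task = list(n_rules = 9L, criterion_run = 6L, max_trials_per_rule = 50L,
                feedback_duration = 0.5, inter_trial_onset_gap = 2.7),
    agent = list(p_asymptote = 0.9, learn_rate = 0.5, lapse = 0.1,
                 rt_lognormal_mu = log(940), rt_lognormal_sigma = 0.45,
                 rt_post_error_shift = 0.11),
    lfp = list(fs = 2500, noise_scale = 5, effect_scale = 1,
               n_sessions = 4L),
    preproc = list(notch_freqs = c(50, 100, 150), notch_q = 35,
                   resample_fs = 512, epoch_window_ms = c(-4000, 2000),
                   baseline_ms = c(-2000, 0)),
    spectral = list(freq_range = c(3, 100), n_freqs = 40, cycles_at_min = 3,
                    cycle_expansion = 0.5, ersp_baseline_ms = c(-2000, 0),
                    n_permutations = 1000, alpha = 0.05,
                    theta_band = c(3, 8), time_decim = 8,
                    stat_time_range_ms = c(-500, 1000),
                    stimulus_stat_time_range_ms = c(-500, 600)),
    discriminant = list(window_ms = 50, center_start_ms = -200,
                        center_end_ms = 600, center_step_ms = 10,
                        n_bootstrap = 1000, alpha = 0.01, l2_lambda = 1e-3,
                        bootstrap_step_ms = 100, min_separation_ms = 100),
    contrasts = list(outcome = TRUE, novelty = TRUE)),
    class = "run_config")
}

# recursive unknown-key check; returns character vector of dotted paths
.unknown_keys <- function(cfg, ref, prefix = "") {
  bad <- character(0)
  for (nm in names(cfg)) {
    path <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (!nm %in% names(ref)) {
      bad <- c(bad, path)
    } else if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) &&
               is.list(cfg[[nm]])) {
      bad <- c(bad, .unknown_keys(cfg[[nm]], ref[[nm]], path))
    }
  }
  bad
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a JSON configuration (or takes a list), fills every missing field
#' from [default_run_config()], rejects unknown keys, and enforces
#' cross-field invariants (baseline windows inside epoch windows, resampling
#' rate not above the acquisition rate, discriminant windows inside the
#' epoch). All violations are reported together, not first-only.
#'
#' @param config Path to a JSON file, a list, or `NULL`/empty for pure
#'   defaults.
#' @return The normalized `run_config`.
#' @export
validate_config <- function(config = NULL) {
  def <- default_run_config()
  if (is.character(config)) {
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (nzchar(trimws(txt)))
      jsonlite::fromJSON(txt, simplifyVector = TRUE) else list()
  }
  if (is.null(config)) config <- list()
  stopifnot(is.list(config))

  errors <- character(0)
  bad <- .unknown_keys(config, def)
  if (length(bad))
    errors <- c(errors, paste0("unknown config key: ", bad))

  cfg <- modifyList(unclass(def), config)

  with(cfg, {
    if (preproc$baseline_ms[1] < preproc$epoch_window_ms[1] ||
        preproc$baseline_ms[2] > preproc$epoch_window_ms[2])
      errors <<- c(errors, "preproc.baseline_ms must lie inside preproc.epoch_window_ms")
    if (preproc$resample_fs > lfp$fs)
      errors <<- c(errors, "preproc.resample_fs must not exceed lfp.fs")
    if (spectral$ersp_baseline_ms[1] < preproc$epoch_window_ms[1] ||
        spectral$ersp_baseline_ms[2] > preproc$epoch_window_ms[2])
      errors <<- c(errors, "spectral.ersp_baseline_ms must lie inside the epoch window")
    if (discriminant$center_start_ms - discriminant$window_ms / 2 <
        preproc$epoch_window_ms[1] ||
        discriminant$center_end_ms + discriminant$window_ms / 2 >
        preproc$epoch_window_ms[2])
      errors <<- c(errors, "discriminant window grid must lie inside the epoch window")
    if (task$criterion_run > task$max_trials_per_rule)
      errors <<- c(errors, "task.criterion_run must not exceed task.max_trials_per_rule")
  })
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "),
         call. = FALSE)
  structure(cfg, class = "run_config")
}

.dcfg_from_run <- function(cfg, seed) {
  dc <- cfg$discriminant
  centers_bs <- seq(dc$center_start_ms, dc$center_end_ms,
                    by = dc$bootstrap_step_ms)
  discriminant_config(window_ms = dc$window_ms,
                      center_start_ms = dc$center_start_ms,
                      center_end_ms = dc$center_end_ms,
                      center_step_ms = dc$center_step_ms,
                      n_bootstrap = dc$n_bootstrap, alpha = dc$alpha,
                      l2_lambda = dc$l2_lambda,
                      bootstrap_centers = centers_bs,
                      min_separation_ms = dc$min_separation_ms, seed = seed)
}

.scfg_from_run <- function(cfg) {
  sp <- cfg$spectral
  spectral_config(freq_range = sp$freq_range, n_freqs = sp$n_freqs,
                  cycles_at_min = sp$cycles_at_min,
                  cycle_expansion = sp$cycle_expansion,
                  ersp_baseline_ms = sp$ersp_baseline_ms,
                  n_permutations = sp$n_permutations, alpha = sp$alpha,
                  theta_band = sp$theta_band, time_decim = sp$time_decim,
                  stat_time_range_ms = sp$stat_time_range_ms)
}

.sig_fraction <- function(contrast, channel, band = NULL) {
  m <- contrast$mask[channel, , ]
  v <- !is.na(contrast$p_values[channel, , ])
  if (!is.null(band)) {
    rows <- contrast$freqs >= band[1] & contrast$freqs <= band[2]
    m <- m[rows, , drop = FALSE]; v <- v[rows, , drop = FALSE]
  }
  sum(m, na.rm = TRUE) / max(sum(v), 1)
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> spectral contrasts -> discriminant ->
#' behaviour, with deterministic sub-seeds derived from the run seed.
#' Several behavioural sessions (`lfp$n_sessions`) are simulated and their
#' epochs pooled, mirroring the pooling of subjects' trials. When an output
#' directory is configured, the event table, Az curve, spatial weights and
#' the JSON report are written there; the report is written atomically
#' (temp file + rename) so an aborted run leaves no partial report.
#'
#' @param config A `run_config`, a JSON path, or `NULL` for defaults (see
#'   [validate_config()]).
#' @param quiet Suppress per-stage progress messages.
#' @return A `run_report` list: per-stage provenance (seed, sizes, config
#'   hash), headline metrics (component latencies, Az threshold,
#'   significant-pixel fractions, behaviour rates) and warnings.
#' @export
run_pipeline <- function(config = NULL, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  seed <- as.integer(cfg$seed)
  say <- function(...) if (!quiet) message(sprintf(...))
  warnings_log <- character(0)
  stages <- list()
  t_stage <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    val <- withCallingHandlers(force(expr), warning = function(w) {
      warnings_log <<- c(warnings_log, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    say("stage %-12s %6.1f s", name, proc.time()[["elapsed"]] - t0)
    val
  }

  # --- simulate -------------------------------------------------------
  task <- do.call(task_config, cfg$task)
  agent <- do.call(agent_config, cfg$agent)
  n_sessions <- cfg$lfp$n_sessions
  sims <- t_stage({
    lapply(seq_len(n_sessions), function(s) {
      tr <- simulate_behavior(task, agent, seed = seed + 11L + s)
      simcfg <- lateralized_sim_config(seed = seed + 211L + s,
                                       noise_scale = cfg$lfp$noise_scale,
                                       effect_scale = cfg$lfp$effect_scale)
      simcfg$fs <- cfg$lfp$fs
      list(trials = tr, rec = simulate_lfp(tr, simcfg))
    })
  }, "simulate")
  all_trials <- do.call(rbind, lapply(seq_along(sims), function(s) {
    tr <- sims[[s]]$trials; tr$session <- s; tr
  }))
  # pooled numbering; per-session prev_outcome ("none" at session starts)
  # keeps transition counts from chaining across sessions
  all_trials$index <- seq_len(nrow(all_trials))

  # --- preprocess -----------------------------------------------------
  pp <- cfg$preproc
  ppc <- preproc_config(notch_freqs = pp$notch_freqs, notch_q = pp$notch_q,
                        resample_fs = pp$resample_fs,
                        epoch_window_ms = pp$epoch_window_ms,
                        baseline_ms = pp$baseline_ms)
  eps <- t_stage({
    lapply(sims, function(s) {
      rec <- notch_filter(s$rec, ppc)
      rec <- resample_recording(rec, ppc$resample_fs)
      lapply(c(feedback = "feedback", stimulus = "stimulus"), function(lk) {
        ep <- extract_epochs(rec, lk, ppc$epoch_window_ms)
        baseline_and_zscore(ep, ppc$baseline_ms)
      })
    })
  }, "preprocess")
  pool_epochs <- function(lock) {
    parts <- lapply(eps, `[[`, lock)
    out <- parts[[1]]
    out$data <- do.call(abind3, lapply(parts, `[[`, "data"))
    out$trials <- do.call(rbind, lapply(parts, `[[`, "trials"))
    out
  }
  ep_fb <- pool_epochs("feedback")
  ep_st <- pool_epochs("stimulus")

  # --- spectral contrasts --------------------------------------------
  scfg <- .scfg_from_run(cfg)
  contrasts <- list()
  if (isTRUE(cfg$contrasts$outcome)) {
    contrasts$outcome <- t_stage(
      compare_ersp_permutation(ep_fb,
                               function(tr) tr$outcome == "correct",
                               function(tr) tr$outcome == "incorrect",
                               scfg, seed = seed + 33L), "ersp_outcome")
  }
  if (isTRUE(cfg$contrasts$novelty)) {
    # stimulus-locked statistics end before the earliest selections so
    # feedback-locked activity cannot leak into the novelty contrast
    scfg_st <- scfg
    scfg_st$stat_time_range_ms <- cfg$spectral$stimulus_stat_time_range_ms
    contrasts$novelty <- t_stage(
      compare_ersp_permutation(ep_st,
                               function(tr) tr$novelty == "novel",
                               function(tr) tr$novelty == "familiar",
                               scfg_st, seed = seed + 34L), "ersp_novelty")
  }

  # --- discriminant ---------------------------------------------------
  dcfg <- .dcfg_from_run(cfg, seed + 55L)
  y <- .as_binary(ep_fb$trials$outcome)
  n_ch <- dim(ep_fb$data)[2]
  disc <- NULL
  if (min(sum(y == 1), sum(y == 0)) < n_ch + 2) {
    warnings_log <- c(warnings_log, sprintf(
      "discriminant skipped: only %d trials in the smaller outcome class (need >= %d) - not enough to reliably train the discriminant",
      min(sum(y == 1), sum(y == 0)), n_ch + 2))
  } else {
    disc <- t_stage(discriminant_analysis(ep_fb, cfg = dcfg), "discriminant")
  }

  # --- behaviour ------------------------------------------------------
  behav <- t_stage(behavior_summary(all_trials), "behavior")

  # --- report ---------------------------------------------------------
  cfg_for_hash <- unclass(cfg)
  cfg_for_hash$out_dir <- NULL         # hash the analysis, not its location
  cfg_json <- jsonlite::toJSON(cfg_for_hash, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)

  theta <- cfg$spectral$theta_band
  headline <- list(
    n_trials = nrow(all_trials),
    n_correct = sum(all_trials$outcome == "correct"),
    n_incorrect = sum(all_trials$outcome == "incorrect"),
    rate_after_correct_pct = unname(behav$rates["rate_after_correct"]),
    rate_after_incorrect_pct = unname(behav$rates["rate_after_incorrect"]),
    median_rt_correct_ms = behav$rt$median[behav$rt$group == "correct"],
    median_rt_incorrect_ms = behav$rt$median[behav$rt$group == "incorrect"],
    az_threshold = if (!is.null(disc)) disc$az_threshold else NA,
    max_az = if (!is.null(disc)) max(disc$az) else NA,
    components = if (!is.null(disc)) disc$components else NULL,
    theta_sig_fraction = lapply(contrasts, function(ct) {
      stats::setNames(lapply(seq_along(ct$channel_labels), function(ch)
        .sig_fraction(ct, ch, theta)), ct$channel_labels)
    }))

  report <- list(seed = seed, config_hash = cfg_hash,
                 stages = list(
                   simulate = list(seed = seed + 11L, n_sessions = n_sessions,
                                   n_trials = nrow(all_trials)),
                   preprocess = list(fs = ppc$resample_fs,
                                     n_feedback_epochs = dim(ep_fb$data)[1],
                                     n_stimulus_epochs = dim(ep_st$data)[1]),
                   spectral = list(seed = seed + 33L,
                                   n_permutations = scfg$n_permutations),
                   discriminant = list(seed = seed + 55L, ran = !is.null(disc)),
                   behavior = list(n_trials = nrow(all_trials))),
                 headline = headline, warnings = warnings_log)
  class(report) <- "run_report"

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events_tsv(.events_from_trials(all_trials),
                     file.path(cfg$out_dir, "events.tsv"))
    if (!is.null(disc)) {
      write.table(data.frame(center_ms = disc$centers, az = disc$az),
                  file.path(cfg$out_dir, "az_curve.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(disc$weights, file.path(cfg$out_dir, "weights.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
    rpt_path <- file.path(cfg$out_dir, "report.json")
    tmp <- paste0(rpt_path, ".tmp")
    jsonlite::write_json(unclass(report), tmp, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
    file.rename(tmp, rpt_path)
  }
  report$results <- list(behavior = behav, discriminant = disc,
                         contrasts = contrasts,
                         epochs = list(feedback = ep_fb, stimulus = ep_st))
  report
}

# bind trial arrays along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  n <- sum(vapply(parts, function(p) dim(p)[1], 0))
  out <- array(0, c(n, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, %d trials\n", x$seed,
              x$headline$n_trials))
  cat(sprintf("  consecutive correct %.1f%%, consecutive incorrect %.1f%%\n",
              x$headline$rate_after_correct_pct,
              x$headline$rate_after_incorrect_pct))
  if (!is.null(x$headline$components) && nrow(x$headline$components))
    cat(sprintf("  components: %s\n",
                paste(sprintf("%s %g ms (Az %.2f)",
                              x$headline$components$label,
                              x$headline$components$peak_center_ms,
                              x$headline$components$peak_az), collapse = ", ")))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}
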