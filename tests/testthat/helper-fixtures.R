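# In-code fixtures shared across the suite. Everything is generated at test
# time; no data files.

# epochs object built directly from an array (trials x channels x samples)
make_epochs <- function(data, fs = 512, window_ms = NULL, trials = NULL,
                        labels = NULL, lock_event = "feedback") {
  d <- dim(data)
  if (is.null(window_ms)) window_ms <- c(0, d[3] / fs * 1000)
  if (is.null(labels)) labels <- paste0("ch", seq_len(d[2]))
  t0 <- 1L - round(window_ms[1] / 1000 * fs)
  if (is.null(trials))
    trials <- data.frame(trial_index = seq_len(d[1]),
                         outcome = rep(c("correct", "incorrect"),
                                       length.out = d[1]))
  structure(list(data = data, fs = fs, window_ms = as.numeric(window_ms),
                 t0_index = t0,
                 times_ms = (seq_len(d[3]) - t0) / fs * 1000,
                 trials = trials, channel_labels = labels,
                 lock_event = lock_event, normalization = "raw"),
            class = "lfp_epochs")
}

# single-rule session: N trials with outcomes drawn at a flat rate
flat_session <- function(n, p_correct, seed) {
  task <- task_config(n_rules = 1, criterion_run = n, max_trials_per_rule = n)
  agent <- agent_config(p_asymptote = p_correct, learn_rate = Inf, lapse = 0)
  simulate_behavior(task, agent, seed = seed)
}

# label-exchangeable epochs: multichannel 1/f noise with agent-drawn labels
noise_epochs <- function(seed, n_trials = 200, n_channels = 8,
                         window_ms = c(-1000, 1000), p_correct = 0.714) {
  tr <- flat_session(n_trials, p_correct, seed)
  simcfg <- lfp_sim_config(fs = 512, n_channels = n_channels, noise_scale = 5,
                           line_amps = c(0, 0, 0), seed = seed + 9000L)
  rec <- simulate_lfp(tr, simcfg)
  ep <- extract_epochs(rec, "feedback", window_ms)
  baseline_and_zscore(ep, c(window_ms[1] / 2, 0))
}

# epochs with lateralized incorrect-only theta deflections at 200/350 ms
# (window-averaged effect size d ~ 1.5 at amplitude = 7)
injected_epochs <- function(seed, amplitude = 7, n_rules = 20) {
  task <- task_config(n_rules = n_rules,
                      rule_types = rep(c("simple discrimination",
                                         "simple reversal"), n_rules / 2))
  agent <- agent_config(p_asymptote = 0.8, learn_rate = 1.2, lapse = 0.1)
  tr <- simulate_behavior(task, agent, seed = seed)
  comps <- list(
    injected_component("feedback", list(outcome = "incorrect"), c(1, 0.3),
                       200, 6.6, 45, amplitude,
                       amplitude_jitter_sd = amplitude / 8,
                       latency_jitter_sd = 5, phase = pi / 2),
    injected_component("feedback", list(outcome = "incorrect"), c(0.5, 1),
                       350, 6.6, 55, amplitude,
                       amplitude_jitter_sd = amplitude / 8,
                       latency_jitter_sd = 5, phase = pi / 2))
  simcfg <- lfp_sim_config(fs = 512, noise_scale = 5, components = comps,
                           seed = seed + 1000L, line_amps = c(0, 0, 0))
  rec <- simulate_lfp(tr, simcfg)
  ep <- extract_epochs(rec, "feedback", c(-1000, 1000))
  baseline_and_zscore(ep, c(-500, 0))
}

# brute-force ROC area by threshold sweep over all distinct scores
roc_area_bruteforce <- function(scores, y) {
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[y == 1] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[y == 0] >= t), 0)
  fpr <- c(1, spec, 0)
  tpr <- c(1, sens, 0)
  sum(-diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
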