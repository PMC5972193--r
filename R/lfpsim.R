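#' Injected oscillatory burst component
#'
#' A Gaussian-windowed sinusoid,
#' `s(t) = A * exp(-(t - t0)^2 / (2 * width^2)) * sin(2*pi*freq*(t - t0) +
#' phase)`, added at `lock_event` onset + `center_latency` on every trial
#' matched by `condition_selector`, scaled per channel by `channel_gains`.
#' Amplitude and latency may jitter trial-to-trial (Gaussian, truncated at
#' zero amplitude). `phase = 0` gives an odd (sine) burst whose broadband
#' time-domain mean vanishes at the centre; `phase = pi/2` gives an even
#' (cosine) burst with an ERP-like net deflection at `center_latency`.
#'
#' @param lock_event `"feedback"` or `"stimulus"`.
#' @param condition_selector Named list of trial-field filters, e.g.
#'   `list(outcome = "incorrect")`; `NULL` matches every trial.
#' @param channel_gains Per-channel amplitude multipliers (lateralization).
#' @param center_latency Burst centre in ms after the locking event.
#' @param freq Carrier frequency, Hz.
#' @param width Gaussian envelope SD in ms.
#' @param amplitude Peak amplitude in microvolts.
#' @param amplitude_jitter_sd,latency_jitter_sd Trial-to-trial jitter SDs
#'   (microvolts / ms).
#' @param phase Carrier phase at the burst centre, radians (default 0).
#' @return An object of class `injected_component`.
#' @export
injected_component <- function(lock_event = "feedback",
                               condition_selector = NULL,
                               channel_gains = c(1, 1),
                               center_latency = 200,
                               freq = 6,
                               width = 50,
                               amplitude = 1,
                               amplitude_jitter_sd = 0,
                               latency_jitter_sd = 0,
                               phase = 0) {
  if (!lock_event %in% c("feedback", "stimulus")) stop("unknown lock_event")
  if (freq < 1) stop("freq must be >= 1 Hz")
  if (width <= 0) stop("width must be positive")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(lock_event = lock_event,
                 condition_selector = condition_selector,
                 channel_gains = channel_gains,
                 center_latency = center_latency, freq = freq, width = width,
                 amplitude = amplitude,
                 amplitude_jitter_sd = amplitude_jitter_sd,
                 latency_jitter_sd = latency_jitter_sd,
                 phase = phase),
            class = "injected_component")
}

#' LFP simulation configuration
#'
#' Continuous-signal model: per channel, 1/f^alpha Gaussian background noise
#' (synthesized in the frequency domain with random phases, scaled to
#' `noise_scale` microvolts RMS) + fixed-phase line sinusoids at 50/100/150
#' Hz + the injected burst components.
#'
#' @param fs Sampling rate, Hz (default 2500, the acquisition rate).
#' @param n_channels Channel count (default 2: left and right dACC bipolar
#'   pairs).
#' @param channel_labels Labels, default `dACC_left`, `dACC_right`.
#' @param noise_exponent 1/f slope alpha (default 1).
#' @param noise_scale Background RMS in microvolts (default 5). Zero
#'   disables the background.
#' @param line_amps Named or positional amplitudes in microvolts of the
#'   50/100/150 Hz contaminants (default `c(2, 1, 0.5)`).
#' @param line_freqs Line frequencies, Hz.
#' @param components List of [injected_component()] objects.
#' @param seed Positive integer seed.
#' @return An object of class `lfp_sim_config`.
#' @export
lfp_sim_config <- function(fs = 2500,
                           n_channels = 2,
                           channel_labels = NULL,
                           noise_exponent = 1,
                           noise_scale = 5,
                           line_amps = c(2, 1, 0.5),
                           line_freqs = c(50, 100, 150),
                           components = list(),
                           seed = 1L) {
  if (fs <= 200) stop("fs must exceed twice the highest analysis frequency (100 Hz)")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  if (is.null(channel_labels)) {
    channel_labels <- if (n_channels == 2) c("dACC_left", "dACC_right")
    else paste0("ch", seq_len(n_channels))
  }
  stopifnot(length(channel_labels) == n_channels,
            length(line_amps) == length(line_freqs))
  for (cm in components) {
    stopifnot(inherits(cm, "injected_component"))
    if (cm$freq >= fs / 2) stop("component frequency at or above Nyquist")
    if (length(cm$channel_gains) != n_channels)
      stop("component channel_gains must match n_channels")
  }
  structure(list(fs = fs, n_channels = as.integer(n_channels),
                 channel_labels = channel_labels,
                 noise_exponent = noise_exponent, noise_scale = noise_scale,
                 line_amps = line_amps, line_freqs = line_freqs,
                 components = components, seed = as.integer(seed)),
            class = "lfp_sim_config")
}

# 1/f^alpha Gaussian noise via frequency-domain synthesis (exact target
# spectrum, one FFT per channel); unit RMS before scaling
.powerlaw_noise <- function(n, alpha) {
  nf <- floor(n / 2)
  f <- seq_len(nf)
  amp <- f^(-alpha / 2)
  ph <- runif(nf, 0, 2 * pi)
  half <- amp * exp(1i * ph)
  spec <- complex(n)
  spec[2:(nf + 1)] <- half
  if (n %% 2 == 0) {
    spec[nf + 1] <- Re(spec[nf + 1])  # Nyquist bin must be real
    spec[seq(n, nf + 2)] <- Conj(half[seq_len(nf - 1)])
  } else {
    spec[seq(n, nf + 2)] <- Conj(half)
  }
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

.match_selector <- function(trials, selector) {
  keep <- rep(TRUE, nrow(trials))
  if (is.null(selector)) return(keep)
  for (nm in names(selector)) {
    if (!nm %in% names(trials)) stop("selector field '", nm, "' not in trials")
    keep <- keep & trials[[nm]] %in% selector[[nm]]
  }
  keep
}

#' Simulate a continuous LFP recording for a behavioural session
#'
#' Builds the continuous signal (background + line contamination + injected
#' bursts placed at each matching trial's locking event) and embeds the
#' session's event table. Event times are snapped to the nearest sample at
#' `cfg$fs`. The noise stream depends only on `cfg$seed`, and each
#' component's jitter draws use a seed derived from `cfg$seed` and the
#' component's position, so a signal generated with two components equals
#' the sum of the single-component signals (minus one copy of the shared
#' background).
#'
#' @param trials An `ied_trials` table from [simulate_behavior()].
#' @param cfg An [lfp_sim_config()].
#' @param duration_s Optional total duration; default last feedback + 3 s,
#'   rounded up to a whole second.
#' @return An `lfp_recording` with the event table embedded.
#' @export
simulate_lfp <- function(trials, cfg, duration_s = NULL) {
  stopifnot(is.data.frame(trials), inherits(cfg, "lfp_sim_config"))
  if (nrow(trials) == 0) stop("empty trial list")
  fs <- cfg$fs
  if (is.null(duration_s)) duration_s <- ceiling(max(trials$feedback_onset) + 3)
  n <- round(duration_s * fs)
  if (max(trials$feedback_onset) > duration_s)
    stop("trial onsets do not fit within the generated duration")

  data <- matrix(0, cfg$n_channels, n)
  tvec <- (seq_len(n) - 1) / fs

  if (cfg$noise_scale > 0) {
    set.seed(cfg$seed)
    for (ch in seq_len(cfg$n_channels)) {
      data[ch, ] <- cfg$noise_scale *
        .powerlaw_noise(n, cfg$noise_exponent)
    }
  }
  for (k in seq_along(cfg$line_freqs)) {
    if (cfg$line_amps[k] > 0) {
      line <- cfg$line_amps[k] * sin(2 * pi * cfg$line_freqs[k] * tvec)
      data <- sweep(data, 2, line, "+")
    }
  }

  for (k in seq_along(cfg$components)) {
    cm <- cfg$components[[k]]
    sel <- .match_selector(trials, cm$condition_selector)
    if (!any(sel)) next
    onsets <- if (cm$lock_event == "feedback") trials$feedback_onset
    else trials$stimulus_onset
    onsets <- round(onsets[sel] * fs) / fs  # snap to sample grid
    set.seed(cfg$seed + 7919L * k)
    amps <- cm$amplitude + rnorm(length(onsets), 0, cm$amplitude_jitter_sd)
    amps <- pmax(amps, 0)
    lats <- cm$center_latency + rnorm(length(onsets), 0, cm$latency_jitter_sd)
    for (j in seq_along(onsets)) {
      t0 <- onsets[j] + lats[j] / 1000
      half_support <- 4 * cm$width / 1000
      i1 <- max(1L, floor((t0 - half_support) * fs) + 1L)
      i2 <- min(n, ceiling((t0 + half_support) * fs) + 1L)
      if (i1 > i2) next
      tt <- tvec[i1:i2] - t0
      burst <- amps[j] * exp(-tt^2 / (2 * (cm$width / 1000)^2)) *
        sin(2 * pi * cm$freq * tt + cm$phase)
      for (ch in seq_len(cfg$n_channels)) {
        g <- cm$channel_gains[ch]
        if (g != 0) data[ch, i1:i2] <- data[ch, i1:i2] + g * burst
      }
    }
  }

  events <- .events_from_trials(trials)
  new_recording(data, fs, cfg$channel_labels, events)
}

# two event rows (stimulus, feedback) per trial, metadata riding along
.events_from_trials <- function(trials) {
  meta <- trials[, intersect(c("index", "outcome", "prev_outcome", "novelty",
                               "expectancy_class", "rt_ms"), names(trials))]
  names(meta)[names(meta) == "index"] <- "trial_index"
  rbind(
    cbind(data.frame(onset_s = trials$stimulus_onset, event = "stimulus"), meta),
    cbind(data.frame(onset_s = trials$feedback_onset, event = "feedback"), meta)
  )[order(rep(trials$index, 2), rep(c(1, 2), each = nrow(trials))), ]
}

#' Lateralized "two-system" simulation preset
#'
#' The default generator conditions used throughout the package's examples
#' and tests. Feedback-locked theta bursts carry outcome information with a
#' strong left-hemisphere bias (a valence-independent feedback response of
#' 0.8 uV left / 0.3 uV right, plus left-only incorrect-trial early
#' (200 ms) and late (350 ms) 6.6 Hz components), while a stimulus-locked
#' novelty response appears on the right channel only: outcome valence is
#' carried by the left hemisphere and stimulus novelty by the right. Effect amplitudes are set well above the 5 uV
#' background so that injection-recovery analyses probe the analysis code,
#' not the noise realisation.
#'
#' @param seed Positive integer seed.
#' @param noise_scale Background RMS, microvolts.
#' @param effect_scale Multiplier on all condition-dependent burst
#'   amplitudes (default 1).
#' @return An [lfp_sim_config()].
#' @export
lateralized_sim_config <- function(seed = 1L, noise_scale = 5,
                                   effect_scale = 1) {
  lfp_sim_config(
    fs = 2500, n_channels = 2, noise_scale = noise_scale, seed = seed,
    components = list(
      injected_component("feedback", NULL, channel_gains = c(1, 0.375),
                         center_latency = 120, freq = 6, width = 60,
                         amplitude = 0.8, phase = pi / 2),
      injected_component("feedback", list(outcome = "incorrect"),
                         channel_gains = c(1, 0),
                         center_latency = 200, freq = 6.6, width = 45,
                         amplitude = 8 * effect_scale,
                         amplitude_jitter_sd = 1, latency_jitter_sd = 5,
                         phase = pi / 2),
      injected_component("feedback", list(outcome = "incorrect"),
                         channel_gains = c(1, 0),
                         center_latency = 350, freq = 6.6, width = 70,
                         amplitude = 8 * effect_scale,
                         amplitude_jitter_sd = 1, latency_jitter_sd = 5,
                         phase = pi / 2),
      injected_component("stimulus", list(novelty = "novel"),
                         channel_gains = c(0, 1),
                         center_latency = 300, freq = 5, width = 70,
                         amplitude = 8 * effect_scale,
                         amplitude_jitter_sd = 1, latency_jitter_sd = 5,
                         phase = pi / 2)
    ))
}
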