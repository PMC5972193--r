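#' Preprocessing configuration
#'
#' Defaults reproduce the acquisition-and-analysis chain used for
#' feedback-locked dACC epochs: 50/100/150 Hz notches, resampling to 512 Hz,
#' six-second epochs from -4000 ms to +2000 ms around feedback onset, and a
#' -2000..0 ms pre-feedback baseline.
#'
#' @param notch_freqs Mains/harmonic frequencies to remove, Hz.
#' @param notch_q Notch quality factor (centre frequency / -3 dB width).
#' @param resample_fs Target sampling rate, Hz.
#' @param epoch_window_ms Length-2 numeric `(start, end)` in ms relative to
#'   the locking event.
#' @param baseline_ms Length-2 numeric baseline window in ms; must lie
#'   inside `epoch_window_ms`.
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(notch_freqs = c(50, 100, 150),
                           notch_q = 35,
                           resample_fs = 512,
                           epoch_window_ms = c(-4000, 2000),
                           baseline_ms = c(-2000, 0)) {
  stopifnot(length(epoch_window_ms) == 2, length(baseline_ms) == 2)
  if (epoch_window_ms[1] >= epoch_window_ms[2]) stop("epoch window reversed")
  if (baseline_ms[1] < epoch_window_ms[1] || baseline_ms[2] > epoch_window_ms[2])
    stop("baseline window must lie inside the epoch window")
  if (notch_q <= 0) stop("notch_q must be positive")
  if (resample_fs <= 0) stop("resample_fs must be positive")
  structure(list(notch_freqs = notch_freqs, notch_q = notch_q,
                 resample_fs = resample_fs,
                 epoch_window_ms = as.numeric(epoch_window_ms),
                 baseline_ms = as.numeric(baseline_ms)),
            class = "preproc_config")
}

# zero-phase filtering with odd-reflection padding at both ends, so filter
# startup transients decay inside the pad rather than inside the data
.filtfilt_padded <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  xp <- c(left, x, right)
  b <- as.numeric(b)
  a <- as.numeric(a)
  fwd <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(fwd))))
  y[(pad + 1):(pad + n)]
}

# RBJ biquad notch coefficients at f0 (Hz) for sampling rate fs
.notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch-filter a recording
#'
#' Removes each configured line frequency with a second-order IIR notch
#' applied forward and backward (zero phase) per channel. Duration and
#' sampling rate are unchanged.
#'
#' @param rec An `lfp_recording`.
#' @param cfg A [preproc_config()]; `notch_freqs` and `notch_q` are used.
#' @return The filtered `lfp_recording`.
#' @export
notch_filter <- function(rec, cfg = preproc_config()) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (any(cfg$notch_freqs >= rec$fs / 2))
    stop("notch frequency at or above Nyquist")
  out <- rec
  for (f0 in cfg$notch_freqs) {
    co <- .notch_coefs(f0, rec$fs, cfg$notch_q)
    # ringing time constant of the notch is Q/(pi f0); pad well past it
    pad <- ceiling(8 * cfg$notch_q / (pi * f0) * rec$fs)
    for (ch in seq_len(nrow(out$data))) {
      out$data[ch, ] <- .filtfilt_padded(co$b, co$a, out$data[ch, ], pad)
    }
  }
  out
}

#' Resample a recording
#'
#' Anti-aliased resampling of every channel to `target_fs`: a zero-phase
#' Hamming-FIR low-pass at 90% of the new Nyquist frequency followed by
#' cubic-spline evaluation on the new sample grid. Event onsets are stored
#' in seconds and therefore carry over unchanged; the new sample count is
#' `round(duration * target_fs)`.
#'
#' @param rec An `lfp_recording`.
#' @param target_fs Target rate in Hz; must not exceed the original rate.
#' @return The resampled `lfp_recording`.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (target_fs > rec$fs) stop("upsampling beyond the original rate is not supported")
  if (target_fs == rec$fs) return(rec)
  fs <- rec$fs
  n_old <- ncol(rec$data)
  n_new <- round(n_old / fs * target_fs)
  cutoff <- 0.9 * (target_fs / 2)
  trans <- 0.1 * target_fs / 2
  ord <- ceiling(3.3 * fs / trans)
  if (ord %% 2 == 1) ord <- ord + 1
  b <- as.numeric(signal::fir1(ord, cutoff / (fs / 2)))
  b <- b / sum(b)                      # exact unity gain at DC
  t_old <- (seq_len(n_old) - 1) / fs
  t_new <- (seq_len(n_new) - 1) / target_fs
  new_data <- matrix(0, nrow(rec$data), n_new)
  for (ch in seq_len(nrow(rec$data))) {
    low <- .filtfilt_padded(b, 1, rec$data[ch, ], ord)
    new_data[ch, ] <- stats::spline(t_old, low, xout = t_new,
                                    method = "fmm")$y
  }
  out <- rec
  out$data <- new_data
  rownames(out$data) <- rec$channel_labels
  out$fs <- target_fs
  out
}

#' Extract event-locked epochs
#'
#' Slices one window per qualifying event into a trials x channels x samples
#' array. Windows are half-open `[start, end)` in ms relative to the event;
#' the event sample itself (t = 0) belongs to the post-event side, giving an
#' unambiguous sample count `round((end - start)/1000 * fs)` (3072 for a
#' six-second window at 512 Hz). Events whose window would overrun the
#' recording are dropped with a warning.
#'
#' @param rec An `lfp_recording` with an event table.
#' @param lock_event `"feedback"` or `"stimulus"`.
#' @param window_ms Length-2 window in ms relative to the event.
#' @return An object of class `lfp_epochs`: list with `data`
#'   (trials x channels x samples), `fs`, `window_ms`, `t0_index`, `times_ms`,
#'   `trials` (event metadata rows), `channel_labels`, `normalization`.
#' @export
extract_epochs <- function(rec, lock_event = "feedback",
                           window_ms = c(-4000, 2000)) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (is.null(rec$events)) stop("recording carries no events")
  ev <- rec$events[rec$events$event == lock_event, , drop = FALSE]
  if (nrow(ev) == 0) stop("no qualifying events for lock '", lock_event, "'")
  fs <- rec$fs
  n_samp <- round((window_ms[2] - window_ms[1]) / 1000 * fs)
  off_start <- round(window_ms[1] / 1000 * fs)
  n_total <- ncol(rec$data)

  ev_sample <- round(ev$onset_s * fs) + 1L   # sample i <-> time (i-1)/fs
  first <- ev_sample + off_start
  last <- first + n_samp - 1L
  keep <- first >= 1L & last <= n_total
  if (any(!keep)) {
    warning(sum(!keep), " trial(s) dropped: epoch window exceeds recording bounds")
    ev <- ev[keep, , drop = FALSE]
    first <- first[keep]
  }
  if (nrow(ev) == 0) stop("no epochs remain inside recording bounds")

  n_ch <- nrow(rec$data)
  arr <- array(0, dim = c(nrow(ev), n_ch, n_samp))
  for (i in seq_len(nrow(ev))) {
    arr[i, , ] <- rec$data[, first[i]:(first[i] + n_samp - 1L), drop = FALSE]
  }
  t0_index <- 1L - off_start  # sample index within the epoch where t = 0
  structure(list(data = arr, fs = fs, window_ms = as.numeric(window_ms),
                 t0_index = t0_index,
                 times_ms = (seq_len(n_samp) - t0_index) / fs * 1000,
                 trials = ev, channel_labels = rec$channel_labels,
                 lock_event = lock_event, normalization = "raw"),
            class = "lfp_epochs")
}

#' @export
print.lfp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lfp_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat(sprintf("  lock: %s, window %g..%g ms, normalization: %s\n",
              x$lock_event, x$window_ms[1], x$window_ms[2], x$normalization))
  invisible(x)
}

#' Baseline-correct and z-score epochs
#'
#' Per trial and channel, the mean over the baseline window is subtracted;
#' each channel is then z-scored by the mean and sample standard deviation of
#' the normalization pool: by default all trials of the recording pooled
#' together (cross-subject comparability), or per trial with
#' `pool = "trial"`.
#'
#' @param ep An `lfp_epochs` object.
#' @param baseline_ms Length-2 baseline window in ms (inside the epoch
#'   window).
#' @param pool `"recording"` (default) or `"trial"`: the pool over which the
#'   z-scoring mean/SD are computed.
#' @return The normalized `lfp_epochs` (`normalization = "zscored"`).
#' @export
baseline_and_zscore <- function(ep, baseline_ms = c(-2000, 0),
                                pool = c("recording", "trial")) {
  stopifnot(inherits(ep, "lfp_epochs"))
  pool <- match.arg(pool)
  if (baseline_ms[1] < ep$window_ms[1] || baseline_ms[2] > ep$window_ms[2])
    stop("baseline window must lie inside the epoch window")
  bl <- ep$times_ms >= baseline_ms[1] & ep$times_ms < baseline_ms[2]
  if (!any(bl)) stop("baseline window contains no samples")
  d <- dim(ep$data)
  out <- ep$data
  for (i in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      out[i, ch, ] <- out[i, ch, ] - mean(out[i, ch, bl])
    }
  }
  for (ch in seq_len(d[2])) {
    if (pool == "recording") {
      v <- as.vector(out[, ch, ])
      s <- sd(v)
      if (!is.finite(s) || s == 0)
        stop("zero-variance channel '", ep$channel_labels[ch],
             "': cannot z-score")
      out[, ch, ] <- (out[, ch, ] - mean(v)) / s
    } else {
      for (i in seq_len(d[1])) {
        v <- out[i, ch, ]
        s <- sd(v)
        if (!is.finite(s) || s == 0)
          stop("zero-variance channel '", ep$channel_labels[ch],
               "' in trial ", i, ": cannot z-score")
        out[i, ch, ] <- (v - mean(v)) / s
      }
    }
  }
  ep$data <- out
  ep$normalization <- "zscored"
  ep$baseline_ms <- as.numeric(baseline_ms)
  ep
}

#' Assign expectancy classes to trials
#'
#' Each trial receives exactly one `expectancy_class`:
#' * `expected_correct` - a correct trial whose previous five trials were all
#'   correct;
#' * `unexpected_correct` - the first correct response to novel stimuli (a
#'   lucky guess on a freshly introduced object pair);
#' * `expected_incorrect` - the first incorrect response to novel stimuli (a
#'   guess that failed, as expected for unknown objects);
#' * `unexpected_incorrect` - the first incorrect trial of a reversal rule
#'   block (the learned prediction suddenly fails);
#' * `unclassified` otherwise.
#'
#' When several definitions match the precedence is
#' `unexpected_incorrect > expected_incorrect > unexpected_correct >
#' expected_correct` (reversal-first reading).
#'
#' @param trials Trial table ordered by `index`, with `outcome`,
#'   `rule_index`, `rule_type`, `novelty` columns.
#' @param task Optional [task_config()]; when absent, reversal and
#'   novel-stimulus rules are inferred from the `rule_type` column.
#' @return The trial table with `expectancy_class` filled in.
#' @export
categorize_trials <- function(trials, task = NULL) {
  stopifnot(is.data.frame(trials))
  if (anyDuplicated(trials$index)) stop("duplicate trial indices")
  if (is.unsorted(trials$index)) stop("trials must be ordered by index")
  n <- nrow(trials)
  reversal_rules <- if (!is.null(task)) .reversal_rules(task) else
    unique(trials$rule_index[grepl("reversal", trials$rule_type, fixed = TRUE)])
  novel_rules <- if (!is.null(task)) .novel_stimulus_rules(task) else
    unique(trials$rule_index[trials$novelty == "novel"])

  cls <- rep("unclassified", n)
  correct <- trials$outcome == "correct"

  for (i in seq_len(n)) {
    r <- trials$rule_index[i]
    in_block <- which(trials$rule_index == r)
    first_of <- function(ok) {
      w <- in_block[ok[in_block]]
      length(w) > 0 && i == w[1]
    }
    if (r %in% reversal_rules && first_of(!correct)) {
      cls[i] <- "unexpected_incorrect"
    } else if (r %in% novel_rules && first_of(!correct)) {
      cls[i] <- "expected_incorrect"
    } else if (r %in% novel_rules && first_of(correct)) {
      cls[i] <- "unexpected_correct"
    } else if (correct[i] && i > 5 && all(correct[(i - 5):(i - 1)])) {
      cls[i] <- "expected_correct"
    }
  }
  trials$expectancy_class <- cls
  trials
}
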