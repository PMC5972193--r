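#' Spectral analysis configuration
#'
#' Morlet-wavelet ERSP over a log-spaced 3-100 Hz grid. The cycle schedule
#' follows the EEGlab-style `[3, 0.5]` convention: the wavelet carries
#' `cycles_at_min` cycles at the lowest frequency and expands linearly with
#' frequency until, at `cycle_expansion = 1`, the highest frequency carries
#' `f_max/f_min * cycles_at_min` cycles (constant time resolution);
#' `cycle_expansion = 0` keeps the cycle count constant (constant Q).
#'
#' @param freq_range Hz range of the grid (default `c(3, 100)`).
#' @param n_freqs Number of log-spaced grid points (default 40).
#' @param cycles_at_min Wavelet cycles at the minimum frequency (default 3).
#' @param cycle_expansion Expansion factor in `[0, 1]` (default 0.5).
#' @param ersp_baseline_ms Baseline window for the dB reference (default
#'   `c(-2000, 0)`, the pre-feedback interval).
#' @param n_permutations Label permutations for contrasts (default 1000).
#' @param alpha Significance level after FDR (default 0.05).
#' @param theta_band Theta range in Hz (default `c(3, 8)`).
#' @param time_decim Keep every `time_decim`-th sample on the ERSP time axis
#'   (default 8: 64 Hz map resolution at 512 Hz).
#' @param stat_time_range_ms Optional `(start, end)` in ms restricting the
#'   pixels entering the permutation statistics (maps are still computed on
#'   the full epoch); `NULL` = all valid pixels.
#' @return An object of class `spectral_config`.
#' @export
spectral_config <- function(freq_range = c(3, 100),
                            n_freqs = 40,
                            cycles_at_min = 3,
                            cycle_expansion = 0.5,
                            ersp_baseline_ms = c(-2000, 0),
                            n_permutations = 1000,
                            alpha = 0.05,
                            theta_band = c(3, 8),
                            time_decim = 8,
                            stat_time_range_ms = NULL) {
  if (freq_range[1] < 1 || freq_range[1] >= freq_range[2])
    stop("invalid frequency range")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (cycle_expansion < 0 || cycle_expansion > 1)
    stop("cycle_expansion must be in [0, 1]")
  structure(list(freq_range = as.numeric(freq_range),
                 n_freqs = as.integer(n_freqs),
                 cycles_at_min = cycles_at_min,
                 cycle_expansion = cycle_expansion,
                 ersp_baseline_ms = as.numeric(ersp_baseline_ms),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, theta_band = as.numeric(theta_band),
                 time_decim = as.integer(time_decim),
                 stat_time_range_ms = stat_time_range_ms),
            class = "spectral_config")
}

#' Frequency grid and cycle schedule of a spectral config
#' @param cfg A [spectral_config()].
#' @return List with `freqs` (Hz) and `n_cycles` per frequency.
#' @export
morlet_grid <- function(cfg) {
  fr <- cfg$freq_range
  freqs <- exp(seq(log(fr[1]), log(fr[2]), length.out = cfg$n_freqs))
  cmin <- cfg$cycles_at_min
  n_cycles <- cmin + cfg$cycle_expansion *
    (freqs - fr[1]) / (fr[2] - fr[1]) * (fr[2] / fr[1] * cmin - cmin)
  list(freqs = freqs, n_cycles = n_cycles)
}

# Single-trial wavelet power via frequency-domain Morlet filtering.
# The analytic Morlet at centre f0 with temporal SD sigma_t has spectrum
# exp(-2 pi^2 sigma_t^2 (f - f0)^2) on positive frequencies and 0 on
# negative ones; multiplying the trial FFT by it and inverting yields the
# zero-phase analytic band signal. Returns trials x channels x freqs x
# times array plus the decimated time axis and a freqs x times validity
# mask (edges within 3 sigma_t of an epoch boundary are invalid).
.trial_power <- function(ep, cfg) {
  d <- dim(ep$data)
  n <- d[3]
  fs <- ep$fs
  grid <- morlet_grid(cfg)
  sigma_t <- grid$n_cycles / (2 * pi * grid$freqs)
  if (max(6 * sigma_t) * fs > n)
    stop("epoch shorter than the longest wavelet (", round(max(6 * sigma_t), 2),
         " s support at ", round(min(grid$freqs), 2), " Hz)")
  nfft <- stats::nextn(n, 2)
  fbins <- (seq_len(nfft) - 1) / nfft * fs
  keep_t <- seq(1L, n, by = cfg$time_decim)
  times <- ep$times_ms[keep_t]

  H <- matrix(0, length(grid$freqs), nfft)
  pos <- fbins <= fs / 2
  for (k in seq_along(grid$freqs)) {
    H[k, pos] <- 2 * exp(-2 * pi^2 * sigma_t[k]^2 * (fbins[pos] - grid$freqs[k])^2)
  }

  pw <- array(NA_real_, c(d[1], d[2], length(grid$freqs), length(keep_t)))
  for (i in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      X <- fft(c(ep$data[i, ch, ], numeric(nfft - n)))
      for (k in seq_along(grid$freqs)) {
        y <- fft(X * H[k, ], inverse = TRUE)[seq_len(n)] / nfft
        pw[i, ch, k, ] <- Mod(y[keep_t])^2
      }
    }
  }

  valid <- matrix(TRUE, length(grid$freqs), length(keep_t))
  for (k in seq_along(grid$freqs)) {
    margin <- 3 * sigma_t[k] * 1000   # ms
    valid[k, ] <- times >= ep$times_ms[1] + margin &
      times <= ep$times_ms[n] - margin
  }
  list(power = pw, freqs = grid$freqs, n_cycles = grid$n_cycles,
       times = times, valid = valid)
}

.dB <- function(p, baseline) 10 * log10(sweep(p, 1, baseline, "/"))

# baseline power per frequency from a freqs x times mean-power matrix
.baseline_power <- function(meanpw, times, valid, baseline_ms) {
  bl <- times >= baseline_ms[1] & times < baseline_ms[2]
  vapply(seq_len(nrow(meanpw)), function(k) {
    use <- bl & valid[k, ]
    if (!any(use)) return(NA_real_)
    mean(meanpw[k, use])
  }, 0)
}

#' Event-related spectral perturbation
#'
#' Per channel, single-trial Morlet power is averaged over the selected
#' trials and expressed in dB relative to the mean baseline-window power at
#' each frequency. Samples closer than three wavelet SDs to an epoch edge
#' are reported as `NA`.
#'
#' @param ep An `lfp_epochs` object.
#' @param cfg A [spectral_config()].
#' @param selector Optional logical vector or trial predicate (function of
#'   the trial table returning a logical) restricting the trials used.
#' @return An object of class `ersp_map`: `values` (channels x freqs x
#'   times, dB), `freqs`, `times`, `valid`, `n_trials`, `channel_labels`.
#' @export
compute_ersp <- function(ep, cfg = spectral_config(), selector = NULL) {
  stopifnot(inherits(ep, "lfp_epochs"))
  keep <- .resolve_selector(ep, selector)
  if (!any(keep)) stop("selector matches no trials")
  sub <- ep
  sub$data <- ep$data[keep, , , drop = FALSE]
  tp <- .trial_power(sub, cfg)
  d <- dim(tp$power)
  vals <- array(NA_real_, c(d[2], d[3], d[4]))
  for (ch in seq_len(d[2])) {
    meanpw <- apply(tp$power[, ch, , , drop = FALSE], c(3, 4), mean)
    bl <- .baseline_power(meanpw, tp$times, tp$valid, cfg$ersp_baseline_ms)
    vals[ch, , ] <- .dB(meanpw, bl)
    vals[ch, , ][!tp$valid] <- NA_real_
  }
  structure(list(values = vals, freqs = tp$freqs, times = tp$times,
                 valid = tp$valid, n_trials = sum(keep),
                 channel_labels = ep$channel_labels),
            class = "ersp_map")
}

#' @export
print.ersp_map <- function(x, ...) {
  cat(sprintf("<ersp_map> %d channel(s), %d freqs (%.1f-%.1f Hz) x %d times, %d trials\n",
              dim(x$values)[1], length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), x$n_trials))
  invisible(x)
}

.resolve_selector <- function(ep, selector) {
  n <- dim(ep$data)[1]
  if (is.null(selector)) return(rep(TRUE, n))
  if (is.function(selector)) {
    keep <- selector(ep$trials)
  } else keep <- selector
  stopifnot(is.logical(keep), length(keep) == n)
  keep & !is.na(keep)
}

#' Permutation comparison of two ERSP conditions
#'
#' Builds the null distribution of the condition ERSP difference (dB) by
#' randomly reassigning trials to the two groups (group sizes preserved)
#' `n_permutations` times and recomputing both group maps from the pooled
#' single-trial power. Two-sided pixelwise p-values are corrected with
#' Benjamini-Hochberg FDR at `cfg$alpha`, jointly across all valid pixels of
#' all channels.
#'
#' @param ep An `lfp_epochs` object holding both conditions.
#' @param selA,selB Logical vectors or trial predicates defining the two
#'   groups (disjoint).
#' @param cfg A [spectral_config()].
#' @param seed Positive integer seed for the permutations.
#' @return An object of class `ersp_contrast`: `diff` (channels x freqs x
#'   times observed A-B dB difference), `p_values`, `mask` (FDR-adjusted
#'   p <= alpha), `method = "permutation+FDR"`, grids and group sizes.
#' @export
compare_ersp_permutation <- function(ep, selA, selB, cfg = spectral_config(),
                                     seed = 1L) {
  stopifnot(inherits(ep, "lfp_epochs"))
  if (cfg$n_permutations < 1) stop("n_permutations must be >= 1")
  kA <- .resolve_selector(ep, selA)
  kB <- .resolve_selector(ep, selB)
  if (any(kA & kB)) stop("groups must be disjoint")
  nA <- sum(kA); nB <- sum(kB)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 trials")

  sub <- ep
  keep <- kA | kB
  sub$data <- ep$data[keep, , , drop = FALSE]
  isA <- kA[keep]
  tp <- .trial_power(sub, cfg)
  d <- dim(tp$power)  # trials x ch x freq x time
  n_pix <- d[3] * d[4]
  # trials x (freq*time by channel blocks) matrix for fast group means
  P <- matrix(aperm(tp$power, c(1, 3, 4, 2)), d[1], d[2] * n_pix)

  diff_map <- function(sel) {
    mA <- colMeans(P[sel, , drop = FALSE])
    mB <- colMeans(P[!sel, , drop = FALSE])
    out <- array(NA_real_, c(d[2], d[3], d[4]))
    for (ch in seq_len(d[2])) {
      ix <- ((ch - 1) * n_pix + 1):(ch * n_pix)
      ma <- matrix(mA[ix], d[3], d[4]); mb <- matrix(mB[ix], d[3], d[4])
      blA <- .baseline_power(ma, tp$times, tp$valid, cfg$ersp_baseline_ms)
      blB <- .baseline_power(mb, tp$times, tp$valid, cfg$ersp_baseline_ms)
      out[ch, , ] <- .dB(ma, blA) - .dB(mb, blB)
    }
    out
  }

  obs <- diff_map(isA)
  set.seed(seed)
  exceed <- array(0, dim(obs))
  for (b in seq_len(cfg$n_permutations)) {
    perm <- sample(d[1])
    nd <- diff_map(seq_len(d[1]) %in% perm[seq_len(nA)])
    exceed <- exceed + (abs(nd) >= abs(obs))
  }
  p <- (1 + exceed) / (cfg$n_permutations + 1)
  valid3 <- aperm(array(tp$valid, c(d[3], d[4], d[2])), c(3, 1, 2))
  if (!is.null(cfg$stat_time_range_ms)) {
    out_t <- tp$times < cfg$stat_time_range_ms[1] |
      tp$times > cfg$stat_time_range_ms[2]
    valid3[, , out_t] <- FALSE
  }
  p[!valid3] <- NA_real_
  padj <- p
  padj[valid3] <- p.adjust(p[valid3], method = "BH")
  mask <- padj <= cfg$alpha & valid3
  structure(list(diff = obs, p_values = p, p_adjusted = padj, mask = mask,
                 method = "permutation+FDR", alpha = cfg$alpha,
                 freqs = tp$freqs, times = tp$times, valid = tp$valid,
                 n_A = nA, n_B = nB, seed = seed,
                 channel_labels = ep$channel_labels),
            class = "ersp_contrast")
}

#' @export
print.ersp_contrast <- function(x, ...) {
  nsig <- sum(x$mask, na.rm = TRUE)
  nval <- sum(!is.na(x$p_values))
  cat(sprintf("<ersp_contrast> %s, alpha=%g: %d/%d pixels significant (%.2f%%)\n",
              x$method, x$alpha, nsig, nval, 100 * nsig / nval))
  invisible(x)
}

#' Event-related potential with peak report
#'
#' Arithmetic mean over the selected trials, per channel, plus the largest
#' absolute deflection (reported with its sign) within a post-event search
#' window.
#'
#' @param ep An `lfp_epochs` object.
#' @param selector Logical vector or trial predicate; `NULL` = all trials.
#' @param peak_window_ms Search window for the peak, ms (default
#'   `c(0, 600)`).
#' @return List with `erp` (channels x samples), `times_ms`, and `peaks`
#'   (`data.frame` of channel, latency_ms, magnitude).
#' @export
compute_erp <- function(ep, selector = NULL, peak_window_ms = c(0, 600)) {
  stopifnot(inherits(ep, "lfp_epochs"))
  keep <- .resolve_selector(ep, selector)
  if (!any(keep)) stop("selector matches no trials")
  erp <- apply(ep$data[keep, , , drop = FALSE], c(2, 3), mean)
  win <- ep$times_ms >= peak_window_ms[1] & ep$times_ms < peak_window_ms[2]
  peaks <- do.call(rbind, lapply(seq_len(nrow(erp)), function(ch) {
    seg <- erp[ch, win]
    j <- which.max(abs(seg))
    data.frame(channel = ep$channel_labels[ch],
               latency_ms = ep$times_ms[win][j], magnitude = seg[j])
  }))
  list(erp = erp, times_ms = ep$times_ms, peaks = peaks, n_trials = sum(keep))
}

#' Zero-phase theta band-pass of epochs
#'
#' Hamming-windowed FIR band-pass applied forward-backward per trial and
#' channel; the epoch shape is preserved. The filter order follows the
#' transition width (3.3 / normalized width taps) and is capped so the
#' filter remains much shorter than the epoch.
#'
#' @param ep An `lfp_epochs` object.
#' @param band Pass band in Hz (default `c(3, 8)`, theta).
#' @param transition_hz Transition band width, Hz (default 2).
#' @return The filtered `lfp_epochs`.
#' @export
bandpass_theta <- function(ep, band = c(3, 8), transition_hz = 2) {
  stopifnot(inherits(ep, "lfp_epochs"))
  fs <- ep$fs
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("invalid band")
  n <- dim(ep$data)[3]
  ord <- ceiling(3.3 * fs / transition_hz)
  ord <- min(ord, floor(n / 3) - 1)
  if (ord %% 2 == 1) ord <- ord + 1   # even order: symmetric, integer delay
  b <- signal::fir1(ord, band / (fs / 2), type = "pass")
  out <- ep
  for (i in seq_len(dim(ep$data)[1])) {
    for (ch in seq_len(dim(ep$data)[2])) {
      out$data[i, ch, ] <- .filtfilt_padded(b, 1, ep$data[i, ch, ],
                                                     ord)
    }
  }
  out
}
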