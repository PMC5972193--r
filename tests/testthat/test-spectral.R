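test_that("the wavelet grid spans 3-100 Hz with the configured point count", {
  g <- morlet_grid(spectral_config())
  expect_length(g$freqs, 40L)
  expect_equal(g$freqs[1], 3)
  expect_equal(g$freqs[40], 100)
  expect_equal(g$n_cycles[1], 3)
  expect_true(all(diff(g$n_cycles) > 0))
})

test_that("the ERP of one trial is that trial and symmetric trials cancel", {
  set.seed(2)
  x <- rnorm(400)
  one <- make_epochs(array(x, c(1, 1, 400)), fs = 200,
                     window_ms = c(-1000, 1000))
  erp1 <- compute_erp(one)
  expect_equal(erp1$erp[1, ], x)

  pm <- array(0, c(10, 1, 400))
  for (i in 1:10) pm[i, 1, ] <- if (i %% 2) x else -x
  erp0 <- compute_erp(make_epochs(pm, 200, c(-1000, 1000)))
  expect_equal(max(abs(erp0$erp)), 0)
})

test_that("a noise-free injected deflection is recovered by the ERP peak", {
  tr <- flat_session(12, 1, seed = 8)
  cm <- injected_component("feedback", NULL, 1, center_latency = 250,
                           freq = 6, width = 80, amplitude = 0.5,
                           phase = pi / 2)
  cfg <- lfp_sim_config(fs = 2500, n_channels = 1, noise_scale = 0,
                        line_amps = c(0, 0, 0), components = list(cm),
                        seed = 1)
  rec <- resample_recording(simulate_lfp(tr, cfg), 512)
  ep <- extract_epochs(rec, "feedback", c(-1000, 1000))
  erp <- compute_erp(ep, peak_window_ms = c(0, 600))
  # analytic oracle: peak of the burst waveform itself
  tt <- seq(-0.4, 0.4, by = 1 / 5120)
  burst <- 0.5 * exp(-tt^2 / (2 * 0.08^2)) * sin(2 * pi * 6 * tt + pi / 2)
  expect_lt(abs(erp$peaks$magnitude - max(burst)), 0.02 * max(burst))
  expect_lt(abs(erp$peaks$latency_ms - (250 + 1000 * tt[which.max(burst)])),
            1000 / 512 + 1e-9)
  expect_error(compute_erp(ep, selector = rep(FALSE, 12)), "no trials")
})

test_that("ERSP of stationary noise stays near 0 dB away from the edges", {
  tr <- flat_session(400, 0.7, seed = 9)
  simcfg <- lfp_sim_config(fs = 512, n_channels = 1, noise_scale = 5,
                           line_amps = c(0, 0, 0), seed = 90)
  rec <- simulate_lfp(tr, simcfg)
  ep <- baseline_and_zscore(extract_epochs(rec, "feedback", c(-2000, 1200)),
                            c(-1200, 0))
  er <- compute_ersp(ep, spectral_config(ersp_baseline_ms = c(-1200, 0)))
  vals <- er$values[1, , ][er$valid]
  expect_lt(max(abs(vals)), 1)
  expect_lt(abs(mean(vals)), 0.5)
})

test_that("an injected theta burst lands where the band-power oracle says", {
  tr <- flat_session(30, 0.7, seed = 10)
  cm <- injected_component("feedback", NULL, 1, center_latency = 300,
                           freq = 6, width = 50, amplitude = 6)
  simcfg <- lfp_sim_config(fs = 512, n_channels = 1, noise_scale = 2,
                           line_amps = c(0, 0, 0), components = list(cm),
                           seed = 11)
  rec <- simulate_lfp(tr, simcfg)
  ep <- baseline_and_zscore(extract_epochs(rec, "feedback", c(-2000, 1200)),
                            c(-1200, 0))
  er <- compute_ersp(ep, spectral_config(ersp_baseline_ms = c(-1200, 0)))
  theta_rows <- er$freqs >= 3 & er$freqs <= 8
  sub <- er$values[1, theta_rows, ]
  peak <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)
  peak_t <- er$times[peak[1, 2]]
  expect_gt(peak_t, 100)
  expect_lt(peak_t, 500)

  # oracle: zero-phase theta band-pass + envelope peak of the trial mean
  bp <- bandpass_theta(ep)
  m <- colMeans(bp$data[, 1, ])
  nn <- length(m)
  H <- numeric(nn); H[1] <- 1; H[2:ceiling(nn / 2)] <- 2
  if (nn %% 2 == 0) H[nn / 2 + 1] <- 1
  env <- Mod(fft(fft(m) * H, inverse = TRUE)) / nn  # analytic envelope
  t_env <- ep$times_ms[which.max(env)]
  expect_lt(abs(peak_t - t_env), 150)
})

test_that("the theta band-pass keeps 3-8 Hz and rejects out-of-band power", {
  fs <- 512
  n <- 3072
  tt <- (seq_len(n) - 1) / fs
  ep6 <- make_epochs(array(sin(2 * pi * 6 * tt), c(1, 1, n)), fs,
                     c(-3000, 3000))
  out6 <- bandpass_theta(ep6)
  mid <- 700:2400
  expect_lt(abs(max(abs(out6$data[1, 1, mid])) - 1), 0.05)

  ep30 <- make_epochs(array(sin(2 * pi * 30 * tt), c(1, 1, n)), fs,
                      c(-3000, 3000))
  out30 <- bandpass_theta(ep30)
  att <- 20 * log10(max(abs(out30$data[1, 1, mid])))
  expect_lt(att, -30)

  mix <- make_epochs(array(sin(2 * pi * 5 * tt) + sin(2 * pi * 40 * tt),
                           c(1, 1, n)), fs, c(-3000, 3000))
  outm <- bandpass_theta(mix)
  expect_gt(cor(outm$data[1, 1, mid], sin(2 * pi * 5 * tt)[mid]), 0.99)
  expect_error(bandpass_theta(ep6, band = c(8, 3)), "band")
})

test_that("wavelet power tracks the FFT spectral density across frequency", {
  # on stationary 1/f noise, power(f) x bandwidth(f) should follow f^-alpha
  set.seed(12)
  tr <- flat_session(40, 0.7, seed = 13)
  simcfg <- lfp_sim_config(fs = 512, n_channels = 1, noise_scale = 1,
                           noise_exponent = 1, line_amps = c(0, 0, 0),
                           seed = 14)
  rec <- simulate_lfp(tr, simcfg)
  ep <- extract_epochs(rec, "feedback", c(-2000, 1200))
  cfg <- spectral_config(freq_range = c(4, 64), n_freqs = 5,
                         ersp_baseline_ms = c(-1200, 0))
  tp <- iedlfp:::.trial_power(ep, cfg)
  g <- morlet_grid(cfg)
  pw <- vapply(seq_along(g$freqs), function(k) {
    mean(tp$power[, 1, k, tp$valid[k, ]])
  }, 0)
  # divide by wavelet bandwidth (proportional to f / n_cycles)
  dens <- pw / (g$freqs / g$n_cycles)
  slope <- coef(lm(log(dens) ~ log(g$freqs)))[2]
  expect_lt(abs(slope - (-1)), 0.25)
})

test_that("same-condition ERSP contrasts stay at the nominal false-positive level", {
  fracs <- p_all <- NULL
  for (s in 1:3) {
    ep <- noise_epochs(s + 40, n_trials = 40, n_channels = 1,
                       window_ms = c(-2000, 1200))
    n <- dim(ep$data)[1]
    grpA <- seq_len(n) <= n / 2
    ct <- compare_ersp_permutation(ep, grpA, !grpA,
                                   spectral_config(n_permutations = 200,
                                                   ersp_baseline_ms = c(-1000, 0)),
                                   seed = s)
    fracs <- c(fracs, sum(ct$mask, na.rm = TRUE) / sum(!is.na(ct$p_values)))
    p_all <- c(p_all, as.vector(ct$p_values[!is.na(ct$p_values)]))
  }
  expect_lt(mean(fracs), 0.05)
  # permutation p-values are super-uniform under the null
  expect_lte(mean(p_all <= 0.05), 0.05 + 2 * sd(p_all <= 0.05) / sqrt(3))
  expect_lte(mean(p_all <= 0.2), 0.2 + 2 * sd(p_all <= 0.2) / sqrt(3))
})

test_that("an injected group difference is localized to its support", {
  tr <- flat_session(60, 0.5, seed = 15)
  cm <- injected_component("feedback", list(outcome = "incorrect"), 1,
                           center_latency = 300, freq = 6, width = 50,
                           amplitude = 8, phase = pi / 2)
  simcfg <- lfp_sim_config(fs = 512, n_channels = 1, noise_scale = 4,
                           line_amps = c(0, 0, 0), components = list(cm),
                           seed = 16)
  rec <- simulate_lfp(tr, simcfg)
  ep <- baseline_and_zscore(extract_epochs(rec, "feedback", c(-2000, 1200)),
                            c(-1200, 0))
  ct <- compare_ersp_permutation(
    ep, function(t) t$outcome == "incorrect",
    function(t) t$outcome == "correct",
    spectral_config(n_permutations = 500, ersp_baseline_ms = c(-1200, 0),
                    stat_time_range_ms = c(-500, 1000)),
    seed = 17)
  support <- outer(ct$freqs >= 3 & ct$freqs <= 9,
                   ct$times >= 100 & ct$times <= 500, "&")
  hit <- ct$mask[1, , ] & support
  union <- (ct$mask[1, , ] | support) & !is.na(ct$p_values[1, , ])
  expect_gt(sum(hit, na.rm = TRUE) / sum(union, na.rm = TRUE), 0)
  expect_gt(sum(hit, na.rm = TRUE), 0)
})

test_that("invalid spectral configurations and groups are rejected", {
  ep <- make_epochs(array(rnorm(20 * 512 * 4), c(20, 1, 2048)), 512,
                    c(-2000, 2000))
  cfg0 <- spectral_config()
  cfg0$n_permutations <- 0L
  g <- rep(c(TRUE, FALSE), 10)
  expect_error(compare_ersp_permutation(ep, g, !g, cfg0), "n_permutations")
  expect_error(compare_ersp_permutation(ep, g, g, spectral_config()),
               "disjoint")
  one <- rep(FALSE, 20); one[1] <- TRUE
  expect_error(compare_ersp_permutation(ep, one, !one, spectral_config()),
               "at least 2")
  expect_error(spectral_config(alpha = 0), "alpha")
  # epoch shorter than the longest wavelet at 3 Hz
  short <- make_epochs(array(rnorm(5 * 256), c(5, 1, 256)), 512,
                       c(-250, 250))
  expect_error(compute_ersp(short, spectral_config()), "shorter")
})
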