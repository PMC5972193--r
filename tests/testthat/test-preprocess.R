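sine_rec <- function(freqs, amps, fs = 2500, dur = 10, events = NULL) {
  tvec <- (seq_len(fs * dur) - 1) / fs
  x <- rowSums(vapply(seq_along(freqs),
                      function(k) amps[k] * sin(2 * pi * freqs[k] * tvec),
                      tvec))
  new_recording(matrix(x, 1), fs, "chan", events)
}

amp_at <- function(x, f0, fs) {
  n <- length(x)
  2 * Mod(fft(x))[round(f0 * n / fs) + 1] / n
}

test_that("the notch removes line frequencies and spares neighbours", {
  rec50 <- sine_rec(50, 1)
  out <- notch_filter(rec50)
  # steady-state stop-band attenuation, away from the edge transients of
  # the zero-phase pass (the notch rings for ~Q/(pi*f0) = 0.22 s)
  mid <- 2500:22500
  rms_in <- sqrt(mean(rec50$data[1, mid]^2))
  rms_out <- sqrt(mean(out$data[1, mid]^2))
  expect_gt(20 * log10(rms_in / rms_out), 40)

  rec10 <- sine_rec(10, 1)
  out10 <- notch_filter(rec10)
  expect_lt(abs(sqrt(mean(out10$data^2)) / sqrt(mean(rec10$data^2)) - 1), 0.05)

  mix <- sine_rec(c(10, 50), c(1, 1))
  outm <- notch_filter(mix)
  expect_lt(abs(amp_at(outm$data[1, ], 10, 2500) - 1), 0.05)
  expect_lt(amp_at(outm$data[1, ], 50, 2500), 0.01)

  expect_error(notch_filter(sine_rec(10, 1, fs = 80)), "Nyquist")
})

test_that("resampling preserves DC, length arithmetic and wave shape", {
  const <- new_recording(matrix(3.7, 1, 25000), 2500, "c")
  down <- resample_recording(const, 512)
  expect_equal(ncol(down$data), 5120L)
  expect_equal(down$data[1, ], rep(3.7, 5120), tolerance = 1e-6)

  rec <- sine_rec(5, 1)
  out <- resample_recording(rec, 512)
  expect_equal(out$fs, 512)
  ref <- sin(2 * pi * 5 * (seq_len(5120) - 1) / 512)
  expect_gt(cor(out$data[1, ], ref), 0.999)

  expect_error(resample_recording(rec, 5000), "upsampling")
})

test_that("six-second epochs at 512 Hz contain exactly 3072 samples", {
  ev <- data.frame(onset_s = c(5, 10, 15), event = "feedback",
                   trial_index = 1:3, outcome = "correct")
  rec <- new_recording(matrix(rnorm(512 * 20), 1), 512, "c", ev)
  ep <- extract_epochs(rec, "feedback", c(-4000, 2000))
  expect_equal(dim(ep$data), c(3L, 1L, 3072L))
  expect_equal(ep$t0_index, 2049L)
})

test_that("epochs whose window leaves the recording are dropped with a warning", {
  ev <- data.frame(onset_s = c(1, 10), event = "feedback",
                   trial_index = 1:2, outcome = "correct")
  rec <- new_recording(matrix(0, 1, 512 * 20), 512, "c", ev)
  expect_warning(ep <- extract_epochs(rec, "feedback", c(-4000, 2000)),
                 "dropped")
  expect_equal(dim(ep$data)[1], 1L)
  expect_equal(ep$trials$onset_s, 10)
  expect_error(extract_epochs(rec, "stimulus"), "no qualifying events")
})

test_that("epoching copies samples exactly and aligns t = 0 to the event", {
  fs <- 512
  x <- as.numeric(seq_len(fs * 20))  # ramp: sample index is its own value
  ev <- data.frame(onset_s = 8, event = "feedback", trial_index = 1,
                   outcome = "correct")
  rec <- new_recording(matrix(x, 1), fs, "c", ev)
  ep <- extract_epochs(rec, "feedback", c(-1000, 1000))
  ev_sample <- round(8 * fs) + 1
  expect_identical(as.vector(ep$data[1, 1, ]),
                   x[(ev_sample - 512):(ev_sample + 511)])
  expect_equal(ep$data[1, 1, ep$t0_index], x[ev_sample])

  # unit impulse placed at the event onset appears exactly at t0_index
  x2 <- numeric(fs * 20); x2[ev_sample] <- 1
  rec2 <- new_recording(matrix(x2, 1), fs, "c", ev)
  ep2 <- extract_epochs(rec2, "feedback", c(-1000, 1000))
  expect_equal(which(ep2$data[1, 1, ] == 1), ep2$t0_index)
})

test_that("baseline subtraction and z-scoring behave as defined", {
  set.seed(1)
  # constant c inside the baseline window, arbitrary signal after
  fs <- 100
  arr <- array(0, c(4, 1, 300))        # window (-1000, 2000) ms at 100 Hz
  sig <- sin(seq(0, 6 * pi, length.out = 200))
  for (i in 1:4) arr[i, 1, ] <- c(rep(i, 100), sig + i)
  ep <- make_epochs(arr, fs = fs, window_ms = c(-1000, 2000))
  bl <- baseline_and_zscore(ep, c(-1000, 0))
  expect_equal(bl$normalization, "zscored")
  pooled <- as.vector(bl$data[, 1, ])
  expect_equal(mean(pooled), 0, tolerance = 1e-9)
  expect_equal(sd(pooled), 1, tolerance = 1e-9)
  # after baselining, all four trials are identical up to the common scale
  for (i in 2:4) expect_equal(bl$data[i, 1, ], bl$data[1, 1, ],
                              tolerance = 1e-9)

  arr0 <- array(5, c(3, 1, 300))
  expect_error(baseline_and_zscore(make_epochs(arr0, fs, c(-1000, 2000)),
                                   c(-1000, 0)), "zero-variance")
  expect_error(baseline_and_zscore(ep, c(-2000, 0)), "inside the epoch")
})

test_that("notch and resampling commute on band-limited signals", {
  rec <- sine_rec(c(7, 23, 50), c(1, 0.5, 0.8))
  cfg <- preproc_config()
  a <- resample_recording(notch_filter(rec, cfg), 512)
  b <- notch_filter(resample_recording(rec, 512), cfg)
  mid <- 512:(ncol(a$data) - 512)      # away from filter edge transients
  expect_lt(max(abs(a$data[1, mid] - b$data[1, mid])), 0.02)
})

test_that("expectancy classes follow their definitions and partition trials", {
  base <- data.frame(
    index = 1:8, rule_index = 1, rule_type = "simple discrimination",
    outcome = c("incorrect", rep("correct", 7)), novelty = "other",
    stringsAsFactors = FALSE)
  out <- categorize_trials(base)
  # the first five correct trials cannot be expected_correct; later ones are
  expect_equal(out$expectancy_class[7:8], rep("expected_correct", 2))
  expect_true(all(out$expectancy_class[1:6] != "expected_correct"))

  # session's very first trial is never expected_correct
  allc <- data.frame(index = 1:6, rule_index = 1, rule_type = "x",
                     outcome = "correct", novelty = "other")
  expect_false(categorize_trials(allc)$expectancy_class[1] == "expected_correct")

  # reversal: first incorrect trial of the block is unexpected_incorrect
  rev <- data.frame(
    index = 1:4, rule_index = c(1, 1, 2, 2),
    rule_type = c("simple discrimination", "simple discrimination",
                  "simple reversal", "simple reversal"),
    outcome = c("correct", "correct", "incorrect", "correct"),
    novelty = "other")
  expect_equal(categorize_trials(rev)$expectancy_class[3],
               "unexpected_incorrect")

  # novel-stimulus block: first correct is unexpected_correct, first
  # incorrect is expected_incorrect
  nov <- data.frame(
    index = 1:3, rule_index = 3, rule_type = "compound 1",
    outcome = c("incorrect", "correct", "correct"),
    novelty = c("novel", "other", "other"))
  cl <- categorize_trials(nov)$expectancy_class
  expect_equal(cl[1], "expected_incorrect")
  expect_equal(cl[2], "unexpected_correct")

  # partition: every trial gets exactly one class; duplicates rejected
  tr <- simulate_behavior(task_config(), agent_config(), seed = 13)
  expect_equal(sum(table(tr$expectancy_class)), nrow(tr))
  dup <- base; dup$index[2] <- 1
  expect_error(categorize_trials(dup), "duplicate")
})
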