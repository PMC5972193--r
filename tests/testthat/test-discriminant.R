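test_that("window averaging matches closed forms and a naive loop", {
  fs <- 500
  n <- 500                       # window (-500, 500) ms
  ep <- make_epochs(array(3.25, c(2, 2, n)), fs, c(-500, 500))
  expect_equal(window_average(ep, 100, 50),
               matrix(3.25, 2, 2, dimnames = list(NULL, c("ch1", "ch2"))))

  # linear ramp a*t over a symmetric window averages to a*tau
  ramp <- array(0, c(1, 1, n))
  ramp[1, 1, ] <- 0.4 * ep$times_ms
  epr <- make_epochs(ramp, fs, c(-500, 500))
  expect_equal(unname(window_average(epr, 100, 40)[1, 1]), 0.4 * 100)

  set.seed(3)
  arr <- array(rnorm(20 * 3 * n), c(20, 3, n))
  epx <- make_epochs(arr, fs, c(-500, 500))
  wa <- window_average(epx, -120, 50)
  use <- epx$times_ms >= -145 & epx$times_ms <= -95
  naive <- matrix(0, 20, 3)
  for (i in 1:20) for (ch in 1:3) {
    s <- 0
    for (t in which(use)) s <- s + arr[i, ch, t]
    naive[i, ch] <- s / sum(use)
  }
  expect_lt(max(abs(wa - naive)), 1e-12)
  expect_error(window_average(epx, 490, 50), "out of epoch bounds")
})

test_that("the classifier separates separable data and orients to positive outcomes", {
  set.seed(4)
  n <- 40
  y <- rep(c("correct", "incorrect"), each = n / 2)
  f1 <- ifelse(y == "correct", 1, -1) + rnorm(n, 0, 0.05)
  fit <- fit_window_classifier(cbind(f1), y, discriminant_config())
  expect_gt(fit$weights[1], 0)
  # flipped feature: the orientation convention flips the weight
  fit2 <- fit_window_classifier(cbind(-f1), y, discriminant_config())
  expect_lt(fit2$weights[1], 0)
  # held-out Az on separable 1-D features is 1
  sc <- iedlfp:::cpp_loo_scores(cbind(f1), as.numeric(y == "correct"), 1e-3)
  expect_equal(iedlfp:::cpp_auc(sc, as.numeric(y == "correct")), 1)
  expect_error(fit_window_classifier(cbind(f1), rep("correct", n),
                                     discriminant_config()), "both outcome")
})

test_that("random labels give an Az inside the central permutation band", {
  set.seed(5)
  n <- 200
  F <- array(rnorm(n * 4), c(n, 4, 1))
  y <- rbinom(n, 1, 0.5)
  az <- iedlfp:::cpp_az_grid(F, y, 1e-3)[1]
  perms <- t(vapply(1:200, function(b) sample.int(n) - 1L, integer(n)))
  null_az <- iedlfp:::cpp_null_az(F, y, perms, 1e-3)[, 1]
  expect_gt(az, quantile(null_az, 0.025))
  expect_lt(az, quantile(null_az, 0.975))
})

test_that("a duplicated channel stays finite and barely changes the Az", {
  set.seed(6)
  n <- 80
  f <- rnorm(n) + rep(c(0.8, 0), each = n / 2)
  y <- rep(c(1, 0), each = n / 2)
  az1 <- iedlfp:::cpp_auc(iedlfp:::cpp_loo_scores(cbind(f), y, 1e-3), y)
  fit <- fit_window_classifier(cbind(f, f), ifelse(y == 1, "correct", "incorrect"),
                               discriminant_config())
  expect_true(all(is.finite(fit$weights)))
  az2 <- iedlfp:::cpp_auc(iedlfp:::cpp_loo_scores(cbind(f, f), y, 1e-3), y)
  expect_lt(abs(az1 - az2), 0.02)
})

test_that("the default window grid has 81 centres and ties give Az = 0.5", {
  expect_length(window_centers(discriminant_config()), 81L)
  # projections identical for every trial: only ties, Az is exactly 1/2
  y <- rep(c(1, 0), 6)
  expect_equal(iedlfp:::cpp_auc(rep(1.3, 12), y), 0.5)
})

test_that("LOO Az equals brute-force ROC integration on eight trials", {
  set.seed(7)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  X <- cbind(rnorm(8, y, 1.2), rnorm(8))
  sc <- iedlfp:::cpp_loo_scores(X, y, 1e-3)
  expect_equal(iedlfp:::cpp_auc(sc, y), roc_area_bruteforce(sc, y))
  # and with heavy ties
  sc2 <- c(1, 1, 1, 2, 1, 1, 2, 0)
  expect_equal(iedlfp:::cpp_auc(sc2, y), roc_area_bruteforce(sc2, y))
})

test_that("Az is rank-based: monotone transforms and label flips behave", {
  set.seed(8)
  y <- rbinom(60, 1, 0.5)
  sc <- rnorm(60)
  a <- iedlfp:::cpp_auc(sc, y)
  expect_equal(iedlfp:::cpp_auc(exp(sc), y), a)
  expect_equal(iedlfp:::cpp_auc(sc, 1 - y), 1 - a)
})

test_that("projection-then-average equals average-then-projection", {
  set.seed(9)
  ep <- make_epochs(array(rnorm(15 * 3 * 500), c(15, 3, 500)), 500,
                    c(-500, 500))
  w <- c(0.7, -1.2, 0.4)
  fa <- window_average(ep, 50, 60) %*% w
  pr <- project_profile(ep, w, c(-500, 498),
                        outcomes = rep(c("correct", "incorrect"),
                                       length.out = 15))
  use <- pr$times_ms >= 20 & pr$times_ms <= 80
  ap <- rowMeans(pr$profiles[, use])
  expect_lt(max(abs(fa - ap)), 1e-12)
})

test_that("bootstrap thresholds sit above chance with sane edge cases", {
  ep <- noise_epochs(61, n_trials = 60, n_channels = 2,
                     window_ms = c(-500, 1000))
  cfg <- discriminant_config(n_bootstrap = 200,
                             bootstrap_centers = c(0, 200, 400), seed = 1)
  thr <- bootstrap_threshold(ep, cfg = cfg)
  expect_gt(as.numeric(thr), 0.5)
  null_az <- attr(thr, "null_az")
  expect_equal(dim(null_az), c(200L, 3L))
  # alpha = 1 gives the minimum of the null distribution
  cfg1 <- cfg; cfg1$alpha <- 1 - 1e-12
  thr1 <- bootstrap_threshold(ep, cfg = cfg1)
  expect_equal(as.numeric(thr1), min(attr(thr1, "null_az")), tolerance = 1e-6)
  expect_warning(bootstrap_threshold(ep, cfg = discriminant_config(
    n_bootstrap = 50, bootstrap_centers = c(0, 200))), "unstable")
  expect_error(discriminant_config(n_bootstrap = 0), "n_bootstrap")
  # identical seeds reproduce the threshold exactly
  expect_identical(as.numeric(thr), as.numeric(bootstrap_threshold(ep, cfg = cfg)))
})

test_that("component detection obeys threshold, separation and ranking rules", {
  centers <- seq(-200, 600, 10)
  az <- rep(0.5, 81)
  expect_equal(nrow(detect_components(az, 0.6, centers)), 0L)

  az2 <- 0.5 + 0.3 * exp(-(centers - 200)^2 / 2500) +
    0.25 * exp(-(centers - 350)^2 / 2500)
  cm <- detect_components(az2, 0.6, centers)
  expect_equal(cm$label, c("early", "late"))
  expect_true(all(abs(cm$peak_center_ms - c(200, 350)) <= 20))

  # three peaks: only the top two by Az survive, relabelled in time order
  az3 <- 0.5 + 0.30 * exp(-(centers - 0)^2 / 800) +
    0.20 * exp(-(centers - 250)^2 / 800) +
    0.28 * exp(-(centers - 500)^2 / 800)
  cm3 <- detect_components(az3, 0.55, centers)
  expect_equal(nrow(cm3), 2L)
  expect_equal(cm3$peak_center_ms, c(0, 500))

  # peaks closer than the separation merge into the stronger one
  az4 <- 0.5 + 0.3 * exp(-(centers - 200)^2 / 400) +
    0.28 * exp(-(centers - 260)^2 / 400)
  cm4 <- detect_components(az4, 0.6, centers, min_separation_ms = 100)
  expect_equal(nrow(cm4), 1L)
  expect_equal(cm4$peak_center_ms, 200)
})

test_that("profiles follow the weights: zero, identity and dimension checks", {
  set.seed(10)
  arr <- array(rnorm(10 * 2 * 500), c(10, 2, 500))
  ep <- make_epochs(arr, 500, c(-500, 500))
  pr0 <- project_profile(ep, c(0, 0))
  expect_true(all(pr0$profiles == 0))
  one <- make_epochs(arr[, 1, , drop = FALSE], 500, c(-500, 500))
  pr1 <- project_profile(one, 1, c(-500, 498))
  expect_equal(pr1$profiles, arr[, 1, ])
  expect_error(project_profile(ep, c(1, 2, 3)), "per channel")
})

test_that("multivariate weighting beats any single channel when signal is differential", {
  set.seed(11)
  n <- 120
  y <- rep(c(1, 0), each = n / 2)
  shared <- rnorm(n, 0, 3)              # common-mode noise swamps each channel
  delta <- ifelse(y == 1, 0.8, -0.8)
  arr <- array(0, c(n, 2, 200))
  for (i in seq_len(n)) {
    arr[i, 1, ] <- shared[i] + delta[i] + rnorm(200, 0, 0.3)
    arr[i, 2, ] <- shared[i] - delta[i] + rnorm(200, 0, 0.3)
  }
  ep <- make_epochs(arr, 500, c(-100, 300),
                    trials = data.frame(trial_index = 1:n,
                                        outcome = ifelse(y == 1, "correct",
                                                         "incorrect")))
  cfg <- discriminant_config(center_start_ms = 0, center_end_ms = 200,
                             center_step_ms = 50)
  cu <- compare_univariate(ep, cfg = cfg)
  expect_gt(max(cu$multivariate), max(cu$az))
  expect_gt(max(cu$multivariate), 0.9)
  # single-channel input: univariate and multivariate coincide
  ep1 <- make_epochs(arr[, 1, , drop = FALSE], 500, c(-100, 300),
                     trials = ep$trials)
  cu1 <- compare_univariate(ep1, cfg = cfg)
  expect_lt(max(abs(cu1$az[1, ] - cu1$multivariate)), 1e-12)
})

test_that("a pure-noise channel stays inside the null band univariately", {
  ep <- noise_epochs(62, n_trials = 100, n_channels = 2,
                     window_ms = c(-500, 1000))
  cfg <- discriminant_config(center_start_ms = 0, center_end_ms = 400,
                             center_step_ms = 100)
  cu <- compare_univariate(ep, cfg = cfg)
  # with 5 windows x 2 channels, all Az should stay below a generous null
  # bound for n ~ 100 (3 SD of the null Az ~ 0.5 + 3 * 0.66/sqrt(n_min))
  y <- ep$trials$outcome == "correct"
  bound <- 0.5 + 3 * 0.66 / sqrt(min(sum(y), sum(!y)))
  expect_true(all(cu$az < bound))
})

test_that("parameter recovery: injected latencies, gains and profiles come back", {
  ep <- injected_epochs(301)
  cfg <- discriminant_config(n_bootstrap = 200,
                             bootstrap_centers = seq(-200, 600, 100),
                             seed = 301)
  dr <- discriminant_analysis(ep, cfg = cfg)
  expect_equal(dr$components$label, c("early", "late"))
  expect_lt(abs(dr$components$peak_center_ms[1] - 200), 21)
  expect_lt(abs(dr$components$peak_center_ms[2] - 350), 21)
  # argmax of the Az curve is within one step of an injected latency
  best <- dr$centers[which.max(dr$az)]
  expect_true(min(abs(best - c(200, 350))) <= 10)
  # spatial weights mirror the injected channel gains: the early component
  # is left-dominant (gains 1 vs 0.3), oriented toward negative outcomes
  w_early <- dr$weights[match(dr$components$peak_center_ms[1], dr$centers), ]
  expect_gt(abs(w_early[1]), abs(w_early[2]))
  # the difference profile of the late component peaks near 350 ms
  pr <- dr$profiles$late
  dd <- abs(pr$mean_negative - pr$mean_positive)
  expect_lt(abs(pr$times_ms[which.max(dd)] - 350), 21)
  # sign convention: positive outcomes project higher on average
  expect_gt(mean(dr$projections[ep$trials$outcome == "correct", ]),
            mean(dr$projections[ep$trials$outcome == "incorrect", ]))
})
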