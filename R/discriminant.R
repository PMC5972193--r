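#' Sliding-window discriminant configuration
#'
#' Defaults reproduce the outcome-valence decoding setup: 50 ms windows,
#' centres from -200 ms to +600 ms after feedback in 10 ms steps (81
#' windows), 1000 label randomizations for the Az significance threshold at
#' alpha = 0.01, and a small ridge penalty stabilising the logistic fits in
#' low-trial-count windows (`l2_lambda -> 0` recovers plain logistic
#' regression).
#'
#' @param window_ms Window width N in ms (default 50).
#' @param center_start_ms,center_end_ms,center_step_ms Window-centre grid in
#'   ms relative to the locking event (defaults -200, 600, 10).
#' @param n_bootstrap Label randomizations for the null (default 1000).
#' @param alpha Significance level for the Az threshold (default 0.01).
#' @param l2_lambda Ridge penalty on the spatial weights (default 1e-3).
#' @param max_iter,tol IRLS controls.
#' @param bootstrap_centers Optional subsampled centre grid (ms) used only
#'   for the bootstrap null, for tractability; `NULL` = the full grid.
#' @param familywise If `TRUE` the null pools the max Az across windows per
#'   randomization (familywise threshold); default pools all window Az
#'   values (per-window threshold).
#' @param min_separation_ms Minimum separation between detected component
#'   peaks (default 100).
#' @param seed Default seed for the bootstrap.
#' @return An object of class `discriminant_config`.
#' @export
discriminant_config <- function(window_ms = 50,
                                center_start_ms = -200,
                                center_end_ms = 600,
                                center_step_ms = 10,
                                n_bootstrap = 1000,
                                alpha = 0.01,
                                l2_lambda = 1e-3,
                                max_iter = 100,
                                tol = 1e-3,
                                bootstrap_centers = NULL,
                                familywise = FALSE,
                                min_separation_ms = 100,
                                seed = 1L) {
  if (center_step_ms <= 0) stop("center_step_ms must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1")
  if (l2_lambda < 0) stop("l2_lambda must be >= 0")
  structure(list(window_ms = window_ms,
                 center_start_ms = center_start_ms,
                 center_end_ms = center_end_ms,
                 center_step_ms = center_step_ms,
                 n_bootstrap = as.integer(n_bootstrap), alpha = alpha,
                 l2_lambda = l2_lambda, max_iter = as.integer(max_iter),
                 tol = tol, bootstrap_centers = bootstrap_centers,
                 familywise = isTRUE(familywise),
                 min_separation_ms = min_separation_ms,
                 seed = as.integer(seed)),
            class = "discriminant_config")
}

#' Window-centre grid of a discriminant config
#' @param cfg A [discriminant_config()].
#' @return Numeric vector of centres in ms (81 under the defaults).
#' @export
window_centers <- function(cfg) {
  seq(cfg$center_start_ms, cfg$center_end_ms, by = cfg$center_step_ms)
}

# outcomes -> 0/1 with 1 = positive class ("correct")
.as_binary <- function(outcomes) {
  if (is.character(outcomes) || is.factor(outcomes)) {
    outcomes <- as.character(outcomes)
    bad <- setdiff(unique(outcomes), c("correct", "incorrect"))
    if (length(bad)) stop("unknown outcome label(s): ", paste(bad, collapse = ", "))
    as.numeric(outcomes == "correct")
  } else if (is.logical(outcomes)) {
    as.numeric(outcomes)
  } else {
    if (!all(outcomes %in% c(0, 1))) stop("numeric outcomes must be 0/1")
    as.numeric(outcomes)
  }
}

#' Within-window mean feature vector
#'
#' Per trial and channel, the mean of the samples whose times fall in
#' `[center - width/2, center + width/2]` (closed; the time average of the
#' linear projection equals the projection of the time average, so this mean
#' feature vector is all the classifier needs).
#'
#' @param ep An `lfp_epochs` object.
#' @param center Window centre in ms.
#' @param width Window width N in ms.
#' @return Numeric matrix, trials x channels.
#' @export
window_average <- function(ep, center, width = 50) {
  stopifnot(inherits(ep, "lfp_epochs"))
  lo <- center - width / 2
  hi <- center + width / 2
  if (lo < ep$times_ms[1] || hi > ep$times_ms[length(ep$times_ms)])
    stop("window [", lo, ", ", hi, "] ms out of epoch bounds")
  use <- ep$times_ms >= lo & ep$times_ms <= hi
  out <- apply(ep$data[, , use, drop = FALSE], c(1, 2), mean)
  colnames(out) <- ep$channel_labels
  out
}

# trials x channels x windows feature cube over a centre grid
.window_features <- function(ep, centers, width) {
  d <- dim(ep$data)
  F <- array(0, c(d[1], d[2], length(centers)))
  for (w in seq_along(centers)) F[, , w] <- window_average(ep, centers[w], width)
  F
}

#' Fit the spatial weighting of one time window
#'
#' Ridge-penalized logistic regression of outcome on the window-averaged
#' channel features, maximising the regularized likelihood. The orientation
#' is normalized so that the mean projection of positive-outcome (correct)
#' trials is at least that of negative-outcome trials.
#'
#' @param features Trials x channels matrix (from [window_average()]).
#' @param outcomes Trial outcomes (`"correct"`/`"incorrect"`, logical or
#'   0/1; positive class = correct).
#' @param cfg A [discriminant_config()].
#' @return List with `weights` (per channel), `intercept`, `converged`,
#'   `iterations`.
#' @export
fit_window_classifier <- function(features, outcomes,
                                  cfg = discriminant_config()) {
  features <- as.matrix(features)
  y <- .as_binary(outcomes)
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  if (nrow(features) < ncol(features) + 1)
    stop("need at least channels + 1 trials")
  fit <- cpp_ridge_logistic(features, y, cfg$l2_lambda, cfg$max_iter, cfg$tol)
  if (!fit$converged)
    warning("IRLS did not converge in ", fit$iterations, " iterations")
  proj <- drop(features %*% fit$weights)
  if (mean(proj[y == 1]) < mean(proj[y == 0])) {
    fit$weights <- -fit$weights
    fit$intercept <- -fit$intercept
  }
  names(fit$weights) <- colnames(features)
  fit[c("weights", "intercept", "converged", "iterations")]
}

#' Leave-one-out Az over the window grid
#'
#' For each window centre, each trial is held out in turn, the classifier is
#' refit on the remaining trials (warm-started at the full-data solution and
#' re-solved to tolerance), and the held-out trial is projected. The pooled
#' held-out projections give one ROC area (Az, midrank Mann-Whitney form)
#' per window.
#'
#' @param ep An `lfp_epochs` object.
#' @param outcomes Trial outcomes; default taken from `ep$trials$outcome`.
#' @param cfg A [discriminant_config()].
#' @return List with `centers` (ms) and `az` (one value per window).
#' @export
loo_az <- function(ep, outcomes = NULL, cfg = discriminant_config()) {
  stopifnot(inherits(ep, "lfp_epochs"))
  if (is.null(outcomes)) outcomes <- ep$trials$outcome
  y <- .as_binary(outcomes)
  if (min(sum(y == 1), sum(y == 0)) < 2)
    stop("need at least 2 trials per class")
  centers <- window_centers(cfg)
  F <- .window_features(ep, centers, cfg$window_ms)
  az <- as.vector(cpp_az_grid(F, y, cfg$l2_lambda, cfg$max_iter, cfg$tol))
  list(centers = centers, az = az)
}

#' Bootstrap Az significance threshold
#'
#' Repeats the full leave-one-out Az procedure after randomizing the trial
#' labels, `n_bootstrap` times, and returns the empirical `1 - alpha`
#' quantile of the pooled null Az values (or of the per-randomization max
#' across windows when `cfg$familywise`). `cfg$bootstrap_centers` may name a
#' subsampled window grid for tractability.
#'
#' @inheritParams loo_az
#' @param seed Positive integer seed (default `cfg$seed`).
#' @return The Az threshold (scalar), with the null matrix
#'   (randomizations x windows) attached as attribute `"null_az"`.
#' @export
bootstrap_threshold <- function(ep, outcomes = NULL,
                                cfg = discriminant_config(),
                                seed = cfg$seed) {
  stopifnot(inherits(ep, "lfp_epochs"))
  if (is.null(outcomes)) outcomes <- ep$trials$outcome
  y <- .as_binary(outcomes)
  if (min(sum(y == 1), sum(y == 0)) < 2)
    stop("need at least 2 trials per class")
  if (cfg$n_bootstrap < 100)
    warning("n_bootstrap < 100 gives an unstable threshold quantile")
  centers <- cfg$bootstrap_centers
  if (is.null(centers)) centers <- window_centers(cfg)
  F <- .window_features(ep, centers, cfg$window_ms)
  n <- length(y)
  set.seed(seed)
  perms <- t(vapply(seq_len(cfg$n_bootstrap),
                    function(b) sample.int(n) - 1L, integer(n)))
  null_az <- cpp_null_az(F, y, perms, cfg$l2_lambda, cfg$max_iter, cfg$tol)
  pool <- if (cfg$familywise) apply(null_az, 1, max) else as.vector(null_az)
  thr <- unname(quantile(pool, 1 - cfg$alpha, type = 7))
  attr(thr, "null_az") <- null_az
  thr
}

#' Detect early/late discriminating components
#'
#' Strict local maxima of the Az curve above the threshold, thinned to a
#' minimum mutual separation (`min_separation_ms`, keeping the higher peak;
#' ties break toward the earlier centre). At most two are returned (the top
#' two by Az when more survive); the earliest is labelled `early`, the next
#' `late`.
#'
#' @param az Az values over the window grid.
#' @param az_threshold Significance threshold from [bootstrap_threshold()].
#' @param centers Window centres in ms.
#' @param min_separation_ms Minimum peak separation (default 100 ms).
#' @return `data.frame` with columns `label`, `peak_center_ms`, `peak_az`
#'   (zero rows when nothing is significant).
#' @export
detect_components <- function(az, az_threshold, centers,
                              min_separation_ms = 100) {
  stopifnot(length(az) == length(centers))
  n <- length(az)
  is_peak <- vapply(seq_len(n), function(i) {
    if (az[i] <= az_threshold) return(FALSE)
    left <- if (i > 1) az[i] > az[i - 1] else TRUE
    right <- if (i < n) az[i] >= az[i + 1] else TRUE  # tie -> earlier centre
    left && right
  }, TRUE)
  cand <- which(is_peak)
  cand <- cand[order(-az[cand], centers[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(centers[i] - centers[kept]) >= min_separation_ms))
      kept <- c(kept, i)
  }
  if (length(kept) > 2) kept <- kept[1:2]  # ranked by Az beyond two
  kept <- kept[order(centers[kept])]
  if (length(kept) == 0)
    return(data.frame(label = character(0), peak_center_ms = numeric(0),
                      peak_az = numeric(0)))
  data.frame(label = c("early", "late")[seq_along(kept)],
             peak_center_ms = centers[kept], peak_az = az[kept])
}

#' Temporal profile of a discriminating component
#'
#' Applies a spatial weighting vector to every sample of an extended window:
#' `y_i(t) = w' x_i(t)` (no intercept - the spatial pattern only), returning
#' per-trial traces and the mean traces of positive (correct) and negative
#' (incorrect) outcome trials.
#'
#' @param ep An `lfp_epochs` object.
#' @param w Spatial weights, one per channel.
#' @param extended_window_ms Window in ms (default `c(-200, 600)`).
#' @param outcomes Trial outcomes; default `ep$trials$outcome`.
#' @return List with `times_ms`, `profiles` (trials x samples),
#'   `mean_positive`, `mean_negative`.
#' @export
project_profile <- function(ep, w, extended_window_ms = c(-200, 600),
                            outcomes = NULL) {
  stopifnot(inherits(ep, "lfp_epochs"))
  d <- dim(ep$data)
  if (length(w) != d[2]) stop("weights must have one entry per channel")
  if (is.null(outcomes)) outcomes <- ep$trials$outcome
  y <- .as_binary(outcomes)
  use <- ep$times_ms >= extended_window_ms[1] &
    ep$times_ms <= extended_window_ms[2]
  prof <- matrix(0, d[1], sum(use))
  for (i in seq_len(d[1])) {
    prof[i, ] <- drop(w %*% ep$data[i, , use])
  }
  list(times_ms = ep$times_ms[use], profiles = prof,
       mean_positive = colMeans(prof[y == 1, , drop = FALSE]),
       mean_negative = colMeans(prof[y == 0, , drop = FALSE]))
}

#' Univariate (single-channel) Az curves
#'
#' Runs the leave-one-out Az procedure per individual channel, for
#' comparison with the multivariate curve.
#'
#' @inheritParams loo_az
#' @return List with `centers`, `az` (channels x windows matrix) and
#'   `multivariate` (the full-channel Az vector).
#' @export
compare_univariate <- function(ep, outcomes = NULL,
                               cfg = discriminant_config()) {
  stopifnot(inherits(ep, "lfp_epochs"))
  if (is.null(outcomes)) outcomes <- ep$trials$outcome
  y <- .as_binary(outcomes)
  centers <- window_centers(cfg)
  F <- .window_features(ep, centers, cfg$window_ms)
  d <- dim(F)
  az <- matrix(0, d[2], d[3],
               dimnames = list(ep$channel_labels, NULL))
  for (ch in seq_len(d[2])) {
    az[ch, ] <- as.vector(cpp_az_grid(F[, ch, , drop = FALSE], y,
                                      cfg$l2_lambda, cfg$max_iter, cfg$tol))
  }
  multi <- as.vector(cpp_az_grid(F, y, cfg$l2_lambda, cfg$max_iter, cfg$tol))
  list(centers = centers, az = az, multivariate = multi)
}

#' Full sliding-window discriminant analysis
#'
#' Convenience wrapper running [loo_az()], [bootstrap_threshold()],
#' per-window spatial weights and projections, [detect_components()], and
#' the component temporal profiles ([project_profile()]) in one call.
#'
#' @inheritParams loo_az
#' @param seed Seed for the bootstrap (default `cfg$seed`).
#' @return An object of class `discriminant_result`: `centers`, `az`,
#'   `az_threshold`, `weights` (windows x channels), `projections`
#'   (trials x windows, Eq.-style `w' x` window means), `components`, and
#'   `profiles` (one [project_profile()] result per detected component).
#' @export
discriminant_analysis <- function(ep, outcomes = NULL,
                                  cfg = discriminant_config(),
                                  seed = cfg$seed) {
  stopifnot(inherits(ep, "lfp_epochs"))
  if (is.null(outcomes)) outcomes <- ep$trials$outcome
  y <- .as_binary(outcomes)
  centers <- window_centers(cfg)
  F <- .window_features(ep, centers, cfg$window_ms)
  az <- as.vector(cpp_az_grid(F, y, cfg$l2_lambda, cfg$max_iter, cfg$tol))
  thr <- bootstrap_threshold(ep, outcomes, cfg, seed = seed)

  n_ch <- dim(F)[2]
  weights <- matrix(0, length(centers), n_ch,
                    dimnames = list(NULL, ep$channel_labels))
  projections <- matrix(0, dim(F)[1], length(centers))
  for (wdx in seq_along(centers)) {
    fit <- fit_window_classifier(F[, , wdx, drop = TRUE], y, cfg)
    weights[wdx, ] <- fit$weights
    projections[, wdx] <- F[, , wdx] %*% fit$weights
  }
  comps <- detect_components(az, as.numeric(thr), centers,
                             cfg$min_separation_ms)
  profiles <- lapply(seq_len(nrow(comps)), function(k) {
    wdx <- match(comps$peak_center_ms[k], centers)
    project_profile(ep, weights[wdx, ], outcomes = outcomes)
  })
  names(profiles) <- comps$label
  structure(list(centers = centers, az = az,
                 az_threshold = as.numeric(thr),
                 null_az = attr(thr, "null_az"),
                 weights = weights, projections = projections,
                 components = comps, profiles = profiles,
                 n_trials = length(y), seed = seed, config = cfg),
            class = "discriminant_result")
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat(sprintf("<discriminant_result> %d windows (%g..%g ms), %d trials\n",
              length(x$centers), min(x$centers), max(x$centers), x$n_trials))
  cat(sprintf("  max Az %.3f at %g ms; threshold (alpha=%g) %.3f\n",
              max(x$az), x$centers[which.max(x$az)], x$config$alpha,
              x$az_threshold))
  if (nrow(x$components)) {
    for (k in seq_len(nrow(x$components)))
      cat(sprintf("  %s component: %g ms, Az %.3f\n",
                  x$components$label[k], x$components$peak_center_ms[k],
                  x$components$peak_az[k]))
  } else cat("  no significant components\n")
  invisible(x)
}
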