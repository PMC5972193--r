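#' Task configuration for the IED set-shifting schedule
#'
#' Describes the nine-rule intra-/extradimensional (IED) set-shifting
#' schedule: a rule is "learned" (and the schedule advances) after
#' `criterion_run` consecutive correct choices; a rule block that reaches
#' `max_trials_per_rule` trials without the criterion run ends the session
#' with a failure flag. Feedback lasts `feedback_duration` seconds and the
#' next trial's stimuli appear `inter_trial_onset_gap` seconds after feedback
#' onset.
#'
#' `rule_types` labels each rule; `"reversal"` rules reuse the on-screen
#' objects of the preceding rule, while discrimination/shift rules
#' (`"compound 1"`, `"compound 2"`, `"intradimensional shift"`,
#' `"extradimensional shift"`) introduce novel stimuli on their first trial.
#'
#' @param n_rules Number of rules in the schedule (default 9).
#' @param criterion_run Consecutive correct trials required to advance
#'   (default 6).
#' @param max_trials_per_rule Trial cap per rule block (default 50).
#' @param feedback_duration Feedback duration in seconds (default 0.5).
#' @param inter_trial_onset_gap Seconds from feedback onset to the next
#'   stimulus onset (default 2.7).
#' @param rule_types Character vector of rule labels, recycled/truncated to
#'   `n_rules`. Defaults to the standard nine-rule IED order.
#' @param stop_on_failure Terminate the session when a rule block fails
#'   (default `TRUE`, the task's own behaviour).
#' @return An object of class `ied_task_config`.
#' @export
task_config <- function(n_rules = 9L,
                        criterion_run = 6L,
                        max_trials_per_rule = 50L,
                        feedback_duration = 0.5,
                        inter_trial_onset_gap = 2.7,
                        rule_types = NULL,
                        stop_on_failure = TRUE) {
  if (is.null(rule_types)) {
    rule_types <- c("simple discrimination", "simple reversal",
                    "compound 1", "compound 2", "reversal",
                    "intradimensional shift", "reversal",
                    "extradimensional shift", "reversal")
  }
  n_rules <- as.integer(n_rules)
  criterion_run <- as.integer(criterion_run)
  max_trials_per_rule <- as.integer(max_trials_per_rule)
  if (n_rules < 1L) stop("n_rules must be >= 1")
  if (criterion_run < 1L) stop("criterion_run must be >= 1")
  if (max_trials_per_rule < criterion_run)
    stop("impossible config: criterion_run > max_trials_per_rule")
  if (feedback_duration <= 0 || inter_trial_onset_gap <= 0)
    stop("durations must be positive")
  rule_types <- rep_len(as.character(rule_types), n_rules)
  structure(list(n_rules = n_rules,
                 criterion_run = criterion_run,
                 max_trials_per_rule = max_trials_per_rule,
                 feedback_duration = feedback_duration,
                 inter_trial_onset_gap = inter_trial_onset_gap,
                 rule_types = rule_types,
                 stop_on_failure = isTRUE(stop_on_failure)),
            class = "ied_task_config")
}

#' Behavioural agent configuration
#'
#' A simple monotone learning model. On trial `t` of a rule block the
#' probability of a correct choice is
#' `p(t) = p_asymptote - (p_asymptote - 0.5) * exp(-learn_rate * (t - 1))`,
#' mixed with a `lapse` probability of responding at random. Reaction times
#' are log-normal in milliseconds; trials following an incorrect trial get
#' `rt_post_error_shift` added on the log scale (post-error slowing).
#'
#' @param p_asymptote Correct-choice probability once the rule is learned.
#' @param learn_rate Per-trial exponential approach rate towards
#'   `p_asymptote`.
#' @param lapse Probability of a random (coin-flip) choice.
#' @param reset_on_rule_change Reset the learning curve at each rule change
#'   (default `TRUE`).
#' @param rt_lognormal_mu,rt_lognormal_sigma Log-millisecond location and
#'   scale of the reaction-time distribution. The defaults give a median
#'   near 0.94 s with a right-skewed interquartile range, typical of
#'   touch-screen choice tasks.
#' @param rt_post_error_shift Additive log-ms slowing applied to trials whose
#'   predecessor was incorrect.
#' @param force_reversal_error Force the first trial of a reversal rule
#'   incorrect when the previous rule was learned (default `TRUE`): the
#'   agent, still applying the old rule, necessarily errs, which populates
#'   the unexpected-incorrect expectancy class. Disable for idealised
#'   agents.
#' @details `learn_rate = Inf` means instant learning: `p(t) = p_asymptote`
#'   from the first trial of a block.
#' @return An object of class `ied_agent_config`.
#' @export
agent_config <- function(p_asymptote = 0.9,
                         learn_rate = 0.5,
                         lapse = 0.1,
                         reset_on_rule_change = TRUE,
                         rt_lognormal_mu = log(940),
                         rt_lognormal_sigma = 0.45,
                         rt_post_error_shift = 0.11,
                         force_reversal_error = TRUE) {
  if (p_asymptote < 0 || p_asymptote > 1) stop("p_asymptote must be in [0, 1]")
  if (lapse < 0 || lapse > 1) stop("lapse must be in [0, 1]")
  if (learn_rate < 0) stop("learn_rate must be >= 0")
  if (rt_lognormal_sigma < 0) stop("rt_lognormal_sigma must be >= 0")
  structure(list(p_asymptote = p_asymptote,
                 learn_rate = learn_rate,
                 lapse = lapse,
                 reset_on_rule_change = isTRUE(reset_on_rule_change),
                 rt_lognormal_mu = rt_lognormal_mu,
                 rt_lognormal_sigma = rt_lognormal_sigma,
                 rt_post_error_shift = rt_post_error_shift,
                 force_reversal_error = isTRUE(force_reversal_error)),
            class = "ied_agent_config")
}

# rules whose first trial shows novel on-screen objects (new discriminanda)
.novel_stimulus_rules <- function(task) {
  which(task$rule_types %in% c("compound 1", "compound 2",
                               "intradimensional shift",
                               "extradimensional shift"))
}

.reversal_rules <- function(task) {
  which(grepl("reversal", task$rule_types, fixed = TRUE))
}

#' Simulate an IED behavioural session
#'
#' Runs the agent through the rule schedule and returns one row per trial
#' with outcomes, novelty and expectancy labels, reaction times and event
#' onsets. A rule block ends at the first run of `criterion_run` consecutive
#' correct trials, or with a failure flag at `max_trials_per_rule` trials
#' (by default the session then terminates, as the task itself does). The
#' first trial of a reversal rule is forced incorrect when the previous rule
#' was learned: the agent, still applying the old rule, necessarily errs.
#'
#' Onsets are in seconds from recording start: `selection_time =
#' stimulus_onset + rt/1000`, feedback is delivered at selection
#' (`feedback_onset = selection_time`), and the next stimulus appears
#' `inter_trial_onset_gap` seconds after feedback onset.
#'
#' @param task An [task_config()] object.
#' @param agent An [agent_config()] object.
#' @param seed Positive integer seed; the sequence is fully reproducible.
#' @param session_start Stimulus onset of the first trial, seconds
#'   (default 2).
#' @return A `data.frame` of class `ied_trials`, ordered by `index`, with
#'   columns `index`, `rule_index`, `rule_type`, `trial_in_rule`, `outcome`,
#'   `prev_outcome`, `novelty`, `expectancy_class`, `rt_ms`,
#'   `stimulus_onset`, `selection_time`, `feedback_onset`, `rule_failed`.
#'   Attributes `passed_rules` and `failed` summarise the session.
#' @export
simulate_behavior <- function(task = task_config(), agent = agent_config(),
                              seed, session_start = 2) {
  if (missing(seed)) stop("seed must be given")
  seed <- as.integer(seed)
  if (is.na(seed) || seed <= 0L) stop("seed must be a positive integer")
  stopifnot(inherits(task, "ied_task_config"),
            inherits(agent, "ied_agent_config"))
  set.seed(seed)

  novel_rules <- .novel_stimulus_rules(task)
  reversal_rules <- .reversal_rules(task)

  rows <- list()
  idx <- 0L
  prev_outcome <- "none"
  failed <- FALSE
  passed_rules <- 0L
  t_cursor <- session_start

  for (r in seq_len(task$n_rules)) {
    streak <- 0L
    trial_in_rule <- 0L
    prior_learned <- (r > 1L) && (passed_rules == r - 1L)
    repeat {
      trial_in_rule <- trial_in_rule + 1L
      idx <- idx + 1L
      tt <- if (agent$reset_on_rule_change) trial_in_rule else idx
      p_curve <- if (is.infinite(agent$learn_rate)) agent$p_asymptote else
        agent$p_asymptote -
          (agent$p_asymptote - 0.5) * exp(-agent$learn_rate * (tt - 1L))
      p_correct <- (1 - agent$lapse) * p_curve + agent$lapse * 0.5
      forced_error <- agent$force_reversal_error && trial_in_rule == 1L &&
        r %in% reversal_rules && prior_learned
      correct <- if (forced_error) FALSE else runif(1) < p_correct

      log_rt <- rnorm(1, agent$rt_lognormal_mu, agent$rt_lognormal_sigma)
      if (prev_outcome == "incorrect") log_rt <- log_rt + agent$rt_post_error_shift
      rt_ms <- exp(log_rt)

      stim_on <- t_cursor
      sel_t <- stim_on + rt_ms / 1000
      rows[[idx]] <- data.frame(
        index = idx, rule_index = r, rule_type = task$rule_types[r],
        trial_in_rule = trial_in_rule,
        outcome = if (correct) "correct" else "incorrect",
        prev_outcome = prev_outcome,
        novelty = if (trial_in_rule == 1L && r %in% novel_rules) "novel" else "other",
        rt_ms = rt_ms, stimulus_onset = stim_on,
        selection_time = sel_t, feedback_onset = sel_t,
        rule_failed = FALSE, stringsAsFactors = FALSE)

      prev_outcome <- if (correct) "correct" else "incorrect"
      t_cursor <- sel_t + task$inter_trial_onset_gap
      streak <- if (correct) streak + 1L else 0L
      if (streak >= task$criterion_run) {
        passed_rules <- passed_rules + 1L
        break
      }
      if (trial_in_rule >= task$max_trials_per_rule) {
        rows[[idx]]$rule_failed <- TRUE
        failed <- TRUE
        break
      }
    }
    if (failed && task$stop_on_failure) break
  }

  trials <- do.call(rbind, rows)
  trials$novelty <- .label_familiar(trials, task$criterion_run)
  trials <- categorize_trials(trials, task = task)
  class(trials) <- c("ied_trials", "data.frame")
  attr(trials, "task") <- task
  attr(trials, "passed_rules") <- passed_rules
  attr(trials, "failed") <- failed
  trials
}

# familiar = inside a maximal run of >= criterion_run consecutive correct
# trials within one rule block; novel labels (first trial of new-object
# rules) take precedence.
.label_familiar <- function(trials, criterion_run) {
  nov <- trials$novelty
  correct <- trials$outcome == "correct"
  runs <- rle(paste(trials$rule_index, correct))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$lengths)) {
    if (runs$lengths[k] >= criterion_run && correct[starts[k]]) {
      span <- starts[k]:ends[k]
      nov[span][nov[span] != "novel"] <- "familiar"
    }
  }
  nov
}

#' @export
print.ied_trials <- function(x, ...) {
  cat(sprintf("<ied_trials> %d trials, %d rules reached, %s\n",
              nrow(x), max(x$rule_index),
              if (isTRUE(attr(x, "failed"))) "session failed" else "session passed"))
  cat(sprintf("  correct %d / incorrect %d; duration %.1f s\n",
              sum(x$outcome == "correct"), sum(x$outcome == "incorrect"),
              max(x$feedback_onset)))
  invisible(x)
}
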