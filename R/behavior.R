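#' Trial-transition table
#'
#' Classifies every trial that has a predecessor by the pair (own outcome,
#' predecessor outcome): `cc` correct-after-correct, `ci`
#' correct-after-incorrect, `ic` incorrect-after-correct, `ii`
#' incorrect-after-incorrect. Trials without a predecessor (the session's
#' first trial, or any trial whose `prev_outcome` is `"none"`) are excluded
#' and counted in `n_excluded`.
#'
#' @param trials Trial table ordered by `index`, with `outcome` and
#'   optionally `prev_outcome` (derived from the ordering when absent).
#' @return An object of class `transition_table`: counts `cc`, `ci`, `ic`,
#'   `ii`, `n_excluded`, and totals `n_correct`, `n_incorrect`, `n_total`.
#' @export
transition_table <- function(trials) {
  stopifnot(is.data.frame(trials), "outcome" %in% names(trials))
  if (!is.null(trials$index) && is.unsorted(trials$index))
    stop("trials must be ordered by index")
  n <- nrow(trials)
  prev <- if ("prev_outcome" %in% names(trials)) trials$prev_outcome
  else c("none", trials$outcome[-n])
  own <- trials$outcome
  has_prev <- prev %in% c("correct", "incorrect")
  tab <- list(
    cc = sum(own == "correct" & prev == "correct"),
    ci = sum(own == "correct" & prev == "incorrect"),
    ic = sum(own == "incorrect" & prev == "correct"),
    ii = sum(own == "incorrect" & prev == "incorrect"),
    n_excluded = sum(!has_prev))
  tab$n_correct <- sum(own == "correct")
  tab$n_incorrect <- sum(own == "incorrect")
  tab$n_total <- n
  structure(tab, class = "transition_table")
}

#' Build a transition table from printed counts
#'
#' For working with published transition counts directly (e.g. re-deriving
#' rates from a published table) rather than from a trial sequence.
#'
#' @param cc,ci,ic,ii Counts: correct-after-correct, correct-after-incorrect,
#'   incorrect-after-correct, incorrect-after-incorrect.
#' @param n_excluded Trials without a predecessor (default 0).
#' @return A `transition_table`.
#' @export
transition_table_from_counts <- function(cc, ci, ic, ii, n_excluded = 0) {
  stopifnot(cc >= 0, ci >= 0, ic >= 0, ii >= 0, n_excluded >= 0)
  structure(list(cc = cc, ci = ci, ic = ic, ii = ii,
                 n_excluded = n_excluded,
                 n_correct = cc + ci, n_incorrect = ic + ii,
                 n_total = cc + ci + ic + ii + n_excluded),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat("<transition_table>\n")
  cat(sprintf("  correct   (n=%d): after correct %d, after incorrect %d\n",
              x$n_correct, x$cc, x$ci))
  cat(sprintf("  incorrect (n=%d): after correct %d, after incorrect %d\n",
              x$n_incorrect, x$ic, x$ii))
  cat(sprintf("  excluded (no predecessor): %d of %d\n", x$n_excluded, x$n_total))
  invisible(x)
}

#' Consecutive-outcome rates
#'
#' Percentage of trials following a correct trial that were again correct,
#' `cc/(cc+ic)*100`, and of trials following an incorrect trial that were
#' again incorrect, `ii/(ii+ci)*100`.
#'
#' @param t A [transition_table()] (or a trial table, converted first).
#' @return Named numeric vector `c(rate_after_correct, rate_after_incorrect)`
#'   in percent.
#' @export
consecutive_rates <- function(t) {
  if (is.data.frame(t)) t <- transition_table(t)
  stopifnot(inherits(t, "transition_table"))
  if (t$cc + t$ic == 0 || t$ii + t$ci == 0)
    stop("zero denominator: no trials follow one of the outcome types")
  c(rate_after_correct = 100 * t$cc / (t$cc + t$ic),
    rate_after_incorrect = 100 * t$ii / (t$ii + t$ci))
}

.rt_quartiles <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(n = length(x), median = q[2], q25 = q[1], q75 = q[3])
}

#' Reaction-time summaries by trial group
#'
#' Medians with 25-75% interquartile ranges (linear interpolation between
#' order statistics) for the standard groups: all correct trials, all
#' incorrect trials, and the four transition categories
#' (correct/incorrect following correct/incorrect).
#'
#' @param trials Trial table with `outcome`, `rt_ms` and (derivable)
#'   `prev_outcome`.
#' @param groups Character vector naming the groups to include; default all
#'   six.
#' @param drop_empty Silently drop empty groups instead of erroring
#'   (default `FALSE`).
#' @return `data.frame` with `group`, `n`, `median`, `q25`, `q75` (ms).
#'   Empty groups are an error unless `drop_empty`.
#' @export
rt_summary <- function(trials,
                       groups = c("correct", "incorrect",
                                  "correct_after_correct",
                                  "correct_after_incorrect",
                                  "incorrect_after_correct",
                                  "incorrect_after_incorrect"),
                       drop_empty = FALSE) {
  stopifnot(is.data.frame(trials), all(c("outcome", "rt_ms") %in% names(trials)))
  n <- nrow(trials)
  prev <- if ("prev_outcome" %in% names(trials)) trials$prev_outcome
  else c("none", trials$outcome[-n])
  pick <- list(
    correct = trials$outcome == "correct",
    incorrect = trials$outcome == "incorrect",
    correct_after_correct = trials$outcome == "correct" & prev == "correct",
    correct_after_incorrect = trials$outcome == "correct" & prev == "incorrect",
    incorrect_after_correct = trials$outcome == "incorrect" & prev == "correct",
    incorrect_after_incorrect = trials$outcome == "incorrect" & prev == "incorrect")
  out <- lapply(groups, function(g) {
    sel <- pick[[g]]
    if (is.null(sel)) stop("unknown group '", g, "'")
    if (!any(sel)) {
      if (drop_empty) return(NULL)
      stop("empty group '", g, "'")
    }
    cbind(data.frame(group = g), .rt_quartiles(trials$rt_ms[sel]))
  })
  do.call(rbind, out)
}

#' Two-sample rank-sum test
#'
#' Mann-Whitney U with midrank tie handling, normal approximation with tie
#' and continuity correction, two-sided.
#'
#' @param a,b Numeric samples (e.g. reaction times of two trial groups).
#' @return List with `U` (Mann-Whitney statistic of sample `a`), `p`
#'   (two-sided).
#' @export
ranksum_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Kruskal-Wallis test across trial groups
#'
#' Rank-based k-sample test with tie correction; chi-square p-value with
#' k - 1 degrees of freedom. Degenerate input (all observations equal)
#' yields `H = 0`, `p = 1`.
#'
#' @param groups List of numeric vectors (>= 2 nonempty groups).
#' @return List with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups))
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least 2 nonempty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  kt <- kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Full behavioural analysis of a session
#'
#' Transition table, consecutive-outcome rates, reaction-time summaries and
#' the nonparametric RT tests (correct vs incorrect; consecutive-correct vs
#' consecutive-incorrect; Kruskal-Wallis across the four transition
#' categories).
#'
#' @param trials Trial table from [simulate_behavior()] or
#'   [read_events_tsv()] (feedback rows).
#' @return List with `transitions`, `rates`, `rt`, `tests`.
#' @export
behavior_summary <- function(trials) {
  tab <- transition_table(trials)
  rates <- consecutive_rates(tab)
  rt <- rt_summary(trials, drop_empty = TRUE)
  n <- nrow(trials)
  prev <- if ("prev_outcome" %in% names(trials)) trials$prev_outcome
  else c("none", trials$outcome[-n])
  rt_corr <- trials$rt_ms[trials$outcome == "correct"]
  rt_inc <- trials$rt_ms[trials$outcome == "incorrect"]
  rt_cc <- trials$rt_ms[trials$outcome == "correct" & prev == "correct"]
  rt_ii <- trials$rt_ms[trials$outcome == "incorrect" & prev == "incorrect"]
  four <- list(cc = rt_cc,
               ci = trials$rt_ms[trials$outcome == "correct" & prev == "incorrect"],
               ic = trials$rt_ms[trials$outcome == "incorrect" & prev == "correct"],
               ii = rt_ii)
  pair_test <- function(a, b) {
    if (length(a) == 0 || length(b) == 0) return(NULL)
    ranksum_test(a, b)
  }
  tests <- list(
    correct_vs_incorrect = pair_test(rt_corr, rt_inc),
    consecutive_correct_vs_incorrect = pair_test(rt_cc, rt_ii),
    across_transitions = if (sum(lengths(four) > 0) >= 2)
      kruskal_wallis(four) else NULL)
  list(transitions = tab, rates = rates, rt = rt, tests = tests)
}
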