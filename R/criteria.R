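#' Applied learning criterion: 17 correct of the most recent 20 trials
#'
#' The criterion used for all birds in the analysis: a learner finishes a
#' phase at the first trial `t >= 17` at which the last `min(t, 20)`
#' completed trials contain at least 17 correct choices. Trial 17 is
#' therefore the earliest possible finish (a perfect run).
#'
#' Incomplete trials (no choice made) must be removed before calling; the
#' criterion is defined over completed trials only.
#'
#' @param correct_flags Integer or logical vector of 0/1 correctness flags,
#'   one per completed trial, in trial order.
#' @return The finish trial (1-based index into `correct_flags`) as an
#'   integer, or `NA_integer_` if the criterion is never met.
#' @seealso [criterion_fixed_window()], [criterion_sliding_window()] for the
#'   legacy rules this criterion replaces.
#' @examples
#' criterion_applied(rep(1, 17))            # 17
#' criterion_applied(c(0, 0, 0, rep(1, 17)))  # 20
#' @export
criterion_applied <- function(correct_flags) {
  flags <- check_flags(correct_flags)
  n <- length(flags)
  if (n < 17L) return(NA_integer_)
  cs <- c(0L, cumsum(flags))
  for (t in 17:n) {
    lo <- max(1L, t - 19L)
    if (cs[t + 1L] - cs[lo] >= 17L) return(as.integer(t))
  }
  NA_integer_
}

#' Legacy fixed-window learning criterion
#'
#' The rule originally applied to core- and middle-population birds:
#' assessed only at the end of each 10-trial set (trials 20, 30, 40, ...),
#' requiring 17 of the last 20 choices correct with minimum counts of 8 and
#' 9 correct across the last two sets of 10 trials. Passing birds were
#' assigned the set-end trial, which can overshoot the true passing trial.
#'
#' Whether the (8, 9) minima are tied to the order of the two sets is not
#' documented; both readings are available. The default `minima_ordered =
#' TRUE` requires the penultimate set to hold >= 8 and the final set >= 9;
#' `FALSE` accepts the counts in either order. A 7/10 + 10/10 split fails
#' under both readings.
#'
#' @inheritParams criterion_applied
#' @param minima_ordered If `TRUE` the first of the two 10-trial sets needs
#'   >= 8 correct and the second >= 9; if `FALSE` either assignment passes.
#' @return The set-end finish trial (a multiple of 10, >= 20) or
#'   `NA_integer_`.
#' @export
criterion_fixed_window <- function(correct_flags, minima_ordered = TRUE) {
  flags <- check_flags(correct_flags)
  n <- length(flags)
  if (n < 20L) return(NA_integer_)
  for (t in seq(20L, n, by = 10L)) {
    if (window_pass(flags[(t - 19L):t], minima_ordered)) return(as.integer(t))
  }
  NA_integer_
}

#' Legacy sliding-window learning criterion (with early-pass anomaly)
#'
#' The rule originally applied to edge-population birds: the fixed-window
#' requirements (17/20 overall, set minima 8 and 9) assessed at every trial
#' from 20 onwards. Because the 20-trial window slides, a learner can reach
#' criterion at the *start* of a trial, before choosing: e.g. after three
#' wrong then seventeen correct choices, the window at the start of trial 21
#' holds 8/10 and at least 9/10 correct whatever the next choice is. This
#' replica of the legacy behaviour exists for data audits; use
#' [criterion_applied()] for analysis.
#'
#' @inheritParams criterion_fixed_window
#' @return The finish trial as an integer with attribute `pre_choice`:
#'   `FALSE` if a full 20-trial window passed at that trial, `TRUE` if the
#'   pass happened at the start of that trial irrespective of its outcome
#'   (in which case the returned index may be `length(correct_flags) + 1`).
#'   `NA_integer_` if never met.
#' @export
criterion_sliding_window <- function(correct_flags, minima_ordered = TRUE) {
  flags <- check_flags(correct_flags)
  n <- length(flags)
  if (n < 20L) return(NA_integer_)
  for (t in 20:n) {
    if (window_pass(flags[(t - 19L):t], minima_ordered)) {
      return(structure(as.integer(t), pre_choice = FALSE))
    }
    # Start of trial t+1: window holds trials (t-18)..(t+1); the trial-(t+1)
    # flag is unknown, so pass only if both outcomes would satisfy the rule.
    known <- flags[(t - 18L):t]
    if (window_pass(c(known, 0L), minima_ordered) &&
        window_pass(c(known, 1L), minima_ordered)) {
      return(structure(t + 1L, pre_choice = TRUE))
    }
  }
  NA_integer_
}

# Shared 20-trial window test: >=17/20 plus the (8, 9) set minima.
window_pass <- function(window20, minima_ordered) {
  c1 <- sum(window20[1:10])
  c2 <- sum(window20[11:20])
  if (c1 + c2 < 17L) return(FALSE)
  if (minima_ordered) c1 >= 8L && c2 >= 9L
  else min(c1, c2) >= 8L && max(c1, c2) >= 9L
}

check_flags <- function(correct_flags) {
  if (length(correct_flags) == 0L) return(integer(0))
  flags <- as.integer(correct_flags)
  if (anyNA(flags) || !all(flags %in% c(0L, 1L))) {
    stop("`correct_flags` must contain only 0/1 values for completed trials",
         call. = FALSE)
  }
  flags
}

#' Count choice-option switches
#'
#' A switch is an adjacent pair of completed trials on which different
#' options were chosen. When `upto` is given (typically the finish trial),
#' switches are counted up to and including that trial.
#'
#' @param choices Vector of chosen options (any atomic type; `NA` entries,
#'   e.g. incomplete trials, must be removed beforehand).
#' @param upto Optional last trial index to include.
#' @return Non-negative integer count.
#' @examples
#' count_switches(c("A", "B", "A", "B"))  # 3
#' @export
count_switches <- function(choices, upto = NULL) {
  if (anyNA(choices)) stop("`choices` must not contain NA; drop incomplete trials first",
                           call. = FALSE)
  if (!is.null(upto)) {
    stopifnot(upto >= 1, upto <= length(choices))
    choices <- choices[seq_len(upto)]
  }
  if (length(choices) < 2L) return(0L)
  sum(choices[-1L] != choices[-length(choices)])
}
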