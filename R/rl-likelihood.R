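#' Rescorla-Wagner attraction update
#'
#' Moves the chosen option's attraction towards the experienced payoff:
#' `A_chosen' = (1 - phi) * A_chosen + phi * payoff`. The unchosen option's
#' attraction is untouched (no forgetting term). The update is a convex
#' combination, so the new attraction always lies between the old value and
#' the payoff.
#'
#' @param attractions Numeric vector of length 2, one attraction per option.
#' @param choice Index of the chosen option (1 or 2).
#' @param payoff Experienced payoff on this trial.
#' @param phi Information-updating rate in `[0, 1]`; 0 leaves attractions
#'   unchanged, 1 replaces the chosen attraction with the payoff.
#' @return Updated attraction vector.
#' @export
update_attraction <- function(attractions, choice, payoff, phi) {
  stopifnot(length(attractions) == 2, choice %in% c(1, 2))
  if (phi < 0 || phi > 1) stop("`phi` must lie in [0, 1]", call. = FALSE)
  attractions[choice] <- (1 - phi) * attractions[choice] + phi * payoff
  attractions
}

#' Softmax choice probabilities
#'
#' Probability of choosing each of the two options given their attractions
#' and the risk-sensitivity rate `lambda`:
#' `P(i) = exp(lambda * A_i) / sum_m exp(lambda * A_m)`. Computed on the
#' attraction difference (log-sum-exp form) so it is stable for large
#' `lambda * gap`. `lambda = 0` generates random choice.
#'
#' @param attractions Numeric vector of length 2.
#' @param lam Risk-sensitivity rate, `>= 0`; larger values make choice more
#'   deterministic towards the higher attraction.
#' @return Numeric vector of two probabilities summing to 1.
#' @export
choice_probability <- function(attractions, lam) {
  stopifnot(length(attractions) == 2)
  if (lam < 0) stop("`lam` must be non-negative", call. = FALSE)
  p1 <- stats::plogis(lam * (attractions[1] - attractions[2]))
  c(p1, 1 - p1)
}

#' Log-likelihood of one bird's choice sequence
#'
#' Sums the log softmax probability of each observed completed choice,
#' updating attractions after every trial with the phase-specific
#' information-updating rate. Attractions persist across the
#' initial-to-reversal boundary while `(phi, lambda)` switch to the
#' reversal-phase values, so reversal estimation starts from the attraction
#' state accumulated over all previous choices.
#'
#' @param bird_trials Trial records for a single bird, sorted by phase
#'   (initial before reversal) then trial; incomplete trials are dropped
#'   internally.
#' @param params Named list with elements `phi` and `lam`, each a numeric
#'   vector of length 2 (initial, reversal values).
#' @param a0 Initial attraction for both options (default 0).
#' @param payoff Payoff magnitude of a rewarded choice (default 1).
#' @return Total log-likelihood (scalar).
#' @export
sequence_log_likelihood <- function(bird_trials, params, a0 = 0, payoff = 1) {
  stopifnot(length(unique(bird_trials$bird_id)) <= 1)
  ph <- match(bird_trials$phase, PHASES)
  if (is.unsorted(ph)) stop("records must be sorted with initial before reversal",
                            call. = FALSE)
  if (any(diff(bird_trials$trial[ph == 1]) <= 0) ||
      any(diff(bird_trials$trial[ph == 2]) <= 0)) {
    stop("records must be sorted by trial within phase", call. = FALSE)
  }
  rows <- bird_trials[bird_trials$completed == 1L, ]
  A <- c(a0, a0)
  ll <- 0
  for (r in seq_len(nrow(rows))) {
    p <- match(rows$phase[r], PHASES)
    ch <- match(rows$choice[r], OPTIONS)
    pr <- choice_probability(A, params$lam[p])
    ll <- ll + log(pr[ch])
    pay <- if (rows$correct[r] == 1L) payoff else 0
    A <- update_attraction(A, ch, pay, params$phi[p])
  }
  ll
}

#' Highest posterior density interval
#'
#' Shortest interval containing a given fraction of the sample: the
#' minimal-width window over the sorted draws.
#'
#' @param x Numeric vector of posterior draws.
#' @param prob Target mass (default 0.89).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(x, prob = 0.89) {
  stopifnot(length(x) > 1, prob > 0, prob < 1)
  xs <- sort(x)
  n <- length(xs)
  m <- max(2L, ceiling(prob * n))  # draws the interval must contain
  if (m >= n) return(c(lower = xs[1], upper = xs[n]))
  widths <- xs[m:n] - xs[1:(n - m + 1L)]
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + m - 1L])
}
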