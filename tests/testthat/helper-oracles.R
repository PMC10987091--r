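# Independent brute-force oracles, deliberately written differently from the
# package implementations they check.

oracle_applied <- function(flags) {
  n <- length(flags)
  for (t in seq_len(n)) {
    if (t < 17) next
    w <- flags[max(1, t - 19):t]
    if (sum(w) >= 17) return(t)
  }
  NA_integer_
}

oracle_fixed <- function(flags, ordered = TRUE) {
  n <- length(flags)
  t <- 20L
  while (t <= n) {
    c1 <- sum(flags[(t - 19):(t - 10)])
    c2 <- sum(flags[(t - 9):t])
    ok <- if (ordered) (c1 >= 8 && c2 >= 9) else
      ((c1 >= 8 && c2 >= 9) || (c2 >= 8 && c1 >= 9))
    if (ok && c1 + c2 >= 17) return(t)
    t <- t + 10L
  }
  NA_integer_
}

oracle_switches <- function(choices) {
  k <- 0L
  for (j in seq_along(choices)[-1]) if (choices[j] != choices[j - 1]) k <- k + 1L
  k
}

# Trial-by-trial re-derivation of the RL sequence likelihood: attractions
# recomputed by folding over the history from scratch at every trial.
oracle_loglik <- function(bird_trials, params, a0 = 0, payoff = 1) {
  rows <- bird_trials[bird_trials$completed == 1L, ]
  rows <- rows[order(match(rows$phase, c("initial", "reversal")), rows$trial), ]
  attractions_before <- function(r) {
    A <- c(a0, a0)
    if (r == 1) return(A)
    for (q in 1:(r - 1)) {
      p <- if (rows$phase[q] == "initial") 1 else 2
      ch <- if (rows$choice[q] == "option1") 1 else 2
      pay <- if (rows$correct[q] == 1) payoff else 0
      A[ch] <- (1 - params$phi[p]) * A[ch] + params$phi[p] * pay
    }
    A
  }
  ll <- 0
  for (r in seq_len(nrow(rows))) {
    A <- attractions_before(r)
    p <- if (rows$phase[r] == "initial") 1 else 2
    num <- exp(params$lam[p] * A)
    pr <- num / sum(num)
    ch <- if (rows$choice[r] == "option1") 1 else 2
    ll <- ll + log(pr[ch])
  }
  ll
}

# O(n^2) search over all candidate intervals made of two sample points.
oracle_hpdi <- function(x, prob = 0.89) {
  xs <- sort(x)
  n <- length(xs)
  need <- ceiling(prob * n)
  best <- c(xs[1], xs[n])
  for (i in 1:n) {
    for (j in i:n) {
      if (j - i + 1 >= need && (xs[j] - xs[i]) < (best[2] - best[1])) {
        best <- c(xs[i], xs[j])
      }
    }
  }
  best
}

# Tiny hand-built valid trial table: two birds, both phases.
make_two_bird_trials <- function() {
  b1i <- data.frame(bird_id = "core_M01", population = "core", sex = "M",
                    phase = "initial", trial = 1:20,
                    choice = c("option2", "option2", "option1",
                               rep("option1", 17)),
                    completed = 1L)
  b1i$correct <- as.integer(b1i$choice == "option1")
  b1r <- data.frame(bird_id = "core_M01", population = "core", sex = "M",
                    phase = "reversal", trial = 1:22,
                    choice = c(rep("option1", 3), rep("option2", 19)),
                    completed = 1L)
  b1r$correct <- as.integer(b1r$choice == "option2")
  b2i <- data.frame(bird_id = "edge_F01", population = "edge", sex = "F",
                    phase = "initial", trial = 1:18,
                    choice = c("option2", rep("option2", 16), "option2"),
                    completed = 1L)
  b2i$choice <- rep("option2", 18)
  b2i$correct <- 1L
  # one incomplete trial in the female's reversal
  b2r <- data.frame(bird_id = "edge_F01", population = "edge", sex = "F",
                    phase = "reversal", trial = 1:19,
                    choice = c(rep("option1", 18), NA),
                    completed = c(rep(1L, 18), 0L))
  b2r$correct <- ifelse(b2r$completed == 1L, 1L, NA_integer_)
  rbind(b1i, b1r, b2i, b2r)[, c("bird_id", "population", "sex", "phase",
                                "trial", "choice", "correct", "completed")]
}

quick_cfg <- function(seed = 1L, chains = 2, adapt = 200, burnin = 100,
                      iter = 300) {
  rl_config(chains = chains, adapt = adapt, burnin = burnin, iter = iter,
            seed = seed, min_ess = 10)
}
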