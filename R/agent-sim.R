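#' Simulate one agent on the two-phase reversal task
#'
#' Generative loop of the learning model: on each trial the agent chooses
#' by softmax over its attractions, experiences the payoff, and updates the
#' chosen option's attraction. Option 1 is rewarded during initial
#' learning; at the phase boundary the rewarded option flips to option 2,
#' attractions carry over, and the reversal-phase `(phi, lambda)` take
#' over. Each phase ends at the applied learning criterion (or at the
#' trial cap, in which case the trajectory is marked unfinished via an `NA`
#' finish trial).
#'
#' Uses R's RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param phi,lam Numeric vectors of length 2: the (initial, reversal)
#'   information-updating and risk-sensitivity rates.
#' @param payoff Payoff magnitude of a rewarded choice (default 1).
#' @param a0 Initial attraction of both options (default 0).
#' @param max_trials Per-phase trial cap (default 300); prevents unbounded
#'   runs at pathological parameter values.
#' @param stop_at_criterion If `FALSE`, run exactly `max_trials` trials per
#'   phase regardless of the criterion (used for fixed-length recovery
#'   cohorts); the first criterion pass is still recorded.
#' @param extra_trials Integer vector of length 2: post-criterion trials to
#'   append per phase (emulating birds kept in test past criterion).
#' @return A list with `trials` (data frame: `phase`, `trial`, `choice`,
#'   `correct`, `reward`), `finish` (length-2 integer, `NA` when
#'   unfinished) and `switches` (length-2 integer, switches up to the
#'   finish trial, `NA` when unfinished).
#' @export
simulate_agent <- function(phi, lam, payoff = 1, a0 = 0, max_trials = 300,
                           stop_at_criterion = TRUE, extra_trials = c(0L, 0L)) {
  stopifnot(length(phi) == 2, length(lam) == 2,
            all(phi >= 0 & phi <= 1), all(lam >= 0), max_trials >= 1)
  raw <- simulate_agent_cpp(phi[1], lam[1], phi[2], lam[2], payoff, a0,
                            as.integer(max_trials), stop_at_criterion,
                            as.integer(extra_trials[1]),
                            as.integer(extra_trials[2]))
  trial <- unlist(lapply(raw$n_trials, seq_len))
  trials <- data.frame(phase = PHASES[raw$phase], trial = trial,
                       choice = OPTIONS[raw$choice], correct = raw$correct,
                       reward = raw$reward)
  switches <- vapply(1:2, function(ph) {
    fin <- raw$finish[ph]
    if (is.na(fin)) return(NA_integer_)
    ch <- raw$choice[raw$phase == ph]
    as.integer(count_switches(ch, upto = fin))
  }, integer(1))
  list(trials = trials, finish = raw$finish, switches = switches)
}

#' Draw per-bird learning parameters from a posterior or a fixed cell table
#'
#' In `"full"` mode each synthetic bird takes one posterior draw of the
#' group means plus a bird offset drawn from that draw's fitted
#' 4-dimensional offset covariance, preserving the correlation structure
#' among sex- and phase-specific learning parameters. In `"averaged"` mode
#' every bird gets the posterior-mean parameters of its cell
#' (representative average individuals).
#'
#' @param fit An `rl_fit` object (pooled level).
#' @param sex `"M"` or `"F"`.
#' @param n Number of birds to draw.
#' @param mode `"full"` or `"averaged"`.
#' @return Matrix with columns `phi_initial`, `phi_reversal`,
#'   `lam_initial`, `lam_reversal` on the natural scale.
#' @export
draw_bird_params <- function(fit, sex, n, mode = c("full", "averaged")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "rl_fit"))
  if (fit$level != "pooled") {
    stop("forward simulation draws from the pooled (across-population) fit",
         call. = FALSE)
  }
  cells <- cell_index(sex, PHASES)
  mu_p <- fit$draws$mu_phi[, sapply(cells, function(l)
    grep(mu_col(1, l), colnames(fit$draws$mu_phi), fixed = TRUE)), drop = FALSE]
  mu_l <- fit$draws$mu_lam[, sapply(cells, function(l)
    grep(mu_col(1, l), colnames(fit$draws$mu_lam), fixed = TRUE)), drop = FALSE]
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("phi_initial", "phi_reversal",
                                        "lam_initial", "lam_reversal")))
  if (mode == "averaged") {
    latent <- c(colMeans(mu_p), colMeans(mu_l))
    for (i in seq_len(n)) out[i, ] <- c(plogis(latent[1:2]), exp(latent[3:4]))
    return(out)
  }
  ndraw <- nrow(mu_p)
  Sig_cols <- matrix(seq_len(16), 4, 4)
  for (i in seq_len(n)) {
    d <- sample.int(ndraw, 1L)
    Sigma <- matrix(fit$draws$Sigma[d, ], 4, 4)
    off <- MASS::mvrnorm(1, mu = rep(0, 4), Sigma = Sigma)
    latent <- c(mu_p[d, 1] + off[1], mu_p[d, 2] + off[2],
                mu_l[d, 1] + off[3], mu_l[d, 2] + off[4])
    out[i, ] <- c(plogis(latent[1:2]), exp(latent[3:4]))
  }
  out
}

#' Forward-simulate synthetic learning trajectories from a fitted model
#'
#' Posterior prediction: simulates `n_per_sex` synthetic 'males' and
#' 'females' whose learning parameters are drawn from the fitted posterior
#' ([draw_bird_params()]), runs each through the two-phase task under the
#' applied criterion, and summarises trials-to-finish and
#' switches-at-finish per sex and phase. Unfinished trajectories (trial
#' cap reached) are excluded from the means and counted.
#'
#' @param fit An `rl_fit` object, or `NULL` when `params` supplies fixed
#'   per-cell values directly.
#' @param n_per_sex Number of simulants per sex.
#' @param mode `"full"` or `"averaged"` (see [draw_bird_params()]).
#' @param params Optional fixed parameter table bypassing the posterior: a
#'   named list `list(M = c(phi_initial, phi_reversal, lam_initial,
#'   lam_reversal), F = ...)` on the natural scale.
#' @param max_trials Per-phase trial cap (default 300).
#' @param payoff,a0 Passed to [simulate_agent()].
#' @return A list with `trajectories` (data frame: `sex`, `phase`,
#'   `trials_to_finish`, `switches_at_finish`, one row per simulant-phase,
#'   `NA` when unfinished) and `summary` (per sex and phase: mean trials,
#'   mean switches, `n`, `n_unfinished`).
#' @export
forward_simulate <- function(fit = NULL, n_per_sex = 1000,
                             mode = c("full", "averaged"), params = NULL,
                             max_trials = 300, payoff = 1, a0 = 0) {
  mode <- match.arg(mode)
  rows <- vector("list", 2L * n_per_sex)
  r <- 0L
  for (sex in c("M", "F")) {
    pm <- if (is.null(params)) draw_bird_params(fit, sex, n_per_sex, mode)
    else matrix(rep(params[[sex]], each = n_per_sex), n_per_sex, 4,
                dimnames = list(NULL, c("phi_initial", "phi_reversal",
                                        "lam_initial", "lam_reversal")))
    for (i in seq_len(n_per_sex)) {
      sim <- simulate_agent(phi = pm[i, 1:2], lam = pm[i, 3:4],
                            payoff = payoff, a0 = a0, max_trials = max_trials)
      r <- r + 1L
      rows[[r]] <- data.frame(sex = sex, phase = PHASES,
                              trials_to_finish = sim$finish,
                              switches_at_finish = sim$switches)
    }
  }
  traj <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(traj, list(traj$sex, traj$phase)), function(g) {
    data.frame(sex = g$sex[1], phase = g$phase[1],
               mean_trials = mean(g$trials_to_finish, na.rm = TRUE),
               mean_switches = mean(g$switches_at_finish, na.rm = TRUE),
               n = nrow(g), n_unfinished = sum(is.na(g$trials_to_finish)))
  }))
  rownames(summ) <- NULL
  list(trajectories = traj, summary = summ)
}

#' Parameter-recovery study
#'
#' The model-vetting loop: simulate cohorts at known `(phi, lambda)` per
#' sex, fit the hierarchical model, and report (i) whether each group-level
#' truth falls inside its 89% HPDI and (ii) the sign of the fitted
#' male-female contrasts. Recovery cohorts use fixed-length phases
#' (default 70 trials each) rather than criterion stopping, which makes
#' both learning phases informative about the parameters.
#'
#' @param truth Named list `list(M = list(phi = c(i, r), lam = c(i, r)),
#'   F = ...)` of true natural-scale cell means.
#' @param n_per_sex Birds per sex in each simulated cohort.
#' @param n_trials Completed trials per phase per bird.
#' @param bird_sd Bird-level spread of the latent (logit/log scale)
#'   parameters.
#' @param n_reps Number of independent simulate-and-fit repetitions.
#' @param config Sampler settings for each fit.
#' @param seed Seed governing all simulation and fitting randomness.
#' @return A list with `coverage` (data frame: one row per repetition and
#'   group parameter, with truth, HPDI and an `inside` flag), `contrasts`
#'   (per repetition: mean and `P(>0)` of the reversal-phase lambda and
#'   initial-phase phi contrasts), and the overall `coverage_rate`.
#' @export
recovery_study <- function(truth, n_per_sex = 15, n_trials = 70,
                           bird_sd = 0.3, n_reps = 10,
                           config = rl_config(chains = 2, adapt = 500,
                                              burnin = 300, iter = 1000,
                                              min_ess = 100),
                           seed = 1L) {
  cov_rows <- list(); con_rows <- list()
  for (rep in seq_len(n_reps)) {
    set.seed(seed + 7919L * rep)
    spec <- cohort_spec(
      counts = data.frame(population = "core", n_M = n_per_sex, n_F = n_per_sex),
      means = truth, bird_sd = bird_sd, bird_cor = 0,
      incomplete_rate = 0, fixed_trials = n_trials)
    cohort <- generate_cohort(spec)
    fit <- fit_rl(cohort$trials, level = "pooled",
                  config = rl_config(chains = config$chains,
                                     adapt = config$adapt,
                                     burnin = config$burnin,
                                     iter = config$iter,
                                     seed = config$seed + rep,
                                     min_ess = config$min_ess),
                  exclude_extra = FALSE)
    for (sex in c("M", "F")) {
      for (p in 1:2) {
        for (par in c("phi", "lam")) {
          tr_nat <- truth[[sex]][[par]][p]
          d <- cell_draws(fit, par, sex, PHASES[p])
          h <- hpdi(d)
          cov_rows[[length(cov_rows) + 1L]] <- data.frame(
            rep = rep, sex = sex, phase = PHASES[p], param = par,
            truth = tr_nat, post_mean = mean(d),
            lower = h[1], upper = h[2],
            inside = tr_nat >= h[1] & tr_nat <= h[2])
        }
      }
    }
    con_lam <- posterior_contrast(fit, "lam", "reversal")
    con_phi <- posterior_contrast(fit, "phi", "initial")
    con_rows[[length(con_rows) + 1L]] <- data.frame(
      rep = rep,
      lam_reversal_mean = con_lam$mean, lam_reversal_p_pos = con_lam$prob_positive,
      lam_reversal_lower = con_lam$hpdi[1], lam_reversal_upper = con_lam$hpdi[2],
      phi_initial_mean = con_phi$mean, phi_initial_p_pos = con_phi$prob_positive,
      phi_initial_lower = con_phi$hpdi[1], phi_initial_upper = con_phi$hpdi[2])
  }
  coverage <- do.call(rbind, cov_rows)
  rownames(coverage) <- NULL
  contrasts <- do.call(rbind, con_rows)
  rownames(contrasts) <- NULL
  list(coverage = coverage, contrasts = contrasts,
       coverage_rate = mean(coverage$inside))
}
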