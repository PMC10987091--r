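#' Cohort specification for the synthetic-data generator
#'
#' Describes a synthetic study cohort: how many birds of each sex per
#' population, the true sex-by-phase learning-parameter means, bird-level
#' spread and correlation of the latent (logit-phi / log-lambda)
#' parameters, the incomplete-trial rate, post-criterion extra trials, and
#' which birds drop out of reversal early. Defaults mirror the study
#' composition: core 17M/5F, middle 4M/4F, edge 11M/8F (49 birds, 32 males
#' and 17 females) with three males (two core, one middle) dropped early
#' from reversal.
#'
#' @param counts Data frame with columns `population`, `n_M`, `n_F`.
#' @param means Named list `list(M = list(phi = c(initial, reversal), lam =
#'   c(initial, reversal)), F = ...)` of natural-scale cell means, e.g.
#'   from [sex_effect_preset()].
#' @param bird_sd Standard deviation of bird-level offsets on the latent
#'   scale.
#' @param bird_cor Exchangeable correlation among the four latent bird
#'   offsets.
#' @param incomplete_rate Probability of an incomplete (no-choice) trial
#'   being interleaved before any completed trial.
#' @param extra_max Maximum number of post-criterion extra trials per bird
#'   and phase (actual count uniform on `0:extra_max`).
#' @param drop_reversal_at Completed reversal trials after which dropped
#'   birds leave the test.
#' @param n_dropped Number of males dropped early from reversal (taken
#'   from the core population first, then middle, then edge).
#' @param fixed_trials If not `NULL`, ignore the criterion and give every
#'   bird exactly this many completed trials per phase (no extras); used
#'   for recovery cohorts.
#' @param max_trials Per-phase trial cap under criterion stopping.
#' @param payoff,a0 Learning-model constants.
#' @param seed Integer seed; regeneration with the same spec is
#'   byte-identical.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(counts = data.frame(population = c("core", "middle", "edge"),
                                            n_M = c(17L, 4L, 11L),
                                            n_F = c(5L, 4L, 8L)),
                        means = sex_effect_preset("paper_like"),
                        bird_sd = 0.3, bird_cor = 0.2,
                        incomplete_rate = 0.05, extra_max = 2L,
                        drop_reversal_at = 30L, n_dropped = 3L,
                        fixed_trials = NULL, max_trials = 300L,
                        payoff = 1, a0 = 0, seed = 1L) {
  stopifnot(all(counts$n_M >= 0), all(counts$n_F >= 0),
            bird_sd >= 0, bird_cor > -1, bird_cor < 1,
            incomplete_rate >= 0, incomplete_rate < 1,
            all(c("M", "F") %in% names(means)))
  structure(list(counts = counts, means = means, bird_sd = bird_sd,
                 bird_cor = bird_cor, incomplete_rate = incomplete_rate,
                 extra_max = as.integer(extra_max),
                 drop_reversal_at = as.integer(drop_reversal_at),
                 n_dropped = as.integer(n_dropped),
                 fixed_trials = fixed_trials,
                 max_trials = as.integer(max_trials),
                 payoff = payoff, a0 = a0, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sex-effect presets for synthetic cohorts
#'
#' `"null"` gives both sexes identical learning parameters. `"paper_like"`
#' gives males a lower information-updating rate and a higher
#' risk-sensitivity rate than females in both phases, with the female
#' updating rate dropping to the male level in reversal -- the qualitative
#' pattern estimated from the grackle data.
#'
#' @param name `"null"` or `"paper_like"`.
#' @return Named list of natural-scale cell means suitable for
#'   [cohort_spec()].
#' @export
sex_effect_preset <- function(name = c("paper_like", "null")) {
  name <- match.arg(name)
  if (name == "null") {
    one <- list(phi = c(0.04, 0.025), lam = c(3.5, 4.3))
    return(list(M = one, F = one))
  }
  list(M = list(phi = c(0.030, 0.025), lam = c(4.3, 5.3)),
       F = list(phi = c(0.050, 0.025), lam = c(2.8, 3.3)))
}

#' Generate a synthetic trial-level cohort with known ground truth
#'
#' Draws each bird's per-phase `(phi, lambda)` from the spec's multivariate
#' latent distribution, simulates its choices with [simulate_agent()]
#' (criterion stopping plus post-criterion extras, or fixed-length phases),
#' counterbalances which option is rewarded across birds, interleaves
#' incomplete trials, and truncates dropped birds' reversal phases. The
#' observable table passes [validate_trials()]; the ground-truth table is
#' returned alongside but is never read by any analysis stage.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `trials` (observable records) and `truth` (one row
#'   per bird: true natural-scale parameters, finish trials, extras,
#'   dropped flag).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  rho <- spec$bird_cor
  Sigma <- spec$bird_sd^2 * ((1 - rho) * diag(4) + rho)
  trial_rows <- list()
  truth_rows <- list()
  # early-dropped males: first populations in counts order
  drop_left <- spec$n_dropped
  bird_no <- 0L
  for (r in seq_len(nrow(spec$counts))) {
    popn <- spec$counts$population[r]
    for (sex in c("M", "F")) {
      n <- spec$counts[[paste0("n_", sex)]][r]
      for (i in seq_len(n)) {
        bird_no <- bird_no + 1L
        bird_id <- sprintf("%s_%s%02d", popn, sex, i)
        mu <- spec$means[[sex]]
        latent <- c(qlogis(mu$phi), log(mu$lam)) +
          MASS::mvrnorm(1, rep(0, 4), Sigma)
        phi <- plogis(latent[1:2])
        lam <- exp(latent[3:4])
        # first two males of the first population, then one of the next,
        # mirroring the study's early drop-outs (two core, one middle)
        dropped <- sex == "M" && drop_left > 0L && i <= 2L &&
          is.null(spec$fixed_trials)
        if (dropped) drop_left <- drop_left - 1L
        if (is.null(spec$fixed_trials)) {
          extras <- sample.int(spec$extra_max + 1L, 2L, replace = TRUE) - 1L
          sim <- simulate_agent(phi, lam, payoff = spec$payoff, a0 = spec$a0,
                                max_trials = spec$max_trials,
                                stop_at_criterion = TRUE,
                                extra_trials = extras)
        } else {
          extras <- c(0L, 0L)
          sim <- simulate_agent(phi, lam, payoff = spec$payoff, a0 = spec$a0,
                                max_trials = spec$fixed_trials,
                                stop_at_criterion = FALSE)
        }
        tt <- sim$trials
        if (dropped) {
          keep <- tt$phase == "initial" |
            (tt$phase == "reversal" & tt$trial <= spec$drop_reversal_at)
          tt <- tt[keep, ]
        }
        # counterbalance the rewarded colour across birds
        if (bird_no %% 2L == 0L) {
          tt$choice <- ifelse(tt$choice == "option1", "option2", "option1")
        }
        rec <- data.frame(bird_id = bird_id, population = popn, sex = sex,
                          phase = tt$phase, trial = tt$trial,
                          choice = tt$choice, correct = as.integer(tt$correct),
                          completed = 1L)
        if (spec$incomplete_rate > 0) {
          rec <- interleave_incomplete(rec, spec$incomplete_rate)
        }
        trial_rows[[bird_no]] <- rec
        truth_rows[[bird_no]] <- data.frame(
          bird_id = bird_id, population = popn, sex = sex,
          phi_initial = phi[1], phi_reversal = phi[2],
          lam_initial = lam[1], lam_reversal = lam[2],
          finish_initial = sim$finish[1],
          finish_reversal = if (dropped) NA_integer_ else sim$finish[2],
          extra_initial = extras[1],
          extra_reversal = if (dropped) 0L else extras[2],
          dropped_reversal = dropped)
      }
    }
  }
  trials <- do.call(rbind, trial_rows)
  rownames(trials) <- NULL
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(trials = validate_trials(trials), truth = truth)
}

# Insert incomplete (no-choice) rows before completed trials at the given
# rate, then renumber trials consecutively within each phase.
interleave_incomplete <- function(rec, rate) {
  out <- list()
  for (ph in unique(rec$phase)) {
    rows <- rec[rec$phase == ph, ]
    pieces <- list()
    for (j in seq_len(nrow(rows))) {
      while (runif(1) < rate) {
        inc <- rows[j, ]
        inc$choice <- NA_character_
        inc$correct <- NA_integer_
        inc$completed <- 0L
        pieces[[length(pieces) + 1L]] <- inc
      }
      pieces[[length(pieces) + 1L]] <- rows[j, ]
    }
    ph_rows <- do.call(rbind, pieces)
    ph_rows$trial <- seq_len(nrow(ph_rows))
    out[[length(out) + 1L]] <- ph_rows
  }
  do.call(rbind, out)
}
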