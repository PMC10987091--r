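#' Configuration of the evolutionary algorithm
#'
#' Study-condition defaults: populations of `N = 300` learning agents,
#' lifetimes of `t_total = 1000` binary foraging choices with fitness the
#' rewards collected over the last 800 (the first 200 are ignored so
#' selection responds to the steady state), logit/log-scale mutation
#' standard deviation 0.05 for both parameters, `lambda` restricted to
#' (0, 15], 10 independent runs of 7000 generations each, and summaries
#' averaged over the last 5000 generations of each run.
#'
#' @param n_pop Population size `N`.
#' @param t_total Foraging choices per lifetime.
#' @param fitness_window Final choices counted towards fitness.
#' @param generations Generations per run.
#' @param runs Independent runs.
#' @param burnin Generations discarded from the start of each run when
#'   averaging; must leave at least one retained generation.
#' @param mu_phi,mu_lam Mutation standard deviations on the logit (phi)
#'   and log (lambda) scales.
#' @param lam_max Upper bound on the risk-sensitivity rate (values above
#'   produce identical choice behaviour).
#' @param payoff Reward magnitude of a successful choice.
#' @param reward_swap Reward semantics of a stochastic failure event: if
#'   `FALSE` (default) the optimal option simply fails to pay that choice;
#'   if `TRUE` the reward instead moves to the other option.
#' @param seed Integer seed; identical configs and seeds give identical
#'   traces.
#' @return A list of class `evo_config`.
#' @export
evo_config <- function(n_pop = 300L, t_total = 1000L, fitness_window = 800L,
                       generations = 7000L, runs = 10L, burnin = 2000L,
                       mu_phi = 0.05, mu_lam = 0.05, lam_max = 15,
                       payoff = 1, reward_swap = FALSE, seed = 1L) {
  stopifnot(n_pop >= 2, t_total >= 1, fitness_window <= t_total,
            fitness_window >= 1, runs >= 1, mu_phi >= 0, mu_lam >= 0,
            lam_max > 0)
  if (generations < burnin + 1L) {
    stop("`generations` must exceed `burnin` by at least one retained generation",
         call. = FALSE)
  }
  structure(list(n_pop = as.integer(n_pop), t_total = as.integer(t_total),
                 fitness_window = as.integer(fitness_window),
                 generations = as.integer(generations), runs = as.integer(runs),
                 burnin = as.integer(burnin), mu_phi = mu_phi, mu_lam = mu_lam,
                 lam_max = lam_max, payoff = payoff,
                 reward_swap = reward_swap, seed = as.integer(seed)),
            class = "evo_config")
}

#' Lifetime fitness of learning genotypes
#'
#' Runs one naive-born agent per genotype through `t_total` binary
#' foraging choices in an environment where the optimal option flips with
#' probability `u` before every choice and, with probability `s`, optimal
#' behaviour fails to pay on a given choice. Choices and learning follow
#' the same attraction/softmax rules as the reinforcement learning model,
#' applied to the realised (possibly failed) rewards. Fitness is the
#' number of rewards collected over the final `fitness_window` choices.
#'
#' @param phi,lam Numeric vectors of genotype parameters (recycled to a
#'   common length).
#' @param u Environmental stability: per-choice probability the optimal
#'   option changes.
#' @param s Environmental stochasticity: per-choice probability optimal
#'   behaviour goes unrewarded.
#' @param config An [evo_config()] (supplies lifetime length, window,
#'   payoff and failure semantics).
#' @return Integer vector of fitness values in `[0, fitness_window]`.
#' @export
run_lifetime <- function(phi, lam, u, s, config = evo_config()) {
  stopifnot(u >= 0, u <= 1, s >= 0, s <= 1,
            all(phi >= 0 & phi <= 1), all(lam >= 0))
  n <- max(length(phi), length(lam))
  lifetime_fitness_cpp(rep_len(phi, n), rep_len(lam, n), u, s,
                       config$t_total, config$fitness_window,
                       config$payoff, config$reward_swap)
}

#' Roulette-wheel selection with mutation
#'
#' Produces the next generation: each offspring's parent is drawn with
#' probability proportional to fitness (uniformly when every fitness is
#' zero, where the wheel is undefined), then zero-centred normal mutation
#' is added to the parental values on the logit (phi) and log (lambda)
#' scales, keeping phi inside (0, 1) automatically and clipping lambda to
#' (0, `lam_max`].
#'
#' @param population Data frame (or list) with numeric `phi` and `lam` of
#'   equal length.
#' @param fitness Non-negative numeric vector, one value per member.
#' @param config An [evo_config()].
#' @return Data frame of the offspring generation (`phi`, `lam`).
#' @export
select_and_reproduce <- function(population, fitness, config = evo_config()) {
  n <- length(population$phi)
  stopifnot(length(fitness) == n, all(fitness >= 0))
  total <- sum(fitness)
  parents <- if (total == 0) sample.int(n, n, replace = TRUE)
  else sample.int(n, n, replace = TRUE, prob = fitness / total)
  phi <- plogis(qlogis(population$phi[parents]) + rnorm(n, 0, config$mu_phi))
  lam <- exp(log(population$lam[parents]) + rnorm(n, 0, config$mu_lam))
  data.frame(phi = phi, lam = pmin(lam, config$lam_max))
}

#' Evolve learning parameters in one environment
#'
#' Runs the evolutionary algorithm: generation 0 is seeded with phi
#' uniform on (0, 1) and lambda uniform on (0, lam_max); each generation
#' every member lives one lifetime ([run_lifetime()]) and reproduces by
#' roulette-wheel selection with mutation ([select_and_reproduce()]).
#' Reported optima are the population-mean genotypes averaged over the
#' post-burn-in generations of all runs.
#'
#' @inheritParams run_lifetime
#' @param config An [evo_config()].
#' @return A list with `summary` (one row: `u`, `s`, `mean_phi`,
#'   `mean_lam`, `runs`, `generations`) and `trace` (per run and
#'   generation population means).
#' @export
run_evolution <- function(u, s, config = evo_config()) {
  traces <- vector("list", config$runs)
  for (run in seq_len(config$runs)) {
    set.seed(config$seed + 104729L * run)
    pop <- data.frame(phi = runif(config$n_pop),
                      lam = runif(config$n_pop, 0, config$lam_max))
    mean_phi <- numeric(config$generations)
    mean_lam <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      fitness <- run_lifetime(pop$phi, pop$lam, u, s, config)
      mean_phi[g] <- mean(pop$phi)
      mean_lam[g] <- mean(pop$lam)
      pop <- select_and_reproduce(pop, fitness, config)
    }
    traces[[run]] <- data.frame(run = run, generation = seq_len(config$generations),
                                mean_phi = mean_phi, mean_lam = mean_lam)
  }
  trace <- do.call(rbind, traces)
  kept <- trace[trace$generation > config$burnin, ]
  list(summary = data.frame(u = u, s = s,
                            mean_phi = mean(kept$mean_phi),
                            mean_lam = mean(kept$mean_lam),
                            runs = config$runs,
                            generations = config$generations),
       trace = trace)
}

#' Sweep the environmental grid
#'
#' Runs [run_evolution()] on every `(u, s)` pair of the grid and returns a
#' tidy table of mean optimal learning parameters, suitable for heat-map
#' rendering. The default grid spans low-to-high stability and
#' stochasticity values.
#'
#' @param u_grid,s_grid Numeric vectors of environment parameter values.
#' @param config An [evo_config()].
#' @return Data frame with one row per `(u, s)` pair: `mean_phi`,
#'   `mean_lam`, `runs`, `generations`.
#' @export
evolution_sweep <- function(u_grid = c(0.001, 0.01, 0.05, 0.1, 0.2),
                            s_grid = c(0, 0.1, 0.3, 0.5, 0.7),
                            config = evo_config()) {
  rows <- list()
  for (s in s_grid) {
    for (u in u_grid) {
      rows[[length(rows) + 1L]] <- run_evolution(u, s, config)$summary
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
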