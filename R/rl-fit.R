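#' Sampler configuration for the hierarchical models
#'
#' Settings for the MCMC fits. The defaults (4 chains, 1000 adaptation,
#' 500 burn-in, 2000 retained iterations per chain) are chosen to clear
#' 1000 effective samples for the group-level parameters on cohorts of the
#' study's size; reduce them for quick checks at the cost of effective
#' sample size.
#'
#' @param chains Number of MCMC chains.
#' @param adapt Adaptation iterations for the JAGS samplers.
#' @param burnin Burn-in iterations discarded after adaptation.
#' @param iter Retained sampling iterations per chain.
#' @param seed Integer seed; per-chain RNG seeds are derived from it, and
#'   refitting with the same seed reproduces the draws exactly.
#' @param min_ess Effective-sample-size contract for reported group-level
#'   parameters; a warning is raised when any falls short.
#' @param a0,payoff Initial attraction and payoff magnitude entering the
#'   learning model (RL fit only).
#' @return A list of class `rl_config`.
#' @export
rl_config <- function(chains = 4, adapt = 1000, burnin = 500, iter = 2000,
                      seed = 1L, min_ess = 1000, a0 = 0, payoff = 1) {
  stopifnot(chains >= 1, iter >= 1, seed == as.integer(seed))
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 burnin = as.integer(burnin), iter = as.integer(iter),
                 seed = as.integer(seed), min_ess = min_ess,
                 a0 = a0, payoff = payoff),
            class = "rl_config")
}

RL_MODEL_TEMPLATE <- "
model {
  for (k in 1:K) {
    for (l in 1:4) {
      mu_phi[k, l] ~ dnorm(0, 1)
      # log-lambda means need a wider scale: lambda is admissible up to 15
      # (log 15 ~ 2.7) and only weakly likelihood-identified at the top of
      # that range, where a unit-scale prior shrinks noticeably
      mu_lam[k, l] ~ dnorm(0, 0.444)
    }
  }
  Omega[1:4, 1:4] ~ dwish(R4[,], 6)
  Sigma[1:4, 1:4] <- inverse(Omega[,])
  for (i in 1:I) {
    v[i, 1:4] ~ dmnorm(zero4[], Omega[,])
    for (ph in 1:2) {
      logit(phi[i, ph]) <- mu_phi[pop[i], cell[i, ph]] + v[i, ph]
      log(lam[i, ph])   <- mu_lam[pop[i], cell[i, ph]] + v[i, ph + 2]
    }
    A[i, 1, 1] <- a0
    A[i, 1, 2] <- a0
    for (t in 1:T[i]) {
      p[i, t] <- max(min(1 / (1 + exp(-lam[i, phs[i, t]] *
                                      (A[i, t, 1] - A[i, t, 2]))),
                         0.9999999), 0.0000001)
      y[i, t] ~ dbern(p[i, t])
      A[i, t + 1, 1] <- A[i, t, 1] +
        y[i, t] * phi[i, phs[i, t]] * (pay[i, t] - A[i, t, 1])
      A[i, t + 1, 2] <- A[i, t, 2] +
        (1 - y[i, t]) * phi[i, phs[i, t]] * (pay[i, t] - A[i, t, 2])
    }
  }
}"

#' Fit the hierarchical Bayesian reinforcement learning model
#'
#' Estimates the information-updating rate `phi` and risk-sensitivity rate
#' `lambda` from completed tube choices. Group-level means are indexed by
#' sex-by-phase cell (F/initial, F/reversal, M/initial, M/reversal) and,
#' at `level = "population"`, additionally by population; each bird gets a
#' correlated 4-dimensional offset vector (phi and lambda per phase) with a
#' freely estimated covariance, giving partial pooling across birds.
#' Attractions persist across the phase boundary; extra post-criterion
#' learning trials are excluded by default, incomplete trials always.
#'
#' Priors are weakly informative: Normal(0, 1) on the logit-phi group
#' means, Normal(0, 1.5) on the log-lambda group means (wide enough to
#' cover the admissible risk-sensitivity range up to 15, where the
#' likelihood identifies lambda only weakly), and Wishart(I, 6) on the
#' offset precision matrix.
#' Sampling uses JAGS; convergence diagnostics (effective sample size and
#' potential scale reduction) are computed for all group-level parameters
#' and a warning is raised, rather than output silently returned, when the
#' effective-sample-size contract is not met.
#'
#' @param trials Validated trial records (see [validate_trials()]).
#' @param level `"pooled"` (across populations, the default) or
#'   `"population"` (separate group means per population).
#' @param config Sampler settings from [rl_config()].
#' @param exclude_extra Drop post-criterion learning trials before fitting
#'   (default `TRUE`).
#' @return An object of class `rl_fit`: a list with `draws` (matrices of
#'   posterior draws for `mu_phi`, `mu_lam` with columns per population and
#'   cell, and `Sigma` columns for the offset covariance), `diagnostics`
#'   (`ess`, `rhat`), `populations`, `cells`, `config` and data summaries.
#' @export
fit_rl <- function(trials, level = c("pooled", "population"),
                   config = rl_config(), exclude_extra = TRUE) {
  level <- match.arg(level)
  trials <- validate_trials(trials)
  if (exclude_extra) trials <- exclude_extra_trials(trials)
  done <- trials[trials$completed == 1L, ]
  birds <- unique(done[, c("bird_id", "population", "sex")])
  birds <- birds[order(birds$bird_id), ]
  I <- nrow(birds)
  if (I < 1) stop("no completed trials to fit", call. = FALSE)
  pops <- if (level == "population") POPULATIONS[POPULATIONS %in% birds$population] else "all"
  K <- length(pops)
  pop_idx <- if (level == "population") match(birds$population, pops) else rep(1L, I)

  Tn <- integer(I)
  rows_by_bird <- vector("list", I)
  for (i in seq_len(I)) {
    b <- done[done$bird_id == birds$bird_id[i], ]
    b <- b[order(match(b$phase, PHASES), b$trial), ]
    rows_by_bird[[i]] <- b
    Tn[i] <- nrow(b)
  }
  Tmax <- max(Tn)
  y <- pay <- phs <- matrix(NA_real_, I, Tmax)
  for (i in seq_len(I)) {
    b <- rows_by_bird[[i]]
    y[i, seq_len(Tn[i])] <- as.integer(b$choice == "option1")
    pay[i, seq_len(Tn[i])] <- ifelse(b$correct == 1L, config$payoff, 0)
    phs[i, seq_len(Tn[i])] <- match(b$phase, PHASES)
  }
  cell <- cbind(cell_index(birds$sex, "initial"), cell_index(birds$sex, "reversal"))

  data <- list(I = I, K = K, T = Tn, y = y, pay = pay, phs = phs,
               pop = pop_idx, cell = cell, zero4 = rep(0, 4), R4 = diag(4),
               a0 = config$a0)
  monitors <- c("mu_phi", "mu_lam", "Sigma", "v")
  samp <- run_jags(RL_MODEL_TEMPLATE, data, monitors, config)

  m <- as.matrix(samp)
  fit <- structure(list(
    draws = list(
      mu_phi = m[, grep("^mu_phi", colnames(m)), drop = FALSE],
      mu_lam = m[, grep("^mu_lam", colnames(m)), drop = FALSE],
      Sigma = m[, grep("^Sigma", colnames(m)), drop = FALSE],
      v = m[, grep("^v\\[", colnames(m)), drop = FALSE]),
    level = level, populations = pops, cells = CELL_LEVELS,
    birds = birds, config = config, n_trials = sum(Tn)),
    class = "rl_fit")
  fit$diagnostics <- group_diagnostics(samp, "^mu_(phi|lam)", config$min_ess)
  fit
}

# Shared JAGS driver: reproducible per-chain seeds, one mcmc.list out.
run_jags <- function(model_string, data, monitors, config) {
  inits <- lapply(seq_len(config$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (config$seed * 1009L + ch) %% 2147483646L + 1L)
  })
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = inits, n.chains = config$chains,
                             n.adapt = config$adapt, quiet = TRUE)
  if (config$burnin > 0) stats::update(model, config$burnin, progress.bar = "none")
  rjags::coda.samples(model, monitors, n.iter = config$iter,
                      progress.bar = "none")
}

# ESS and Rhat for parameters matching `pattern`; warn below the contract.
group_diagnostics <- function(samp, pattern, min_ess) {
  keep <- grep(pattern, coda::varnames(samp))
  sub <- samp[, keep, drop = FALSE]
  ess <- coda::effectiveSize(sub)
  rhat <- tryCatch(
    coda::gelman.diag(sub, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, length(ess)))
  if (any(ess < min_ess)) {
    warning(sprintf(
      "effective sample size below %d for: %s (min %.0f); increase iterations",
      min_ess, paste(names(ess)[ess < min_ess], collapse = ", "), min(ess)),
      call. = FALSE)
  }
  list(ess = ess, rhat = rhat)
}

# Column name of a group-mean draw matrix for population k, cell l.
mu_col <- function(k, l) sprintf("[%d,%d]", k, l)

#' Extract natural-scale group-level draws
#'
#' Returns per-draw natural-scale values of the group mean for one
#' parameter and cell: `plogis(mu)` for `phi`, `exp(mu)` for `lambda`
#' (the typical-bird value, i.e. the group mean with the bird offset at
#' zero).
#'
#' @param fit An `rl_fit` object.
#' @param param `"phi"` or `"lam"`.
#' @param sex `"M"` or `"F"`.
#' @param phase `"initial"` or `"reversal"`.
#' @param population Population name for population-level fits; ignored
#'   (with a message) for pooled fits.
#' @return Numeric vector of posterior draws on the natural scale.
#' @export
cell_draws <- function(fit, param = c("phi", "lam"), sex, phase,
                       population = NULL) {
  param <- match.arg(param)
  stopifnot(inherits(fit, "rl_fit"))
  k <- if (fit$level == "population") {
    if (is.null(population)) stop("population-level fit needs `population`",
                                  call. = FALSE)
    match(population, fit$populations)
  } else 1L
  if (is.na(k)) stop("unknown population", call. = FALSE)
  l <- cell_index(sex, phase)
  draws <- fit$draws[[paste0("mu_", param)]]
  col <- grep(mu_col(k, l), colnames(draws), fixed = TRUE)
  mu <- draws[, col]
  if (param == "phi") stats::plogis(mu) else exp(mu)
}

#' Male-female posterior contrast of a learning parameter
#'
#' Draw-wise male-minus-female difference of the natural-scale group-level
#' parameter in one phase, summarised by its mean and 89% highest posterior
#' density interval.
#'
#' @inheritParams cell_draws
#' @param prob Mass of the HPD interval (default 0.89).
#' @return A list of class `rl_contrast` with elements `draws`, `mean`,
#'   `hpdi`, `prob_positive` and labels.
#' @export
posterior_contrast <- function(fit, param = c("phi", "lam"),
                               phase = c("initial", "reversal"),
                               population = NULL, prob = 0.89) {
  param <- match.arg(param)
  phase <- match.arg(phase)
  d <- cell_draws(fit, param, "M", phase, population) -
    cell_draws(fit, param, "F", phase, population)
  structure(list(draws = d, mean = mean(d), hpdi = hpdi(d, prob),
                 prob_positive = mean(d > 0), param = param, phase = phase,
                 population = population %||% fit$populations[1]),
            class = "rl_contrast")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rl_contrast <- function(x, ...) {
  cat(sprintf("M-F contrast of %s (%s, %s): mean %.3f, 89%% HPDI [%.3f, %.3f], P(>0) = %.2f\n",
              x$param, x$phase, x$population, x$mean, x$hpdi[1], x$hpdi[2],
              x$prob_positive))
  invisible(x)
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf("Hierarchical RL fit (%s level): %d birds, %d completed trials\n",
              x$level, nrow(x$birds), x$n_trials))
  cat(sprintf("  draws: %d; min ESS (group means): %.0f\n",
              nrow(x$draws$mu_phi), min(x$diagnostics$ess)))
  for (l in seq_along(x$cells)) {
    ph <- stats::quantile(stats::plogis(x$draws$mu_phi[, grep(mu_col(1, l),
      colnames(x$draws$mu_phi), fixed = TRUE)]), c(.055, .5, .945))
    la <- stats::quantile(exp(x$draws$mu_lam[, grep(mu_col(1, l),
      colnames(x$draws$mu_lam), fixed = TRUE)]), c(.055, .5, .945))
    cat(sprintf("  %-10s phi %.3f [%.3f, %.3f]  lambda %.2f [%.2f, %.2f]\n",
                x$cells[l], ph[2], ph[1], ph[3], la[2], la[1], la[3]))
  }
  invisible(x)
}
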