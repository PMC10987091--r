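POISSON_MODEL_TEMPLATE <- "
model {
  for (k in 1:K) {
    for (l in 1:4) {
      a[k, l] ~ dnorm(0, 1)
    }
  }
  sigma_b ~ dnorm(0, 1) T(0,)
  tau_b <- pow(sigma_b, -2)
  for (i in 1:I) {
    b[i] ~ dnorm(0, tau_b)
  }
  for (n in 1:N) {
    log(mu[n]) <- a[pop[n], cell[n]] + b[bird[n]]
    y[n] ~ dpois(mu[n])
  }
}"

#' Multilevel Bayesian Poisson model of learning behaviour
#'
#' Log-link Poisson regression of a per-bird, per-phase count
#' (trials-to-finish or switches-at-finish) on sex-by-phase cell, with a
#' varying intercept per bird to account for repeated measures. Cells are
#' index-coded (an independent mean per sex-by-phase combination) so that
#' contrasts are formed directly from the cell means. Priors: Normal(0, 1)
#' on the log-scale cell means, half-Normal(0, 1) on the bird-intercept
#' scale. At `level = "population"` each population gets its own cell
#' means; empty cells are reported and fitted from the prior, with wide
#' uncertainty.
#'
#' Birds without a finished phase (e.g. dropped early from reversal)
#' contribute no row for that phase, mirroring the exclusion used in the
#' behavioural analysis.
#'
#' @param outcomes Data frame from [behaviour_outcomes()] (columns
#'   `bird_id`, `population`, `sex`, `phase` and the count responses).
#' @param response `"trials"` or `"switches"`.
#' @param level `"pooled"` (default) or `"population"`.
#' @param config Sampler settings from [rl_config()]; the RL-specific
#'   fields are ignored.
#' @return An object of class `behaviour_fit` with draw matrices (`a` on
#'   the log scale, `sigma_b`), diagnostics, and metadata.
#' @export
fit_behaviour_poisson <- function(outcomes, response = c("trials", "switches"),
                                  level = c("pooled", "population"),
                                  config = rl_config()) {
  response <- match.arg(response)
  level <- match.arg(level)
  stopifnot(all(c("bird_id", "population", "sex", "phase", response) %in%
                  names(outcomes)))
  y <- outcomes[[response]]
  stopifnot(all(is.finite(y)), all(y >= 0))
  pops <- if (level == "population") POPULATIONS[POPULATIONS %in% outcomes$population] else "all"
  K <- length(pops)
  pop_idx <- if (level == "population") match(outcomes$population, pops) else rep(1L, nrow(outcomes))
  cells <- cell_index(outcomes$sex, outcomes$phase)
  if (level == "population") {
    seen <- unique(cbind(pop_idx, cells))
    empty <- K * 4 - nrow(seen)
    if (empty > 0) {
      message(empty, " population-by-cell combination(s) have no data; ",
              "their means are prior-driven")
    }
  }
  birds <- sort(unique(outcomes$bird_id))
  data <- list(N = nrow(outcomes), I = length(birds), K = K,
               y = as.integer(y), pop = pop_idx, cell = cells,
               bird = match(outcomes$bird_id, birds))
  samp <- run_jags(POISSON_MODEL_TEMPLATE, data, c("a", "sigma_b"), config)
  m <- as.matrix(samp)
  fit <- structure(list(
    draws = list(a = m[, grep("^a\\[", colnames(m)), drop = FALSE],
                 sigma_b = m[, "sigma_b"]),
    response = response, level = level, populations = pops,
    cells = CELL_LEVELS, n_obs = nrow(outcomes), config = config),
    class = "behaviour_fit")
  fit$diagnostics <- group_diagnostics(samp, "^a\\[", config$min_ess)
  fit
}

#' Male-female contrast of expected counts
#'
#' Draw-wise male-minus-female difference of the natural-scale expected
#' count (`exp(a)`, the typical bird's rate) in one phase, with mean and
#' 89% highest posterior density interval. A contrast lying below zero
#' means males need fewer trials (or make fewer switches) than females.
#'
#' @param fit A `behaviour_fit` object.
#' @param phase `"initial"` or `"reversal"`.
#' @param population Population name for population-level fits.
#' @param prob HPD interval mass (default 0.89).
#' @return A list of class `rl_contrast`.
#' @export
contrast_mf <- function(fit, phase = c("initial", "reversal"),
                        population = NULL, prob = 0.89) {
  phase <- match.arg(phase)
  stopifnot(inherits(fit, "behaviour_fit"))
  k <- if (fit$level == "population") {
    if (is.null(population)) stop("population-level fit needs `population`",
                                  call. = FALSE)
    match(population, fit$populations)
  } else 1L
  if (is.na(k)) stop("unknown population", call. = FALSE)
  a <- fit$draws$a
  col_m <- grep(mu_col(k, cell_index("M", phase)), colnames(a), fixed = TRUE)
  col_f <- grep(mu_col(k, cell_index("F", phase)), colnames(a), fixed = TRUE)
  d <- exp(a[, col_m]) - exp(a[, col_f])
  structure(list(draws = d, mean = mean(d), hpdi = hpdi(d, prob),
                 prob_positive = mean(d > 0), param = fit$response,
                 phase = phase, population = population %||% fit$populations[1]),
            class = "rl_contrast")
}
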