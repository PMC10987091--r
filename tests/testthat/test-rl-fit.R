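# Small MCMC smoke checks; statistical performance of the fit is exercised
# at larger scale by the parameter-recovery acceptance test.

small_cohort <- function(seed, n_per_sex = 6, n_trials = 40) {
  generate_cohort(cohort_spec(
    counts = data.frame(population = "core", n_M = n_per_sex, n_F = n_per_sex),
    bird_sd = 0.2, incomplete_rate = 0, n_dropped = 0L,
    fixed_trials = n_trials, seed = seed))
}

test_that("hierarchical RL fit returns valid, reproducible posteriors", {
  cohort <- small_cohort(31L)
  fit1 <- suppressWarnings(fit_rl(cohort$trials, config = quick_cfg(5L)))
  expect_s3_class(fit1, "rl_fit")
  expect_identical(nrow(fit1$draws$mu_phi), 2L * 300L)
  # natural-scale draws respect the parameter supports for every cell
  for (sex in c("M", "F")) {
    for (ph in c("initial", "reversal")) {
      phi <- cell_draws(fit1, "phi", sex, ph)
      lam <- cell_draws(fit1, "lam", sex, ph)
      expect_true(all(phi > 0 & phi < 1))
      expect_true(all(lam > 0))
    }
  }
  # same config and seed reproduce the draws exactly
  fit2 <- suppressWarnings(fit_rl(cohort$trials, config = quick_cfg(5L)))
  expect_identical(fit1$draws$mu_phi, fit2$draws$mu_phi)
  expect_identical(fit1$draws$Sigma, fit2$draws$Sigma)
  # a different seed gives different draws
  fit3 <- suppressWarnings(fit_rl(cohort$trials, config = quick_cfg(6L)))
  expect_false(identical(fit1$draws$mu_phi, fit3$draws$mu_phi))
  # diagnostics cover all 8 group means
  expect_length(fit1$diagnostics$ess, 8L)
})

test_that("a self-contrast is degenerate at zero and contrasts are draw-wise", {
  cohort <- small_cohort(32L)
  fit <- suppressWarnings(fit_rl(cohort$trials, config = quick_cfg(7L)))
  d_m <- cell_draws(fit, "lam", "M", "reversal")
  d_f <- cell_draws(fit, "lam", "F", "reversal")
  con <- posterior_contrast(fit, "lam", "reversal")
  expect_equal(con$draws, d_m - d_f)
  expect_equal(con$mean, mean(d_m - d_f))
  expect_identical(unname(con$hpdi), unname(hpdi(d_m - d_f)))
  expect_equal(max(abs(d_m - d_m)), 0)
})

test_that("single-bird fits run with partially pooled offsets", {
  co <- generate_cohort(cohort_spec(
    counts = data.frame(population = "core", n_M = 1L, n_F = 1L),
    bird_sd = 0, incomplete_rate = 0, n_dropped = 0L,
    fixed_trials = 40, seed = 33L))
  fit <- suppressWarnings(fit_rl(co$trials, config = quick_cfg(8L)))
  expect_s3_class(fit, "rl_fit")
  expect_true(all(is.finite(fit$draws$v)))
  # one bird cannot pin the group parameters; the claim here is that the
  # model remains proper and the random-effect prior keeps the posterior
  # mean offsets regularised rather than letting them run away
  v_bar <- colMeans(fit$draws$v)
  expect_true(all(abs(v_bar) < 5))
  for (sex in c("M", "F")) {
    phi <- cell_draws(fit, "phi", sex, "reversal")
    expect_true(all(phi > 0 & phi < 1))
  }
})

test_that("an early-dropped bird is included with wider uncertainty", {
  co <- generate_cohort(cohort_spec(
    counts = data.frame(population = "core", n_M = 6L, n_F = 6L),
    bird_sd = 0.2, incomplete_rate = 0, n_dropped = 1L, seed = 34L))
  # bird core_M01 has a truncated reversal phase
  expect_true(co$truth$dropped_reversal[co$truth$bird_id == "core_M01"])
  fit <- suppressWarnings(fit_rl(co$trials, config = quick_cfg(9L)))
  expect_true("core_M01" %in% fit$birds$bird_id)
  i_drop <- which(fit$birds$bird_id == "core_M01")
  others <- which(fit$birds$bird_id != "core_M01" & fit$birds$sex == "M")
  # reversal-phase phi offset (column 2) of the dropped bird is less
  # constrained than the average fully-observed male's
  sd_drop <- stats::sd(fit$draws$v[, sprintf("v[%d,2]", i_drop)])
  sd_rest <- mean(vapply(others, function(i)
    stats::sd(fit$draws$v[, sprintf("v[%d,2]", i)]), numeric(1)))
  expect_gt(sd_drop, 0.8 * sd_rest)
})

test_that("population-level fits index group means by population", {
  co <- generate_cohort(cohort_spec(
    counts = data.frame(population = c("core", "edge"), n_M = c(3L, 3L),
                        n_F = c(3L, 3L)),
    bird_sd = 0.2, incomplete_rate = 0, n_dropped = 0L,
    fixed_trials = 30, seed = 35L))
  fit <- suppressWarnings(fit_rl(co$trials, level = "population",
                                 config = quick_cfg(10L, iter = 200)))
  expect_identical(fit$populations, c("core", "edge"))
  expect_identical(ncol(fit$draws$mu_phi), 8L)
  expect_error(posterior_contrast(fit, "lam", "reversal"), "population")
  con <- posterior_contrast(fit, "lam", "reversal", population = "edge")
  expect_s3_class(con, "rl_contrast")
})
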