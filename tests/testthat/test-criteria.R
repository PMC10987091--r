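test_that("applied criterion matches its defining cases", {
  expect_identical(criterion_applied(rep(1, 17)), 17L)
  expect_identical(criterion_applied(rep(0, 40)), NA_integer_)
  expect_identical(criterion_applied(integer(0)), NA_integer_)
  expect_identical(criterion_applied(c(0, 0, 0, rep(1, 17))), 20L)
  # 16 correct then an error postpones the finish
  expect_identical(criterion_applied(c(rep(1, 16), 0, 1)), 18L)
  expect_error(criterion_applied(c(1, NA)), "0/1")
})

test_that("applied criterion equals the brute-force oracle on random sequences", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(0:60, 1)
    flags <- rbinom(n, 1, runif(1, 0.3, 0.95))
    expect_identical(criterion_applied(flags), oracle_applied(flags))
  }
})

test_that("applied criterion is monotone under prepending and appending", {
  set.seed(202)
  for (i in 1:100) {
    flags <- rbinom(sample(17:50, 1), 1, 0.8)
    f <- criterion_applied(flags)
    if (!is.na(f)) {
      # appending trials never changes an already-returned finish
      expect_identical(criterion_applied(c(flags, rbinom(10, 1, 0.5))), f)
      # prepending a correct trial never delays the finish beyond the shift
      f2 <- criterion_applied(c(1L, flags))
      expect_false(is.na(f2))
      expect_lte(f2, f + 1L)
    }
  }
})

test_that("fixed-window criterion honours set minima and assessment points", {
  # perfect performance passes any reading
  expect_identical(criterion_fixed_window(rep(1, 20)), 20L)
  # 8/10 then 9/10 with 17/20 total passes at trial 20
  seq8_9 <- c(0, 0, rep(1, 8), 0, rep(1, 9))
  expect_identical(criterion_fixed_window(seq8_9), 20L)
  expect_identical(criterion_fixed_window(seq8_9, minima_ordered = FALSE), 20L)
  # 7/10 + 10/10 fails the minima under both readings (the split the
  # original experimenters wrongly passed two birds on)
  seq7_10 <- c(0, 0, 0, rep(1, 17))
  expect_identical(criterion_fixed_window(seq7_10), NA_integer_)
  expect_identical(criterion_fixed_window(seq7_10, minima_ordered = FALSE),
                   NA_integer_)
  # 9/10 then 8/10: only the unordered reading passes
  seq9_8 <- c(0, rep(1, 9), 0, 0, rep(1, 8))
  expect_identical(criterion_fixed_window(seq9_8), NA_integer_)
  expect_identical(criterion_fixed_window(seq9_8, minima_ordered = FALSE), 20L)
})

test_that("fixed-window finishes are multiples of 10 and agree with the oracle", {
  set.seed(303)
  for (i in 1:150) {
    flags <- rbinom(sample(0:65, 1), 1, runif(1, 0.4, 0.95))
    for (ord in c(TRUE, FALSE)) {
      f <- criterion_fixed_window(flags, minima_ordered = ord)
      expect_identical(f, oracle_fixed(flags, ord))
      if (!is.na(f)) {
        expect_gte(f, 20L)
        expect_identical(f %% 10L, 0L)
      }
    }
  }
})

test_that("sliding-window criterion reproduces the legacy early-pass anomaly", {
  # three wrong then seventeen correct: full window fails at 20 (7/10 +
  # 10/10), but at the start of trial 21 the window holds 8/10 and >= 9/10
  # whatever the bird does next
  f <- criterion_sliding_window(c(0, 0, 0, rep(1, 17)))
  expect_identical(as.integer(f), 21L)
  expect_true(attr(f, "pre_choice"))
  # perfect performance passes the full window at 20
  f <- criterion_sliding_window(rep(1, 20))
  expect_identical(as.integer(f), 20L)
  expect_false(attr(f, "pre_choice"))
  # 17 correct then 3 wrong: window halves at 20 are 10/10 then 7/10,
  # failing the set minima, and later windows are worse
  expect_identical(criterion_sliding_window(c(rep(1, 17), rep(0, 3))),
                   NA_integer_)
  # the anomaly window also passes mid-sequence
  f <- criterion_sliding_window(c(0, 0, 0, rep(1, 17), 0, 0, 0, 0))
  expect_identical(as.integer(f), 21L)
  expect_true(attr(f, "pre_choice"))
})

test_that("switch counting equals the adjacent-difference oracle", {
  expect_identical(count_switches(c("A", "A", "A", "A")), 0L)
  expect_identical(count_switches(c("A", "B", "A", "B")), 3L)
  expect_identical(count_switches(c("A", "A", "B", "B", "A")), 2L)
  expect_identical(count_switches(character(0)), 0L)
  expect_error(count_switches(c("A", NA)), "NA")
  set.seed(404)
  for (i in 1:100) {
    ch <- sample(c("option1", "option2"), sample(1:40, 1), replace = TRUE)
    expect_identical(as.integer(count_switches(ch)), oracle_switches(ch))
    upto <- sample(seq_along(ch), 1)
    expect_identical(as.integer(count_switches(ch, upto = upto)),
                     oracle_switches(ch[1:upto]))
  }
})
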