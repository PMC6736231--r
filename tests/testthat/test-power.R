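# Independent Monte-Carlo oracle: rejection rate of the pooled-variance
# two-sample t-test over `reps` simulated normal datasets.
mc_power_t <- function(d, n1, n2, alpha = 0.05, reps = 4e4) {
  x1 <- matrix(stats::rnorm(n1 * reps, mean = d), nrow = n1)
  x2 <- matrix(stats::rnorm(n2 * reps, mean = 0), nrow = n2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  ss1 <- colSums((x1 - rep(m1, each = n1))^2)
  ss2 <- colSums((x2 - rep(m2, each = n2))^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  crit <- stats::qt(1 - alpha / 2, n1 + n2 - 2)
  mean(abs(tstat) > crit)
}

test_that("two-sample power reproduces published worked values at 2 dp", {
  expect_equal(round(power_two_sample_t(0.76, 30, 19)$power, 2), 0.72)
  expect_equal(round(power_two_sample_t(0.38, 30, 19)$power, 2), 0.25)
  expect_equal(round(power_two_sample_t(0.16, 30, 19)$power, 2), 0.08)
  expect_equal(round(power_two_sample_t(0.38, 64, 64)$power, 2), 0.57)
})

test_that("at d = 0 the two-tailed power equals alpha exactly", {
  for (a in c(0.01, 0.05, 0.10)) {
    expect_equal(power_two_sample_t(0, 50, 50, alpha = a)$power, a,
                 tolerance = 1e-12)
  }
})

test_that("two-sample power agrees with a Monte-Carlo rejection-rate oracle", {
  withr::with_seed(1301, {
    for (case in list(c(0.76, 30, 19), c(0.38, 64, 64), c(0.5, 20, 35))) {
      reps <- 4e4
      hat <- mc_power_t(case[1], case[2], case[3], reps = reps)
      theo <- power_two_sample_t(case[1], case[2], case[3])$power
      se <- sqrt(theo * (1 - theo) / reps)
      expect_lt(abs(hat - theo), 3 * se)
    }
  })
})

test_that("power is monotone in effect, group sizes, and alpha", {
  d <- seq(0, 1.5, by = 0.1)
  p <- vapply(d, function(x) power_two_sample_t(x, 25, 25)$power, numeric(1))
  expect_true(all(diff(p) > 0))
  n <- c(4, 8, 16, 32, 64, 128, 1024, 1e4)
  pn <- vapply(n, function(x) power_two_sample_t(0.3, x, x)$power, numeric(1))
  expect_true(all(diff(pn) > 0))
  pn2 <- vapply(n, function(x) power_two_sample_t(0.3, 20, x)$power, numeric(1))
  expect_true(all(diff(pn2) > 0))
  pa <- vapply(c(.01, .05, .1, .2), function(a) power_two_sample_t(0.3, 20, 20, a)$power,
               numeric(1))
  expect_true(all(diff(pa) > 0))
})

test_that("equal groups are the special case ncp = d * sqrt(n/2) of the unequal formula", {
  res <- power_two_sample_t(0.4, 33, 33)
  expect_equal(res$ncp, 0.4 * sqrt(33 / 2), tolerance = 1e-12)
  expect_equal(res$power, power_two_sample_t(0.4, 33)$power)
})

test_that("correlation power reproduces published worked values at 2 dp", {
  expect_equal(round(power_correlation(0.32, 129)$power, 2), 0.96)
  expect_equal(round(power_correlation(0.20, 129)$power, 2), 0.63)
  expect_equal(round(power_correlation(0.12, 129)$power, 2), 0.27)
})

test_that("correlation power approximation is near alpha at r = 0 and monotone", {
  expect_lt(abs(power_correlation(0, 100)$power - 0.05), 0.01)
  r <- seq(0.05, 0.9, by = 0.05)
  p <- vapply(r, function(x) power_correlation(x, 50)$power, numeric(1))
  expect_true(all(diff(p) > 0))
  # the Fisher-z approximation dips between n = 4 and n = 6 (boundary artifact
  # of the bias term at sqrt(n - 3) ~ 1); monotone from n = 6 onward
  n <- c(6, 10, 20, 50, 200, 1e3, 1e4)
  pn <- vapply(n, function(x) power_correlation(0.2, x)$power, numeric(1))
  expect_true(all(diff(pn) > 0))
})

test_that("domain errors are raised for invalid power queries", {
  expect_error(power_correlation(0.3, 3), "n >= 4")
  expect_error(power_correlation(1.0, 50), "r must")
  expect_error(power_two_sample_t(0.3, 1, 10), "at least 2")
  expect_error(power_two_sample_t(0.3, 10, 10, alpha = 1.2), "alpha")
})

test_that("sample-size solvers return published worked values", {
  expect_identical(solve_n_two_sample(0.50, 0.80), 64L)
  expect_identical(solve_n_two_sample(0.38, 0.80), 110L)
  expect_identical(solve_n_correlation(0.32, 0.60), 47L)
  expect_identical(solve_n_correlation(0.32, 0.80), 74L)
  expect_identical(solve_n_correlation(0.32, 0.90), 98L)
})

test_that("solvers return the smallest integer n meeting the target", {
  for (d in c(0.2, 0.38, 0.5, 0.8)) {
    for (tp in c(0.6, 0.8, 0.9)) {
      n <- solve_n_two_sample(d, tp)
      expect_gte(power_two_sample_t(d, n, n)$power, tp)
      if (n > 2) expect_lt(power_two_sample_t(d, n - 1, n - 1)$power, tp)
    }
  }
  for (r in c(0.12, 0.2, 0.32, 0.5)) {
    for (tp in c(0.6, 0.8, 0.9)) {
      n <- solve_n_correlation(r, tp)
      expect_gte(power_correlation(r, n)$power, tp)
      if (n > 4) expect_lt(power_correlation(r, n - 1)$power, tp)
    }
  }
})

test_that("unattainable targets and invalid effects produce errors", {
  expect_error(solve_n_two_sample(1e-9, 0.8), "not attainable")
  expect_error(solve_n_two_sample(0, 0.8), "d > 0")
  expect_error(solve_n_correlation(0.3, 0.04), "target power")
})

test_that("corpus power summary matches a brute-force per-row loop", {
  one <- r_corpus(0.25, 129)
  s1 <- corpus_power_summary(one, reference = c(r = 0.20))
  expect_equal(s1$fraction_adequate[["overall"]], 0)  # power .63 < .80
  expect_equal(s1$medians$r[["n_total"]], 129)

  big <- g_corpus(rep(0.4, 5), 5000, 5000)
  expect_equal(corpus_power_summary(big, c(g = 0.38))$fraction_adequate[["overall"]], 1)

  corpus <- normalize_corpus(generate_corpus(default_calibration(seed = 11, n_meta = 60L)))
  s <- corpus_power_summary(corpus, reference = c(r = 0.20, g = 0.38))
  brute <- vapply(seq_len(nrow(corpus)), function(i) {
    if (corpus$metric[i] == "r") power_correlation(0.20, corpus$n1[i])$power
    else power_two_sample_t(0.38, corpus$n1[i], corpus$n2[i])$power
  }, numeric(1))
  expect_equal(s$records$power, brute)
  expect_equal(s$fraction_adequate[["overall"]], mean(brute >= 0.80))
})
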