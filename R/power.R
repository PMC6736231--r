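#' Exact power of the two-sample t-test
#'
#' Computes the power of the independent-samples t-test for a standardized
#' mean difference `d`, with possibly unequal group sizes, from the
#' noncentral t distribution. With `df = n1 + n2 - 2` and noncentrality
#' `ncp = d * sqrt(n1 * n2 / (n1 + n2))`, the two-tailed power at level
#' `alpha` is
#' `1 - F(t*; df, ncp) + F(-t*; df, ncp)`
#' where `t*` is the upper `1 - alpha/2` quantile of the central t
#' distribution and `F` the noncentral-t CDF. One-tailed tests use the
#' `1 - alpha` quantile and drop the lower-tail term. At `d = 0` the
#' two-tailed power equals `alpha` exactly (the size of the test).
#'
#' @param d standardized mean difference (Cohen's d / Hedges' g scale),
#'   taken as the population value.
#' @param n1,n2 group sizes (each >= 2); `n2` defaults to `n1`.
#' @param alpha significance level in (0, 1).
#' @param tails `"two"` (default) or `"one"`.
#' @return a `power_result` with elements `power`, `df`, `ncp`, `crit`.
#' @examples
#' power_two_sample_t(0.76, n1 = 30, n2 = 19)  # power ~ .72
#' power_two_sample_t(0.38, n1 = 64, n2 = 64)  # power ~ .57
#' @export
power_two_sample_t <- function(d, n1, n2 = n1, alpha = 0.05,
                               tails = c("two", "one")) {
  tails <- match.arg(tails)
  check_alpha(alpha)
  if (any(n1 < 2) || any(n2 < 2)) stop("group sizes must each be at least 2")
  df <- n1 + n2 - 2
  if (any(df < 1)) stop("degrees of freedom must be at least 1")
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (tails == "two") {
    crit <- stats::qt(1 - alpha / 2, df)
    power <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
  } else {
    crit <- stats::qt(1 - alpha, df)
    power <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  }
  power_result(power = power, df = df, ncp = ncp, crit = crit,
               test = "two-sample t (noncentral)", effect = d,
               n1 = n1, n2 = n2, alpha = alpha, tails = tails)
}

#' Approximate power of the test of zero correlation
#'
#' Power of the t-test that a Pearson correlation is zero, via the Fisher-z
#' approximation: the critical correlation `r_c` is mapped from the central
#' t quantile at `df = n - 2` through `r_c = sqrt(t*^2 / (t*^2 + df))`, and
#' the test statistic distribution under the alternative is approximated as
#' normal on the atanh scale with mean `atanh(r) + r / (2 * (n - 1))`
#' (a bias-corrected Fisher z) and standard deviation `1 / sqrt(n - 3)`:
#' two-tailed power is
#' `pnorm((z_r - z_c) * sqrt(n - 3)) + pnorm((-z_r - z_c) * sqrt(n - 3))`.
#'
#' @param r population correlation, `0 <= r < 1`.
#' @param n total sample size, at least 4.
#' @param alpha significance level in (0, 1).
#' @param tails `"two"` (default) or `"one"`.
#' @return a `power_result` with elements `power`, `df`, `ncp` (the
#'   standardized Fisher-z effect `z_r * sqrt(n - 3)`), `crit` (the central
#'   t critical value).
#' @examples
#' power_correlation(0.32, n = 129)  # power ~ .96
#' power_correlation(0.20, n = 129)  # power ~ .63
#' @export
power_correlation <- function(r, n, alpha = 0.05, tails = c("two", "one")) {
  tails <- match.arg(tails)
  check_alpha(alpha)
  if (any(r < 0) || any(r >= 1)) stop("r must satisfy 0 <= r < 1")
  if (any(n < 4)) stop("correlation power requires n >= 4")
  df <- n - 2
  crit <- if (tails == "two") stats::qt(1 - alpha / 2, df) else stats::qt(1 - alpha, df)
  r_c <- sqrt(crit^2 / (crit^2 + df))
  z_c <- atanh(r_c)
  z_r <- atanh(r) + r / (2 * (n - 1))
  s <- sqrt(n - 3)
  power <- stats::pnorm((z_r - z_c) * s)
  if (tails == "two") power <- power + stats::pnorm((-z_r - z_c) * s)
  power_result(power = power, df = df, ncp = z_r * s, crit = crit,
               test = "correlation (Fisher z approximation)", effect = r,
               n1 = n, n2 = NA_real_, alpha = alpha, tails = tails)
}

#' Smallest per-group n reaching a target power (two-sample t)
#'
#' Solves for the smallest integer per-group sample size `n` such that
#' [power_two_sample_t()] with equal groups reaches `target_power`. The
#' continuous power curve is bracketed over n in \[2, 1e7\] and the root
#' found by [stats::uniroot()]; the result is the ceiling, adjusted so that
#' minimality holds exactly: `power(n) >= target_power > power(n - 1)`.
#'
#' @param d standardized mean difference, > 0.
#' @param target_power target power in (alpha, 1).
#' @inheritParams power_two_sample_t
#' @return integer sample size per group.
#' @examples
#' solve_n_two_sample(0.50, 0.80)  # 64
#' solve_n_two_sample(0.38, 0.80)  # 110
#' @export
solve_n_two_sample <- function(d, target_power = 0.80, alpha = 0.05,
                               tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (d <= 0) stop("sample-size solving requires d > 0")
  check_target(target_power, alpha)
  pw <- function(n) power_two_sample_t(d, n, n, alpha, tails)$power
  solve_n_integer(pw, lower = 2, target = target_power)
}

#' Smallest n reaching a target power (correlation test)
#'
#' Solves for the smallest integer total sample size `n >= 4` such that
#' [power_correlation()] reaches `target_power` (ceiling of the continuous
#' root, with exact integer minimality enforced).
#'
#' @param r population correlation, > 0.
#' @inheritParams solve_n_two_sample
#' @return integer total sample size.
#' @examples
#' solve_n_correlation(0.32, 0.80)  # 74
#' @export
solve_n_correlation <- function(r, target_power = 0.80, alpha = 0.05,
                                tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (r <= 0) stop("sample-size solving requires r > 0")
  check_target(target_power, alpha)
  pw <- function(n) power_correlation(r, n, alpha, tails)$power
  solve_n_integer(pw, lower = 4, target = target_power)
}

# bracketed continuous root + ceiling, then exact integer minimality
solve_n_integer <- function(pw, lower, target, upper = 1e7) {
  if (pw(upper) < target) {
    stop("target power not attainable with n up to ", format(upper, scientific = FALSE))
  }
  if (pw(lower) >= target) return(as.integer(lower))
  root <- stats::uniroot(function(n) pw(n) - target, c(lower, upper),
                         tol = 1e-8)$root
  n <- as.integer(ceiling(root - 1e-9))
  while (n > lower && pw(n - 1) >= target) n <- n - 1L
  while (pw(n) < target) n <- n + 1L
  n
}

#' Achieved power across a corpus at reference effects
#'
#' For every record of a normalized corpus, computes the power its own
#' sample sizes achieve to detect a per-metric reference effect (typically
#' the field's medium benchmark), and summarizes: the fraction of records
#' reaching the conventional .80 threshold, and median sample sizes.
#'
#' @param corpus a normalized [es_corpus] (metrics `r` and `g` only).
#' @param reference named numeric vector of reference effects, e.g.
#'   `c(r = 0.20, g = 0.38)`; only metrics present in the corpus are needed.
#' @param alpha significance level.
#' @param power_threshold adequacy cutoff (default .80).
#' @return a `corpus_power_summary`: list with `records` (per-row data.frame
#'   of metric, n1, n2, power, adequate), `fraction_adequate` (overall and
#'   per metric), and `medians` (n1, n2, total n by metric).
#' @export
corpus_power_summary <- function(corpus, reference = c(r = 0.20, g = 0.38),
                                 alpha = 0.05, power_threshold = 0.80) {
  stopifnot(inherits(corpus, "es_corpus"))
  if (any(corpus$metric == "d")) {
    stop("corpus must be normalized first (d records present); see normalize_corpus()")
  }
  pow <- numeric(nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    m <- corpus$metric[i]
    if (!m %in% names(reference)) {
      stop("no reference effect supplied for metric '", m, "'")
    }
    pow[i] <- if (m == "r") {
      power_correlation(reference[["r"]], corpus$n1[i], alpha)$power
    } else {
      power_two_sample_t(reference[["g"]], corpus$n1[i], corpus$n2[i], alpha)$power
    }
  }
  rec <- data.frame(metric = corpus$metric, n1 = corpus$n1, n2 = corpus$n2,
                    power = pow, adequate = pow >= power_threshold)
  frac <- c(overall = mean(rec$adequate))
  for (m in unique(rec$metric)) frac[[m]] <- mean(rec$adequate[rec$metric == m])
  med <- lapply(split(rec, rec$metric), function(dd) {
    c(n1 = stats::median(dd$n1), n2 = stats::median(dd$n2),
      n_total = stats::median(ifelse(is.na(dd$n2), dd$n1, dd$n1 + dd$n2)))
  })
  structure(list(records = rec, fraction_adequate = frac, medians = med,
                 reference = reference, alpha = alpha,
                 power_threshold = power_threshold),
            class = "corpus_power_summary")
}

#' @export
print.corpus_power_summary <- function(x, ...) {
  cat("<corpus_power_summary>\n")
  cat(sprintf("reference effects: %s; alpha = %.3g\n",
              paste(sprintf("%s = %.3g", names(x$reference), x$reference),
                    collapse = ", "), x$alpha))
  cat(sprintf("fraction with power >= %.2f: %.3f overall\n",
              x$power_threshold, x$fraction_adequate[["overall"]]))
  for (m in setdiff(names(x$fraction_adequate), "overall")) {
    med <- x$medians[[m]]
    cat(sprintf("  %s: %.3f adequate; median n1 = %g, n2 = %g, total = %g\n",
                m, x$fraction_adequate[[m]], med[["n1"]], med[["n2"]],
                med[["n_total"]]))
  }
  invisible(x)
}

power_result <- function(power, df, ncp, crit, test, effect, n1, n2, alpha, tails) {
  structure(list(power = power, df = df, ncp = ncp, crit = crit, test = test,
                 effect = effect, n1 = n1, n2 = n2, alpha = alpha, tails = tails),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("%s power analysis\n", x$test))
  n_txt <- if (is.na(x$n2)) sprintf("n = %g", x$n1) else sprintf("n1 = %g, n2 = %g", x$n1, x$n2)
  cat(sprintf("  effect = %.4g, %s, alpha = %.3g (%s-tailed)\n",
              x$effect, n_txt, x$alpha, x$tails))
  cat(sprintf("  power = %.4f  (df = %g, ncp = %.4f, crit = %.4f)\n",
              x$power, x$df, x$ncp, x$crit))
  invisible(x)
}

check_alpha <- function(alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
}
check_target <- function(target_power, alpha) {
  if (target_power <= alpha || target_power >= 1) {
    stop("target power must lie in (alpha, 1)")
  }
}
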