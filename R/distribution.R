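#' Quantile of effect magnitudes (linear order-statistic interpolation)
#'
#' Fixed to the convention where, with sorted values `x_(1..N)` and
#' `h = (N - 1) * p + 1`, the quantile is
#' `x_floor(h) + (h - floor(h)) * (x_ceil(h) - x_floor(h))` — i.e. the
#' default of `stats::quantile()` (type 7). Percentile benchmarks depend on
#' this choice, so it is pinned here rather than left to the caller.
#'
#' @param values numeric vector, at least one finite value.
#' @param p proportions in \[0, 1\]; vectorized.
#' @return quantiles, unnamed.
#' @export
es_quantile <- function(values, p) {
  if (length(values) == 0L) stop("cannot take quantiles of an empty collection")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  stats::quantile(values, probs = p, type = 7, names = FALSE)
}

#' Percentile benchmark table for a corpus
#'
#' Computes effect magnitudes at a grid of percentiles for one metric
#' (optionally within a subfield category). The 25th, 50th, and 75th
#' percentiles — when present in the grid — are labeled small, medium, and
#' large, following the convention of defining field-specific benchmarks by
#' the quartiles of observed effects.
#'
#' @param corpus a normalized [es_corpus].
#' @param metric `"g"` or `"r"`.
#' @param subgroup `"all"` (default), `"biomedical"`, or `"psychosocial"`.
#' @param grid percentiles in (0, 100), strictly increasing; default
#'   `seq(5, 95, by = 5)`.
#' @return a `benchmark_table`: data.frame with columns `percentile`,
#'   `effect`, `label`, plus attributes `metric`, `subgroup`, `n_records`.
#' @export
benchmark <- function(corpus, metric = c("g", "r"),
                      subgroup = c("all", "biomedical", "psychosocial"),
                      grid = seq(5, 95, by = 5)) {
  metric <- match.arg(metric)
  subgroup <- match.arg(subgroup)
  if (any(grid <= 0 | grid >= 100)) stop("percentile grid must lie in (0, 100)")
  if (is.unsorted(grid, strictly = TRUE)) stop("percentile grid must be strictly increasing")
  sel <- select_records(corpus, metric, subgroup)
  if (nrow(sel) == 0L) {
    stop("no records with metric '", metric, "' in subgroup '", subgroup, "'")
  }
  eff <- es_quantile(sel$value, grid / 100)
  label <- rep(NA_character_, length(grid))
  label[grid == 25] <- "small"
  label[grid == 50] <- "medium"
  label[grid == 75] <- "large"
  structure(data.frame(percentile = grid, effect = eff, label = label),
            metric = metric, subgroup = subgroup, n_records = nrow(sel),
            class = c("benchmark_table", "data.frame"))
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat(sprintf("<benchmark_table> metric = %s, subgroup = %s, k = %d records\n",
              attr(x, "metric"), attr(x, "subgroup"), attr(x, "n_records")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fraction of effects at or above a threshold
#'
#' @param corpus a normalized [es_corpus].
#' @param metric `"g"` or `"r"`.
#' @param threshold effect-magnitude cutoff.
#' @param subgroup subfield selection as in [benchmark()].
#' @return fraction in \[0, 1\] of matching records with `value >= threshold`.
#' @export
proportion_at_least <- function(corpus, metric = c("g", "r"), threshold,
                                subgroup = c("all", "biomedical", "psychosocial")) {
  metric <- match.arg(metric)
  subgroup <- match.arg(subgroup)
  sel <- select_records(corpus, metric, subgroup)
  if (nrow(sel) == 0L) stop("no records match metric '", metric, "'")
  mean(sel$value >= threshold)
}

#' Moment-based shape of a distribution
#'
#' Skewness `m3 / m2^(3/2)` and kurtosis from central moments. Because
#' reporting conventions differ, kurtosis is returned both raw
#' (`m4 / m2^2`; 3 for a normal) and as excess (`m4 / m2^2 - 3`).
#'
#' @param values numeric vector with at least 3 values and nonzero variance.
#' @return list with `skewness`, `kurtosis_raw`, `kurtosis_excess`.
#' @export
es_moments <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("moments require at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("moments undefined for zero-variance data")
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  list(skewness = m3 / m2^1.5,
       kurtosis_raw = m4 / m2^2,
       kurtosis_excess = m4 / m2^2 - 3)
}

#' Round an effect benchmark to the nearest 0.05
#'
#' Practical guideline values are rounded to the nearest multiple of 0.05;
#' exact ties (e.g. 0.125) round up.
#'
#' @param value nonnegative effect magnitude(s).
#' @return value(s) rounded to a multiple of 0.05.
#' @examples
#' round_guideline(c(0.16, 0.38, 0.76))  # 0.15 0.40 0.75
#' @export
round_guideline <- function(value) {
  if (any(value < 0)) stop("guideline rounding expects nonnegative values")
  floor(value / 0.05 + 0.5 + 1e-9) * 0.05
}

#' Histogram bins and counts for effect magnitudes
#'
#' Equal-width bins spanning the data; counts sum to the number of values.
#'
#' @param values numeric vector, at least one value.
#' @param bins number of bins (default 30).
#' @return list with `edges` (length `bins + 1`), `counts`, `mids`.
#' @export
histogram_prep <- function(values, bins = 30) {
  if (length(values) == 0L) stop("no values to bin")
  if (bins < 1) stop("bins must be positive")
  rng <- range(values)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  h <- graphics::hist(values, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  list(edges = h$breaks, counts = h$counts, mids = h$mids)
}

#' Kernel density curve for effect magnitudes
#'
#' Gaussian kernel; bandwidth defaults to Silverman's rule of thumb
#' (`stats::bw.nrd0`). The returned curve integrates to approximately 1.
#'
#' @param values numeric vector, at least 2 distinct values.
#' @param bandwidth kernel bandwidth; `NULL` for Silverman's rule.
#' @param n number of evaluation points.
#' @return data.frame with columns `x`, `y`; attribute `bandwidth`.
#' @export
density_prep <- function(values, bandwidth = NULL, n = 512) {
  if (!is.null(bandwidth) && bandwidth <= 0) stop("bandwidth must be positive")
  d <- if (is.null(bandwidth)) {
    stats::density(values, kernel = "gaussian", n = n)
  } else {
    stats::density(values, bw = bandwidth, kernel = "gaussian", n = n)
  }
  structure(data.frame(x = d$x, y = d$y), bandwidth = d$bw)
}
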