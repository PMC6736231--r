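#' Benchmark report: percentile grid and guideline comparison
#'
#' Produces the benchmark tables for one metric: the full percentile grid,
#' and a comparison block with Cohen's conventional guidelines, the
#' quartile benchmarks observed in the corpus, and the observed benchmarks
#' rounded to the nearest 0.05 for practical use.
#'
#' @param corpus a normalized [es_corpus].
#' @param metric `"g"` or `"r"`.
#' @param subgroup subfield selection as in [benchmark()].
#' @param grid percentile grid; must contain 25, 50, and 75.
#' @param out_csv optional path; when given, the percentile grid and the
#'   comparison block are written as CSV (`<path>` and
#'   `<path base>_comparison.csv`).
#' @return list with `percentiles` (a [benchmark()] table) and `comparison`
#'   (data.frame with rows cohen / observed / rounded and columns
#'   small / medium / large).
#' @export
report_benchmarks <- function(corpus, metric = c("g", "r"),
                              subgroup = c("all", "biomedical", "psychosocial"),
                              grid = seq(5, 95, by = 5), out_csv = NULL) {
  metric <- match.arg(metric)
  subgroup <- match.arg(subgroup)
  if (!all(c(25, 50, 75) %in% grid)) stop("grid must include the quartiles 25, 50, 75")
  bt <- benchmark(corpus, metric, subgroup, grid)
  quart <- bt$effect[match(c(25, 50, 75), bt$percentile)]
  cohen <- if (metric == "g") c(0.20, 0.50, 0.80) else c(0.10, 0.30, 0.50)
  comparison <- data.frame(source = c("cohen", "observed", "rounded"),
                           small = c(cohen[1], quart[1], round_guideline(quart[1])),
                           medium = c(cohen[2], quart[2], round_guideline(quart[2])),
                           large = c(cohen[3], quart[3], round_guideline(quart[3])))
  if (!is.null(out_csv)) {
    utils::write.csv(as.data.frame(bt), out_csv, row.names = FALSE)
    utils::write.csv(comparison,
                     sub("\\.csv$", "_comparison.csv", out_csv),
                     row.names = FALSE)
  }
  list(percentiles = bt, comparison = comparison)
}

#' Required-sample-size tables across a power grid
#'
#' For each labeled effect size, solves for the smallest sample size
#' (per group for the two-group design, total for correlations) achieving
#' each power level — the shape of the familiar a priori power-analysis
#' tables. Sample sizes use the ceiling convention: the returned integer
#' always meets or exceeds the target power.
#'
#' @param effects named numeric vector of effect magnitudes (names become
#'   row labels, e.g. `c(small = 0.16, medium = 0.38, large = 0.76)`).
#' @param metric `"g"` (two-group, n per group) or `"r"` (total n).
#' @param power_grid target power levels in (0, 1); default .60/.70/.80/.90.
#' @param alpha significance level (two-tailed).
#' @param out_csv optional CSV output path.
#' @return data.frame: one row per effect, one column per power level;
#'   attributes `alpha`, `tails`, `rounding`.
#' @export
report_power_tables <- function(effects, metric = c("g", "r"),
                                power_grid = c(0.60, 0.70, 0.80, 0.90),
                                alpha = 0.05, out_csv = NULL) {
  metric <- match.arg(metric)
  if (any(power_grid <= 0 | power_grid >= 1)) stop("power grid values must lie in (0, 1)")
  if (is.null(names(effects))) names(effects) <- sprintf("effect_%g", effects)
  solver <- if (metric == "g") solve_n_two_sample else solve_n_correlation
  tab <- t(vapply(effects, function(e) {
    vapply(power_grid, function(p) as.numeric(solver(e, p, alpha)), numeric(1))
  }, numeric(length(power_grid))))
  out <- data.frame(effect_label = names(effects), effect = unname(effects))
  for (j in seq_along(power_grid)) {
    out[[sprintf("power_%g", 100 * power_grid[j])]] <- tab[, j]
  }
  attr(out, "alpha") <- alpha
  attr(out, "tails") <- "two"
  attr(out, "rounding") <- "ceiling (returned n always meets the target power)"
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Funnel-region report with optional figure
#'
#' Tabulates significance-contour region percentages for one or more
#' subgroups and optionally renders a contour-enhanced funnel plot.
#'
#' @param corpus a normalized [es_corpus].
#' @param subgroups character vector of subgroups to tabulate.
#' @param out_csv optional CSV output path for the combined table.
#' @param out_figure optional figure path (extension selects the device,
#'   e.g. `.png` or `.svg`); the first subgroup is plotted.
#' @return data.frame stacking the [funnel_table()] rows for each subgroup
#'   with a `subgroup` column.
#' @export
report_funnel <- function(corpus, subgroups = "all", out_csv = NULL,
                          out_figure = NULL) {
  tabs <- lapply(subgroups, function(sg) {
    ft <- funnel_table(corpus, sg)
    cbind(subgroup = sg, as.data.frame(ft))
  })
  out <- do.call(rbind, tabs)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  if (!is.null(out_figure)) {
    p <- plot_funnel(corpus, subgroups[1],
                     title = sprintf("Contour-enhanced funnel plot (%s)", subgroups[1]))
    ggplot2::ggsave(out_figure, p, width = 7, height = 5, dpi = 150)
  }
  out
}

#' Achieved-power report at the corpus' own benchmarks
#'
#' Summarizes how well powered the studies in a corpus are: median sample
#' sizes per design, the power those medians achieve at the small, medium,
#' and large benchmark effects, and the fraction of individual records
#' adequately powered (power >= .80) for the medium benchmark.
#'
#' @param corpus a normalized [es_corpus].
#' @param benchmarks optional list with elements `r` and/or `g`, each a
#'   numeric vector `c(small, medium, large)`; when `NULL`, the quartile
#'   benchmarks are computed from the corpus itself.
#' @param alpha significance level.
#' @return an `achieved_power_report` list: per metric, `benchmarks`,
#'   `medians`, `power_at_median` (power at each benchmark using the
#'   median sample sizes), and `fraction_adequate` at the medium benchmark.
#' @export
report_achieved <- function(corpus, benchmarks = NULL, alpha = 0.05) {
  stopifnot(inherits(corpus, "es_corpus"))
  metrics <- intersect(c("r", "g"), unique(corpus$metric))
  if (length(metrics) == 0L) stop("corpus has no r or g records")
  out <- list()
  for (m in metrics) {
    bm <- if (!is.null(benchmarks) && !is.null(benchmarks[[m]])) {
      benchmarks[[m]]
    } else {
      benchmark(corpus, m, grid = c(25, 50, 75))$effect
    }
    names(bm) <- c("small", "medium", "large")
    sel <- select_records(corpus, m)
    if (m == "r") {
      med <- c(n = stats::median(sel$n1))
      pam <- vapply(bm, function(e) power_correlation(e, med[["n"]], alpha)$power,
                    numeric(1))
    } else {
      med <- c(n1 = stats::median(sel$n1), n2 = stats::median(sel$n2))
      pam <- vapply(bm, function(e) {
        power_two_sample_t(e, med[["n1"]], med[["n2"]], alpha)$power
      }, numeric(1))
    }
    ref <- stats::setNames(bm[["medium"]], m)
    cps <- corpus_power_summary(sel, reference = ref, alpha = alpha)
    out[[m]] <- list(benchmarks = bm, medians = med, power_at_median = pam,
                     fraction_adequate = cps$fraction_adequate[["overall"]])
  }
  structure(c(out, list(alpha = alpha)), class = "achieved_power_report")
}

#' @export
print.achieved_power_report <- function(x, ...) {
  cat("Achieved power report (alpha =", x$alpha, ", two-tailed)\n")
  for (m in intersect(c("r", "g"), names(x))) {
    y <- x[[m]]
    cat(sprintf("\nmetric %s: median sample size(s): %s\n", m,
                paste(sprintf("%s = %g", names(y$medians), y$medians), collapse = ", ")))
    cat(sprintf("  benchmarks (small/medium/large): %s\n",
                paste(sprintf("%.2f", y$benchmarks), collapse = " / ")))
    cat(sprintf("  power at median n:               %s\n",
                paste(sprintf("%.2f", y$power_at_median), collapse = " / ")))
    cat(sprintf("  fraction adequately powered for the medium effect: %.2f\n",
                y$fraction_adequate))
  }
  invisible(x)
}
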