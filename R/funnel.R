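# Significance-contour boundaries on the standard-normal scale:
# p = .10, .05, .01 two-sided.
CONTOUR_Z <- c(p10 = 1.644854, p05 = 1.959964, p01 = 2.575829)

#' Standard error of Hedges' g
#'
#' Large-sample standard error of a standardized mean difference:
#' `sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))`. Decreasing in
#' both group sizes, increasing in `|g|`.
#'
#' @param g effect magnitude on the g scale.
#' @param n1,n2 group sizes, each at least 2.
#' @return standard error(s).
#' @export
se_hedges_g <- function(g, n1, n2) {
  if (any(is.na(n1) | is.na(n2)) || any(n1 < 2 | n2 < 2)) {
    stop("se of g requires n1 >= 2 and n2 >= 2")
  }
  sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2)))
}

#' Standard error of a Fisher-z transformed correlation
#'
#' `1 / sqrt(n - 3)` on the atanh scale.
#'
#' @param n total sample size, at least 4.
#' @return standard error(s).
#' @export
se_fisher_z <- function(n) {
  if (any(is.na(n)) || any(n < 4)) stop("Fisher-z se requires n >= 4")
  1 / sqrt(n - 3)
}

#' Two-sided normal-theory p-value
#'
#' `p = 2 * (1 - pnorm(effect / se))`, the p-value underlying the
#' significance contours of a funnel plot (effects are nonnegative after
#' normalization, so this is the two-sided p of the observed magnitude).
#'
#' @param effect effect magnitude (nonnegative).
#' @param se standard error, > 0.
#' @return p-value(s) in (0, 1\].
#' @export
p_value_z <- function(effect, se) {
  if (any(se <= 0)) stop("se must be positive")
  2 * stats::pnorm(effect / se, lower.tail = FALSE)
}

#' Classify a p-value into a funnel contour region
#'
#' Regions follow the conventional contour-enhanced funnel shading:
#' white `p >= .10`, orange `.05 <= p < .10`, red `.01 <= p < .05`,
#' gray `p < .01`. Exact boundary ties go to the less significant region.
#'
#' @param p p-value(s) in (0, 1\].
#' @return factor with levels `white, orange, red, gray`.
#' @export
contour_region <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  out <- ifelse(p < 0.01, "gray",
                ifelse(p < 0.05, "red",
                       ifelse(p < 0.10, "orange", "white")))
  factor(out, levels = c("white", "orange", "red", "gray"))
}

#' Per-record funnel coordinates and contour regions
#'
#' Maps every usable record of a normalized corpus into (effect, standard
#' error) space: Hedges' g records keep their magnitude with the analytic
#' g standard error; correlations are moved to the Fisher-z scale
#' (`effect = atanh(r)`, `se = 1 / sqrt(n - 3)`), the standard
#' meta-analytic geometry. When the corpus carries a numeric `se` column,
#' those values take precedence over the recomputed ones. Records lacking
#' the sample sizes needed for a standard error are skipped; the count of
#' skipped records is attached as attribute `n_skipped`.
#'
#' @param corpus a normalized [es_corpus].
#' @param subgroup subfield selection as in [benchmark()].
#' @return data.frame with columns `metric`, `effect`, `se`, `p`, `region`;
#'   attributes `n_skipped`, `subgroup`.
#' @export
funnel_points <- function(corpus, subgroup = c("all", "biomedical", "psychosocial")) {
  subgroup <- match.arg(subgroup)
  stopifnot(inherits(corpus, "es_corpus"))
  if (any(corpus$metric == "d")) {
    stop("corpus must be normalized first; see normalize_corpus()")
  }
  sel <- select_records(corpus, c("r", "g"), subgroup)
  if (nrow(sel) == 0L) stop("no records in subgroup '", subgroup, "'")
  is_r <- sel$metric == "r"
  usable <- ifelse(is_r, !is.na(sel$n1) & sel$n1 >= 4,
                   !is.na(sel$n1) & !is.na(sel$n2) & sel$n1 >= 2 & sel$n2 >= 2)
  has_se <- !is.null(sel$se) && is.numeric(sel$se)
  if (has_se) usable <- usable | (!is.na(sel$se) & sel$se > 0)
  n_skipped <- sum(!usable)
  if (n_skipped > 0L) {
    message(n_skipped, " record(s) skipped: no usable sample sizes for a standard error")
  }
  sel <- sel[usable, , drop = FALSE]
  is_r <- sel$metric == "r"
  effect <- ifelse(is_r, atanh(pmin(sel$value, 1 - 1e-12)), sel$value)
  se <- numeric(nrow(sel))
  se[is_r] <- se_fisher_z(sel$n1[is_r])
  if (any(!is_r)) se[!is_r] <- se_hedges_g(sel$value[!is_r], sel$n1[!is_r], sel$n2[!is_r])
  if (has_se) {
    override <- !is.na(sel$se) & sel$se > 0
    se[override] <- sel$se[override]
  }
  p <- p_value_z(effect, se)
  structure(data.frame(metric = sel$metric, effect = effect, se = se,
                       p = p, region = contour_region(p)),
            n_skipped = n_skipped, subgroup = subgroup,
            class = c("funnel_points", "data.frame"))
}

#' Funnel contour-region percentages
#'
#' Counts and percentages of records per significance-contour region — the
#' diagnostic table of a contour-enhanced funnel plot. An
#' overrepresentation of the orange (.05 <= p < .10) and red
#' (.01 <= p < .05) regions suggests inflation bias (publication bias or
#' p-hacking).
#'
#' @inheritParams funnel_points
#' @param metric restrict to `"r"` or `"g"` records, or `NULL` (default)
#'   for both.
#' @return a `funnel_summary`: data.frame with columns `region`, `count`,
#'   `percent` (percentages sum to 100 over classified records); attributes
#'   `subgroup`, `n_classified`, `n_skipped`.
#' @export
funnel_table <- function(corpus, subgroup = c("all", "biomedical", "psychosocial"),
                         metric = NULL) {
  subgroup <- match.arg(subgroup)
  pts <- funnel_points(corpus, subgroup)
  if (!is.null(metric)) pts <- pts[pts$metric %in% metric, , drop = FALSE]
  if (nrow(pts) == 0L) stop("no classified records")
  counts <- table(pts$region)
  structure(data.frame(region = names(counts),
                       count = as.integer(counts),
                       percent = 100 * as.integer(counts) / nrow(pts)),
            subgroup = subgroup, n_classified = nrow(pts),
            n_skipped = attr(pts, "n_skipped"),
            class = c("funnel_summary", "data.frame"))
}

#' @export
print.funnel_summary <- function(x, ...) {
  cat(sprintf("<funnel_summary> subgroup = %s, %d records classified (%d skipped)\n",
              attr(x, "subgroup"), attr(x, "n_classified"), attr(x, "n_skipped")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot data for a one-directional contour-enhanced funnel plot
#'
#' Returns the classified points plus the significance-contour boundary
#' lines `effect = z_q * se` for the two-sided p = .10, .05, .01 contours
#' (`z_q` = 1.644854, 1.959964, 2.575829). Effects are absolute
#' magnitudes, so contours are shaded on the positive side only and the
#' standard-error axis is conventionally drawn increasing downward.
#'
#' @inheritParams funnel_points
#' @return list with `points` (see [funnel_points()]) and `contours`
#'   (data.frame `se`, `effect_p10`, `effect_p05`, `effect_p01` over a
#'   standard-error grid from 0 to just above the largest observed se).
#' @export
funnel_plot_prep <- function(corpus, subgroup = c("all", "biomedical", "psychosocial")) {
  subgroup <- match.arg(subgroup)
  pts <- funnel_points(corpus, subgroup)
  se_grid <- seq(0, max(pts$se) * 1.05, length.out = 100)
  contours <- data.frame(se = se_grid,
                         effect_p10 = CONTOUR_Z[["p10"]] * se_grid,
                         effect_p05 = CONTOUR_Z[["p05"]] * se_grid,
                         effect_p01 = CONTOUR_Z[["p01"]] * se_grid)
  list(points = pts, contours = contours)
}

#' Draw a one-directional contour-enhanced funnel plot
#'
#' @inheritParams funnel_points
#' @param title optional plot title.
#' @return a ggplot object (standard error on the y axis, reversed).
#' @export
plot_funnel <- function(corpus, subgroup = c("all", "biomedical", "psychosocial"),
                        title = NULL) {
  subgroup <- match.arg(subgroup)
  prep <- funnel_plot_prep(corpus, subgroup)
  co <- prep$contours
  pts <- prep$points
  xmax <- max(pts$effect, co$effect_p01) * 1.02
  ggplot2::ggplot() +
    ggplot2::geom_ribbon(data = co,
      ggplot2::aes(y = .data$se, xmin = .data$effect_p10, xmax = .data$effect_p05),
      fill = "orange", alpha = 0.5, orientation = "y") +
    ggplot2::geom_ribbon(data = co,
      ggplot2::aes(y = .data$se, xmin = .data$effect_p05, xmax = .data$effect_p01),
      fill = "red", alpha = 0.5, orientation = "y") +
    ggplot2::geom_ribbon(data = co,
      ggplot2::aes(y = .data$se, xmin = .data$effect_p01, xmax = xmax),
      fill = "gray60", alpha = 0.5, orientation = "y") +
    ggplot2::geom_point(data = pts,
      ggplot2::aes(x = .data$effect, y = .data$se), size = 0.6, alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_cartesian(xlim = c(0, xmax)) +
    ggplot2::labs(x = "effect magnitude", y = "standard error", title = title) +
    ggplot2::theme_minimal()
}
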