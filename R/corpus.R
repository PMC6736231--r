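#' Effect-size corpora
#'
#' An `es_corpus` is a validated, ordered collection of extracted effect
#' sizes: one row per effect, with its metric (Pearson's `r`, Cohen's `d`,
#' or Hedges' `g`), magnitude, sample sizes, and an optional subfield
#' category. It is a plain `data.frame` subclass so all the usual verbs
#' (subsetting, `nrow()`, `split()`) work on it.
#'
#' Required columns:
#' \describe{
#'   \item{meta_id}{opaque identifier of the source meta-analysis}
#'   \item{study_id}{opaque identifier of the individual effect/study}
#'   \item{metric}{one of `"r"`, `"d"`, `"g"`}
#'   \item{value}{effect magnitude (may be negative before normalization)}
#'   \item{n1}{group-1 size, or total n for correlational designs}
#'   \item{n2}{group-2 size; `NA` for correlational designs}
#'   \item{category}{`"biomedical"`, `"psychosocial"`, or `"unclassified"`;
#'     missing values default to `"unclassified"`}
#' }
#'
#' Row invariants enforced at construction:
#' * `metric == "r"`: `|value| < 1`, `n1 >= 4`, `n2` absent;
#' * `metric %in% c("d", "g")`: `n1 >= 2` and `n2 >= 2`.
#'
#' An optional numeric `se` column (per-record standard error) is carried
#' through and, when present, takes precedence over the recomputed standard
#' errors in the funnel functions.
#'
#' @param records a data.frame with the columns above.
#' @param provenance free-text note on where the records came from.
#' @param on_invalid `"error"` to fail with row-indexed messages (default),
#'   or `"drop"` to discard offending rows with a warning.
#' @return an `es_corpus` object.
#' @seealso [read_corpus()], [normalize_corpus()], [generate_corpus()]
#' @export
es_corpus <- function(records, provenance = "", on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  required <- c("meta_id", "study_id", "metric", "value", "n1", "n2")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("corpus schema error: missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$category)) records$category <- "unclassified"
  records$category <- as.character(records$category)
  records$category[is.na(records$category) | records$category == ""] <- "unclassified"
  records$metric <- as.character(records$metric)
  records$meta_id <- as.character(records$meta_id)
  records$study_id <- as.character(records$study_id)
  for (col in c("value", "n1", "n2")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  problems <- validate_records(records)
  if (length(problems) > 0L) {
    if (on_invalid == "error") {
      stop("invalid corpus rows:\n", paste(problems, collapse = "\n"))
    }
    bad <- as.integer(sub("^row ([0-9]+):.*$", "\\1", problems))
    warning(length(unique(bad)), " invalid row(s) dropped")
    if (length(unique(bad)) > 0L) records <- records[-unique(bad), , drop = FALSE]
  }
  rownames(records) <- NULL
  structure(records,
            provenance = provenance,
            class = c("es_corpus", "data.frame"))
}

# one message per violated invariant, prefixed "row <i>:"
validate_records <- function(records) {
  msgs <- character(0)
  note <- function(i, txt) sprintf("row %d: %s", i, txt)
  for (i in seq_len(nrow(records))) {
    m <- records$metric[i]; v <- records$value[i]
    n1 <- records$n1[i]; n2 <- records$n2[i]
    if (is.na(m) || !m %in% c("r", "d", "g")) {
      msgs <- c(msgs, note(i, sprintf("metric must be one of r, d, g (got '%s')", m)))
      next
    }
    if (is.na(v) || !is.finite(v)) {
      msgs <- c(msgs, note(i, "value must be a finite number"))
      next
    }
    if (m == "r") {
      if (abs(v) >= 1) msgs <- c(msgs, note(i, "metric=r requires |value| < 1"))
      if (is.na(n1) || n1 < 4) msgs <- c(msgs, note(i, "metric=r requires n1 >= 4 (total n)"))
      if (!is.na(n2)) msgs <- c(msgs, note(i, "metric=r requires n2 absent (single-sample design)"))
    } else {
      if (is.na(n1) || n1 < 2) msgs <- c(msgs, note(i, sprintf("metric=%s requires n1 >= 2", m)))
      if (is.na(n2) || n2 < 2) msgs <- c(msgs, note(i, sprintf("metric=%s requires n2 >= 2", m)))
    }
    if (!is.na(n1) && n1 != round(n1)) msgs <- c(msgs, note(i, "n1 must be an integer count"))
    if (!is.na(n2) && n2 != round(n2)) msgs <- c(msgs, note(i, "n2 must be an integer count"))
    if (!records$category[i] %in% c("biomedical", "psychosocial", "unclassified")) {
      msgs <- c(msgs, note(i, "category must be biomedical, psychosocial, or unclassified"))
    }
  }
  msgs
}

#' @export
print.es_corpus <- function(x, ...) {
  counts <- table(factor(x$metric, levels = c("r", "d", "g")))
  cat(sprintf("<es_corpus> %d effect sizes (r: %d, d: %d, g: %d)\n",
              nrow(x), counts[["r"]], counts[["d"]], counts[["g"]]))
  if (nzchar(attr(x, "provenance") %||% "")) {
    cat("provenance:", attr(x, "provenance"), "\n")
  }
  if (isTRUE(attr(x, "normalized"))) cat("normalized: absolute values, d converted to g\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an effect-size corpus from CSV
#'
#' The file must be comma-delimited UTF-8 with a header naming at least
#' `meta_id, study_id, metric, value, n1, n2` (plus optional `category` and
#' `se`). Rows violating the record invariants are reported with their row
#' index (or dropped, see `on_invalid`).
#'
#' @param path path to a CSV file.
#' @param provenance free-text source note; defaults to the file path.
#' @inheritParams es_corpus
#' @return an [es_corpus].
#' @export
read_corpus <- function(path, provenance = path, on_invalid = c("error", "drop")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = c("NA", ""))
  es_corpus(raw, provenance = provenance, on_invalid = on_invalid)
}

#' Write an effect-size corpus to CSV
#'
#' Emits the same schema [read_corpus()] expects, so write/read round-trips
#' preserve all fields.
#'
#' @param corpus an [es_corpus].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "es_corpus"))
  utils::write.csv(as.data.frame(corpus), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert Cohen's d to Hedges' g
#'
#' Applies the small-sample bias correction
#' `g = d * (1 - 3 / (4 * (n1 + n2) - 9))`. The correction factor lies in
#' (0, 1) and tends to 1 as the total sample size grows, so `|g| <= |d|`
#' and the sign of `d` is preserved.
#'
#' @param d Cohen's d (any sign); vectorized.
#' @param n1,n2 group sizes, each at least 2.
#' @return Hedges' g, same length as `d`.
#' @examples
#' d_to_g(0.5, 32, 32)  # 0.493927
#' @export
d_to_g <- function(d, n1, n2) {
  if (any(is.na(n1) | is.na(n2))) stop("d to g conversion requires n1 and n2")
  if (any(n1 < 2 | n2 < 2)) stop("d to g conversion requires n1 >= 2 and n2 >= 2")
  N <- n1 + n2
  d * (1 - 3 / (4 * N - 9))
}

#' Normalize a corpus: absolute values, d converted to g
#'
#' Replaces every effect magnitude by its absolute value (the analysis
#' concerns the distribution of magnitudes, not directions) and converts
#' every Cohen's d record to Hedges' g via [d_to_g()]. Records already on
#' the g metric pass through the conversion untouched; correlations keep
#' their magnitude. The operation is idempotent and preserves record count
#' and order.
#'
#' @param corpus an [es_corpus].
#' @return the normalized [es_corpus], flagged with attribute
#'   `normalized = TRUE`.
#' @export
normalize_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "es_corpus"))
  out <- corpus
  out$value <- abs(out$value)
  is_d <- out$metric == "d"
  if (any(is_d)) {
    if (any(is.na(out$n1[is_d]) | is.na(out$n2[is_d]))) {
      stop("cannot convert d to g: record(s) lacking n1 or n2")
    }
    out$value[is_d] <- d_to_g(out$value[is_d], out$n1[is_d], out$n2[is_d])
    out$metric[is_d] <- "g"
  }
  attr(out, "normalized") <- TRUE
  out
}

# rows of `corpus` matching a metric and subgroup selection
select_records <- function(corpus, metric = NULL,
                           subgroup = c("all", "biomedical", "psychosocial")) {
  subgroup <- match.arg(subgroup)
  keep <- rep(TRUE, nrow(corpus))
  if (!is.null(metric)) keep <- keep & corpus$metric %in% metric
  if (subgroup != "all") keep <- keep & corpus$category == subgroup
  corpus[keep, , drop = FALSE]
}
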