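# Small corpora built in code, shared across test files.

tiny_records <- function() {
  data.frame(
    meta_id = c("MA1", "MA1", "MA2"),
    study_id = c("s1", "s2", "s3"),
    metric = c("r", "d", "g"),
    value = c(0.20, -0.40, 0.76),
    n1 = c(129, 32, 30),
    n2 = c(NA, 32, 19),
    category = c("unclassified", "biomedical", "psychosocial"),
    stringsAsFactors = FALSE)
}

tiny_corpus <- function() es_corpus(tiny_records(), provenance = "fixture")

write_tiny_csv <- function(records = tiny_records()) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(records, path, row.names = FALSE, na = "")
  path
}

# corpus of pure-g or pure-r records with given values and sizes
g_corpus <- function(values, n1, n2) {
  k <- length(values)
  es_corpus(data.frame(meta_id = "M", study_id = paste0("s", seq_len(k)),
                       metric = "g", value = values,
                       n1 = rep_len(n1, k), n2 = rep_len(n2, k)))
}

r_corpus <- function(values, n) {
  k <- length(values)
  es_corpus(data.frame(meta_id = "M", study_id = paste0("s", seq_len(k)),
                       metric = "r", value = values,
                       n1 = rep_len(n, k), n2 = NA))
}
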