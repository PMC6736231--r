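test_that("invalid generator configurations fail before any draw", {
  expect_error(synth_config(g_shape = -1), "g_shape")
  expect_error(synth_config(bias_strength = 1.5), "bias_strength")
  expect_error(synth_config(p_correlational = -0.1), "p_correlational")
  expect_error(synth_config(n_meta = 0), "n_meta")
})

test_that("the generator is deterministic given its seed and leaves the RNG alone", {
  cfg <- default_calibration(seed = 77, n_meta = 40L)
  a <- generate_corpus(cfg)
  set.seed(1234); before <- stats::runif(3)
  set.seed(1234)
  b <- generate_corpus(cfg)  # must not disturb the caller's stream
  after <- stats::runif(3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(before, after)
  expect_false(identical(as.data.frame(a),
                         as.data.frame(generate_corpus(default_calibration(seed = 78, n_meta = 40L)))))
})

test_that("generated records satisfy all corpus invariants", {
  corpus <- generate_corpus(default_calibration(seed = 5, n_meta = 150L))
  # es_corpus() already validated; double-check the load-bearing facts
  expect_true(all(corpus$value >= 0))
  is_r <- corpus$metric == "r"
  expect_true(all(corpus$value[is_r] < 1))
  expect_true(all(corpus$n1[is_r] >= 4) && all(is.na(corpus$n2[is_r])))
  expect_true(all(corpus$n1[!is_r] >= 2) && all(corpus$n2[!is_r] >= 2))
  expect_true(all(corpus$category[is_r] == "unclassified"))
  expect_true(all(corpus$category[!is_r] %in% c("biomedical", "psychosocial")))
  # shared true effect per meta-analysis: repeated meta ids exist
  expect_gt(max(table(corpus$meta_id)), 1)
})

test_that("sample-size medians sit at their calibrated values", {
  corpus <- generate_corpus(default_calibration(seed = 3, n_meta = 1250L))
  g <- corpus[corpus$metric == "g", ]
  r <- corpus[corpus$metric == "r", ]
  expect_gt(nrow(corpus), 8000)
  expect_lt(abs(stats::median(g$n1) - 30), 3)
  expect_lt(abs(stats::median(g$n2) - 19), 3)
  expect_lt(abs(stats::median(r$n1) - 129), 5)
})

test_that("default calibration's theoretical quartiles match the field targets", {
  cfg <- default_calibration()
  qg <- theoretical_quantiles(cfg, "g")
  qr <- theoretical_quantiles(cfg, "r")
  expect_true(all(abs(qg - c(0.16, 0.38, 0.76)) <= 0.03))
  expect_true(all(abs(qr - c(0.12, 0.20, 0.32)) <= 0.03))
})

test_that("with negligible noise the observed quantiles reduce to the Gamma's", {
  # huge samples make the standard errors vanish, so the observed-effect
  # distribution collapses onto the true-effect distribution
  cfg <- synth_config(nr_log_mu = log(1e6), nr_log_sigma = 1e-4,
                      n1_log_mu = log(1e6), n1_log_sigma = 1e-4,
                      n2_log_mu = log(1e6), n2_log_sigma = 1e-4)
  qg <- theoretical_quantiles(cfg, "g")
  expect_equal(unname(qg),
               stats::qgamma(c(.25, .5, .75), cfg$g_shape, scale = cfg$g_scale),
               tolerance = 1e-3)
  qr <- theoretical_quantiles(cfg, "r")
  expect_equal(unname(qr),
               tanh(stats::qgamma(c(.25, .5, .75), cfg$r_shape, scale = cfg$r_scale)),
               tolerance = 1e-3)
})

test_that("the publication-bias knob inflates just-significant regions", {
  unbiased <- normalize_corpus(generate_corpus(default_calibration(seed = 5, n_meta = 600L)))
  biased <- normalize_corpus(generate_corpus(default_calibration(seed = 5, n_meta = 600L,
                                                                 bias_strength = 0.9)))
  share <- function(corpus) {
    ft <- funnel_table(corpus)
    sum(ft$percent[ft$region %in% c("orange", "red")])
  }
  expect_gt(share(biased), share(unbiased))
  # and nonsignificant (white) results become rarer
  white <- function(corpus) {
    ft <- funnel_table(corpus)
    ft$percent[ft$region == "white"]
  }
  expect_lt(white(biased), white(unbiased))
})

test_that("pipeline recovery: per-record designed power is exactly recomputable", {
  corpus <- normalize_corpus(generate_corpus(default_calibration(seed = 9, n_meta = 80L)))
  s <- corpus_power_summary(corpus, reference = c(r = 0.20, g = 0.38))
  expect_equal(nrow(s$records), nrow(corpus))
  i <- which(s$records$metric == "g")[1]
  expect_equal(s$records$power[i],
               power_two_sample_t(0.38, s$records$n1[i], s$records$n2[i])$power)
})
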