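Package: esbench
Title: Effect-Size Benchmarks, Power Analysis, and Funnel Diagnostics for
    Research Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking the distribution of published effect
    sizes in a research field and auditing its statistical power. Reads and
    validates corpora of extracted effect sizes (Pearson's r, Cohen's d,
    Hedges' g), normalizes them (absolute values, small-sample bias
    correction of d to g), derives percentile-based small/medium/large
    benchmarks, computes exact noncentral-t power for two-sample designs and
    Fisher-z approximate power for correlation tests, solves for required
    sample sizes, classifies effects into significance-contour regions of
    one-directional funnel plots, and generates seeded synthetic corpora
    with realistic right-skewed effect distributions and an optional
    publication-bias filter for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ggplot2,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
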