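---
title: "Benchmarking effect sizes and statistical power in a research field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking effect sizes and statistical power in a research field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esbench)
```

## The problem

Conventional effect-size guidelines (Cohen's small/medium/large of r = .10/.30/.50
and d = 0.20/0.50/0.80) were proposed for the behavioral sciences at large. Fields
whose published effects run smaller — gerontology is the motivating case for this
package — will systematically underpower studies planned against those guidelines:
a researcher expecting d = 0.50 recruits 64 participants per group for 80% power,
but if the field's true medium effect is g = 0.38 the study actually runs at 57%
power. esbench implements the meta-research workflow that replaces generic
guidelines with empirical ones:

1. assemble a corpus of effect sizes extracted from published meta-analyses
   (`read_corpus()`, `normalize_corpus()`);
2. define small/medium/large as the 25th/50th/75th percentiles of the observed
   distribution (`benchmark()`);
3. audit achieved power at the field's typical sample sizes and tabulate the
   sample sizes future studies need (`power_two_sample_t()`, `power_correlation()`,
   the `solve_n_*()` solvers, `report_*()`);
4. screen for inflation bias with contour-enhanced funnel classification
   (`funnel_table()`, `plot_funnel()`).

A seeded synthetic-corpus generator (`generate_corpus()`) emulates the statistical
structure such corpora exhibit, so the entire pipeline is testable without any
external download.

## Corpus model and normalization

A corpus row is one extracted effect: metric (`r`, `d`, or `g`), magnitude, sample
sizes (`n1`/`n2` for two-group designs; total n in `n1` for correlations), a
meta-analysis identifier, and a subfield category (`biomedical`, `psychosocial`,
or `unclassified`; the category is optional labeling, so missing values default to
`unclassified` rather than erroring). Validation enforces the design minima:
correlations need `|r| < 1` and n ≥ 4; group differences need both group sizes ≥ 2.

Normalization does two things, both reflecting that the object of study is the
*distribution of magnitudes*, not directions or raw biased estimates:

* every value is replaced by its absolute value;
* Cohen's d is converted to Hedges' g with the small-sample bias correction
  `g = d (1 − 3 / (4N − 9))`, N = n1 + n2. Records already on the g metric pass
  through untouched, even when sample sizes are present. The correction factor
  lies in (0, 1) and increases to 1 with N, so conversion never inflates a value.

Normalization is idempotent, making it safe to call defensively.

## Percentile benchmarks

Field-specific benchmarks are the quartiles of the normalized corpus: the 25th,
50th, and 75th percentiles are labeled small, medium, and large. The quantile
convention is pinned to linear interpolation of order statistics
(`h = (N−1)p + 1`; the default type-7 rule of `stats::quantile()`), because
percentile benchmarks are only comparable across analyses if the convention is
fixed. Practical guideline values are additionally rounded to the nearest 0.05
(`round_guideline()`; exact ties round up), e.g. quartiles of 0.16/0.38/0.76
become recommended thresholds of 0.15/0.40/0.75.

Shape summaries (`es_moments()`) report moment-based skewness and kurtosis;
kurtosis is returned both raw (`m4/m2²`) and as excess (`− 3`) because published
reports rarely state which convention they used, and the two are trivially
interconvertible but easily confused.

## Power computations

**Two-sample t-test (exact).** With df = n1 + n2 − 2 and noncentrality
δ = d·√(n1·n2/(n1+n2)), two-tailed power at level α is
1 − F(t*; df, δ) + F(−t*; df, δ), where t* is the central-t quantile at 1 − α/2
and F the noncentral-t CDF (evaluated by `stats::pt(ncp = )`, not a normal
approximation — at df = 47 and small effects the exact tail is what distinguishes
power .08 from .09). At d = 0 this degenerates to the size of the test: power
equals α exactly.

**Correlation test (Fisher-z approximation).** The critical correlation is mapped
from the central-t quantile (r_c = √(t*²/(t*² + df)), df = n − 2), and the
sampling distribution under the alternative is taken as normal on the atanh scale
with mean atanh(r) + r/(2(n−1)) (a bias-corrected Fisher z) and standard
deviation 1/√(n−3). This is the classical approximation used by standard power
software; it is accurate to two decimals for the n of interest here but is *not*
exact: at r = 0 it returns ≈ α within 0.01 rather than exactly, and it is
non-monotone in n right at the n = 4–6 boundary (the bias term is large while
√(n−3) ≈ 1). Monotonicity holds from n = 6 onward; the sample-size solver is
unaffected because it brackets from below.

**Sample-size solvers** find the continuous root of power(n) = target by
bisection over n ∈ [2, 10⁷] (`stats::uniroot`) and return the ceiling, adjusted
so integer minimality holds exactly: power(n) ≥ target > power(n − 1). The
ceiling convention guarantees the returned n meets the target; published tables
produced under a round-to-nearest convention can differ by 1 in entries whose
continuous root sits just above an integer (e.g. a root of 58.3 prints as 58
under rounding, 59 under ceiling). The bracket's upper bound exists to fail
loudly on effectively-zero effects instead of looping.

`corpus_power_summary()` applies these per record: given a reference effect per
metric (typically the medium benchmark), it computes the power each study's own
sample sizes achieve and reports the fraction reaching the conventional .80.

## Funnel classification

Each record maps into (effect, standard error) space: g records keep their
magnitude with SE = √((n1+n2)/(n1·n2) + g²/(2(n1+n2))); correlations move to the
Fisher-z scale (effect = atanh r, SE = 1/√(n−3)), standard meta-analytic practice.
When the input carries its own `se` column those values take precedence — the
recomputed SEs exist so the analysis is reproducible from sample sizes alone.

The two-sided normal-theory p-value p = 2(1 − Φ(effect/SE)) classifies each
record into the conventional contour regions: white (p ≥ .10), orange
(.05 ≤ p < .10), red (.01 ≤ p < .05), gray (p < .01). Boundary ties deterministically
go to the less significant region. Because effects are absolute magnitudes, the
funnel is one-directional: contours `effect = z·SE` (z = 1.645, 1.960, 2.576) are
shaded on the positive side only, with the SE axis increasing downward. An
overrepresentation of the orange and red bands — just-significant results — is
the signature of publication bias or p-hacking. Classification is
scale-equivariant: rescaling all (effect, SE) pairs by a common factor leaves
regions unchanged.

## The synthetic corpus generator

`generate_corpus()` emulates the structure such corpora exhibit, with every
default chosen once and fixed:

* **True effects** are Gamma-distributed — the minimal positive, right-skewed
  two-parameter family consistent with the strong positive skew of published
  effect distributions. Correlations live on the Fisher-z scale (r = tanh z) so
  the support stays in [0, 1). This is a stand-in generative model, not a claim
  about the real data-generating process.
* **Clustering**: each synthetic meta-analysis has a single shared true effect;
  its records differ only in sample sizes and sampling noise. Real meta-analyses
  are heterogeneous within themselves; the shared-effect design deliberately
  omits that, trading realism for exact per-record recomputability. Consequently
  the default of ~8 effects per meta-analysis (zero-truncated Poisson) keeps the
  clustering design effect moderate (~6.5); a corpus with many more effects per
  meta-analysis under a *fully shared* effect would be more clustered than any
  real corpus, since real within-meta heterogeneity breaks up that dependence.
* **Sample sizes** are lognormal, rounded to integers and clamped to validity
  minima, with medians 30 and 19 (two-group designs) and 129 (correlational
  designs) — the medians observed in the motivating field — and log-scale spreads
  of 0.6 and 0.7, a realistic order-of-magnitude range of study sizes.
* **Observed effects** are true effect + normal noise with the *same* SE
  formulas the funnel module uses (evaluated at the true effect), then absolute
  value. Using one set of SE formulas end to end makes pipeline self-consistency
  testable.
* **Publication bias** (`bias_strength` ∈ [0, 1]): each record with two-sided
  p ≥ .05 is discarded with that probability and redrawn (new sizes and noise,
  same true effect). At 0 the filter is off; near 1 the funnel's significant
  regions visibly inflate.
* **Scale**: 506 meta-analyses × ~8 effects ≈ 4,000 records, the order of the
  corpus the workflow targets; mixing proportions (27% correlational; 21% of
  two-group meta-analyses biomedical) follow the same source. Categories are
  attached to two-group meta-analyses only, mirroring a corpus in which only the
  group-difference studies were hand-categorized; a single Gamma governs g
  effects across categories, so between-category distribution differences are
  *not* emulated.

**Calibration.** The Gamma parameters were found once by numerical quantile
matching: `theoretical_quantiles()` computes the marginal distribution of the
*observed* absolute effect implied by a configuration — discretizing the Gamma
and the lognormal sample sizes at probability midpoints through their inverse
CDFs, averaging the noise CDF `Φ((x−T)/σ) − Φ((−x−T)/σ)`, and inverting by root
finding — and the two Gamma parameters per metric were chosen by least squares
so the observed quartiles match g = 0.16/0.38/0.76 and r = .12/.20/.32. The
fitted constants (g: shape 0.5151, scale 0.9518; Fisher-z: shape 2.5884, scale
0.08842) reproduce the targets within ±0.01 — a two-parameter family cannot hit
three quartiles exactly — and are frozen in `synth_config()`. The same
theoretical-quantile function serves as the reference in tests: sample quartiles
of a ~50,000-record corpus recover it to within ±0.02.

Determinism: a single integer seed drives one generator stream
(`withr::with_seed`), so identical configurations give identical corpora and the
caller's RNG state is untouched.

**What passing tests do and do not show.** The generator reproduces the
right-skew, the quartiles, the sample-size medians, and the designed power
distribution of a realistic corpus; it does not reproduce within-meta
heterogeneity, between-category differences, duplicate effects across
overlapping meta-analyses, or any p-hacking mechanism beyond the retention
filter. Pipeline results on synthetic data therefore validate the *computations*,
not substantive claims about any real literature.

## Numerical choices and degenerate inputs

* Quantiles: type-7 linear interpolation, fixed (see above).
* Noncentral-t CDF: `stats::pt(ncp = )`; solver tolerance 1e-8 on the continuous
  root, then exact integer adjustment.
* Guideline rounding: nearest 0.05, ties up (deterministic on exact .025 ties).
* Funnel boundary ties (p exactly .10/.05/.01): the less significant region.
* Density prep: Gaussian kernel, Silverman bandwidth (`bw.nrd0`) — visual only.
* Empty selections (no records of a metric/subgroup), zero variance, n below the
  design minima, and nonpositive bandwidths all raise errors rather than
  returning NA.
* Duplicate effects across overlapping meta-analyses are not deduplicated; no
  defensible automatic rule exists without study-level metadata.

## Problem sizes used in the test suite

Monte-Carlo cross-checks of the noncentral-t power run at 2×10⁵ replicates
(agreement within 3 binomial standard errors); generator recovery uses one
~50,000-record corpus; the remaining property checks run on corpora of a few
hundred to a few thousand records. The whole suite completes in well under a
minute on a single core.

## Limitations

* The correlation-test power is an approximation (two-decimal accuracy in the
  practically relevant range; boundary behavior noted above).
* Funnel SEs recomputed from n are large-sample formulas; corpora carrying
  exact per-study SEs should supply them via the `se` column.
* Benchmarks are descriptive percentiles of published (hence potentially
  inflated) effects; the funnel diagnostic flags, but cannot correct, such
  inflation. Trim-and-fill and related corrections are out of scope — they are
  unreliable under the heterogeneity these corpora certainly have.
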