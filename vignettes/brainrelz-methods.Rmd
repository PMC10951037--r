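---
title: "Region-relative cerebellar expression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-relative cerebellar expression: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the pipeline answers

Bulk developmental transcriptomes such as the BrainSpan atlas sample up
to sixteen grey-matter structures per donor across ages from the
embryonic period to adulthood. For a gene of interest (by default
*ATM*, whose loss causes the cerebellum-dominated degeneration of
ataxia–telangiectasia), the pipeline asks: **is the gene's cerebellar
expression disproportionately high relative to the rest of the brain,
when, and what co-varies with it?**

The unit of analysis is the *region-relative z-score*. For gene $g$ and
specimen $s$ with cerebellar RPKM $c_{gs}$ and non-cerebellar regional
values $x_{gs1},\dots,x_{gsk}$:

$$ z_{gs} = \frac{c_{gs} - \bar{x}_{gs}}{\mathrm{sd}(x_{gs})}, $$

with the sample standard deviation (divisor $k-1$). Everything
downstream — the two-phase age trajectory, the genome-wide centile
benchmark, the co-expression sets and the term-overrepresentation
analysis — operates on this matrix.

```{r, eval = FALSE}
library(brainrelz)
sim <- simulate_brainspan(sim_config(n_null_genes = 2000, seed = 1))
sel <- select_specimens(sim$dataset)
zm  <- relative_z(drop_never_expressed(sel$included)$kept)
two_phase_report(zm, "ATM")
```

## The common age scale

Prenatal ages ("12 pcw") and postnatal ages ("4 mos", "8 yrs") are
placed on one days-post-conception axis with birth at 280 days
(40 weeks), one month = 30.44 days and one year = 365.25 days. Any
monotone convention preserves the *ordering* of specimens; Pearson
correlations against age are only approximately invariant to the choice,
which is why the constants are exported (`age_constants`) rather than
buried. Ages enter analyses linearly; a log-age display is available in
the plot method.

## Inclusion rule and missingness

A specimen is analysable only when its cerebellum was sampled (whole
cerebellum `CB` in early fetal donors, cerebellar cortex `CBC`
otherwise) *and* at least four other regions anchor the comparison
distribution (`select_specimens()`, `min_other_regions = 4`). Absent
samples are absent columns, never zeros: a zero is a measurement, and
imputing zeros would corrupt both the mean and the SD in the z-score
denominator.

A z-score cell is *missing* (rather than 0 or ±Inf) when the cerebellar
value is absent, fewer than two other regions exist, or the
non-cerebellar SD is exactly zero. The degenerate-SD case arises in
practice for near-silent genes whose regional values are all identical
after the dialect's 3-decimal rounding; forcing such cells to a number
would bias every downstream correlation.

## Two-phase trajectory

The target's z-scores are correlated with age separately over an early
window (conception through the first postnatal year, `[0, 645.25)` days)
and a late window (birth onward, `[280, Inf)`), with two-sided p-values
from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df. Whether first-year
infants belong to the late phase as well is genuinely ambiguous in this
kind of two-panel design; the default includes them in both windows and
`default_phases(first_year_in_phase2 = FALSE)` starts the late phase at
one year. Both conventions are first-class because the late-phase
correlation is sensitive to the choice. Elevation uses a strict
inequality at $z > 1.96$ (the two-sided 5% normal critical value); a
specimen at exactly 1.96 is not elevated.

## Centile benchmark

Per specimen, the target's z is ranked against all other genes' z
(midrank over the pooled sample of background plus target):

$$ \mathrm{centile} = 100\cdot\frac{\#\{z_b < z_t\} + \tfrac12\#\{z_b = z_t\} + \tfrac12}{n_b + 1}. $$

This convention was chosen over the simpler
$100\cdot(\mathrm{below} + \tfrac12\,\mathrm{ties})/n_b$ because it is
the one under which a target drawn from the same null as the background
is *exactly* discrete-uniform, so the calibration test (KS against
uniform) has no convention-induced drift; it also gives the natural
boundary answers (99.5 when above all of 99 background genes, 50 when
tied with everything). The target is excluded from its own background by
default. Background quantiles use linear interpolation
(`quantile type 7`).

## Gene filters and co-expression sets

Before genome-wide correlation, two filters are applied *in order*,
and the filter report makes the order auditable:

1. **Lowest-quartile expression filter.** Genes whose mean RPKM across
   all samples is strictly below the 25th percentile (type-7 linear
   interpolation) of the per-gene means are dropped. The quartile is
   computed after removing never-expressed genes, following the order in
   which the steps are reported in practice.
2. **Missingness filter.** Genes with more than `max_missing_z = 5`
   missing z cells across the included specimens are dropped (with 30
   specimens this is the "at least 25 z-scores" form of the rule).

Correlations to the target profile are pairwise-complete Pearson —
with at most 5 missing cells per retained gene, pairwise and listwise
differ by at most a few specimens, and pairwise wastes none of the
data. Set membership is strict: positive means $r > 0.6$, negative
means $r < -0.6$; a gene at exactly 0.6 is in neither set.

## Overrepresentation analysis

Each annotation term is a 2×2 table over a finite universe, scored by
fold enrichment $(k/n)/(K/N)$ and the exact two-sided hypergeometric
probability (the Fisher convention: sum of all point probabilities not
exceeding the observed one, with a $1+10^{-7}$ tie tolerance), then
BH-FDR across terms. Design choices:

* **Universe = the filtered gene list**, not the whole genome. The
  tested background is the set of genes that *could* have entered a
  correlated set; using anything larger inflates enrichment.
* **Two-sided test, direction from fold** ($>1$ over, otherwise
  under), so under-representation is captured in the same sweep.
* **No ontology propagation**: a gene annotated to a child term is not
  auto-added to parents. Propagation depends on an ontology-graph
  snapshot that a GMT does not carry; the GMT is the contract.

## The synthetic-data generator

`simulate_brainspan()` emulates what the analysis needs from the real
atlas, with ground truth recorded for every planted feature:

* **Null genes.** $\log \mathrm{RPKM} = b_g + u_{gd} + \varepsilon_{gdr}$
  with per-gene baselines $b_g \sim N(0, 2^2)$ (giving the many
  near-zero genes characteristic of RPKM data), donor effects
  ($\sigma = 0.3$) and region-exchangeable noise ($\sigma = 0.5$),
  exponentiated and rounded to 3 decimals like the public downloads.
* **Study geometry.** 42 donors, log-uniform ages from 8 pcw to 40 yrs
  (mimicking dense prenatal coverage), 16 structures of which one is
  cerebellar, 28% per-sample dropout — chosen so that, in expectation,
  about 30 of 42 donors pass the inclusion rule, as in the atlas.
* **The target gene.** A per-specimen z value is planted directly:
  mean trajectory rising linearly to a peak of 4 at one postnatal year
  and declining linearly to 1 at 40 years, plus $N(0, 0.5^2)$ noise;
  the cerebellar RPKM is then set to
  $\bar{x} + z^\ast\,\mathrm{sd}(x)$ (clamped at 0) so the z stage
  recovers the plant exactly. An additive-on-log-scale effect was
  rejected: the cerebellar draw's own multiplicative noise contributes
  variance growing with the planted z itself, which caps the
  recoverable age–z correlation far below the levels the recovery
  studies plant (e.g. 0.9), regardless of the slope.
* **Modules.** Positive/negative module genes get z profiles
  $0.6\,(\pm r_{\mathrm{mod}}\tilde z + \sqrt{1-r_{\mathrm{mod}}^2}\,\epsilon)$
  against the standardized target profile — exactly correlation
  $\pm r_{\mathrm{mod}}$ in population, with the 0.6 scale keeping
  planted cerebellar values away from the zero clamp. Module baselines
  are kept well-expressed so the quartile filter cannot remove what
  the recovery test is supposed to find.
* **Never-expressed genes.** A configured fraction (default 3.63%) is
  all-zero; any other gene whose row rounds to all zeros gets one cell
  bumped to 0.001, so the planted set and the all-zero set coincide
  exactly and the exclusion stage can be checked against bookkeeping.

What the generator does **not** emulate: real gene–gene covariance
beyond the planted modules, region-specific expression programs,
batch/donor covariates, or length/GC biases of RPKM. Passing recovery
tests therefore demonstrates that the *pipeline machinery* recovers
known structure through realistic missingness, rounding and filtering —
not that the biological findings generalise.

`simulate_gmt()` plants one term whose overlap with a designated query
is fixed at the rounded expected count for a requested fold; the other
terms are uniform draws. At fold 3, a 50-gene term against a 200-gene
query in a 5,000-gene universe implies an overlap of only 6 and is not
reliably separable from the minimum of 99 null p-values; the recovery
study therefore plants a 200-gene term over the pipeline's own
retained-gene universe (~1,600 genes), where the fold-3 signal is
decisive. This is a power consideration, not a tuning of the fold.

## Problem sizes and numerical choices

The validation suite runs entirely on synthetic data: oracle
equivalences use 100–800-gene instances; the exact-test sweep
enumerates every 2×2 table with $N \le 60$; null calibration uses 200
specimens (centile uniformity) and 200 replicates (enrichment false
positives); recovery studies use 200 replicates at $n = 12$ specimens
(trajectory) and $n = 30$ (modules). These sizes give Monte-Carlo
standard errors comfortably inside the asserted tolerances while
keeping the suite fast. The full-scale reporting script uses the
default 50,000-gene, 42-donor conditions.

Ties in the exact test are compared with a $1+10^{-7}$ relative
tolerance (the standard guard against floating-point inequality between
mathematically equal hypergeometric point masses). The dataset writer
emits the shortest decimal representation that parses back to the same
double, so written datasets round-trip bit-exactly.

## Known limitations

* Coarse age labels (integer weeks/months/years) quantize the age
  axis; with ranges of hundreds to thousands of days the attenuation
  of correlations is negligible, but it exists.
* The quartile filter's threshold depends on the interpolation rule;
  type-7 is fixed here and reported in the filter report, so reruns are
  comparable.
* Pearson trajectory fits assume linearity within each phase window;
  no curve-shape selection is attempted.
* The enrichment stage tests one term at a time; correlated terms
  (shared genes) make BH conservative rather than invalid.
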