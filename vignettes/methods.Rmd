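---
title: "Methods: Delphi consultation, indicator screening and input-oriented DEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Delphi consultation, indicator screening and input-oriented DEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhrdea)
```

This vignette documents the statistical and optimization methodology
implemented by **nhrdea**: the Delphi consultation statistics, the
indicator-screening rules that prepare a DEA model, the envelopment
models themselves, the synthetic-data generators, and the numerical
choices behind each. It also states what the package deliberately does
*not* do.

## 1. Delphi consultation statistics

A consultation round is a matrix of integer ratings on a 1–5 Likert
scale: `n_experts` rows, `n_items` columns, no missing entries
(`rating_matrix()` validates this; `read_ratings_csv()` drops experts
who returned nothing and rejects partially answered forms, since a
partial form cannot enter the rank-based coordination statistic).

**Enthusiasm.** `response_rate()` is the percentage of distributed
questionnaires returned, half-up rounded to one decimal.

**Authority.** Each expert's authority coefficient is
`Cr = (Ca + Cs) / 2`. The judgment-basis coefficient `Ca` is a sum of
four source weights (`judgment_basis()`): practical experience
(0.5/0.4/0.3 for high/medium/low influence), theoretical analysis
(0.3/0.2/0.1), and fixed 0.1 each for literature and intuition. The
familiarity coefficient `Cs` maps five self-assessed familiarity
levels to 1.0, 0.8, 0.6, 0.4, 0.2. `authority_coefficient()` rounds
half-up to two decimals by default.

**Item statistics.** Per item: arithmetic mean, *sample* standard
deviation (`n − 1` denominator), coefficient of variation
`CV = sd / mean`, and full-score rate (proportion of experts awarding
the maximum of the scale). Using the sample SD is a deliberate choice;
with 15–20 experts the population-SD alternative shifts CVs by roughly
3%, which can matter near the screening threshold, so the convention
is fixed and documented rather than configurable.

**Coordination.** `kendalls_w()` computes Kendall's coefficient of
concordance from average ranks (ties shared), with the tie correction
on by default:

$$W = \frac{\sum_j R_j^2 - m^2 n (n+1)^2 / 4}
          {m^2 (n^3 - n)/12 - m \sum (t^3 - t)/12}$$

where `m` is the number of experts, `n` the number of items, and `t`
runs over tie-group sizes within each expert. Significance uses the
large-sample statistic `chi2 = m (n − 1) W` on `n − 1` degrees of
freedom; for the uncorrected statistic this identity is exact and is
asserted in the tests. Likert ratings of many items are heavily tied,
so the uncorrected W systematically understates agreement; the
correction is therefore the default, and the test suite cross-checks
the corrected statistic against `vegan::kendall.global` when that
package is available. A fully tied matrix (every expert constant)
leaves the denominator at zero and raises a classed error rather than
returning `NaN`.

**Screening.** `screen_delphi_items()` retains an item when mean ≥
`mean_min` (3.5 by default; the `"strict"` preset uses 4.0), CV <
`cv_max` (0.25) and full-score rate > `fsr_min` (0.70). Setting a
threshold to `NA` disables that criterion. The returned table carries
a `reason` column naming each violated criterion, so the audit trail
of a two-round consultation can be reconstructed from the artifacts.

## 2. Indicator screening for DEA

DEA discriminates poorly when the indicator count approaches the
number of decision-making units (DMUs). `dea_rule_of_thumb()` reports
three conventional checks — inputs + outputs ≤ n/2, inputs × outputs ≤
n, and n ≥ 2(inputs + outputs) — and its overall `feasible` verdict
requires the first two; the third is informational. With 12 DMUs this
admits at most 6 indicators, e.g. 3 inputs and 2 outputs.

`indicator_correlations()` computes all pairwise Pearson correlations
with two-sided t-tests (`stats::cor.test`), dropping zero-variance
columns. `select_indicators()` keeps indicators that participate in at
least one *cross-role* pair (input vs output) with `|r| > r_min` (0.7)
and `p` below the significance ladder (0.01, then 0.05), ranks
survivors by their maximum cross-role `|r|`, takes the top `k`
(default `floor(n/2)`), and finally trims — never emptying a role —
until the rules of thumb hold. Ties are broken by column order, making
the selection deterministic.

## 3. Input-oriented DEA

For DMU 0 with inputs `x0` and outputs `y0` among `n` units, the CCR
envelopment program is

$$\min\ \theta \quad \text{s.t.}\quad X\lambda + s^- = \theta x_0,\quad
Y\lambda - s^+ = y_0,\quad \lambda, s^-, s^+ \ge 0,$$

and the BCC program adds `sum(lambda) = 1`. Both are solved
input-oriented only. Instead of the non-Archimedean
epsilon-in-the-objective formulation, the default is the standard
two-phase procedure: minimize the radial score `theta`, then maximize
the slack sum with `theta` fixed at its optimum. This avoids choosing
an arbitrary epsilon whose magnitude interacts with the units of
measurement; a literal single-phase mode is still available through
the `epsilon` argument of `solve_envelopment()` and agrees with the
two-phase solution in the tests.

Derived quantities:

* **Scale efficiency** `SE = OE / TE` (CCR score over BCC score),
  half-up rounded to 3 decimals by `efficiency_decomposition()` unless
  `digits = NULL`.
* **Returns to scale** from the CCR intensity-weight sum: `crs` when a
  unit is efficient or `sum(lambda)` can equal 1 within its
  alternative-optima interval (obtained by minimizing and maximizing
  `sum(lambda)` at fixed `theta*`), `irs` below, `drs` above.
* **Classification**: `efficient` (OE = TE = SE = 1, zero slack),
  `weakly_efficient` (radially efficient, positive slack),
  `scale_inefficient` (TE = 1, SE < 1), `tech_inefficient` (TE < 1,
  SE = 1), `tech_and_scale_inefficient` (both below 1).
  `classify_efficiency()` also checks `OE ≈ TE × SE` and raises a
  classed error on inconsistent triples.
* **Projection targets**: `"standard"` puts inefficient units on the
  frontier at `theta x0 − s^-` / `y0 + s^+`; `"slack_only"` applies
  only the slack movement, `x0 − s^-`. Targets that fall nonpositive
  are flagged and warned about, not silently clipped.

### The solver

The package solves its LPs with an internal dense two-phase primal
simplex (Bland's smallest-index rule, artificial-variable phase 1 with
drive-out of degenerate artificials and removal of redundant rows).
DEA envelopment programs are structurally degenerate — efficient units
solve with many basic variables at zero, and panels whose units share
an input mix give rank-deficient bases — and general-purpose dense LP
routines that do not anticipate this can fail on exactly these
instances. Bland's rule guarantees termination without cycling at the
cost of speed, which is irrelevant at DEA problem sizes (tens of DMUs,
a handful of indicators: matrices of a few dozen columns).

Correctness is established in the test suite against two independent
oracles that share no code with the simplex: a closed-form ratio
solution for single-input single-output panels, and a
vertex-enumeration solver for the dual (multiplier) form on small
panels (up to 5 DMUs, 2 inputs, 2 outputs). Tolerances are 1e-9 for
the closed form and 1e-7 for vertex enumeration.

## 4. Synthetic data generators

All generators take an explicit `seed`, restore the caller's RNG state,
and are byte-reproducible.

* `generate_rating_matrix(n_experts, n_items, consensus_strength,
  full_score_bias, seed)` draws item ratings around equally spaced
  latent means on [1, 5] with noise SD `2 (1 − consensus)`, clipped and
  rounded to the integer scale. `consensus_strength = 1` yields
  identical experts and W = 1; the tests assert W increases with
  consensus in expectation. Because ratings are clipped at the scale
  ends, even low consensus retains some agreement — the generator
  spans realistic, not pathological, disagreement.
* `generate_dmu_panel(n_dmu, n_inputs, n_outputs, frontier_kind,
  inefficiency_factors, seed)` builds panels with *known* efficiency.
  Under `"crs"` every unit shares one input and one output mix
  (a single-ray technology), inefficient units use `1/c` times the
  frontier input level, and the CCR score of every unit is exactly its
  factor `c`. Under `"vrs"` input cost scales convexly with output
  scale (`t^1.7`) and inefficient units are placed at the scale of an
  efficient unit, so the BCC score recovers the planted factor
  exactly. The generator requires `max(factor) == 1` (someone must be
  on the frontier) and factors in (0, 1]. These panels are
  deliberately *narrow*: they plant exact truth for solver validation,
  and are not calibrated to resemble any observed institution mix.
* `generate_correlated_indicators(n_dmu, target_corr, seed)` draws a
  Gaussian copula with the requested correlation matrix (validated
  positive semi-definite) and maps it to positive indicator values via
  `100 exp(0.25 Z)`.

## 5. Reporting conventions

Reported coefficients use half-up rounding (`round_half_up()`), not
banker's rounding, because published evaluation tables round half away
from zero; efficiency tables are reported at 3 decimals, rates and CVs
at 1–2. `render_report()` writes an efficiency table with an appended
`Average` row (returns-to-scale shown as an em dash for
constant-returns units), a per-indicator slack table for inefficient
units, and a text summary naming each inefficient unit's efficient
peers (units with positive CCR intensity weights). `run_pipeline()`
chains the stages on CSV inputs, records its full configuration as
JSON, and writes a manifest of MD5 hashes so identical configurations
produce byte-identical artifacts.

## 6. Scope and limitations

* Input orientation only; output-oriented and non-radial (SBM,
  additive) models are out of scope.
* Pearson screening assumes roughly linear indicator relationships;
  rank-based alternatives are not implemented.
* The chi-squared test for W is a large-sample approximation; exact
  small-sample tables for fewer than about 7 items are not included.
* The simplex is dense and intended for DEA-scale problems, not
  general large LPs.
* The generators plant clean truth for validation; they do not model
  measurement error in real institutional statistics beyond optional
  input noise.
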