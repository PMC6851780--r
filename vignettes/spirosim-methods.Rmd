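---
title: "Measurement error from spirometric repeatability criteria: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement error from spirometric repeatability criteria: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spirosim)
```

## The problem

Clinical spirometry summarises a testing session by a single "maximum" FEV1.
To get there, the ATS/ERS protocol (i) requires the highest and
second-highest maneuver to agree within a repeatability criterion (RC,
0.15 L/sec since 2005), (ii) allows the test to stop as soon as that
criterion is met, and (iii) leaves unstated what to do with subjects who
never meet it. Each of these steps throws away information. For a clinician
deciding about one patient that is usually harmless; for research that
attaches regulatory meaning to group FEV1 decrements of a few percent it is
not, because the discarded variation is of the same order as the effects
being estimated.

`spirosim` quantifies that loss by Monte Carlo simulation: it generates
cohorts of tests under an explicit two-level variability model, pushes each
test through the conventional protocol and through an unconstrained
eight-maneuver alternative, and reports the difference between the two
reported-FEV1 distributions as measurement error.

## The model

One subject with predicted normal FEV1
$\mu = \exp(-8.240 + 1.9095\ln H - 0.0037A - 0.000033A^2)$, the default
being $H = 173$ cm, $A = 59$ y, $\mu = 3.55$ L/sec. For test $t$ and
maneuver $m$:

$$\mu_t \sim N(\mu, \sigma_t^2), \qquad X_{tm} \sim N(\mu_t, \sigma_m^2),$$

all draws independent. The two standard deviations come from coefficients
of variation: intertest $CV_t$ (default 3%, $\sigma_t = 0.11$ L/sec) and
intratest $CV_m$ (default 6%, $\sigma_m = 0.21$ L/sec, a population value
inferred from NHANES exclusion rates — see below). The default cohort is
20,902 tests of 8 maneuvers, a size chosen in the source analysis for 90%
power at a 5% type I error rate and treated here as a constant.

Parameters that matter, with defaults:

| parameter | default | units | why |
|---|---|---|---|
| height, age | 173 cm, 59 y | cm, y | reference-equation inputs, $\mu = 3.55$ |
| $CV_t$ | 0.03 | fraction | intertest variability; results are insensitive to it |
| $CV_m$ | 0.06 | fraction | intratest variability; results are highly sensitive to it |
| RC | 0.15 | L/sec | 2005 ATS/ERS repeatability criterion |
| maneuvers | 3 min, 8 max | count | ATS/ERS protocol bounds |
| tests | 20,902 | count | power-derived cohort size |

`derive_sigmas()` rounds $CV\cdot\mu$ to two decimals by default
(`rounded_2dp`), because the source carries 0.11 and 0.21 rather than
0.1065 and 0.2130; an `exact` mode exists for sensitivity checks and the
two never differ by more than 0.005 L/sec. The between-subject SD of the
reference population (0.51 L/sec) is stored on the subject profile for
context but plays no role in the single-subject simulation.

## The protocol engine

`apply_ats_protocol()` / `protocol_outcomes()` implement the sequential
rule literally: after the minimum three maneuvers the test qualifies if the
top two values agree within RC; each later maneuver is compared to the
running maximum, and on success the larger of the two is reported. A
brute-force oracle (`first_qualifying_maneuver_oracle()`, prefix-wise
sorting) restates the rule as "the first prefix whose top-two gap is within
RC"; that the two agree on every sequence is a small theorem about the
rule, and the test suite checks it on 10^5 random sequences rather than
assuming it.

Three stopping rules are exposed because the source analysis uses two
framings: `early_stop` (the full iterative protocol, used for the
rejection curves), `fixed_stop` at 3 (termination after the minimum
maneuvers, used for the headline error comparison — the configuration that
maximises the effect of early termination and, per the source, best
approximates research practice), and `no_stop`. Tests that never qualify
follow one of three policies: `discard` (the default reading of the
protocol), `report_highest`, or `flag_only`.

Ties at the criterion boundary qualify (the comparison is $\le$ RC, as
printed); no floating-point special-casing is applied.

## Measurement error: which average?

Per test, measurement error is the unconstrained eight-maneuver maximum
minus the protocol-reported value, and is non-negative by construction.
Aggregation is where a genuine design choice lives:

* **`distribution`** (default): mean of the unrestricted maxima over *all*
  tests minus the mean of protocol-reported values over *retained* tests —
  the average horizontal gap between the two reported CDFs. The
  unconstrained protocol discards nothing, so its distribution is not
  conditioned on repeatability; the conventional protocol's is.
* **`paired`**: mean of the per-test difference over retained tests only.
  This conditions *both* arms on retention and is systematically smaller
  (≈0.16 vs ≈0.19 L/sec in the default model), because a tightly clustered
  first triple predicts a lower eight-maneuver maximum too.

Only the `distribution` aggregation reproduces the published sensitivity
table (0.08/0.19/0.31/0.42 L/sec across $CV_m$ = 3/6/9/12% at RC = 0.15,
and 5.1% of baseline) and the published sensitivity ratios (halving $CV_m$
−55%, 1.5× +65%, 2× +125%); it is therefore the default, with `paired`
retained as an explicit alternative.

The percent error divides by the mean protocol-reported value by default
(the baseline a conventional analysis would use); predicted-$\mu$ and
unrestricted denominators are selectable.

One known irreconcilability: with either aggregation the simulated mean
error *decreases* slightly as RC widens at fixed $CV_m$ (looser criteria
retain less-selected tests), while the source's own table and figure text
have it increasing from ≈0.15–0.18 (RC = 0.10) to ≈0.20 (RC = 0.20). The
RC = 0.15 column — the one with published, internally consistent values —
is reproduced; the RC-direction discrepancy is surfaced here rather than
tuned away. (The published cell at RC = 0.20, $CV_m$ = 6% — "0.07 L/sec
4.7%" — contradicts its own percentage and is treated as a typo.)

## Rejection curves and the analytic check

`rejection_curve()` reports, for each maneuver count $m$, the fraction of
tests that have not yet produced a qualifying pair after $m$ maneuvers
under the sequential protocol. This is nonincreasing in $m$ by
construction. Note it is *not* identical to "top-two gap among the first
$m$ exceeds RC" for $m > 3$: a test can qualify at an earlier prefix and a
later high outlier can re-open the top-two gap. The protocol (and the
published curves) follow the sequential definition: ≈20/50/65% rejected at
three maneuvers for $CV_m$ = 3/6/9%, and ≈15% still unpaired after eight at
$CV_m$ = 6%. The two-maneuver closed form
$P(|X_1 - X_2| > RC) = 2(1 - \Phi(RC/\sigma_m\sqrt{2}))$ provides an
analytic anchor (61% at $CV_m$ = 6%), and a numeric-integration
order-statistic oracle checks the $m = 3$ point independently of the
simulator.

On the closed form's published row: no single rounding convention for
$\sigma_m$ reproduces every printed value. The 6% entry (61%) requires the
stated $\sigma_m = 0.21$; the 1%, 3% and 10% entries (0.3%, 32%, 77%)
require the exact $CV_m\cdot\mu$. The package follows the stated sigma
where one is printed and the exact product elsewhere; the 9% entry (closed
form 74% vs printed 76%) does not reconcile under either convention and is
flagged, not asserted.

## Inferring the population CVm from exclusion rates

Under a minimum-three protocol, the number of $(m{+}1)$-th maneuvers
performed equals the number of tests still failing the RC at maneuver $m$,
so a published maneuver-count table implies per-maneuver exclusion rates
($E_m/N_m$). The packaged NHANES 2009–2010 count table reproduces the
published 70/63/64/57/71% (maneuvers 3–7). Two quirks of the printed table
are preserved deliberately: counts *rise* from the first to the third
maneuver (unexplained in the source; a warning, not an error), and the
printed excluded count at maneuver 6 (1,164) differs from the seventh-
maneuver count (1,364) that the table's own arithmetic implies. The
fixture carries the printed values; `exclusion_rates()` warns on both
inconsistencies and prefers printed excluded counts when present (only
that choice reproduces the published 57%).

`infer_cvm()` grid-searches the $CV_m$ whose predicted exclusion fraction
best fits observed rates under mean absolute deviation (the source states
no loss function; MAD over maneuvers 3–7 is this package's choice). It
returns the full loss profile rather than a bare argmin: against the
published rates the minimum sits at 6.5% with a shallow basin over 6–7%,
consistent with the source's "about 6%". A `simulated` method replaces the
two-maneuver closed form with per-maneuver continuation fractions from the
full sequential protocol.

## Minimum detectable differences

Two deliberately different constructions are implemented, because the two
published figures require different formulas:

* `mdd_paired_difference()`: the gap two *single test values* must exceed,
  intertest variability only: $2 z_{0.90} \sqrt{2}\, \sigma_t = 0.40$
  L/sec (11%) at $\sigma_t = 0.11$ — the $\sqrt 2$ is the SD of a
  difference of two values.
* `mdd_percentile_separation()`: the gap between two *distribution means*
  at which the post 90th percentile meets the pre 10th percentile:
  $2 z_{0.90} \sigma = 0.61$ L/sec at
  $\sigma = \sqrt{0.11^2 + 0.21^2} = 0.2371$.

The inconsistency (with vs without $\sqrt 2$) is surfaced rather than
harmonised; only the first reproduces 0.4 and only the second reproduces
0.6. The source's discussion separately prints 0.57 L/sec (16%); no
combination of the stated sigmas and either formula yields exactly that
value, and it is documented here as unreconciled. Default coverage is 0.80
two-sided (10th/90th percentiles; two-tailed p < 0.10, equivalently
one-tailed p < 0.05 for an expected decline).

## Numerical and reproducibility choices

* One seeded base-R generator per cohort; draw order is fixed (all test
  means, then maneuvers test by test), so a seed pins the cohort bitwise.
  The source names no RNG; all cross-checks are statistical.
* Negative FEV1 draws are not truncated — at the default parameters their
  probability is ≈0 — and the simulator warns if $\sigma_m/\mu > 0.3$.
* $CV_m = 0$ cells are simulated with $\sigma_m$ exactly 0 (the source
  substitutes 0.01%); every test then qualifies at maneuver 3 with error
  identically zero, and the difference from 0.01% is below reporting
  precision.
* Cohort CSVs are written with 17 significant digits and round-trip
  bit-identically. Config files are JSON (no YAML parser is assumed);
  unknown keys are rejected by name and defaults fill every gap.
* Monte-Carlo acceptance comparisons run at the full n = 20,902 and are
  judged at the published rounding (±1–2 units in the last printed digit,
  ≈3 simulation SEs at this n).

## What the generator does and does not emulate

The synthetic cohorts realise exactly the stated world of the model:
independent normal tests and maneuvers for a single subject with fixed
$\sigma_m$. Real spirometry has learning and fatigue across maneuvers,
technician and device effects, diurnal/seasonal structure, and
subject-specific $CV_m$ heterogeneity — none of which are modelled, and
all of which would *increase* the variability the protocol discards. A
green test therefore establishes that the implementation reproduces the
stated model's consequences, not that 0.19 L/sec is the measurement error
of any particular study population.

## Known limitations

FEV1 only (no FVC/PEF); no maneuver quality grading; no acceptability
screening other than the repeatability criterion; the RC-direction
discrepancy and the 0.57 vs 0.6 L/sec discrepancy described above are
reported, not resolved.
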