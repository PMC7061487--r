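---
title: "Assessing the quality of mortality and cause-of-death data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the quality of mortality and cause-of-death data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codqc)
```

`codqc` assesses how fit for purpose a national (or sub-national)
tabulation of deaths by ICD-10 cause, sex and age group is. This
vignette explains the models and conventions behind each step, the
tunable parameters, the design decisions taken where more than one
reasonable choice existed, what the synthetic-data generator does and
does not emulate, and the known limitations.

## Input model

Deaths are keyed by (year, sex, age group, ICD-10 code). The age ladder
is `"<1"`, `"1-4"`, then 5-year bands to an open interval (default
`"85+"`, configurable: the under-5 split is a demographic necessity,
while the top band varies between national tabulations). `"unknown"`
age and sex are retained as explicit categories — they carry diagnostic
information and are never imputed. ICD-10 codes are stored uppercased
and dot-stripped (`I219`), a chapter letter plus two digits and an
optional third; classification operates on the 3-character category, so
4-digit codes inherit their category's class. Duplicate keys are summed
on input; malformed codes and negative counts are hard errors rather
than silent repairs, because a quality-assessment tool must not paper
over the defects it is meant to expose.

The code-classification metadata is deliberately data-driven: a packaged
CSV maps code patterns (single categories or inclusive ranges) to
usability, broad cause group, the two garbage typologies, a package
label and redistribution targets. Patterns must be non-overlapping after
expansion; an overlap is an error, not a precedence rule, because silent
first-match-wins ordering makes user-edited tables treacherous. The
packaged table seeds the canonical garbage entries (R00–R99 ill-defined
codes, cardiac arrest I46, heart failure I50, hypertension I10,
unspecified stroke I64, unspecified cancer C76/C80, the sepsis cluster
A40/A41/D65/R02, respiratory failure J96, volume depletion E86,
unspecified external causes X59 and Y10–Y34) plus a synthetic 192-cause
usable reference set spanning the three broad groups. Codes absent from
the metadata are classified insufficiently specified, ICD-error category
5, severity 3, with a warning — a documented guess, chosen so the
classification stays total without hiding gaps in the mapping.

## Demographic checks

**Rates.** m_x = D_x / P_x per sex and band. Unknown-age and
unknown-sex deaths are excluded from rate numerators (no redistribution
before consistency checks — the rates describe the reported data), but
they are included in the crude death rate, which measures how many
deaths were captured rather than how well they were described.

**Log-linearity.** Under the Gompertz–Makeham law m(x) = λ + α e^{βx},
ln m_x is nearly linear in age once the senescent term dominates. The
check regresses ln m_x on band midpoints for bands with lower bound at
or above 30 (configurable; the exponential regime is established by
then), using midpoint = lower bound + 2.5 for the open interval. At
least four positive bands are required; fewer is reported as
insufficient data rather than a fit. Bands whose rate drops below the
previous band's are flagged non-monotone — a classic signature of age
heaping, age exaggeration or differential completeness.

**Sex pattern.** Any band at ages 5+ with m_f > m_m is flagged, using a
strict comparison with a configurable tolerance defaulting to zero.
Under-5 bands are reported but not flagged, since near-parity in early
childhood is biologically common. A comparator-based expected sex
pattern is not implemented; the check is deliberately restricted to the
robust raw signal.

**Child mortality.** Band rates are converted to probabilities with
separation factors a0 = 0.3 and a1 = 1.4 — standard demographic values
for the skewed distribution of deaths within the first year and ages
1–4 — both configurable. 5q0 combines multiplicatively, and child
registration completeness is the ratio of observed to comparator 5q0,
capped at 1 with the raw ratio retained.

## Completeness

The primary estimator compares the observed CDR with an externally
estimated CDR trend, linearly interpolated in year (terminal value with
a warning outside the trend). The ratio is capped at 1: values above 1
are diagnostically meaningful (over-coverage, population denominator
errors), so they warn and are kept in the method notes rather than
being reported as >100% completeness.

The secondary, comparator-free estimator predicts the expected CDR from
the data themselves: log-linear in ln(observed 5q0), the proportion of
the population aged 65+, and child registration completeness. The
published coefficients of this model are not bundled; the model runs
only when coefficients are supplied (a `default_empirical_coefficients()`
set exists for worked examples and simulations and is labelled
illustrative). The functional form is this package's operationalization
of the stated covariates.

A third summary figure weights child and adult completeness by the
estimated true deaths in each block (observed deaths divided by block
completeness), which is the natural weighting when the two blocks are
under-registered to different degrees.

## Cause quality

Garbage codes carry two orthogonal classifications: the ICD-error
category (1 symptoms/ill-defined, 2 impossible as underlying cause, 3
intermediate, 4 immediate, 5 insufficiently specified), which speaks to
certification practice, and the severity level (1 very high to 4 low),
which speaks to policy impact. Packages group related garbage codes;
package importance is ranked by total deaths — the most defensible
single operationalization of "importance" — with within-package ties
broken by code order so output is deterministic.

Redistribution moves each garbage code's deaths onto its metadata
target groups proportionally to the observed usable-cause distribution
within the same (year, sex, age) stratum, falling back to the
whole-dataset distribution and then to an equal split. This is a
transparent, configurable approximation: the country-specific
redistribution algorithms used in burden-of-disease work are not
reproducible from their public descriptions, and a proportional scheme
with auditable targets is preferable to a black box. Totals are
conserved exactly; masses may be fractional.

The epidemiological-transition measure is G1/(G1+G2) over usable
deaths. The exact functional used by comparable tools is not published;
this choice is documented rather than asserted, and the comparator
envelope's own measure and the delta are reported alongside.

Leading causes aggregate to the metadata's category labels; garbage
entries in the top-20 are flagged red for severity 1–2 and orange for
3–4 (the severity scale's "most impact" versus "lesser consequence"
halves).

## The VSPI(Q)

Five component scores in [0,1]:

* **Completeness** — comparator method by default; configurable to the
  empirical or weighted variant.
* **Garbage** — S = clamp(1 − (2(f1+f2+f3) + f4)/2, 0, 1), where f_l is
  the fraction of all deaths at severity level l. The per-death penalty
  of levels 1–3 is exactly twice that of level 4; the form is
  normalized so a dataset entirely of level-1 garbage scores 0 and
  entirely of level-4 garbage scores 0.5.
* **Detail** — the fraction of the 192-entry reference cause list with
  at least one death.
* **Age/sex** — 1 minus the fraction of deaths with unknown age or sex
  (counted once when both are missing).
* **Plausibility** — 1 minus the fraction of deaths violating
  biological edit rules (maternal causes require female aged 10–54;
  prostate/cervical/ovarian cancers the matching sex; perinatal causes
  age <1). Unknown age or sex makes a rule unverifiable, and such
  deaths are not double-punished here — the age/sex component already
  prices that in.

Transformed scores multiply into the 0–100 composite. Transforms are a
configuration block of (x, f(x)) knots, validated monotone
non-decreasing with f(0)=0 and f(1)=1, defaulting to identity: the
simulation-derived transforms used in published applications of the
index are not reproducible from their description, so the contract is
enforced and the shape left to the user. Transformed scores are
multiplied directly, without further capping or flooring. The gap to
100 is attributed to components proportionally to 1 − f_i(S_i) — a
first-order decomposition that is exact for a single deficient
component and sums to 1 whenever the composite is below 100.

When population or comparators are absent, the completeness and detail
components cannot be computed; the composite is then computed over the
available components, flagged `partial`, and the missing components are
listed in the skip notes. An alternative would be reporting no
composite at all; the partial composite was chosen because the four
cause-side components remain meaningful for hospital-style datasets
with no population at risk.

## The synthetic generator

The generator exists so that every check can be exercised against known
truth. Population structure is a one-parameter exponential in age;
deaths follow the Gompertz–Makeham schedule (default λ = 2e-4,
α = 3e-5, β = 0.095, child m0 = 0.02, m1 = 0.0012, female rates = male
/ 1.4) — values typical of a middle-mortality population yielding a CDR
near 11 per 1,000 under the default structure. Causes are drawn from
age-specific broad-group mixtures (communicable-heavy in childhood,
injury-heavy at 15–39, non-communicable-heavy at 40+) over the 192
usable reference causes with Zipf-decaying within-group weights;
age-restricted causes (maternal, perinatal) receive a fixed weight
because a positional Zipf weight would under-represent causes that are
leading causes within their few eligible strata. Cause assignment
respects the biological edit rules, so defect-free data are fully
plausible.

Deterministic mode rounds expected counts (band totals are exactly
round(P_x m_x)) and integerizes cause allocations with a
carried-remainder scheme that conserves stratum totals exactly while
staying globally proportional — this is what lets acceptance checks be
exact. Poisson mode draws band counts and multinomial cause splits.

Defects are applied in a fixed, documented order: thinning (optionally
child-differential, since child deaths are the most under-registered),
garbage recoding by severity mix, age then sex blanking on disjoint
masses, and implausible recoding (male deaths to cervical cancer,
overflow from female deaths to prostate cancer). Recoding rather than
insertion keeps totals interpretable; the order matters (garbage
fractions are relative to the thinned total) and is part of the
contract. Comparators are derived from the realized undegraded data, so
recovery is exact rather than approximate-by-construction.

What the generator does **not** emulate: real ICD coding depth (it
emits 3-character codes only), seasonality, multi-year trends, cause
misclassification between usable causes, correlated defects (e.g.
garbage concentrated in specific hospitals), and any real country's
profile. Passing recovery tests therefore demonstrates the arithmetic
and statistical correctness of the pipeline, not robustness to every
failure mode of real CRVS data.

## Problem sizes and numerical choices

The test suite and the acceptance script use a 2-million population
(about 23,000 deaths) for exact deterministic checks, a 0.5-million
population for recovery checks, and about 50,000 Poisson deaths for the
Gompertz slope-recovery check — sizes at which sampling error is well
below the tolerances being asserted while the whole suite runs in
about a minute. Conservation assertions use 1e-9, the 5q0 identity
1e-12, and stochastic recovery three standard errors over 100
replicates. Ties in integer allocation are broken by position;
regression uses ordinary least squares via `lm`; interpolation via
`approx`.

## Limitations

Single underlying cause only (no multiple-cause analysis), ICD-10 only,
no verbal-autopsy cause lists, no timeliness dimension in the
composite, and comparator series must be supplied locally — their
accuracy bounds the accuracy of the completeness and envelope
comparisons. The bundled metadata is a seed, not an authority: serious
use requires a nationally reviewed mapping, and every classification
the package makes is exported so that review is possible.
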