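---
title: "Decomposing life expectancy and lifespan inequality gaps by avoidable causes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing life expectancy and lifespan inequality gaps by avoidable causes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidgap)
```

## The problem

Two populations with the same life expectancy (LE) can have very different
mortality regimes: one can concentrate deaths tightly around the modal age at
death while the other spreads them from infancy to very old age. The second
dimension — lifespan inequality (LI), here the standard deviation of the
life-table distribution of age at death — matters for policy because it
measures how unequal the mortality experience is *within* a population.
`avoidgap` quantifies how much each age group and each cause-of-death group
contributes to the gap in LE **and** in LI between a reference country and a
comparator, with causes classified by whether the deaths were avoidable
(treatable through healthcare, preventable through public health, both,
ischaemic heart disease, or non-avoidable).

## Pipeline and model

1. **Input.** Cause-of-death counts by (country, year, sex, age group,
   ICD-10 code) plus mid-year population counts, on the standard abridged
   ladder 0, 1–4, 5–9, …, 85+ (19 groups, the last open-ended). Counts can
   arrive in a canonical long CSV (`read_long()`) or in the WHO Mortality
   Database wide dialect (`read_who_wide()`, with a user-supplied column map
   because the meaning of `Deaths1…DeathsN` varies by age format).
2. **Pooling.** Years are pooled by summing deaths and summing annual
   mid-year populations (`pool_years()`); each calendar year contributes one
   person-year of exposure per person, the standard demographic
   approximation. Pooling two years damps year-to-year random fluctuation in
   small-count strata.
3. **Avoidability classification.** `classify_icd10()` applies an ordered,
   first-match-wins table of inclusive ICD-10 ranges; `collapse_causes()`
   folds the cause axis down to the five mutually exclusive groups. Deaths at
   ages at or above the cap (default 75, i.e. capped at 74 completed years)
   are non-avoidable regardless of cause. The cap is applied by age-group
   lower bound, so 70–74 can be avoidable and 75–79 cannot — the only
   consistent reading on a 5-year ladder.
4. **Life tables.** `build_lifetable()` converts all-cause rates m to death
   probabilities with the Greville-type relation
   \(q = n m / (1 + (n - a) m)\), chains survivorship from a radix of
   100 000, and closes the table with \(q = 1\), \(L = l/m\) in the open
   group (exponential tail). LE is \(T_0 / l_0\); LI is the SD of age at
   death with closed-group deaths as point masses at \(x + a\) and the open
   group at mean age \(x + 1/m\) with within-group variance \((1/m)^2\).
5. **Decomposition.** `horiuchi_decompose()` implements the
   continuous-change method: the difference in any scalar functional of a
   covariate vector is attributed to individual covariates by summing
   central partial differences at the midpoints of `n_steps` equal segments
   of the straight line between the two covariate vectors.
   `decompose_gap()` specializes it to LE and LI with the flattened
   age-by-cause rate matrix as covariates. Contributions plus a residual sum
   to the total gap *identically*; the residual is the (small) path
   integration error and shrinks as \(O(1/n\_steps^2)\).
6. **Recalibration (sensitivity).** Where death registration is incomplete,
   all-cause rates can be forced to match an external life table:
   `implied_population()` computes \(P[a] = D[a]/m^*[a]\), the population
   that would reproduce the external rate given the observed death count,
   and `recalibrate()` rescales every cause-specific rate by it. Row sums
   then equal the external rates exactly and the observed cause mix within
   each age group is untouched.

### Sign convention

Everywhere, gap = **reference minus comparator**. Mortality conditions that
give the reference a larger LE (or a larger LI) produce positive
contributions. This is enforced in `gap()`, in the orientation of the
decomposition path, and in the summary tables, so all outputs agree.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_steps` | 20 | path segments | conventional default of public continuous-change implementations; residual is reported so users can raise it |
| `age_cap` | 75 | years | deaths from age 75 up are never avoidable |
| `radix` | 100 000 | persons | cosmetic; LE and LI are radix-invariant (test-pinned) |
| `a0_rule` | `"coale-demeny"` | — | infant separation factor from the two-branch approximation keyed on m0, sex-specific; `"midpoint"` available for sensitivity |
| a for 1–4 | 1.5 | years | standard abridged convention |
| open-group a | 1/m | years | exponential tail |

The a (nax) conventions are the one place where reasonable texts differ;
results are mildly sensitive to them, which is why the rule is an explicit
argument rather than a constant.

### Numerical choices

- The decomposition path is linear on the **rate scale**, not the log scale:
  it is well-defined when a cell rate is zero (common for rare causes in
  young age groups), and covariates with zero difference contribute exactly
  zero by construction.
- The residual is reported, never redistributed; `residual_report()` warns
  when it exceeds 1e-4 of the gap.
- Death probabilities are clamped to [0, 1] with a warning if the Greville
  formula overshoots under extreme synthetic rates.
- Ties/degenerate inputs: a table with all closed-group rates zero closes
  through the open group; an all-zero open-group rate is an error ("cannot
  close") because the tail exposure 1/m is undefined.

## What the synthetic generator emulates — and what it does not

`hazard_spec()` + `make_country_pair()` generate two-country scenarios from
a Gompertz–Makeham hazard (defaults `makeham = 2e-4`,
`gompertz_level = 2e-5`, `gompertz_slope = 0.115`, `infant_excess = 0.006`),
chosen once to give a realistic middle-income schedule — LE at birth ≈ 69
years and lifespan SD ≈ 13 years for the base country, the broad range of
the populations this pipeline targets. Cause shares are configurable
functions of age; death counts are Poisson draws with one deterministic RNG
substream per (country, age, cause) cell, so adding a cause never perturbs
the other cells' draws and every run is reproducible from the master seed.

The generator deliberately does **not** emulate: garbage-coded or
ill-defined causes, under-registration, age heaping, migration, or cohort
effects. Passing tests on synthetic data therefore demonstrate that the
*arithmetic* of the pipeline is right (conservation, additivity, recovery of
injected differences, calibration identities), not that real-world cause
assignment is unbiased — the recalibration stage exists precisely because
registration completeness differs across countries.

## Design choices made where the design was open

- **Default avoidability table.** The full OECD/Eurostat list is long and
  versioned; the package ships a compact default covering the major cause
  families (injuries, drug/alcohol, maternal/perinatal, infections, lung and
  screening-amenable cancers, diabetes, hypertensive disease, IHD) plus a
  catch-all, labelled synthetic in its header, and takes any user-supplied
  rule CSV. Shipping a fabricated "complete" list would be worse than
  shipping an honest default.
- **Unknown-age deaths** in WHO wide files are dropped with a logged count.
  Redistribution models are out of scope and inventing one silently would
  bias age-specific rates.
- **Coarse age buckets** (wider than the ladder) are rejected, not split:
  disaggregation requires a model we refuse to invent. Sub-ladder buckets
  are summed upward, which is exact.
- **Zero-death age groups under recalibration** get zero rates plus a
  warning: the observed cause mix there is 0/0 and borrowing a neighbour's
  mix would be invention.
- **LI from birth.** The SD is unconditional (not conditional on surviving
  infancy); the infant group is part of the distribution of age at death.
- **External tables on coarser ladders are rejected**, not interpolated.

## Problem sizes used in the test-suite and validation runs

Module tests run on the 19-group ladder with 2–5 causes; the Monte-Carlo
check of the count simulator uses 500 replicates of a 38-cell fixture; the
fine-path decomposition oracle compares 20 against 2000 path steps; the
end-to-end scenarios use two countries, two pooled years and 500 000
person-years per age group. These sizes were chosen so each suite exercises
the asymptotics it tests (the Poisson standard errors, the
\(O(1/n^2)\) residual) while remaining quick to re-run.

## Known limitations

- LI is the standard deviation only; e-dagger, Gini and IQR variants are not
  implemented.
- No uncertainty intervals: the decomposition is deterministic given the
  rates, and count-level sampling variation is not propagated.
- ICD-9/ICD-8 coding, subnational geographies and automated download of WHO,
  IHME or UN inputs are out of scope.
- The threshold-age behaviour of LI (mortality improvements below the
  threshold compress, above it expand, the distribution of ages at death) is
  verified on Gompertz schedules by finite differences; the threshold is not
  reported as an estimate.

## A worked synthetic example

```{r}
sc <- scenario_spec(
  hazard_spec(cause_mix = list(V40 = 0.2, C33 = 0.1, E11 = 0.1,
                               I21 = 0.1, J80 = 0.5)),
  perturbations = list(list(country = "CMP", cause = "V40",
                            age_from = 15, age_to = 49, factor = 0.6)),
  population = 5e5, years = 2015:2016, sex = "male", seed = 7)
pair <- make_country_pair(sc)
cm <- decompose_gap("LE", pair$exact_rates$REF, pair$exact_rates$CMP)
cm
residual_report(cm)
```

The comparator was given 40% lower preventable (`V40`) mortality at ages
15–49, so the whole LE gap is negative and sits in exactly those cells —
which is what the recovery tests assert cell by cell.
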