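---
title: "Modelling the cost-effectiveness of osteoporotic fracture risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of osteoporotic fracture risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteocea)
```

## The decision problem

Adults with intellectual disabilities (ID) fracture more often than the
general population, yet rarely have their fracture risk assessed. `osteocea`
models, from a UK NHS perspective, three ways of finding the people worth
treating:

* **S1 — current practice**: the QFracture risk score for the minority who
  meet age/risk criteria (about 3% of 40–49-year-olds), followed by a DXA
  scan for those scoring above the intervention threshold;
* **S2 — universal risk scoring**: an ID-specific risk score (IDFracture)
  for everyone, followed by DXA for screen-positives;
* **S3 — universal DXA**: a one-time DXA scan for everyone.

DXA classifies bone mineral density by T-score: osteoporosis (≤ −2.5 SD),
osteopenia (−1 to −2.5 SD) or normal. Osteoporosis is treated with a
bisphosphonate plus vitamin D and calcium; osteopenia with vitamin D and
calcium alone; normal BMD is not treated. The model is run separately for
two endpoints: major osteoporotic fracture (MOF — hip, vertebral, shoulder
or wrist) and hip fracture (HF) alone.

## Model structure

### Screening cascade (decision tree)

The cascade runs once, at model entry. A fraction *s* of the cohort is risk
scored; scored persons test positive with probability equal to the tool's
sensitivity if their true BMD category is low (osteoporosis or osteopenia)
and `1 − specificity` otherwise. Positives receive a DXA — assumed perfectly
accurate — and start the Markov model in the treated state matching their
category; normal-BMD positives return to the normal state untreated.
Negatives and the unscreened stay untreated. Under S3 the risk-score stage
is skipped and every screened person goes straight to DXA.

A fraction of the at-risk population (treated and untreated osteoporosis and
osteopenia, and normal BMD alike) is then moved to a lifetime **no
fracture** state representing people who will never sustain an osteoporotic
fracture. We deliberately drain *all* at-risk states proportionally: an
earlier variant that spared the treated states made osteopenia treatment
(relative risk 0.8) *riskier* than remaining untreated (where 30% are
immune), which inverts the economics of screening. The cost of this choice
is that the no-fracture share of treated persons stops accruing treatment
cost, slightly understating treatment spending in the universal strategies.

The cascade's money is `n_scored × cost_risk_score + n_DXA × cost_DXA`,
charged at cycle 0.

### Markov cohort model

Nine states: untreated/treated osteoporosis, untreated/treated osteopenia,
normal BMD, no fracture, fracture, post fracture, dead. Cycles are annual,
with no half-cycle correction; the cohort enters at 40 and is followed to
age 100 (60 cycles) or for 10 cycles under the ten-year horizon.

Transition rows resolve competing risks **death-first**: background
mortality `m(age)` applies to every alive state, and the annual fracture
probability applies to survivors, so an untreated row is
`(stay, fracture, dead) = ((1−m)(1−p), (1−m)p, m)`. This keeps every row
exactly stochastic without renormalisation. Treated rows multiply `p` by the
arm's relative risk and move a `(1 − adherence)` share of non-fracturing
survivors to the matching untreated state — discontinuation is permanent and
treatment cost stops on exit, while adherent persons are treated for life.
The fracture state is a strict one-cycle tunnel (matching the year-1
vs. later-years cost split), with mortality `m × fracture multiplier`;
survivors move to post fracture, where a single memoryless annual
re-fracture probability applies regardless of pre-fracture BMD or treatment
arm — the nine-state structure cannot remember either, which is a known
limitation. Death is absorbing. Any product exceeding 1 (extreme PSA draws
at old ages) is capped at 1 with a warning.

Ten-year fracture risks are converted to annual probabilities by
constant-hazard compounding, `p1 = 1 − (1 − p10)^(1/10)`, the standard
convention in decision modelling. The lifetime-risk sensitivity analysis
first scales the 10-year risk linearly to the model horizon
(`min(1, p10·H/10)`, H = 60 years) and then compounds it back to an annual
probability over H years; this enters through the config's `risk_scale`
switch.

Costs and QALYs accrue on **start-of-cycle** occupancy, consistent with the
absence of a half-cycle correction: treatment costs in treated states, the
year-1 fracture cost in the tunnel, a constant annual cost thereafter in
post fracture; utilities are the age-specific fracture-free baseline
(shared by treated, untreated and normal states), multiplied down in the
fracture year and post-fracture years, zero when dead. Both streams are
discounted at `(1 + r)^(−k)` with cycle 0 undiscounted and r = 3.5%/year.

### Economics

For each pair, `ΔC` and `ΔE` are differences in per-person discounted mean
cost and QALYs; `ICER = ΔC/ΔE`, always reported with its dominance quadrant
because a lone negative ICER is ambiguous. Incremental net monetary benefit
is `NMB(λ) = λ·ΔE − ΔC`, evaluated at £15 000, £20 000 and £30 000 per
QALY; `NMB(λ) = 0` exactly at `λ = ICER` when `ΔE > 0`. Exact zeros in
dominance classification fall in the trade-off quadrants (`ΔE ≥ 0` → NE).
S2 and S3 are each compared with S1, plus S3 with S2.

## Uncertainty analyses

**Deterministic**: one parameter changes at a time. The built-in grid covers
adherence at 80% of base and at 100%; each risk tool's sensitivity and
specificity at 80% of base and at the maximum (100%, except 99.9% for the
IDFracture sensitivity); every unit cost halved and doubled; the S1 screened
fraction at 1% and 5%; the ten-year horizon; and the lifetime risk scale.

**Probabilistic**: every probability and utility is replaced by a
moment-matched beta draw and every cost by a moment-matched gamma draw
(`shape = 1/cv²`, `scale = mean·cv²`), sampled independently — no
correlation structure is imposed. Prevalences are renormalised onto the
simplex after sampling. Structural settings (discounting, horizon, cohort
size) and the mortality multipliers (> 1, neither probabilities nor costs)
are never sampled, and parameters sitting exactly on a boundary (e.g. DXA
sensitivity 1.0) stay fixed because a beta cannot be moment-matched there.
The default is 1000 draws; the decision tree is re-run each draw so
screening uncertainty propagates. `CEAC(λ)` is the fraction of draws with
*strictly* positive NMB — ties at exactly zero count as not cost-effective,
which pins down the curve's value at `λ = ICER`.

The coefficients of variation default to 0.2 for every parameter group
(matching the 20% perturbation span of the deterministic analysis) and are
overridable per group in the bundle; the study's true parameter-level
standard errors are not publicly available, so these are stand-ins.

## Subgroups

Screened fractions for the current-practice arm follow the NICE-derived
bands: 1%–5% (base 3%) at 40–49 for either sex; 35%–50% (base: the midpoint
42.5%, the bands' centre in the absence of a stated base) for women 50–64
and men 50–74; 100% for women from 65 and men from 75. Subgroup cohorts
enter at the band's lower age and still run to 100. Sex enters through two
scalar multipliers on the fracture risks and the mortality table (defaults:
women ×1.15 fracture, ×0.90 mortality; men ×0.90 and ×1.20), since no
sex-specific tables are published for this population.

## The synthetic parameter generator

The study's full parameter tables live in a non-public supplement, so
`generate_parameter_set()` stands in for them. Structural settings are the
published design verbatim: cohort 1000, entry at 40, follow-up to 100,
annual cycles, 3.5% discounting, thresholds 15/20/30 k£/QALY, S1 screened
fraction 3%, S2/S3 universal. The remaining defaults are field-realistic
choices for a UK ID cohort, fixed once:

* prevalences 20% osteoporosis / 40% osteopenia / 40% normal (low BMD is
  markedly more common in ID populations than in the general population);
* 10-year fracture risks 25%/15%/6% (MOF) and 7%/3%/1% (HF) by BMD
  category; annual re-fracture 5% (MOF) / 2% (HF);
* treatment relative risks 0.55 (bisphosphonate) and 0.80 (vitamin
  D/calcium); annual adherence 80%;
* background mortality as a Gompertz-like log-linear hazard through anchors
  m(40) = 0.006 and m(100) = 0.40, reflecting the substantial excess
  mortality of adults with ID; fracture-year multipliers 1.5 (MOF) / 2.5
  (HF), post-fracture 1.1 / 1.5;
* unit costs (GBP, 2021/22): risk score £10, DXA £80, osteoporosis
  treatment £55/yr and osteopenia treatment £40/yr (generic alendronate
  plus supplements), fracture year £3 800 (MOF) / £14 000 (HF), later years
  £1 200 / £2 800;
* utilities declining linearly from 0.85 at 40 to 0.68 at 100, with
  fracture-year multipliers 0.77 (MOF) / 0.60 (HF) and post-fracture 0.92 /
  0.80; the no-fracture share is 30%.

The seed applies small multiplicative jitter so different seeds give
different but equally valid bundles; every invariant (prevalence closure,
risk ordering osteoporosis > osteopenia > normal, strictly increasing
mortality) holds for any seed, and the same seed always reproduces the same
bundle bit-for-bit.

With these defaults the model sits in the published qualitative regime —
universal screening is dominant (cheaper, more effective) for MOF and
costlier with a positive ICER for HF — but the generator emulates *shapes
and magnitudes*, not the study's actual numbers: passing tests demonstrate
the machinery (conservation, discounting, economics identities, sampling),
not agreement with any real cohort. Real data differ in ways the generator
does not emulate: correlated parameters, non-Gompertz mortality, age- and
sex-specific fracture risk tables, and DXA uptake below 100%.

## Numerical choices and degenerate inputs

* Occupancy conservation is asserted every cycle at 1e−6 relative; row
  sums of transition matrices are exact by construction.
* Probabilities pushed past 1 by multipliers are capped with a warning, not
  an error, because legitimate PSA draws reach the cap at ages 95+.
* `ICER` with `ΔE = 0` returns a labelled undefined result, not an error.
* Bundle JSON is written with 17 significant digits so round trips are
  bit-exact.
* Moment matching rejects means on the boundary of (0, 1) and variances
  exceeding `mean(1 − mean)`, naming the offending parameter.
* The microsimulation oracle replays the cohort model's own transition rows
  individual-by-individual; it validates the expectation machinery
  (law-of-large-numbers agreement within Monte-Carlo error), not the model's
  clinical content.

## Problem sizes used by the test-suite

The tests run the cohort engine on 200+ randomly generated bundles,
validate the cohort/microsimulation agreement at 20 000 individuals per
scenario on three fixture scenarios, check beta/gamma moment matching at
10⁵ draws, and exercise the PSA at 200 draws with CV 0.01 for the
degeneracy check; these sizes give Monte-Carlo standard errors small enough
for 3-SE acceptance bands while keeping the default suite under a minute
for the deterministic parts.

## Known limitations

* Post-fracture risk, cost and utility are memoryless — independent of
  pre-fracture BMD category and treatment arm.
* Bisphosphonate adverse events, societal costs and re-assessment of
  treatment after five years are out of scope, as in the source design.
* The no-fracture share of treated persons accrues no treatment cost (see
  above).
* Sex-specific epidemiology is two scalar multipliers, not full tables.
* Published mean costs/QALYs are not reproducible without the non-public
  parameter supplement; the arithmetic identities on the published
  incremental values are reproduced instead (see `scripts/acceptance.R`).
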