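# osteocea

Decision-analytic cost-effectiveness modelling of osteoporotic fracture
risk assessment strategies for adults with intellectual disabilities (ID),
from a UK NHS perspective.

Adults with ID fracture more often than the general population but are
rarely assessed for fracture risk. `osteocea` compares three assessment
strategies for a cohort entering at age 40:

* **S1** — current practice: QFracture risk score for the ~3% meeting
  age/risk criteria, DXA scan for screen-positives;
* **S2** — universal risk scoring with an ID-specific tool (IDFracture),
  DXA for screen-positives;
* **S3** — a one-time DXA scan for everyone.

DXA-confirmed osteoporosis (T-score ≤ −2.5) is treated with a
bisphosphonate plus vitamin D/calcium, osteopenia (−1 to −2.5) with vitamin
D/calcium alone. The model runs separately for major osteoporotic fracture
(MOF) and hip fracture (HF).

## Model and statistics

A screening-cascade decision tree feeds a nine-state annual-cycle Markov
cohort model (untreated/treated osteoporosis, untreated/treated osteopenia,
normal BMD, no fracture, fracture tunnel, post fracture, dead) followed from
age 40 to 100 with 3.5% annual discounting of costs and QALYs and no
half-cycle correction. Competing risks are resolved death-first,
`(stay, fracture, dead) = ((1−m)(1−p), (1−m)p, m)`; 10-year fracture risks
are annualised by constant-hazard compounding `p₁ = 1 − (1 − p₁₀)^(1/10)`.

Strategies are compared pairwise by the incremental cost-effectiveness
ratio `ICER = ΔC/ΔE` (with dominance quadrant) and incremental net monetary
benefit `NMB(λ) = λ·ΔE − ΔC` at λ = £15 000, £20 000 and £30 000 per QALY.
Uncertainty is handled by a one-way deterministic scenario grid and a
1000-draw probabilistic sensitivity analysis with moment-matched beta
(probabilities, utilities) and gamma (costs) distributions, summarised as a
cost-effectiveness plane and acceptability curves (CEAC). Age/sex subgroup
analyses use NICE-derived screened fractions. An individual-level
microsimulation oracle validates the cohort engine.

Because the source study's full parameter tables are not public, a
synthetic parameter generator (`generate_parameter_set()`) supplies
complete, invariant-checked bundles with the published structural settings
(cohort 1000, discount 3.5%, thresholds 15/20/30 k£/QALY, S1 screened
fraction 3%) and field-realistic epidemiology, costs and utilities — see
the vignette `vignettes/fracture-risk-cea.Rmd` for every default and why.

## Worked example

```r
library(osteocea)
bundle <- generate_parameter_set(seed = 1, scenario = "mof")
res <- run_cea(bundle)
res
#> <cea_result>
#>   S1: mean cost 2998.77, mean QALYs 14.7124
#>   S2: mean cost 2961.73, mean QALYs 14.7221
#>   S3: mean cost 2955.91, mean QALYs 14.7259
#>   intervention comparator mean_cost mean_qaly delta_cost delta_qaly  icer
#> 1           S2         S1      2962     14.72    -37.044   0.009691 -3822
#> 2           S3         S1      2956     14.73    -42.857   0.013557 -3161
#> 3           S3         S2      2956     14.73     -5.814   0.003865 -1504
#>   dominance nmb_15000 nmb_20000 nmb_30000
#> 1  dominant     182.4    230.87     327.8
#> 2  dominant     246.2    313.99     449.6
#> 3  dominant      63.8     83.12     121.8
```

Per person over the lifetime horizon, universal IDFracture screening (S2)
saves £37 and gains 0.0097 QALYs relative to current practice, and
universal DXA (S3) saves £43 and gains 0.0136 QALYs — both strictly
dominant here (cheaper *and* more effective), with positive net monetary
benefit at every threshold. The negative ICERs are reported together with
the quadrant label because a negative ratio alone does not distinguish
dominance from being dominated.

Downstream analyses:

```r
psa  <- run_psa(bundle, n_draws = 1000, seed = 1)   # CE plane points
ceac <- compute_ceac(psa)                            # acceptability curves
dsa  <- run_dsa(bundle)                              # one-way scenarios
sub  <- run_subgroups(bundle)                        # age/sex subgroups
plot_ce_plane(psa); plot_ceac(ceac)
```

`report_base_case()`, `report_psa()`, `report_dsa()` and
`report_subgroups()` write the corresponding CSV tables plus a seeded run
manifest; `inst/cli/osteocea.R` wraps them for shell use.

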