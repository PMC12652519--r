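---
title: "Model methods: beta-blocker adjunct therapy in TNBC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model methods: beta-blocker adjunct therapy in TNBC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the modelling choices behind `bbtnbc`: the state
structure and transition mathematics, the uncertainty-distribution
conventions, what the synthetic data generator emulates, and the
numerical and design decisions a reviewer or maintainer would want
spelled out.

## Decision problem and state structure

The model compares two strategies for Australian women aged 50–79
diagnosed with triple-negative breast cancer (TNBC): standard care alone
versus standard care plus lifelong β-blocker therapy (propranolol 40 mg
twice daily) started at diagnosis. TNBC lacks targeted therapies and
carries high early mortality; observational evidence associates
β-adrenergic blockade with improved TNBC-specific survival, and the drug
is a low-cost generic, which makes the cost-effectiveness question —
rather than a conventional efficacy question — the decision-relevant
one.

A three-state cohort Markov model with one-year cycles tracks each
5-year age band (50–54 … 75–79, entering at the band midpoint) from
diagnosis to age 85: *Alive with TNBC*, *TNBC death*, *non-TNBC death*;
both death states are absorbing. There are no recurrence or progression
tunnel states: the TNBC-specific annual death probability is constant
over time since diagnosis, which is the model's central structural
simplification (see Limitations).

## Transition probabilities

TNBC-specific mortality is supplied as an annual probability (base case
0.039, with stage-specific values 0.017/0.066/0.290); it derives from a
five-year cumulative risk α via `r = -log(1 - α)/5` and
`p = 1 - exp(-r)`, both exposed as package functions so the derivation
is testable. The treatment effect is a hazard ratio applied on the
hazard scale, `p' = 1 - (1 - p)^HR`, not as a probability multiplier;
at these magnitudes the difference is below 2% but the convention is
fixed for determinism.

Non-TNBC mortality is the age-specific all-cause probability `q(a)`
from the input schedule. Within a cycle the two risks are combined with
a symmetric half-overlap correction:

* P(TNBC death) = `p (1 - q/2)`
* P(other death) = `q (1 - p/2)`

This split is order-free, reduces to each marginal probability when the
competing risk vanishes, keeps the total at `p + q - pq ≤ 1`, and makes
the per-cycle survival factor factor exactly as `(1 - p)(1 - q)` — the
engine exploits this to compute the whole occupancy path as a cumulative
product, and an independent individual-level microsimulation in the test
suite confirms the cohort algebra to Monte-Carlo precision.

## Accrual, utilities and costs

Life years use the half-cycle correction `(N_start + N_end)/2`, so
members dying within a cycle contribute half a year. Consistently, all
flows are discounted with mid-cycle timing `(1 + r)^-(t + 0.5)` at
r = 5%/year (Australian guideline rate; scenarios explore 0% and 3.5%,
and a switch allows end-of-cycle timing). Whether the original analysis
discounted drug cost at start- or mid-cycle occupancy is not
documented; this package accrues drug cost over half-cycle-corrected
alive person-years, i.e. perfect adherence until death, which is
conservative in maximising intervention cost.

QALYs weight each alive person-year by `u_norm(age) + d_tnbc`, where
`u_norm` is the age-specific population utility norm and
`d_tnbc = -0.024` the TNBC health-state decrement; new TNBC deaths
additionally receive the terminal decrement `-0.11` in their death
cycle. evLYs value *incremental* survival at the population-average
utility 0.90 instead of the diseased-state utility:
`evLY_int = QALY_std + 0.90 × ΔYLL`, so `ΔevLY = 0.90 × ΔYLL` — a
deliberate equity convention that stops severity-adjusted utilities from
shrinking the value of life extension in serious disease.

Costs (2022 AUD) per cycle: drug cost (113.95/year, intervention arm
only) and breast-cancer management cost over alive person-years —
42,409 in the first year since diagnosis, then 8,745 / 3,487 / 3,595 /
2,839, and 0 beyond year five in the base case (2,838/year for life in
scenario 6) — plus 44,327 per TNBC death (terminal phase) and 5,844 per
non-TNBC death. Cycle `t ∈ [0,1)` maps to the "0–1 years" cost and so
on. Management costs are deliberately not stage-specific, so the stage
sub-group ICERs are driven solely by survival differences.

## Uncertainty distributions

Each uncertain parameter is published as mean plus 95% range; the range
is treated as a normal-approximation interval, `se = (high - low)/3.92`
(the printed-precision constant 3.92, not `2 × qnorm(0.975)`), and
hyper-parameters are fitted by matching moments:

* **beta** (probabilities, utilities): `a = m(m(1-m)/se² - 1)`,
  `b = (1-m)(m(1-m)/se² - 1)`; the fitted mean recovers the input
  exactly. Utility *decrements* carry a beta label with a negative
  mean; they are fitted on the magnitude and draws are negated.
* **gamma** (costs): `shape = (m/se)²`, `scale = se²/m`, with
  `se = 0.1 × m` for every cost row — a rule that reproduces each
  printed cost range.
* **lognormal** (hazard ratios): `meanlog = log(HR)`,
  `sdlog = (log(high) - log(low))/3.92`; the point estimate is the
  *median*, the natural convention for ratio estimates from
  proportional-hazards regression.
* The terminal-cycle decrement's range (−0.27, 0.05) crosses zero and
  admits no beta fit; it uses a normal with sd 0.32/3.92 truncated to
  [−1, 1].

Parameters are sampled independently (no correlation structure is
available). Each parameter draws from its own RNG sub-stream keyed by a
hash of its name and the run seed, so adding, dropping or reordering
parameters never perturbs the others' draws, and a given seed
reproduces a PSA bit-for-bit. Zero-width ranges become point masses that
consume no random numbers.

## Input schedules: what the generator emulates

Four age-indexed inputs cover ages 50–85: all-cause mortality `q(a)`,
utility norms `u_norm(a)`, incident breast-cancer counts `n_bc(a)` and
the triple-negative fraction `prev_tnbc(a)`. The authoritative path is
`load_schedule()` on a registry-derived CSV; results computed from the
synthetic stand-in reproduce the *conclusions* (dominance, orderings)
and land within a few percent on survival-side magnitudes, but are not
expected to match cost-side magnitudes exactly (see Limitations).

`synthesize_schedule()` builds, deterministically given a seed:

* **Mortality**: a Gompertz law `q(a) = 1 - exp(-A e^{Ba})` with slope
  `B = 0.1`/year (typical of adult female mortality) and level `A`
  solved numerically so period life expectancy at 50 is 35 years —
  death around age 85, the average Australian female life expectancy
  and the model's censoring age. Monotone non-decreasing by
  construction.
* **Utility norms**: linear decline of 0.002/year, with the level
  calibrated so the cohort-weighted average equals 0.90, the Australian
  female population average used in the evLY valuation.
* **Incidence × prevalence**: the relative age mix follows the
  published per-band cohort sizes, spread uniformly within bands with
  mild seeded lognormal jitter (sd 0.05) across single years of age; a
  constant triple-negative fraction of 0.15 reflects the subtype's
  share of breast cancers. The absolute level is rescaled so that the
  post-exclusion eligible cohort totals exactly 767.

Eligibility applies two exclusions multiplicatively — 14.8% of women
already on β-blockers for another indication and 20% assumed
contraindicated, `(1 - 0.148)(1 - 0.20) = 0.6816` — treating the groups
as independent, since their overlap is not documented.

The generator does **not** emulate: cohort effects or mortality
improvement over calendar time; age-varying TNBC prevalence;
breast-cancer mortality being embedded in all-cause mortality (a
potential double count with the TNBC-specific probability that the
source life tables may or may not net out); or non-linear utility-age
profiles. Tests passing on synthetic schedules therefore validate the
model mechanics and directional conclusions, not registry-level point
estimates.

## Analyses

* **Base case**: both arms over all six bands, aggregated; ICER per
  QALY and per evLY; per-patient values over the 767 treated women.
* **Sub-groups**: per age band; per disease stage (localized 60.5%,
  regional 35.6%, distant 3.9%) with stage-specific mortality and
  hazard ratios but unchanged costs.
* **Scenarios** (one override each): discount 0%; discount 3.5%;
  RR 0.74 (applied on the hazard scale like the base HR); carvedilol at
  258.18/year; propranolol 80 mg twice daily at 227.90/year (exactly
  double the base drug cost, a useful invariance check); lifetime
  management costs of 2,838/year beyond year five.
* **DSA**: one-way tornado over every base-case parameter's 95% bounds,
  ranked by ICER span. The treatment-effect hazard ratio and the
  terminal-phase cost dominate the ranking.
* **PSA**: 1000 joint draws re-evaluating the full model; nonparametric
  2.5/97.5 percentile intervals (the printed intervals are asymmetric,
  so percentiles rather than normal approximations); "cost-saving"
  means Δcost < 0 irrespective of ΔQALY.
* **EVPI**: nonparametric `mean(max NMB) - max(mean NMB)` per person
  (population increments divided by the 767 treated women), scaled by
  an *undiscounted* multiplier of 767 women/year × 10 years — the
  convention consistent with reporting "per woman commenced over the
  period"; discounted accrual is available as an option.
* **Trial sample size**: unpooled-variance normal approximation without
  continuity correction for 12% vs 18% five-year mortality, 80% power,
  two-sided α = 0.05 → 555/group, 1110 total. The simplest standard
  formula is used; adding a continuity correction raises the number and
  does not change the over-1100 conclusion.

## Numerical choices

* Cycle loop truncates when alive occupancy falls below 1e-12 of a
  woman; occupancy conservation is tested at 1e-9 relative.
* Fractional cohort counts are retained throughout (the model is a
  expectation over the cohort, not a person count); nothing rounds
  until presentation.
* Dominance uses strict sign tests with an equivalence guard at 1e-12;
  a dominant strategy's ICER is still computed and reported signed,
  with the flag carrying the interpretation.
* Infeasible beta moments (`se² ≥ m(1-m)`) and out-of-domain inputs
  fail fast with named errors rather than clamping.
* Problem sizes: 1000 PSA iterations for reported analyses (matching
  the published design), 2000 for the convergence property test, 1e5
  individuals for the microsimulation oracle.

## Limitations

Treatment effectiveness rests on observational data; adverse events and
discontinuation are not modelled (adherence is perfect, which maximises
intervention drug cost). The fixed annual TNBC death probability ignores
the front-loading of TNBC mortality in the first years after diagnosis
and any effect of treatment on recurrence. The synthetic schedule is a
calibrated stand-in: survival-side outputs land close to registry-based
values, but incremental cost is more favourable to the intervention than
registry-based analysis reports, so cost-side magnitudes from synthetic
runs should be read as indicative only, with conclusions carried by the
dominance and ordering results that are stable across seeds.
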