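---
title: "Model structure, calibration, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, calibration, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the cohort model and its assumptions, the survival-extrapolation
protocol, the economic accounting conventions, what the synthetic data
emulate (and do not), and the choices made where the design was
genuinely open.

## The decision problem

Patients with chronic-phase chronic myeloid leukemia (CML-CP) on
tyrosine kinase inhibitors (TKIs) can reach a deep molecular response
(DMR, BCR-ABL1 ≤ 0.01% IS) and, if it is sustained, attempt
treatment-free remission (TFR) — full quality of life with no drug cost.
But DMR is only *observable* with regular BCR-ABL1 qPCR monitoring.
The model therefore compares two strategies that differ in exactly one
respect: whether molecular monitoring is performed. Unmonitored patients
follow the same treatment-discontinuation (TTD) and progression (PFS)
curves, but can never be identified as DMR candidates and so never reach
the DMR or TFR states.

## States, clocks, and the transition cascade

The cohort engine (`run_cohort()`) tracks compartments
`(state, treatment line, state-time)`:

* **CML-CP** on imatinib, nilotinib, dasatinib, or best supportive care
  (BSC = imatinib + interferon-α). Per cycle a compartment faces, in
  fixed order: background death (age/sex life-table probability),
  progression to AP/BC (the line's PFS curve), DMR achievement (the
  line's time-to-MR4.5 curve; monitored arm and TKI lines only), and
  discontinuation (the line's TTD curve, routed by the line-sequencing
  matrix; BSC is terminal). Each event's per-cycle probability applies
  to the survivors of the preceding events — a *conditional cascade*.
  This guarantees every flow is a probability and occupancy is conserved
  exactly, at the cost of making the ordering an explicit assumption;
  the order (death → progression → DMR → discontinuation) puts the most
  severe event first. If the *raw* probabilities from one compartment
  sum beyond 1 the engine aborts and names the compartment — a
  pathological curve should be seen, not rescaled away.
* **DMR** is a one-cycle tunnel: after background death, a line-specific
  probability (57% imatinib / 77% nilotinib / 72% dasatinib) sends the
  patient to TFR, otherwise back to CML-CP on the same line. A single
  one-year maintenance probability supports exactly one resolution
  cycle; treatment-duration eligibility gates (≥5 years on TKI, ≥2 years
  in DMR) are *not* modelled because the input set contains no such
  parameters — a simplification relative to clinical guidelines.
* **TFR**: relapse-free survival curve on a time-since-entry clock;
  relapse restarts the same TKI line with a fresh line clock (immediate
  restart is the clinical course on molecular relapse). The same fresh
  clock is used when DMR is lost — the inputs give no basis for
  resuming a part-run clock, and restart-at-zero is the conservative
  reading for TTD (discontinuation risk is highest early).
* **AP/BC** is absorbing until death. Its mortality is the fitted
  overall-survival hazard *floored at* the background age-specific
  probability: a progressed patient cannot out-survive the general
  population.
* Every curve runs on its own semi-Markov clock: TTD/PFS/MR4.5 on time
  since the line started, TFR relapse on time since TFR entry, AP/BC OS
  on time since progression, background mortality on attained age.

## Survival extrapolation from digitized coordinates

Digitized Kaplan-Meier points are not individual-level data: there are
no event counts, no censoring times, and therefore no likelihood. The
fitting protocol (`fit_curve()`) is:

1. **Monotonicity repair** — pool-adjacent-violators (isotonic,
   non-increasing) absorbs digitization jitter; the repair magnitude is
   kept on the fit object.
2. **Nonlinear least squares on the survival scale** over nine families
   (exponential, gamma, generalized gamma, log-normal, log-logistic,
   Gompertz, Weibull, and Royston-Parmar spline models on the
   proportional-hazards and proportional-odds scales with two interior
   knots at the 33rd/67th percentiles of observed log time). Parameters
   are transformed to an unconstrained scale and optimized by
   Levenberg-Marquardt from five deterministic data-derived starts per
   family, so fits are exactly reproducible without seeds.
3. **Model selection** by the Gaussian pseudo-likelihood criterion
   `AIC = n·ln(RSS/n) + 2p`; ties break toward fewer parameters, then
   the canonical family order. A fit that fails to converge, has
   invalid parameters, or produces a non-monotone S(t) over the
   60-year guard horizon is excluded — the latter mainly disciplines
   spline extrapolation.

The pseudo-AIC is a pragmatic stand-in for a likelihood the data cannot
support; reconstructing pseudo-individual data from the coordinates
would be the principled extension and is deliberately out of scope.

In the recovery benchmark (50 points, noise SD 0.005 on the survival
scale) the protocol returns Weibull parameters within 5% of truth and
selects the generating family or one nesting it (generalized gamma, the
PH spline) in 19 of 20 seeded replicates. The benchmark digitizes the
curve over a 15-year span — most of the distribution's support (down to
S ≈ 0.07) — because a truncated curve carries too little tail
information to separate similar families; the result is unchanged for
any span from 12 to 18 years. For a Gompertz generator, note that *no*
other family in the set formally nests Gompertz; the spline-on-log-
cumulative-hazard is the only shape flexible enough to mimic it and
occasionally wins on AIC, which the tests treat as a correct
identification of the hazard shape.

## Economic accounting

* **Half-cycle correction** is the trapezoid: the value credited to the
  interval between cycles k and k+1 is the mean of the per-year rates at
  its two bounding cycle starts, for LYs, QALYs, and recurring costs.
* **Discounting** divides the interval value by `(1+r)^(k+1)`
  (end-of-cycle convention, applied after the correction); benefits and
  costs carry separate rates (both 3% in the base case; 0% and 5% in
  scenarios). The convention is stated here because the choice of
  cycle-start/mid/end discounting is otherwise invisible in results.
* **Costs** per compartment-year: drug list price × 12 monthly periods
  (list prices carry no period in the source inputs, so the periods-per-
  year multiplier is an explicit config knob, default monthly); BSC adds
  interferon drug and administration; AP/BC uses a 50/50
  imatinib/dasatinib mix plus 36 hospital days at ¥300 — additive on top
  of the AP/BC follow-up total, which is provably the bare
  resource-frequency dot product; follow-up is the 13-resource dot
  product per state; monitoring is tests/year × ¥250 with the TFR
  schedule dropping from 9 tests in year one to 2 thereafter (monitored
  arm only). TFR accrues no drug cost; DMR patients remain on therapy
  and keep accruing theirs.
* **Terminal care** is a one-off (fixture: ¥8,000, an assumption — the
  unit cost is not among the printed inputs) attached to incident deaths
  without half-cycle correction. By default every death triggers it; a
  config switch restricts it to AP/BC deaths, since the source tables do
  not settle the trigger.

## Scenario and sensitivity machinery

`scenario_library()` packages the twenty alternative-input runs
(demographics, discounting, first-line mix, line routing, DMR
achievement × 0.9/0.8/0.7 — multiplicative on the per-cycle achievement
probabilities, the natural reading of a "10% reduction in achieving
DMR" —, DMR maintenance × 0.9–1.1, utilities × 0.9, an intensified
TFR monitoring schedule, drug prices × 0.9/0.8/0.7). The intensified
schedule follows guideline text — monthly for the first six months of
TFR, 8-weekly for months 6–12, 12-weekly thereafter — annualized to
9.25 tests in TFR year one and 52/12 afterwards. The 50%
imatinib-to-nilotinib routing scenario is numerically the base case and
ships as an explicit identity. Scenario overrides are validated against
the full configuration invariants *before* any simulation runs, and the
base configuration is never mutated.

`run_owsa()` varies each scalar parameter by ±25%, clamps probabilities
and utilities to [0, 1] with a message, and returns tornado-ordered
bars; on the packaged calibration the CML-CP utilities produce the
widest QALY bars, the expected signature of a model whose life-years
are dominated by the chronic-phase state.

## The synthetic data: what it does and does not emulate

The generating study digitized its TTD/PFS/MR4.5/TFR/OS curves from
published figures and did not print the coordinates, so every
non-printed input is synthesized (`make_base_fixture()`), with the
printed inputs embedded verbatim:

| curve set | generating truth | rationale |
|---|---|---|
| TTD imatinib / nilotinib / dasatinib | Weibull(0.9, 9 / 11 / 10) | mildly decreasing discontinuation hazard, multi-year medians, second-generation TKIs retained slightly longer |
| PFS imatinib / nilotinib / dasatinib | exponential(0.030 / 0.022 / 0.025) | rare, roughly constant-rate progression on TKIs |
| PFS hydroxyurea+IFN (BSC stand-in) | exponential(0.10) | markedly worse progression off TKIs |
| time to MR4.5 | Weibull(1.1, 16) / (1.2, 7) / (1.2, 9) | cumulative DMR achievement ≈ 25–50% by 5 years, fastest on nilotinib |
| TFR relapse-free | log-logistic(0.7, 4) | front-loaded relapse consistent with the intensified year-one monitoring schedule and ≈50% long-run relapse-free |
| AP/BC overall survival | Weibull(1.2, 1.8) | median ≈ 1.5–2 years after progression |

Digitization noise is Gaussian (SD 0.005) on the survival scale,
clipped and isotonic-repaired, with every curve anchored at (0, 1); all
randomness flows through one explicit seed. The life table is
Gompertz–Makeham per sex with coefficients giving ≈2 per 1,000 annual
mortality at 41 rising to a few per 100 at 80, male above female.

What passing tests show: the *mechanism* — conservation, clock
handling, accounting identities, recovery of known generators, and the
qualitative dominance of monitoring whenever TFR is reachable. What
they cannot show: agreement with the original study's yuan-level
totals, which depend on the exact digitized curves; the synthetic
calibration is explicitly approximate, and no attempt is made to
reverse-engineer the originals.

## Numerical choices and problem sizes

* Occupancy conservation is enforced to 1e-9 and achieved at machine
  precision; engine-vs-oracle agreement is required to 1e-12 on
  5-cycle instances (exhaustive path enumeration) and to three
  Monte-Carlo standard errors against a 200,000-walker seeded
  microsimulation at cycles 1/5/10/25.
* The tests run the full 50-year horizon for the base case and all
  twenty scenarios, both arms; the closed-form life-expectancy check
  uses a 200-cycle horizon where the trapezoid error bound
  `(λΔ²/12)·(1/λ)` is verified explicitly.
* RSS is floored at 1e-300 before the log in the pseudo-AIC so perfect
  noiseless fits stay finite; depleted curves (S = 0) convert to
  probability 1 with a classed warning rather than NaN.
* Zero-denominator ICERs are reported as `NA` with an
  `icer_undefined` flag and the sign context preserved, never ±Inf, so
  tabular output stays parseable.

## Known limitations

Adverse-event costs and disutilities, TKI-resistance mutation dynamics
(e.g. T315I), adherence, probabilistic sensitivity analysis, and
willingness-to-pay thresholds are out of scope by design. The DMR
tunnel's single-cycle resolution and the fresh-clock restart rules are
modelling choices the inputs cannot adjudicate; both are isolated
behind the configuration and engine seams where alternative rules could
be swapped in.
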