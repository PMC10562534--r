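---
title: "Model structure, assumptions and numerical choices"
author: "periopCEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the engineering judgment behind
`periopCEA`: the cohort model and its assumptions, the parameters that
matter and their defaults, what the synthetic-data generator does and does
not emulate, and the choices we made where the underlying evidence base is
silent.

## The decision problem

Perioperative pembrolizumab — four 21-day cycles of neoadjuvant
pembrolizumab (200 mg flat) plus cisplatin-based chemotherapy, surgery
and/or radiotherapy, then up to thirteen cycles of adjuvant pembrolizumab —
improves event-free survival over neoadjuvant chemotherapy alone in
resectable early-stage non-small cell lung cancer, at a very large drug
cost. The package quantifies whether the survival and quality-of-life
gains justify that cost for a United States payer, over a 10-year horizon
with 3%/year discounting and a willingness-to-pay of $150,000 per QALY.

## Cohort engine

Five states — neoadjuvant treatment, post-surgery/radiotherapy residency,
adjuvant treatment, progressive disease (PD), death — advanced in 21-day
cycles (`21/30.4375` months; 174 cycles in 10 years). Key structural
assumptions, each surfaced as a configuration knob in `engine_config()`:

* **Survival-derived hazards.** For fitted curves `S_OS`, `S_EFS`, cycle
  `c` (1-based) uses conditional probabilities
  `1 − S((c)Δ)/S((c−1)Δ)`. Death is applied *uniformly* across alive
  states, which makes total cohort survival reproduce `S_OS` exactly (a
  property tested to 1e-6 with floors disabled). The evidence base does
  not report state-specific death hazards; uniform death is the unique
  choice that preserves the fitted OS curve.
* **Background-mortality floor.** The per-cycle death probability is
  floored by general-population mortality from a *synthetic* Gompertz life
  table (`background_mortality_table()`, `q(a) = B e^{Ca}` anchored to
  published US combined-sex period values q65 ≈ 1.3%, q75 ≈ 3.4%,
  q85 ≈ 9.3%). No official life table is shipped; the Gompertz stand-in
  deviates from any specific official table by design. Within 10 years the
  floor is almost never binding (trial-derived hazards exceed it); it
  matters in 15–20-year scenarios.
* **Cycle windows.** Surgery/radiotherapy is reachable only at the end of
  cycles 5–6, adjuvant entry (intervention arm only) at the end of cycles
  6–10. Within a window the per-cycle probability is the geometric split
  `1 − (1 − p)^{1/len}`, so the configured proportion `p` moves over a
  fully open window. Patients arriving late in the surgery window see a
  truncated adjuvant window — the realized adjuvant uptake is therefore
  slightly below the nominal product, an accepted artifact of window
  discretization (quantified in the unit tests).
* **Operative mortality.** The surgical fraction of local-therapy movers
  (`prop_surgery_among_local`, default 0.92) is charged a 30-day operative
  mortality of 0.023 as an additional one-cycle death flow.
* **Time-in-state without tunnel states.** Adjuvant residency (13
  administrations) and the first 6 post-progression chemotherapy cycles
  are tracked with exact age-in-state vectors maintained alongside the
  5-state trace; because death and progression hazards do not depend on
  time in state, this bookkeeping is exact, and a patient-level
  micro-simulation over the same matrices is used as a test oracle.
* **Accrual.** State residency (utilities, supportive care, follow-up)
  uses half-cycle (life-table) correction; administrations (drugs,
  infusion fees) are charged on start-of-cycle occupancy because they
  happen on day 1 of a cycle; one-off costs (local therapy, radiotherapy
  at progression, end-of-life, expected SAE burden in cycle 1) attach to
  per-cycle entrant counts. Discounting uses
  `(1 + r)^{−c·21/365.25}`.

## Parameters

All scalar inputs live in a typed table (`table1_fixture()`): name, base
value, deterministic range, PSA distribution class, units. Costs are USD
(inflation-adjusted upstream; the package performs no currency work),
utilities are annual weights in [0,1], the discount rate is per year.
Dosing uses a reference patient (65 years, 70 kg, 1.86 m² BSA); cisplatin
75 mg/m², pemetrexed 500 mg/m² (nonsquamous fraction, default 0.57) or
gemcitabine 1000 mg/m² days 1 and 8 (squamous), pembrolizumab 200 mg flat.

Three proportions that steer the pathway are not part of the printed cost
table and were transcribed from the source trial's publication: the
proportion receiving surgery/radiotherapy after neoadjuvant treatment
(0.821 intervention / 0.793 comparator), the adjuvant uptake among
local-therapy patients (0.889) and the surgical share of local therapy
(0.92). They carry ±25% ranges and beta PSA classes.

### Accrual periodicities (the main open design decision)

The published inputs give a best-supportive-care (BSC) cost of $3,674.65
and a follow-up cost of $545.92 without stating their accrual period. A
simple audit shows the period cannot be the 21-day model cycle for BSC:
the comparator arm spends roughly 30 discounted cycles in PD, so per-cycle
BSC alone (~$112k) would exceed that arm's entire published 10-year total
(~$110k). We therefore treat both periodicities as explicit knobs
(`bsc_days_per_charge`, `fu_days_per_charge`), calibrated **once** against
the published per-arm totals over a small grid of natural periods
(21-day cycle, month, quarter), together with the half-cycle switch and
the background floor, and then frozen: BSC accrues per quarter
(91.3125 days), follow-up per cycle, half-cycle correction and the floor
stay on. No other quantity was adjusted, and the calibration was not
revisited afterwards.

## Survival machinery

* Seven families with closed-form survival/density/quantile functions;
  the generalized gamma uses the Prentice (μ, σ, Q) form (Q→0 log-normal,
  Q=1 Weibull; Q<0 allowed). Agreement with an independent reference
  implementation is part of the test suite.
* Right-censored maximum likelihood on transformed (log) parameters,
  Nelder–Mead then BFGS from a fixed set of data-driven starts (5 for the
  generalized gamma, whose likelihood can be multimodal), tolerance 1e-10
  on the log-likelihood; deterministic for a given sample. Ranking is AIC,
  ties by BIC then parsimony.
* Pseudo-IPD reconstruction from digitized Kaplan–Meier coordinates and
  numbers at risk follows the Guyot algorithm: per risk-table interval,
  integer event/censor counts are iterated until the implied risk set
  matches the published one (a final reconciliation pass absorbs any
  residual into censoring, then latest events, so the risk table is
  honored exactly); censor times are placed uniformly; an optional total
  event count pins the final open interval.

A caveat worth stating: exact *family identification* through the
digitize → reconstruct → fit pipeline is not a stable target, because the
generalized gamma nests the Weibull and the gamma/Gompertz shadow it
closely. The tests therefore require the true family to stay near the top
of the AIC ranking and the *selected curve* to track the truth on the
observed window — which is what matters to the cohort engine — rather
than exact top-1 identification.

## Scenario machinery

Horizon, parameter and survival-family scenarios re-run the full pipeline
under overrides. For the common-OS-family scenarios the alternative fits
are not published; the package derives them by *projecting* the base-case
curve onto the target family over the trial's observed window (42 months):
maximizing the expected right-censored log-likelihood
∫₀ᵂ f₀ log f₁ dt + S₀(W) log S₁(W), i.e. the large-sample limit of
refitting the target family to data generated by the base-case model and
censored at W. This is deterministic and uses no sampling. The break-even
drug price is found by bisection to $1/QALY after a numeric monotonicity
check.

## Uncertainty analysis

One-way DSA re-runs the full model at each parameter's bounds (±25%
costs/proportions/BSA, ±10% utilities, 0–0.08 discount) and ranks by ICER
spread. PSA draws all parameters independently — gamma for costs (shape
100 by the 10%-of-mean SD rule), beta for proportions and utilities
(moment-matched), normal for anthropometrics, uniform for the discount
rate; survival-model parameters are deliberately *not* varied (they have
no published ranges) and move only in scenarios. Draws are seeded and
clamped to their supports.

## Synthetic data

`generate_ipd()` draws event times by inverse transform from any of the
seven families with administrative and/or exponential censoring;
`digitize()` emulates manual figure extraction (quantile-spaced sampling
points, denser where the curve drops; optional vertical jitter clipped to
keep monotonicity; numbers at risk at fixed calendar intervals). The
generator does **not** emulate pixel-level digitizer artifacts, correlated
reading errors, or patient covariates — so passing round-trip tests show
the algorithms are faithful to their inputs, not that published figures
are error-free.

## Problem sizes in the test suite

The suite exercises the full pipeline at sizes chosen to balance power
against runtime: cohort traces at the full 174–348 cycles; pseudo-IPD
round trips at n = 300–500 with 35–40 digitization points; parameter
recovery at n = 400 (fixed seed); fitting recovery at n = 500–5000;
micro-simulation equivalence at 10⁶ walkers; PSA at the full 1,000
repetitions; distribution-moment checks at 10⁵ draws.

## Known limitations

* The model inherits every limitation of extrapolating ~3 years of trial
  follow-up to 10–20 years; the long-horizon scenarios are the sensitivity
  handle, not extra evidence.
* PD is a single state: recurrence type (local vs distant), time-varying
  post-progression treatment mixes and treatment-related deaths beyond
  30-day operative mortality are not modeled.
* PSA treats parameters as independent; no correlation structure or EVPI.
* The life table is a two-parameter Gompertz stand-in, not an official
  table; results that hinge on old-age general-population mortality
  (beyond ~15-year horizons) should be re-run with a user-supplied table.
* Cost realism is limited to the listed CPT-anchored fees; vial sharing,
  wastage and price concessions are out of scope (drug costs use exact-mg
  pricing).
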