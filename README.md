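# periopCEA

A Markov cohort cost-effectiveness model for **perioperative pembrolizumab**
(neoadjuvant pembrolizumab + platinum chemotherapy for 4 cycles, surgery or
radiotherapy, then adjuvant pembrolizumab for up to 13 cycles) versus
**neoadjuvant chemotherapy alone** in resectable early-stage non-small cell
lung cancer, from the United States healthcare payer perspective.

The package is aimed at health-economics analysts who want the whole
analysis — survival-curve machinery, cohort engine, economics, sensitivity
analyses — as tested, reusable functions rather than a one-off script.

## The model

**Disease model.** A five-state Markov cohort with 21-day cycles:

```
NEOADJ -> POST_SURG_RT -> ADJUVANT
   \            \            |
    +--> PD <---+------------+      all states -> DEATH (absorbing)
```

The NEOADJ→POST_SURG_RT transition is open only in cycles 5–6 and
POST_SURG_RT→ADJUVANT only in cycles 6–10 (intervention arm), mirroring the
trial schedule. Transitions are time-varying and survival-derived: for a
fitted curve S, the per-cycle probability at time *t* is

&nbsp;&nbsp;&nbsp;&nbsp;p(t) = 1 − S(t + Δ) / S(t),&nbsp;&nbsp;Δ = 21/30.4375 months.

Death is applied uniformly across alive states at the overall-survival (OS)
conditional probability, floored by general-population mortality, so cohort
survival reproduces the fitted OS curve by construction; progression
receives the remainder of the event-free-survival (EFS) probability,
p_PD = max(0, p_EFS − p_death).

**Survival inputs.** Each arm's OS and EFS are parametric extrapolations
(log-normal OS and generalized-gamma EFS for the intervention; Weibull OS
and generalized-gamma EFS for the comparator, Prentice (μ, σ, Q)
parameterization). The package also ships the upstream machinery used to
obtain such fits from published figures: Kaplan–Meier pseudo-IPD
reconstruction from digitized coordinates and numbers at risk (the Guyot
algorithm), right-censored maximum-likelihood fitting of seven families
(exponential, Weibull, log-logistic, log-normal, generalized gamma, gamma,
Gompertz) and AIC/BIC model ranking.

**Economics.** Costs (USD) cover drugs (BSA-dosed chemotherapy, flat-dose
pembrolizumab), CPT-anchored infusion fees, surgery/radiotherapy events,
follow-up, post-progression radiotherapy + 6 cycles of chemotherapy + best
supportive care, end-of-life care and severe-adverse-event management.
QALYs weight state occupancy by published utilities (PF 0.75, post-surgery
0.73, post-radiotherapy 0.79, PD 0.65) minus one-off SAE disutilities.
Both streams are discounted at 3%/year and accrued with half-cycle
correction. Headline statistics: ΔCost, ΔQALY, ICER = ΔC/ΔE and net
monetary benefit NMB = λ·ΔE − ΔC at λ = $150,000/QALY.

**Uncertainty.** One-way DSA (±25% costs/proportions/BSA, ±10% utilities,
discount rate 0–8%) ranked as a tornado; probabilistic SA with 1,000
Monte-Carlo draws (gamma costs, beta proportions/utilities, normal BSA,
uniform discount; mean = base, SD = 10% of base) with cost-effectiveness
acceptability curves; scenario machinery for horizons, common OS families
and drug prices.

## Worked example

```r
library(periopCEA)
res <- run_cea()   # packaged base case: 10-year horizon, 174 cycles
print(res)
#> Cost-effectiveness: pembrolizumab vs placebo
#>                   cost  qaly
#> pembrolizumab 224595.0 4.343
#> placebo       105651.9 3.064
#>   Incremental cost  $118943.1
#>   Incremental QALY  1.279199
#>   ICER              $92982.51 per QALY
#>   NMB at $150,000/QALY: $72936.7
```

Read: over ten years a perioperative-pembrolizumab patient accrues about
$224.6k in discounted direct medical costs and 4.34 discounted QALYs versus
$105.7k and 3.06 for neoadjuvant chemotherapy alone; each QALY gained costs
about $93k, below the conventional $150k willingness-to-pay, with a
positive net monetary benefit of about $73k per patient.

Other entry points:

```r
tor <- one_way(table1_fixture())          # tornado (drug price dominates)
psa <- run_psa(table1_fixture(), n = 1000, seed = 1)
ceac(psa)                                 # acceptability curve
run_scenario("5y", list(horizon_years = 5))
price_threshold(wtp = 150000)             # break-even pembrolizumab $/mg
```

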