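Package: periopCEA
Title: Markov Cohort Cost-Effectiveness Model for Perioperative
    Immunotherapy in Early-Stage Non-Small Cell Lung Cancer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A five-state Markov cohort model with 21-day cycles for the
    cost-effectiveness of perioperative (neoadjuvant plus adjuvant)
    pembrolizumab versus neoadjuvant chemotherapy in resectable early-stage
    non-small cell lung cancer, from the United States healthcare payer
    perspective.  Transition probabilities are driven by parametric survival
    models (exponential, Weibull, log-logistic, log-normal, generalized
    gamma, gamma, Gompertz) fitted by right-censored maximum likelihood to
    pseudo individual-patient data reconstructed from digitized Kaplan-Meier
    coordinates (Guyot algorithm).  Includes deterministic (tornado) and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves, scenario machinery (time horizon, survival-family and drug-price
    scenarios), and a synthetic-data generator so the whole pipeline is
    testable with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
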