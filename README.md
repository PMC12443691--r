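# rrtccw

Clone–censor–weight emulation of target trials comparing **early versus
delayed initiation of renal replacement therapy (RRT)** in ICU patients
with acute kidney injury (AKI), from hourly longitudinal EHR-style data.

## The problem

When to start RRT in AKI is a live clinical question. Observational
answers are plagued by two biases. Confounding by indication: sicker
patients (higher SOFA, vasopressors, sepsis) start RRT earlier *and* die
more, so "treated" looks deadly. Immortal time bias: classifying subjects
by whether they *ever* started RRT credits starters with the person-time
they had to survive before starting, so "treated" looks protective. A
naive Cox model inherits some mixture of both.

`rrtccw` implements the target-trial-emulation remedy for analysts of
ICU cohort data:

1. **Eligibility & time zero** — hour-level screening (KDIGO creatinine
   staging, respiratory rate, ICU stay, CKD/code status, RRT-naive), time
   zero at the first qualifying hour; a broad trial (stage ≥ 1) and a
   severe trial (stage 3).
2. **Clone** — every eligible subject enters *both* strategies: initiate
   RRT within a 72 h grace period, or do not initiate; grace-period deaths
   belong to both clones.
3. **Censor** — a clone is artificially censored at the hour its subject's
   data deviate from the assigned strategy (hourly checkpoints).
4. **Weight** — pooled logistic models of the hourly initiation hazard
   give stabilized inverse-probability weights
   `sw(t) = prod_{s<=t} ratio(s)`, with `ratio = (1-p0)/(1-p)` for
   untreated hours and `p0/p` at the initiation hour (`p` conditional,
   `p0` marginal), removing the selection the censoring induces.
5. **Estimate** — weighted Cox HR with subject-clustered robust errors and
   Schoenfeld PH diagnostics; Weibull accelerated-failure-time sensitivity
   model (acceleration factor AF, with `HR = AF^(-k)` on Weibull data);
   doubly robust AIPW 30/90-day risks and risk differences,
   `psi_a = mean(m_a(X)) + sum(D_a sw (Y - m_a(X))) / sum(D_a sw)`;
   SMD balance and VIF diagnostics; baseline "Table 1".

A synthetic ICU cohort generator with confounded initiation and **known
counterfactual ground truth** (shared-randomness replay of the death
process under each strategy) validates the whole pipeline.

## Worked example

```r
library(rrtccw)

cfg    <- sim_config(3000, seed = 42, scenario = "protective")
cohort <- simulate_cohort(cfg)
cohort
#> Synthetic ICU cohort: 3000 subjects, hourly panel 0-168 h
#>   RRT initiated: 573 (19.1%)   deaths: 865 (28.8%)

emu <- ccw_emulate(cohort, horizons = 90)
summary(emu)
#> == trial1: KDIGO stage >= 1, 1519 eligible (312 initiated within 72 h) ==
#>   mean stabilized weight 1.001; max |SMD| after weighting 0.129; max VIF 2.99
#>   -- 90-day mortality --
#>    Cox HR 0.659 (0.506-0.860), p=0.00209; PH global p=0.199
#>    AFT AF 2.578 (1.616-4.111): 2.58 (95% CI: 1.62-4.11) times longer survival
#>    AIPW risk early 14.6% never 22.0%; rd -7.4 pp (-12.1 to -2.7)
#> == trial2: KDIGO stage >= 3, 399 eligible (37 initiated within 72 h) ==
#>   ...

simulate_counterfactual_truth(cfg)
#> Counterfactual ground truth (early = natural timing within grace)
#>   n eligible: 1519
#>   90-day risk: early 0.1587  never 0.2113  rd -0.0527
```

Reading the output: the generator planted a protective effect (log-HR
−0.35 once treated). The stabilized weights average ≈ 1 and the weighted
arms are near-balanced (312 initiators at this cohort size leave a little
Monte-Carlo imbalance; the severe trial, with 37 initiators, is noisier
still), and the single-cohort AIPW risk difference (−7.4 pp, CI −12.1 to
−2.7) brackets the true counterfactual value (−5.3 pp). `coef(emu)` returns the estimate
table, `plot(emu)` the weighted survival curves, and `write_results()`
the full bundle (JSON estimates, CSV balance/VIF/Table 1/curves).

Cohorts round-trip through CSV or Parquet (`write_cohort()` /
`read_cohort()`), so the same pipeline runs on real extracts shaped as a
baseline table plus an hourly panel.

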