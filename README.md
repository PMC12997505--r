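# becdose

Model-informed dose selection for long-acting anti-IL-5 biologics from
blood eosinophil count (BEC) pharmacology.

Anti-IL-5 antibodies treat severe eosinophilic asthma, chronic
rhinosinusitis with nasal polyps (CRSwNP), eosinophilic granulomatosis with
polyangiitis (EGPA) and hypereosinophilic syndrome (HES) by suppressing
blood eosinophils. When a same-class comparator has already established
which depth of BEC suppression translates into clinical efficacy, a new
molecule can move from a single-ascending-dose Phase I trial directly to
Phase III by *pharmacology matching*. `becdose` implements the full
quantitative workflow, with a synthetic-data generator (known ground truth)
replacing proprietary clinical data:

1. **Bayesian dose-time response model** for log BEC after a single dose
   (`fit_dose_time()`), with a time-drifting ED50:

   log BEC = b1 + E0 + E2·log(BASE) +
   (Emax + b2 − E0) / (1 + exp{SLP·(b3 + LNED50 + KE·(t − 182) − log F − log d)})

   (placebo: b1 + E1 + E3·log(BASE)), random effects (b1, b2, b3) ~ N(0, S²B),
   lognormal residual. Derived quantities: ED50(t) = exp(LNED50 + KE·(t−182)),
   T½ = ln2/KE, CV = √(exp(s²) − 1).

2. **Quantitative decision making** (`build_qdm_grid()`): for each dose ×
   time, the probability that the log BEC ratio vs placebo exceeds the
   Minimum Value (78% reduction, log 0.22) and Target Value (84%, log 0.16)
   reference pharmacology; go if P(>MV) > 80% and P(>TV) ≥ 10%, no-go if
   P(>TV) < 10%, otherwise consider.

3. **Phase IIb trial simulation** (`sample_designs()`, `run_trial()`,
   `summarize_trials()`): negative-binomial exacerbation counts with an
   Emax dose-response on the rate, analyzed by a class-effect NB GLM and a
   nonlinear NB Emax fit; ED90 = 9·ED50 with profile-likelihood intervals,
   power and precision summaries against the pharmacology benchmark.

4. **Population PK/PD turnover model** (`simulate_population()`,
   `fit_reduced()`): one-compartment first-order-absorption PK driving an
   indirect-response model,
   d eos/dt = KOUT·[KRO·(1 + (Imax − 1)·Cᵞ/(Cᵞ + IC50ᵞ)) − eos],
   with the published covariate structure, for cross-indication (CRSwNP /
   EGPA / HES) dose selection and Laplace-ML estimation of the
   drug-specific IC50 and variabilities.

BEC is carried in GI/L (10⁹ cells/L); 1.0 GI/L = 1000 cells/µL.

## Worked example

Generate a Phase-I-like panel from the published reference parameters, fit
the dose-time model, and build the decision grid:

```r
library(becdose)

truth <- depemokimab_dose_time_params()
panel <- generate_phase1(phase1_config(seed = 7), truth)
nrow(panel)                    # 624 BEC records from 48 subjects
fit <- fit_dose_time(panel, n_chains = 2, n_iter = 1500, seed = 3)
posterior_summary(fit, c("emax", "lned50", "ke"))
#>   parameter    mean      sd  median hpd_lower hpd_upper
#> 1      emax -2.4715 0.21518 -2.4875   -2.8427   -1.9377
#> 2    lned50  2.9469 0.20323  2.9679    2.5172    3.2736
#> 3        ke  0.0229 0.00302  0.0225    0.0177    0.0294
```

The generating values (Emax −2.60, LNED50 2.95, KE 0.0207) sit inside the
posterior intervals. Held-out Day-29 records are covered by 95%
posterior-predictive intervals (`predictive_coverage(fit)` ≈ 0.92 here),
and `derive_quantities(fit)` reports the fitted ED50 at Day 182
(median ≈ 19 mg) and effect half-life (≈ 31 days).

The decision grid from a surrogate posterior at the published summary
statistics reproduces the published boundary — at Day 182 every dose
≥ 60 mg is a go:

```r
draws <- synthetic_posterior_normal(n = 4000, seed = 2)
g <- build_qdm_grid(draws, doses = qdm_default_grid()$doses, days = 188)
#>  dose p_mv  p_tv  decision
#>    30 0.340 0.072 no_go
#>    40 0.587 0.215 consider
#>    60 0.820 0.472 go
#>   100 0.927 0.695 go
```

Cross-indication PK/PD simulation (1000 subjects per scenario):

```r
pd <- pd_params(); pk <- pk_params()
simulate_population(pd, pk, regimen(100), "CRSwNP", n = 1000, seed = 1)
#> GM baseline 0.439 GI/L; % reduction at day 364: 82.2%
```

i.e. 100 mg every 26 weeks holds a ~82% BEC reduction in CRSwNP at Week 52,
the level precedented for efficacy. `run_pipeline()` chains all stages and
writes per-stage CSV/JSON artifacts plus a hash manifest for bit-identical
re-runs.

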