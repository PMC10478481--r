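# metsim

Life-course microsimulation of educational inequalities in metabolic
syndrome (MetS).

## What problem this package addresses

Cross-sectional prevalence understates the burden of a relapsing-remitting
condition like MetS: far more people experience it at some point between
ages 18 and 65 than have it at any given moment, and the educational
gradient in that *life-course* burden cannot be read off a single survey
wave. `metsim` is for epidemiologists and health-inequality researchers
who have (or want to emulate) two-wave cohort data — MetS status at
baseline and at a follow-up a few years later, by sex, education, and a
set of modifiable factors — and want to project individual life courses
forward to quantify:

* **life-course prevalence** — the proportion ever experiencing MetS
  between 18 and 65,
* **mean age of onset** — among those who start healthy and convert,
* **mean duration** — years lived with MetS among those who ever have it,

by sex and educational level, together with **counterfactual** versions of
these in which the low-education group is given the high-education
distribution of modifiable factors (smoking, alcohol use, diet quality,
health literacy).

## The model

Individuals follow a two-state continuous-time Markov process between ages
18 and 65 with age-dependent incidence hazard λ(a) (healthy → MetS) and
recovery hazard μ(a) (MetS → healthy), per sex-by-education stratum;
mortality is not modelled. The pipeline:

1. estimate, per stratum, MetS prevalence at 18 and annual
   incidence/recovery rates per 5-year age group from the two-wave data
   (logistic models + marginal standardization, annualized via
   r = −log(1−p)/Δt);
2. parameterize the age-group rates as continuous curves — a 3-parameter
   logistic L/(1+e^(−k(a−a0))) for incidence, a fourth-degree polynomial
   for recovery;
3. simulate life courses exactly by thinning/uniformization
   (counter-based per-individual random streams);
4. summarize, and compare low vs high education;
5. counterfactuals by distribution-ratio reweighting
   w = Π P_high(category)/P_low(category), and 95% CIs by a
   perturb–refit–resimulate ensemble (2.5/97.5 percentiles).

A deterministic oracle (the model's Kolmogorov forward equations, solved
with `deSolve`) provides analytic values for every simulated summary and
anchors the test suite. A synthetic-cohort generator with analytic ground
truth (exact two-state interval probabilities per person) emulates the
structure of the access-restricted cohort data this class of analysis
uses, including NCEP-ATPIII component-level classification.

## Worked example

```r
library(metsim)

cfg    <- default_generator_config(n_participants = 30000, seed = 42)
cohort <- generate_cohort(cfg)

rates  <- rbind(estimate_rates(cohort, "incidence"),
                estimate_rates(cohort, "recovery"))
prev18 <- estimate_prevalence_at_18(cohort)
curves <- fit_all_curves(rates)

lcs <- simulate_cohort(curves, prev18, n_per_group = 20000, seed = 42)
obs <- summarize_by_stratum(lcs)
print(obs, digits = 3)
#>      sex  edu     n life_course_prevalence mean_age_onset mean_duration
#> 1 female high 20000                  0.705           42.7          10.7
#> 2 female  low 20000                  0.837           40.7          14.6
#> 3   male high 20000                  0.775           41.9          11.7
#> 4   male  low 20000                  0.928           38.9          17.3
```

Under the generator's default conditions, 83.7% of low-educated women ever
experience MetS versus 70.5% of high-educated women (a 13.2-point gap);
low-educated men convert on average 3 years earlier than high-educated men
and spend 5.6 more years with MetS. (These synthetic levels are higher
than published population estimates — see the methods vignette — but the
gradients behave like the real thing.)

A counterfactual giving low-educated individuals the high-education
smoking distribution, simulated with the same seed:

```r
cf <- run_counterfactual_pipeline(cohort, "smoking", n_per_group = 20000,
                                  seed = 42, observed_rates = rates,
                                  prev18 = prev18)$summary
report <- build_report(obs, list(counterfactual_smoking = cf))
str(report$counterfactual_smoking$reductions, digits.d = 3)
#> List of 2
#>  $ female:List of 3
#>   ..$ prevalence: num 14.6
#>   ..$ onset     : num 27.2
#>   ..$ duration  : num 11.6
#>  $ male  :List of 3
#>   ..$ prevalence: num 9.27
#>   ..$ onset     : num 20.3
#>   ..$ duration  : num 5.87
```

i.e. equalizing smoking alone closes 14.6% of the female prevalence gap
and 9.3% of the male one in this synthetic cohort. The full orchestration
(including ensemble CIs, the 6-month episode-merging sensitivity
transform, and JSON/CSV artifacts) is available as
`run_pipeline("all", metsim_config(...))`.

Externally published age-group transition-rate tables can be fed straight
into stages 2–5 through `read_rates()` (schema:
`sex, edu, kind, age_lo, age_hi, rate_per_year, se, n_at_risk`), bypassing
estimation entirely.

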