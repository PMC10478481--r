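---
title: "Modelling life-course inequalities in metabolic syndrome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling life-course inequalities in metabolic syndrome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`metsim` treats metabolic syndrome (MetS) over the adult life course as a
two-state continuous-time Markov process. Between ages 18 and 65 an
individual occupies either the *healthy* or the *MetS* state and moves
between them with two age-dependent hazards: an incidence rate
$\lambda(a)$ (healthy $\to$ MetS, per person-year) and a recovery rate
$\mu(a)$ (MetS $\to$ healthy). Mortality is deliberately absent: the
window ends at 65, below which survival in the target population is high,
and differential mortality by MetS status cannot be estimated from the
kind of two-wave data the model ingests. All analyses are stratified into
four groups: females/males with low (10 years) or high (16 years)
education.

The pipeline has five stages.

1. **Rate estimation.** From a two-wave cohort (status at baseline and at
   a follow-up roughly four years later), per-stratum logistic regressions
   give (i) MetS prevalence at age 18, predicted from a model of baseline
   status on continuous baseline age, and (ii) interval transition
   probabilities per 5-year age group, from a model of the transition
   indicator on age-group indicators plus four modifiable factors
   (smoking, alcohol use, diet quality, health literacy). The age-group
   probability is the *marginally standardized* probability: the average
   of the model's predicted probabilities over the at-risk records of that
   cell at their observed covariates. Probabilities are annualized under a
   constant-hazard-within-interval assumption,
   $r = -\log(1-p)/\overline{\Delta t}$, which is the exact inverse of the
   two-state occupancy formula used everywhere else in the package.
2. **Curve parameterization.** The ten age-group rates per stratum are
   condensed into continuous-age curves: a fourth-degree polynomial
   (ordinary least squares at bin midpoints) for recovery and a
   three-parameter logistic $L/(1+e^{-k(a-a_0)})$ (Levenberg–Marquardt
   with a grid of starting values) for incidence. Evaluation clips at
   zero, so a polynomial that dips negative acts as a zero hazard there.
3. **Microsimulation.** Individual life courses are drawn exactly from the
   non-homogeneous two-state process by thinning/uniformization (below),
   giving an alternating episode sequence from age 18 to exactly 65.
4. **Summaries.** Life-course prevalence (ever in MetS), mean age of onset
   (among those starting healthy who convert), mean years lived with MetS
   (among those ever in MetS), and the age-specific point prevalence
   curve.
5. **Counterfactuals and uncertainty.** Low-education rates are
   re-standardized under the high-education mediator distribution
   (below); confidence intervals come from a perturb–refit–resimulate
   ensemble.

## Age bins

The 47-year window is not divisible by five. Bins are half-open,
`[18,20), [20,25), ..., [60,65)`, i.e. a 2-year remainder bin first, then
nine 5-year bins; curve fitting uses bin midpoints. Age-group membership
of an at-risk record is taken at baseline age, because the timing of the
transition inside the interval is unobserved.

## The event engine

Event times are sampled by uniformization, a form of thinning: with
$B \ge \max_a\{\lambda(a) + \mu(a)\}$ (computed on a 0.01-year grid with a
1.001 safety factor), proposal times arrive as an Exponential($B$) stream,
and at each proposal a single uniform $u$ updates the state — healthy
$\to$ MetS iff $u < \lambda(a)/B$; MetS $\to$ healthy iff
$u > 1-\mu(a)/B$. This is distribution-exact for bounded hazards (no
quadrature or discretization error), and the one-uniform update is
monotone in both the current state and the incidence curve. Consequently
two simulations sharing a seed *and* a bound are coupled pathwise: raising
the incidence curve can never decrease an individual's time in MetS. The
test suite exploits this to make counterfactual comparisons exact rather
than merely statistical; `simulate_group(..., bound = )` exposes the
shared bound. A proposal-time guard verifies $\lambda + \mu \le B$ at
every evaluation, so a bound violation is an error, never a silent bias.

Randomness is counter-based: each individual owns a SplitMix64 stream
keyed by (seed, individual id), so results are independent of cohort size
and simulation order — simulating 100 or 100,000 individuals leaves the
first 100 trajectories unchanged.

## The analytic oracle

The same model admits a deterministic description through its forward
equations,
$$P'(a) = \lambda(a)\,(1-P) - \mu(a)\,P, \qquad S'(a) = -\lambda(a)\,S,$$
with $P(18)=p_0$ (point prevalence) and $S(18)=1-p_0$ ($S$ = probability
of never having entered MetS). Augmented states accumulate
$\int P\,da$ (expected years in MetS), and the onset-density moments
$\int \lambda S\,da$ and $\int a\,\lambda S\,da$. Solved with `deSolve`
(lsoda, rtol 1e-8), these give analytic twins of every simulated summary:
ever-prevalence $1-S(65)$, mean onset age
$\int a \lambda S / \int \lambda S$ (conditioning on starting healthy,
mirroring the simulation's exclusion rule), and mean duration
$\int P\,da \,/\, (1-S(65))$ — never-MetS individuals contribute zero
occupancy, so dividing by the ever-probability yields the mean among
experiencers. The test suite requires simulated summaries to sit within
three Monte-Carlo standard errors of these oracle values for several
qualitatively different curve sets.

## Counterfactual standardization

The counterfactual question — what would low-education transition rates
be if that group had the high-education distribution of a modifiable
factor — is answered by distribution-ratio reweighting. Each low-education
at-risk record gets the weight
$$w \;=\; \prod_{f \in \text{factors}} \frac{P_{\text{high}}(\text{category}_f)}{P_{\text{low}}(\text{category}_f)},$$
and the counterfactual age-group probability is the $w$-weighted mean of
the fitted model's predicted probabilities at the observed covariates.
This is marginal standardization to the high-education factor margins: it
is deterministic, closed-form, reduces exactly to the observed rates when
the two distributions coincide (the identity is tested to 1e-12), and the
weights average to one whenever the marginals are computed on the same
records they reweight. Factor marginals are taken on the stratum-wide
at-risk set by default — per-cell marginals are available via
`marginals = "cell"` but are noisier in sparse cells. The joint
counterfactual multiplies the four single-factor weight ratios, which
corresponds to shifting each factor's margin while leaving their
dependence structure to the data. High-education rates are untouched by
construction.

Factor importance is ranked by the difference method: the mediated
percentage is the proportional attenuation of the low-education log-odds
coefficient when the factor enters a logistic model of the transition
indicator on education and age group. Negative (inconsistent) mediation
percentages are reported as-is. Rankings average the incidence and
recovery percentages.

## Uncertainty

Confidence intervals repeat the whole simulation: each repetition draws
every age-group rate from Normal(estimate, SE) truncated below at zero
(hazards cannot be negative; the baseline prevalence is treated the same
way, truncated to $[0,1]$), refits the curves, simulates a reduced cohort,
and recomputes the three summaries per stratum. The 2.5 and 97.5
percentiles across repetitions (linear interpolation between order
statistics; two repetitions give the range) form the interval; the point
estimate comes from a larger main run with the unperturbed rates. Because
the interval describes an independent ensemble, it is *not* guaranteed to
contain the point estimate — only `lower <= upper` is an invariant — but
in a well-specified setting it covers the point in the large majority of
cells, which the tests check at reduced scale (100 repetitions of 2,500
individuals per group). The reference analysis scale is 1000 repetitions
of 12,500 per group, with a main run of 125,000 per group; the reduced
scale keeps the full suite within a routine test run while exercising the
identical code path.

## The synthetic cohort generator

Real two-wave cohort data of this kind are access-restricted, so the
package ships a generator that emulates their structure with analytic
ground truth. Defaults: 93,249 participants, 58.9% female, baseline ages
Uniform(18, 61), follow-up gap Normal(4, 1) truncated to [1, 8] years
(the real waves are roughly four years apart; no per-person value is
published), and modifiable-factor distributions per education level taken
from the published cohort description. One published column (alcohol use,
high education: 11.8/59.6/40.4) sums to 111.8% — its footnote only covers
rounding, so the generator renormalizes each column to 1 and keeps the raw
percentages in the config attributes; this is a flagged guess at intent,
not a resolution.

Wave-4 status is drawn from the *exact* time-homogeneous two-state
solution per person — constant hazards
$\lambda = e^{\text{lp}_{\text{inc}}}$, $\mu = e^{\text{lp}_{\text{rec}}}$
over that person's own interval — rather than any discrete approximation,
so generating hazards are analytically recoverable. Hazard models are
log-linear in age since 18 with optional per-bin offsets (for
piecewise-constant ground truth in parameter-recovery tests) and additive
coefficients for sex, education and the four factors.

Default coefficients were chosen once, for plausibility rather than
replication: a baseline cross-sectional MetS prevalence near 14% with the
at-risk split of roughly 86/14, incidence rising about five-fold from 18
to 65, recovery around 0.2/yr and declining, and modest same-signed
education and lifestyle effects. These defaults produce life-course
prevalences (roughly 70–90% depending on stratum) that are higher than
published estimates for the Dutch population — the defaults were
calibrated to cross-sectional levels only, and no attempt is made to
reverse-engineer any published life-course figure. What the tests rely on
is the *known ground truth*, not the realism of the levels: parameter
recovery, closed-form interval probabilities, and directional
counterfactual constructions are all checked against the generator's own
analytic implications. The generator also omits features of real cohort
data — missingness (the package is complete-case by design), family
structure, measurement error beyond the component level, and time-varying
mediators — so a passing suite demonstrates internal validity of the
machinery, not external validity of any particular rate table.

A small component-level layer (`generate_components`,
`classify_mets`) realizes or verifies NCEP-ATPIII classification —
at least three of: elevated waist (sex-specific), elevated blood pressure
or BP medication, elevated triglycerides or medication, low HDL
(sex-specific) or lipid medication, elevated fasting glucose or diabetes
diagnosis/medication — with thresholds in mmol/L.

## Numerical choices and edge cases

* **Separation.** A stratum (or age cell) with all-zero or all-one
  outcomes gets the Agresti-style corrected proportion
  $(k+0.5)/(n+1)$ with a warning and a `corrected` flag; empty cells are
  flagged `absent` and skipped by curve fitting.
* **Flat incidence data.** With rate spread below 1e-10 the logistic
  parameters are non-identifiable; the fit returns the exact constant
  curve ($L = 2\bar r$, $k = 0$) instead of an arbitrary converged point.
* **Annualization domain.** Probabilities must lie in $[0,1)$; the SE is
  propagated by the delta method, $\mathrm{se}_r = \mathrm{se}_p /
  ((1-p)\overline{\Delta t})$.
* **Episode merging (sensitivity analysis).** Episodes shorter than six
  months are reassigned to the nearest *preceding* episode of sufficient
  length; a leading short episode is absorbed forward into the first
  valid one. Backward absorption was chosen because the transform's
  purpose is to discard transient threshold crossings — the state that
  preceded the blip persists. Whether the original analysis merged
  forward or backward mid-trajectory is not documented; this choice is
  the package's own and is flagged as such. The transform is idempotent,
  conserves the 47-year window exactly, and never increases the episode
  count; an individual with no valid episode collapses to their
  longest-occupancy state with a warning.
* **Reporting precision.** Reported one-decimal numbers use
  round-half-away-from-zero computed in decimal (tenths) arithmetic, and
  sex averages of reported gaps are averaged on the tenths scale, so
  printed per-sex values average exactly to the printed mean. Percentage
  reductions recomputed from one-decimal table cells can differ from
  reductions computed on unrounded internal values by a few tenths of a
  percentage point; both are exposed (`inequality_from_table` vs.
  `build_report`).
* **Estimand of the rate estimator.** A two-wave design cannot see a
  transition that reverses within the interval, so the annualized
  age-group "incidence rate" targets $-\log(1-\pi)/\Delta t$ where $\pi$
  is the two-state interval probability — slightly below the true hazard
  when recovery is non-negligible. Parameter-recovery tests therefore
  compare against this estimand, which is what the design identifies.

## Problem sizes used by the test suite

The reference analysis simulates 125,000 life courses per stratum and
1000 ensemble repetitions. The package's own validation runs use sizes
chosen to keep Monte-Carlo error well below the tested tolerances while
remaining routine to execute: 100,000 individuals per curve set for
oracle-equivalence checks, a 200,000-participant cohort for parameter
recovery, 25,000 per stratum for counterfactual direction (with common
random numbers), and 100 repetitions of 2,500 per group for the ensemble.

## Known limitations

* No mortality, migration, or education change over the life course;
  transition rates are assumed stationary into the future.
* Complete-case analysis only; the multiple-imputation layer used with
  real interview data is out of scope here.
* Two education levels only (10 vs 16 years); intermediate levels would
  shrink the contrasts.
* The mediation ranking uses the difference method on logistic
  coefficients, which inherits the non-collapsibility of odds ratios;
  percentages should be read as a ranking device, not a causal
  decomposition with exposure–mediator interactions.
* Reproducing any published rate table's simulated summaries requires
  that table as input (`read_rates()`); the package validates the
  pathway, not the table.
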