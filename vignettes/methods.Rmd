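---
title: "Methods: from label-driven reformulation to cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from label-driven reformulation to cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foplcea)
```

`foplcea` models a supply-side obesity intervention: a front-of-pack
nutrition label that nudges manufacturers to reformulate packaged foods
towards lower energy density. This vignette is the package's own account of
the model — its assumptions, the parameters that matter, the numerical
choices, and what the synthetic-data tests do and do not demonstrate.

## 1. The reformulation effect

The causal claim is a difference-in-difference: products that adopted the
label between the pre and post survey years are the treated arm, products
that did not are the controls, and the label-attributable effect per food
category is

$$\text{attributable pp} = 100\,\frac{\Delta \bar{E}_{\text{lab}}}{\bar{E}^{0}_{\text{lab}}} - 100\,\frac{\Delta \bar{E}_{\text{unlab}}}{\bar{E}^{0}_{\text{unlab}}}$$

where $\bar E$ are unweighted mean energy densities (kJ/100 g) per arm. Arms
are defined by the post-year label flag, and only products present in both
years enter (a matched panel; `compute_category_effects()` does not attempt
cross-sectional estimation because the package's input schema carries both
years on one product row). No sales weighting is applied — sales weights are
simply not part of the input contract, and unweighted product means are what
the DiD identity in the tests pins down.

The voluntary-scenario change applied to the food supply is, per category,

$$\Delta E_{\text{vol}} = s \cdot \bar{E}^{0}_{\text{lab}} \cdot
  \frac{\text{attributable pp}}{100}$$

with $s$ the category's label share: only the labelled share of the category
actually reformulated. This is the reading under which the mandatory
cross-multiplication $\Delta E_{\text{mand}} = \Delta E_{\text{vol}} / s$
recovers "every product reformulates the way labelled products did", and it
makes `scale_to_mandatory()` an exact inverse of multiplying by the uptake.
The attributable fraction (default 1) is a univariate sensitivity lever that
scales all category changes; the package deliberately keeps it a plain
multiplier so dose-response tests can check near-linearity downstream.

Uptake uses a Wald binomial interval. It reproduces the published interval
for the reference counts (1004/14,986 gives 6.3–7.1%), which is why the Wald
form was chosen over Wilson or Clopper–Pearson; for proportions this far
from 0/1 at $n \approx 15{,}000$ the three agree to the reported precision.

## 2. Intake, weight and BMI

Per age–sex cohort, $\Delta\text{kJ/day} = \sum_c \Delta E_c \cdot g_c$ with
$\Delta E_c$ in kJ/g (the kJ/100 g → kJ/g division by 100 is done once, in
`scenario_effect()`, because a unit slip here is the most likely silent bug
in this pipeline) and $g_c$ the cohort's grams/day of category $c$. No
compensatory eating is modelled: consumers keep buying the same grams.

Energy to weight uses a steady-state linear coefficient:
$\Delta\text{kg} = \Delta\text{kJ}/\rho$, with $\rho = 100$ kJ/day per kg
for adults and (by default) the same for children. Published dynamic
weight-change equations imply a mildly different and age-dependent
coefficient (values near 107 kJ/day/kg reproduce some published weight
figures); $\rho$ is therefore an explicit parameter of
`energy_weight_params()` rather than a constant, and results scale exactly
linearly in $1/\rho$. Children get the same permanent-shift treatment as
adults — no growth modelling — which is a documented simplification, not an
oversight: the health model only lets BMI act on adult-onset diseases, so
child cohorts' shifts matter only once they age into adulthood.

BMI is $\Delta\text{kg}/h^2$ at the cohort's mean height. The shift is
interpreted as a uniform location shift of the cohort's BMI distribution:
the natural-scale mean moves, the shape is otherwise preserved. That is the
simplest distributional reading of a population-level mean shift and is what
the potential impact fraction below consumes.

## 3. The proportional multi-state life table

Each age–sex cohort of the baseline population is simulated in annual
cycles from its age-group midpoint to age 100 (or extinction), with
age-group rates held constant within each group — standard life-table
practice that keeps input tables small. Two arms run in lockstep:

* **Comparator**: baseline all-cause mortality $q(a)$ and total YLD
  (years-lived-with-disability morbidity rate) $y(a)$, with each disease's
  sub-model running at baseline incidence.
* **Intervention**: each disease's incidence is multiplied by $1 - \text{PIF}$,
  where for a cohort with lognormal BMI $B$ and reduction $\delta > 0$

  $$\text{PIF} = 1 - \frac{E[\text{RR}(B-\delta)]}{E[\text{RR}(B)]}, \qquad
  \text{RR}(b) = \text{RR}_5^{(b-b_0)/5} \text{ for } b > b_0, \; 1
  \text{ otherwise.}$$

The PIF is applied to incidence only — not to prevalence or case fatality —
which is the standard proportional-life-table mechanism: risk-factor change
prevents new cases, and mortality/morbidity consequences follow through the
disease sub-models. The reference BMI $b_0$ (default 21 kg/m²) floors the
relative risk at 1 so the model never rewards pushing people into
underweight.

Disease sub-models are healthy/cases/dead difference equations (annual
incidence $i$, case fatality $f$, remission $r$, all in $[0,1)$), conserving
people exactly. Remission defaults to 0 — no remission data exist for the
disease slots — but is a per-row input. The intervention arm's all-cause
mortality is the baseline rate plus $\sum_d f_d \,\Delta p_d$ and its YLD is
the baseline rate plus $\sum_d w_d \,\Delta p_d$, where $\Delta p_d$ is the
prevalence-rate difference against the comparator and $w_d$ the disability
weight. This "background rate plus disease-attributable delta" bookkeeping
was chosen over rebuilding total YLD from disease-wise weights because the
input contract provides a total YLD rate; it also guarantees the exact null:
a zero BMI shift reproduces the comparator bit for bit.

Accounting is annual with no half-cycle correction: person-years in cycle
$t$ equal survivors at the start of the cycle, HALYs are
$\text{PY}_t (1-y_t) (1+\rho_d)^{-t}$ with discount rate $\rho_d$ (default
3%/year) and cycle 0 = baseline year. With constant mortality and no
diseases this reduces to a geometric sum, which the tests check to 1e-12.
The intervention effect is constant over time: each cohort's $\delta$ is
fixed for all cycles.

## 4. Costs and cost-effectiveness

Cost items carry schedules: government administration is an **annual** item
over the scheme's lifetime, industry relabelling recurs **per labelling
cycle** (default 3 years, the reported upper bound for a relabelling
round), and legislation (mandatory scenario only) is a **one-off** at year
0. Each occurrence is discounted at the model rate and summed. Published
lifetime cost totals for this intervention family are not derivable from
the per-period cost table by any single obvious schedule, so the schedule
is data (a column of the cost table), not code; the net-cost and ICER
arithmetic is validated against published totals taken as inputs.

Cost offsets price the difference in prevalent case-years between arms at
each disease's annual treatment cost, discounted; they are negative when
cases are averted. Net cost is intervention cost plus offsets. ICER is net
cost over incremental HALYs with the usual dominance semantics (gains
health and saves money: dominant; loses health and costs money: dominated);
zero incremental HALYs leave the ICER undefined rather than raising an
error, since a null scenario is a legitimate query.

## 5. Uncertainty

`run_psa()` draws, independently per iteration:

| Quantity | Family | Parameters |
|---|---|---|
| Weight-change effect | Normal | mean = point estimate, SD = mean (`effect_cv = 1`) |
| Industry / government costs | Pert (λ = 4) | min / mode / max from the cost table |
| Legislation cost | Gamma | mean = point, SD = range/3.92 |
| Relative risks | Lognormal | meanlog = log(RR), sdlog = reported log-scale SE |
| Cohort BMI log-mean | Normal | SE column of the population table |

The SD-equals-mean convention for the effect is the standard wide-margin
choice when no effect-size variance data exist; it implies roughly 16% of
iterations reverse the sign of the effect, which propagates into
negative-HALY iterations (the tests check the realised fraction lands in
10–25% after downstream nonlinearities). The effect draw rescales the whole
cohort effect vector by draw/mean, preserving the age–sex structure, because
one distribution is assigned to the overall weight change, not one per
cohort. The RR lognormal is median-preserving (meanlog = log of the point
estimate); the source description of the RR standard deviation is not a
well-defined recipe, so the generator supplies a log-scale SE directly and
this parameterisation is documented as the package's choice. The gamma for
the legislation cost is parameterised by mean = point and SD = range/3.92,
reading the elicited range as a 95% interval.

None of the drawn quantities enter the comparator arm, so the comparator is
computed once and shared across iterations — an exact factorisation, not an
approximation — and each iteration reruns only the PIFs, the intervention
arm, offsets and cost aggregation. Iteration $k$ seeds its own substream
derived from the master seed, so single iterations are reproducible in
isolation; iterations that violate model consistency (rates leaving
$[0,1)$) are recorded as failures and counted, never dropped silently.

Summaries are percentile 95% uncertainty intervals. The mean ICER averages
per-iteration ICERs over iterations with positive health gain, with
cost-saving (dominant) iterations contributing their negative ratios — the
summary under which a published mean ICER can exceed the ratio of mean net
cost to mean HALYs. CE-plane quadrants put boundary iterations on the
positive-cost/positive-effect side.

## 6. The synthetic-data generator

The generator emulates the *structure* of the real inputs, not their
marginals: category energy-density baselines spanning ~200–3100 kJ/100 g
(beverages to oils); a Bernoulli label flag at 6.7% uptake; a shared secular
drift plus a labelled-only mean extra change of −7.11 kJ/100 g with product
noise; adult total pre-packaged consumption around 1.4 kg/day split by
once-drawn category shares; lognormal BMI rising from ~17 (children) to
~27.5 (mid-adulthood) with log-SD ≈ 0.15; Gompertz-shaped mortality; nine
anonymous adult-onset disease slots with RR per 5 BMI units in 1.1–2.2 and
treatment costs of A$1000–12,000 per case-year. The disease slots are
anonymous by design — the model family does not pin down which nine
diseases — so per-disease results are interpretable only as slots. The cost
table is not simulated at all: it carries the published point/range values
for the two scenarios.

What passing tests on this fixture show: the estimators recover the planted
reformulation signal; the life-table, costing and PSA machinery satisfy
their exact identities (conservation, null effect, closed-form discounting,
dose-response linearity) and statistical properties (PIF vs Monte Carlo,
sampler moments, orthant probabilities). What they do not show: agreement
with any real population's headline HALY or ICER values, which depend on
proprietary product, consumption and epidemiological data. On the shipped
fixture the offsets happen to exceed the scheme costs, making the synthetic
voluntary scenario dominant; that is a property of the fixture, not a
finding about any real labelling scheme.

## 7. Problem sizes and defaults

The reference fixture (`fixture_inputs()`, seed 20100614) defaults to 4000
products (the test suite uses 2000 for speed, and the acceptance script
simulates a same-shaped 4000-product input set under its command-line
seed); 20
five-year age groups × 2 sexes = 40 cohorts simulated to age 100; 9
diseases; PSA runs use 200 iterations in tests and scripts with the 2000
default reserved for full analyses. The PIF grid uses 2001 points over the
central 99.99% of the lognormal mass, which agrees with a 10⁶-draw Monte
Carlo oracle well within sampling error in the tests. Defaults: discount
3%/year, WTP A$50,000/HALY, horizon age 100, reference BMI 21, labelling
cycle 3 years, adult age 18.

## 8. Known limitations

No demand-side behaviour (label-guided consumer choices would add benefit);
no nutrient-specific pathways (sugar/sodium/saturated fat effects beyond
energy density); no disease comorbidity interactions or time trends in
background rates; no half-cycle correction (a conservative, documented
accounting choice); homogeneous cohorts within age–sex strata; cost and
effect draws are independent in the PSA.
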