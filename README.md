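# foplcea

Cost-effectiveness modelling of front-of-pack nutrition labelling through its
effect on food reformulation.

Voluntary front-of-pack labels (such as star-rating schemes) give
manufacturers an incentive to reformulate packaged foods towards lower energy
density. `foplcea` provides a tested, reusable R pipeline for asking whether
that supply-side effect is worth paying for, from the perspective of a
government weighing a voluntary scheme against making it mandatory:

1. **Reformulation effect.** A difference-in-difference (DiD) estimate of the
   label-attributable energy-density change per food category: the percent
   change among labelled products minus the percent change among unlabelled
   products between a pre- and a post-implementation year, plus the label
   uptake proportion with a Wald 95% interval and a paired t-test of the
   overall shift. A mandatory scenario rescales each category's voluntary
   change by 100%/uptake%.
2. **Intake and anthropometry.** Category energy-density changes (kJ/100 g →
   kJ/g) are weighted by grams/day consumed per age–sex cohort to give
   ΔkJ/day, converted to steady-state weight change by Δkg = ΔkJ/ρ
   (default ρ = 100 kJ/day per kg), and to a BMI shift Δkg/height².
3. **Proportional multi-state life table (PMSLT).** Each cohort is simulated
   annually to age 100 under a "do nothing" comparator and an intervention
   arm whose BMI distribution is shifted by Δ BMI. The shift acts through the
   potential impact fraction for each obesity-related disease,

   PIF = 1 − E[RR(B − Δ)] / E[RR(B)],  RR(b) = RR₅^((b − b₀)/5) for b > b₀,

   with B lognormal and b₀ a reference BMI of 21 kg/m². The PIF scales
   disease incidence; changes in disease prevalence feed back into all-cause
   mortality (via case fatality) and morbidity (via disability weights).
   Outputs are discounted health-adjusted life years (HALYs).
4. **Costing.** Scheduled intervention costs (annual government costs,
   per-labelling-cycle industry costs, one-off legislation) are discounted
   and summed; averted prevalent case-years are priced at per-disease annual
   treatment costs (cost offsets); net cost = cost + offsets and
   ICER = net cost / incremental HALYs, with dominant/dominated semantics
   against a willingness-to-pay threshold (default A$50,000/HALY).
5. **Uncertainty.** A seeded Monte Carlo probabilistic sensitivity analysis
   (2000 iterations by default) over the weight-change effect (normal with SD
   equal to the mean), cost ranges (Pert; gamma for legislation), relative
   risks (lognormal) and cohort BMI means, summarised with percentile 95%
   uncertainty intervals, cost-effectiveness-plane quadrant shares and
   `ggplot2` CE planes.

A synthetic-data module generates all five input tables (products,
consumption, population, diseases, costs) with the statistical structure the
analysis assumes, so the whole pipeline runs and is tested without any
external data.

## Worked example

```r
library(foplcea)

inputs <- fixture_inputs(2000)          # reference synthetic input set
run <- run_scenario(inputs, "voluntary")
run
#> <fopl_run> voluntary scenario, attributable fraction 100%
#>   uptake: 6.7% (5.6% to 7.8%)
#>   intervention cost: A$67.1 m | offsets: A$-713.5 m | net: A$-646.4 m
#>   incremental HALYs: 123,876 | ICER: dominant
```

The uptake line is the share of fixture products carrying the label with its
binomial 95% interval. Offsets are negative (treatment costs averted exceed
scheme costs on this synthetic fixture), so the net cost is negative while
HALYs are gained: the intervention is dominant. On real inputs the balance is
decided by the data; the published evaluation this model family is used for
found a small positive net cost and an ICER well under the threshold.

Uncertainty analysis and plots:

```r
psa <- run_psa(inputs, "voluntary", n_iter = 200, seed = 1)
glance(psa)       # one-row tibble: means, 95% UIs, quadrant shares
autoplot(psa)     # cost-effectiveness plane
sensitivity_analysis(inputs, fractions = c(0.5, 0.3, 0.1))
```

All user-facing functions take and return tibbles (or small classed objects
with `tidy()`/`glance()`/`autoplot()` methods), so stages chain with the
pipe.

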