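---
title: "Methods: a two-model cost-effectiveness analysis of tobacco control for CVD prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-model cost-effectiveness analysis of tobacco control for CVD prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tobaccoCEA)
```

## Overview

`tobaccoCEA` implements a cost-effectiveness analysis of five
population-based tobacco control interventions — an advertisement,
promotion and sponsorship ban; package labelling; smoke-free public
places; smoke-free workplaces; mass media campaigns; and tobacco excise
tax increases — for the prevention of ischaemic heart disease (IHD) and
stroke, contextualised to Tanzania and taking a government perspective.

Two models are chained:

1. a **smoking prevalence model**: a three-state (never / current /
   former smoker) cohort model with status-specific mortality, whose
   unknown initiation and cessation rates are calibrated to repeated
   cross-sectional survey prevalence by weighted least squares;
2. an **epidemiological Markov model**: four health states — S1 no
   history of CVD, S2 history of IHD, S3 history of stroke, S4 dead —
   run in annual cycles over fourteen 5-year cohorts (15–19 through
   80+), in which smoking-prevalence changes act on disease incidence
   through the potential impact fraction (PIF).

Outcomes are discounted disability-adjusted life years (DALYs) averted;
costs come from a six-cost-center ledger with capital annuitisation and
step-down allocation of shared items; results are summarised as average
and incremental cost-effectiveness ratios (ACER/ICER) with simple
dominance, and uncertainty is propagated by layered Monte Carlo.

## The prevalence model

Within each age–sex stratum the all-cause mortality rate $M^p$ is
decomposed by smoking status using prevalence weights and mortality
relative risks $RR^c$ (current) and $RR^f$ (former):

$$M^n = \frac{M^p}{RR^c\,\mathrm{Prev}^c + RR^f\,\mathrm{Prev}^f +
(1 - \mathrm{Prev}^c - \mathrm{Prev}^f)},\qquad
M^c = RR^c M^n,\qquad M^f = RR^f M^n.$$

The prevalence-weighted mean of the three status rates reproduces
$M^p$ exactly; this conservation identity is property-tested across
random valid inputs. Rates convert to one-year probabilities by
$P = 1 - e^{-MR}$.

Each stratum carries **one signed flow parameter**: a negative value is
an annual initiation rate (proportion of never smokers starting per
year), a positive value an annual cessation rate (proportion of current
smokers quitting). This keeps the model identified with two survey
waves and matches the sign convention used in the published rate table
shipped with the package. Relapse of former smokers is excluded.

The annual update order is: status-specific survival first, then
initiation/cessation flows among survivors (both computed from the
post-survival, pre-flow stocks), then aging — a fraction
$1/\text{band width}$ of each band advances per year (stationary-within-
band assumption) — then new never-smoking entrants into the youngest
band from age-specific fertility and the sex ratio at birth. The
published account does not fix this order; a single documented order is
required for reproducibility, and the straight-loop reference simulator
in the test suite pins it down to $10^{-10}$.

### Calibration

The signed parameters minimise

$$\sum_{\text{obs}} w \,(\text{observed} - \text{simulated})^2$$

over current- and former-smoker prevalence at every survey year, with
the model seeded from the earliest wave. Weights are inverse variances
$n_{\mathrm{eff}} / (p(1-p))$ when effective sample sizes are supplied,
else equal weights with a warning. The optimiser is `nlminb` under box
constraints $[-1, 1]$ with seeded multi-start (default 5 starts: one at
zero, the rest uniform in $[-0.2, 0.2]$) to guard against local minima
— any bounded WLS routine is acceptable here; the estimand is the WLS
optimum, not a particular algorithm's output. Sexes are calibrated
independently (the joint/independent choice is not documented in the
source analysis; independent is the less-coupled default). On noiseless
synthetic surveys the calibration recovers every stratum's generating
parameter to well below $10^{-3}$.

The signed parameterisation has a kink at zero (initiation switches to
cessation). When the true rate is within a couple of sampling standard
errors of zero, estimates pile up on the boundary; the bootstrap is
then a conditional spread and need not match the unconditional sampling
SD. The nested-simulation check in the test suite therefore runs at a
survey size that keeps both parameters many SDs from the kink.

### Rate uncertainty

A parametric bootstrap resamples survey prevalence triples from
Dirichlet distributions (concentrations $=$ proportions $\times
n_{\mathrm{eff}}$; a default $n_{\mathrm{eff}} = 1000$ with a warning
when none is given) and mortality RRs from lognormals fitted to their
95% CIs, recalibrating per draw from the base-case optimum. Failed
draws are counted and excluded, never silently dropped. The production
default is 10,000 iterations; analysis drivers and tests use a few
hundred, which already estimate the spread to a few percent.

## The Markov disease model

Transition probabilities per cycle and stratum:

* S1→S2: $1 - e^{-\mathrm{inc}_{IHD}(1-\mathrm{PIF}_{IHD})}$, and
  analogously S1→S3 for stroke;
* S1→S4: background mortality, i.e. the all-cause rate net of the two
  cause-specific rates (clipped at zero with a warning if the causes
  exceed it);
* S2→S4 (and S3→S4): background plus the disease's case-fatality rate
  among prevalent cases, computed as cause-specific mortality divided by
  prevalence;
* rows close with self-loops; S4 is absorbing.

The PIF uses two exposure categories — smokers versus non-smokers with
former smokers counted as non-smokers, since the disease-risk table
provides no former-smoker RR:

$$\mathrm{PIF} = \frac{\sum_x P_x RR_x - \sum_x \hat P_x RR_x}
{\sum_x P_x RR_x},$$

with $P$ the base-year smoker prevalence and $\hat P$ the scenario's
future prevalence. The baseline comparison year is fixed at the start
of the simulation for both the base and intervention scenarios, so a
secular trend also carries a (common) PIF and the scenario difference
isolates the intervention. Disease RRs are given on broad bands (35–64,
65+); ages below 35 receive RR = 1 (no estimate exists there). Smokers'
RR values map onto 5-year model bands by containment.

Structural assumptions: no transitions between the two disease-history
states (a person with IHD history cannot enter the stroke state —
states are mutually exclusive and second events are not modelled); no
half-cycle correction (spreadsheet-model fidelity; an optional matter
for future work); cohorts are followed until age 100, the operational
end of the open-ended 80+ band. Disease schedules are taken as
internally consistent inputs; the package validates rather than
re-derives them (the original analysis used external disease-modelling
software for that step, which is out of scope here).

Each cohort starts with its prevalent disease fraction already in
S2/S3 — the youngest cohort effectively starts CVD-free. Person
conservation (S1+S2+S3+S4 constant per cohort) and monotonicity of the
dead state are asserted per run, and the vectorised population runner
is tested to be exactly equivalent to the generic single-cohort
matrix route.

## Interventions

Effect sizes enter as:

* **relative risks on initiation or cessation** — multiply the
  calibrated flow rates during the effect horizon (10 years by
  default), after which flows revert to baseline while accrued
  prevalence changes persist; hazard ratios are treated as RRs on
  annual rates. Odds ratios from source studies convert exactly via
  $RR = OR / (1 - p_0 + p_0 OR)$.
* **relative prevalence reductions** (e.g. a 4% reduction for the
  advertisement ban) — move that fraction of current smokers into the
  former state at the start of year 1. Quitting, not "never-ing":
  adults cannot re-enter the never state.
* **price elasticities** — a tax scenario's retail price change under
  full pass-through is $(t_1 - t_0)/(1 - t_1)$ for excise shares
  $t_0 \to t_1$ of retail price (the default scenario moves a 20%
  excise share to 50%, a +60% price change; pass-through is
  configurable). Prevalence elasticity $\epsilon$ scales current-smoker
  prevalence by $1 + \epsilon \Delta p$; initiation elasticity scales
  the initiation rate by $\max(0, 1 + \epsilon \Delta p)$. The tax
  cessation elasticity is zero, as assumed in the source table.

Interventions are evaluated one at a time against no intervention;
their effects are assumed independent. Scaled rates outside $[0,1]$ are
clipped with a warning. Monotone comparative statics (initiation RR < 1
or cessation RR > 1 never increase current-smoker prevalence at any
horizon) are property-tested.

## Costing

Cost items belong to six cost centers (program development; human
resources; promotion, media and advocacy; program supplies; rent,
equipment and office supplies; operations). Capital items are
annuitised at 9.6% per year over their useful life
($\mathrm{EAC} = A\,r / (1 - (1+r)^{-L})$; straight-line at $r = 0$);
capital items under US\$62 (TSh 100,000) are treated as recurrent —
a strict less-than rule, so the boundary value stays capital. Local
prices deflate to base-year (2013) terms with a GDP deflator and
convert at Tshs 1605 per US\$. Direct items attach to their
intervention; shared items split by named allocation keys (step-down
allocation); the grand total is conserved to $10^{-6}$ US\$.

The original shared-cost allocation keys are unpublished, so the
packaged cost table ships as already-allocated cost-center amounts and
the ledger preset reproduces its column totals exactly; the random
ledger generator exercises the full capital/recurrent and
direct/shared machinery. Useful-life defaults (vehicles 10 y, computers
5 y, buildings 30 y, furniture 10 y) stand in for the original
assumption table and are overridable.

The published per-intervention cost in the results table differs from
the annual cost-center totals by intervention-specific factors that no
printed reconciliation explains (plausibly some time adjustment of the
five-year program stream). Both tables are preserved verbatim; the
package's own evaluation discounts the five-year annual-cost stream at
3% and reports the mean discounted annual cost (`discounted_program_cost`),
with the raw annual figure retained alongside. The costing horizon is a
config field.

## Outcomes and cost-effectiveness

DALYs are GBD-2013 style: no age weighting, 3% discounting. Years lived
with disability accrue in S2/S3 weighted by disability weights; years
of life lost accrue at death as the discounted annuity of residual life
expectancy at the age of death, taken from the supplied life table (the
original health-outcome supplement is unavailable; this is the
package's documented reconstruction, with the life-table source
explicit). Costs are discounted at the same 3%.

ACERs are cost per DALY averted versus no intervention, rounded
half-away-from-zero to integer US\$ for reporting. The ICER frontier
sorts options by effect against a zero-cost/zero-effect comparator,
flags simple dominance, and computes ICERs along the efficient
frontier; extended dominance is implemented but off by default, since
the published results report only simple dominance. Exact ties break
deterministically by name. WTP classification uses the WHO bands with a
strict "below one GDP per capita" rule (US\$910, 2013) for "very
cost-effective"; boundaries go to the upper class.

## Probabilistic sensitivity analysis

The PSA samples all base-case parameters concurrently: PERT for costs
(mode = base cost, ±20% — the spread convention used for
PERT-distributed effects, as no cost spread is printed), lognormal for
effect sizes fitted to their CIs (median-preserving, so the PSA mean
ACER need not equal the base-case ACER — documented, not "corrected"),
and lognormal for disease RRs. The signed-rate distributions from the
bootstrap can be layered in via shifted-beta distributions (beta moment-
matched on $[-1,1]$, allowing negative initiation values). The two
Monte Carlo layers are sequential, not nested: the bootstrap summarises
rate uncertainty into distributions that the PSA then samples.

Each parameter draws from its own substream derived deterministically
from the root seed and the parameter's name, so adding or removing a
parameter never perturbs the other draws, and identical seeds give
bitwise-identical outputs. The published iteration count ("2000
iterations for each of the 14 age groups") is implemented as 2000
whole-model iterations with coherent per-age-group draws — the
cost-effectiveness plane is a whole-intervention object, so draws must
be coherent across ages. Iterations that fail are recorded with their
draw; more than 5% failures aborts the run.

One row of the published effect table (the tax prevalence elasticity,
−0.88 with interval −0.78 to −0.37) has an interval that does not
bracket its point estimate as printed; the sampler falls back to a PERT
±20% around the point for that row, with a warning.

## The synthetic-data generator

The external inputs of the original analysis (census population,
national life tables, GBD-style disease schedules, CPS-II mortality
RRs) are not redistributable, so the package generates synthetic
stand-ins with known ground truth:

* **life tables**: Gompertz mortality plus a constant background rate
  with a sex differential; band rates at band midpoints; residual life
  expectancies computed from the same single-year rates by survivorship
  summation, so the table is internally consistent (checked against an
  independent summation oracle to 0.01 years);
* **disease schedules**: exponentially age-increasing incidence;
  prevalence at the steady-state heuristic incidence × duration with
  duration $1/(\text{case fatality} + \text{mortality})$;
  cause-specific mortality strictly below all-cause;
* **survey panels**: the true prevalence trajectory simulated forward
  from known signed rates, observed with multinomial noise of chosen
  size (or exactly, in noiseless mode);
* **population and demography**: exponentially declining pyramid,
  fertility concentrated at ages 15–45, sex ratio 1.03;
* **cost ledgers**: random mixtures of capital/recurrent and
  direct/shared items with valid keys, plus the preset reproducing the
  packaged cost table.

Default magnitudes sit in the Tanzanian regime (adult male current
smoking roughly 0.1–0.3, female much lower) so fixtures resemble the
study setting; this is resemblance, not replication. What passing tests
on synthetic data show is internal validity — the estimator recovers
known truth, invariants hold, the pipeline is deterministic under
seeds; they cannot show that the synthetic inputs match real Tanzanian
epidemiology, and absolute DALY magnitudes from the synthetic bundle
are not comparable to the published ones. The desk-reproducible
published quantities (ACERs from printed cost/DALY columns, dominance
structure, cost-center totals) are reproduced exactly from the shipped
fixtures instead.

## Numerical choices and problem sizes

* Strata are closed–open $[{\rm low}, {\rm high})$; open tails are 75+
  (survey scheme) and 80+ (Markov scheme); the survey "<25" band is
  bounded below at 15, the assumed earliest initiation age (a config
  choice).
* Extrapolated proportions clamp to $[0,1]$ with a warning; simplex
  triples that print to ±0.001 of 1 renormalise on load.
* Base smoking trajectories are simulated for 30 years by default
  (12 in the faster test/PSA configurations), after which the last year
  is held; cohort follow-up ends at age 100. These sizes are the
  package's defaults for a desk-scale analysis and are config fields.
* Calibration: `nlminb`, `rel.tol = 1e-12`, 5 starts; convergence codes
  are reported, and a non-zero code is a flagged diagnostic, not an
  error. On noisy data "false convergence" codes are common and the
  returned optimum is still the best found.
* Analysis drivers run a 200-iteration PSA and a 200-draw bootstrap as
  demonstrations; production sizes (2000 / 10,000) are the config
  defaults.

## Known limitations

Only IHD and stroke are modelled, so health gains from other
tobacco-related disease are excluded (a conservative direction). No
relapse, no smoking-intensity dimension, no tunnel states for acute
events, no second events. Tax revenue effects are out of scope. The
published results table's DALY magnitudes depend on unpublished inputs
and are not a validation target for the synthetic pipeline; one row of
that table carries a 2-DALY discrepancy between its sex split and its
printed total, preserved as printed. The female 25–34 published
cessation rate (0.5088) is implausibly large and is shipped as printed
but flagged.
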