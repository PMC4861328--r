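---
title: "Measuring impoverishment from medicine purchase with grouped expenditure data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring impoverishment from medicine purchase with grouped expenditure data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdburden)
```

## The problem

Most health expenditure in India is paid out of pocket, and most of that
goes to medicines. Chronic cardiovascular disease is treated with
multi-drug regimens taken indefinitely, so even modest daily prices
accumulate into a substantial claim on household resources. `cvdburden`
asks: if the adults who would benefit from preventive cardiovascular
regimens bought them out of pocket at statutory ceiling prices, how many
would be pushed below the poverty line, and by how much would the depth
of poverty increase?

The difficulty is that household expenditure *microdata* are often
unavailable; what is published is a grouped summary — cumulative
population fractions with the monthly per-capita expenditure (MPCE)
upper bound of each bracket. The package's central method turns that
grouped table back into a continuous expenditure distribution accurate
enough for poverty accounting, and validates the reconstruction against
synthetic microdata where the truth is known.

## The model

### Expenditure quantile curves

Order the population from poorest to richest and let $E(p)$ be the
monthly per-capita expenditure of the person at population fraction
$p \in [0, 1]$ — the quantile function of the expenditure distribution.
A published bracket table supplies the points
$E(p_k) = e_k$ at the cumulative fractions $p_k$ (here
$0.05, 0.10, 0.20, \ldots, 0.90, 0.95$); the open top bracket
(95–100%) has no finite bound and is excluded, so the fitted curve's
domain ends at the last closed fraction. `expenditure_curve()`
interpolates these knots with a monotonicity-preserving cubic Hermite
scheme, so that $E$ is smooth, passes through every knot exactly, and is
non-decreasing — any overshoot of an ordinary spline would invent
non-monotone "wealth" between brackets.

Two slope limiters are available. The default, `method = "monotone"`,
is the Fritsch–Carlson limiter (`stats::splinefun`, `monoH.FC`);
`method = "hyman"` applies the Hyman filter. Both are admissible
monotone schemes; on the shipped bracket tables the Fritsch–Carlson
variant tracks the closed-form piecewise-linear reference (retained as
`method = "linear"`) more tightly through the steep upper brackets, and
every published headcount is reproduced within 0.10 percentage points
at baseline and 0.5 points after cost deduction, so it is the default.
The piecewise-linear curve is exactly invertible bracket by bracket and
reproduces the published grouped-data poverty ratios to two decimals;
it is used throughout the tests as the independent oracle.

**Anchor.** The table says nothing about $E(0)$, the poorest person's
expenditure. The fit anchors the curve at $(0, E_0)$ with $E_0 = 0$ by
default (`anchor_E0`). Headcount results are insensitive to this choice
because the poverty lines fall well inside interior brackets; the
poverty gap index integrates over the lower tail and *is* sensitive to
it, which is why gap results should be read with a tolerance of around
one percentage point rather than as point estimates.

### Poverty measures

For a poverty line of $z$ rupees/month (daily lines are converted at 30
days/month, the factor under which the daily thresholds and the monthly
brackets are commensurate), the headcount ratio is the intersection of
the line with the curve,
$$H = \min\{p : E(p) = z\},$$
found in closed form on linear segments and by bracketed root finding
(tolerance $10^{-8}$ in $p$) on cubic curves. The poverty gap index is
the normalised area between the line and the curve up to the headcount
point,
$$\mathrm{PGI} = \frac{1}{z}\int_0^{H} \left(z - E(p)\right)\,dp,$$
computed as an exact trapezoid sum on linear curves and by adaptive
quadrature (absolute tolerance $10^{-6}$) otherwise.

Buying a medicine at daily cost $c$ removes $30c$ rupees/month from
every individual's resources: `shift_curve()` translates the whole
curve down, and poverty is re-measured on the shifted curve ("gross"
poverty). The difference from baseline is the "net" impoverishment
attributable to the purchase. Shifting the curve rather than inflating
the line matters for the gap: the denominator stays $z$. When the shift
exceeds the anchor the shifted curve is negative at small $p$ —
resources fully exhausted — and the gap integrand uses the negative
value as-is by default; `floor_at_zero = TRUE` floors it, for readers
who prefer a shortfall never to exceed the line.

### Step-up regimens

The catalog (`drug_catalog()`) carries tax-inclusive daily ceiling
prices (0% excise, 6% VAT, compounded multiplicatively, excise first)
and, for the primary-prevention drugs, relative risks (RR) of ischemic
heart disease under treatment. Cost-effectiveness is daily cost per
unit relative risk reduction, $c / (1 - \mathrm{RR})$; ranking the four
primary-prevention drugs ascending gives aspirin 75mg <
hydrochlorothiazide 12.5mg < losartan 25mg < atorvastatin 10mg, and
Steps 1–4 are the cumulative prefixes of that order. Step 5 intensifies
the statin to 40mg; Step 6 is the secondary-prevention regimen
(aspirin, hydrochlorothiazide, atenolol 50mg, atorvastatin 40mg). The
40mg atorvastatin price is not separately regulated in the shipped
source and is priced dose-proportionally at four times the 10mg daily
cost (Rs 25.04/day), the unique value consistent with the Step 5 and 6
totals of Rs 28.85 and Rs 28.39. Risk reductions for multiple
anti-hypertensives are treated as additive (`combined_rrr()`, capped at
1) for reporting; the poverty arithmetic uses only costs.

```{r regimens}
build_step_regimens(drug_catalog())
```

### The treatment-need cascade

Poverty percentages describe the whole population; only part of it
needs any regimen. `allocate()` expands a small decision tree: a
fraction $r$ of adults has high short-term cardiovascular risk (10-year
risk > 10%) and needs at least aspirin; among them a fraction $h$ is
hypertensive; hypertensives without hyperlipidemia split
stage 1 : stage 2 as $s_1 : (1 - s_1)$ (one vs two anti-hypertensives,
Steps 2/3); hypertensives with hyperlipidemia (fraction $l$) split by
single vs multiple lipid disorders $s_l : (1 - s_l)$ (low- vs high-dose
statin, Steps 4/5). Adults with prevalent coronary heart disease need
Step 6, independently. Steps 1–5 therefore sum to $r$ exactly, and the
two hypertensive branches conserve mass — properties the test suite
asserts. The stage-1/stage-2 split is applied only to hypertensives
*without* hyperlipidemia; that reading reproduces all ten published
sector shares to two decimals, which the alternative (splitting all
hypertensives) does not. Rural and urban parameter files share all
conditional prevalences and differ only in the high-risk fraction
(12% vs 21.8%) and CHD prevalence (4.5% vs 10.5%).

### Burden and sensitivity

`burden_table()` multiplies each step's population share by the
sector's gross (burdened) and net (impoverished) headcounts and by the
adult population (545 million rural, 238 million urban), assuming the
expenditure distribution within each clinical subgroup matches the
general population. All intermediates are unrounded; totals are sums of
unrounded contributions, so a displayed total can differ in the last
digit from the sum of displayed rows. `uptake_scenario()` scales person
counts linearly by the fraction actually purchasing out of pocket.
`univariate_sensitivity()` perturbs one cascade parameter at a time by
±10% (relative), holding the poverty percentages fixed — only treatment
*need* is varied, not the expenditure distribution — and orders
parameters by output range (tornado convention). Because person counts
are linear in each share-scaling parameter, the bars can be verified in
closed form, and the CHD prevalence (the Step 6 share — the largest and
costliest group) dominates in both sectors.

## The synthetic-data experiment

The grouped-data method's accuracy is established by round-trip against
microdata generated where the truth is known. `simulate_expenditure()`
draws lognormal per-capita expenditures — the simplest right-skewed,
positive-support shape consistent with the convex quantile profile of
the published brackets — calibrated with median
$\exp(\mu) = 1270$ Rs/month and $\sigma = 0.55$, which puts the decile
bounds in the range of the rural table; a two-component mixture is
available for stress tests. Seeds are mandatory and the global RNG
state is restored, so every stochastic result is reproducible.

`aggregate_to_brackets()` collapses a sample to the published table
layout using type-1 (inverse-CDF) weighted quantiles, and
`validate_aggregate_method()` compares headcounts computed from the
full sample (empirical quantile curve through midpoint plotting
positions $(\mathrm{cum}_i - w_i/2)/W$) with headcounts computed from
the aggregated-then-interpolated curve, for the baseline and all six
regimens. At $n = 10^5$ the two agree within about 0.1 percentage
points, comfortably inside the 0.7-point band the tests assert, and the
agreement tightens as the bracket grid is refined.

What this does *not* show: the generator is unimodal and i.i.d., with
no survey design effects, no household clustering, and no heaping at
round numbers, all of which real consumption surveys exhibit. Passing
the round-trip demonstrates the interpolation machinery is faithful to
the grouped summary; it does not certify the grouped summary's own
fidelity to any real population.

## Numerical choices, in one place

* Days per month: 30 (fixed; the unique factor reconciling daily lines
  with monthly brackets).
* Anchor `anchor_E0 = 0`; configurable; gap results anchor-sensitive.
* Interpolant: Fritsch–Carlson monotone cubic; Hyman and linear
  selectable; linear is the test oracle.
* Root finding: `uniroot` at tolerance $10^{-10}$ (reported accuracy
  $10^{-8}$ in $p$); quadrature: `integrate`, absolute tolerance
  $10^{-6}$.
* Cost-effectiveness ties broken by lower daily cost.
* Display rounding: half-up at 2 decimals, everywhere a published table
  is mirrored; internal arithmetic unrounded.
* Open top bracket: excluded; evaluation beyond the last closed
  fraction raises a domain error rather than extrapolating; poverty
  lines beyond the domain clamp the headcount to the domain maximum
  with a warning.
* Degenerate inputs: constant microdata produce tied bracket bounds,
  which the curve fitter rejects; a zero-cost regimen reproduces the
  baseline row exactly; thresholds below the anchor give headcount 0.

Problem sizes in the shipped tests: bracket tables with 11 closed
knots; microdata validations at $n = 2\times10^4$ (unit tests) and
$n = 10^5$ across 5 seeds (round-trip check), sizes at which the
sampling error of the comparison is well below the asserted bands.

## Worked example

```{r example}
ana <- cvd_burden_analysis("rural")
ana$poverty
attr(ana$burden, "totals")
```

## Known limitations

* The poverty gap index depends on the unobserved lower tail below the
  5th percentile; treat gap levels as band estimates.
* The top 5% of the distribution is not modelled at all; any measure
  needing the upper tail (means, inequality indices) is out of scope.
* Sensitivity analysis is univariate and deterministic, not
  probabilistic; parameter interactions are not explored.
* High-risk adults with hyperlipidemia but no hypertension are not
  assigned a regimen by the cascade, so treatment need is conservatively
  understated for that group.
* Ceiling prices are upper bounds on retail prices; cheaper generics
  exist, which pushes the burden estimates toward overstatement.
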