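---
title: "Screening for unexpected increases in reporting frequency: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for unexpected increases in reporting frequency: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uifscan)
```

## The problem

Spontaneous-report databases accumulate individual case safety reports
(ICSRs) of suspected adverse drug reactions. Safety issues such as product
quality defects (a contaminated batch), medication errors (a device that
administers the wrong dose) or waves of abuse and misuse often manifest not
as a *new* kind of reaction but as a short, concentrated *increase in the
monthly number of reports* of known reactions for one drug.
Disproportionality statistics, computed on cumulative counts, are largely
blind to such transients. `uifscan` implements a prospective screen of
monthly report counts per drug–event combination designed to flag exactly
these unexpected increases in frequency (UIF).

## Counting conventions

The counting unit is a distinct (case, drug, PT) triple — a case reporting
two PTs contributes one unit to each PT series — assigned to the calendar
month of the *receive date* (the date the sender received the report).
Study-module reports are excluded at load time; routine screening uses
post-marketing spontaneous reports only. Months without reports are
explicit zeros: the heuristic branch's "null history" is only well defined
on a gap-free monthly axis.

Unit-counting (rather than distinct-case counting) at pooled levels is a
deliberate choice the data dictionary leaves open: it makes pooling exactly
additive, so the pooled-all series equals the element-wise sum of the PT
series and conservation of units is a testable invariant rather than an
approximation.

Stratification axes, all set in `screen_config()`:

| parameter | default | meaning |
|---|---|---|
| `window_months` | 6 | history length fitted by the trend model (months) |
| `threshold_tau` | 5 | minimum monitored-month count for eligibility (reports) |
| `include_literature` | `TRUE` | count reports stemming from published literature |
| `drug_level` | `substance` | or `product` (commercial product name) |
| `event_level` | `pt` | or `pooled_all` / `grouping` (HLT, HLGT or SMQ series) |
| `restrict_ime_dme` | `TRUE` | screen only important/designated medical event PTs |
| `bound_level` | 0.95 | level of the forecast upper bound |
| `bound_type` | `ci_mean` | or `prediction` (count-scale quantile bound) |

The threshold default of 5 follows routine signal-detection practice, where
minimum counts of 3–5 reports are used; a *minimum* is attained, so
eligibility is `y0 >= tau`, while the forecast bound must be strictly
exceeded. Reports without a product name take part in substance-level
screens but are dropped from product-level ones, mirroring real extracts
where many reports specify only the active substance.

## The detector

For a monitored month $t_0$ with observed count $y_0$ and history
$y_{-w},\dots,y_{-1}$ (default $w = 6$):

1. **Eligibility.** If $y_0 < \tau$, nothing is flagged and no model is
   fitted.
2. **Branch choice.** If at least $w - 2$ history months are zero (4 of 6
   at the default window), the history cannot support a two-parameter
   trend fit; the month is flagged iff $y_0 \ge \tau$ (heuristic branch).
3. **Regression branch.** Otherwise a negative binomial log-linear trend
   is fitted by maximum likelihood:
   $y_t \sim \mathrm{NB}(\mu_t, \alpha)$,
   $\log \mu_t = \beta_0 + \beta_1 t$, with variance
   $\mu + \alpha \mu^2$. Time is coded $t = -w,\dots,-1$ with $t_0 = 0$,
   so the forecast is $\hat y = e^{\beta_0}$ and the standard error of the
   forecast linear predictor is read directly off the intercept's
   covariance. The month is flagged iff $y_0$ strictly exceeds the upper
   bound *and* $y_0 \ge \tau$.

The intercept-plus-slope structure is the smallest model that can
extrapolate drift from six points; with so short a window, seasonality or
richer covariates are not identifiable and are deliberately out of scope.

### Upper bounds

Two bounds are implemented because "the upper bound of the forecast" admits
two readings:

* `ci_mean` (default): $e^{\beta_0 + z\,\mathrm{se}(\eta_0)}$, the Wald
  upper confidence limit of the *forecast mean* at level `bound_level`.
  This is the literal decision rule of comparing $y_0$ to the confidence
  interval of $\hat y$; it ignores outcome-level variability, and is
  therefore the more sensitive (and more false-alarm-prone) choice.
* `prediction`: the smallest integer $q$ whose NB (or Poisson) CDF at mean
  $e^{\beta_0 + z\,\mathrm{se}(\eta_0)}$ reaches `bound_level` — a
  conservative count-scale bound that stacks parameter and outcome
  uncertainty. Its null false-alarm rate is below nominal by
  construction, which the calibration test verifies by simulation.

No level is canonical for this screen; 0.95 is the conventional default
and is exposed in the configuration. No multiplicity correction is applied
across the screened universe — the operating metric of such screens is the
positive predictive value, not a family-wise error rate.

### Numerical choices

The dispersion is estimated by *profile likelihood*: for fixed $\alpha$
the model is an ordinary GLM fitted by IRLS
(`MASS::negative.binomial` family), and a one-dimensional search over
$\log\alpha \in [\log 10^{-6}, \log 50]$ maximises the profile. This is
markedly more robust on 6-point series than joint quasi-Newton steps.
If the profiled optimum does not beat the Poisson log-likelihood (the
$\alpha \to 0$ boundary), or no NB fit converges, the Poisson GLM is used
(`family_used = "poisson"`) rather than dropping the series — six points
frequently cannot identify $\alpha$, and discarding the candidate would
silently shrink the screen. `se(eta0)` comes from the expected-information
covariance at the fixed dispersion estimate, the GLM convention.
Degenerate cases: constant histories yield a zero slope with the Poisson
family; a count-scale quantile below a sub-unit forecast mean is clamped
to the mean so the bound never falls below $\hat y$.

The null-history cutoff generalises to `window - 2` zeros for non-default
windows (e.g. a 3-month sensitivity window), chosen so the regression
always has at least three informative points.

## Evaluation against historical concerns

A concern register row carries a substance (optionally product names), an
index date — the date the issue entered the issue-tracking system — a type
(quality defect QD, medication error ME, abuse/misuse AM) and grouping
terms. Its case definition is the union of PTs grouped under those terms,
restricted to IME/DME terms when the screen is, and, for QD concerns,
always excluding product-quality-issue PTs: a quality defect should be
detectable from the reported *harms*, because explicit quality-complaint
reports already trigger action through other regulatory channels.

A detection is a **true positive** if some concern covers its drug, its
event PT (or the PT expansion of its grouped event key) intersects the
concern's case definition, and its month lies in
$[\text{index month} - 12, \text{index month} + 6]$, both ends inclusive.
The window is month-granular because the detection unit is a month; the
asymmetric span reflects that historical concerns were logged without a
real-time monitoring tool (detection may predate the register entry by up
to a year) and persist past it while stock washes out of the market.
Detections on drugs no concern covers are *out of universe* and excluded
from the PPV denominator — they cannot be adjudicated either way.

The PPV is reported as the pooled ratio TP / (TP + FP) over in-universe
detections, overall and restricted per branch (an average of per-concern
ratios would be dominated by small denominators). An empty denominator
yields `NA`, never 0/0 = 0. AM concerns are substance-wide ("all
products"), so product-level screens skip them.

## The synthetic scenario

Real EudraVigilance extracts are access-restricted and MedDRA is licensed,
so the package ships a synthetic stand-in for both (the hierarchy under
`inst/extdata/synthetic_hierarchy/` is labelled synthetic and its PT
content is invented; its grouping-term names mirror the packaged register
so case definitions resolve). The simulator draws, per drug–event pair and
month, counts from the same NB parameterisation the detector fits —
variance $\mu + \alpha\mu^2$ — so calibration checks are exact, and
expands them into report rows (random day of month, Bernoulli literature
flag, product name present with probability 0.7). Episodes are *additive*:
extra Poisson reports with mean $(\text{fold} - 1)\mu$ per member PT and
episode month are appended on top of the background, keeping the ground
truth unambiguous.

The packaged demo scenario (`default_scenario()`) mirrors the structure of
the shipped 13-concern register: one 3-month, 6-fold episode per concern,
ending in the concern's index month, over a 2007-01 to 2016-06 span;
background $\mu = 2$ reports/month per pair (a typical low-volume
drug–event pair), $\alpha = 0.3$, stationary trend, 10% literature
reports, 8 background PTs per substance. These values were fixed once as
a realistic operating point; the seed alone distinguishes runs.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: duplicate reports (including
literature-duplication clusters), the Weber effect and other
stimulated-reporting waves, country strata and reporting-rate drift,
multi-drug cases, and MedDRA multi-axiality. Performance figures computed
on the synthetic scenario characterise the algorithm under its own
generative assumptions, not its PPV on a real database.

## Problem sizes

The shipped tests fit the trend on 200 random histories against a dense
grid-search likelihood oracle, run a 10,000-replicate null-calibration
study of the regression branch, and screen the full packaged scenario
(~110 months × ~200 series) twice to verify bit-for-bit reproducibility;
`scripts/acceptance.R` repeats the scenario screen and a 3,000-replicate
calibration from a caller-supplied seed.

## Known limitations

* The trend model carries no seasonality or exposure denominator; an
  increase in product usage is indistinguishable from an increase in
  risk.
* Six points rarely identify the dispersion; the Poisson fallback then
  under-covers slightly on genuinely over-dispersed series under the
  `ci_mean` bound.
* The heuristic branch's PPV depends entirely on how sparse the database
  is: on dense data it almost never runs, on sparse data it dominates.
* Deduplication is out of scope; duplicated reports inflate counts and
  can fabricate increases, which is why the literature toggle exists.
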