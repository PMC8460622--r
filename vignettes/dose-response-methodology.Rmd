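---
title: "Estimating skin-sensitization potency from GARDskin dose-response data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating skin-sensitization potency from GARDskin dose-response data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdv0)
```

## The problem

The GARDskin assay classifies chemicals as skin sensitizers or
non-sensitizers from the transcriptional response of a dendritic-like cell
line, summarized by a frozen support-vector classifier into a single signed
*decision value* (DV): DV ≥ 0 classifies the sample as a sensitizer. The
binary call carries no information about *potency* — how little of the
chemical suffices to sensitize. Titrating each chemical over a
concentration series and asking for the **lowest concentration at which the
decision value reaches the classification border** turns the assay into a
continuous potency measurement. That concentration is the **cDV0**, the
quantity this package estimates, by direct analogy with the murine LLNA,
where the EC3 is the concentration interpolated to reach a threefold
stimulation index.

`cdv0` implements the complete workflow downstream of the classifier: the
concentration-series design, constrained log-logistic modelling of DV
versus concentration, a likelihood-ratio *no-effect* test, two cDV0
estimators with uncertainty, and benchmarking of cDV0 against reference
potency metrics (LLNA EC3, human NOEL). Computing DVs from gene expression
is out of scope — DVs are inputs here, never outputs.

## Study design: the concentration ladder

Concentration series are geometric with ratio 3/5, twelve steps, anchored
so that the third step equals the chemical's *GARD input concentration*
(the low-cytotoxicity concentration used in standard single-dose testing):
$c_i = c_{\mathrm{input}} \cdot (3/5)^{\,i-3}$, $i = 1,\dots,12$. The top
of the ladder is therefore two steps above the input concentration, unless
that would exceed the 500 µM assay limit, in which case `design_series()`
re-anchors the whole ladder to descend from the cap. Re-anchoring (rather
than truncating) is the default because chemicals tested at a 500 µM input
concentration are assayed at and below 500 µM on a full-length ladder; a
`cap_mode = "truncate"` alternative is available. After cytotoxicity
screening, `select_for_assay()` drops non-viable steps and the lowest
evaluated concentration, typically carrying 8–9 concentrations forward —
one biological replicate each, favouring coverage of the concentration axis
over replication.

```{r}
design_series(100)$concentration_uM
```

## The response model

Dose-response relationships are modelled with the four-parameter
log-logistic (4PL) curve

$$f(x) = c + \frac{d - c}{1 + \exp\{b(\log x - \log e)\}},$$

with two constraints that encode assay knowledge:

* the lower asymptote $c$ is **fixed** at the decision value of
  unstimulated controls (supplied per dataset as `control_dv`, required to
  be negative — a control must classify negative);
* the slope $b$ is restricted to negative values, so fitted curves rise
  monotonically with concentration.

That leaves three free parameters $(b, d, e)$, fitted by least squares on
the DV scale, which under i.i.d. Gaussian errors is the maximum-likelihood
fit. The error model is a modelling convention (the DV is an unbounded
continuous score, and inspection of real curves shows roughly constant
scatter); it is also what makes the likelihood-ratio test below concrete.

**Optimization.** The RSS surface of the 4PL in $(b, d, \log e)$ is smooth
but can be multimodal under noise, so the fit is multi-start
box-constrained L-BFGS-B from a deterministic grid of seven starts
(midpoint at the geometric mean of the assayed concentrations and at the
range ends; slope from a logit linearization of the centred responses and
at −0.3/−1/−3; upper limit at the DV maximum), with $b \le -10^{-6}$ as
the box form of the strict constraint and $\log e$ bounded ten decades
outside the assayed range. The wide $e$ bound deliberately includes the
flat-curve limit ($e$ far below the range makes $f \equiv d$), and one
start is placed in that limit at $d = \bar y$, which guarantees the fitted
RSS never exceeds the horizontal line's — the nesting the
likelihood-ratio test requires. Convergence is accepted when any start
terminates cleanly within relative $10^{-8}$ of the best RSS found; the
optimizer's own tolerance is `factr = 1e4` (relative RSS change around
$10^{-12}$). Failures never throw: the best parameters found are returned
flagged `converged = FALSE`, and downstream estimates come out censored.
Fits that collapse onto or below the control level ($d \le c$) are flagged
`degenerate`.

## The no-effect test

Whether a chemical shows *any* concentration dependence is tested by
comparing the 4PL fit against the best horizontal line (the mean DV) with
a likelihood ratio. Under the Gaussian error model
$\mathrm{LR} = n \log(\mathrm{RSS}_{\mathrm{flat}} / \mathrm{RSS}_{4\mathrm{PL}})$,
referred to $\chi^2_2$ — the difference in free mean parameters (3 vs 1).
Two caveats are documented rather than hidden:

* the slope constraint places the null hypothesis on the boundary of the
  parameter space, so the $\chi^2_2$ reference is approximate and somewhat
  conservative;
* the degrees of freedom follow from counting free mean parameters, a
  choice the package makes explicitly (the error variance cancels in the
  ratio).

The acceptance script measures the realized type-I error at nominal 0.05
on 1 000 simulated flat curves each run; with the package defaults it lands
near the nominal level, within the 0.01–0.10 band the Gaussian-theory
approximation is expected to hold.

## Estimating cDV0

**From the model.** The fitted curve's intersection with the threshold
$t$ (default 0) has the closed form
$x_0 = e\,\big(\tfrac{d-c}{t-c} - 1\big)^{1/b}$, valid when $c < t < d$.
When the upper asymptote never reaches the threshold the estimate is
censored as `NS` (non-sensitizing); a non-converged fit likewise yields a
censored estimate rather than an error. Uncertainty comes from inverse
regression: the delta method applied to $\log x_0$ with the parameter
covariance approximated by $\hat\sigma^2 (J^\top J)^{-1}$ (Gauss–Newton)
at the optimum, then exponentiated — bounds are positive and asymmetric by
construction. A bound that overflows or a singular $J^\top J$ is reported
as `NA`, which reproduces the one-sided intervals seen in practice for
shallow or barely-crossing curves.

**By interpolation.** The simpler, less constrained estimator applies
local linear interpolation between the two assayed points on adjacent
sides of the decision border:
$cDV_0 = c_- - DV_- (c_+ - c_-) / (DV_+ - DV_-)$, using the
lowest-concentration qualifying bracket — "lowest concentration generating
a positive decision value" is the definition, and locality is exactly what
makes this estimator robust to non-sigmoidal shapes. A window-3 running
median (with symmetrically shrinking windows at the sequence ends) can be
applied first so an isolated noisy positive does not become the crossing
point; the `"auto"` policy applies it only when the sign pattern of
$DV - t$ changes more than once, which is the noise signature it guards
against. Window width and policy are configuration, not constants.

Censoring is explicit and never numeric: `NS` when no (smoothed) DV
reaches the threshold, `below_range` when the lowest assayed concentration
is already positive (the true crossing is unobserved). `compare_estimators()`
runs both estimators and flags chemicals where they disagree (one censored,
or ratio > 2 by default) — two-phase and U-shaped responses surface here
for analyst review instead of being silently excluded.

```{r}
d <- simulate_dataset(c(b = -1.5, c = -1, d = 1, e = 20), seed = 1)
fit <- fit_log_logistic(d)
cdv0_from_model(fit)
cdv0_linear_interpolation(d, smooth = "auto")
```

## Benchmarking against reference potency data

The package bundles a reference table of the 29 chemicals used to
establish the methodology (7 non-sensitizers, 22 sensitizers), with LLNA
EC3 (%), human NOEL (µg/cm²), GARD input concentrations, the study's cDV0
estimates in µM and mg/L, and molecular weights. Censoring tokens (`NS`,
`ND`, `NA`, `NM`) are parsed into status columns, never sentinel numbers.
Two transcription notes: the benzalkonium chloride molecular weight is
back-computed from the table's paired µM/mg-L values (it is a mixture),
and the dimethyl fumarate row is internally inconsistent between its µM
and mg/L columns (the loader warns); both printed values are preserved
as-is.

Benchmarking correlates $\log$ cDV0 — expressed **weight-based** (mg/L,
via `um_to_mg_per_l()`), because the reference metrics are weight-based —
against $\log$ EC3 and $\log$ NOEL with Pearson's $r$ and a two-sided
t-test ($n-2$ df). Pairs with a censored value on either side are dropped;
with the bundled table that leaves 17 EC3 pairs and 15 NOEL pairs. GHS
sub-categories follow the standard EC3 rule (1A ≤ 2% < 1B, inclusive
boundary), and `class_separation_report()` counts 1A/1B ordering
violations when chemicals are ranked by cDV0.

```{r}
ref <- suppressWarnings(read_reference_table())
correlate_potency(ref, "llna_ec3")
correlate_potency(ref, "human_noel")
class_separation_report(ref)$violations
```

## The synthetic-data generator

No raw DV-versus-concentration series are published, so validation rests
on simulation with known truth. `simulate_dataset()` draws
$DV_i = f(c_i) + \varepsilon_i$ with homoscedastic Gaussian noise — the
same structure the fit assumes — with the control DV equal to the lower
asymptote. Defaults are chosen once to emulate the study conditions: the
12-step ladder anchored at the 500 µM cap, one replicate per
concentration, DV magnitudes spanning roughly −1.5 to +1.5, and noise
σ = 0.1 on the DV scale (the raw-data scatter is not quantified anywhere;
0.1 is a visual calibration to published curves and is exposed as a
parameter). `simulate_panel()` builds study-like panels (22 sensitizers /
7 non-sensitizers by default) with sensitizer curves parameterized so the
true crossing equals the midpoint $e$ exactly ($c = -1$, $d = +1$), drawn
log-uniformly over 1–500 µM, slopes uniform in (−2.5, −0.8); true
crossings below the ladder floor (1.81 µM) come out censored
`below_range`, as they would in the laboratory. Two deterministic
contamination modes reproduce documented failure shapes: `"u_shape"`
(positive limb at the lowest concentrations) and `"two_phase"` (early
secondary rise to a moderate positive plateau). All randomness is funneled
through one integer seed.

What the generator does **not** emulate: classifier-induced dependence
between neighbouring concentrations, heteroscedastic or heavy-tailed DV
noise, batch effects between exposure experiments, and cytotoxic
truncation correlated with potency. Passing recovery tests therefore
demonstrate correctness of the estimators under the model's own
assumptions, not assay-level accuracy on real chemicals.

## Numerical choices and problem sizes

Reference tolerances: optimizer `factr = 1e4`, parameter-tie tolerance
$10^{-8}$ relative RSS, strict-negativity bound $b \le -10^{-6}$,
degenerate-collapse tolerance $10^{-8}$ on $d - c$. Replicate
concentrations are retained as separate residual contributions. Equal
replicate concentrations straddling the border interpolate to that
concentration itself. Output CSVs round to 6 significant digits so reruns
are byte-identical.

The validation suites use Monte-Carlo sizes chosen to estimate the rates
they check to about a percentage point: 1 000 flat-curve simulations for
the type-I error, 500 for interval coverage, 200 panels of 22 sensitizers
for log-scale recovery, 1 000 random parameter sets for the
closed-form-versus-bisection identity.

## Known limitations

* The $\chi^2_2$ reference for the no-effect test ignores the boundary
  constraint; p-values near the significance border should be read with
  that in mind.
* Delta-method intervals are first-order; for shallow slopes they can be
  wide or one-sided (`NA` bound). Fieller-type inversion would be the
  natural refinement and is deliberately left unimplemented.
* The interpolation estimator inherits the grid: its resolution is the
  bracketing interval, and a crossing below the lowest assayed
  concentration is only ever reported as censored.
* Reference NOEL values are no-observed-effect levels from human
  repeated-insult patch testing — informative of potency but not a potency
  measure proper; correlation magnitudes against them should be
  interpreted accordingly.
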