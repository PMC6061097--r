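---
title: "Evaluating and optimizing sampling designs for a QE TMDD model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and optimizing sampling designs for a QE TMDD model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Clinical studies of monoclonal antibodies against soluble targets are
typically rich: many sampling days spread over months, several dose groups,
and several analytes measured in every sample. `tmddesign` asks how much of
that richness is actually needed. It evaluates reduced single-dose designs
for an omalizumab-like antibody whose pharmacokinetics follow a
quasi-equilibrium (QE) target-mediated drug disposition (TMDD) model of
binding to IgE, and it quantifies the loss of each reduction with four
complementary metrics: D-efficiency from the population Fisher information
matrix (FIM), empirical parameter precision from stochastic
simulation-estimation (SSE), population prediction areas (PPA) for free
target, and the probability of an incorrect go/no-go dose-selection
decision.

## The model

Three states are tracked after a subcutaneous dose: the depot amount, the
total drug concentration $D_{tot}$ and the total target concentration
$R_{tot}$ (internally in nM; analytes are reported in ng/mL). Binding is
assumed to be at instantaneous equilibrium, so free drug solves the
quadratic

$$D_f = \tfrac12\left[(D_{tot}-R_{tot}-K_D) +
\sqrt{(D_{tot}-R_{tot}-K_D)^2+4K_D D_{tot}}\right],$$

with complex $C = D_{tot}-D_f$ and free target $R_f = R_{tot}-C$. The
differential system is

$$\dot A = -k_a A, \qquad
\dot D_{tot} = k_a A/V - \frac{CL_{OMA}}{V}D_f - \frac{CL_{COMP}}{V}C,$$
$$\dot R_{tot} = \frac{CL_{IGE}}{V}R_0 -
\frac{CL_{IGE}}{V}R_0\left(\frac{R_f}{R_0}\right)^{\alpha} -
\frac{CL_{COMP}}{V}C,$$

where the zero-order synthesis term fixes $R_{tot}=R_0$ at the drug-free
steady state for any $\alpha$. The three analytes are total drug
($D_{tot}$), free target ($R_f$) and total target ($R_{tot}$), converted to
mass concentrations with the molar masses of the drug (149 kDa) and the
target (190 kDa). The day-0 sample is pre-dose: total drug is exactly zero
there and both IgE analytes equal $R_0$.

### The role of $\alpha$

$\alpha$ is the exponent on normalised free target in the target-elimination
term; $\alpha = 1$ is ordinary linear clearance of free IgE. Its definition
was a genuinely open structural choice, settled as follows: the parameter
had to (a) preserve the drug-free steady state, and (b) be informed chiefly
by the free-target analyte, so that designs that stop measuring free IgE
lose most of their information about it while the FIM stays nonsingular. A
saturable-elimination exponent has exactly that signature. Its typical value
is 1, so the shipped model's dynamics are linear in the target at the
typical subject, but the parameter is estimated (and its uncertainty
propagates into every downstream metric).

## The parameter set is synthetic and calibrated

The packaged values
(`inst/extdata/params_omalizumab_qe_synthetic.yaml`) are **not** published
estimates — they are a calibrated stand-in, and the file name says so.
Literature-plausible values for a ~70 kg adult fix most of the vector
(bioavailability $F=0.62$, $V = 5.9$ L, drug clearance 0.24 L/day, target
clearance 1.7 L/day giving the ~2.4-day IgE half-life). Three remaining
parameters were calibrated once, before any acceptance measurement, against
published summary characteristics of the omalizumab–IgE system:

* $k_a = 0.3144$/day, so the typical total-drug peak falls at ~7.5 days
  (published omalizumab SC absorption peaks at 7–8 days);
* $CL_{COMP} = 0.2136$ L/day, so the terminal total-drug half-life is
  18.2 days;
* $K_D = 1.6163$ nM, so a 277.5 mg dose reduces typical free IgE by exactly
  95% of the 422.82 ng/mL baseline at day 14.

IIV is log-normal on the three clearances with variance 0.09 (~30% CV), and
the residual model is proportional with variance 0.0225 (15% CV) per
analyte — conventional magnitudes for this setting, chosen a priori. $F$ is
shipped as a fixed (non-estimated) effect because SC-only data cannot
separate $F$ from $V$; the estimated-parameter count (p = 14 for
three-analyte designs) is always derived from the parameter file, never
hard-coded.

Because the parameter set is a reconstruction, FIM-based efficiencies agree
with the published per-design values only approximately: designs dominated
by dose-group structure track closely, while duration-reduced designs
compute somewhat lower and analyte-omission designs somewhat higher than
the published table. Those residuals are a property of the reconstructed
parameter vector (parameter count, IIV placement, residual model), not of
the FIM machinery, which is verified independently against closed-form
sensitivities in a linear one-compartment limit.

## Fisher information, efficiency and the reduced parameterization

The FIM uses the first-order (FO) linearization: a subject's observation
vector (analytes stacked within times) is Gaussian with mean the typical
prediction and covariance
$V = J_\eta \Omega J_\eta^\top + \mathrm{diag}(\sigma^2_a f^2)$, derivatives
at $\eta = 0$. The *reduced* FIM is block-diagonal: the fixed-effect block is
$J_\theta^\top V^{-1} J_\theta$ and the variance block is
$\tfrac12\,\mathrm{tr}(V^{-1}\partial_i V\, V^{-1}\partial_j V)$, with the
fixed–random cross-block exactly zero. Sensitivities are central finite
differences with relative step $10^{-4}$ (step-halving changes them by less
than $10^{-3}$ relative); for the log-normal random effects
$\partial f/\partial\eta_k = \theta_k\,\partial f/\partial\theta_k$ exactly
at $\eta=0$. Pre-dose total-drug observations have zero variance under
proportional error; they are structural zeros and are excluded from the FIM
and the likelihood rather than regularized.

D-efficiency is $(|FIM|/|FIM^\ast|)^{1/p}$ against the reference design.
When a design does not measure an analyte, that analyte's residual variance
is not estimable; the comparison is then made on the common estimable
parameter subset (both matrices restricted, $p$ reduced accordingly).
Determinants are always compared on the log scale.

## Line-search optimization

Sampling times are optimized by a deterministic cyclic coordinate search
over a discretized grid: `make_time_grid(max_time, 84)` gives 85 equally
spaced candidates, each time coordinate in turn moves to the best candidate,
and cycles repeat until a full pass yields no improvement (cap: 50 cycles).
Clustered (duplicate) times are allowed and do occur at optima, as in the
published schedules. Ties within $10^{-10}$ relative keep the current time,
otherwise the earliest tying candidate wins — this makes runs exactly
reproducible. Per-group sensitivities are pre-computed on the grid, so each
candidate evaluation is pure linear algebra. A toy two-time problem verifies
that the search reaches the exhaustive-enumeration optimum.

```{r ls-example}
library(tmddesign)
params <- omalizumab_params()
res <- optimize_times(design_catalogue("4"), params)
glance(res)
autoplot(res)
```

## The simulator and the FO estimator

`simulate_dataset()` is the package's synthetic-data generator and stands in
for the study's raw data: per subject it draws $\eta \sim N(0,
\mathrm{diag}(\omega^2))$ (no correlations), computes individual predictions
and applies proportional residual error. Randomness is split per subject by
a counter-derived seed, so datasets are bit-reproducible and per-subject
draws do not depend on simulation order. Negative simulated concentrations
are kept as drawn (with 15% proportional error they essentially never
occur); no lower limit of quantification is modelled. What the generator
deliberately does **not** emulate: covariate structure (body weight,
baseline IgE distributions), parameter correlations, dropout, dosing
deviations, or assay censoring — so green tests certify the methodology
under the stated model, not robustness to those real-data features.

`fit_dataset()` maximizes the FO marginal likelihood — the same
linearization as the FIM — over log-transformed parameters with BFGS,
starting at the simulation truth (standard SSE practice). This choice keeps
the estimator consistent with the design criterion and fast enough for
replicate loops; it is not a reimplementation of any specific estimation
software, and empirical %RSE from it will differ in detail from published
values obtained with other estimators. Optimizer failures set a flag and
never abort the SSE loop; `empirical_rse()` includes non-converged
replicates by default and can exclude them
(`exclude_nonconverged = TRUE`) — both views are reported in `glance()`.

## Downstream metrics

* **PPA**: typical free-IgE predictions at the 13 reference days for a
  150 mg dose, one curve per replicate estimate vector; per time point the
  2.5th/97.5th percentiles (type-7 linear interpolation between order
  statistics — fixed because n = 100 makes the extreme percentiles
  method-sensitive) form a 95% interval and the PPA is the sum of widths.
  PPAR divides the reference design's PPA by the competing design's.
* **True dose**: bisection on the typical day-14 free-IgE dose-response for
  a 95% reduction from baseline. The decision threshold defaults to
  $0.05\,R_0 = 21.141$ ng/mL (the printed 21 ng/mL is available as an
  override); the dose grid is 1.5 to 450 mg in 1.5 mg steps, which places
  277.5 mg exactly on the grid.
* **Decision errors**: a replicate vector predicting free IgE above
  threshold at a dose above the true dose (or below threshold below it) is
  an incorrect decision; strict inequalities, and the true dose itself can
  only err on the high side. Inside `decision_probability()` the true dose
  is located to ±0.001 mg so that the strict comparisons at neighbouring
  grid doses are meaningful.

## Problem sizes and numerical choices

The integrator is lsoda with `rtol = 1e-8`, `atol = 1e-10` for predictions
(halving the tolerances moves the 13 reference-time predictions by less than
0.01%), relaxed to `1e-6`/`1e-8` inside the estimation objective where the
optimizer's finite-difference gradients dominate the error budget. Many
model instances are stacked into one block-diagonal ODE system (compiled C
right-hand side, banded Jacobian), which is what makes replicate loops and
grid-cached sensitivities cheap.

The packaged analyses use 100 SSE replicates for the reference design (the
published replicate count) and 30 for the reduced designs; 30 replicates
resolve order-of-magnitude precision differences between designs while
keeping a full run of the suite inexpensive. The tests document the exact
seeds.

## Known limitations

* The parameter set is a calibrated reconstruction; per-design efficiency
  and %RSE values inherit that uncertainty (the three calibration anchors
  are reproduced essentially exactly).
* FO everywhere (FIM and estimator). FOCE/Laplace refinements would shift
  empirical %RSE, particularly for the poorly informative 2-day design.
* Single dose only; no covariates; no random-effect correlations; no
  LLOQ/censoring; sampling times are shared across analytes and groups.
* D-optimality only (no ED/C/Ds criteria), and only sampling times are
  optimized — not doses, group sizes or analyte panels.
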