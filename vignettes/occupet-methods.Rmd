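---
title: "Quantifying non-displaceable binding in TSPO PET blocking studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying non-displaceable binding in TSPO PET blocking studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Second-generation TSPO radioligands such as [11C]PBR28 have no reference
region: the 18-kDa translocator protein is expressed throughout the brain,
so every regional signal mixes specific binding with free and
non-specifically bound tracer. The total distribution volume
$V_T = V_{ND} + V_S$ is therefore the standard outcome measure, and the
question of how much of it is non-displaceable ($V_{ND}$) can only be
answered by pharmacological blocking: scanning each subject at baseline and
again after an oral dose of the selective TSPO ligand XBD173 (emapunil),
chosen to occupy roughly 66--77% of binding sites. `occupet` implements the
full quantification chain for such a study — arterial input-function
modelling, compartment-model fitting, occupancy-plot estimation of
$V_{ND}$, and the blocking-free SIME alternative — together with a
synthetic-data generator so that every stage is testable without scan data.

## Arterial input function

The metabolite-corrected plasma input is composed from three fitted pieces,

$$C_p(t) = C_b(t-d)\,\mathrm{POB}(t-d)\,\mathrm{PPf}(t-d),$$

where $C_b$ is whole-blood activity, POB the plasma-over-blood ratio, PPf
the parent plasma fraction and $d$ a fitted delay. All curves are assumed
decay-corrected on input; no decay constant is applied anywhere.

* **Parent fraction.** `fit_parent_fraction()` uses the extended Hill form
  $\mathrm{PPf}(t) = 1 - a t^b/(t^b + c)$ with $a \in [0,1]$, $b, c > 0$.
  The literature that names this model does not fix one parameterization;
  this form is adopted because it starts at 1 (no metabolites at
  injection), declines monotonically and has an interpretable asymptote
  $1-a$. This choice is an assumption of the package and is stated here so
  the self-inversion tests are well defined.
* **Plasma-over-blood ratio.** `fit_pob()` uses the same family anchored at
  a fitted early ratio instead of 1:
  $\mathrm{POB}(t) = r_0 + d\,t^b/(t^b+c)$ with a signed amplitude $d$,
  since for this tracer the ratio typically rises with time.
* **Whole blood.** `fit_wholeblood()` models a linear rise from zero to the
  measured peak and a sum of decaying exponentials after it, continuous at
  the peak by construction; 2 versus 3 exponentials are chosen by AIC.
  Evaluation past the last sample extrapolates with the fitted
  exponentials (no clamp).
* **Calibration and delay.** The continuous (automatic) and discrete
  (manual) whole-blood modalities are cross-calibrated by a single
  least-squares-through-origin factor at the 5/10/15-min overlap samples.
  The blood-to-tissue delay is found by a grid search (default $\pm 1$ min
  in 0.01-min steps, a typical radial-line range) minimizing the weighted
  residual of a single-tissue fit to the early (<= 5 min) whole-brain TAC;
  a solution on the grid boundary is flagged.

## Compartment models

The two-tissue compartment model (2TCM) is

$$\dot C_1 = K_1 C_p - (k_2+k_3) C_1 + k_4 C_2, \qquad
  \dot C_2 = k_3 C_1 - k_4 C_2,$$

with measured signal $C_T = (1-V_B)(C_1+C_2) + V_B C_b$ and macro-parameter
$V_T = (K_1/k_2)(1+k_3/k_4)$. The solution is computed as the convolution
of the bi-exponential impulse response with $C_p$ on a uniform fine grid.
Because the input is taken piecewise linear on that grid, the convolution
with each exponential has an exact one-step recursion, so model evaluation
is $O(n)$ and agrees with a stiff ODE integration to numerical precision
(this is verified in the test suite). Model values are averaged over each
frame interval rather than sampled at midpoints: the 15-s early frames make
midpoint evaluation biased.

The vascular extension (2TCM1K) adds an irreversible endothelial binding
compartment fed from whole blood, $\dot C_{vasc} = K_b C_b$, whose
accumulated signal is added to the measured curve. With $K_b = 0$ it
reproduces the 2TCM exactly; $K_b$ is excluded from $V_T$, which keeps its
meaning on the exchangeable compartments. The source study that introduced
the vascular variant does not print its equations; the system above is the
package's stated formulation and is unit-tested against its own quadrature
oracle.

### Weighted fitting

`fit_wnlls()` minimizes $\sum_i w_i (C_i - \hat C_i)^2$ with frame weights
$w_i \propto \Delta t_i / \max(C_i, \epsilon)$ normalized to sum to one.
This is inverse-variance weighting under the count-statistics assumption
$\sigma_i^2 \propto C_i/\Delta t_i$, and it matches the noise model of the
synthetic generator, so weighting is self-consistent end to end. Fitting
uses bounded Levenberg–Marquardt least squares with three deterministic
starts: the default initialization ($K_1 = 0.1$, $k_2 = 0.1$, $k_3 = 0.05$,
$k_4 = 0.05$, $V_B = 0.05$, $K_b = 0.01$) and two perturbations that move
the $k_3/k_4$ ratio in opposite directions. The asymmetric perturbations
matter: uniform rescaling preserves the ratio and can leave every start in
the same local basin (slowly reversible, high-$V_T$ solutions with $k_4$
at its bound). For the 2TCM1K an additional start is seeded from the nested
2TCM optimum with $K_b \approx 0$; since Levenberg–Marquardt only accepts
improving steps, the fitted 2TCM1K residual can then never exceed the
nested model's.

Parameter uncertainty uses the Jacobian-based asymptotic covariance
$\hat\sigma^2 (J^\top J)^{-1}$ propagated to $V_T$ by the delta method; a
singular covariance yields infinite CVs rather than an error. Regions with
$V_T > 10$ mL/cm$^3$ or CV($V_T$) $> 50\%$ are flagged as non-physiological
and excluded from the occupancy analysis. The covariance estimator behind
the published CVs is unstated in the source literature; the asymptotic
choice here is the common one for WNLLS.

`compute_suv()` summarizes a TAC as the time-weighted mean SUV over the
scan. Whether an SUV "computed 90 min after injection" means the scan mean
or the final frame is ambiguous; the mean is the default and
`summary = "final"` provides the alternative.

## Occupancy (Lassen) plot

Under the assumptions that $V_{ND}$ is unchanged by the drug and occupancy
is uniform across regions,

$$V_T^{base} - V_T^{block} = \mathrm{Occ}\,(V_T^{base} - V_{ND}),$$

so regressing $\Delta V_T$ on $V_T^{base}$ across regions gives the
occupancy as the slope and $V_{ND}$ as the x-intercept.
`lassen_individual()` uses plain OLS — deliberately, for comparability with
the blocking-study literature, although both axes are noisy — with
nonparametric bootstrap CIs over regions (2000 resamples, fixed internal
seed). Occupancies outside $[0,1]$ are reported as computed and flagged,
never clipped; a non-positive slope leaves $V_{ND}$ undefined rather than
negative.

`lassen_population()` implements the constrained variant: one shared
$V_{ND}$, subject-specific occupancies, fitted as a joint nonlinear least
squares. For fixed $V_{ND}$ each occupancy has a closed-form
through-origin solution, so the joint fit reduces to a 1-D profile over
$V_{ND}$; the 95% CI comes from the F-based profile-likelihood threshold
on the pooled residuals. This is an explicit joint fit, not an average of
individual intercepts — the individual estimates are reported separately.

### A caution on noise

Because the baseline $V_T$ estimation error appears in both the regressand
($\Delta V_T$) and the regressor, the OLS slope is inflated and the pooled
$V_{ND}$ is biased upward at realistic noise. In the package's replicate
simulations (run by `scripts/acceptance.R`) this bias is comparable to the
estimator's standard deviation, and the nominal 95% profile CI covers the
true shared $V_{ND}$ in roughly four cohorts out of five rather than 19
out of 20. This is a property of the estimator, not of the implementation:
the same behaviour appears when the full TAC-level pipeline is run on
replicate cohorts. Orthogonal-regression or likelihood variants that model
noise on both axes would reduce it, but OLS is retained as the default for
comparability with the published occupancy studies this package mirrors.

## SIME

The SIME estimator needs no blocking scan: it assumes all regions share one
$K_1/k_2 = V_{ND}$, sweeps a grid of candidates (default 0.01 to 5 in 0.01
steps), refits every region's 2TCM with $k_2$ eliminated through the
constraint, and selects the grid value minimizing the pooled weighted RSS
over regions and frames. Ties resolve toward the smaller candidate. Each
region's weights are normalized within the region; pooling sums weighted
residuals without cross-region reweighting, consistent with the
unconstrained fits (whether the original implementation pooled raw or
weighted residuals is not documented; weighted is this package's stated
choice). Fits are warm-started from the previous grid point, which is what
makes the 500-point sweep desk-scale. When the shared-$K_1/k_2$ assumption
is violated (heterogeneous regional non-displaceable binding), the
estimate is a compromise within the regional range and need not agree with
the occupancy plot — the mechanism behind the large SIME-vs-Lassen
discrepancies seen in blocking data.

## The synthetic-data generator

`cohort_config()` fixes the study conditions: seven subjects by default,
twelve regions with baseline $V_T$ means at the scale published for a
seven-subject [11C]PBR28 blocking cohort of high-affinity binders, a
shared true $V_{ND}$ of 1.99 mL/cm$^3$, per-subject occupancy drawn
uniformly from 0.66--0.77 (the design range of the 90-mg XBD173 dose), a
log-normal between-subject specific-binding scale (SD 0.25, matching the
published regional SD-to-mean ratios of about a quarter), and an optional
outlier subject whose every regional $V_T$ is inflated by 38%. Regional
micro-parameters are not published anywhere, so the generator uses
plausible TSPO-tracer defaults: regional $K_1$ 0.075--0.11 mL cm$^{-3}$
min$^{-1}$ (lower in white matter), $k_2 = K_1/V_{ND}$,
$k_4 = 0.06$ min$^{-1}$, $k_3$ set from the regional specific volume, and
$V_B = 0.05$. Blood curves follow the fitted families themselves
(tri-exponential whole blood peaking before 2 min; Hill PPf falling to
about 0.22 at 90 min; rising Hill POB), with independent realizations per
scan.

Frame noise is zero-mean Gaussian with SD
$\propto \sqrt{C/\Delta t}$ scaled by `noise_scale`; the default 0.1
produces late-frame TAC noise of a few percent and region-level $V_T$
estimation errors with a CV of about 3.5% after exclusion — if anything
optimistic for this tracer, whose reported test-retest variability is
larger. The generator emulates ROI-level curves only: no voxel data, no
scanner resolution or motion effects, no dispersion of the automatic
sampling line, and no biological $V_{ND}$ differences between subjects
unless configured. Passing tests therefore demonstrate correctness of the
estimators under the stated statistical model, not robustness to every
artefact of real acquisitions.

`simulate_vt_table()` is a deliberate shortcut for studying the occupancy
stage at scale: it generates regional $V_T$ values directly from the same
truth structure with multiplicative log-normal estimation noise whose CV
(3.5% at the default noise) was measured from TAC-level fits of
default-noise synthetic scans. Replicate-cohort studies (100 cohorts in
the acceptance script) use this path; the TAC-level path is exercised
end-to-end at smaller sizes.

## Numerical choices

* Fine-grid spacing for model evaluation defaults to 1 s; the test suite
  uses 5 s, which leaves all self-inversion checks unaffected because the
  generator and the fitters share the grid. Grid spacing must divide all
  frame boundaries so frame averages are exact trapezoids.
* The exponential-kernel convolution switches to a plain trapezoid when
  $\theta\,\Delta t < 10^{-8}$; repeated eigenvalues of the 2TCM system
  are separated by a $5\times10^{-10}$ nudge.
* Weight floor $\epsilon = 0.01$ kBq/mL protects against non-positive
  frames in noisy data.
* Table display uses half-up integer rounding of percentages.
* Bootstrap and generator randomness always run under locally scoped
  seeds (`withr::with_seed`), so results are reproducible and the user's
  RNG state is never disturbed.

## Problem sizes

The shipped tests fit single subjects and 2--4 region subsets at the 5-s
grid, run the full default SIME grid once on a noiseless 12-region
subject, and evaluate occupancy-plot coverage on 100 V_T-level replicate
cohorts. `scripts/acceptance.R` additionally runs the complete TAC-level
pipeline on one 7-subject cohort. These sizes are the package's stated
simulation protocol; all of them scale up by changing the configuration
objects.

## Known limitations

* No dispersion correction for the continuous sampling system and no
  plasma free-fraction measurement.
* No image-domain processing (reconstruction, motion correction,
  segmentation): the package starts from regional TACs.
* The OLS occupancy plot's noise-induced bias is documented, not
  corrected, by default.
* Graphical methods (Logan, MA1) and reference-tissue models are out of
  scope — the blocking data themselves show no valid reference region for
  this tracer.
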