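---
title: "Competing instabilities of thin active nematic elastomers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing instabilities of thin active nematic elastomers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activegel)
```

## The physical system and the model

A crosslinked microtubule–kinesin network confined to a thin, flat channel
behaves as a sheet of *active nematic elastomer*: the filaments are
orientationally ordered along the channel axis, permanently crosslinked
into a soft solid, and driven by ATP-consuming motor clusters that exert
extensile dipolar stresses.  Such a sheet can lose stability in two
distinct ways,

* an **in-plane bend** of the displacement component transverse to the
  alignment (the generic instability of extensile active nematics), or
* an **out-of-plane buckle** of the height field, the active analogue of
  Euler buckling.

For small deformations $\vec u = (u_x, u_y, h)$ varying along the
alignment direction $x$, the elastic free energy per unit width is

$$\mathcal F = \tfrac12 \int \mathrm dx\,
  \Big[\nu (\partial_x u_x)^2 + \mu (\partial_x u_y)^2 +
  \kappa (\partial_x^2 h)^2 +
  K\big[(\partial_x^2 u_y)^2 + (\partial_x^2 h)^2\big]\Big],$$

with $\nu$ the effective bulk modulus (Pa), $\mu$ the shear modulus (Pa),
$\kappa$ the bending modulus (Pa µm²) and $K$ the nematic elasticity
(Pa µm²).  Units are fixed package-wide to Pa, µm, s.  Balancing the
destabilising active force $\zeta\,\nabla\!\cdot\!(\vec n\,\vec n)$
against the elastic restoring force and a friction $-\gamma\,\partial_t
\vec u$ gives overdamped, linear dynamics whose Fourier modes
$e^{iqx}$ grow at

$$\sigma_y(q) = \frac{(\zeta-\mu)q^2 - Kq^4}{\gamma}, \qquad
  \sigma_h(q) = \frac{\zeta q^2 - (K+\kappa)q^4}{\gamma}.$$

`growth_rate_in_plane()` and `growth_rate_out_of_plane()` implement these
directly; `most_unstable_mode()` maximises them in closed form
($q^*_y = \sqrt{(\zeta-\mu)/2K}$, $\sigma^*_y = (\zeta-\mu)^2/4\gamma K$,
and the analogous expressions with $\zeta$ and $K+\kappa$ for the height
branch).  The structure of the competition is:

* height modes grow at *any* non-zero activity;
* bend modes require $\zeta > \mu$;
* when both grow, the bend wins once
  $\zeta/\mu > \left[1 - (1+\kappa/K)^{-1/2}\right]^{-1}$
  (`critical_activity_ratio()`).

`classify_regime()` returns the resulting three regimes.  Exactly on the
boundary the out-of-plane label is kept, consistent with the strict
inequality that defines the in-plane regime.  Two degenerate limits are
refused rather than silently extrapolated: $\mu = 0$ (the theory becomes
that of an active fluid and the regime structure is undefined) and a
vanishing quartic stiffness on an unstable branch (growth is unbounded at
$q \to \infty$; the continuum description has lost its cutoff).  The bulk
modulus $\nu$ is carried in `elastomer_params()` because it enters the
free energy through the (always stable) axial mode; it never affects
stability.  Whether $\nu$ and $\kappa$ need anisotropic corrections from
the nematic order is not decidable at this level of description; the
isotropically parameterised form is used.

The friction $\gamma$ is a free timescale: no published value exists for
this system, and every direction prediction is invariant under
$\gamma \to c\gamma$ (asserted in the tests).  It defaults to 1 Pa s µm⁻².

## From molecular composition to mechanics

The kinetics module maps $([\mathrm{ATP}], [\mathrm{motors}],
[\mathrm{PRC1}], L)$ — µM, nM, nM, µm — onto $(\zeta, \mu, \kappa, K)$:

* **Activity.**  Motor stepping follows Michaelis–Menten kinetics in ATP,
  $f = [\mathrm{ATP}]/(K_M + [\mathrm{ATP}])$, and the extensile stress is
  proportional to the stepping motors:
  $\zeta = \zeta_0\,[\mathrm{motors}]\,f$.
  $K_M$ defaults to 30 µM, a representative value for kinesin-1; it is a
  configurable constant, not a fitted parameter.
* **Crosslinking.**  Motors that are not stepping act as passive
  crosslinkers, and only a fraction $p_0$ of the PRC1 is functionally
  active, so $[\mathrm{XL}] = p_0[\mathrm{PRC1}] +
  [\mathrm{motors}](1-f)$.  Using the Michaelis–Menten occupancy for the
  stepping fraction is this package's sub-model choice; it is the
  simplest closure consistent with the saturation of the activity and
  with the observation that motors crosslink rather than slide at
  vanishing ATP.
* **Moduli.**  For crosslinked networks above the isostatic point,
  $\mu = \mu_0[\mathrm{XL}]^2$ and $\kappa = \kappa_0[\mathrm{XL}]^2$.
  The quadratic exponent is fixed (it is an empirical scaling law for
  this class of networks), so $\kappa/\mu$ is composition-independent.
* **Nematic elasticity.**  $K = K_0 L^a$ with $a = 2$ by default.  The
  correct length scaling for a microtubule nematic elastomer is genuinely
  ambiguous, so $a$ is exposed as `length_exponent` rather than
  hard-coded.

This map produces the two non-trivial experimental signatures: softening
with ATP (more fuel converts crosslinking motors into stress generators)
and the **re-entrant** out-of-plane → in-plane → out-of-plane sequence as
motor concentration rises at limiting ATP, because added motors first
raise $\zeta$ linearly but eventually dominate $[\mathrm{XL}]$, whose
square wins.  The maximiser of $\zeta/\mu$ over motors is
$p_0[\mathrm{PRC1}]/(1-f)$, verified in the tests against numerical
optimisation.

Only $\zeta_0/\mu_0$, $K_0/\kappa_0$, $\kappa_0/\zeta_0$ and $p_0$ affect
direction predictions; a common rescaling of all four prefactors rescales
stresses only.  `kinetic_constants_from_ratios()` builds a full constant
set from the identifiable ratios with $\zeta_0 = 1$.

## Phase diagrams and boundaries

`predict_grid()` classifies every cell of a two-axis composition grid;
cells with $\zeta = 0$ (no ATP or no motors) are labelled `"stable"`, a
state the instability diagrams cannot show but zero fuel implies.
`boundary_trace()` locates the in/out boundary by per-scan-line bisection
on the sign of $\sigma_y^* - \sigma_h^*$ rather than by contouring: scan
lines are robust for re-entrant boundaries, which cross a line twice, and
the number of crossings sought is explicit (`max_crossings`, default 2).
Every returned point satisfies the closed-form condition
$\zeta/\mu = [1-(1+\kappa/K)^{-1/2}]^{-1}$ to the same tolerance, which
the tests assert.

## Exact spectral dynamics

Because the linearised dynamics are diagonal in $q$, `evolve()` advances
each Fourier mode by its exact propagator
$\hat u(q, t_1) = \hat u(q, t_0)\,e^{\sigma(q)(t_1 - t_0)}$.  There is no
time-discretisation error, which is the point: the simulator is a
trustworthy numerical oracle for the closed-form results rather than a
second approximation.  Growth is unbounded (linear theory makes no claim
past the linear regime), so runs are capped by an overflow guard (a
present mode reaching $e^{700}$ raises an error) instead of an ad-hoc
saturation.  Boundaries are periodic; the channel walls of the experiment
are not modelled, matching the wall-free linear analysis.

`dominant_wavelength()` reads the emergent wavelength from the power
spectrum (parabolic interpolation of log-power around the peak, $q = 0$
excluded).  A single noise realisation can misplace the peak by more than
a bin when the dispersion curve is nearly flat across neighbouring bins,
so `ensemble_dominant_wavelength()` measures the way a repeated
experiment would: fixed log-amplification ($e^{300}$ at the fastest mode)
and an average of power spectra over independent noise seeds.  With 10
seeds on the default 512-point, 256 µm grid this recovers the analytic
$\lambda^* = 2\pi/q^*$ to within one spectral bin across random parameter
draws (asserted in the tests at 20 draws).

## The blurriness statistic

Widefield fluorescence collapses the third dimension: material that
buckles out of the focal plane appears *out of focus*.  The blurriness
$B \in [0, 1]$ is the area fraction of the image segmented as
out-of-focus; $B \le 0.05$ is classified in-plane, $B > 0.5$
out-of-plane, intermediate values as a superposition of both modes.  The
0.05 floor replaces the idealised "exactly zero" of a noiseless
description.

Segmentation pipeline (all knobs exposed):

1. **Focus score**: variance of the Laplacian-of-Gaussian response in a
   15 px box window.  The σ = 1 px pre-smoothing suppresses shot noise,
   which survives defocus and would otherwise dominate the Laplacian in
   blurred regions; bundle-scale structure is barely attenuated.
2. **Normalisation**: for cross-image comparisons the score is divided by
   the squared mean intensity.  The mean is preserved by a normalised
   defocus kernel and scales linearly with exposure, so this is invariant
   both to global intensity rescaling and to the defocus itself — unlike
   the image variance, which defocus collapses.
3. **Threshold**: Otsu's method on the log-score histogram (the two score
   populations are roughly log-normal), with a floor: pixels whose
   normalised score exceeds the calibrated sharp reference are never
   called out-of-focus.
4. **Bias correction**: the sliding window calls any pixel within half a
   window of sharp structure "in focus", dilating the sharp region by a
   predictable margin; the out-of-focus mask is therefore dilated back by
   a disc of the window half-width.  On synthetic composites this reduces
   the systematic area error from ≈ 0.05 to < 0.01.
5. **Degenerate histograms**: an all-sharp or all-defocused frame has a
   unimodal score histogram (dynamic range below a 50× spread), where any
   relative threshold is meaningless.  These are resolved by comparing
   the median normalised score against a reference calibrated once on the
   package's own synthetic sharp and defocused fixtures, and the result
   is flagged `low_confidence`.

For time series, `blurriness_series()` freezes the normalisation and the
threshold across frames (pooled log scores, percentiles anchored on the
first frame) so that trends in $B(t)$ reflect the sample, not the
segmentation.

## Synthetic data as ground truth

All pipeline inputs can be generated with known truth
(`generate_phase_observations()`, `generate_bundle_image()`,
`generate_growth_series()`), seeded and bitwise-reproducible.

The default study conditions (`default_generator_config()`) mirror the
standard scans for this system: ATP × PRC1 at 60 nM motors, motors ×
PRC1 at 1 mM ATP, ATP × motors at 100 nM PRC1, and microtubule length ×
motors at 8 µM ATP / 100 nM PRC1, with axes spanning ATP 1–1500 µM
(log), motors 5–200 nM, PRC1 10–500 nM, length 0.5–10 µm.  The planted
kinetic truth — $\zeta_0/\mu_0 = 1200$, $K_0/\kappa_0 = 200$,
$\kappa_0/\zeta_0 = 0.5$, $p_0 = 0.6$ — was chosen once, by scanning the
ratio plane for the qualitative structure the experiments show: the
in/out boundary inside the ATP × PRC1 window, a re-entrant out–in–out
band along the motor axis at limiting ATP with the fluid extremum near
70 nM motors, a bend-to-buckle transition with increasing filament
length, and instability wavelengths of tens of µm.  These defaults are
the study conditions, not tuning knobs.

Blurriness readouts are drawn from Beta distributions centred at
regime-typical values (0.02 in-plane, 0.65 out-of-plane, concentration
50); cells whose two growth rates are within $e^{\pm 0.4}$ of each other
draw from a mixed band at 0.3.  The Beta noise law is a stand-in — the
experiments report $B$ ranges qualitatively, not a noise model.
Wavelength observations carry lognormal noise (sdlog 0.2).

The image generator composes an anisotropic striped bundle texture
(period 9 px, smooth undulations, fine speckle) with its Gaussian-defocused
copy (σ = 8 px) inside a smooth random region of exactly the requested
area fraction, then adds Poisson-like shot noise.  It emulates the
defocus signature of buckling, not microscopy itself: no optics model, no
depth continuum, no photobleaching; a defocused *region* stands in for
gradually escaping material.  Passing blurriness tests therefore
establish that the statistic measures out-of-focus area accurately and
scale-invariantly, not that it would be unbiased on any particular
microscope.

## Bayesian inference of the kinetic parameters

`run_mcmc()` estimates $\theta = (\log \zeta_0/\mu_0, \log K_0/\kappa_0,
\log \kappa_0/\zeta_0, \mathrm{logit}\,p_0)$ from phase observations.
The likelihood (this package's construction; the choices below are design
decisions, documented here):

* **Direction channel**: each observation is reduced to $y = 1$ (out,
  $B > 0.5$), $y = 0$ (in, $B \le 0.05$) or mixed (down-weighted 0.5,
  labelled by the nearer threshold), and modelled as Bernoulli with
  $P(\mathrm{out}) = \mathrm{logistic}\!\left(s \log
  \sigma_h^*/\sigma_y^*\right)$, $s = 5$.  When only the height branch
  grows, $P(\mathrm{out}) = 1 - \varepsilon$; when neither does, $1/2$.
* **Wavelength channel**: a Gaussian on $\log \lambda$ with
  $\sigma_\lambda = 0.2$, as a *mixture* over the two branch wavelengths
  weighted by $P(\mathrm{out})$.  A hard Gaussian at the winning branch's
  wavelength makes the log-posterior jump by several nats whenever a
  cell's winning branch flips as $\theta$ moves, leaving the surface
  riddled with row-level steps that trap random-walk chains; the mixture
  is continuous and sampled cleanly in our checks (split-$\hat R$
  ≈ 1.005 versus ≈ 1.7 for the hard version).
* $s$ and $\sigma_\lambda$ are fixed hyperparameters, not sampled,
  keeping the four-parameter structure of the theory.

Priors are log-uniform over six decades ($10^{-2}$–$10^{4}$) for the
three ratios and uniform(0, 1) for $p_0$.  The sampler is an adaptive
random-walk Metropolis (running-covariance proposal, global scale tuned
toward 0.234 acceptance), with all adaptation confined to the discarded
first half.  Because the posterior typically occupies a vanishing
fraction of the prior volume, chains start near a multistart posterior
mode (best of 100 prior draws, top 5 refined by Nelder–Mead) rather than
from the prior bulk; with an empty data set the optimiser is skipped and
the sampler reproduces the prior (tested by Kolmogorov–Smirnov distance).
Convergence is reported per parameter as split-$\hat R$, with warnings
above 1.1.

Validation is by parameter recovery: on synthetic four-panel studies
(10 × 10 cells per panel) with the planted truth above, 95% credible
intervals cover every component in ≥ 90% of 20 seeded repetitions with
scaled-down chains (4 × 5000 steps) — the acceptance suite runs exactly
this.  `posterior_predictive_boundary()` propagates posterior draws
through the boundary tracer to give pointwise 2.5/50/97.5% boundary
bands.

## Numerical choices and limitations

* Problem sizes in the tests — 512-point spectral grids, 512² px images,
  10 × 10 × 4 observation tables, 4 × 5000-step chains — were chosen as
  the smallest sizes at which each check is statistically meaningful.
* Absolute stress calibration (activities in Pa, transition
  concentrations for a specific preparation) requires experimental
  source data and an absolute $\mu_0$ from bulk rheology; it is out of
  scope here, and $\mu_0$ enters only through ratios.
* The model is quasistatic and linear: no post-instability dynamics,
  defects or active turbulence, and no claim at amplitudes where
  linearity fails.
* Load-dependence of motor stepping and depletant-bundled network
  variants are deliberately not modelled.
* The in/out tie-break, the $B$ classification cutoffs, and the
  segmentation operator are documented conventions; alternatives would
  shift individual labels near boundaries but not the regime structure.
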