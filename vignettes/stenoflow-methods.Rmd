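---
title: "Methods: pulsatile non-Newtonian flow and wall indices in an idealized stenosed vessel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsatile non-Newtonian flow and wall indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoflow)
```

## What the package computes

`stenoflow` is a desk-scale pipeline for studying how arterial stenosis
severity reshapes the mechanical load on the vessel wall. It couples four
pieces:

1. a generalized-Newtonian rheology model (Carreau-Yasuda shear thinning);
2. a synthetic cardiac boundary-waveform generator;
3. an unsteady incompressible axisymmetric Navier-Stokes solver on an
   idealized stenosed vessel;
4. the wall-index chain WSS → TAWSS → OSI → RRT and a cross-severity
   report.

Each stage is exposed as ordinary R functions, so every intermediate object
(waveform, grid, flow solution, traction series, index profile) can be
inspected and tested on its own.

## Model and assumptions

The flow model is mass continuity plus momentum for an incompressible fluid
with a shear-dependent viscosity, in axisymmetric cylindrical coordinates
$(z, r)$:

$$\nabla\cdot\vec v = 0,\qquad
\rho\left(\partial_t \vec v + \vec v\cdot\nabla\vec v\right)
 = -\nabla p + \nabla\cdot\big(\mu(\dot\gamma)\,\nabla \vec v\big)_{\!ax},$$

with no-slip rigid walls, a prescribed velocity profile at the inlet, a
prescribed pressure at the outlet, and no body forces. Dropping gravity is
harmless here: in rigid incompressible flow it only shifts the pressure
hydrostatically and leaves velocities and wall shear unchanged. The flow is
treated as laminar throughout — adequate for wall-shear and TAWSS
assessment in this regime, and the package makes no attempt at transition
or turbulence modelling.

Two deliberate simplifications of the viscous stress are worth stating
precisely, because they bound where the solver is quantitatively trustworthy:

* the component-wise generalized-Laplacian form
  $\nabla\cdot(\mu\nabla u_i)$ (plus the axisymmetric hoop term
  $-\mu u_r/r^2$) is used instead of the full
  $\nabla\cdot\mu(\nabla\vec v + \nabla\vec v^{T})$. The dropped
  transpose-gradient term is identically zero for constant viscosity
  (it reduces to $\mu\nabla(\nabla\cdot\vec v)$) and vanishes for fully
  developed generalized-Newtonian tube flow, so every quantitative oracle in
  the test suite is unaffected; in the stenosis bump it is $O(\nabla\mu)$
  and small against the advection terms that dominate there;
* in the mapped coordinates described below, the metric cross-derivatives
  of the *axial* diffusion term are dropped. They vanish identically in
  straight sections ($R'(z)=0$) and are $O(R'^2)$ on the bump.

The shear-rate magnitude fed to the viscosity law is the frame-invariant
second invariant $\dot\gamma = \sqrt{2\,D\!:\!D}$ with
$D = (\nabla\vec v + \nabla\vec v^T)/2$, computed with all four gradient
components plus the hoop strain $u_r/r$. A printed shorthand of the wall
stress that omits the invariant's summation and half factor is sometimes
seen in the applied literature; it is dimensionally inconsistent as a
tensor norm, so the package always uses the invariant form, which reduces
to $\partial u/\partial y$ in simple shear.

### Rheology

The Carreau-Yasuda law
$\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)\,
 (1+(\lambda\dot\gamma)^a)^{-(1-n)/a}$
uses the standard whole-blood constants
($\mu_0=0.056$, $\mu_\infty=0.0035$ Pa s, $\lambda=3.313$ s, $n=0.3568$,
$\rho = 1060$ kg/m³). The transition exponent defaults to $a=2$, the value
that collapses the law onto the classical Carreau blood fit these four
constants were estimated under; it is exposed in the configuration for
sensitivity studies. The law is monotone non-increasing, bounded by
$(\mu_\infty, \mu_0]$, and degenerates to a Newtonian fluid when
$\mu_0=\mu_\infty$ — all three properties are asserted by tests.

### Geometry and severity convention

The vessel is an axisymmetric cylinder of radius $R_0$ with a smooth
cosine bump: $r_w(z) = R_0\sqrt{1 - S\,b(z)}$, where $b$ is a raised cosine
of compact support $L_s$ centred at $z_c$ and $S$ is the **area** severity:
the throat area is exactly $(1-S)$ times the inlet area. Area severity
(rather than diameter severity) is the convention that makes the continuity
estimate of throat velocity amplification equal $1/(1-S)$ — i.e. a factor
of two at 50% blockage — which is the yardstick the severity sweep is
judged against. The cosine bump is $C^1$, and the healthy sections are
exactly cylindrical (a Gaussian bump would not be), which keeps the
straight-tube oracles exact.

Defaults (all configurable): $R_0 = 2$ mm, length 40 mm, $z_c = 20$ mm,
$L_s = 6$ mm — a plaque length at the upper end of the few-millimetre
lesions the severity grid targets; severities $\{0, 0.25, 0.35, 0.50,
0.65\}$.

### Boundary waveforms

No tabulated physiological waveforms ship with the package; the generator
produces parametric shape emulations with every constant exposed:

* **inlet velocity** (cross-section mean, m/s): a $\sin^2$ systolic
  ejection bump of height `peak_velocity` occupying
  `systolic_time_fraction` of the cycle, followed by a brief negative notch
  of depth `reverse_fraction × peak_velocity` (the early-diastolic
  reverse-flow notch of arterial flow), then zero diastolic flow. The
  waveform is $C^1$ and its cycle mean is strictly positive.
* **outlet pressure** (mmHg): $p = p_{dia} + (p_{sys}-p_{dia})
  \sin^2(\pi u(t))$ with the monotone phase warp
  $u = t/T + \kappa\sin(2\pi t/T)/2\pi$. The extremes are attained
  *exactly* ($p_{sys}$ at $t = T/2$, $p_{dia}$ at $t=0$), the waveform is
  smooth, and $\kappa$ (default 0.45) skews the peak toward early systole.

Defaults: 70 bpm (period $60/70 \approx 0.857$ s), peak mean velocity
0.4 m/s, reverse fraction 0.15, 120/80 mmHg. These emulate the *shape*
features of aortic-root boundary data (single systolic peak, reverse-flow
notch, pulse pressure); they are not a fit to any patient. Pressures are
mmHg at the interface (clinical convention) and Pa internally
(1 mmHg = 133.322 Pa).

The same module generates analytic wall-traction fixtures (`constant`,
`reversing`, `offset_sine`, `rotating`) so the index chain is testable
without running the solver; the constant and reversing patterns realize the
OSI endpoints 0 and 0.5 exactly.

## Numerical scheme

### Discretization

The half-plane $(z, r)$ is mapped to a rectangle by $\eta = r/r_w(z)$, and
discretized with a staggered (MAC-type) arrangement: pressure at cell
centers, axial velocity on vertical faces, radial velocity on mapped
horizontal faces. Radial faces follow a smooth tanh clustering toward the
wall; the `growth_rate` parameter (default 1.2, the conventional boundary
layer growth ratio) sets the stretching strength, and the mapping is a
fixed smooth function of the index fraction, so grid-refinement studies
refine a self-similar family — a prerequisite for clean observed-order
estimates.

Key discrete design points:

* **Divergence**: the exact finite-volume net volume flux of each annular
  cell in *physical* space. Slanted $\eta$-faces carry the appropriate
  $u_z$ contribution where the wall slopes, and wall/axis faces carry none
  (no-slip rigid wall, zero radius).
* **Gradient**: the mapped-coordinate physical pressure gradient at each
  velocity point, with zero rows at Dirichlet velocity DOFs and an affine
  part for the Dirichlet outlet pressure.
* **Projection**: the pressure-correction Poisson operator is assembled as
  the sparse *product* of those two operators and LU-factored once per
  grid. Because the correction uses the same discrete gradient, the
  post-projection divergence is zero to linear-solver precision — the
  inflow/outflow balance of every run sits at round-off
  (about $10^{-13}$ of peak flow in the test fixtures), regardless of
  truncation error elsewhere.
* **Time stepping**: second-order implicit BDF2 with a backward-Euler
  startup step; default $\Delta t = 0.01$ s, the step used for the
  transient cardiac analyses this pipeline mirrors.
* **Advection**: implicit first-order upwind in the mapped coordinates.
  Robust at the throat-jet CFL numbers of severe stenoses; its numerical
  diffusion is the main reason the *centerline* velocity at the throat is
  flatter than the physical jet (see "Amplification" below). It does not
  affect the fully developed oracles, where the advection terms vanish
  identically.
* **Wall fluxes**: the viscous wall flux and the wall-shear extraction both
  use one-sided quadratic stencils through the two outermost rings and the
  no-slip wall value; both are exact for parabolic profiles. On a uniform
  radial grid the discrete steady Poiseuille solution is then exact to
  solver precision; on the clustered default family the centerline error
  converges at observed order ≈ 2 (the suite asserts ≥ 1.8).

### Picard iteration for the nonlinearities

Within each step the viscosity field (and the advecting field it rides on)
is lagged and re-solved: apparent viscosity is evaluated from the current
shear-rate field, under-relaxed with factor 0.3, the momentum systems are
re-assembled and re-solved, and the loop stops when the relative L2-norm
change of the viscosity field drops below `picard_tol` (default 0.1);
exceeding `max_inner_iterations` is a hard error that names the residual.

The tolerance is deliberately normwise. In thin annuli where the wall
shear passes through zero (flow reversal during systolic deceleration) the
pointwise feedback loop between $\dot\gamma$ and $\mu$ of a strongly
shear-thinning law has gain above one near the $\lambda\dot\gamma \approx
1$ knee and oscillates instead of contracting, whatever the damping — while
the induced change of the *velocity* iterate is two orders of magnitude
smaller and still shrinking. At the default tolerance the measured relative
velocity-iterate change is below $5\times10^{-3}$, far below spatial
truncation error at the default resolution. Newtonian runs bypass the loop
(one linearized solve).

### Steady initialization and cycle count

Each pulsatile run starts from a steady solve at the cycle-mean inflow
(pseudo-time backward Euler, relative-change tolerance $10^{-5}$), then
marches `n_cycles` cardiac cycles and post-processes only the final one.
The default of three cycles washes out the start-up transient: the
cycle-to-cycle periodicity residual (normalized L2 difference of the axial
velocity between the last two cycles at matched phases) is reported with
every solution and sits near $2\times10^{-3}$ at default settings; a
residual above `periodicity_warn` (2%) is recorded as a warning in the
solution metadata, not an error.

### Wall traction and indices

Wall shear stress at each axial station is
$\tau_w = \mu(|\partial u_t/\partial n|)\,\partial u_t/\partial n$
evaluated at the wall, signed along the downstream wall tangent
(axisymmetry makes the circumferential component zero). One hundred
uniformly spaced instants of the final cycle are exported — the
conventional per-cycle WSS sampling for index computation — by linear
interpolation in time between stored steps.

TAWSS and OSI integrate that series with the composite trapezoid rule with
periodic closure, which on a uniform grid over one period reduces to the
sample mean (and integrates any pure harmonic exactly — that is why the OSI
endpoints come out exact on the analytic fixtures). RRT is singular where
OSI → 0.5; positions with $(1-2\,\mathrm{OSI}) < \varepsilon$ (default
$10^{-3}$) are *flagged* and reported at the capped value
$1/(\varepsilon\,\mathrm{TAWSS})$, so tabular outputs stay finite while
downstream summaries can exclude (and count) the singular zones, which are
exactly the high-residence-time regions of interest. Zero-traction
positions return OSI 0 by convention, keeping the range invariant testable.

## The severity experiment

`run_severity_sweep()` runs the healthy vessel plus each requested severity
with identical waveforms and resolution and reports, per severity: peak
throat velocity and its amplification over healthy, inlet-probe pressure at
peak systole / mid-diastole / end diastole, TAWSS and OSI maxima, RRT order
statistics with flag counts, and the periodicity residual; a Spearman rank
correlation between systolic pressure and maximal RRT across severities is
attached (n is small — five severities — so no significance testing is
attempted, deliberately).

Definitions decided here (the underlying phase conventions have no unique
standard):

* **Amplification** is measured on the *bulk* (cross-section mean) velocity
  at the throat station. That is the quantity incompressible continuity
  governs — identical inlet flow-rate waveforms through an area reduced by
  $(1-S)$ give a peak ratio of $1/(1-S)$: 1.54 at 35%, 2.00 at 50%, 2.86 at
  65% — so "beyond half blockage the peak doubles" is reproduced with its
  mechanism explicit. The centerline velocity is recorded alongside; its
  ratio is systematically smaller because the accelerating jet flattens the
  profile (physically, and additionally through upwind diffusion at
  desk-scale resolution), which is why it is not the reported metric.
* **Mid-diastole** has no formulaic definition in clinical waveform
  descriptions; it is taken as the temporal midpoint of the diastolic
  interval, whose start is a configurable decay fraction (default 0.15 of
  the cycle) after the systolic peak and whose end is the cycle end.
* **Probes** default to the inlet plane, the throat plane, and one diameter
  downstream of the bump — analogues of ascending-aorta, blockage and
  distal measurement points; with an idealized geometry these are
  analogues, not replications of any patient's landmarks.

Everything is deterministic: no RNG enters the pipeline, and identical
configurations produce bit-identical `report.csv` files (asserted by the
suite).

## Problem sizes and defaults

The default grid is 96 axial × 24 radial cells with three cardiac cycles at
$\Delta t = 0.01$ s — the resolution at which the full five-severity sweep
completes in a few minutes on one CPU while keeping the verification
oracles comfortably within their tolerances (Poiseuille wall shear within
0.4% at 16 radial cells; Womersley at $\alpha = 4$ within 0.1% relative L2
at 32 radial cells). The test suite uses coarser grids (down to 32 × 12)
for pipeline-level properties that do not require resolved physics.

## What the synthetic conditions do and do not show

The waveform generator emulates shape features, not patient data: passing
tests demonstrate that the solver and index chain behave correctly under
physiologically *shaped* forcing, that severity trends follow the
continuity mechanism, and that the index definitions are implemented
exactly. They do not validate against any measured pressure or velocity
record, and the idealized axisymmetric geometry cannot reproduce
patient-specific magnitudes (aortic-arch branch flows, asymmetric plaques,
secondary curvature flows, catheter-measured pressures). Known limitations,
summarized:

* axisymmetric single-outlet geometry; no arch branches or eccentric
  plaques;
* rigid walls (no fluid-structure interaction) and laminar flow only;
* first-order upwind advection smears the throat jet at default
  resolution — trends and bulk quantities are reliable, pointwise jet
  magnitudes are resolution-dependent;
* the OSI/RRT fields downstream of a severe bump sit near the OSI = 0.5
  singularity, where RRT is reported through the epsilon-cap convention
  described above;
* the Womersley oracle's complex Bessel function is evaluated by power
  series, accurate for Womersley numbers up to about 15 — beyond any value
  reachable with the package's vessel radii and heart rates.
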