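---
title: "Phase-field thrombus biomechanics: model, calibration, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-field thrombus biomechanics: model, calibration, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

thromboflow models the mechanical interaction between flowing blood and a
thrombus (a blood clot) as a two-phase continuum. A single phase variable
$\phi$ marks flowing blood ($\phi = 1$), thrombus ($\phi = 0$), and a thin
diffuse interface in between. The clot is porous — interstitial plasma
percolates through its fibrin network — and viscoelastic, with a
Kelvin–Voigt (parallel spring–dashpot) response whose spring is a
neo-Hookean elastic network tracked in the Eulerian frame. This vignette
describes the model, its parameters, the two virtual calibration
experiments, the numerical choices, and the limitations of what the test
suite demonstrates.

## The coupled model

The free energy of the blood–thrombus mixture is the Cahn–Hilliard mixing
energy plus the elastic energy of the network:

$$E = \int_\Omega \Big[\tfrac{\lambda}{2}|\nabla\phi|^2 +
\tfrac{\lambda}{2h^2}\phi^2(\phi-1)^2\Big]\,dx +
\int_\Omega \tfrac{\lambda_e}{2}\,\mathrm{tr}(F^TF - I)\,dx,$$

where $\lambda$ is the mixing energy density, $h$ the interface
thickness, $\lambda_e$ the elastic shear modulus, and $F$ the Eulerian
deformation gradient. The governing system couples

* incompressible momentum balance with three phase-dependent forces: the
  divergence of the neo-Hookean stress
  $\lambda_e(1-\phi)(FF^T - I)$, the capillary force
  $-\lambda\nabla\cdot(\nabla\phi\otimes\nabla\phi)$, and the
  Darcy–Brinkman interstitial drag $-\eta(\phi)(1-\phi)\,u/\kappa(\phi)$;
* transport of the deformation gradient,
  $\partial_t F + u\cdot\nabla F = (\nabla u)F$ with
  $(\nabla u)_{ij} = \partial u_i/\partial x_j$ (in 2D a two-component
  curl potential $\psi$ is advected instead, with $F$ recovered as the
  per-component curl);
* a conservative Cahn–Hilliard equation
  $\partial_t\phi + u\cdot\nabla\phi = \tau\Delta\mu$, with
  $\mu = -\lambda\Delta\phi + \lambda\gamma\,g_1(\phi) +
  \tfrac{\lambda_e}{2}\mathrm{tr}(F^TF-I)$ and
  $g_1(\phi) = \phi(\phi-1)(2\phi-1)/h^2$.

Mixture density and viscosity are linear blends between the blood and
thrombus endpoint values (the blend law is a documented, swappable
choice; nothing in the formulation pins it down). Permeability follows
either a shell–core assignment (geometric masks with $\kappa_s$,
$\kappa_c$) or Davies' law for fibrous beds,
$\kappa/a_f^2 = [16\,\Psi_f^{1.5}(1 + 56\,\Psi_f^3)]^{-1}$, evaluated at
the local solid fraction $\Psi_f = 1-\phi$.

### Conventions worth stating once

* **Volume fraction.** The bulk thrombus volume fraction is
  $\int(1-\phi)\,dv / V$ for $\phi\in[0,1]$. The alternative
  normalization $\int(1-\phi)/2\,dv/V$ (which presumes
  $\phi\in[-1,1]$) is retained as `as_printed` for comparison, but it
  cannot produce volume fractions above $1/2$ and is not the default.
* **Interface profile.** For the $[0,1]$ double well used here the 1D
  equilibrium profile is $\phi = \tfrac12(1+\tanh(d/2h))$ — width $2h$,
  not $\sqrt2 h$ — and its mixing energy per unit interface area is
  $\lambda/(6h)$. The companion relation
  $\lambda = \tfrac{3}{2\sqrt2}\sigma h$ is the classical result for a
  $\phi\in[-1,1]$ well; both are implemented exactly as written, which
  means $\sigma$ should be read as a *parameter* of the energy rather
  than the literal interface tension of this functional. Initial
  interfaces use the true equilibrium width $2h$.
* **Curl potential.** The advected potential carries Lagrangian labels
  $(Y, -X)$, and inverting the label gradient at unit Jacobian gives
  $F$ column-wise: column $j$ of $F$ is the curl of $\psi_j$. This is
  the unique convention under which advancing $\psi$ and transporting
  $F$ directly commute (verified against the closed-form simple-shear
  solution, where $F_{12} = \dot\gamma t$).

## Parameters and defaults

| parameter | meaning | default | notes |
|---|---|---|---|
| $\rho_1,\rho_2$ | blood/thrombus density | 1, 2 | ratios 1–10 across scenarios |
| $\eta_1,\eta_2$ | blood/thrombus viscosity | 1, 2 | ratio 2 in the calibrations |
| $\sigma$, $h$ | surface tension, interface width | $10^{-3}$, $2\,\max\Delta x$ | $\sigma$ has negligible mechanical effect |
| $\gamma$ | interfacial mobility factor | 1 | multiplies $g_1$ in $\mu$, verbatim |
| $\tau$ | phase mobility | $10^{-5}$ | see below |
| $\kappa_s,\kappa_c$ | shell/core permeability | $10^{-2}$, $10^{-4}$ | shell–core mode |
| $a_f$ | fibrin fiber radius | 1 | cancels in $\kappa/a_f^2$ plots |
| $\rho_{Fbg}$ | fibrinogen molecular density | 1.4 g/mL | fibrin fraction relation |

The phase mobility $\tau$ is never stated in the source material. It
multiplies $\Delta\mu$, and $\mu$ contains the elastic energy density;
at the calibrated moduli ($\lambda_e \sim 40$ nondimensional) a mobility
of order one would let elastic energy gradients redistribute the phase
field on the flow time scale, which destroys any prescribed clot within
a few steps. We use $\tau = 10^{-5}$, the standard nondimensional
phase-field scaling at which interface relaxation is active but
elastic-driven phase transport is negligible over a cardiac cycle.

The fibrin volume-fraction relation
$\Psi_f = c_{Fbg} / [\rho_{Fbg}(0.015\log c_{Fbg} + 0.13)]$ is written
with an ambiguous logarithm; base 10 is the default (the companion
power-law fits in the same calibration are written in $\log_{10}$) and
the base is configurable. Its inverse (needed to map a volume fraction
back to a concentration) has no closed form and is computed by monotone
bisection over $c \in [10^{-3}, 10^3]$ mg/mL; the upper end must exceed
100 because the calibration volume fraction 0.5219 maps to
$c \approx 116$ mg/mL.

## Discretization

Uniform structured grids, node-centred, second-order centred finite
differences, with Fourier differentiation available on periodic axes.
All implicit operators are assembled in finite-volume (flux) form
`K = -W L` with trapezoid cell volumes `W`, which makes them symmetric
positive definite and gives discrete conservation (zero column sums)
for free. Every constant-coefficient operator is factorized once per
run (sparse Cholesky), so a time step costs a handful of triangular
solves.

One operator-split cycle advances, in order:

1. **Deformation transport** — explicit SSP-RK2 on the deviation
   $F - I$ (or $\psi$ minus the identity potential, whose advection
   source is the exact $(-v, u)$), with entropy-viscosity artificial
   diffusion. The entropy viscosity is capped by
   $\min(c_{max}h_{min}|u|,\; 0.2\,h_{min}^2/\Delta t)$ — the second
   term is the explicit diffusion stability bound, which matters on
   anisotropic grids — and applied through a compact flux-form stencil
   (a wide first-derivative-of-first-derivative stencil is blind to
   grid-scale sawtooth modes and cannot stabilize them).
2. **Phase update** — the advective part uses the same stabilized
   SSP-RK2 (plain forward-Euler centred advection is weakly unstable
   over long runs); the Cahn–Hilliard part is semi-implicit with the
   linear fourth-order operator implicit and the double-well term split
   with stabilization constant $S = \lambda\gamma/h^2$. With zero-flux
   boundaries and direct solves, $\int\phi$ is conserved to rounding.
   The phase field is never clipped; excursions beyond
   $[-0.05, 1.05]$ raise a warning and beyond $[-0.2, 1.2]$ abort
   (clipping would silently destroy mass conservation).
3. **Flow update** — velocity-correction projection. The maximum
   kinematic viscosity is implicit (constant-coefficient Helmholtz),
   the variable remainder explicit; the stiff Darcy drag is pointwise
   implicit (and folded into the matrix when the drag field is static:
   wall penalization, frozen clots). The elastic force is stabilized by
   a defect-correction stiffness shift
   $\Delta t\,\max(\lambda_e(1-\phi))/\rho_0$ added to the implicit
   viscosity and subtracted explicitly: this removes the shear-wave
   time-step restriction with an $O(\Delta t^2)$ consistency error
   (von-Neumann-checked on the 1D shear-wave model). The incremental
   pressure projection uses the compact Poisson operator and runs
   `n_proj` passes (default 2); divergence is monitored every step
   against `div_tol`.

Curved geometries (circular vessel, fusiform aneurysm) are realized by
volume penalization: nodes outside the lumen receive a
$\phi$-independent drag with $\kappa_{wall} = 10^{-8}$, reusing the
Darcy term instead of body-fitted meshing. The deformation boundary
conditions are $F = I$ (identity potential) at the inflow and free
elsewhere; the outlet imposes zero pressure and zero-Neumann velocity.
Outlet conditions for $F$ are a convention, flagged in the scenario
config.

## The permeation chamber

A clot block spans the full cross-section of a channel
($6 \times 2 \times 1$, $z$ periodic) over $x \in [2,4]$, at uniform
volume fraction with Davies permeability. A parabolic inlet drives
Stokes-regime flow (Re = 0.02, set through $\eta_1$); the effective
permeability is $\kappa_{eff} = \bar v\,\eta_1 L_{clot}/\Delta P$ with
plane-averaged pressures sampled half a channel height up- and
downstream of the clot extent and $\bar v$ the superficial velocity.

Two choices here are load-bearing and were fixed by closed-form
Brinkman analysis before any simulation:

* **Spanwise boundary.** The source setup leaves the $z$ faces
  unstated. With no-slip $z$ walls, wall friction at the published volume
  fractions pushes $\kappa_{eff}$ 30–50% below Davies; with periodic
  $z$ the four published levels (0.33, 0.45, 0.57, 0.66) land within
  roughly 5–20% of Davies — the only reading consistent with the
  reported good agreement. Periodic $z$ is the default.
* **Rigid clots take sharp edges.** In frozen mode the phase field
  never evolves, so the block edges are one cell wide; smeared edges
  would inflate the measured clot length.

The deformable variant (`rigid = "none"`) is available and exercised in
the tests; the permeability curve itself uses the frozen mode, matching
the way the experiment isolates permeability.

## The oscillatory shear cell

A plate-gap cell: no-slip bottom plate, top plate moving at a
sinusoidal velocity, periodic in $x$. The sample fills the measuring
gap at uniform volume fraction (as a rheometry sample fills a plate
gap); a mid-channel slab flanked by fluid is available as a variant but
suffers edge stress relief at desk-scale aspect ratios. The recorded
loop is plate displacement (analytic integral of the plate law —
numerical quadrature would add a spurious phase) against the
area-averaged tangential traction on the contact patch, viscous plus
elastic contributions. The loop analysis is

$$\delta = \sin^{-1}\frac{4A_r}{\pi\,\Delta T_s\,\Delta d},\qquad
G' = \frac{\Delta T_s}{\Delta d}\cos\delta,\qquad
G'' = \frac{\Delta T_s}{\Delta d}\sin\delta,$$

with $\Delta T_s$, $\Delta d$ peak-to-peak (only then does the formula
recover an ellipse exactly: $\pi ab\sin\delta = \tfrac\pi4\Delta
T_s\Delta d\sin\delta$), and the Kelvin–Voigt relations
$G'' = 2\pi f(\eta_1 + \lambda_s G')$,
$\lambda_s = [G''/(2\pi f) - \eta_1]/G'$. The first cycle is discarded
and the next two are phase-folded and averaged (transient handling is
not prescribed by the source).

Three parameterization decisions, each from analysis done before the
calibration was run:

* **Frequency.** The published nondimensional plate law
  $0.2\sin(1.2\pi t)$ is inconsistent with the published scale registry
  ($U = 3.33\times10^{-3}$ m/s, $L = 3\times10^{-4}$ m at 0.5 Hz, which
  give $\omega_{nd} = 0.283$). At $\omega_{nd} = 1.2\pi$ the slab sits
  near its first shear-wave resonance ($kH \approx 1.2$ at the
  candidate moduli) and the measured moduli are inertia-dominated,
  while the published relaxation times ($\sim 3\times10^{-3}$ s) are
  quasi-static. The dimensional (quasi-static) law is therefore the
  default; the literal nondimensional law remains available.
* **Amplitude.** The published plate velocity implies a strain amplitude
  of about 0.7 across the gap, far outside the linear regime the loop
  analysis presumes (the underlying experiment used
  $\gamma_0 = 0.01$). The dimensional law uses $\gamma_0 = 0.01$;
  moduli are amplitude-independent in the linear regime, so this does
  not bias the result.
* **Drag.** No permeability is listed for the shear runs. With Davies
  drag at $\Psi_f = VF$ the slab anchors to the laboratory frame and
  the loss modulus becomes drag-dominated (relaxation times 50–200
  times the published ones); the cell therefore defaults to no
  interstitial drag.
* **Timestamp of the elastic traction.** The deformation update
  integrates the strain rate with a left-endpoint rule, so the elastic
  traction at step $k$ represents time $t_k - \Delta t/2$; averaging
  consecutive samples re-centres it. Without this correction a
  first-order phase bias contaminates the small quantity
  $G''/(2\pi f) - \eta_1$ that the relaxation time is built from.

So parameterized, the virtual rheometer is clean to cross-checks:
$G' = \lambda_e\,VF$ within 0.3% and $G''/\omega = \eta(\phi) = 1+VF$
within 0.5% of the closed-form Couette values. The extracted relaxation
time is then $(\eta_2-\eta_1)/\lambda_e$ — in dimensional terms
$\eta_1^{dim}/\lambda_e$, e.g. 2.3 ms at 0.44 Pa — and essentially flat
in fibrinogen concentration, because both the measured loss in excess
of the solvent and the measured stiffness are proportional to the
volume fraction. The candidate-selection step (least-squares
log-distance between each candidate's extrapolated
$\lambda_s(c_{Fbg})$ line and the experimental curve built from
$G' = 10\,c^{2.6}$ Pa and $G'' = 0.7\,c^{1.7}$ Pa over 1–6 mg/mL)
consequently selects the *softest* candidate, 0.22 Pa. The reference
calibration this pipeline emulates reports a concentration-*dependent*
relaxation time whose slope traces back to a small volume-
fraction-dependent excess loss that an ideal Kelvin–Voigt cell does not
produce; with flat candidate lines the least-squares criterion always
rewards the lowest modulus. We report what the model computes rather
than tune the cell toward a target.

## The aggregation front end

Coarse-grained platelets carry a three-state machine
(passive → triggered → activated, irreversible): contact with a
deposition site or an activated platelet triggers; activation follows
after the delay $\tau_{act} = 0.2$ s (range 0.1–0.3 s) and grows the
radius to $r_{eff} = 60\,r_p$ (pseudo-platelet: platelet plus
associated fibrin). Activated platelets interact through a Morse
attraction and exponential repulsion; deposition-site surface points
enter the force sum as fixed partners, so aggregates anchor at the
sites. Adhesion itself is contact stickiness — an activated platelet
touching a site or an adhered platelet freezes — because resolving the
stiff bound-state dynamics of calibrated adhesion springs under
explicit Euler would demand sub-stepping far below the transport step.
The stationarity rule (net displacement under 1/100 diameter per
cardiac cycle) is the per-cycle classifier for membership in the
thrombus.

The interaction constants are placeholders scaled to balance Stokes
drag at a reference wall shear rate: the shear-rate-resolved force
table of the original model is not public, and the two shear-rate bins
(attraction halved in the high-shear bin) mark where a real calibration
would slot in. Transport uses a quasi-steady carrier flow (a frozen
steady solve modulated by the cardiac waveform) — adequate at low
Womersley number and orders of magnitude cheaper than co-integrating
the flow; a desk-scale run uses hundreds of enlarged particles
($r_{eff}$ a few percent of the vessel diameter), not the physiological
count and size.

The handoff evaluates
$\Psi_{fcm}(x) = \sum_n V_p^n\,\Delta(x - Y^n)$ with a normalized
Gaussian envelope of width $\sigma_\Delta = r/\sqrt\pi$ (resolvable
envelopes enforced: at least 3 cells per $\sigma_\Delta$), scales it by
the composition factor $\Psi_f(c_{Fbg}) + \Psi_p(c_{plat})$, clips to
$[0,1)$ with the clipped fraction logged, and smooths
$\phi_0 = 1 - VF$ with conservative explicit diffusion over the
interface length (maximum-principle-safe, mass-preserving to
rounding).

The default inlet waveform is a truncated Fourier series (four cosine
modes of a von-Mises pulse, concentration 2): positive, mean equal to
its leading coefficient, systolic peak about 3.2 times the mean. It is
a generic pulse shape, deliberately not digitized from any figure.

## Problem sizes and determinism

The shipped tests and the acceptance script run at reduced scale chosen
as the coarsest resolutions at which each phenomenon is still clean:
oscillatory shear at $96\times32$ (tests: $48\times24$; the cell is
uniform in $x$, so $x$-resolution is immaterial), the permeability
curve at $96\times32\times16$, channel and vessel trend runs at
$48$–$72$ nodes axially, aggregation with 300 platelets over 4 cardiac
cycles. Every random draw flows from a single seed (platelet seeding
uses it directly; the solvers are deterministic), so end-to-end runs
reproduce bit-for-bit.

## What passing tests do and do not show

The generators emulate idealized geometries with prescribed shell–core
clots, Newtonian blood, rigid walls, and a frozen composition: no
fibrin polymerization kinetics, no strain stiffening, no blood-cell
suspension effects beyond the margination insertion profile, no
remodeling. Agreement with the closed-form oracles (Poiseuille,
Brinkman, Stokes layer, Couette moduli) validates the discretization;
the qualitative trend tests (shell deforms more than core, lumen
velocity rises as shell permeability falls, tip displacement grows with
inflow, aggregates localize at deposition sites) validate the coupled
physics at desk scale. None of this demonstrates quantitative fidelity
for patient-scale, high-Reynolds pulsatile runs, which are outside the
scope of this package.

## Known limitations

* The approximate (compact-stencil) projection leaves an $O(h^2)$
  divergence residual in strongly forced, under-resolved runs; the
  monitored norm is small in the conservation suite but visibly larger
  in coarse trend runs.
* First-order operator splitting: phase and deformation see the
  velocity one step behind; second-order splitting is not implemented.
* The Morse/repulsion constants are placeholder-calibrated; aggregate
  *locations* are meaningful, aggregate growth *rates* are not.
* The shear-cell relaxation-time pipeline inherits the
  measured-loss-minus-solvent structure of its defining formula, which
  is a small difference of near-equal quantities; it needs the
  half-step timestamp correction and a few hundred steps per cycle to
  be trustworthy, and its concentration dependence is structurally flat
  for an ideal Kelvin–Voigt sample (see the calibration section).
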