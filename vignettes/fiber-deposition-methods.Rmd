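---
title: "Methods: Lagrangian fiber-aerosol transport and deposition in synthetic airways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Lagrangian fiber-aerosol transport and deposition in synthetic airways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberdep)
```

## Scope and intent

`fiberdep` studies how the size and shape of elongated (fiber-like) aerosol
particles control where they deposit in the conducting airways during a
dry-powder-inhaler (DPI) inhalation maneuver.  Particles are prolate
spheroids characterized by two numbers: the volume-equivalent sphere
diameter $d_p$ and the aspect ratio $AR$ (major over minor semi-axis;
$AR = 1$ is a sphere).  The package builds *synthetic* airway domains — a
generic constricted-and-bent upper-airway analog and a symmetric
dichotomous bronchial tree — imposes analytic laminar velocity fields
scaled in time by the DPI waveform, tracks one-way-coupled particles under
drag, shear lift and gravity with quasi-steady rotational dynamics, and
reports deposition efficiencies (DE) and dispersion statistics over a grid
of $(d_p, AR)$ groups.

Everything here is a surrogate for resolved CFD in anatomical geometry:
the goal is a tested, reproducible pipeline whose *mechanistic*
ingredients (fiber aerodynamics, interception, sedimentation, impaction)
are each validated against closed-form results, not a claim of anatomical
fidelity.  The limitations section below is explicit about what does and
does not carry over.

## Fiber descriptors

A fiber group is defined by $d_p$, $AR$ and density $\rho_p$
(default 1000 kg/m$^3$, the unit-density aerosol convention).  Volume
equivalence fixes the semi-axes:
$$a_p = \tfrac{d_p}{2}\,AR^{-1/3},\qquad b_p = AR\,a_p,$$
so that $\tfrac43\pi a_p^2 b_p = \tfrac43\pi (d_p/2)^3$ exactly.  The
aerodynamic behaviour in the Stokes regime is summarized by the
Stokes-equivalent diameter
$$d_{Stk} = 2a_p\sqrt{\frac{AR\,\ln\!\big(AR+\sqrt{AR^2-1}\big)}
{\sqrt{AR^2-1}}},$$
whose $AR \to 1$ limit is $d_p$ (taken analytically by series near
$AR = 1$), the relaxation time
$t_0 = \rho_p d_{Stk}^2 / (18 \mu_{air})$ and the Stokes number
$Stk = t_0 u_0 / D$ with $u_0$ the peak inlet velocity and $D$ the inlet
diameter of a domain.  As $AR$ grows at fixed $d_p$, $d_{Stk}$, $t_0$ and
$Stk$ all decrease: elongated particles behave more like flow tracers.

## Forces and rotation

* **Drag** is the orientation-dependent Stokes resistance of a prolate
  spheroid (Oberbeck's elliptic-integral solution): with
  $e = \sqrt{1 - AR^{-2}}$ and $L = \ln\frac{1+e}{1-e}$,
  $$K_\parallel = \frac{16\pi b_p e^3}{(1+e^2)L - 2e},\qquad
    K_\perp = \frac{32\pi b_p e^3}{(3e^2-1)L + 2e},$$
  and $\mathbf F = \mu\,[K_\parallel \hat p\hat p^T + K_\perp(I -
  \hat p\hat p^T)]\,(\mathbf u - \mathbf v)$.  Both coefficients reduce to
  $3\pi d_p$ for a sphere; their ratio grows logarithmically toward 2 in
  the slender limit (it is about 1.66 at $AR = 100$ — the convergence is
  slow, as the package's tests document against independent slender-body
  asymptotics).
* **Rotation** follows quasi-steady Jeffery dynamics,
  $\dot{\hat p} = W\hat p + \lambda\,(S\hat p - (\hat p^T S\hat p)\hat p)$
  with $S, W$ the symmetric/antisymmetric parts of $\nabla u$ and
  $\lambda = (AR^2-1)/(AR^2+1)$.  Rotational inertia is neglected: for
  micron fibers the rotational relaxation time is far below every flow
  timescale here, so the orientation is slaved to the local velocity
  gradient.  In simple shear this produces the classical tumbling orbit
  with period $T = 2\pi(AR + 1/AR)/\dot\gamma$, which the test suite
  reproduces within 1% for $AR \in \{3, 10, 30\}$.
* **Lift** is a Saffman-type shear-induced force evaluated with $d_{Stk}$
  as the particle length scale,
  $\mathbf F_L = 1.615\,\mu\,d_{Stk}^2\,
  (\mathbf u_{rel}\times\boldsymbol\omega)/\sqrt{\nu|\boldsymbol\omega|}$,
  exactly zero in uniform flow or at zero slip, and pushing a lagging
  particle toward faster fluid.  The lift model sits behind a flag
  (`lift` in `track_options()`) so an orientation-resolved form can be
  substituted.
* **Gravity** acts along a configurable unit vector per domain ($-y$ for
  the upper surrogate, $+z$ — initially streamwise — for the tree).
  Buoyancy ($\rho_{air}/\rho_p \approx 0.12\%$), Brownian motion,
  electrostatics, hygroscopic growth and particle–particle interactions
  are all neglected; the particles are one-way coupled.

## Time integration

The translational equation $m\dot{\mathbf v} = \mathbf F_{drag} +
\mathbf F_{lift} + m\mathbf g$ is integrated with an exponential scheme
that is *exact* for linear drag when the flow velocity, gradient and drag
coefficients are frozen over the step; they are evaluated at a midpoint
predictor position.  Decomposing along and across $\hat p$, each
component relaxes as $e^{-a\,\Delta t}$ with
$a = \mu K / m$, and the position update integrates that relaxation in
closed form.  The orientation is advanced by RK2 on the unit sphere and
renormalized each step (norm preserved to $10^{-9}$).

Because the integrator is exact for the stiff drag term, the step does
**not** need to resolve $t_0$ (which is $10^{-7}$–$10^{-3}$ s across the
sweep).  The default ("desk") step is therefore set by flow and geometry
resolution only:
$$\Delta t = \min\!\Big(\Delta t_{max},\; 0.1\,\frac{R}{\max(|\mathbf
v|,|\mathbf u|)},\; \frac{0.05}{\dot\gamma}\ \text{(fibers)}\Big),$$
with $\Delta t_{max} = 10^{-3}$ s: at most a tenth of the local tube
radius per step and a twentieth of a radian of fiber rotation.  This is
validated by a convergence property (halving $\Delta t$ moves a 1 s
trajectory endpoint by less than $10^{-4}$ relative).  A fidelity mode
(`track_options(mode = "fidelity")`) instead uses a fixed
$2\times10^{-7}$ s discrete-element step.  Wall contact is checked every
step in both modes.

## Synthetic airway domains

Both domains are unions of straight tube segments with connectivity;
walls are the lateral capsule/cone surfaces (giving a smoothly filleted
carina at bifurcations), while inlet and terminal outlet planes are open.

**Bronchial tree.**  The tree spans conducting-airway generations 7–16:
"nine generations" is read as nine *bifurcation stages* joining ten
airway levels, which reconciles the stage count with the 2.45 mm → 0.5 mm
diameter range.  Per-level diameters follow the geometric progression
solved between those endpoints (ratio $(0.5/2.45)^{1/9}$ per level).
Branch length is $3.5\times$ diameter (a representative conducting-airway
proportion; configurable), the branching half-angle is 35° (not stated by
morphometry used here; configurable), and the branching plane rotates 90°
between successive levels to fill 3D space.

**Junctions.**  Each child branch opens at its parent's radius and tapers
conically to its own over one own-diameter.  The laminar field inside a
taper carries the continuity-derived radial velocity (see below), so
tracers are steered through constrictions and into daughters; the wedge
that develops between the two sibling cones forms the carina, which
inertial particles hit.  This replaces a naive piecewise-cylinder model
in which every diameter change geometrically blocks the near-wall annulus
and would deposit even perfect tracers — an artifact, not physics.

**Embedding.**  A ten-level symmetric tree with these proportions cannot
be embedded with straight segments without *remote* branches
interpenetrating: subtree envelopes (of order the summed branch lengths,
tens of mm) exceed subtree separations regardless of the branching-plane
scheme.  The tree is therefore treated as intrinsically defined; particle
transport, wall distance and contact are evaluated on the local branch
neighborhood, so remote interpenetration has no dynamical effect.  The
builder still rejects *locally* degenerate geometry (siblings that fail
to separate, intersections within graph distance 4).

**Upper surrogate.**  The upper domain is deliberately generic: a
horizontal mouth tube (2 cm diameter), a tapered constriction at half the
inlet diameter (larynx analog; jet-like acceleration by continuity), a
90° bend turning the airway vertical, a trachea analog, and five outlet
branches labeled with the lobar tokens LU/LL/RU/RM/RL.  It stands in for
an anatomical mouth–throat plus proximal-airway model solved with a RANS
closure, which is out of scope; results on this domain are surrogate
results and the region labels deliberately do not promise anatomical
generation numbers.

## Flow model

**Waveform.**  The DPI maneuver is characterized by three printed
numbers: tidal volume 2.95 L, peak flow 90 L/min, inspiration 3 s.  The
profile shape between them is not tabulated, so any smooth profile
meeting the constraints is admissible; the package uses a $\sin^2$ ramp
(0.4 s, DPI onsets are sharp), a plateau, and a $\cos^2$ decay, with the
plateau end solved in closed form from the volume constraint
($t_h = 2\,TV/P - T + t_r = 4/3$ s at the defaults).  Particle injection
is confined to a bolus spanning 0.45–0.6 s.

**Velocity field.**  Each segment carries its flux share of $Q(t)$ with
the parabolic profile $u = 2\bar u\,(1 - (r/R)^2)$ (no-slip exact,
centerline twice the mean).  Inside a conical taper $R(s)$, continuity
adds the radial component $u_r = 2\bar u R'\rho(1-\rho^2)$ and makes
$\bar u(s) = Q_{seg}/(\pi R(s)^2)$; the velocity-gradient tensor is
analytic everywhere (verified against central finite differences at
$10^{-4}$ relative).  Terminal flux shares are equal across tree outlets
and follow the lobar split (15/31/14/7/33% to LU/LL/RU/RM/RL) in the
upper domain; interior segments carry their descendants' sum, so flux is
conserved exactly at every bifurcation.  Laminar fields are used in both
domains: the upper airways are turbulent in reality, and no turbulent
dispersion is modelled — a stated surrogate simplification.

**Hand-off.**  The tree is driven by the same waveform scaled so its
mean inlet velocity equals the mean velocity leaving the upper outlets
(`tree_inlet_scale()`, area ratio ≈ 0.012 at the defaults).  Particles
escaping the upper domain re-enter the tree inlet after a delay equal to
the upper lumen volume over the mean flow (≈ 73 ms at the defaults), with
velocity scaled by the ratio of mean inlet velocities (≈ 0.8) and
orientation rotated into the tree frame.  The Reynolds diagnostic
decreases monotonically from the upper inlet (~6×10³ at peak) to the tree
terminals (~6), consistent with the expected order-of-magnitude band.

## Deposition model

Any wall contact deposits the particle (entrapment by the mucus layer;
no bounce or resuspension).  For contact purposes a fiber is the axial
segment $[\mathbf x - b_p\hat p,\ \mathbf x + b_p\hat p]$ of radius
$a_p$: contact occurs when the minimum wall distance over samples along
the segment (tips included, spacing $a_p/2$, at most 64 points) falls
below $a_p$.  Spheres reduce to center distance ≤ radius.  This makes
interception orientation-dependent — a fiber pointing at the wall
touches it while the same fiber lying parallel does not — and guarantees
no missed contact deeper than about $a_p/4$ on convex walls.

Deposited contacts are labeled by a diagnostic (not physical) convention:
tip-only contacts (center farther than $a_p$ from the wall) are
*interception*; otherwise *sedimentation* if the gravity-aligned velocity
component exceeds half the speed, else *impaction*.  The 0.5 split is a
convention; mechanisms are named but never quantified by a threshold in
the underlying physics.

An integer conservation ledger tracks injected = airborne + deposited +
exited per group at all times, and the dispersion index reports, for each
deposited particle, the number of deposited neighbors within 10 mm
(upper domain) or 5 mm (tree).

## Sweep design and the synthetic-data conditions

The default grid is $d_p \in \{1,\dots,7,10,20\}$ µm ×
$AR \in \{1,3,10,30\}$ — 36 groups — at 3000 particles per group
(108,000 total).  Particles are released from a uniform Cartesian lattice
clipped to the inlet disc (~3000 points), at uniformly spaced times across
the bolus, round-robin over lattice points, with initial velocity equal to
the local flow and initial orientation streamwise (inhaled fibers align
quickly with the flow).  The temporal spacing within the bolus is a
package choice; the window and the spatial lattice are part of the study
conditions.  The only stochastic element is the subsampling of lattice
points when a group is smaller than the lattice; it is governed by the
seed, and a run is byte-reproducible from its seed.  Desk-scale analyses
in the test suite use 500 particles per group (and 2000 for the
straight-tube Monte-Carlo benchmark), sizes chosen so binomial error is
small relative to the asserted effects.

## Validation strategy

Every mechanistic ingredient has a closed-form oracle in the test suite:
Stokes drag and the sphere limits; slender-body asymptotics for the
resistance ratio; the Jeffery period; the Saffman magnitude; terminal
settling ($v_s = t_0 g$ within 0.5%); and, end-to-end, gravitational
deposition of spheres in steady horizontal-tube Poiseuille flow against
the classical flux-weighted closed form
$$\eta = \frac2\pi\Big(2\kappa\sqrt{1-\kappa^{2/3}} -
\kappa^{1/3}\sqrt{1-\kappa^{2/3}} + \arcsin\kappa^{1/3}\Big),\qquad
\kappa = \frac{3 v_s L}{8 \bar u R},$$
itself re-derived in the tests by an independent quadrature.  The
simulated deposition fraction at $n = 2000$ agrees within three binomial
standard errors.

## What passing tests do and do not show

The surrogate reproduces the *mechanistic* trends that depend on fiber
aerodynamics: upper-domain DE grows with $d_p$ (impaction at the
constriction and bend, sedimentation in the horizontal inlet) and falls
with $AR$ at fixed $d_p \ge 4$ µm (smaller $d_{Stk}$, hence smaller
$Stk$ — elongation lets large particles slip through the proximal
filter), with complete capture of 20 µm spheres.  These are asserted with
binomial-error tolerance on the surrogate, not as anatomical claims.

The mid-bronchial *optimum* (peak DE for mid-size particles in the tree)
does **not** emerge in this surrogate, and the corresponding acceptance
check is deliberately left failing rather than weakened.  The reasons are
structural: in a smooth laminar tree at plateau flow, per-branch
gravitational capture over ten generations is only a few percent for
3–7 µm particles (a per-branch closed-form estimate agrees with the
simulation), whereas the anatomical result relies on sharp carinas,
turbulent/secondary-flow dispersion and profile skewing — all outside
this model class.  Meanwhile the particles that survive the upper
surrogate are concentrated near the axis and impact the first carinas at
large $d_p$, so tree DE keeps rising with size instead of falling.  This
is a faithful account of what a laminar smooth-wall surrogate can and
cannot reproduce.

## Numerical choices and degenerate inputs

Tolerances: volume equivalence and diameter progressions to $10^{-12}$
relative; flux conservation exact by construction; orientation norm to
$10^{-9}$ per step; gradient consistency to $10^{-4}$ relative.
Degenerate inputs are signalled rather than repaired: infeasible waveform
volumes, oblate aspect ratios, lobar maps that do not cover the five
lobes, branching angles that cannot separate siblings, negative segment
flows, zero upstream flow in the hand-off, and a zero DE denominator
(distinct from DE = 0).  `NaN` states during integration abort with the
particle id and time.

## Known limitations

No turbulence or turbulent dispersion (upper airways are transitional to
turbulent in reality); no secondary flows beyond the analytic taper
convergence; no cartilaginous rings or anatomical surface detail; fixed
gravity orientation per domain; no exhalation phase; no two-way coupling
or agglomeration; remote-branch interpenetration in the tree embedding
(dynamically inert, see above); the quantitative DE magnitudes of
anatomical CFD are out of reach by design.
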