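---
title: "Modelling in-plane tear propagation in the dissected aorta"
author: "aortafem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling in-plane tear propagation in the dissected aorta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortafem)
```

## The problem

Aortic dissection propagates *in plane*: blood entering the media through
an intimal tear splits the bonding between concentric elastic lamellae,
carving a false lumen that advances circumferentially and axially. The
clinically decisive quantity is the critical pressure $P_c$ at which an
existing tear starts to propagate, and the mode of interfacial damage
(opening versus sliding) that drives it.

`aortafem` models this with a cohesive-zone finite-element framework:

* the bulk wall is a fiber-reinforced, nearly incompressible hyperelastic
  solid (the HGO model) with separate medial and adventitial parameter
  sets;
* the lamellar interface inside the media is a surface of zero-thickness
  cohesive elements obeying a bilinear mixed-mode traction–separation
  law;
* an idealized bilayer tube with a parametric initial tear is
  pressurized quasi-statically until the first cohesive element is
  completely damaged — that pressure is $P_c$.

## Bulk constitutive model

The strain energy per reference volume is

$$W = C_{10}(\bar I_1 - 3) + \frac{1}{D}\!\left(\frac{J^2-1}{2} - \ln J\right)
    + \sum_{i=1,2} \frac{k_1}{2k_2}\!\left[e^{k_2 \varepsilon_i^2} - 1\right],
\qquad
\varepsilon_i = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar I_{4,6} - 1),$$

with $\bar I_4 = \bar{\mathbf C} : \mathbf M \otimes \mathbf M$,
$\bar I_6 = \bar{\mathbf C} : \mathbf N \otimes \mathbf N$ and two fiber
families $\mathbf M, \mathbf N$ at $\pm\theta$ from the circumferential
direction. The bundled parameters (`hgo_media()`, `hgo_adventitia()`)
come from biaxial testing of human thoracic aorta; their fiber angles
are below $10^{-3}$ degrees, i.e. the families are effectively
circumferential, and the dispersion parameters sit near (but below) the
isotropic limit $\kappa = 1/3$.

Two conventions the energy function itself does not fix:

* **Tension-only fibers.** A family contributes only while
  $\varepsilon_i > 0$. Compressed fibers store no energy; this is the
  standard convention for collagen recruitment and prevents unphysical
  compressive stiffening.
* **Near-incompressibility.** $D = 10^{-6}\,\mathrm{kPa}^{-1}$ makes the
  volumetric modulus six orders of magnitude above the shear modulus.
  Plain displacement elements lock under such constraints, so the bulk
  elements use selective reduced integration: the isochoric part at the
  full $2\times2\times2$ Gauss rule, the volumetric part at the element
  centroid — the classic mean-dilatation treatment, equivalent to a
  condensed constant-pressure mixed element.

Units are mm / mN / kPa throughout, so fracture energies carry
mN/mm $=$ N/m and all bundled tables can be used as printed.

## Interface model

Each cohesive point carries a normal separation $d_n$ (tension positive)
and two sliding separations $d_s$ (circumferential) and $d_t$ (axial).
Pre-initiation response is linear, $T_i = K_i d_i$. Damage initiates by
the quadratic nominal stress criterion

$$\left(\frac{\langle T_n\rangle}{T_n^C}\right)^2 +
  \left(\frac{T_s}{T_s^C}\right)^2 +
  \left(\frac{T_t}{T_t^C}\right)^2 = 1,$$

(Macaulay bracket: compression never initiates damage), then softens
linearly with a scalar damage variable $d$ driven by the effective
separation $\delta_m = \sqrt{\langle d_n\rangle^2 + d_s^2 + d_t^2}$.
Unloading returns along the secant through the origin; $d$ and the
per-mode dissipated energies $G_I, G_{II}, G_{III}$ never decrease. The
point is completely damaged when the power law

$$\left(\frac{G_I}{G_{IC}}\right)^\alpha +
  \left(\frac{G_{II}}{G_{IIC}}\right)^\alpha +
  \left(\frac{G_{III}}{G_{IIIC}}\right)^\alpha = 1, \qquad \alpha = 1,$$

is met; the element is then removed (its tractions drop at the next
increment) while a smooth exponential contact backstop keeps resisting
interpenetration of the failed faces. The mode mix ratio
$m = 1 - G_I/G_T$ distinguishes opening-dominated ($m \to 0$) from
sliding-dominated ($m \to 1$) damage.

Design choices where the criteria alone do not pin down an algorithm:

* **Mixed-mode softening internals.** The damage variable evolves on the
  effective separation with the mode mix evaluated instantaneously; the
  initiation separation follows from the quadratic criterion and the
  failure separation from the power law, so pure-mode paths dissipate
  exactly $G_{iC}$ (the bilinear triangle) and proportional mixed paths
  meet the power law exactly at $d = 1$. Energies are integrated
  incrementally as dissipative work (work minus the change of
  recoverable energy), which makes the bookkeeping exact on piecewise
  linear paths regardless of step size.
* **Compression and contact.** An intact interface transmits compression
  through its full penalty stiffness (secant stiffness through the
  origin); failed and pre-torn faces are protected by an adhesion-free
  exponential penalty $T_n = -A e^{-d_n/w}$ with
  $w = 0.025\,T_n^C/K_n \approx 2\,\mu$m and $A = 5\times10^{-4}\,T_n^C$.
  The smooth backstop avoids the active-set chatter of piecewise-linear
  hard contact and keeps Newton's method quadratically convergent; the
  price is a pressure-dependent penetration depth
  $w\ln(p/A) \approx 15\,\mu$m at 100 kPa, far below the element sizes
  used. Contact work is excluded from the fracture-energy bookkeeping.
* **Stabilization.** A Duvaut–Lions viscous regularization of the damage
  variable is available (`mu_visc`), and the solver offers automatic
  volume-proportional damping (`stabilize`) whose dissipated energy is
  accumulated on the trajectory so that its share of the external work
  can be verified. Both default to zero; all calibration results in
  this package are produced without them.

## Virtual calibration experiments

The interface constants bundled with the package
(`cohesive_media()`: $T^C = 131/97/120$ kPa, $G_C = 49/200/240$ N/m,
$K = 1638/35000/35000$ mN/mm³) reproduce peel, direct-tension and shear
experiments on human medial strips. The package re-creates those
experiments as FEM models:

* `run_peel_test()` — a 4.0 mm × 1.2 mm medial strip in the $r$–$\theta$
  plane, realised as a one-element-thick plane-strain slice with a
  mid-thickness interface and a 0.5 mm starter tear. Both arms are
  gripped and pulled apart symmetrically in the radial direction
  (T-peel). The steady plateau of the pulling force per unit width is
  extracted over the window from three cohesive element lengths of tear
  advance until 80% of the bonded interface is consumed (the run stops
  once 55% is consumed, which covers the window). For rigid arms the
  energy balance gives plateau $\approx G_{IC}/2$ per arm; arm bending
  and the finite process zone leave the simulated plateau a few percent
  below that bound.
* `calibrate_GIC()` — safeguarded secant iteration on $G_{IC}$ (holding
  $T_n^C$ at its direct-tension value) until the simulated plateau
  matches a target force per width within 2%.
* `run_direct_tension()` — uniform opening of an interface patch with
  lateral motion suppressed, so every point follows the same history:
  the peak nominal traction is $T_n^C$ and the dissipated energy at full
  separation is $G_{IC}$.
* `run_shear_test()` — the 4 mm × 4 mm × 1 mm block sheared between its
  radial surfaces in the circumferential (mode II) or axial (mode III)
  direction. Radial displacement is suppressed throughout the thin
  glued specimen, so the interface follows a pure sliding history and
  the late-stage wrinkling instability of a nearly-failed sheared
  interface (an artefact the physical specimen avoids through its glue
  constraints) cannot occur. The curve reports interface shear stress
  against the amount of shear (tangential displacement over the 1 mm
  radial thickness); `calibrate_shear_GC()` adjusts a sliding fracture
  energy until the amount of shear at complete damage matches a target.

Discretizations: the peel strip uses 40 elements along the interface
(0.1 mm, about three elements per cohesive process zone) and three per
arm through the thickness; the shear block uses 4 × 4 in-plane elements.
These resolutions keep every calibration run at desk scale (tens of
seconds to a few minutes) while resolving the process zone; the
acceptance checks carry tolerances that absorb the residual
discretization error.

## The bilayer tube pipeline

`build_tube_mesh()` discretizes the idealized descending aorta
($R_i = 7.5$ mm, $R_o = 9$ mm, media:adventitia 5:3) with hexahedra and
embeds one cohesive surface at the tear radius $R_i + t\,t_m$. The tear
(central angle $\eta$, axial length $s$, depth ratio $t$) is a pre-torn
patch: no cohesive stiffness, contact retained, and its two faces form
the false-lumen pressure set. The tube is $s + 3$ mm long (1.5 mm per
end); symmetric halves (circumferential and axial) can be modelled with
symmetry boundary conditions. The mesh is graded: a refined band
straddles each tear front, since the critical pressure is meaningful
only when the front process zone is resolved.

Boundary conditions follow the study setup: the bottom face (or the
axial symmetry plane) is fixed axially, the top face carries the axial
stretch $\lambda$, and the node lines at $\theta = 0°, 90°, 180°, 270°$
are fixed circumferentially. `run_pressurization()` applies $\lambda$,
then ramps the true- and false-lumen pressures proportionally until the
first cohesive element is completely damaged, refining the load factor
so $P_c$ is bracketed to 1 kPa. The critical event records the failed
element(s), a propagation-direction label (axial versus circumferential
front, from the element centroid relative to the tear boundary, ties
reported deterministically), the mode mix $m$ and the tractions at
criticality.

Residual stress is included through classical opening-angle kinematics
(`apply_residual_prestrain()`): the stress-free state is a sector of
angle $2\pi - \alpha$ closed into the reference cylinder, applied as a
multiplicative, isochoric prestrain per Gauss point; the opened inner
radius is chosen so the closed unloaded tube satisfies both radial
traction conditions (hence zero net hoop force), and the FEM relaxes
the discretization remainder. This is a deliberately simplified
stand-in for growth-based residual-stress generation: opening angles
map to self-equilibrated circumferential prestress fields that compress
the inner wall, so residual-stress trends are meaningful while exact
magnitudes tied to a particular growth history are not. Note that an
opening-angle field carries a nonzero section bending moment — that
moment is precisely what springs a cut ring open — so self-equilibrium
is asserted through the vanishing net force and traction-free surfaces,
not a vanishing moment.

`semi_analytic_inflation()` provides an independent verification path
for the intact tube: incompressible axisymmetric extension–inflation by
radial integration of the equilibrium equation with the same energy
function. The FEM reproduces its transmural stress profiles within 2%
at the in vivo state (12.8 kPa, $\lambda = 1.02$).

## Numerical methods

The solver is a total-Lagrangian Newton iteration with analytic
consistent tangents for the bulk (an exact closed-form linearisation of
the HGO second Piola–Kirchhoff stress) and finite-difference element
tangents for the cohesive elements (which capture the co-rotational
frame coupling of the corner pairs). Load stepping is adaptive: steps
halve on non-convergence and regrow after consecutive successes; a
secant predictor extrapolates the previous converged increment, which
is what makes gradual ramps cheap; a backtracking line search rejects
steps that cannot at least roughly hold the residual. Follower pressure
contributes its exact load stiffness. Sparse assembly caches the CSC
pattern of the mesh, and the free-dof submatrix extraction is cached as
a gather operation.

Degenerate inputs are guarded: non-positive $\det F$ raises an
invalid-deformation error at the API level and rejects the load step
inside the solver; non-finite separations are refused; fiber-term
overflow flags non-finite energy. Ties in simultaneous element failures
are reported in deterministic (direction, index) order. The pipeline
contains no random numbers; identical configurations reproduce
identical outputs.

## Problem sizes and what the tests show

The test suite builds every model programmatically at desk scale: the
peel strip at its calibration resolution, shear/tension blocks, an
intact tube at 24 × 8 elements for the semi-analytic comparison, and
coarse graded tear meshes (about 600 hexahedra) for the tube studies.
At these sizes the calibration quantities (peel plateau, peak
tractions, dissipated energies) are within a few percent of their
targets, and the tube studies are run as *trend* checks at fixed
sub-critical pressure: the interface failure criterion grows with tear
depth and the circumferential front is more shear-dominated than the
axial front — the desk-scale surrogates of the published findings that
deeper tears propagate at lower pressure, that axial propagation is
opening-driven and circumferential propagation sliding-driven. Full
critical-pressure searches on production meshes (the 52 kPa validation
case and the 130/125/120 kPa axial-stretch series) take hours per case
on a workstation and are reachable through the same
`run_pressurization()`/`parameter_sweep()` API with a finer
`tube_spec`; they are not part of the test suite.

What passing desk-scale tests do *not* show about real arteries: the
generator of all inputs is the idealized geometry and the printed
parameter tables, so patient-specific curvature, branch vessels,
fluid–structure interaction, axial/circumferential differences in
mode-I toughness, bulk damage and viscoelasticity are all outside the
model. Quantitative critical pressures are also sensitive to the provenance
of the bulk parameters: published parameter sets for the same vessel
differ enough to shift predicted critical pressures several-fold.

## Known limitations

* Tear propagation is detected (first complete element failure), not
  tracked post-criticality.
* The penalty/backstop contact admits micrometer-scale interpenetration;
  a hard-contact tolerance of $10^{-4}$ mm is not attainable with the
  bundled penalty stiffness (documented where tested).
* The quasi-static solver has no arc-length continuation; strongly
  snapping configurations rely on small steps (and optional
  stabilization, which is off by default and energy-audited when on).
* The coarse tube meshes of the test suite overestimate critical
  pressures; they are used only for direction-of-effect statements.
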