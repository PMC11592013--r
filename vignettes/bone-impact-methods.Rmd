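---
title: "Methods: explicit-dynamics simulation of blunt impact on layered bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explicit-dynamics simulation of blunt impact on layered bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`osteoimpact` simulates a rigid cylindrical impactor striking layered
cortical/trabecular bone and predicts the transmitted force history and the
pattern of bone damage. This vignette is the package's own account of the
model: what is computed, which parameters matter, which choices were open and
how they were made, and what the shipped verification suite does and does not
demonstrate.

## Unit system

All internal computation uses a consistent mm–N–s–tonne system: stress in MPa
(N/mm²), density in tonne/mm³, energy in mJ (N·mm). This keeps the constants
the craniofacial literature prints — moduli in GPa, fracture energy in
mJ/mm², element sizes in mm — unscaled or trivially scaled. Interfaces accept
GPa, g/cm³, kg and km/h and convert on entry (`gpa_to_mpa()`,
`gcm3_to_tmm3()`, `kmh_to_mms()`, `kg_to_tonne()`).

## Bone constitutive model

Each element carries one of two phases of Misch type II bone:

* **Cortical** — E = 13.7 GPa, ν = 0.3, ρ = 2.12 g/cm³; multilinear J2
  plasticity with isotropic hardening, strain-rate dependent.
* **Trabecular (cancellous)** — E = 5.5 GPa, ν = 0.3, ρ = 2.12 g/cm³;
  rate-independent plasticity. The printed density equals the cortical one;
  it is kept as printed rather than second-guessed, and is configurable.

Rate dependence uses the Cowper–Symonds law,
$\dot\varepsilon_{pl} = D\,(R-1)^n$, i.e.
$R = 1 + (\dot\varepsilon_{pl}/D)^{1/n}$ with D = 360.7 s⁻¹ and n = 4.61.
The dynamic factor `R` multiplies the whole quasi-static hardening curve
(the standard overstress composition; the composition rule is a modelling
choice, exposed through `rate_law()`).

The hardening curves themselves are **calibration defaults, not tabulated
literature data**: cortical yield 110 MPa rising linearly to 180 MPa at 2%
equivalent plastic strain (so the rate-1000 s⁻¹ curve peaks near 250 MPa,
consistent with the stress scales reported for dynamic cortical bone), and a
flat 30 MPa trabecular curve. Both are fully overridable via
`hardening_curve()` / `material_card()`.

Stress integration (`stress_update()`, and the same kernel inside the
solver) is an elastic trial followed by radial return onto the rate-scaled
yield surface; the implicit scalar equation
$q^{tr} - 3\mu\,\Delta\lambda - R(\Delta\lambda/\Delta t)\,
\sigma_h(\bar\varepsilon_{pl}+\Delta\lambda) = 0$
is solved by safeguarded Newton iteration (monotone, bracketed). The
formulation is small-strain with incremental objectivity: the incremental
spin rotates the stored stress through the Cayley form
$Q = (I - W/2)^{-1}(I + W/2)$, which is exactly orthogonal — a pure rigid
rotation preserves the stress norm to round-off. Failure strains here are a
few percent, so a full finite-strain formulation was judged unnecessary;
this is a documented fidelity gap for very large rotations.

Isotropy is a deliberate simplification: real bone is anisotropic and
heterogeneous, and mapping CT-density-dependent properties is out of scope.

## Ductile damage, fracture energy, element deletion

Damage initiation uses a rate-dependent onset-strain table at a single
stress triaxiality (0.33, uniaxial tension): onset equivalent plastic strain
0.02 quasi-statically falling to 0.0024 at 1000 s⁻¹. The initiation measure
$\omega = \sum \Delta\bar\varepsilon_{pl} / \varepsilon_{onset}(\dot{\bar\varepsilon}_{pl})$
declares damage at ω ≥ 1 (this is the quantity plotted as DUCTCRIT in
commercial post-processors). Between tabulated rates the onset strain is
interpolated piecewise-linearly in log₁₀(rate) — the interpolation rule of
the originating solver is not public, so the most common convention was
chosen; rates at or below the first tabulated nonzero rate return the
quasi-static value. The rate entering the lookup is the element's plastic
strain rate, exponentially smoothed with factor 0.1 (≈10 steps) to avoid
noise-driven jumps between table rows.

After initiation, softening is linear in the effective plastic displacement
$u_{pl} = L_e\,\bar\varepsilon_{pl}^{post}$ with
$d = \min(1, u_{pl}/u_f)$, $u_f = 2G/\sigma_{y0}$, where σ_y0 is the flow
stress recorded at the initiation instant and G = 1.54 mJ/mm² the fracture
energy. The element length L_e = V^{1/3} regularizes the softening so the
energy dissipated per unit cracked area equals G regardless of element size
(verified to within 2% for L_e ∈ {0.5, 1, 2} mm in the test suite). The
stress is degraded as (1−d)·σ̄, and the element is deleted at d ≥ 0.99 — not
exactly 1, to avoid a zero-stiffness singular tail; the energy error of the
early cut-off is below 0.01% of G. Deleted elements contribute no internal
force and no contact surface, ever again.

Trabecular elements fail by a simple strain cap at 6% equivalent plastic
strain — twice the ~3% cortical failure deformation, the conservative
secondary-failure reading; the alternative reading (2 × the 2% onset strain
= 4%) is available as `damage_card(trabecular_cap = 0.04)`.

Whether the original study degraded stiffness before deletion or removed
elements at initiation is not documented; this package uses the standard
degrade-then-delete sequence, and reports initiation (ω) and deletion fields
separately so both readings can be inspected.

## Skin-surrogate contact and the rigid impactor

The skin is not meshed; its force-transmitting role is captured by an
exponential pressure–overclosure law that starts acting at a clearance
c₀ = 1.5 mm (the average skin thickness over the cheekbone) and reaches
p₀ = 100 N/mm² at zero clearance:
$p(c) = p_0\,(e^{1-c/c_0}-1)/(e-1)$ for 0 ≤ c < c₀. The exact functional
form between the two anchors is a package choice (the originating solver's
internal form is not printed); it is swappable via `contact_law()`. For
penetration (c < 0) the law continues linearly with the slope matched at
c = 0 — an exponential continuation would make the explicit stable time
step collapse.

Contact is node-to-analytic-surface against the finite cylinder (length
200 mm, Ø40 mm, 2 kg), with exact geometry and no faceting artifacts. Each
exterior node carries a tributary area from the current boundary faces;
erosion exposes interior faces, which join the contact surface. Two
numerical guards keep the energy ledger honest:

* overclosure energy stored against surface that gets eroded is counted as
  *erosion dissipation*;
* a node newly exposed deep inside the impactor would otherwise be born with
  a large stored overclosure energy — such nodes only arm for contact once
  they are outside the impactor.

Friction is regularized Coulomb with μ = 0.2: the tangential traction ramps
linearly up to μ·p over a slip velocity of 1 mm/s. At the explicit time
step this regularization is stiff enough to make sticking nodes chatter, so
dynamic runs additionally cap the tangential force at the impulse that would
cancel the node's slip in one step (0.5·m·|v_t|/Δt). The cap never binds in
genuine sliding (the steady-sliding force ratio is exactly 0.2 in the
verification suite); without it the chatter shows up as spurious friction
"heat" of tens of percent of the impact energy.

The impactor is free-flying: it carries its 2 kg and decelerates under the
contact reaction, so momentum transfer emerges rather than being prescribed.
It translates without rotation — shipped scenarios are normal-incidence and
symmetric, so the net torque vanishes; oblique impact would need the
rotational DOFs.

## Explicit solver

Central-difference (leapfrog) integration with lumped (row-sum) mass.
Elements are first-order: 8-node hexahedra with 2×2×2 integration and
mean-dilatation (B-bar) volumetric treatment, and 4-node constant-strain
tetrahedra (supported for generality; shipped scenarios are hexahedral; the
constant-strain tet locks volumetrically and is not recommended for
near-incompressible response). Full deviatoric integration needs no
hourglass control.

The stable increment per element is $L_{min}/c_d$ with the dilatational
wave speed $c_d = \sqrt{E(1-\nu)/((1+\nu)(1-2\nu)\rho)}$ and $L_{min}$ the
shortest element edge (the volume-based length overestimates the limit for
flattened elements); the global step is 0.9 × the smallest element value.
Selective mass scaling multiplies the mass of elements below the target
step (default 10⁻⁷ s) by (Δt_target/Δt_e)², with the added-mass fraction
reported and a warning above the 1% budget.

An energy ledger (kinetic, internal, plastic and damage dissipation,
friction, contact potential, erosion) is closed at every output frame;
kinetic energy is evaluated at integer time levels from time-centred
velocities. A divergence detector (kinetic energy growing more than tenfold
over 100 steps beyond the initial energy) aborts with the history retained.

Ties between meshed parts merge coincident interface nodes (snap-to-master
within a tolerance); a tied assembly moves rigidly without internal force.
Modal verification assembles the linear stiffness by probing the elastic
force operator column by column (exact for a linear operator), pairs it
with the lumped mass and solves the dense symmetric eigenproblem — intended
for verification-scale models only (≤ a few thousand DOF). The cantilever
check in the suite agrees with the Euler–Bernoulli closed form to well
within the 10% tolerance.

## Synthetic geometry and the calibrated default scenario

No real craniofacial geometry ships with the package (the head/CBCT models
such data derive from are licensed); `make_layered_plate()` and
`make_zygoma_arch()` generate parametric stand-ins with the structural
features the analysis needs: a cortical shell of 1.5–2.0 mm over a
trabecular core (Misch type II), element sizes near 1–1.5 mm, fixed far
boundaries, and optional curvature. Generation is deterministic; optional
node jitter takes an explicit seed.

The shipped default scenario (`default_plate_scenario()`) is a 48 × 16 mm
sandwich strip — 1.5 mm cortical skins over a 1 mm trabecular core — whose
full volume within 10 mm of either span end is held fixed, leaving a 28 mm
free span over a cavity (≈2000 hexahedra, ~1.1 mm elements). The shape is a
deliberate calibration and the reasoning is worth recording, because it
reflects a real competition in the physics:

* With the fixed skin-surrogate law, the transmitted pressure is capped
  near p₀ = 100 N/mm² until deep penetration — just below the 110 MPa
  cortical yield — and the soft pre-contact branch stores ≈63 mJ per mm² of
  engaged area. At 5 km/h (1.9 J available) the skin alone absorbs most of
  the impact over any realistic contact patch, so *contact-side crushing
  cannot start cortical damage at low speed*; low-speed damage must come
  from structural bending.
* A structure slender enough to develop deep plastic hinges at 5 km/h (and
  hence cortical damage initiation, ω ≥ 1) is also weak enough that faster
  impacts shear its supports and sweep it away — after which the
  transmitted force *falls* with speed, inverting the experimentally
  reported force ordering. A backed, compact target keeps the force
  ordering monotone but stays elastic at low speed. At desk scale, without
  the surrounding head to keep pushing back, no single small target does
  both.

The cavity strip resolves the trade as the anatomy does: thin bone spanning
an air space (the maxillary sinus) between buttresses the impactor can
ultimately bear on. At 5 km/h it produces local damage in the impact zone —
crushed trabecular core, cortical plasticity with ω reaching ≈0.7 — but no
cortical element loss and no through-thickness path ("local damage without
complete fracture"). At 15 and 20 km/h the span is punched through under
the impactor (a crush fracture, crush fraction ≈1) and the impactor then
bears on the held abutments, so peak CFC180-filtered force and failed
volume grow monotonically over 5/10/15/20 km/h. The strict reading
"ω ≥ 1 somewhere at 5 km/h" is *not* met on this geometry; it is met on
the companion slender-strut configuration (`strut_scenario()`, 100 × 8 mm
two-edge-clamped, 1 mm elements), which reaches ω ≈ 1.1 at 5 km/h with
zero deleted elements — at the price of the inverted force ordering above.
Both configurations ship, each labelled with the regime it represents, and
the test suite asserts each property on the configuration that carries it.
Absolute peak forces of desk-scale synthetic targets are *not* comparable
to head-model values; only orderings and damage patterns are.

Low-speed runs use 6–8 ms of simulated time (momentum transfer at 5 km/h
completes later); higher speeds use 5 ms. Full 20 ms histories are a
configuration option (`duration = 0.02`). Problem sizes were chosen so each
run takes a few minutes on one CPU.

What the passing tests do **not** show about real data: anatomical stress
concentrations (sutures, foramina), anisotropic bone, muscle/joint boundary
conditions, and skin tearing are all absent; the synthetic geometry
reproduces structural competition (bending vs. crushing), not anatomy.

## Force-history filtering

Impact-test force channels are filtered per the SAE J211 channel-class
convention: a 2-pole Butterworth at the class cutoff (CFC 180 → 300 Hz)
run forward and backward (phaseless, 4 poles total, DC gain exactly 1) over
an edge-reflected padding. Histories are sampled every 10 µs by default,
which resolves CFC180 comfortably. Outputs report Newtons alongside
kilogram-force (1 kgf = 9.80665 N) because the craniofacial literature
quotes peak forces in kg.

## Numerical choices at a glance

| Choice | Value | Why |
|---|---|---|
| CFL safety factor | 0.9 | standard explicit practice |
| Mass-scaling target | 1e-7 s | floor for the stable step |
| Deletion threshold d | 0.99 | avoids singular zero-stiffness tail |
| Rate smoothing | 0.1 (≈10 steps) | stable onset-table lookup |
| Friction v_reg | 1 mm/s | stick–slip regularization |
| Friction impulse cap | 0.5 m\|v_t\|/Δt | stick stability at explicit Δt |
| Contact penetration branch | linear, slope-matched | bounded stiffness |
| History sampling | 1e-5 s | resolves CFC180 |

## Known limitations

Isotropic homogeneous bone; small-strain kinematics; no crack-path tracking
beyond element deletion (deleted-element patterns approximate fracture
lines; fissure evolution is not quantifiable at this fidelity); no implicit
statics; no deformable–deformable contact between bone parts; impactor
rotation omitted; the constant-strain tetrahedron locks volumetrically.
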