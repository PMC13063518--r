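---
title: "Patient-specific TMJ biomechanics with tmjmech: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-specific TMJ biomechanics with tmjmech: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmjmech)
```

`tmjmech` implements a desk-scale version of a patient-specific
temporomandibular joint (TMJ) assessment pipeline: function-assessment
signal processing that turns bite-force and surface-EMG recordings into
simulation inputs, a rigid-mandible forward-dynamics simulator with
force-tracking muscle-activation optimization, articular-surface joint-gap
and congruency mapping, and the morphometric bookkeeping (biting arms,
condylar areas, scaling stresses) used to compare subjects. This vignette
is the package's own account of the underlying models, the tunable
parameters, the numerical choices, and what the synthetic data do and do
not establish.

## The function-assessment signal chain

A unilateral bite task is recorded at 2000 Hz: one bite-force channel (N)
and four surface-EMG channels (left/right temporalis, left/right
masseter), while the subject performs five consecutive static bites at
10/20/30/40/50 N targets.

Each EMG channel is processed as
detrend → rectify → low-pass → normalize:

* `detrend()` removes the full-record least-squares line (baseline drift
  and offset);
* `rectify()` takes absolute values;
* `lowpass()` applies a 4th-order Butterworth filter with a 6 Hz cutoff
  forward and backward, giving a zero-phase linear envelope. Zero-phase
  application is chosen so envelope timing stays aligned with the force
  channel; a causal filter would lag the envelope by tens of milliseconds
  and bias the activation-ratio windows.
* `emg_envelope()` divides by the mean envelope inside an explicitly
  supplied window covering the 20 N bite plateau. Windows are inputs, not
  auto-detected: plateau detection is subject- and protocol-specific and
  an explicit window keeps the operation deterministic.

The force channel is low-pass filtered with the same filter, then
`clip_resample()` extracts the highest-force bite and linearly
interpolates it onto 250 samples spanning 0.25 s (a 1 kHz grid matching
the simulator's 1 ms step; window endpoint values are preserved). The
force channel is *not* blanket-detrended: removing a least-squares line
from a multi-bite record destroys the absolute force level the simulator
must track. Instead, `process_recording(rest_window = )` optionally fits
sensor offset and drift on an unloaded segment and subtracts that line —
the behaviour of zeroing a force sensor against a rest reading.

One ipsilateral-to-contralateral (IC) activation ratio per muscle pair is
computed by `ic_ratio()` as the ratio of window means of the normalized
envelopes over the clipped task window. The mean was preferred over peak
or integral statistics as the most robust single-scalar summary; the
choice is a configuration point (the window is an argument), and because
both envelopes are normalized to their own 20 N baseline, the ratio is
invariant to any common rescaling of the channels.

### Filtering numerics

The 6 Hz cutoff at 2000 Hz sampling gives a normalized cutoff of 0.006,
for which the expanded transfer-function polynomials are numerically
ill-conditioned. The filter is therefore factored into second-order
sections (biquads) and applied as a cascade, each section with
steady-state ("step-matched") initial conditions and odd-reflection
padding at the record edges. This makes a constant series pass through
bit-nearly unchanged and keeps the forward-backward filter linear to
better than 1e-9, which the test suite asserts.

## Morphometrics and scaling stress

Landmarks are selected repeatedly by the observer; `average_landmark()`
uses the centroid and `mean_radial_error()` quantifies intra-observer
variability as the mean distance of selections from their set's centroid.
`biting_arm()` is the Euclidean distance from a first-premolar tip to a
condyle top; `condylar_area()` is the product of the manually measured
condylar major and minor axes (axes are inputs; fitting axes to meshes is
out of scope). The **scaling stress** of `scaling_stress()` is the task's
final bite force divided by the condylar area (N/mm² = MPa); simulated
disc stresses are reported as ratios to it so subjects with different
bite forces and condyle sizes are comparable. Table renderings round
half-up at the printed precision (1 decimal for morphometrics, 2 for
scaling stresses) while full precision is kept internally; differences
against the reference subject are formed at full precision and rounded
last.

## Articular-surface joint gap and congruency

Surfaces are triangulated meshes at a target mean edge length of 0.3 mm
(`triangle_mesh()` warns above 0.45 mm for analysis use). The joint gap
at each vertex of one surface is the minimum Euclidean distance to the
opposing surface, computed with exact point-to-triangle distance in
compiled code; vertex-to-vertex distances would bias high by the order of
the edge length. On the synthetic condyle/fossa pair with a known
analytic clearance field, the per-vertex gap error is below 0.01 mm at
the 0.3 mm density (asserted in the tests).

Per-vertex principal curvatures are estimated by a least-squares quadric
fit over the 2-ring vertex neighborhood in the vertex tangent frame (ring
order configurable; vertices whose neighborhood stays under 6 points are
flagged undefined). The sign convention is: convex with respect to the
outward normal is positive, with normals oriented out of the bone into
the joint space for both surfaces — so a convex condyle has positive and
a concave fossa negative curvatures, and a perfectly matched pair cancels.

The congruency at a point combines the principal curvatures of the two
surfaces into those of an equivalent surface,

k_e^max, k_e^min = A_S1 + A_S2 ± sqrt(D_S1² + D_S2² − 2 D_S1 D_S2),

with D_Si = k_min^Si − k_max^Si and A_Si = (k_min^Si + k_max^Si)/2, and
reports C = sqrt(((k_e^max)² + (k_e^min)²)/2). C = 0 is a perfect local
match; larger values mean curvature mismatch. The radicand equals
(D_S1 − D_S2)² and is clamped at zero against rounding. As written the
formula carries no dependence on the angle between the two surfaces'
principal directions; classical congruency formulations include a
cos 2α coupling, and `equivalent_curvatures(orientation_aware = TRUE)`
exposes that variant, but the plain form is the default. `congruency_map()`
anchors the per-vertex field on its first argument and interpolates the
second surface's curvature field barycentrically at the closest point
from the joint-gap correspondence.

## Constitutive laws

All values are the reference constants used throughout:

| Element | Law | Parameters |
|---|---|---|
| Articular cartilage | elastic foundation `p(d) = K ln(1 − d/h)` | h = 0.4 mm, E = 2.7 MPa, ν = 0.49, K = −(1−ν)E/((1+ν)(1−2ν)) = −46.208 MPa |
| TMJ disc | Mooney–Rivlin `W = C1(I1−3) + C2(I2−3)` | C1 = 0.9 MPa, C2 = 0.0009 MPa |
| TMJ capsule | Neo-Hookean `W = C1(I1−3)` | C1 = 1.44 MPa |
| TMJ ligaments | tension-only cable | 250 N per unit strain; slack lengths 4, 1.9, 1.9, 7.5, 4, 0, 0 mm (anterior, medial, lateral, posterior, lateral TMJ, sphenomandibular, stylomandibular) |
| Muscles | static Hill-type | `F = F_max (a f_l(l/l_opt) + f_p(l/l_opt))` |

The hyperelastic energies are evaluated only on isochoric deformations
(`det F = 1` within 1e-6); no volumetric penalty term is invented, since
the simulator transfers joint load through the elastic-foundation model
rather than a finite-element disc solve. `mr_uniaxial_stress()` provides
the closed-form incompressible uniaxial Cauchy stress used as an
independent oracle for the energy implementation via numerical
differentiation.

Ligament strain is referenced to the slack-inclusive rest length
(initial + slack); the cable is force-free below it and the force is
continuous at it. The clenching task is static, so the Hill
contraction-velocity factor is unity. Default curve shapes are a
parabola `f_l = max(0, 1 − ((l̃−1)/0.5)²)` and a one-sided quadratic
passive curve `f_p = 0.5 max(0, l̃−1)²`; subject-level Hill parameters are
not published in the source text, so both curves and `F_max`/`l_opt` are
configuration points, and the toy model sets `l_opt` to each muscle's
reference length (activation-ready at the clench posture).

## The rigid-mandible simulator

The mandible is a rigid body (default 0.5 kg, 40 mm gyration radius)
moving against a fixed cranium under muscles, ligaments, joint contact,
gravity (on by default, toggleable) and viscous damping. Coordinates are
mm with +x lateral-right, +y anterior, +z superior; the simulator
converts once to SI internally.

**Bite constraint.** The occlusal plane is fitted through three
landmarks — the lower left and right first premolar tips and the lower
incisor — with the normal oriented superiorly. The simulator attaches the
*task-side premolar* to this plane as a bilateral point-on-plane
connector. This one-point reading matters: constraining all three
landmarks would rigidly lock sagittal pitch and frontal roll, which
removes the class-3 lever load path through the condyles — joint forces
then collapse to a small in-plane residue, the mandible-length validation
inverts, and contralateral dominance cannot arise. With the one-point
connector the condyles act as the fulcrum, the classic
`(b − m)/m` lever relation is recovered (asserted against closed form in
the tests), and simulated joint loads land in the published 10–94 % of
bite force range.

**Joint contact sites.** Each condyle is a spherical cap (radius 8 mm in
the toy model) in a slightly larger socket (8.05 mm, near-conforming,
~0.05–0.09 mm clearance at rest). Contact pressure follows the elastic
foundation law; the force is integrated by ring quadrature over the cap
(80° half-angle, 12 rings by default — wide enough to cover the analytic
contact patch of a near-conforming pair) and only nodes pressing into the
superior socket cap count as contact. Penetration at or beyond the
cartilage thickness raises a saturation error rather than extrapolating
the law.

**Force tracking.** At each 1 ms step the excitation response row `H` is
computed by unit-activation perturbation of the bite-point constraint
reaction: the reaction is affine in activations at fixed state, so column
j is exactly the bite force generated per unit activation of muscle j,
with the passive state (gravity, ligaments, contact, passive muscle
tension) subtracted. The temporalis and masseter left/right pairs are
reduced by the measured IC ratios (`a_ipsi = r u`, `a_contra = u`, bound
`min(1, 1/r)`), and the activations solve

min over a of ½ w_c ‖c̄ − H a‖² + ½ w_a aᵀa + ½ w_d ‖a_prev − a‖²,
0 ≤ a ≤ 1,

with weights w_c = 1, w_a = 0.0025, w_d = 0.00001. The tracking term is
implemented with the squared norm — the standard strictly convex tracking
QP of the forward-dynamics assisted tracking framework — although the
source prints the first term unsquared; the squared form is what makes
the per-step problem a well-posed QP consistent with the damping term.
The QP is solved by an exact active-set method (the problem is
diagonal-plus-rank-one with at most a dozen variables) and each solution
carries a KKT certificate; tests verify the certificate independently and
cross-check against projected quasi-Newton. Coordinate descent was
rejected: with w_a + w_d ≈ 0.0025 against ‖H‖² ≈ 1e4 the Hessian
condition number is ~4e6 and first-order sweeps stall far from the
optimum.

**Integration.** Semi-implicit (symplectic) Euler with the damping terms
folded implicitly into the effective mass matrix, 10 substeps per 1 ms
tracking step for the stiff contact forces, velocity-level constraint
enforcement via a Lagrange multiplier, and position-level Newton
projection to below 1e-8 mm residual. The multiplier is a force, so the
achieved bite force is read directly from it. Determinism is exact:
repeated runs are bit-identical. Quasi-static damping (300 N·s/m,
1 N·m·s) settles the 0.25 s clench to near-equilibrium; the terminal net
force and torque are below 1e-3 N and 1e-3 N·mm in the tests. An
energy-drift check on a deliberately soft elastic-pendulum configuration
(so the symplectic energy bound, not stiffness error, is measured) stays
under 1 % over 0.25 s at dt = 1 ms.

**Outputs.** `simulate_task()` records activations, achieved bite force
and per-side joint contact force histories; steps whose target exceeds
the attainable bite force at the bounds are flagged `saturated` rather
than erroring. `summarize_joint_loading()` reports terminal
`100·|joint force| / bite force` per side.

## Mandible-length validation sweep

`rescale_mandible()` moves every *mandible-fixed* point (muscle and
ligament insertions, bite points, menton, center of mass) along the
anterior-posterior axis in proportion to its AP distance from the
condyle-top plane; cranial origins and sockets stay put, exactly as a
surgical advancement/setback changes the mandible against an untouched
cranium. Mandible length is the mean 3D condyle-top-to-menton distance,
and the scale factor is solved so the target length is met exactly.

`resultant_moment_arm()` is defined torque-consistently: the total muscle
torque about the bilateral condyle-center axis divided by the resultant
force component perpendicular to that axis. An insertion-centroid
anchoring of the resultant was considered and rejected: it does not
preserve the summed torque, so the arm simply tracks the anterior shift
of the insertions under rescaling and the length/moment-arm ratio
degenerates to a near-constant, erasing the relationship the sweep is
meant to expose.

`run_sweep()` simulates a 50 N left unilateral bite at each length
(105–135 mm in 5 mm steps by default, 250 tracking steps each), records
the average bilateral normalized joint force (mean of the two terminal
percentages over 100), and fits it against length/moment-arm by ordinary
least squares. On the toy mandible the fit is essentially exact
(R² ≥ 0.998) with a positive slope; the slope value itself is
geometry-specific and is only checked for sign.

## The synthetic generators

All generators are pure functions of their parameters and seed.

`gen_bite_recording()` emulates the five-bite staircase at 2000 Hz. The
EMG carrier is a constant-envelope frequency-modulated sinusoid wandering
inside the 20–450 Hz surface-EMG band rather than Gaussian noise: a
stochastic carrier's rectified-envelope sampling noise over a 0.25 s
ratio window is 5–10 %, which would swamp a 2–5 % ground-truth recovery
contract, while the FM carrier occupies the same band with a
deterministic envelope (additive Gaussian noise is available via
`noise_sd`). Channel envelopes are power laws of the force level chosen
to be equal at the 20 N baseline bite and to hit the prescribed IC ratio
at the top bite — prescribing the ratio on the *normalized* envelopes,
since per-channel baseline normalization cancels any common
multiplicative asymmetry. Default prescribed ratios are 1.5/1.4 at a
50 N plateau, a realistic left-bite setting.

`gen_surface()` meshes height surfaces (plane, sphere, cylinder,
ellipsoid, saddle) on an equilateral grid at 0.3 mm with analytic
per-vertex curvatures attached; `gen_condyle_fossa_pair()` builds a
convex condyle under a concave socket with a known clearance field, with
an `incongruence` parameter that morphs the socket toward an ellipsoid.

`gen_toy_mandible()` builds a bilaterally symmetric mandible with
condyle-top-to-menton length 117.8 mm by default: six active muscles per
side at anatomically oriented lines of action (superficial masseter ~27°
anterior inclination, posterior temporalis strongly retrusive, medial
pterygoid anteromedial), maximum isometric forces spanning 100–270 N
(placeholders in the physiologic range, overridable), seven ligaments per
side with the reference slack lengths, elastic-foundation joint sites
with the cartilage constants, and first premolars 70 mm anterior of the
condyles (premolar-to-condyle-top distance 78.8 mm, inside the measured
74–104 mm biting-arm range of the study subjects).

### What the synthetic data do and do not show

Passing tests on the generators establish that the signal chain recovers
known envelope ratios and force levels, that the geometric fields match
analytic ground truth, and that the simulator's mechanics obey closed
forms and conservation laws. They do *not* establish clinical validity on
real anatomy: real EMG has non-stationary noise, crosstalk and motion
artifacts; real condyles are not spheres and real fossae are not
ellipsoids; the toy mandible is mirror-symmetric while patient anatomy is
not — and contralateral-versus-ipsilateral joint-load orderings are
sensitive to exactly those asymmetries and to the measured IC ratios, as
the study subjects' own data show. Scaling stresses reproduce a printed
table because they are deterministic arithmetic on measured inputs; they
carry that table's measurement uncertainty.

## Problem sizes and runtimes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale: meshes of roughly 1–4 thousand vertices at the 0.3 mm
density, 250-step clench simulations with 10 integration substeps, a
7-length sweep (about 20 s total), 100-instance QP oracle checks and
20-seed signal-recovery replicates. These sizes were chosen to exercise
every code path at full numerical fidelity while keeping the whole suite
around a minute.

## Known limitations

* No finite-element disc or capsule stress fields: joint load transfer
  uses the elastic-foundation site model; the hyperelastic laws are
  implemented and unit-verified but not assembled into an FE solve.
* Static clenching only — no mouth-opening kinematics, chewing cycles, or
  muscle contraction dynamics; the twelve-muscle full set beyond the six
  active per side is representable but only contributes passive force.
* Viscoelasticity, anisotropy, and region-dependent disc properties are
  out of scope.
* Mesh processing assumes clean, oriented triangulations; no repair or
  remeshing beyond degenerate-face rejection.
* The bite constraint is bilateral (it can pull as well as push), an
  idealization of biting on a rigid plate.
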