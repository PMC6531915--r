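---
title: "Modeling infarct border-zone substrates and in-silico VT induction"
author: "ivtlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling infarct border-zone substrates and in-silico VT induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`ivtlab` implements the chronic-infarct ventricular tachycardia (VT)
modeling pipeline at desk scale: from a delayed-enhancement-MRI-like
intensity volume to a labeled anisotropic tissue model, through
monodomain electrophysiology with healthy and remodeled human
ventricular membranes, to programmed-stimulation inducibility testing
and a forward ECG through a torso volume conductor.

The electrical substrate is the monodomain reaction-diffusion equation

$$\chi C_m \frac{\partial V_m}{\partial t} =
  \nabla\cdot(\sigma \nabla V_m) - \chi\, I_{ion}(V_m, \mathbf{s}),$$

with the conductivity tensor built from the local fiber direction
$\mathbf{f}$ as
$\sigma = \sigma_L \mathbf{f}\mathbf{f}^T + \sigma_T(I -
\mathbf{f}\mathbf{f}^T)$. Membrane kinetics are the ten Tusscher-Panfilov
(2006) human ventricular model with its three transmural parameter sets
(endo, M, epi). Border-zone (BZ) electrical remodeling (ER) scales the
maximal conductances of $I_{Na}$, $I_{CaL}$, $I_{Kr}$ and $I_{Ks}$ to
38%, 31%, 30% and 20% of their healthy values; scalings are always
applied to the published base set, so deriving a phenotype is
idempotent. Fibrotic elements carry the MacCannell (2007) active
fibroblast membrane and an isotropic conductivity of 0.1 S/m; fibroblasts
couple to myocytes purely through the tissue diffusion operator, acting
as current sinks during the plateau and weak sources at rest. Dense scar
is a perfect insulator: scar elements are removed from the conducting
domain, which imposes an internal no-flux boundary at the scar
interface.

## Tissue discretization and its limits

Space is discretized on regular hexahedral grids (default edge
0.4 mm) with a trilinear finite-element stiffness and a consistent
(non-lumped) mass matrix; time stepping is first-order operator
splitting with the paper-standard base step of 0.02 ms: an implicit
diffusion solve (Jacobi-preconditioned conjugate gradient, relative
tolerance $10^{-6}$) followed by an explicit ionic update (Rush-Larsen
for gates, forward Euler for potential and concentrations, substepping
adaptively so no substep moves $V_m$ by more than 0.2 mV).

The product $\chi C_m$ is not separately identifiable from published
tissue measurements, so it is **calibrated once**: on a pseudo-1D strand
at 0.4 mm with $\sigma_L = 0.24$ S/m and the healthy epicardial
membrane, $\chi C_m$ is adjusted until the along-fiber conduction
velocity (CV) equals 0.68 m/s. The calibrated value (about
2.17 uF/mm^3) is then frozen; every other velocity the package reports
is a prediction, not a fit.

Several discretizations were evaluated against the study's CV table
before freezing this scheme (lumped vs consistent mass, backward Euler
vs Crank-Nicolson, nodal vs quadrature-interpolated ionic currents).
Two facts are worth recording:

* For planar wavefronts every consistent spatial stencil collapses to
  the same effective 1D scheme; what differentiates schemes at 0.4 mm
  is the mass treatment and the placement of the ionic current. Lumped
  mass slows slow transverse waves by 25-60% and blocks the slowest
  BZ case outright; interpolating membrane states to quadrature points
  overshoots far above the continuum limit. The consistent-mass
  nodal-current scheme used here is the best-behaved compromise.
* The reference CV table itself cannot be matched in full by any single
  convergent scheme: its healthy transverse entry (sigma_T =
  0.0456 S/m, printed 0.26 m/s) and its BZ longitudinal entry with the
  original membrane (sigma_L = 0.05 S/m, printed 0.225 m/s) correspond
  to nearly identical diffusivities and the same membrane, yet differ
  by 15%; and the BZ transverse entries equal the longitudinal entries
  divided by the healthy anisotropy ratio exactly, suggesting they were
  derived rather than measured. With $\chi C_m$ frozen on the healthy
  longitudinal target, this package reproduces the longitudinal BZ
  velocities and the 75%/65% reductions within 10%, and underestimates
  the transverse entries (by about 15% for healthy tissue and more for
  the slowest BZ settings, which sit in the strongly discrete
  propagation regime at 0.4 mm).

## Substrate synthesis

The synthetic generator emulates the imaging inputs of the pipeline: a
remote myocardium plateau with Gaussian variability, a hyper-enhanced
scar core (plateau >= 3 SD units above the remote mean; default 5), a
BZ rim whose noise-free intensities ramp across the (mean + 2 SD,
mean + 3 SD] band, a lower-intensity channel crossing the scar, and
spatially correlated noise (a Gaussian-smoothed field mixed with white
noise; the correlated fraction makes the brightest BZ voxels cluster
into patches rather than salt-and-pepper). Classification follows the
standard-deviation method with per-slice remote statistics by default
(scar at or above mean + 3 SD, BZ in [mean + 2 SD, mean + 3 SD); both
boundaries closed on the left for determinism). Voxel-to-element
transfer assigns each element the voxel containing its centroid, so a
1.4 mm voxel maps to at most 64 elements at 0.4 mm. Patchy fibrosis at
level $p$ relabels exactly $\mathrm{round}(p/100 \cdot N_{BZ})$ BZ
elements in descending mapped intensity, ties broken by element index.
Fibers follow a rule-based helix angle varying linearly from +60 deg
(endo) to -60 deg (epi) across normalized transmural depth, with
optional 3D Gaussian smoothing; transmural layers use the 17/41/42%
wall-thickness fractions (cut points 0.17 and 0.58).

What the generator does **not** emulate: patient anatomy (curved walls,
papillary muscles, trabeculations), acquisition artifacts, partial
voluming, or registration error. Passing tests on these volumes
demonstrates the correctness of the classification and mapping
operators, not clinical segmentation performance.

## The isthmus fixture and the inducibility loop

The reentry experiments run on a thin-sheet fixture holding two scar
blocks separated by a funnel-shaped BZ channel: a narrow lower
(apical) mouth, a wide upper (basal) mouth, a BZ rim around the scar
and healthy tissue elsewhere; fibers run along the channel. Below the
narrow mouth the scar walls continue as thin diverging tails, so the
channel exit widens gradually. This trumpet-shaped exit is essential:
with an abrupt exit the retrograde wavefront emerging from the narrow,
weakly coupled channel faces the full half-plane as an electrotonic
sink and blocks in both directions, which was confirmed empirically
while designing the fixture. Fixture defaults (sheet 44 x 48 mm, scar
blocks spanning 26 x 22 mm, mouths 3.2/6.4 mm, rim 3.2 mm, tails 6 mm,
dx = 0.8 mm) were chosen once so that a realistic reentrant circuit
(cycle length well above the remodeled refractory period) fits in a
desk-scale simulation.

The programmed-stimulation loop reproduces the clinical protocol: an S1
drive train (defaults 6 x 600 ms), then an S2 coupled at 400 ms,
decremented in 10 ms steps until sustained reentry or capture failure
at the pacing site; if S2 alone never induces, the loop repeats with an
S3 coupled at the same interval as S2 (the joint-decrement reading of
the protocol). Capture is a 0 mV crossing at the pacing site within
10 ms of the stimulus. Sustained reentry requires at least three
activations of a reference node after the last stimulus (three cycles
separate true reentry from a single echo beat); the VT cycle length is
the mean inter-activation interval. Block classification at the mouths
uses the logged 0 mV upstroke times: unidirectional means the narrow
mouth fails to activate in the immediate post-stimulus window but is
re-entered later, retrogradely, after the upper mouth.

On this fixture, the ER-on versions are inducible from the site below
the narrow mouth with S2 at the first tested coupling interval and show
the expected mechanism (antegrade block at the narrow mouth, entry
through the wide mouth, retrograde channel transit, re-excitation), a
VT cycle length around 700-730 ms at dx = 0.8 mm; the ER-off, 0%
fibrosis version is non-inducible at every tested interval. The
desk-scale test runs use a shortened drive (2 S1 beats), a 30 ms
decrement bounded at 340 ms and a 0.05 ms step on the 0.8 mm sheet;
these sizes are the package's choice of test scale and do not change
the protocol logic, which defaults to the full clinical settings.

## Forward ECG

Extracellular potentials come from the passive (diffusion-only)
bidomain relation $\nabla\cdot((\sigma_i + \sigma_e)\nabla\phi_e) =
-\nabla\cdot(\sigma_i\nabla V_m)$ under the equal-anisotropy-ratio
convention, gauge-fixed to zero mean. The torso is a tetrahedral P1
finite-element Laplace problem with Dirichlet values at the
ventricles-torso interface, natural (no-flux) conditions on the body
surface, heterogeneous per-region conductivities (defaults, S/m: lungs
0.0389, liver 0.147, bone 0.02, blood 0.7, unassigned space 0.239) and
sparse Cholesky factorization reused across time steps. Validation
uses closed-form cases: uniform Dirichlet data (harmonic constants),
an l = 1 series solution on a concentric-spheres shell (2% tolerance at
the shipped mesh resolution), conductivity-scale invariance, gauge
shifts and dipole antisymmetry on a symmetric box phantom. The phantom
torso stands in for patient anatomy; ECG comparisons against it are
smoke tests of the solver chain, not physiological validation.

## Numerical choices and degenerate inputs

* Stimuli are transmembrane current densities (pA/pF), default 2 ms,
  amplitude about twice diastolic threshold; a single-cell default of
  -52 pA/pF for 1 ms. Sub-threshold stimuli are reported as
  "no capture", never silently extended.
* APD90 runs from the time of maximum upstroke velocity to 90%
  repolarization toward the per-beat pre-upstroke minimum; local
  activation time (LAT) is the max-dV/dt instant, consistent with
  electrogram conventions. Quiescent traces yield the resting potential
  with other biomarkers absent.
* SD classification with an empty remote ROI in a slice containing
  infarct raises an error naming the slice; a channel wider than the
  scar, non-unit fibers on conducting elements, fibrosis levels outside
  [0, 100]% and layer fractions not summing to one are all rejected.
* All randomness (synthetic volumes, fixture pseudo-intensity) is
  seeded and recorded; identical seeds give bit-identical outputs, and
  repeated simulations of identical configurations are bit-identical.

## Known limitations

* No bidomain tissue solve, bath loading, mechanics or Purkinje system.
* The CV table discrepancies discussed above: transverse velocities at
  0.4 mm are underestimated relative to the published table, which is
  itself internally inconsistent at the 15% level.
* Patient-scale results (scar fraction of the left ventricle, specific
  inducing coupling intervals, VT rate on the patient geometry, ECG
  correlation against patient recordings) are out of scope; the
  fixture-scale experiments reproduce mechanisms and protocol logic,
  not patient numbers.
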