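---
title: "Methods: a desk-scale digital twin for forearm FES"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale digital twin for forearm FES}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(festwin)
```

## The modeling problem

Transcutaneous functional electrical stimulation (FES) of the forearm has to
activate individual wrist and finger muscles selectively before it can drive
complex hand movements. `festwin` implements a desk-scale digital twin of the
stimulated forearm in three coupled stages, following the classical two-step
simulation approach for FES:

1. a **volume conductor**: a layered (bone, anisotropic muscle, fat, skin)
   parametric phantom with hydrogel surface electrodes, on which the
   quasi-static extracellular potential is solved for a unit stimulation
   current;
2. a **muscle-specific fiber arrangement**: for each muscle, an elliptical
   region of interest (ROI) anchored at the nerve entry point (NEP) is seeded
   with straight myelinated fibers drawn from a bimodal diameter
   distribution, with nodes of Ranvier at diameter-dependent spacing;
3. a **nerve model**: the linear cable model (and, as a cheaper alternative,
   the activating function) predicts per-fiber activation from the
   extracellular potential at the nodes; the fraction of activated fibers in
   a ROI is the muscle activation.

On top of these, the package implements the evaluation pipeline that relates
simulated strength–duration (SD) curves to experimental ones: Weiss-hyperbola
fitting, mean relative differences over 1 µs pulse-width steps, per-muscle
activation-threshold (ath) selection over two pulse-width ranges, and
repeat-variability (RSD) summaries.

## Volume conductor

### Governing equation and its reduction

The propagation of a stimulation pulse in tissue is governed, under the
quasi-static approximation, by a conduction–polarization equation containing
both a resistive term (conductivity σ) and a capacitive term (permittivity
ε). For rectangular pulses in linear media the capacitive term contributes
only at the pulse edges, and the standard FES material set places the
corresponding relaxation times well below the shortest pulse widths
simulated here (20 µs plateau with 10 µs ramps). The package therefore solves
the purely resistive problem

> ∇·(σ∇V) = 0

once for a unit current, and factors time through the pulse waveform:
V(p, t) = V_unit(p) · I(t). Relative permittivities are carried in the
material table for future extension but do not enter the solve.

### Discretization

Instead of tetrahedral finite elements in commercial software, the solver
uses a finite-volume scheme on a structured voxel grid: one degree of freedom
per tissue voxel, face conductances as harmonic means of the adjacent
per-axis conductivities, zero normal flux on the outer surface, uniform
current density over the active electrode face, and the outer face of the
indifferent electrode grounded through half-cell conductances (V = 0
reference). The resulting sparse symmetric positive-definite system is
solved by a direct Cholesky factorization and the relative residual is
checked (default tolerance 10⁻⁶; direct solves land near machine precision).

Accuracy is controlled by the voxel size. The test suite pins this with a
closed-form oracle — a homogeneous 10×10×100 mm cuboid with full end-face
electrodes must reproduce ΔV = I·L/(σA) = 3.0 V at 1 mA — plus current
conservation across interior planes and a monotone grid-refinement check.
The half-cell treatment of the electrode faces makes the cuboid oracle exact
at any resolution; genuinely 3D fields (patch electrodes) converge with the
grid. The default phantom resolution is 4 mm, which keeps a full-arm solve
in the single-second range on one CPU; the skin (1 mm) is then deliberately
kept at least one voxel thick by assigning the outermost tissue voxel ring
to skin, which preserves the resistive barrier at the cost of exaggerating
its thickness — refine the grid when absolute amplitudes matter.

### Geometry and coordinates

The published twin was built from MR slices of an individual forearm; those
station ellipses are not available. The default phantom is therefore a
smoothly tapered elliptical cylinder: skin semi-axes 45×40 mm (elbow) to
30×24 mm (wrist), 1 mm skin, 3 mm fat, two tapering elliptical bones — values
a scientist would call a plausible adult forearm. Users can supply a full
per-station table to mimic an individual. The axial coordinate runs from the
lateral humeral epicondyle (LEH, z = 0) to the radial styloid process (RSP,
z = 242 mm by default) with a 5% proximal extension (total 254.1 mm);
electrode and ROI positions are percentages of the LEH–RSP length and of the
skin circumference counterclockwise from a reference line (azimuth anchor).

### Stimulus polarity

The published description places "a current" on the active electrode near
the muscle and a sink at the wrist without stating polarity. Stimulators
deliver the depolarizing phase as a cathodic pulse at the muscle electrode,
so the recruitment functions default to `polarity = "cathodic"`: the drive
seen by the fibers is −amplitude × unit field. The anodic option is kept for
completeness.

## Fiber arrangement

The NEP table (20 ROIs after exclusions) fixes each ROI's axial center at
the median NEP; ROIs extend 10 mm proximally and distally. The brachioradialis
is excluded outright (its tabulated positions come from extended cadaver arms
and fall outside the flexed-arm model) and the remaining negative proximal
bound (ECRL) is clamped to 0. The finger flexors are split into proximal and
distal sub-ROIs because their NEPs span more than half the forearm; both
sub-ROIs share one cross-section hint, since no per-split rule is published.

Because the per-muscle segmentation ellipses behind the published model are
unavailable, cross-section placement (azimuth, depth), semi-axes and
orientation come from a shipped hint table explicitly labelled synthetic
(`roi_hints_synthetic.csv`): flexors ventral, extensors dorsal, semi-axes by
muscle size class, long-axis alignment. Every value is overridable by CSV.
This affects *where* a ROI sits, not *how* the construction rules work, and
it is the main reason the package reproduces the published construction
arithmetic but not the published per-muscle amplitudes.

Each ROI receives 500 fibers (default) with cross-section positions uniform
over the ellipse and diameters from a mixture of two truncated normals on
[2, 16] µm. The published distribution is an averaged histogram with peaks at
5 and 11 µm; its bin heights are not tabulated, so the shipped mixture
(means 5 and 11 µm, spreads 1.5 and 2.0 µm, weights 0.55/0.45) is an
approximate stand-in that reproduces the stated support and modes, and every
parameter is configurable. Internodal spacing is the linear map
2 µm → 155 µm, 16 µm → 1500 µm; the first node sits at a uniform random
offset in [0, Δx) from the ROI bottom face, so node phases differ across
fibers as they do in tissue. Per-ROI random streams are derived as
`root_seed + 1000 × muscle_index`, so adding a muscle never perturbs the
draws of another.

## Nerve models

### Linear cable model

Each fiber is a chain of nodes of Ranvier connected by perfectly insulated
internodes. All ionic currents are lumped into a time-invariant leak
(I_ionic = G_m·V_m with V_m the deviation from rest), giving the linear
system

> dV_m,n/dt = (1/C_m) [ G_a (ΔV_m + ΔV_e)_n − G_m V_m,n ]

where Δ is the spatial second difference along the fiber (single-neighbor,
sealed-end differences at the two terminal nodes of the finite fiber). With
axon diameter d_a = 0.7·d (the classical fiber-to-axon ratio; the node
diameter convention is not stated in the source material, so this is a
package default): G_a = πd_a²/(4ρ_iΔx), C_m = c_mπd_aL, G_m = g_mπd_aL, with
ρ_i = 0.7 Ωm, g_m = 30.4 mS/cm², c_m = 2 µF/cm², L = 2.5 µm, rest −70 mV and
threshold −55 mV. A fiber is activated when any node reaches the threshold
(a 15 mV depolarization) at any simulated time; which node set to examine is
not stated in the source description, and all nodes is the assumption here.

**Integration.** The system is stiff for small fibers (coupling time
constants around 16 µs against a 66 µs membrane constant), so an implicit
scheme is required at the default 1 µs step. The package uses the implicit
trapezoidal (Crank–Nicolson) scheme: like backward Euler it is
unconditionally stable, but its second-order accuracy keeps the trajectory
within 0.1% of the matrix-exponential closed form at dt = 1 µs (verified in
the tests on 3–9 node systems), where a first-order scheme would need a far
smaller step. The simulated window is the pulse plus 1 ms, covering
post-pulse depolarization peaks.

**Thresholds by linearity.** Because the model is linear, the response to an
A mA pulse is A times the response to the 1 mA pulse. Per-fiber threshold
amplitudes are therefore computed in closed form,
A_th = 15 mV / max_{n,t} D_n(t), with D the unit-pulse depolarization — no
amplitude search. The tests verify agreement with bisection on the simulator
to <0.5%. Fields that never depolarize any node give A_th = ∞.

### Activating function

The discrete activating function AF_n = (V_e,n−1 − 2V_e,n + V_e,n+1)/Δx²
predicts depolarization where positive. Activation requires AF to exceed a
threshold depending on axon diameter and pulse width; the cited lookup
values are not reprinted in the source material, so the default table is
**calibrated against the cable model** on a canonical geometry (cathodic
point source 10 mm above a centered fiber in a homogeneous 3 Ωm medium): for
each (d, PW) on a grid, the cable threshold is computed in closed form and
the corresponding peak AF recorded. The table is cached per session,
interpolated bilinearly (edge-clamped with a warning), and overridable by
CSV. On the calibration geometry the two models agree on ≥90% of verdicts
near threshold; away from that geometry the AF remains the cruder
instrument, consistent with its published failure at low pulse widths.

## Recruitment and evaluation

Muscle activation is the activated fraction of the ROI's fibers. A muscle
counts as "active" when the fraction reaches its activation threshold (ath);
simulated SD curves report, per pulse width, the smallest amplitude at which
that happens — under the cable model this is exactly the ⌈ath·n⌉-th order
statistic of the per-fiber thresholds. A grid mode rounds thresholds up to
the 1 mA amplitude grid of the experimental protocol; ties at the order
statistic resolve inclusively (the common value is the threshold).

SD points are fitted with the Weiss hyperbola A(PW) = b(1 + c/PW) — the
standard strength–duration parameterization; the source material names the
rheobase concept but not its fit form, so the form is pluggable. The fit is
linear in (b, b·c) via the regressor 1/PW, hence exact on noiseless data.
Mean relative differences between curves are averaged over *integer* pulse
widths in a range (20–200 µs spans 181 points); fitted-curve evaluation is
the default and point-curve interpolation is provided. Per-muscle ath
selection takes the argmin over the candidate grid {0.05, …, 0.50}, breaking
ties at the printed 3-decimal precision by the fourth decimal and any exact
remainder toward the smaller ath. Range-wise default thresholds average the
selected values and round **up** at the second decimal — the conservative
direction (a higher threshold never overestimates activation for muscles
that were never validated individually), and the convention under which the
packaged selections reproduce the published defaults (0.20 for 20–200 µs,
0.12 for 201–500 µs):

```{r defaults}
sel <- select_ath_table()
default_ath(sel)
```

The repeat-variability summary (RSD) uses the sample (n−1) standard
deviation per pulse width divided by the per-pulse-width mean, averaged over
pulse widths; the convention is documented here because the source material
does not state it and the repeats are few (n = 4).

## Synthetic experimental data

The raw experimental measurements behind the published evaluation are not
deposited, so `generate_experiment()` stands in for them: Weiss-hyperbola
truth (default b = 5 mA, c = 200 µs) on the 13-point experimental pulse-width
grid, with multiplicative zero-mean Gaussian noise per point and repeat. The
default relative noise of 6% places the repeat RSD inside the published
0.04–0.09 band; it emulates electrode-repositioning scatter as white noise
and deliberately ignores the systematic, position-correlated component real
repositioning has. Passing tests on synthetic data therefore demonstrate the
pipeline's arithmetic, not agreement with any individual's physiology.

## Problem sizes, determinism, degenerate inputs

The test suite and examples run on deliberately small instances: 2–5 mm
grids, cuboid verification geometries, populations of 40–500 fibers, a
handful of pulse widths. These sizes keep every stage's verification oracle
(closed forms, matrix exponentials, bisection) cheap while exercising the
same code paths as a full study; the vignette's own chunks use the packaged
table only. All randomness flows from explicit seeds; identical
configuration and seed give bit-identical curves and CSV artifacts.
Degenerate inputs fail loudly: non-nested layer ellipses name the station,
electrodes wider than half the circumference are rejected, ROIs outside the
axial range error, fibers shorter than one internode error, SD fits require
three distinct pulse widths, and a missing sink makes the field solve refuse
rather than return a floating potential.

## Known limitations

- The default phantom and ROI hints are population-plausible, not
  individual: published per-muscle amplitudes and Table-level SD differences
  are out of reach without the MRI-derived geometry, and no claim is made
  about them.
- The resistive solve ignores electrode–skin interface impedance beyond the
  hydrogel layer; no interface network values are published to parameterize
  one.
- Fibers are straight and parallel to the ROI axis; terminal branching and
  curved trajectories are not modeled.
- The linear cable model has no channel kinetics: no refractoriness,
  accommodation, or repetitive-pulse effects; the AF table inherits the
  cable model's simplifications through calibration.
- Muscle force is represented only by the activation fraction; force
  magnitude mapping and musculoskeletal coupling are out of scope.
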