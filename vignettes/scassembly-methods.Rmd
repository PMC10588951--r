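---
title: "Models and methods behind scassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scassembly)
```

# Scope

`scassembly` packages the quantitative machinery used to study whether the
N-terminal head-to-head self-assembly of SYCP1 — the transverse filament
protein of the synaptonemal complex (SC) — is required for chromosome
synapsis. Three strands of analysis are covered:

1. a **steered-dissociation assay** on a coarse-grained model of the SYCP1
   alphaN-end "dimer of dimers", with the trajectory metrics used to read
   it out (superposition RMSD, per-residue RMSF, the interdimer marker
   distance, and an intact/loosened/dissociated classification);
2. an **image-quantification pipeline** for superresolution (SIM-class)
   images of chromosome axes: trace straightening, perpendicular intensity
   profiles, double-Gaussian peak fitting for axis separation, focal
   projection and background-subtracted integrated ROI intensity;
3. the **statistical comparisons** appropriate to those readouts:
   Mann-Whitney U for intensities, Fisher's exact test on dichotomized
   per-tubule apoptosis counts, and the unpaired t test for organ weights —
   each paired with an independent enumeration oracle used in the tests.

Because real steered all-atom trajectories and real SIM acquisitions are
far beyond desk scale, both data-generating stages are backed by synthetic
generators with known ground truth; every analysis claim in the test suite
is a parameter-recovery or closed-form statement about those generators.

# The coarse-grained dissociation assay

## Geometry

`build_tetramer_model()` places four chains of 75 beads (one bead per
residue of the human alphaN-end, residues 101–175; bead spacing 1.5 Å, the
axial rise per residue of a coiled coil). Chains pair into two dimers via
harmonic cross-links; the two dimers approach head-to-head along the z
axis, offset laterally by 6 Å, with their 11-bead alphaN-tips (residues
101–111) interdigitating so that the marker residues (human L109, mouse
L106) of the two dimers start about 6 Å apart. This realizes the defining
geometric property of the closed conformation: an interdimer marker
distance below 10 Å.

The interface itself is a set of attractive Gaussian contact wells between
tip beads of laterally adjacent chains of opposing dimers,

$$U(r) = -\varepsilon\, s_g \exp\!\left(-\frac{(r - r_0)^2}{2 w^2}\right),$$

with contact distance $r_0 = 6$ Å and width $w$ = half the
`interface_cutoff` (default 3 Å). The genotype factor $s_g \in [0, 1]$ is
the only thing that distinguishes wild type from glutamate substitutions
of the tip leucines: mutation is modelled purely as interface weakening,
not as explicit electrostatics.

## Dynamics

`simulate_assembly()` integrates overdamped (position-)Langevin dynamics,

$$\Delta x = \frac{F}{\gamma}\,\Delta t +
  \sqrt{\frac{2 k_B T\, \Delta t}{\gamma}}\; \xi,$$

per bead, in reduced units where $k_BT$ at 310 K is the energy unit and
lengths are in Å. There is no inertia, solvent, thermostat chain or
barostat: the aim is the qualitative force/stability phenomenology of the
steered assay, not thermodynamic fidelity. Two closed forms anchor the
integrator and are enforced in the acceptance suite: free beads diffuse
with $\langle \Delta x^2 \rangle = 6 (k_BT/\gamma) t$ (Einstein relation,
checked to 10%), and with noise and interface off, a steering force $F$
per bead separates the dimers at exactly $2F/\gamma$ (checked to 1%).

Steering mirrors the published setup: a constant force is applied to
*every* bead of each dimer, along the axial axis, in opposite directions
for the two dimers. Forces are specified in the same units as the
published per-atom grid (0.025–0.10 kJ mol⁻¹ nm⁻¹), converted internally
to per-bead reduced forces through a single calibration factor
(`force_scale`, default 130). This follows the original procedure, where
the force range was chosen empirically so that mutant structures
consistently dissociate and the wild type consistently holds within a
100 ns run; a residue bead stands for ~19 atoms and the friction is
phenomenological, so a per-atom-to-per-bead conversion cannot be derived
from first principles and is calibrated instead.

## Calibration — fixed, then frozen

The free parameters (well depth 10 kT/pair, `force_scale` 130, genotype
scales 1.0 / 0.55 / 0.19 / 0.11 for WT / L102E / L106E / L102E+L106E)
were chosen once, before the acceptance checks were written, against the
qualitative behaviour pattern of the steered assay, and then frozen:

* WT intact at all four forces for 100 ns;
* L102E intact at low forces, loose at 0.075, dissociating only at 0.10
  (the behaviour of the peripheral-residue mutant);
* L106E loosened but not dissociated at 0.025, dissociating at 0.05–0.10
  with mid-force disruption around 50 ns;
* the double mutant dissociating fastest, including at the lowest force
  in most replicates.

Quantitative nanosecond disruption times of the all-atom assay are
explicitly out of scope; only the ordering and the intact/dissociated
pattern are claims of this package.

## Dissociation classification

`detect_dissociation()` smooths the interdimer-distance series with a
centred running median (window 5 frames) and calls **dissociated** when
the smoothed distance crosses 30 Å and stays above the 10 Å intact
criterion for the remainder of the run (disruption time reported at frame
resolution, no sub-frame interpolation); **loosened** when the 10 Å
criterion is exceeded persistently but 30 Å is never met; **intact**
otherwise. Only the 10 Å intact criterion comes from the source assay;
the 30 Å dissociation threshold and the 5-frame window are package
defaults (30 Å is far above any intact-state fluctuation yet far below
the drift scale of a dissociated pair), recorded in every result object.

The marker distance is the Euclidean distance between the centroids of
*all* particles of the marker residue in each dimer; the assay's
description does not name an atom, so the residue centroid is the
contract here. RMSD superposition is unweighted (coarse-grained beads are
uniform) and, for RMSD series, against frame 1 of the trajectory —
whether the original analysis referenced frame 0 or the crystal structure
is unstated, so the reference frame is a parameter.

# Synthetic imaging and its quantification

## Generator

`synthesize_axis_pair_stack()` renders two infinitely thin fluorescent
ridges offset by ± half the true separation on either side of a midline
polyline, convolved with an isotropic in-plane Gaussian PSF
(FWHM 120 nm by default, SIM-scale resolution), modulated across z by a
Gaussian focal envelope, over a uniform background, with Poisson shot
noise plus Gaussian read noise — all under an explicit seed. The default
pixel size is 40 nm (the post-reconstruction pixel size of the source
acquisitions is not published, so it is a parameter rather than a
constant). No z-PSF is modelled beyond the focal envelope because the
measured quantity is in-plane separation; no chromatin texture, tracing
errors, or reconstruction artefacts are emulated. Passing recovery tests
on these stacks therefore demonstrates correctness of the measurement
pipeline, not robustness to every failure mode of real SIM data.

## Measurement pipeline

`measure_axis_separation()` chains the published steps:

* `select_projection()` finds the slice with maximal total intensity and
  projects two slices above and below it. The projection operator is the
  per-pixel **maximum** (the original description says only "a
  projection"); the choice is logged.
* `straighten()` resamples the image along the spline-smoothed trace at
  1 px arc spacing with bilinear interpolation, rows being normal offsets.
* `sample_profiles()` takes 10 evenly spaced positions (half-spacing
  margins at the ends) and averages 3 adjacent columns per profile —
  thickness runs along the trace, the profile along the normal.
* `fit_profile()` detects local maxima with a prominence threshold of 3×
  a robust noise estimate (the MAD of second differences — raw-profile or
  first-difference MADs are contaminated by the ridge signal itself),
  keeps the two most prominent peaks (ties by amplitude), and refines
  their positions by least-squares double-Gaussian fitting with a
  constant baseline. Single-peak profiles are *unresolved*, not
  zero-separation, and are excluded from the mean.
* `classify_synapsis()` thresholds the mean separation at 250 nm
  (boundary assigned to unsynapsed). The threshold is a package default
  chosen midway between the reported synapsed (~130–150 nm) and
  unsynapsed (~330–365 nm) regimes, and is configurable.

The acceptance suite requires that true separations of 132, 145, 332 and
365 nm are each recovered with a mean absolute error below 10 nm over 20
seeds (observed: under 1 nm) with perfect synapsed/unsynapsed
classification.

`measure_roi()` implements the intensity readout: ROI area × (ROI mean −
background mean), with even-odd polygon rasterization at pixel centres
under a half-open boundary convention (documented so that pixel counts
are reproducible across implementations). A negative integrated intensity
is possible only when the ROI is dimmer than the background and is
flagged.

# Count models and tests

Per-tubule apoptotic-nucleus counts are modelled as a two-component
Poisson mixture (`tubule_count_model()`): baseline rate 0.2 with a
"bursting" fraction at rate 8, mimicking tubules undergoing apoptotic
arrest. Burst fractions of 0.015 and 0.16 are the study conditions for
the control/mutant contrast (the reported tubule percentages at the
five-or-more threshold are ~1.5% and ~16%). Counts are dichotomized at
five (inclusive on the high side) and compared by Fisher's exact test;
the acceptance suite verifies type-I error at or below nominal and power
above 0.9 at 200 tubules per group.

Test choices mirror the source analysis: Mann-Whitney U for intensity
comparisons (exact for tie-free samples with $n_x + n_y \le 12$,
otherwise tie-corrected normal approximation; the method is recorded),
Welch's t by default for weights (pooled available; the original does not
state which form was used), and no multiple-testing correction (the
source reports unadjusted pairwise tests), which is flagged in the
pipeline report.

# Numerical choices and degenerate inputs

* Timestep stability is guarded explicitly: any per-step bead
  displacement exceeding the bond length aborts with advice to reduce the
  timestep. At the default timestep (0.005 ns) and friction
  (0.5 kT·ns/Å2) the probability of a spurious trip is negligible.
* `kabsch_superpose()` uses the SVD construction with the determinant
  sign correction, and requires ≥3 non-collinear points. Its validation
  oracle, `rmsd_rotation_search()`, is a two-stage random rotation search
  (global quaternion sampling, then local resampling around the
  incumbent) that shares no code path with the SVD route.
* Integer percent identity is reported by truncation toward zero
  alongside the exact ratio: a 62/75 gapless alignment prints as 82%,
  which is the only way an integer percentage of 82 arises from a
  75-residue alignment. The rounding convention of external modelling
  servers is not standardized, hence both values are exposed.
* Sequence positions: the mouse alphaN-end (residues 98–172) maps to the
  human alphaN-end (101–175) by a fixed offset of 3 (human V105 ↔ mouse
  L102, human L109 ↔ mouse L106); the map functions validate their
  domains and are exact inverses.
* Degenerate statistics: Fisher requires positive margins (a dichotomized
  table with an empty column carries no evidence and is treated as a
  non-rejection in simulation studies); a t test between two identical
  constant groups returns p = 1 with a flag.

# Problem sizes

Default run lengths were chosen so the whole test suite and the
acceptance script each complete in a few minutes on one CPU: 100 ns
steered runs (20 000 steps of 0.005 ns, 300 beads), 96×128×7 image
stacks, 20 seeds per true separation, 1000 simulated Fisher tables per
error-rate estimate, and 100 random instances for the superposition
oracle. All of these are parameters, not limits.

# Known limitations

* The simulator is a phenomenological stand-in: no solvent, electrostatics,
  secondary-structure detail, or pressure coupling; nanosecond disruption
  times are qualitative only.
* Glutamate substitution enters only through the interface scale factor;
  charge-charge repulsion and solvent exposure are not modelled.
* The imaging generator does not emulate SIM reconstruction artefacts,
  multi-channel registration, or tracing errors; traces are supplied, not
  segmented.
* Whether the published intensity projection was maximum- or sum-based is
  unknown; per-pixel maximum is the package's documented choice.
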