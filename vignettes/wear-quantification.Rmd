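---
title: "Quantifying acetabular cup wear from micro-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying acetabular cup wear from micro-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Polyethylene acetabular cups wear against their metal femoral heads; the
released debris drives osteolysis and, eventually, revision surgery.  In
pre-clinical joint-simulator testing the standard way to quantify that wear
is gravimetric: weigh the cup on a microbalance before and after the test,
correct for fluid uptake with an unloaded soak-control cup, and call the
difference the wear.  Gravimetry is accurate but blind — it gives one number
per cup and says nothing about *where* material was lost, nor about plastic
deformation.

Metrological micro-CT offers an alternative: scan the cup before and after
testing, determine the material surface in each reconstructed gray-value
volume with sub-voxel accuracy, subtract the enclosed volumes, and convert
the volume deficit to mass with the polyethylene density.  Because the full
3-D geometry is available, the same data also yield a per-point wear map of
the articular surface.  `ctwear` implements this measurement chain, the
gravimetric reference workflow, and the method-agreement statistics used to
validate CT wear measurement against gravimetry — together with a synthetic
phantom generator so every stage can be exercised and tested against known
ground truth without any scan data.

## The phantom model

A cup is modelled as a hemispherical shell (inner radius $R_{in}$, outer
radius $R_{out}$, pole along $+z$, origin at the inner-sphere center) whose
analytic material volume is $\tfrac{2\pi}{3}(R_{out}^3 - R_{in}^3)$.  The
default geometry is the common 32 mm inner / 50 mm outer cup.

Wear is modelled as single-sphere penetration: the articulating head (by
default the same diameter as the inner surface) is translated a distance
$d$ along the load direction and the swept material removed.  This is the
simplest generator that reproduces the localized polar wear scar seen in
worn cups, where the scar position follows the load configuration.  It
deliberately does not separate wear from creep — retrieval wear maps mix
the two, and the validation target (a volume/mass deficit) is agnostic to
the distinction.  The ground-truth deficit `true_wear_volume()` is computed
by two independent brute-force oracles (a spherical-direction quadrature
and rejection Monte-Carlo in a bounding shell); for the default pole-aligned
load it also has a closed form via the equal-sphere lens volume, and the
three agree to well below 0.1%.

CT-likeness is produced by `voxelize()`: per-voxel material occupancy by
$3^3$ supersampling, scaled to a fixed material gray level of 100 over
background 0 (an arbitrary but documented contrast), convolved with an
isotropic Gaussian of one voxel standard deviation (partial volume plus
system blur), plus optional additive Gaussian gray noise under a caller
seed.  The default sampling lattice is offset by an incommensurate fraction
of a voxel so that flat faces of an axis-aligned solid can never coincide
exactly with voxel-center or subsample planes; exact coincidence would turn
the tie-breaking of boundary samples into a systematic volume bias (we
measured roughly +0.24% on the rim of an aligned cup before adopting the
offset).

What the generator does *not* emulate: polychromatic beam physics (beam
hardening, scatter), detector models, ring artifacts, cone-beam geometry,
or fluid-absorption physics beyond a saturating-exponential soak term.
Passing tests on these phantoms therefore demonstrate the correctness of
the geometry processing and statistics, not robustness to every real-world
artifact; the adaptive surface refinement is exercised against a synthetic
additive shading field as a proxy for slowly varying reconstruction
artifacts.

## Surface determination

The surface threshold starts from the ISO-50 convention: the midpoint of
the two dominant modes of the gray histogram.  Modes are found on a
smoothed histogram (256 bins, Gaussian kernel of 2 bins), the dominant mode
is paired with the highest mode at least a quarter of the gray range away,
and the pair must be separated by a valley dropping below half of the
smaller mode — otherwise the volume is declared inseparable (the documented
failure mode for low-contrast data).  Peak positions are refined by
parabolic interpolation, which keeps the noisy-histogram threshold within
±2 gray units of the noiseless answer in our tests.

The iso-surface at that threshold is extracted by marching tetrahedra on a
six-tetrahedron cube decomposition with linear sub-voxel interpolation.
The decomposition's face diagonals match between neighbouring cubes, so
the mesh is watertight and consistently oriented by construction whenever
the surface stays inside the grid; extraction fails loudly otherwise.

With `adaptive = TRUE` (the default) every vertex is then relocated along
the local gray-gradient direction to the 50% crossing between locally
estimated background and material levels — robust 10th/90th percentiles of
the gray profile sampled five voxels to each side at half-voxel steps.
This is a deliberate reimplementation choice: the principle (local
refinement of a global ISO-50 start) is standard in industrial CT
metrology, but the exact algorithm used by commercial packages is not
public.  One honest subtlety found while testing: under an *odd-symmetric*
multiplicative gray gradient the global threshold's volume errors largely
cancel by symmetry, so volume error alone can make the global method look
spuriously good; under a one-sided additive shading field (the realistic
cupping-artifact shape) the adaptive surface beats the global threshold by
about a factor three in volume error.

Enclosed volume is computed from the closed mesh by the divergence theorem
(signed tetrahedra against the origin, absolute value after an orientation
check).  Gray-value-weighted voxel counting is kept as an independent test
oracle only — the mesh is the primary estimator because the same mesh also
feeds registration and wear mapping.

## Registration, volume differencing, wear maps

Unworn and worn surfaces are aligned by rigid ICP: evenly subsampled
vertices of the moving mesh are matched to closest points on the reference
surface and the least-squares rigid transform is re-estimated (Kabsch/SVD)
until the point-to-surface RMS changes by less than 0.1% per iteration.
The articular calotte is excluded from the fit via a radius predicate
(default: everything inside the mid-shell radius), because including the
worn region would bias the alignment toward "explaining away" the wear.

One geometric fact shapes how registration accuracy is reported: the cup's
backside and rim are rotationally symmetric about the pole axis, so a pure
pole-axis rotation is unobservable to any surface-based registration.
Transform recovery is therefore assessed as *surface distance* (how far
the recovered-and-true composition moves points off the true surface), not
as parameter distance; at 0.25 mm voxels both the ICP residual and this
surface-distance error are below 0.06 voxel in our tests.

Volumetric wear is the difference of enclosed volumes,
$\Delta V = V_{before} - V_{after}$, which is invariant to any common rigid
motion; registration matters for the wear *map*, not the volume.  Mass is
$\Delta m = \rho \Delta V$.  Two density values circulate for UHMWPE in
this context, 0.934 and 0.945 mg/mm³, and published reports are not
consistent about which produced their converted masses; `ctwear` therefore
makes density an explicit argument with both values available as named
presets (`density_preset()`), defaulting to 0.934.  A negative measured
wear (worn volume larger than unworn) is reported with a warning rather
than clipped: it is a diagnostic for noise or registration failure.

The wear map casts a ray from each selected vertex of the unworn surface
along the inward material normal and records the signed distance to the
worn surface: negative deviations are material loss, following the
retrieval-analysis convention.  Ray misses within the search distance are
flagged `NA`, never zeroed.  The area-weighted integral of the deviation
field is an independent consistency check on $\Delta V$ (agreement within
about 2% on noiseless phantoms; the tests require 5%).

## The desk-scale CT stage

A parallel-beam forward projector and filtered back-projection pair let
the chain be exercised from projections.  Parallel geometry over 180° with
the exact discrete ramp (Ram-Lak) kernel — built from its band-limited
spatial form to avoid the DC bias of naive $|f|$ sampling — is a stated
simplification of the instrument's cone beam; an optional Hann window
apodizes the ramp for noisy data.  The real workflow treats reconstruction
as a black box, and nothing downstream depends on how the volume was made.

## Gravimetric reference and statistics

The soak correction is the additive control-gain form used in simulator
practice: $loss(t) = (w(0) - w(t)) + (c(t) - c(0))$.  Wear rates are
ordinary least-squares slopes of cumulative loss versus cycles over the
steady-state window; since break-in handling is a protocol choice the
window start is configurable, defaulting to 0.4 Mc (drop only the zero
point).  The weighing generator reproduces the campaign design: triplicate
readings on a 0.01 mg balance every 0.4 Mc to 2 Mc, with a saturating soak
term (amplitude 1 mg, time constant 0.5 Mc — chosen as typical for
pre-soaked polyethylene, where residual uptake is of order a milligram and
saturates early).

Between-material comparisons use the Kruskal–Wallis test with tie
correction.  At three specimens per material the chi-square approximation
is unreliable, so for small totals (N ≤ 12, configurable) the p-value is
computed by complete enumeration of all distinct rank partitions — 1680
for 3/3/3 — and the method used is always reported.  The enumeration is
validated against the chi-square route at moderate N and against
`stats::kruskal.test` for the H statistic.

The agreement analysis (`method_agreement()`) fixes the difference
convention to CT minus gravimetric in the data type itself, regresses CT
on gravimetric mass loss (gravimetric is the reference, hence x), computes
Bland–Altman bias and limits $bias \pm 1.96\,SD$ with the sample (n−1)
standard deviation — the conventional choice where the source material is
silent — Shapiro–Wilk normality of the differences (Royston's
approximation via `stats::shapiro.test`), and signed percentage
differences per specimen.

## Problem sizes and numerical choices

The hardware-scale reconstruction (31 µm voxels over a 50 mm cup,
~1600³ voxels) is far beyond interactive analysis; the package keeps
0.031 mm as the configuration default for real volumes but runs its own
validation at desk scale, chosen so that wear depth per voxel is
comparable to the real case (0.2–0.6 mm penetrations at 0.2–0.3 mm
voxels ≈ 1–2 voxels of wear depth, versus tens of µm wear at 31 µm
voxels).  Specific sizes: wear-volume recovery at 0.2 mm voxels (noiseless
and 20 noise seeds at 5% of the material level), registration recovery at
0.25 mm, and the three-specimen end-to-end pipeline at 0.3 mm with gray
noise SD 2.

Numerical details a maintainer should know: occupancy supersampling is
3³ per voxel; interpolation parameters `t` on lattice edges are clamped to
[1e-8, 1−1e-8] so iso-level ties cannot create degenerate welds; ICP
convergence is relative RMS change below 1e-3 with a hard iteration cap of
100 and an error (with the RMS trace) on non-convergence; the exact
Kruskal–Wallis comparison uses `H >= H_obs - 1e-9` to make ties in H
inclusive; Monte-Carlo wear-truth sampling uses 2×10⁷ points by default
(relative SD ≈ 4×10⁻⁴ for the default scar).

## Known limitations

- The penetration wear model is a stand-in: real scar geometry
  (multidirectional motion, creep ridges) is not reconstructed, and no
  claim is made that the generator's scars match any particular retrieval.
- X-ray physics is out of scope; volumes are geometric ideals plus blur
  and white noise.
- The adaptive refinement implements the contract (local 50% crossing
  within a window), not any specific proprietary algorithm.
- Backside wear is not analyzed; the wear map targets the articular
  calotte.
- Scale-error correction with calibrated artifacts is reduced to the MPE
  utility `mpe_length()` (9 + L/50 µm); no artifact-based correction is
  performed.
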