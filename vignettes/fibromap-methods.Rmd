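---
title: "fibromap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fibromap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and numerical choices behind fibromap:
what each component computes, which parameters matter, what the phantom
generators do and do not emulate, and where the design was genuinely open.
Everything quantitative stated here is recomputed by the test suite or by
`scripts/acceptance.R`; the vignette itself states no empirical result beyond
those.

## The problem

In fibrotic cardiomyopathies (the motivating system is a desmoglein-2 mutant
mouse), collagen accumulates both as dense scars — compact fibrosis, CF —
and diffusely intermixed with surviving myocytes — non-compact fibrosis,
NCF. Functionally, conduction through fibrotic regions deteriorates
selectively at high pacing rates: a "low-pass" behavior in which wavefronts
that traverse the tissue normally at low frequency slow down or block near
fibrosis at high frequency. fibromap provides the analysis chain to
quantify both sides of this correlation — epicardial electrophysiology from
voltage-sensitive-dye optical mapping, and 3D fibrosis/myocyte-orientation
morphometry from dual-channel light-sheet volumes of cleared hearts —
together with two mechanistic simulators that probe candidate explanations.

## Optical-mapping analysis

Movies arrive as 1 kHz frame stacks with 78 µm pixels. `om_preprocess`
subtracts a per-pixel baseline — the mean over the last 20 ms before each
pacing stimulus, a window that is diastolic by construction — converts to
percent ΔF/F₀, inverts (voltage dyes dim on depolarization), and averages
4×4 blocks to a 312 µm map grid. The per-beat analysis then measures, per
binned pixel, the time of maximal upstroke slope (the AP onset; the source
protocol does not fix an onset rule, and maximum dΔF/dt is the standard
choice), time-to-peak, and APD50/70/90 as the time from onset to 50/70/90 %
recovery towards baseline with linear sub-frame interpolation. Per-pixel
values are medians over the beats of a burst (median rather than mean for
robustness to a single distorted beat; configurable).

Activation maps come from normalized cross-correlation of each pixel trace
against a seed-pixel trace, maximized over integer lags and refined to
sub-frame precision by parabolic interpolation of the correlation peak.
Pixels whose best correlation falls below 0.5 are unmapped; the floor is a
choice exposed as an argument. Conduction velocity fits a plane to
activation time over each full 3×3 neighborhood (the smallest symmetric
multi-vector stencil) and inverts the gradient; wavefront deformation is the
circular standard deviation of the velocity angles, which unlike a plain SD
is well defined across the ±180° wrap. Local conduction time is the maximum
absolute activation difference to 4-neighbors. Differential maps are HF −
LF per pixel, and heterogeneity is the population standard deviation over
valid pixels (the population form is forced by the defining example: a map
split evenly between +c and −c has heterogeneity exactly c).

## Segmentation and morphometry

Tissue segmentation normalizes and sums the fluorescence and scattering
channels into a virtual tissue channel, thresholds it (Otsu by default —
the original workflow thresholded interactively; an explicit threshold can
be given), applies the morphological sequence erode(1), dilate(2), erode(2),
dilate(2) with box kernels, and keeps the largest seed-connected component
(26-connectivity; connectivity is not specified by the source workflow).
The atrioventricular separation is a 200 µm slab through three user points;
the identities AVS = T ∧ S, V = CC(T − AVS), T = V ∨ AVS hold exactly on
the output and are asserted by tests.

CF is scattering ≥ 10 inside tissue (the validated threshold on 8-bit-scaled
data). The excess-collagen (EXC) threshold is calibrated per control heart
as the value whose EXC fraction within tissue is closest to 2.5 %, the
collagen fraction expected in healthy murine ventricle; NCF = EXC ∧ ¬CF.
The calibration fraction is computed over the whole tissue mask T rather
than myocardium only — with fibrosis tags not yet assigned at calibration
time the two coincide on control data, and T matches the phrase "percentage
of volume". Absolute thresholds are data-scale dependent, so the calibration
is quantile-based rather than hard-coded.

Morphometry multiplies voxel counts by the voxel volume (8×10⁻⁶ mm³ at
20 µm). Wall thickness automates the standardized manual protocol: three
equal-thickness portions of the chamber's long-axis extent, with six rays
60° apart at the basal and mid levels and four rays 90° apart apically,
cast from the chamber centroid at the central plane of each portion; angle
zero is the +x axis of the recentred volume. Sector maps recenter on the
fluorescence center of mass, find endo/epi radii as the smallest/largest
circles containing signal on the central transverse plane, mean-project
along the long axis, rescale to 0–255 (the 8-bit average view; raw sums are
kept alongside), and sum a 16 radial × 16 angular polar grid. Group
averages use arithmetic-mean radii; since every sector grid is already
radially normalized between its own radii, bins align and sectors average
element-wise.

## Cardiomyocyte orientation

Per-voxel structure tensors are the outer product of the central-difference
gradient, each component smoothed with one isotropic Gaussian (σ = 1 voxel
by default; the source formulation lists per-axis filters without values,
and an isotropic kernel is the internally consistent reading). Tensors are
averaged over 16³-voxel blocks — 96 µm at 6 µm pitch — and the unit
eigenvector of the smallest eigenvalue of the block mean is the prevailing
fiber orientation; fractional anisotropy gates validity at 0.25, and a
degenerate smallest eigenpair (λ₂ − λ₃ below 10⁻⁶·λ₁) invalidates the block
with a recorded reason. Border blocks are completed by reflection. The
helix angle is the signed angle of the vector's projection onto the
circumferential/apico-basal plane, measured from the circumferential axis in
(−90°, 90°]; for phantoms the local axes are analytic (radial, long-axis,
tangential), and for arbitrary anatomies the axes must be supplied — a
Laplace-style transmural coordinate solver is deliberately out of scope.

## Cellular disarray

Fiber directions are axial (f ≡ −f), so angles are folded to [−π/2, π/2)
and doubled into η = (cos 2α, sin 2α) before smoothing. The dominant
direction solves −δ²Δη̄ + η̄ = η with zero-flux boundaries, component-wise,
by symmetric sparse finite differences on the voxel grid (the original used
linear finite elements on a tetrahedral mesh; on regular grids the operator
is the same and meshing adds nothing). δ defaults to 300 µm, the dominant
direction scale. η̄ is renormalized before angle extraction — the PDE does
not preserve |η| = 1 — and ᾱ = ½·atan2(sin-component, cos-component), an
argument order fixed by the requirement that smoothing a constant field
return the same angle (a self-consistency test enforces this). Disarray is
min over k ∈ {−1, 0, 1} of |α + kπ − ᾱ|, bounded by 90°. The angle α is
taken in the circumferential/apico-basal plane (the helix-angle plane); the
source text garbles the plane specification typographically and this is the
reading consistent with its helix-angle convention.

## Morpho-functional registration

The pose search projects the volume (mean intensity along the viewing axis)
at every (θ, φ) in −40…40° × −40…40°, 10° steps — θ about the longitudinal
axis first, then φ about the transverse axis; the composition order is not
specified by the source and is fixed here. Each projection is segmented,
long-axis realigned by the principal axis of the foreground second moments
(rotation-equivalent to gradient-based alignment for silhouettes), cropped
of the upper 40 % of the long axis, centroid-aligned and reduced to edges.
A rigid grid (rotations −30…30° in 5° steps, translations ±20 px in 5 px
steps) is searched, scoring the symmetric average nearest-neighbor edge
distance in µm — "average Hausdorff", averaged over both directed sets; the
classical max-Hausdorff is available by flag but the average is the
operative quantity. Distances are evaluated through Euclidean
distance-to-edge maps so the rigid search costs lookups, not pairwise
scans. Ties resolve to the smallest |θ|, then |φ|, then raster order.
Functional maps project onto the first tissue voxel with a background
neighbor along each viewing ray.

## The cell models

Both simulators use a phenomenological 4-variable ventricular myocyte (fast
inward, slow outward and slow inward currents with three gates, dimensionless
voltage mapped to mV) rather than the large published murine ionic models.
This is a deliberate substitution: re-deriving a ~40-state ionic model
without its published code invites silent transcription errors, whereas the
minimal model's rate-dependence is controlled by a handful of interpretable
time constants that can be verified by the package's own tests. The model
interface is pluggable — every parameter can be overridden and alternative
sets selected by name — so a full ionic model can be dropped in.

Two murine parameterizations are provided, mirroring the common practice of
using different formulations at cell-chain and organ scale:

* `"mouse"` (chain default): repolarization constants scaled six-fold down
  from the human epicardial set (APD90 near 45 ms), upstroke time constant
  0.2 ms (~150 mV/ms, which also keeps tissue wavefronts resolvable on a
  100 µm grid), and fast-inward availability recovering only once the cell
  is nearly repolarized with a ~30 ms constant. Strongly coupled strands
  then follow 13.5 Hz pacing 1:1 while cells fed through a weak electrotonic
  bridge become recovery-limited near 10–12 Hz — the regime the chain
  experiments probe.
* `"mouse_tissue"` (monodomain default): nine-fold-scaled repolarization
  (APD90 near 30 ms) with availability recovering from −60 mV with an
  8.5 ms constant. Control sheets follow the 15 Hz high-frequency protocol
  1:1 with under 5 % conduction-velocity restitution, while tissue whose
  excitability, coupling or load is degraded loses conduction margin
  selectively at high rate.

One constant deserves note: the sub-threshold outward leak's fast time
constant is kept at its human value (6 ms) in both murine sets. Scaling it
down six-fold would give a resting input conductance near 100 nS, an order
of magnitude above murine inward-rectifier values, and no electrotonic
bridge could source against it.

The fibroblast is a passive resistive-capacitive membrane (6.3 pF, 0.1 nS)
with a reversal potential of −24.5 mV — cardiac fibroblasts rest much more
depolarized than myocytes, which is what makes them a depolarizing load at
rest and a current sink during the AP.

## The 1D chain

Ten myocytes, n ∈ [0, 9] fibroblasts, and one end-standing reporter myocyte
are serially coupled by resistive junctions. The protocol stimulates the
first five myocytes (0.5 ms, 10 nA) at rates on the 0.5–19.5 Hz grid in
1 Hz steps, runs 100 preconditioning excitations, and analyses 20 cycles;
a cycle is captured when the reporter's peak exceeds 0 mV with upstroke
velocity above 1 mV/ms (the capture rule is not specified by the source
protocol). The limit-cycle criterion — cross-correlation of the last two
preconditioning cycles ≥ 0.99 — is recorded with every run. Conduction
velocity runs from the proximal (10th) myocyte's −20 mV upstroke crossing to
the reporter's, over an inter-center distance of 100 µm per myocyte and
20 µm per fibroblast; normalization to the 0.5 Hz value removes the
absolute-scale dependence.

Coupling conductances are not given by the source. G_mm = 370 nS gives a
realistic strand delay; G_mf = G_ff were calibrated once so that the
five-fibroblast insert sustains 1:1 conduction at 8.5 Hz and fails by
11.5 Hz, then frozen at 100 nS — the strong end of reported heterocellular
coupling, consistent with the bridge needing to source a ~17 nS resting
leak through six junctions in series. Integration is explicit in voltage
with exponential (Rush–Larsen-style) gate updates at dt = 5 µs; tests
verify that halving dt moves CV by under 1 %.

With these frozen defaults the model reproduces the qualitative findings it
was built for: capture failure is monotone in rate and in insert length,
the reporter's maximum upstroke velocity declines with rate, and normalized
CV falls monotonically — the electrotonic low-pass filter. A known
limitation: the maximum insert length compatible with conduction is
essentially rate-limited only near the failure bracket; the passive
fibroblast bridge attenuates so steeply with length that inserts beyond
five cells fail at all rates, where the source observed a more gradual
rate-by-length staircase with its full ionic models.

## The monodomain tissue model

A 2D sheet at 100 µm spacing (the organ-scale mesh resolution this
substitutes for) integrates the monodomain equation with per-element
anisotropic diffusivity from fiber angles, harmonic face averaging (which
makes interfaces to non-conducting elements exactly no-flux), and explicit
time stepping guarded by the diffusion stability bound. Baseline
diffusivities (0.145 / 0.03625 mm²/ms, anisotropy ratio 4) are sized so the
control sheet conducts near 0.35 / 0.17 m/s along / across fibers. CF is
non-conducting; NCF elements are percolated to non-conducting with
probability k × local scattering intensity (k defaults to normalizing the
maximum intensity to p = 0.5).

The five NCF electrophysiological-alteration scenarios are: (a) conductivity
at 25 % of the control transverse value with the normal anisotropy ratio
preserved; (b) the same reduction made isotropic; (c) fast-inward (sodium)
conductance at 25 %; (d) 12 passive fibroblasts coupled per myocyte at 3 nS
(the modest organ-scale coupling of homogenized formulations — not the
calibrated chain-bridge value, which refers to a single junction); (e) the
combination of the isotropic reduction, the sodium reduction and the
fibroblast coupling. Pacing is a 0.5 × 0.5 mm apical-edge patch with 2 ms
suprathreshold pulses: ten beats at 5 Hz then ten at 15 Hz, analysing the
final beat of each train; activation is the −20 mV upstroke crossing.

The standard fibrotic-strip phantom is a 2 × 4 mm sheet with fibers across
the propagation axis and a 0.6 mm band in which 20 % of elements are NCF
(non-compact fibrosis is collagen intermixed with surviving myocytes, so
the band is patchy, seeded and reproducible). On this phantom all five
scenarios conduct fully at both rates and the combined scenario e prolongs
high-frequency activation strictly more than any single alteration — the
qualitative ordering the acceptance suite asserts. The choice of a patchy
band and of fibers across propagation keeps every scenario in the conducting
regime: a solid severe band simply blocks at high frequency, which collapses
the graded comparison into all-or-nothing outcomes (the censoring-aware
`strip_crossing_delay` metric is provided for such regimes).

## The phantoms

`make_ring_phantom` renders a thick-walled annulus with a linear transmural
helix field. Fluorescence texture has gradients confined to the plane
perpendicular to the fiber: a cosine stripe whose phase is exactly the
radius (so its gradient is exactly radial), plus seeded noise convolved with
a Gaussian along the local fiber direction in a single pass. Two texture
lessons are baked in deliberately: wavelengths sit at the long end of the
4–8 voxel range because second-order central differences bias the gradient
direction of short-wavelength patterns, and the directional convolution is
single-pass because iterating short smears accumulates resampling
artifacts. Scattering is zero in myocardium, the blob intensity inside CF,
and exponentially distributed with a distance-tapered mean inside NCF halos.
All randomness flows through one seeded generator per call; identical specs
and seeds give bit-identical volumes.

`make_movie` renders planar or radial activation with a piecewise-linear AP
template whose APD50/70/90 are exact by construction, at the acquisition
defaults (1 kHz, 78 µm).

What the phantoms do not emulate: light-sheet point-spread functions and
stripe artifacts, vessels and atria, motion, photobleaching, and realistic
collagen micro-texture. Passing tests therefore demonstrate correctness of
the computational chain against exact ground truth, not robustness to every
artifact of real acquisitions.

## Problem sizes and test design

The test-suite phantoms are a few hundred µm to a few mm across (ring
phantoms of 0.6–1.8 mm diameter; tissue sheets of 2 × 4 mm; chain sweeps
with a reduced 8–10-beat preconditioning where the full 100-beat protocol is
not the point of the test). The acceptance checks run the chain bracket at
the full protocol (100 preconditioning beats, dt = 5 µs), and
`scripts/acceptance.R` sweeps the entire rate grid from 0.5 Hz upward with
the frozen defaults. The fiber-recovery budget (median ≤ 3° noise-free,
≤ 8° at SNR 5) is evaluated over blocks lying fully inside the myocardium:
blocks straddling the tissue surface are dominated by the boundary
intensity step, whose gradient is the surface normal rather than anything
fiber-related, and their orientation is not meaningful in phantoms or in
real data.
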