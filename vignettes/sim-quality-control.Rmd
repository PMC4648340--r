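---
title: "Quality control for 3D-SIM data: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control for 3D-SIM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simqc)
```

## The problem

Three-dimensional structured illumination microscopy (3D-SIM) acquires,
for every z-plane, P phase-shifted images of a striped illumination
pattern at A pattern orientations (typically P = 5, A = 3), and
reconstructs a volume with doubled lateral and axial resolution by
reassigning the frequency-mixed content of those raw images. Each stage
can silently fail: the stripe contrast can be too weak to carry
super-resolution information, intensities can drift or bleach between the
temporally separated angle acquisitions, the pattern's axial focus can be
misaligned with the detection focal plane, phase stepping can be
inaccurate, and the reconstruction's optical transfer function (OTF) can
mismatch the sample's actual point-spread conditions. The resulting
artifacts are notoriously easy to mistake for biology. `simqc` quantifies
each failure mode with a small set of objective statistics on the raw and
reconstructed data.

## Data model

Raw data are held as `RawSIMStack`: a 7-D array `(y, x, c, p, z, a, t)`
whose flattened trailing dimensions give the canonical **CPZAT** plane
sequence (channel fastest, then phase, z, angle, time). All checks assume
this ordering; `reorderToCPZAT()` converts vendor orderings, declared
fastest-axis-first. The ordering direction is a package convention: the
canonical sequence name only fixes the axis *names*, and fastest-first
matches the phase-within-z-within-angle acquisition loop of the
commercial instrument this layout originates from. Vendor-specific
orderings are shipped as *editable placeholder presets*
(`dimension-orders.json`) because the actual export orderings vary by
software version; users should verify them once per platform.

Reconstructed data are `ReconStack`: 5-D float `(y, x, c, z, t)`, twice
the raw lateral sampling, with a `fullRange` flag recording that
below-mode/negative intensities were *not* clipped upstream. Histogram-
and minima-based checks are meaningless on clipped data and warn loudly.

TIFF I/O uses the `tiff` package for integer data. Full-range
reconstructed stacks contain negative values, which the available TIFF
bindings clamp to [0, 1] on both read and write; the package therefore
includes a minimal codec for uncompressed 32-bit-float multi-page TIFF
(both endiannesses, strip layout) used for that case, cross-validated in
the tests against the `tiff` package on common ground. Dimension counts,
bit depth and pixel sizes travel in a JSON sidecar; missing pixel sizes
fall back to 0.08 µm (raw xy) and 0.125 µm (z) — typical 3D-SIM voxel
sizes — with a warning.

## The raw-data statistics

**Channel intensity profile.** Plane means are computed per channel in
acquisition order. TIV is the min–max range of plane means as a
percentage of the maximum, over all phases and angles with z in a 9-slice
window about the central slice — the window because the reconstruction of
one z-section consumes neighbouring raw sections, so variation inside it
is what destabilizes the result. Decay is estimated per angle by a
log-linear least-squares fit of plane mean against within-angle
acquisition index, reported as the percentage lost from first to last
plane (exact for exponential bleaching; the estimator choice is ours —
any monotone trend in the sample's own z-profile will contribute, which
is why the synthetic validation uses z-uniform samples). Flicker is the
mean, over (angle, phase) series, of the min–max range of that series
across the window, normalized by the series maximum (the normalization
denominator is a package choice; only the range itself is prescribed by
the underlying method).

**Raw Fourier projection.** Each plane is edge-tapered with a Gaussian
window spanning 6% of the width per side (profile: half-Gaussian with
σ = border/3 — the percentage is standard, the profile shape is a
documented package choice), transformed, log-power scaled, and
max-projected over phases, z and angles. The centre disc (diameter X/8)
is filled with the minimum before min–max rescaling so the first- and
second-order stripe spots dominate the display. In TIRF-mode 2D-SIM data
no spots are expected (the detection NA cannot pass the excitation
frequency); the check is not special-cased for that geometry.

**Motion and illumination variation.** The P phases of each angle are
averaged per z, each angle image is scaled so its mean matches the grand
mean of the three, and the angles are coloured cyan/magenta/yellow and
merged additively (R = (M+Y)/2, G = (C+Y)/2, B = (C+M)/2, each output
channel min–max scaled). The additive CMY→RGB arithmetic is a package
choice; the colour assignment itself is the established convention.
Exactly three angles are required.

**Modulation contrast-to-noise ratio.** The Anscombe transform
2√(x + 3/8) stabilizes Poisson noise to unit variance so that a single
noise normalization applies across intensities. For each voxel and angle
the phase images of the 2·zw + 1 surrounding z-sections (default zw = 1;
edge slices use a truncated window so the map keeps the input geometry)
are stacked into a series of length L_FT = P·(2·zw + 1) and discretely
Fourier-transformed along that axis. Because the stripe pattern repeats
every P planes of the series, the order-O modulation lands exactly at
1-based plane L_FT·O/P + 1 — e.g. planes 4 and 7 for P = 5, zw = 1 —
which the tests verify against a brute-force DFT argmax. The second order
requires P ≥ 5 (it aliases onto the first for P = 3). The voxel statistic
is `sqrt(A1^2 + A2^2) / sigma_N`, with σ_N the standard deviation over
the xy-plane of the highest-frequency component's magnitude at that z,
averaged over angles (arithmetic mean; the angle combination is not
prescribed anywhere, and a symmetric mean matches the single displayed
map). Feature segmentation for the per-channel summary applies Otsu's
threshold to the MCNR map's own 256-level stack histogram. The suggested
Wiener constant is w = 0.17/MCNR² — the empirical formula's exponent is
printed ambiguously in the source material; both readings agree at
MCNR = 1, and the squared reading is the one consistent with its use as a
noise-regularization constant.

Two numerical notes. A constant phase series concentrates all power at
DC; amplitudes below `L·max(series)·1e-12` are treated as exact zeros so
that such series report MCNR 0 rather than floating-point dust. On
noise-free input σ_N = 0; voxels with genuine modulation then report an
infinite MCNR sentinel with a warning (and a Wiener suggestion of 0, its
limit). The pure-noise expectation of the statistic is scale-free and
sits near 2.9 (ratio of the expected quadrature amplitude of two complex
Gaussian components to the standard deviation of a Rayleigh magnitude);
the default "concern" tier threshold of 4 sits just above this floor.
The statistic is invariant under digital rescaling of the counts (the
Anscombe transform is exactly scale-equivariant only in the large-count
limit, so the tests assert ≤5% drift over a 10× gain at λ ≥ 50).

## The reconstructed-data statistics

**Intensity histogram.** The mode of float data is defined as the centre
of the tallest bin of a 256-bin histogram over the stack range (the
underlying definition — "peak of the stack histogram" — does not fix a
binning; 256 bins match the display histogram). Min* and Max* average
the lowest/highest `max(0.05% of voxels, 100)` intensities, and
MMR = (Max* − Mode)/|Min* − Mode|. The tail counts are reported because
truncation zeros or saturated pixels visibly skew the tail means. A zero
|Min* − Mode| denominator is the signature of clipped data and yields an
NA with a warning. MMR is invariant under affine intensity shifts, which
the tests assert.

**Spherical aberration mismatch.** ZMV = sd(per-slice minima) divided by
the mean intensity of Otsu-foreground voxels (threshold from the whole
stack; normalization by the *grand* feature mean). It is a relative
measure: the tests assert the definitional value on constructed stacks,
invariance under global scaling, and the directional phenomenology —
an axially defocused illumination pattern produces deeper reconstruction
dips, hence a larger ZMV, than a focused one.

**Fourier plots.** Default pre-processing subtracts the stack mode and
clips at zero ("auto cutoff": the intensity range below the mode is
noise by construction, and clipping makes unclipped data comparable with
data already clipped by reconstruction software); the fraction of exact
zeros afterwards equals the below-mode fraction before, a property the
tests check. Per-slice amplitude spectra are displayed as amplitude^0.2
with a preset display range of [2, 40] — the clamp is applied as a
*post-gamma display range*, one of the genuinely open choices here, and
is recorded in the result's option list. The alternative scaling is
log(amplitude²) with per-slice mode–max rescaling. Resolution rings are
drawn at radius X·pixel_xy/d for annotated resolutions d (defaults 0.2,
0.13, 0.1 µm — configurable; the defaults bracket the expected 3D-SIM
passband). The radial profile (FTR) is the annulus mean of the displayed
central-slice spectrum over ⌊X/2⌋ integer-radius bins; the effective
resolution is read off its inflection point by eye — automated extraction
is deliberately out of scope. The axial view (FTO) re-slices the central
xz-section and linearly interpolates z by pixel_z/pixel_xy to isotropic
voxels before transforming, displayed with the same scaling as the
lateral spectra.

**Modulation contrast map.** MCNR values are mapped through a 256-entry
purple→red→orange→yellow LUT with a display ceiling of 24 (the LUT
colours and ceiling are package choices; the published figures name a
custom LUT without printing it), multiplied by reconstructed intensity
normalized to its maximum. The MCNR map is registered to the
reconstructed grid by nearest-neighbour 2× upscaling — bicubic would
smear the saturation mask — and voxels saturated in *any* raw
phase/angle (≥ 2^bitDepth − 1) are drawn pure green, because saturated
stripes carry no modulation information and seed local artifacts.

## Calibration tools

**Illumination pattern focus** expects a dense, flat, high-contrast
sample (a sub-resolution bead lawn). Slices are normalized by a simple
ratio of slice means (removing flicker/bleach), the stripe orientation is
estimated from the dominant first-order FFT peak of the central slice
(rather than asking the user), each slice is rotated to make the stripes
vertical, and the xz reslice is max-projected along the stripe direction.
A focused pattern shows one bright layer at the sample plane; an offset
axial modulation staggers bright segments into a "zipper", with the
bright-column peak displaced by the offset — both verified against the
simulator.

**Illumination phase steps** Fourier-transforms each raw slice, masks the
origin (disc radius X/16) and both frequency axes (bands 3 px wide) —
geometry chosen to exclude DC leakage and edge artifacts at the tested
image sizes, and configurable, since only "high-intensity regions are
masked" is prescribed — then takes the strongest remaining peak per angle
(summed over phases at the best-focus slice, defined as the z of maximum
mean intensity; the "plane of best focus" definition is a package
choice). The phase of the complex spectrum at that pixel is read for
every phase image in the z-range, unwrapped per z-series
(`signal::unwrap`), and summarized by the mean step, the standard
deviation of successive steps, and the standard deviation of the
residuals about the ideal staircase. The recovered step's sign follows
the detected peak's half-plane (peaks come in conjugate pairs; the
canonical half-plane is kx > 0), so magnitudes are compared against the
nominal 2π/P.

## The synthetic acquisition model

`generateRawSIM()` renders plane (a, p, z) as

```
gain_a · (1 − b)^acq · (1 + f·η) · D(z) · [1 + m·M(z − δz)·cos(2πk(x cosθ_a + y sinθ_a) + φ_p)]
```

with φ_p = 2π(p−1)/P (+ optional per-exposure jitter), acquisition index
`acq` following the CPZAT sequence (so bleaching couples to the
acquisition loop exactly as the intensity profile check assumes), axial
envelope M(z') = cos(2πz'/T_z) (a cosine envelope reproduces the
focused/zipper phenomenology of the pattern focus tool; the true axial
form of the three-beam interference pattern is not modelled), then
Poisson shot noise at `photonsPerUnit`, Gaussian read noise, rounding to
camera counts when any noise is enabled, and optional saturation
clipping. Frequency vectors are snapped to integer FFT bins by default so
the stripes are exactly periodic on the grid — matching real data, where
patterns are near-periodic over the field, and making noise-free
closed-form checks exact to machine precision.

Deliberate idealizations, and what they imply about the tests: the
illumination multiplies the *already blurred* density, so the nominal
modulation depth m survives exactly into the raw planes (a physical
microscope attenuates stripe contrast through the detection PSF — the
simulator's m is therefore an upper bound, and recovery tests validate
the estimators, not instrument physics); there is no out-of-focus blur
contribution between z-planes beyond the bead PSF; no vectorial PSF or
polarization-dependent excitation. `generateBeadField()` renders beads as
3-D Gaussians of controlled flux (sum ≈ nBeads·flux, boundary loss
< 1%), with a `uniform` sheet option as the ideal dense-lawn limit used
by the calibration tests. Defaults (64×64×9, P = 5, A = 3, k = 0.19
cycles/px ≈ a 0.42 µm pattern at 0.08 µm pixels, orientations 15°/75°/135°,
m = 0.8) describe a small but realistic acquisition and are the
conditions under which the validation suite runs.

`generateReconLike()` emulates the *statistical signature* of
reconstructed data (zero-mode background, bright features, negative
ringing) without running a reconstruction — reconstruction itself is out
of scope. For the mismatch check, `reconFromScenario()` maps an axial
pattern-focus offset to the depth of negative axial side lobes
(amplitude = 0.05 + 0.15·|δz| by default). This is a phenomenological
emulation of how such a mismatch manifests; passing tests show the ZMV
statistic responds in the right direction, not that the mapping is
quantitatively that of any reconstruction algorithm.

## Batch runner and tiers

`runAllChecks()` executes the default set — intensity profile, motion
check and MCNR on raw data; histogram, lateral spectrum and radial
profile on reconstructed data; the contrast map when both are present.
The Fourier projection and the mismatch check have specific sample
requirements (dense sampling; flat bead layers) and are opt-in. Metric
tiers (ok/caution/concern) come from `simqc-config.json` and are
advisory, configurable defaults — e.g. TIV caution at 30%, MCNR concern
below 4 — not published constants; the run always exits successfully.
Re-running on the same inputs is bit-identical (no randomness in any
check).

## Problem sizes and numerical choices

The validation suite simulates at 16–64 px lateral size and 3–15
z-slices, with 5 phases and 3 angles — large enough that every spectral
peak is grid-resolved and every statistic exercises its full code path,
and chosen as the package's standard verification conditions. Key
tolerances: noise-free closed forms to 1e-9 relative; phase-step recovery
to 1e-6; float TIFF round trips exact after one float32 quantization;
MCNR gain-invariance to 5% at λ ≥ 50. Ties in the histogram mode resolve
to the lowest bin; Otsu thresholds use 256 levels over the data range;
degenerate min–max rescales (constant images) map to zero.

## Known limitations

No reconstruction, no OTF generation, no proprietary container parsing
(.czi/.nd/.dv — use TIFF plus a declared ordering), no automated
resolution-number extraction from the radial profile, no red/amber/green
assessment table beyond the configurable tier defaults, and no TIRF
special-casing. The decay estimator conflates sample z-structure with
bleaching on strongly structured samples; compare like with like.
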