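---
title: "Models and methods behind duofoci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind duofoci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duofoci)
```

# Scope

`duofoci` models the computational core of a dual-foci axially swept
light-sheet microscope (ASLM) for cleared-tissue imaging. In an ASLM the
thin waist of a Gaussian light sheet is swept along its propagation axis in
sync with the rolling shutter of an sCMOS camera, so that every camera row
is exposed while the waist crosses its object plane. The dual-foci variant
splits the remote-focusing path into two stacked arms whose mirrors are
displaced by equal and opposite offsets, producing two foci separated by a
fixed half-frame distance (1024 rows on a 2048-row sensor). Two synchronized
rolling shutters then each sweep half the frame concurrently.

The package simulates and quantifies the consequences of that design:
exposure scheduling, actuator drive and tracking, noisy image formation on
synthetic phantoms, PSF quantification, informative-tile triage, and
acquisition time/storage budgeting. It does not control hardware, stitch
tiles, or reproduce measurements that require the physical instrument.

# Optical scaling model

The detection path is multi-immersion: magnification depends on the
immersion refractive index $n$. The package anchors the model at a measured
calibration point, $M = 15.28\times$ in water ($n = 1.33$), and assumes
linearity:

$$M(n) = M_{\mathrm{ref}}\,\frac{n}{n_{\mathrm{ref}}},\qquad
p(n) = \frac{p_{\mathrm{sensor}}}{M(n)},\qquad
\mathrm{FOV}(n) = N_{\mathrm{rows}}\,p(n).$$

With the 6.5 µm sensor pitch this gives a 0.425 µm sample-space pixel and
an 870 µm field of view in water, and it reproduces the published
equivalence of a 0.97 µm width at $n = 1.33$ with 0.83 µm at $n = 1.56$
(`convert_fwhm()`). Linearity in $n$ is an approximation: per-medium
measured magnifications, where available for a given instrument, can be
supplied by overriding `reference_magnification`/`reference_index` per run.
The product $p(n)\,M(n)$ is conserved to machine precision by construction.

The light sheet is a Gaussian beam: $w(z) = w_0\sqrt{1 + (z/z_R)^2}$ with
$z_R = \pi w_0^2 n/\lambda$. The illumination NA of the modelled instrument
is not published; the default waist radius ($w_0 = 0.5$ µm at
$\lambda = 0.488$ µm) is a stated assumption chosen so that the simulated
system resolution lands near the published ~0.97 µm isotropic figure (see
*Image formation*).

The dual-arm geometry exposes the mirror offset $\Delta z$ and the axial
gain $g$ (sample-µm per mirror-µm). Neither is published separately; only
their product is observable through the foci separation
$S = \mathrm{round}(2 g |\Delta z| / p(n))$ (ties away from zero). The
default constructor therefore calibrates $g\,\Delta z$ jointly so that
$S = 1024$ rows at the reference index, and both parameters are
configurable.

# Rolling-shutter schedule and signal doubling

With frame (sweep) time $T$ and shutter width $W$ rows, single-shutter mode
steps one active band through all $N$ rows: row $r$ is active on
$[r\tau,\ r\tau + W\tau)$ with $\tau = T/N$. Dual mode steps two bands, at
rows $r$ and $r + N/2$, through $N/2$ rows each in the same frame time, so
$\tau_d = 2T/N$ and the per-row exposure is

$$e_{\mathrm{single}} = \frac{WT}{N},\qquad
e_{\mathrm{dual}} = \frac{2WT}{N} = 2\,e_{\mathrm{single}}.$$

This exact factor of two is the signal benefit of the dual-foci design, and
it also fixes the speed benefit: covering the full field at the
single-shutter quality needs $T = 100$ ms, while dual mode achieves it at
$T = 25$ ms (40 fps), a four-fold per-frame acquisition time (pfAT)
improvement. These two frame times are configuration facts of the modelled
instrument, adopted as defaults.

The alternative dual-shutter geometry (one full-frame band trailing a
second by half a frame) was rejected: it cannot keep both foci inside the
frame for a full sweep at half the frame time while maintaining the fixed
1024-row separation.

# Drive waveform and actuator tracking

The focus actuator follows a sawtooth: a linear rise over $T$ (laser on,
triggers at period starts) and a flyback/settle return over $F$ (laser
gated off). The supported camera reads out in one direction only, which is
why flyback exists at all. $F$ is not published; the default is
$F = 0.1\,T$ and it is configurable everywhere it appears.

The actuator (a voice-coil linear focus actuator, 10 mm travel, 50 nm
repeatability, 3 ms response time) is modelled as a second-order lag with
natural frequency $\omega_n$ and damping $\zeta$ (critically damped by
default), optionally preceded by a pure transport delay. The default
$\omega_n = 6/t_{\mathrm{resp}}$ makes the closed-form step response settle
within roughly the quoted response time; `response_time = 0` gives an ideal
actuator. Tracking uses fourth-order Runge–Kutta on the sampled command
(default 100 samples over the shortest phase). The model is linear and
time-invariant, so tracking error scales with sweep amplitude and inversely
with sweep time — the qualitative reason full-range single-focus sweeps are
limited to slower frame times than half-range dual sweeps.

`synchronization_map()` reports, per camera row, the offset between the
actual waist position and the row's nominal object plane at the midpoint of
the row's exposure. An ideal actuator gives zero everywhere; a pure lag
$t_\ell$ gives $-(A/T)\,t_\ell$ on interior rows; in dual mode paired rows
share exposure windows and ride the same actuator, so their offsets are
identical by construction.

# Image formation and noise

`simulate_stack()` forms expected photoelectron images of bead phantoms.
Geometry: camera rows = sweep/propagation axis, stage steps along the
detection axis by one lateral pixel per frame (the axial step equals the
pixel size, as in the modelled acquisition protocol). Each emitter
contributes a separable Gaussian whose lateral width combines the detection
blur with the emitter size (a 500 nm sphere approximated as a Gaussian of
$\sigma = d/4$), and whose axial width combines the sheet cross-section at
the emitter's row — the beam radius evaluated at that row's
synchronization offset — with the detection axial blur, in quadrature.
Expected photoelectrons scale with the per-row exposure; counts are
$\mathrm{offset} + g_c\,\mathrm{Poisson}(\mu) + \mathcal N(0, \sigma_r)$,
clipped to 16 bits with a warning. One seed stream per stack makes every
stack a pure function of its arguments and seed.

The defaults (detection FWHM 0.92 µm lateral / 0.71 µm axial, $w_0$ = 0.5
µm) are a calibration, not a claim: they put the simulated 500 nm bead
FWHM near 0.97 µm in all three axes in water, matching the instrument's
published resolution scale so that downstream estimator tests operate in a
realistic regime. The published bead measurements themselves (0.97 ± 0.05
µm, deconvolved 0.80 ± 0.06 µm) are instrument data and are not asserted by
any test; the tests assert estimator properties (bias, monotonicity)
instead.

The SNR model is $\mathrm{SNR}(e) = S e/\sqrt{S e + B e + \sigma_r^2}$.
For the dual(25 ms)/single(100 ms) comparison the per-row exposure ratio is
$1/2$, so the predicted SNR ratio lies between $1/2$ (read-noise-dominated)
and $1/\sqrt 2 \approx 0.707$ (shot-noise limit). The published ~17%
decrease measured in tissue falls inside this bracket but depends on the
real specimen; the package asserts only the bracket and the analytic
limits.

# Phantoms and the synthetic tile dataset

Bead phantoms place beads uniformly at random with an optional minimum
separation (rejection sampling with a bounded retry budget), emulating
500 nm beads in agarose.

Tissue tiles emulate the two classes of a low-resolution pre-scan used for
triage training: *informative* tiles contain an extended soft tissue mass
plus smaller blobs and random-walk filaments over background;
*empty* tiles are background and read noise only (a media-only sample).
The published protocol fixes the dataset size (2,080 images per class,
4,160 total, 80/20 split) but not the tile geometry or content statistics;
the package's defaults — 128 × 128 × 8 voxel tiles, background 100 counts,
read noise 2 counts, structure amplitude 10 noise-sd units — are package
choices fixed once. Structure contrast is expressed in noise-sd units so
that separability is tunable: as contrast approaches 0 the classes become
statistically indistinguishable (triage AUC near 0.5), while at the default
contrast they are cleanly separable, which is the regime the published
training protocol implies (validation accuracy above 99%). The extended
tissue mass is always present in informative tiles because a pre-scan tile
crossing a tissue boundary contains structure at many-pixel scale; tiles
containing only a few point-like objects would not reliably exceed the
intensity recipe's absolute threshold, which is a property of the recipe,
not a defect of it.

What the phantoms deliberately do not model: real tissue texture,
clearing-protocol-specific appearance, scattering, vignetting, and stitched
multi-tile context. Passing tests therefore demonstrate correctness of the
algorithms and their documented contracts on controlled inputs, not
performance on real tissue.

# Informative-tile triage

The intensity recipe is implemented exactly as published: axial MIP, two
uniform box filters (20 × 20 and 40 × 40), difference image, score = percent
of pixels strictly above 2.5, informative iff score ≥ 0.1%. Two conventions
the publication leaves open are fixed and documented: even kernels have no
centre pixel, so the window origin is offset toward the lower index; and
padding is reflective with the edge pixel duplicated. The difference image
is kept in floating point (the 2.5 threshold is applied to floats). The
implementation uses a summed-area table and is tested bit-exact against an
independent nested-loop reference. The score is invariant to constant
offsets (both box means shift equally) but deliberately not
scale-invariant, since the threshold is absolute.

The classification network follows the published training protocol — batch
size 32, 80/20 deterministic split, early stopping on validation accuracy
with patience 10, best-accuracy checkpoint kept, per-epoch CSV log — while
the architecture, which the publication does not specify, is a package
choice: the tile MIP is area-averaged to 32 × 32, normalized by 1st–99th
percentile scaling, and passed through three blocks of (3 × 3 convolution,
ReLU, 2 × 2 max-pool) with 8/16/32 filters, global average pooling and a
sigmoid output. Training is minibatch Adam (learning rate $10^{-3}$) on
binary cross-entropy, implemented with im2col convolutions on BLAS matrix
products. A 32 × 32 input with a ~6k-parameter network is sufficient
because the class signal in these tiles is low-frequency; it keeps a full
training run on the 4,160-tile default dataset to a couple of minutes on a
single CPU core, and all of it (blocks, filters, input size) is
configurable for larger variants. Probabilities are clamped to
$[10^{-12}, 1-10^{-12}]$ and a tile is informative iff $p \ge$ threshold,
so thresholds 0 and 1 are all-or-nothing.

ROC curves use the standard threshold sweep with tie grouping and
trapezoidal AUC, cross-checked in the tests against an independent
implementation.

# Acquisition planning

`plan_tiles()` covers a bounding box with tiles of one field of view
laterally and a configurable depth axially, overlapping by a fraction
(default 10%; the publication states "a defined overlap" without a value)
in all three dimensions. Per-axis counts are minimal (ceiling-based) with
the last tile flush to the box edge. Frames per stack =
$\lceil \mathrm{depth}/p(n)\rceil$ because the stage steps one pixel per
frame. Budgets separate the pure sweep total (cumulative pfAT
= stacks × frames × $T$) from flyback (per frame) and stack delay (between
stacks), summing exactly by construction; hours are reported to 2 decimal
places (round-half-even). The published forepaw example (1,672 dual-channel
stacks) is reproduced as 4.93 h at 25 ms with a four-fold single-shutter
counterpart. Published frame-per-stack figures are internally ambiguous —
time totals imply ≈425 frames per stack while byte totals imply ≈386 — so
the tests state explicitly which value each check uses (425 for the timing
totals, 386 for the 7.03 TB byte total), and whether cumulative pfAT
includes flyback (here: it does not; flyback is budgeted separately).

# Numerical choices

* FWHM estimation fits 1D Gaussians with a background-floor parameter to
  profiles through the bead centroid (Levenberg–Marquardt, bounded), not to
  projections: profiles stay single-peaked for non-overlapping phantoms.
  $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma\,p$. Failed fits are flagged and
  excluded from summaries. Estimator bias is below 1% for
  $\sigma \ge 1.5$ voxels noise-free and below 5% under Poisson noise with
  peak 100 counts.
* Richardson–Lucy deconvolution runs in the Fourier domain on a
  reflectively padded volume (half the PSF support per face), so interior
  flux is conserved to within 1%; the PSF is normalized to unit sum and a
  non-normalizable PSF is an error. Default 10 iterations.
* Box filters use exact summed-area tables; sums are over ≤ 1600 doubles,
  so cancellation is negligible and bit-exactness against the naive loop
  holds on realistic magnitudes.
* Rounding: row separations round ties away from zero; report hours use R's
  round-half-even.
* Degenerate inputs error early and specifically: odd row counts in dual
  mode, shutter widths out of range, zero sample rates, single-class
  training sets, disjointness violations in SNR masks, non-16-bit TIFFs.

# Problem sizes and determinism

Tests and the acceptance script regenerate all data programmatically.
Simulation tests use small sensors (48–64 rows) where the physics is
scale-free; full 2048-row geometry is used wherever a published instrument
quantity is checked. The classifier acceptance runs use the full default
dataset (2,080 tiles per class) across three seeds. All randomness flows
from explicit integer seeds through one documented derivation, so every
generator output, stack, split and training run is reproducible.

# Known limitations

* The magnification model is linear in $n$; real multi-immersion objectives
  deviate at the percent level.
* The actuator model is a generic second-order lag; the real device's
  nonlinearity at high speed is not characterized publicly, so per-mode
  minimum sweep times (100 ms single, 25 ms dual) are taken as
  configuration facts rather than derived.
* Image formation is separable-Gaussian; no vectorial diffraction,
  aberrations, scattering or shadowing.
* The tile phantoms are statistical stand-ins; classifier performance on
  them does not transfer to real tissue, and the published 99.42%
  validation efficiency on the authors' images is out of scope.
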