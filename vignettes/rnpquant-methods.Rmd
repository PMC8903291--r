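---
title: "Quantifying RNP granule dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RNP granule dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnpquant)
```

rnpquant quantifies the standard imaging readouts of RNA-binding-protein
granule biology: FRAP dynamics of individual granules, granule abundance
and morphology in cultured cells, transport of neuronal granules along
neurites, two-channel colocalization, single-molecule FISH transcript
counting, and dual-luciferase translational-repression reporters. Because
raw microscopy for such studies is rarely deposited, the package pairs
every analysis stage with a seeded synthetic-data generator that emulates
the acquisition, so the whole pipeline is testable by parameter recovery:
generate with known parameters, analyze, and compare.

## FRAP: double normalization and one-phase association

A FRAP experiment on a granule produces three mean-intensity traces: the
bleached granule, an unbleached reference granule, and a diffuse
cytoplasmic background region. Two pre-bleach frames are followed by
frames every 1.0878 s (about 218 s total). Two instrumental artifacts
contaminate the raw bleached trace: acquisition photobleaching, which
multiplies *all* fluorescence by a slowly decaying factor, and a constant
additive background. The four-step correction removes them in sequence:

1. **PCV** (photobleach correction value): mean pre-bleach unbleached
   intensity divided by the unbleached intensity at each frame. Because
   acquisition photobleaching affects the reference granule identically,
   PCV measures its reciprocal.
2. **CAI** = bleached × PCV, cancelling the shared decay.
3. **BCFI** = CAI − background (per-frame background; subtracting the
   per-frame value rather than a movie-wide mean also corrects slow
   background drift, and the two coincide when background is constant).
4. **FCV** = 100 × BCFI / mean pre-bleach BCFI, a recovery curve in
   percent of pre-bleach intensity. The pre-bleach baseline averages all
   pre-bleach frames; with one pre-frame it reduces to the single value.

When the only artifact is a shared multiplicative decay $d^t$, the
algebra cancels exactly: with unbleached $= 100\,d^t$ and background 0,
$\mathrm{PCV}_t \propto d^{-t}$ and FCV returns the undistorted signal to
machine precision (a property the test suite asserts at $10^{-6}$). The
cancellation is *not* exact when a nonzero additive background and
nonzero drift are combined: the correction then leaves a bias of order
$b\,(1-d^t)\,(100-S)/100^2$ per frame. This is a property of the
published correction itself, not of this implementation; the synthetic
FRAP generator therefore defaults to zero background so exactness
properties are testable, and the residual bias formula above tells you
what to expect when you add background.

The corrected curve is fit by least squares to the one-phase association

$$Y(t) = Y_0 + (P - Y_0)\,\bigl(1 - e^{-K (t - t_0)}\bigr),$$

with $t_0$ the time of the first post-bleach frame (the 0.5–1 s bleach
interval itself is not modeled; only captured frames are fit). The fit is
solved robustly by variable projection — for fixed $K$ the model is
linear in $(Y_0, P-Y_0)$, so a log-spaced grid over
$K \in [10^{-5}, 10]\,\mathrm{s}^{-1}$ gives a global starting point —
then refined with `minpack.lm::nlsLM` under bounds $K \in (10^{-6}, 10]$
and $P \ge Y_0$. Non-convergence returns the best grid solution flagged
`converged = FALSE` rather than an error. Reported quantities:

* **half-time** $t_{1/2} = \ln 2 / K$;
* **plateau** $P$ (percent of pre-bleach);
* **mobile fraction** $F_m = (P - Y_0)/(100 - Y_0)$, i.e.
  bleach-depth-normalized. With complete bleach ($Y_0 = 0$) the plateau
  and the mobile fraction (in percent) coincide, which is why both
  conventions appear interchangeably in the literature; rnpquant emits
  both so either reading is reproducible.

With 2 pre-bleach frames the normalization scale itself is estimated from
2 noisy values, which puts a noise floor of roughly
$\sigma/(100\sqrt{2})$ on relative accuracy of $F_m$ — about 2% at
$\sigma = 3$. Parameter recovery on a grid of mobile fractions
(0.1–0.9) and half-times (4–100 s) at that noise level keeps the median
relative error under 5%; the hardest cell is $t_{1/2} = 100$ s, where the
218-s window covers only ~2.2 half-lives and the rate is intrinsically
poorly determined.

## Granule detection and morphometrics

Granules are punctate regions above the diffuse cytoplasmic background.
The field's working criterion — brighter than background and at least
3 × 3 pixels — is normally a visual call made at the microscope;
rnpquant makes it reproducible with robust statistics: the
threshold is median + $k\,\hat\sigma_{\mathrm{MAD}}$ over the cytoplasm
($k = 3$ by default), re-estimated once after masking a first round of
detections so bright granules cannot inflate the background estimate.
8-connected components above threshold survive if they cover at least 9
pixels *and* their bounding box can contain a 3 × 3 square (a 2 × 8
ribbon is not a granule). Detection is invariant to adding a constant to
the image, since the median and the MAD both shift with it.

Two perimeter conventions are reported because no single one serves both
purposes. `perimeter_px` is the crack perimeter (count of exposed pixel
edges; a $w \times h$ rectangle scores $2(w+h)$), the natural discrete
quantity. For *circularity* $4\pi A/P^2$, however, the crack perimeter of
a perfect digital disk is $\approx 8r$ rather than $2\pi r$, so a disk
would score $\pi^2/16 \approx 0.62$ — useless for separating "round" from
"amorphic". Circularity is therefore computed on the component's convex
hull (area and Euclidean perimeter of the hull polygon, pixels padded by
their half-pixel extent): an ideal disk scores ~0.97, a 3:1 elongated
blob ~0.5–0.7, and the statistic is insensitive to single-pixel boundary
noise. The cost is that strongly concave shapes are rounded by the hull;
for the elongated amorphic phenotype this classifier targets, that bias
is irrelevant in practice (generated 3:1 blobs classify ≥ 90% amorphic
across seeds). The default circularity cut is 0.8, config-exposed, since
the underlying phenotype was defined visually, not numerically.

Per-cell summaries convert the longest-axis diameter $d$ to a cell area
$\pi (d/2)^2$ and report granules per µm²; a cell with any amorphic
granule is called amorphic, matching how cells were scored. Distances of
neuritic granules from the cell body subtract the radius of a tightly
drawn soma circle from the centroid-to-center distance, flooring at zero,
with granules ≥ 10 µm flagged distal.

## Neurite transport

Kymographs sample the movie along a soma-to-tip polyline at 1-px
arc-length steps, taking the maximum over a small perpendicular width per
position (bilinear interpolation), z-max-projected per frame. Tracks —
either linked from per-frame detections by greedy nearest-neighbour
assignment (gate: 5 × the speed floor × frame interval; fragments
shorter than 5 frames dropped; crossing tracks resolve to minimal total
jump, which is documented rather than guaranteed correct) — or supplied
directly, are classified with the published rule set:

* **stationary** if the mean frame-to-frame speed
  $\overline{|\Delta s|}/\Delta t$ is below the floor
  $v_{\min} = 0.138$ µm/s (one pixel per second at the acquisition's
  pixel size);
* otherwise **anterograde** (net displacement away from soma) or
  **retrograde** (toward it); an exactly-zero net displacement at motile
  speed is broken to stationary and flagged.

Per track the motile velocity averages $|\Delta s|/\Delta t$ over frames
at or above the floor (the whole-track mean is also emitted, since the
source convention is unstated); "total displacement" is emitted both as
cumulative path length $\sum |\Delta s|$ and as net displacement, so
either reading of the published bar charts is reproducible. Bursts —
frames faster than 3 × the track's median speed — are reported
descriptively and never used for classification, because no numeric
burst criterion was published. The default frame interval is 4.84 s
(484 s over 100 frames).

The track generator emulates run-and-pause transport: motile granules
run at a per-track speed (default mean 0.5 µm/s) with probability 0.5
per frame and pause otherwise; stationary granules jitter with mean
speed 0.06 µm/s, well under the floor. Class counts are apportioned
exactly (largest remainder), so recovery tests compare against known
integer compositions. Velocity-recovery tests disable the optional 3×
bursts: the oracle pairs recovered motile-frame velocity with the
generating run speed, and burst frames would shift that comparison by
construction rather than by classifier error.

## Colocalization and smFISH spots

Pearson's coefficient is computed over all pixels of the analysis ROI
with no intensity thresholding, matching the plugin default the field
uses; zero variance in either channel returns a flagged `NA`. Where
background staining differs between channels, images are first
rolling-ball background subtracted (radius 50 px by default):
the background is the grayscale opening with a spherical-cap structuring
element — the morphological formulation of the rolling-ball idea — and
is subtracted with clipping at zero. The cap height scale is 0.5
intensity-units per pixel: shallow enough that structures much narrower
than the ball survive within ~5% and the operator is idempotent to ~1%.
The image is replicate-padded by one radius so the ball is fully
supported at the border. The implementation is a small compiled routine
(no installed package offers non-flat structuring elements) and is
tested against a brute-force double-loop oracle.

Spot detection for smFISH follows the standard single-scale recipe:
scale-normalized Laplacian-of-Gaussian filtering at the PSF sigma
(default 1.3 px), local maxima above a robust threshold (5 × MAD of the
filtered image), and sub-pixel refinement by a 2-D Gaussian least-squares
fit in a 7 × 7 window, falling back to an intensity-weighted centroid if
the fit fails. Localization error on generated scenes at SNR 8 is below
0.5 px RMS. Two spots closer than about twice the PSF sigma merge into
one detection — an intrinsic limitation of single-scale blob detection,
shared with the tools this emulates; the spot-scene generator therefore
enforces a minimum truth separation (default 4 px) so count oracles are
well-posed, and the merge behaviour is tested separately. Spots are
assigned to compartments by the label image containing their rounded
coordinate, soma taking precedence on overlap; the neurite fraction is
$n_{\mathrm{neurite}}/(n_{\mathrm{neurite}} + n_{\mathrm{soma}})$ with
out-of-mask spots excluded.

## Reporter normalization

Each well's firefly reading is divided by its Renilla control; technical
replicates average to one ratio per construct per plate; construct ratios
divide by the control construct's ratio on the same plate. Independent
plates — not wells — are the unit of error, matching how such
experiments report mean ± SE over three repeats. The plate generator
draws multiplicative log-normal noise with unit mean, so noise-free
plates recover $1/\mathrm{fold}$ exactly and the normalization is
invariant to rescaling all FLuc (or all RLuc) readings.

## What the generators do and do not emulate

All generators use one explicitly seeded RNG per call (the caller's RNG
state is untouched) and are bit-reproducible. The camera model is
Poisson shot noise plus Gaussian read noise, rounded to integer counts;
SNR is defined as (peak − background)/σ(background). Granules are
(an)isotropic Gaussian intensity profiles placed without overlap by
rejection sampling; amorphic granules have axis ratio ≥ 3. These scenes
deliberately omit several features of real data: optical PSF structure
beyond a Gaussian, granule overlap and clumping, z-blur, uneven
illumination, and motile-granule interactions. Passing recovery tests
therefore demonstrates correctness of the *measurement pipeline* under
its stated model, not robustness to every real-world artifact; the
config-exposed thresholds are the knobs to retune on real images.

Problem sizes in the test suite (and the reasoning behind them): FRAP
grid recovery uses 9 mobile fractions × 4 half-times × 20 replicates
(720 fits); detection precision/recall uses 20 scenes of 12 granules;
transport recovery uses 100 tracks of 100 frames, the acquisition's
track length; colocalization sweeps 5 shared-fraction levels × 5 seeds.
These sizes give binomial/normal confidence intervals tight enough to
detect real regressions while keeping the suite fast.

## Numerical choices and edge cases

* Pixel coordinates are 1-based `(y, x)` in R, pixel centers at integer
  coordinates; ROI membership is center-inside, boundary inclusive.
* Degenerate FRAP fits (flat recovery, pure noise) never raise: the
  variable-projection grid always yields a best-effort parameter set.
* A mobile fraction marginally above 1 (normalization noise) is tolerated
  to 1.05 and flagged; beyond that it is clamped and flagged.
* Stack round trips are bit-exact for integer data (16-bit TIFF);
  non-integer data falls back to 32-bit float. Axis order and calibration
  travel in a JSON sidecar; reader metadata wins over naive page order.
* `write_table` emits floats at 17 significant digits so CSV round trips
  preserve doubles exactly.
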