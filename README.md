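# rnpquant

Image quantification for RNP-granule cell biology: FRAP dynamics of
individual granules, granule detection and morphometrics, neurite
transport classification, Pearson colocalization, single-molecule FISH
spot counting, and dual-luciferase reporter normalization — together with
seeded synthetic-microscopy generators so every stage can be verified by
parameter recovery against known ground truth.

## Who this is for

Labs that study phase-separated RNA-protein condensates (stress granules,
P-bodies, neuronal transport granules) quantify the same few readouts
over and over, usually as one-off ImageJ/Prism workflows. rnpquant
packages those workflows as tested, scriptable R functions with the
published parameter conventions as defaults, and ships generators that
emulate each acquisition so the pipeline's accuracy is measurable rather
than assumed.

## The models at the core

**FRAP.** Raw traces (bleached granule, unbleached reference, cytoplasmic
background) are double-normalized in four steps — photobleach correction
value PCVₜ = mean(pre-bleach unbleached)/unbleachedₜ, corrected average
intensity CAIₜ = bleachedₜ·PCVₜ, background-corrected BCFIₜ = CAIₜ −
backgroundₜ, and final corrected value FCVₜ = 100·BCFIₜ/BCFI₀ — then fit
by least squares to the one-phase association

    Y(t) = Y0 + (P − Y0) · (1 − exp(−K (t − t0)))

yielding the half-time t½ = ln2/K and the mobile fraction
Fm = (P − Y0)/(100 − Y0). The PCV step exactly cancels any shared
per-frame acquisition photobleaching (an algebraic identity the tests
assert to 1e-6).

**Granules.** Robust threshold (median + 3·MAD-σ of the cytoplasm, one
re-estimation pass), 8-connected components, minimum 3 × 3 px size rule;
circularity 4πA/P² on the component's convex hull separates circular from
amorphic granules (default cut 0.8); cell-level summaries use the
longest-axis diameter d as area π(d/2)².

**Transport.** Tracks are stationary if their mean frame-to-frame speed
is below 0.138 µm/s, else anterograde/retrograde by the sign of net
displacement from the soma; velocities average motile frames; kymographs
sample the movie along the neurite polyline.

**Colocalization / spots.** Pearson's r over all ROI pixels, with
optional rolling-ball background subtraction (grayscale opening with a
spherical-cap element, radius 50 px default); smFISH spots by
Laplacian-of-Gaussian detection plus sub-pixel Gaussian fitting, assigned
to soma/neurite compartments.

**Reporters.** FLuc/RLuc per well, technical replicates averaged, then
normalized to the control construct; plates are the unit of error.

## Worked example

Simulate a FRAP experiment with a 66% mobile fraction and a 21.9 s
half-time under the standard acquisition (1.0878 s frames, 2 pre-bleach +
200 post-bleach, complete bleach, 0.2%/frame acquisition photobleaching,
noise sd 2), then recover the parameters:

```r
library(rnpquant)

sim <- gen_frap_trace(Fm = 0.66, t_half_s = 21.9, bleach_depth = 1,
                      drift_per_frame = 0.002, noise_sd = 2, seed = 42)
fit <- fit_recovery(normalize_trace(sim$trace))
fit
#> frap_fit: Y0 = 1.562%, plateau = 66.37%, K = 0.03115 /s
#>           t1/2 = 22.25 s, mobile fraction = 0.6584  (converged: TRUE)
```

The fitted mobile fraction (0.658) and half-time (22.25 s) recover the
generating values (0.66, 21.9 s) to within the uncertainty this noise
level implies; with `noise_sd = 0` recovery is exact to six significant
figures.

Granule detection against generator ground truth:

```r
sc  <- gen_granule_scene(n_granules = 12, snr = 10, seed = 7)
det <- granule_morphometrics(detect_granules(sc$stack, sc$cell_mask))
nrow(det)                              # 12 of 12 recovered
head(det[, c("area_px", "area_um2", "circularity", "morphology")], 3)
#>   area_px area_um2 circularity morphology
#> 1      28 0.197568   0.9161625   circular
#> 2      15 0.105840   0.8867615   circular
#> 3      53 0.373968   0.9321907   circular
```

Columns are calibrated (µm² from the 0.084 µm pixel size); circularity
near 1 marks round granules.

A command-line wrapper over the same functions lives at
`inst/cli/rnpquant.R`:

```sh
Rscript inst/cli/rnpquant.R simulate kind=frap --seed 7 --outdir out/
Rscript inst/cli/rnpquant.R frap traces=out/trace.csv --outdir out/
```

Every run writes a `manifest.json` (resolved config, seed, package
version, outputs) so deterministic stages are reproducible bit-for-bit.

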