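---
title: "mirloc: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirloc: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirloc)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter and why their
defaults are what they are, what the simulator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## Coordinate conventions

All images use pixel `(i, j)` with `i` = row = y and `j` = column = x,
0-based, origin at the top-left. Pixel `(i, j)` covers
`[j·a, (j+1)·a) × [i·a, (i+1)·a)` nm for pixel pitch `a`, so its center is
at `((j+0.5)·a, (i+0.5)·a)` nm. Localization coordinates are always nm.
The camera pixel pitch in the object plane defaults to 100 nm and is
configurable everywhere — acquisitions at other magnifications simply set
`pixel_size_nm`.

## The acquisition model

A photoswitching acquisition records thousands of frames (a full
acquisition is typically 3000 frames at 50 ms integration) in which sparse
subsets of fluorophores blink on and off. The simulator's forward model:

* **Blinking** is memoryless: each emitter turns on in each frame with
  probability `p_on_per_frame`, independently, at most once per frame.
  Real fluorophores have correlated on/off dwell times; a memoryless
  schedule is the simplest model that exercises the differential-stack
  detector, and it is deliberately replaceable (the schedule is a plain
  data frame of `(emitter, frame, photons)` rows that can be built by any
  other kinetic model).
* **Photons per event** follow an exponential law of mean `mean_photons`,
  truncated at ≥ 10 photons (the truncated exponential is memoryless, so
  this is `10 + Exp(mean)`). No published photon budget exists for the
  acquisitions this emulates; the default of 2000–3000 photons/event is
  typical of a bright organic dye.
* **PSF**: a symmetric 2D Gaussian of sd `psf_sigma_nm` (default 130 nm,
  a diffraction-limited spot for a high-NA objective at ~580 nm emission),
  *integrated over each pixel's area* — the correct camera sampling of a
  continuous spot.
* **Camera**: `counts = offset + gain·Poisson(expected photons) +
  N(0, read noise)`, rounded and clipped at 0. `counts_per_photon`
  collapses EM gain × A/D conversion into one number (acquisitions use EM
  gains of order 100–300; the calibrated combined value is what matters).
  EM-register excess noise is *not* modeled; the Gaussian read-noise term
  is the only non-Poisson noise. The PSF kernel is truncated at 7σ so
  photon mass is conserved to numerical precision for interior emitters.

What passing tests on this simulator do **not** show about real data:
robustness to drift (not modeled, and drift correction is out of scope),
dipole-orientation or 3D-defocus PSF distortions, EM excess noise,
fluorophore reactivation statistics, and labeling/background structure.
They do show that the analysis chain is internally correct: every
estimator is validated against the generating truth.

## Localization

The chain is: photon conversion → differential stack
`D[t] = F[t] − F[t+1]` → per-frame detection of positive peaks → Gaussian
fit → precision estimate → filtering.

* **Why fit the original frame, not the differential frame?** A positive
  peak in `D[t]` marks an emission that ended with frame `t`. The signed
  differential image has negative lobes from neighbouring events that bias
  a least-squares fit; the original photon frame at `t` contains the
  complete event plus a flat background that the fit absorbs in `b`. The
  differential stack is used only to *detect* events. Negative peaks are
  redundant mirrors of positive ones (each on-period produces both) and
  are ignored.
* **Detection**: local maxima of the positive part of `D[t]` at least
  `threshold_photons` above the frame median, non-maximum suppressed to a
  minimum spacing of one fit window. The default threshold is adaptive,
  5× the robust sd (1.4826·MAD) of the differential frame — differential
  frames are background-subtracted by construction, so their MAD tracks
  the shot + read noise floor.
* **Fit model**: `b + N·G(x₀, y₀, s)` with `G` the pixel-integrated
  symmetric Gaussian — the same family as the forward model, parameterized
  directly by the total photon count `N` (the peak amplitude
  `N/(2πs²)` is also reported). Levenberg–Marquardt with box bounds
  (position inside the window, `s` within the configured range), a
  100-iteration cap, and *Pearson weighting*: residuals `(y−m)/√m`, so
  bright central pixels are not overweighted relative to their Poisson
  variance. Unweighted least squares is available (`weighting = "none"`)
  and is measurably less efficient.
* **Window**: 7 px default at `a` = 100 nm (±2.7σ of a 130 nm PSF). Larger
  windows admit more neighbour contamination in dense scenes; smaller ones
  truncate the spot. Configurable (odd, ≥ 5).
* **Precision**: the Thompson estimate
  `σ_loc² = (s² + a²/12)/N + 8π s⁴ b²/(a² N²)`. Localization-accuracy
  histograms are often reported without an operational definition;
  this standard formula is the package's choice, and the end-to-end tests
  verify that empirical per-axis RMSE against ground truth stays within
  1.5× its mean prediction.
* **Filters**: minimum photons (default 200), maximum precision (50 nm),
  PSF-width bounds (50–300 nm). These are quality gates, not published
  values; all configurable.
* **Single-emitter regime**: overlapping spots within one window are
  suppressed, not multi-fitted. When two emitters within ~4 px blink in
  the same frame the fit lands between them; at the sparse blinking
  densities the method assumes this is rare, and the validation protocol
  treats such detections (beyond a 50 nm truth-association gate, ~12× the
  predicted precision) as false positives rather than position errors.

## Rendering

Gaussian mode gives each localization unit mass spread by *its own* σ_loc
(kernel truncated at 4σ, < 0.1% mass loss), so image intensity is molecule
density and blur is uncertainty; histogram mode bins counts. Default
rendering pixel: 10 nm, matching ~10–15 nm localization accuracy. 32-bit
float TIFF output is stored normalized to [0, 1] (a format limitation of
the writer); quantitative values live in the CSV/JSON outputs.

## Cluster analysis

A molecule is clustered when ≥ `k` other signals lie within `r`. The two
published parameterizations of `k = 5` disagree — r = 120 nm in the
results-level description, r = 60 nm in the methods-level one — and the
package ships both as presets (`"results"`, the default because the
figure-level statistics derive from that section, and `"methods"`) rather
than silently resolving the conflict. The tie between them is the critical
density `ρ_c = (k+1)/(πr²)`: 132 molecules/µm² at 120 nm and 530 at 60 nm,
exactly the two printed densities — which also fixes the reading that the
five neighbours *exclude* the center point.

Full DBSCAN semantics: clusters are connected components of core points
(≥ k neighbours within r) plus border points within r of a core; border
points go to the nearest core (ties to the lower index) and labels are
deterministic, ordered by smallest member index. The implementation is a
grid-accelerated neighbour search in C++; the test suite proves label
equality against a brute-force O(n²) union-find oracle on dozens of mixed
Thomas/CSR scenes.

Cluster *diameter* is the maximum pairwise member distance (no published
definition exists; twice the gyration radius is available behind
`diameter_method = "gyration"`). Internal density is `n/(π(d/2)²)`;
coincident-point clusters (d = 0) get an `NA` density rather than an
infinity. Per-cell cluster density divides cluster count by the cell
footprint area from the mask.

**CSR test**: the statistic is the clustered fraction of molecules (no
statistic is published; this one is monotone in exactly the property the
criterion formalizes), compared against `n_sim` CSR patterns of the same
size in the same region, `p = (1 + #{S_sim ≥ S_obs})/(n_sim + 1)`. The
test is exact by construction (ties make it conservative). Calibration is
verified at n = 1500 points in a 5 × 5 µm region — large enough that the
clustered-fraction statistic is effectively continuous; at much lower
densities the statistic is frequently zero and the test loses power but
keeps its level.

## Segmentation and co-localization

Compartments arrive as label masks (0 extracellular, 1 nucleus,
2 cytoplasm+membrane) with a nm georeference; the original workflow has a
user draw these regions by eye on the wide-field membrane image, so
interactivity is out of scope here but the counting logic is identical:
each localization takes the label of the containing mask pixel, points
outside the footprint are extracellular, and counts always sum to the
table size. Coarse masks can be refined with `upscale_mask`, a bilinear
interpolation of each label's indicator followed by argmax (ties to the
lower label), matching the scaling step of the original segmentation tool.

Exosome spots are detected in the GFP wide-field channel by robust
thresholding (median + 5 robust sd) and 8-connected components of ≥ 4 px;
each spot gets an intensity-weighted centroid and equivalent-circle
radius. A miR localization co-localizes with a spot when within
`spot radius + match_radius_nm` (default 50 nm — unpublished, of order a
few localization precisions) of its center, assigned to the nearest
qualifying spot; the per-fraction readout is total co-localized molecules
normalized to the number of detected exosomes.

## Validation problem sizes

The shipped validation uses desk-scale problem sizes chosen to exercise
every code path with tight statistics: the nanoruler standard uses 100
fluorophore pairs at 35 nm over 500 frames (~1000 blink events, ≥ 1000
photons each after filtering) — the pair-separation recovery lands within
a fraction of a nanometer of the design value; precision recovery uses 50
emitters over 500 frames; oracle equivalence covers 50 scenes up to 2000
points; CSR calibration uses 200 replicates of 1500 points with 99
simulations each. Cell-scale biological quantities (per-cell molecule
tallies in the 10³–10⁴ range, 40 vs 111 clusters per cell, 10–15 nm
accuracy histograms) depend on real acquisitions and are *report formats*
here, not reproduced numbers.

## Known limitations

No drift correction, no 3D localization, no multi-emitter fitting, no
sCMOS pixel-wise noise maps, no EM excess-noise factor, and no automated
membrane segmentation (masks are inputs). The blinking kinetics and photon
budgets of the simulator are field-typical defaults, not calibrated to a
specific dye/buffer system, and should be overridden when emulating a
particular instrument.
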