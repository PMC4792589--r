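# mirloc

Single-molecule localization microscopy (SMLM) analysis of subcellular
miRNA distributions, from raw blinking-fluorophore image stacks to
localization tables, super-resolution renderings, density-based cluster
statistics, compartment counts and exosome co-localization — plus a seeded
synthetic-acquisition simulator so the whole chain can be validated without
a microscope.

It is aimed at microscopists and image analysts who have (or want to
simulate) photoswitching acquisitions of fluorophore-tagged small RNAs in
fixed cells and need quantitative, reproducible readouts: how many
molecules per cell, how precisely each was localized, whether and how they
cluster, how they distribute over nucleus / cytoplasm / extracellular
space, and how many sit inside exosomes.

## The method

**Localization.** Camera counts are converted to photons,
`photons = max(0, counts − offset) / gain`, and a *differential stack*
`D[t] = F[t] − F[t+1]` isolates blinking transitions: a positive peak in
`D[t]` is a molecule whose emission ended with frame `t`. Candidate peaks
are fitted on the original photon frame with a pixel-integrated 2D
Gaussian `b + N·G(x₀, y₀, s)` by Levenberg–Marquardt (Pearson-weighted for
Poisson shot noise). Each localization's precision is the Thompson
estimate

    σ_loc² = (s² + a²/12)/N + 8π s⁴ b² / (a² N²)

with photon count `N`, PSF width `s`, pixel pitch `a` and background `b`
photons/px. Renderings blur every position by its own σ_loc.

**Cluster analysis.** Density clustering with DBSCAN semantics: a molecule
is in a cluster when at least `k` other signals lie within radius `r`.
Both published parameterizations of the `k = 5` criterion ship as presets
— `"results"` (r = 120 nm) and `"methods"` (r = 60 nm) — whose implied
critical densities `(k+1)/(πr²)` are 132 and 530 molecules/µm². A
Monte-Carlo test against complete spatial randomness (CSR) uses the
clustered fraction as statistic. Per-cluster diameters, molecule counts
and densities, and per-cell cluster densities are reported.

**Segmentation & co-localization.** Label masks (0 extracellular,
1 nucleus, 2 cytoplasm+membrane) assign every localization to a
compartment; wide-field GFP-exosome channels are thresholded into spots
and miR signals are counted per exosome (total co-localized normalized to
the number of detected exosomes).

**Simulator.** CSR and Thomas-process layouts, nanoruler pair standards,
memoryless blinking schedules, and an EMCCD forward model (pixel-integrated
Gaussian PSF, Poisson shot noise, camera offset/gain/read noise) — with
ground truth retained so every stage has an oracle.

## Worked example

```r
library(mirloc)
cfg <- read_config(system.file("extdata", "demo_config.yaml", package = "mirloc"))
m <- run_pipeline(cfg, out_dir = "demo_out", seed = 7,
                  stages = c("simulate", "localize", "render", "cluster", "segment"))
pipeline_report(m)
```

prints

```
localizations: n = 337
mean precision = 3.07 nm
median precision = 2.65 nm
clusters: n = 6
cluster density = 0.732 per um^2 (area 8.20 um^2)
compartments: nucleus 112 / cytoplasm 19 / extracellular 206
```

i.e. a 200-frame synthetic acquisition of a clustered scene yielded 337
single-molecule localizations at ~3 nm predicted precision (bright
simulated events; real acquisitions land nearer 10–15 nm), 6 detected
clusters at 0.73 clusters/µm² of cell footprint, and the per-compartment
tallies. `demo_out/` then holds the stack (`stack.tif`), localization
table (`localizations.csv`), rendering (`sr.tif`), per-cluster metrics
(`clusters.csv`), compartment counts (`compartments.json`) and a manifest
recording seed and parameter hash. The same stages are available as shell
subcommands via `inst/scripts/mirloc` (`simulate`, `localize`, `render`,
`cluster`, `segment`, `coloc`, `run`, `report`).

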