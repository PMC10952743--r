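# srsphasor

Spectral phasor unmixing of hyperspectral stimulated Raman scattering (SRS)
microscopy images, with a reference-spectrum library for bioorthogonal Raman
tags and a synthetic-scene generator for validating the whole pipeline.

## The problem

Multiplexed vibrational imaging of live cells places small bioorthogonal
reporters — alkynes (C≡C, ~2220 cm⁻¹), carbon–deuterium bonds (C–D,
~2100 cm⁻¹) and boron-cluster B–H stretches (2480–2650 cm⁻¹) — in the
cell-silent region of the Raman spectrum, where no endogenous bands
interfere. A wavelength-scanned SRS microscope produces a hyperspectral
stack: one image per Raman shift, several windows per experiment. The
question is how to turn that stack into labelled cellular regions: nucleus,
nucleolus, cytoplasm, lipid droplets and their periphery, cell boundary,
plus one region per probe.

`srsphasor` implements the spectral phasor approach. Each pixel's spectrum
I(k), k = 0..N−1 over the (ascending, concatenated) frame axis is reduced to
two normalised first-harmonic Fourier coefficients,

    G = Σₖ I(k) cos(2πnk/N) / Σₖ I(k)
    S = Σₖ I(k) sin(2πnk/N) / Σₖ I(k)

so that pixels with similar spectral *shapes* cluster in the (G, S) plane
regardless of intensity. Segmenting the phasor plot — with explicit polygon
gates or seeded k-means — and mapping each cluster back to the image yields
the segmentation. Probe brightness is quantified as RIE (relative intensity
to EdU): the baseline-corrected reporter-band height of a probe spectrum
divided by that of the 5-ethynyl-2′-deoxyuridine alkyne band at 2120 cm⁻¹.

Because measured cell stacks are instrument-bound and not redistributable,
validation runs on a synthetic single-cell scene with pixel-level ground truth: nine
classes with distinct composite spectra over three scan windows
(3050–2800 cm⁻¹ in 40 frames, 2650–2450 in 35, 2250–2000 in 40; ~7 cm⁻¹
per step), Poisson + Gaussian noise, and seeded geometry.

## Worked example

```r
library(srsphasor)

cfg <- pipeline_config(preset = "triplex_crsan", mode = list(kmeans = 9L),
                       seed = 11L)
rep <- run_pipeline(cfg)
print(rep$matching)
#> <segment_matching> 9/9 classes recovered at IoU >= 0.50
#>             class    segment       iou recovered
#>           nucleus cluster_02 1.0000000      TRUE
#>         nucleolus cluster_09 1.0000000      TRUE
#>         cytoplasm cluster_01 1.0000000      TRUE
#>     lipid_droplet cluster_08 1.0000000      TRUE
#>      ld_periphery cluster_04 0.9992151      TRUE
#>     cell_boundary cluster_03 0.9994413      TRUE
#>             crsan cluster_05 1.0000000      TRUE
#>  stearic_am_coloc cluster_06 1.0000000      TRUE
#>         am_pocket cluster_07 1.0000000      TRUE
```

The report says that k-means gating of the phasor plot of the 115-frame
simulated triplex stack recovered all nine ground-truth classes, each
matched one-to-one (Hungarian assignment) at an intersection-over-union of
essentially 1. Restricting the same scene to the two silent-region windows
(`windows = list(c(2450, 2650), c(2000, 2250))`, `mode = list(kmeans = 3L)`,
`truth = "probes"`) unmixes the three probe classes alone.

RIE quantification on the packaged references:

```r
refs <- builtin_references()
grid <- seq(2000, 3100, by = 1)
edu <- evaluate_reference(refs$edu, grid)
compute_rie(evaluate_reference(refs$metallacarborane, grid),
            c(2480, 2650), edu)
#> RIE(sample) = 3  [height]
```

i.e. the metallacarborane B–H envelope scatters 3× the EdU alkyne band,
and the butadiyne AM-ester reference gives 12 (a 4-fold ratio).

The `analysis/` directory holds the same workflow as numbered drivers
(`01_simulate_scene.R` … `04_rie_quantification.R`), each writing its
artifacts under `results/`.

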