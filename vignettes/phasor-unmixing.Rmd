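---
title: "Spectral phasor unmixing of hyperspectral SRS stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral phasor unmixing of hyperspectral SRS stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsphasor)
```

## The measurement and its model

A wavelength-scanned SRS microscope steps the pump laser by a fixed
wavelength increment between image frames; a step of Δλ nm at pump
wavelength λ corresponds to a Raman-shift increment of 10⁷Δλ/λ² cm⁻¹
(`pump_step_to_wavenumber_step()`), about 7 cm⁻¹ for a 0.4 nm step near
760 nm. An experiment covers one or more spectral windows — here the C–H
region (3050–2800 cm⁻¹) for label-free cellular contrast and two
cell-silent windows (2650–2450 and 2250–2000 cm⁻¹) for bioorthogonal
probes. A `hyper_stack` holds the resulting rows × cols × frames array
bound to a `wavenumber_axis` that records each frame's Raman shift and
acquisition window. Frames are stored in acquisition order (descending
wavenumber within a window, mirroring the instrument); every spectral
operation sorts ascending internally so the mathematics stays conventional.

## The phasor transform

For a pixel spectrum $I(k)$, $k = 0,\dots,N-1$ over the ascending
concatenated frame axis, the harmonic-$n$ phasor is

$$G = \frac{\sum_k I(k)\cos(2\pi nk/N)}{\sum_k I(k)}, \qquad
  S = \frac{\sum_k I(k)\sin(2\pi nk/N)}{\sum_k I(k)}.$$

Three properties carry the whole method and are enforced as tests:

* **Scale invariance** — multiplying a spectrum by a positive constant
  leaves (G, S) unchanged, so phasor space encodes spectral shape, not
  brightness.
* **Linearity** — the phasor of a sum of spectra is the total-intensity-
  weighted mean of the component phasors (`phasor_of_mixture()`); mixtures
  lie in the simplex spanned by the pure-component points.
* **Boundedness** — $G^2 + S^2 \le 1$, with an absolute tolerance of
  $10^{-9}$ allowed for double-precision accumulation.

The harmonic defaults to 1: with one-to-few broad features per window the
first harmonic separates shapes best, and nothing in the analysed data
motivates a higher one. For multi-window experiments the transform runs on
the combined stack (`concat_windows()`): windows are abutted on the frame
index, which becomes the Fourier coordinate. Using the index rather than
the physical wavenumber is a deliberate choice — it needs no gap model, is
deterministic, and any fixed monotone reindexing of the spectral axis
yields an equally valid shape space; what matters is that the same
convention is applied to every pixel. A window-subset option
(`select_windows()`) supports silent-region-only analyses, so both a joint
and a gated reading of the multi-window design are available.

Pixels whose total intensity is too small have noise-dominated,
meaningless phasors. `phasor_transform()` flags them invalid (carrying
(0, 0) but excluded from histograms, gating and clustering, which avoids
NaN propagation). Its own default threshold is 1% of the maximum per-pixel
total intensity — a sensible floor for single-window stacks. The pipeline
uses a different default: a two-class k-means (ISODATA-style) split of the
log-total intensities, because with additive noise clipped at zero the
summed intensity of *empty* background grows in proportion to the frame
count times the noise SD, and for a 115-frame stack that floor sits well
above 1% of the cell maximum while remaining far below any cellular class;
the log domain keeps the split from being dragged upward by the brightest
pixels. The threshold is exposed (`intensity_threshold`), so either
convention can be forced.

## Segmentation in phasor space

Manual analyses draw boxes on the phasor plot. `phasor_gate` reproduces
that: a named simple polygon with a priority; `gate_segment()` labels each
valid pixel by the highest-priority gate containing its (G, S) point
(boundary inclusive — a point on a gate edge belongs to the gate). Because
manual gating is not reproducible, `auto_cluster()` automates it: k-means
(k-means++ initialisation, fixed seed, 10 restarts, best within-SS kept)
on the valid-pixel phasor cloud, each cluster returned as the convex hull
of its members. Gates are ordered by descending member count with
priorities increasing along that order, so smaller clusters win hull
overlaps — a large cluster's hull must not swallow a small, separated one.
k was fixed at 9 for the headline triplex analysis (the number of regions
identified by inspection in the motivating experiment) and 3 for the
silent-region analysis.

Recovered segmentations are scored against ground truth by
intersection-over-union under the optimal one-to-one assignment
(Hungarian algorithm, `clue::solve_LSAP`), with IoU ≥ 0.5 — the standard
detection convention — defining "recovered". Empty segments are reported
with pixel count 0, never silently dropped.

## Reference spectra and RIE

Probe and compartment bands are modelled as sums of Gaussian/Lorentzian
peaks (`peak_model`, FWHM-parameterised: σ = FWHM/(2√(2 ln 2)),
γ = FWHM/2). The packaged library (`builtin_references()`) covers: EdU
(alkyne, 2120 cm⁻¹), the metallacarborane B–H envelope — three overlapping
sub-peaks spanning 2480–2650 cm⁻¹, echoing the observed peak splitting,
with its maximum near 2570 cm⁻¹ — ortho-carborane, two butadiynes at
2220 cm⁻¹, stearic acid-d35 (CD₂, 2102 cm⁻¹), a partially deuterated
metallacarborane with a C–D doublet at 2260.4/2273.4 cm⁻¹, and the
label-free protein CH₃ (2930 cm⁻¹) and lipid CH₂ (2851 cm⁻¹) components.
Low-wavenumber fingerprint modes (B–B–M bend ≈635 cm⁻¹, cage rocking
≈250 cm⁻¹, whole-molecule ≈200 cm⁻¹, the latter absent for
ortho-carborane) are present in the library but fall outside every default
scan window.

RIE — relative intensity to EdU — is the baseline-corrected reporter-band
statistic of a sample divided by that of EdU on its fixed 2090–2150 cm⁻¹
band. The baseline is the straight line through the band endpoints, which
makes the ratio exactly invariant to constant offsets; the default
statistic is peak height (band area is available as `method = "area"`),
since the quantity being compared is the intensity of a stretching band.
Library amplitudes are calibrated so the height-RIEs reproduce the
reported whole-molecule values — metallacarborane 3, butadiyne AM-ester 12
(the 4-fold ratio), EdU 1 by definition — with ortho-carborane at 2 (below
the metallacarboranes, as observed; no exact value is reported),
imidazole at 11 and stearic-d35 at 1.5 (plausible placements, no reported
values). Exact sub-peak positions and widths of the B–H envelope are free
parameters recorded in `inst/extdata/reference_library.json`.

## The synthetic scene

The generator emulates a single 2-D cell — matching the single-plane
images the method is used on — as nested analytic geometry: cell ellipse,
boundary band (width 3 px), nucleus ellipse, nucleoli, cytoplasmic lipid
droplets with a periphery annulus, and circular probe "pockets". Nucleoli,
droplets and pockets are placed uniformly at random inside their parent
compartments by rejection sampling (1000 retries per object, then a
placement error naming the compartment). Each class's analytic spectrum is
a non-negative weight vector over the reference library; the triplex
preset realises: metallacarborane throughout the cytoplasm with nuclear
amplitude 0.3× the cytoplasmic one (the "weak nuclear association",
encoded as a configurable factor since no number is reported) and dense
accumulations as class G; droplets co-loaded with stearic-d35 and AM-ester
(class H); AM-ester-dominated pockets with residual metallacarborane
(class I). Compartment C–H weights are plausibility choices — no
compartment amplitudes are tabulated anywhere — fixed once, with distinct
protein:lipid ratios per compartment, and constrained by the generator's
own separability requirement: the pairwise distances between noiseless
class phasors must exceed 4× the noise-induced within-class phasor spread,
the regime in which phasor segmentation is well-posed. The test suite
measures both sides of that inequality rather than assuming them.

Noise is Poisson-scaled shot noise (`x → rpois(x/p)·p`, p = 0.0016, which
puts the SNR near 20 at a unit-amplitude CH₃ band) plus additive Gaussian
noise (SD 0.03 ≈ 2% of the brightest compartment amplitude), clipped at
zero to keep intensities physical. Clipping matters only where the
analytic signal is ≈0 (outside the cell); the Gaussian SD is therefore
verified on a flat non-zero field, where the clip never triggers. All
randomness — placement and noise — derives from the scene seed (noise
sub-seeds offset by window index), making rendered stacks bit-reproducible.

What the scene does *not* emulate: optical blur (class boundaries are
pixel-sharp, which inflates boundary-pixel IoU relative to real optics),
spectral calibration drift, water/non-resonant backgrounds, intra-class
concentration gradients, and 3-D structure. Passing the acceptance checks
therefore demonstrates that the pipeline's mathematics and its
segmentation logic are correct under the stated noise model — not that
real cellular stacks of arbitrary quality will segment this cleanly.

## Numerical choices and degenerate inputs

* Nearest-frame selection (`extract_frequency_image()`) breaks ties toward
  the lower frame index; a request farther than one axis step outside the
  range errors. Off-resonance subtraction clips negatives to zero.
* Integer-valued stacks are stored as 16-bit TIFF pages and round-trip
  bit-exactly; other stacks as scale-normalised 32-bit float pages with
  the scale in the JSON sidecar.
* Convex hulls of collinear clusters are padded to a thin box (±10⁻⁹) so
  gates remain valid polygons.
* Constant spectra cannot be min-max normalised and error explicitly; an
  all-below-threshold phasor field warns and returns an empty field.
* k-means with k exceeding the number of distinct phasor points errors as
  degenerate.
* The end-to-end pipeline derives per-stage seeds from one master seed
  (simulation = seed, clustering = seed + 100), writes every artifact next
  to a resolved YAML config, and hashes the configuration so determinism
  regressions are detectable by `run_report_compare()`; that hash excludes
  the seed so same-analysis/different-seed runs can be diffed.

## Problem sizes

The validation scenes are 256 × 256 pixels × 115 frames for the headline
analyses and 128 × 128 for unit tests — sizes at which every stage (scene
rendering ≈ 5 s, phasor transform ≈ 2 s, k-means gating ≈ 1 s on one core)
is comfortable on a laptop while leaving all nine classes hundreds to
thousands of pixels each.

## Known limitations

Polygon gating operates on the raw (G, S) cloud; no intensity weighting or
median pre-filtering of the phasor planes is applied before clustering,
and no mixture-model or density-based alternatives are provided. The
multi-window abutment convention means phasor coordinates are not
comparable between experiments with different scan plans. RIE values are
whole-molecule ratios of the modelled references; nothing is normalised
per functional group, and no peak fitting to measured spectra is
performed.
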