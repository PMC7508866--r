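---
title: "Quantifying early osteoarthritic cartilage: surface topology and histology metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying early osteoarthritic cartilage: surface topology and histology metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Early osteoarthritis (OA) alters the articular cartilage surface before
classical histological scores can separate different modes of degeneration.
Two common rodent induction models — medial meniscal transection (MMT, a
mechanical insult) and intra-articular monoiodoacetate (MIA, a chemical
insult) — produce comparable Mankin-modified scores at four weeks, yet the
collagen network is in very different mechanical states. `oatopo`
implements a microscale surface-metrology approach that resolves this
difference, alongside the standard quantitative histology it complements.

The measurement regime emulated throughout is white-light confocal
profilometry: 512 × 512 height samples at a 1 µm lateral step, with
observed dominant surface wavelengths between 8 and 28 µm.

## Surface topology metrics

**Wavelengths.** For a height map $z(x, y)$ the in-plane gradient
$(\partial z/\partial x,\ \partial z/\partial y)$ is computed by central
differences (one-sided at borders). Along every scan line of each signed
derivative, strict local maxima are located (plateaus contribute their
midpoint); the per-axis wavelength $\lambda_x$, $\lambda_y$ is the average
over scan lines of each line's mean inter-maxima spacing. Two conventions
matter and are deliberate:

* *Signed* derivatives, not $|\nabla z|$: the modulus of a sinusoid's
  derivative peaks twice per period and would halve every wavelength;
  the signed derivative peaks once per period, so the estimator equals the
  physical period on a pure sinusoid.
* *Per-line averaging*: averaging each line's mean spacing (rather than
  pooling all spacings and dividing by the image size) keeps the estimator
  equal to the period on the pure-sinusoid oracle regardless of how many
  maxima a line holds.

**Deformation ratio.** For an OA surface paired with its healthy
contralateral reference,
$\varepsilon_a = (\bar\lambda_a^{OA} - \bar\lambda_a^{H}) / \bar\lambda_a^{H}$
per axis $a \in \{x, y\}$, reported as a fraction (0.417, not 41.7%; the
`percent` print option rescales). Negative values indicate compression,
positive extension.

**Angular sectors and cohesion.** The 2D Fourier coefficients of the
surface are partitioned by the polar angle of the frequency vector into the
0–90° and 90–180° sectors, taken modulo 180° so that conjugate-symmetric
bins travel together and both inverse transforms are real. The DC bin is
excluded from both parts, making the identity $s_1 + s_2 + \bar z = z$ hold
to floating precision. Boundary conventions: θ = 0° (pure x frequencies)
belongs to sector 1, θ = 90° (pure y) to sector 2; on even grids the
sign-ambiguous Nyquist column goes to sector 1 and the Nyquist row to
sector 2, which keeps the two sectors energy-balanced for isotropic
surfaces (sending both lines to one sector biases white-roughness energy by
several percent; this was measured and rejected). Each sector
reconstruction is then pushed through the same wavelength chain, and the
cohesion index per axis is

$$I_a = \frac{|\bar\lambda_a^{0 \Rightarrow 90^\circ} -
\bar\lambda_a^{90 \Rightarrow 180^\circ}|}{\lambda_{a,\min}},$$

with $\lambda_{a,\min}$ the smaller of the two sector means. That
denominator choice keeps $I$ dimensionless, non-negative, zero at perfect
balance and invariant under swapping the sector labels; it is recorded in
the output for audit. A cohesive, isotropically tensioned network scores
near zero; sector-selective change drives $I$ up.

**Denoising.** White measurement roughness splits gradient maxima into
spurious doublets and collapses the spacing estimator (at 5% roughness the
raw estimator under-reads a 15 µm surface by ~30%). All wavelength chains
therefore apply a separable Gaussian low-pass with mirror-reflection
boundaries, σ = 1.5 µm by default — 1.5× the instrument's lateral
resolution, far below the 8–28 µm band of interest. Linear filtering does
not move a sinusoid's maxima, and the pure-period oracles in the test suite
pass with the filter on, so the default is safe across the operating band;
σ = 0 disables it. A minimum peak prominence (default 0) is available as a
second guard for heavier-tailed noise. Gaussian smoothing is implemented
in-package because reflect padding matters here: circular boundary handling
(the usual FFT convolution convention) wraps the non-periodic surface and
seeds edge artifacts. Planar detrending is available (`detrend_height_map()`)
but off by default: a planar tilt only shifts the gradient by a constant and
leaves maxima spacings unchanged.

## The synthetic study

The generator exists so that every stage has exact ground truth.

**Surfaces** are a bank of five sinusoids per axis with wavelengths drawn
within ±4% of a controllable dominant wavelength (weights 1, 0.2, 0.2,
0.15, 0.15), a mirrored pair of oblique plane waves with the same per-axis
periods (weight 0.5) that places comparable content in both angular
sectors, and white Gaussian roughness. Defaults: 512 × 512 at 1 µm,
dominant wavelength 15 µm (mid-band), amplitude 1 µm, roughness 5% of
amplitude. No profilometric study reports a roughness amplitude for rat
cartilage at this scale, so the amplitude is an explicit free parameter of
the configuration rather than a claim about tissue.

**Pairs.** The OA member is the healthy member's grid resampled at
stretched coordinates (bilinear, mirror-reflection for stretch < 1), so the
deformation ratio has the exact ground truth $\varepsilon = k - 1$ and the
estimator noise largely cancels in the ratio. Sector imbalance is planted
by dilating the 90–180° sector reconstruction along x only by
$1 + s$: this multiplies that sector's x-wavelengths by exactly $1 + s$
(so $I_x \approx s$, strictly monotone), while leaving every y-structure
untouched — a uniform amplitude gain of the sector, the obvious
alternative, is invisible to a spacing-based estimator, and a 2D dilation
leaks into the full-surface y-wavelength and corrupts the planted
$\varepsilon_y$. Both alternatives were implemented and rejected on those
measurements.

**Slides** are a centred rectangular "cartilage" region on a dark
background: colour patches with band-centre hues planted to the pixel
(red 0°, yellow 45°, green 115°), a neutral unsaturated fill, and
non-overlapping dark-blue discs for chondrocytes placed by seeded rejection
sampling below a one-diameter guard band (infeasible packing raises an
error instead of silently planting fewer cells). Defaults give realistic
chondrocyte densities of roughly 350–600 cells/mm². What the slides do
*not* emulate: stain gradients, overlapping or out-of-focus cells,
tissue-boundary irregularity, polarizer angle effects. Passing tests
therefore demonstrate the correctness of the measurement chain, not
robustness to bench-grade image variability.

**The default study** mirrors a 4-group contralateral design (3 animals
per model; each contributes a healthy and an OA knee): MMT plants stretch
(1.213, 1.205) plus sector imbalance 0.5; MIA plants stretch
(1.353, 1.417) with no imbalance; slides plant group-wise colour fractions,
cell counts and Mankin operator scores (healthy ≈ 2, MMT ≈ 4, MIA ≈ 5 of
14). Mankin operator triples are a seeded permutation of
{base − 1, base, base + 1}, so each sample's operator mean equals the
planted base exactly while operator-level variation remains.

## Histology quantification

Segmentation thresholds the HSV value channel (robust to saturated stain
colours) at Otsu's level, keeps the largest connected component, applies a
morphological closing with a brush of about one cell radius — without it,
cells lying on the tissue border notch the mask, because hole filling
cannot close a hole that opens onto the boundary — and fills interior
holes. The bench procedure is semi-automatic, so a user-supplied mask
bypasses all of this. Colour fractions count hue-band pixels inside the
mask over the full mask area (bands: red [0°, 20°) ∪ [340°, 360°), yellow
[20°, 70°), green [70°, 160°); configurable), excluding near-black
(value < 0.15) and near-grey (saturation < 0.2) pixels from every band so
the dark polarized background never registers as colour. The bench colour
thresholds are not standardized anywhere; these are explicit configuration,
not a claim of equivalence to any particular software.

Cell counting is an automated stand-in for manual multi-operator counts:
Otsu threshold over in-mask grey values, connected components, and a
component-area gate of 25–400% of the expected cell area (which also
discards large dark stain regions). The manual path
(`cellularity_from_counts()`) accepts typed per-operator counts. Mankin
totals are validated to the 0–14 scale and aggregated as operator mean and
sample SD; the component rubric is not re-derived, subscores are validated
free-form fields. Profile-line intensity samples the grey image along a
rasterized segment at unit spacing with no sub-pixel interpolation, since
no finer convention is established; the operation is modality-agnostic.

## Group statistics

Small-n designs (3 per group) make normal-theory tests inappropriate, so
the omnibus comparison is Kruskal–Wallis with tie correction and the
chi-square approximation — under which the smallest attainable p for two
tie-free triples is 0.0495, the working floor of the 3 + 3 design — and
pairwise follow-up is a two-sided Dunn z-test on pooled ranks with
Bonferroni correction capped at 1. Two-group comparisons are flagged on the
omnibus p (the Dunn multiplier is 1 there); larger sets on the adjusted
pairwise p. Sidedness and tie policy are configuration, two-sided and
tie-corrected by default. Fully degenerate ranks (all values identical)
raise a typed error rather than returning NaN.

A caveat the package cannot remove: at n = 3 per group the only attainable
sub-0.05 outcome is complete rank separation, which a null comparison also
reaches with probability 0.1 under exchangeability. Null contrasts in the
default study (the MIA cohesion comparisons) must be read with that floor
in mind; the end-to-end checks therefore assert effect sizes near zero for
them rather than the flag bit alone.

## Reproducibility mechanics

Every generator consumes a single integer seed and leaves the global RNG
state untouched; the pipeline derives per-sample seeds from the master
seed, so a full run is byte-deterministic (numeric CSV cells are written at
six significant digits to keep hashes platform-stable). Height maps
interchange as lossless headerless CSV or normalized 32-bit-float TIFF
(offset/scale in a JSON sidecar, since float TIFF storage is defined on
[0, 1]); slides and masks as 8-bit PNG. Each stage records its outputs and
their MD5 hashes in a manifest. Per-sample failures (e.g. an undefined
wavelength on a featureless surface) are logged to `skipped.csv`, the batch
continues, and the report lists the skips with reasons.

Problem sizes used by the test suite and the acceptance script: full-size
512 × 512 surfaces where the wavelength machinery itself is under test
(10-seed deformation recovery, 8–28 µm band oracles, 40-surface cohesion
monotonicity), 128–320 px grids for pipeline mechanics, 1000 simulations
for the type-I error of the omnibus test, and the complete 4 × 3 simulated
study for the end-to-end run.

## Known limitations

* The wavelength estimator assumes a dominant quasi-periodic texture;
  surfaces without one (or a spectral sector without energy) raise typed
  undefined-wavelength errors by design.
* The cohesion index inherits the spacing estimator's small-sample noise;
  at baseline isotropy it sits near 0.005–0.02 rather than exactly zero.
* Real polarized-light colour depends on polarizer angle and section
  thickness; the colour-fraction operation quantifies whatever the imaging
  protocol delivers and cannot correct for it.
* Automated counting assumes roughly convex, non-overlapping, dark cells;
  heavy overlap requires the manual-count path.
* Curvature/form removal, standardized roughness parameters (Sa, Sq) and
  wavelet multi-scale analysis are out of scope.
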