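---
title: "Quantifying Z-disc growth control: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Z-disc growth control: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological problem

Myofibril diameter is set by the diameter of its Z-discs. In
*Drosophila* indirect flight muscle (IFM), Z-disc growth is driven by
oligomerization of Zasp (Alp/Enigma-family) proteins: isoforms carrying
two or more LIM domains ("growing" isoforms) recruit further Zasp
molecules through LIM–ZM binding, while isoforms with zero or one LIM
domain ("blocking" isoforms) are recruited but cannot recruit further,
capping growth. The balance of the two classes sets disc size; excess
growing isoform produces pathological aggregates, excess blocking
isoform produces small discs.

`zdiscquant` reimplements the quantitative readouts this model is
tested with: Z-disc diameter morphometry from longitudinal micrographs,
tile-based aggregate density, within-disc localisation from cross
sections, isoform classification from domain architecture with
class-wise expression time-courses, and the associated statistics. A
seeded synthetic-data generator with exact ground truth stands in for
micrographs and RNA-seq quantifications, so every stage is testable
end to end.

## Segmentation and morphometry

**Auto-threshold.** `auto_threshold_default_dark()` implements the
iterative-intermeans (isodata-variant) threshold on a 256-bin
histogram: the returned threshold *t* is the smallest fixed point of

$$ t = \left\lfloor \tfrac{1}{2}\left(\mu_{\le t} + \mu_{> t}\right)
\right\rfloor $$

where the means are over histogram bins at or below / above *t*. The
iteration starts at the lowest occupied bin, where the map is
non-decreasing, so it converges monotonically to the smallest fixed
point; a brute-force scan over all 256 candidates is used as an
independent oracle in the tests. The mask keeps pixels *strictly
above* the threshold (bright objects on a dark background). For 8-bit
data the bins are the intensities 0–255; otherwise the intensity range
is split into 256 equal bins and the threshold maps to its bin's upper
edge. The reference tool's additional convention of zeroing the two
extreme bins (meant to ignore erased/saturated areas) is available as
`ignore_extremes = TRUE` but off by default, because it departs from
the pure intermeans fixed point on images containing true black or
saturated pixels; this is the one deliberate divergence from the
reference implementation and the only one we are aware of.

**Particle analysis.** `find_particles()` labels 8-connected
components (diagonal contact joins, matching the reference particle
analyzer; the 4-connected labeller available elsewhere in R image
packages would split corner-touching discs), drops components below
`min_area_um2` (default 0.2 µm²) and, by default, components touching
the image border. Touching discs are deliberately **not** split:
merged near-neighbour discs are a documented failure mode of the
measurement protocol and are kept for consistency, as in the original
study design.

**Diameter.** The disc diameter is the particle's bounding-box extent
perpendicular to the myofibril axis ("Z-disc height"), converted to
µm. The axis is an explicit parameter (0° = horizontal, the common
case); for oblique axes the member pixels are projected onto the
perpendicular direction and the span plus one pixel footprint is used.
Feret diameters are not used; bounding-box height matches the default
measurement convention of the reference tool.

**Size categories.** `categorize_sizes()` bins diameters right-open
with under/overflow bins. The published analyses categorise disc sizes
but never print the category bounds; the defaults (0.5, 1.0, 1.5,
2.0 µm) are package defaults chosen to bracket the 1.4 µm wild-type
IFM disc, and are configuration values, not reproduced constants.

## Aggregate scoring

`tile_image()` splits a field into a 16 × 16 grid — a 36 × 36 µm field
gives 256 tiles of 2.25 × 2.25 µm (the protocol describes these as
"2 × 2 µm"; the grid count is authoritative and the stated tile size is
rounding). Tile sizes use the floor rule with right/bottom remainders
dropped, so tiles partition the analysed region exactly.
`tile_above_threshold_area()` measures per-tile area above an
automatic threshold, either one global threshold from the original
image (default, following the prose description of the protocol) or
re-computed per tile (the behaviour of the published macro loop). The
criterion for calling a tile "with aggregates" is not printed anywhere;
it is therefore an explicit area cutoff, and `calibrate_area_cutoff()`
selects it by maximising agreement with ground truth on synthetic
fields. On fields where each aggregate is confined to one tile the
calibrated cutoff separates perfectly; with randomly placed aggregates,
tiles grazed by an aggregate's edge carry little above-threshold area,
so recall against an any-overlap truth definition is lower — visible in
the stage-3 analysis script and expected.

## Cross-section localisation

`rotational_average()` denoises an end-on disc by averaging 180 copies
rotated in 2° steps about the selection centre (the last copy is the
identity; the set `{2°, …, 360°}` is equivalent to `{0°, …, 358°}`).
Rotation uses bilinear interpolation; pixels outside the selection
circle are excluded (NA) rather than zero-filled, to avoid darkening
the rim, and a half-pixel rim is included so every point of the circle
retains full interpolation support. For a rotationally symmetric
noise-free disc the operation is an identity to well under 1% of the
peak; for uncorrelated noise it attenuates fluctuations at every
radius (the effective averaging count grows with radius). It is
idempotent and linear within interpolation tolerance.

`coverage_filter()` operationalises the disc-selection rule — keep
discs whose Z-disc marker covers the whole phalloidin-stained sarcomere
area — as an overlap fraction with default `min_fraction = 0.9`; the
original criterion is verbal and carries no number.

`diameter_profile()` samples a diameter transect (odd sample count so
the centre is sampled) and normalises to max 1. Profiles are
normalised per disc before any cross-disc comparison; whether averaging
across discs happens before or after normalisation is exposed to the
caller simply by choosing what to average, with per-profile
normalisation the default convention. `classify_profile()` smooths
with a 5-sample moving average (edges use shrinking windows), finds
local maxima by topographic prominence (threshold 0.1 of the
normalised scale), and calls `center_peaked` for a single central peak
(within the central 25% of the diameter), `bimodal` for exactly two
flanking peaks of opposite sign around a central minimum, and
`ambiguous` otherwise — ambiguity is a valid outcome, not an error.
The prominence threshold, central fraction and window are
configuration values; the published description of the two patterns is
qualitative.

## Statistics

Size-category tables are compared with Fisher's exact test for count
data: 2 × 2 tables by the hypergeometric two-sided rule (sum of
probabilities not exceeding the observed table's, with a `1e-7`
relative slack for floating-point ties, the convention of the standard
R implementation); R × C tables with total N ≤ 200 by full enumeration
over fixed margins; larger tables by seeded Monte-Carlo
(`stats::r2dtable`) with the standard error reported. Whether the
original analyses tested the full R × C size-category table or
per-category 2 × 2 collapses is not stated; the full table is the
default here and per-category tables are a caller choice. Intensity
and frequency comparisons use Welch's two-sample *t*-test
(Welch–Satterthwaite degrees of freedom). Both tests are implemented
from their definitions and cross-checked against `stats::fisher.test`
and `stats::t.test` in the test suite; `normalize_to_control()` and
`bifc_signal()` provide the control-genotype and signal-to-background
normalisations those comparisons consume. No multiple-testing
correction is applied, matching the per-comparison reporting
convention of the source analyses (which noted p > 0.001 as not
significant — recorded here as metadata only).

## Isoform classes and expression

`classify_isoform()` is the architecture rule: growing iff the
LIM-domain count is ≥ 2, blocking for 0 or 1. `class_timecourse()`
groups transcripts by class ("similar isoforms" is read as same
domain-architecture class; a finer (gene, class) grouping is available
via `by = "gene_class"`), averages TPM per timepoint, and reports
`log10(TPM + 1)` — the published axis is "log TPM" without base or
pseudocount; log10 with a +1 pseudocount is bounded at 0 and standard
for TPM display, and the choice is recorded in the output metadata.
`onset_time()` recovers a class's switch-on hour as the interpolated
first crossing of half the plateau. Quantification from reads is out
of scope: `read_isoform_tpm()` validates externally produced TPM
tables (transcripts × hours APF).

## The synthetic-data generator

The generator encodes the study conditions and is not tuned per test:

* **Longitudinal fields**: 36 × 36 µm at 0.0703 µm/px (512 × 512 px),
  six myofibrils of 3.4 µm sarcomeres, 1.4 µm disc diameters, band
  thickness 0.35 µm, background 10 and signal 100 intensity units,
  PSF σ = 1 px, Poisson gain 50 photons/unit and Gaussian read noise
  SD 2 (2% of signal). The field size and pixel scale are the
  acquisition geometry of the aggregate-density protocol; sarcomere
  length, disc diameter and intensities are not printed in the source
  and are set to realistic IFM values (IFM sarcomeres run ~3.2–3.6 µm,
  discs ~1.4 µm). Bands are rectangles convolved with the Gaussian
  PSF, so the ground-truth diameter is exact by construction; axes of
  0°/90° only are rendered, keeping truth exact to the pixel (oblique
  measurement is still supported on the analysis side). Aggregates are
  bright filled ellipses (4:3 axes, default 3 µm, 1.5× signal) —
  larger and brighter than any band, as in micrographs, with no
  published shape model to follow.
* **Cross sections**: radial Gaussians — centred at radius 0
  (centre-peaked) or at the ring radius (ring, radial width half the
  ring radius). Default pixel size 0.05 µm/px, Nyquist-level sampling
  for a 63×/1.4 confocal: single-disc cross sections are acquired
  zoomed, and adequate sampling is also what keeps the noise-free
  image band-limited enough for the bilinear rotation identity to hold
  within its 1% tolerance. The ring width at the coarser 0.0703 µm/px
  longitudinal scale would violate that tolerance (≈1.03% of peak) —
  the reason the two defaults differ.
* **Expression**: logistic onsets,
  `TPM(t) = plateau · plogis((t − onset)/4 h)`, growing onset 24 h APF
  and blocking onset 60 h APF (the hours stated for strong
  growing-isoform expression and late blocking-isoform expression),
  sampled at 16–90 h APF (the span of the developmental RNA-seq
  series), plateau 100 TPM, mean-one log-normal noise with σ = 0.2.

Noise is Poisson(signal × gain)/gain plus additive Gaussian — the
standard photon + read decomposition — and both terms can be disabled
for exact tests. All generators are pure functions of (parameters,
seed): identical seeds give bit-identical outputs, and every generated
object has exactly one ground-truth row.

What the generator does **not** emulate: optical effects beyond
Gaussian blur (no Airy rings, no depth attenuation), 3-D structure,
myofibril curvature or disorder, fraying/splitting phenotypes,
auto-fluorescent debris, and any transcript-level structure beyond the
two-class onset model. Passing tests therefore demonstrate that the
measurement code recovers known truth under controlled conditions, not
that segmentation is robust to every real-micrograph pathology.

## Numerical choices and degenerate inputs

* Thresholding a constant image is an error (no threshold exists); a
  constant tile in per-tile aggregate mode scores area 0 with a
  warning.
* Bounding boxes are 0-based and half-open; physical quantities are µm
  or µm², stated in column names.
* Bilinear samples with NA corners (outside the averaging circle)
  renormalise over the valid corners; transect samples with no valid
  support are errors.
* An empty actin mask makes `coverage_filter()` return `FALSE` with a
  warning; a flat profile classifies as `ambiguous`; a flat time-course
  has undefined onset (`NA` with a message).
* Fisher Monte-Carlo p uses the add-one estimator
  `(hits + 1)/(B + 1)`; tied table probabilities are grouped with a
  `1e-7` relative slack.
* `calibrate_area_cutoff()` breaks ties towards the largest cutoff
  (most conservative caller).

## Problem sizes in tests and the acceptance script

The bundled analyses and checks use one 512 × 512 px field per
condition (60 discs each), 101 px cross sections (20 + 20 noisy discs
for the localisation check), 1,000 random 8-bit images for the
threshold oracle, all ~9,800 non-degenerate 2 × 2 tables with N ≤ 20
for the Fisher oracle, 10,000 null simulations for the Welch type-I
check and 10 seeds for onset recovery — sizes at which every stage's
behaviour is already asymptotically stable while the full suite runs
in well under a minute on a laptop.

## Known limitations

* The size-category bounds, the aggregate-positivity cutoff and the
  coverage fraction are free parameters of the original protocol that
  were never printed; results depending on them are comparable within
  a configuration, not across publications.
* Merged near-neighbour discs inflate the large-diameter tail exactly
  as in the original measurement; no splitting is attempted.
* The rotational averager assumes the supplied centre is the disc
  centre; no automatic disc detection in cross sections is provided.
* Absolute aggregate frequencies depend on the calibrated cutoff and
  the truth-overlap convention; only within-study contrasts are
  meaningful.
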