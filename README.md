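# zdiscquant

Quantitative image analysis of sarcomeric **Z-discs** and of the
**Zasp isoform balance** that sets their size, for *Drosophila*
indirect flight muscle (IFM) fluorescence micrographs and
developmental transcript (TPM) tables.

Z-disc diameter determines myofibril diameter. Zasp (Alp/Enigma
family) proteins oligomerize at the Z-disc through LIM–ZM binding:
isoforms with **≥ 2 LIM domains** ("growing" isoforms) recruit further
Zasp molecules and enlarge the disc, isoforms with **0–1 LIM domains**
("blocking" isoforms) are recruited but terminate growth. Shifting the
balance produces small discs (excess blocking) or enlarged discs and
pathological aggregates (excess growing). This package implements the
measurements used to test that model, together with a seeded
synthetic-data generator with exact ground truth so that every stage
can be validated end to end:

* **Segmentation & morphometry** — iterative-intermeans
  ("Default dark") auto-threshold, the smallest fixed point of
  `t = ⌊(μ_{≤t} + μ_{>t})/2⌋` on a 256-bin histogram; 8-connected
  particle analysis with a 0.2 µm² area filter and edge exclusion;
  disc diameter as the bounding-box extent perpendicular to the
  myofibril axis ("Z-disc height"); size-category tables.
* **Aggregate density** — 16 × 16 grid tiling of a 36 × 36 µm field
  (256 tiles), per-tile area above an automatic threshold, and
  aggregate-positive tile counts with a ground-truth-calibrated area
  cutoff.
* **Cross-section localisation** — rotational-average denoising
  (180 copies at 2° steps about the disc centre, bilinear
  interpolation, out-of-circle pixels excluded), diameter intensity
  profiles normalised to max 1, and centre-peaked vs bimodal calls by
  prominence-based peak detection.
* **Statistics** — Fisher's exact test for count data (2 × 2
  hypergeometric; R × C by full enumeration up to N = 200, seeded
  Monte-Carlo beyond), Welch's two-sample *t*-test, normalisation to a
  control genotype, and BiFC signal-to-background ratios.
* **Isoform classes** — growing/blocking classification from the
  LIM-domain count, class-wise mean TPM time-courses reported as
  `log10(TPM + 1)`, and half-plateau onset recovery.

## Worked example

The numbered scripts under `analysis/` run the whole study on
synthetic data (`01` simulates; `02`–`05` measure). For instance,
segmenting a simulated control field against a mutant whose discs are
scaled to 0.7× (the small-disc phenotype of LIM-truncating mutants):

```sh
Rscript analysis/01_simulate_fields.R
Rscript analysis/02_zdisc_morphometry.R
```

prints

```
control: 60 discs, mean diameter 1.406 um (threshold 51.0)
mutant: 60 discs, mean diameter 0.984 um (threshold 50.0)
  category control mutant
1     <0.5       0      0
2  [0.5,1)       0     60
3  [1,1.5)      60      0
4  [1.5,2)       0      0
5      >=2       0      0
size categories, control vs mutant: Fisher p = 2.07e-35
relative intensity: control 1.00, mutant 0.986; Welch t = 28.20, p = 6.87e-54
```

i.e. all 60 control discs fall in the 1.0–1.5 µm category (truth:
1.4 µm) and all 60 mutant discs in 0.5–1.0 µm (truth: 0.98 µm), a
separation the size-category Fisher test calls at p ≈ 2 × 10⁻³⁵; the
intensity comparison is control-normalised, so the control group sits
at 1.00 by construction. Stages `03`–`05` score aggregate tiles
(3/256 truth-positive tiles recovered at the calibrated cutoff),
classify cross-section discs (20/20 centre-peaked and 20/20 ring discs
called correctly after rotational averaging) and recover expression
onsets (growing 24.3 h vs blocking 58.6 h APF against generator truth
24 h / 60 h).

Equivalent programmatic use:

```r
library(zdiscquant)
g <- make_longitudinal_image(longitudinal_params(noise = noise_params(seed = 1)))
mask <- auto_threshold_default_dark(g$zdisc)
parts <- find_particles(mask, g$zdisc)          # area >= 0.2 um^2, no edge discs
summary(measure_diameter(parts))                # disc diameters, um
categorize_sizes(measure_diameter(parts))       # size-category counts
```

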