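---
title: "Methods: per-cell membrane scoring of brightfield HER2 IHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell membrane scoring of brightfield HER2 IHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2quant)
```

## The problem

HER2 status in breast cancer is routinely read from DAB
immunohistochemistry as a four-tier score: 0 and 1+ are negative, 3+
(strong, circumferentially complete membrane staining in a sufficient
fraction of tumour cells) indicates eligibility for anti-HER2 therapy,
and 2+ ("equivocal") reflexes to FISH for gene-amplification testing.
The visual read is notoriously rater-dependent precisely in the
equivocal band. `her2quant` implements a digital pipeline that makes the
read explicit: it measures, per cell, the optical density and
circumferential completeness of membrane DAB staining, classifies each
cell 0/1+/2+/3+, and aggregates region scores, together with the
statistics used to compare a digital read against a human one.

## Pipeline

### Stain separation

A brightfield RGB pixel is converted channel-wise to optical density
(OD), $od_c = -\log_{10}(\max(I_c, 1) / I_0)$ with white level $I_0$
(default 255, or the per-image 99th percentile). By the Beer–Lambert
relation ODs of co-localized chromogens add, so the pixel OD vector is
modelled as $od = a\,V_{DAB} + b\,V_{HEM} + r\,V_{res}$ and solved per
pixel for the concentrations $(a, b, r)$. The default stain basis is the
published H-DAB pair of Ruifrok & Johnston, completed by the normalized
cross product as residual axis; both stain vectors are configurable.
Negative unmixed concentrations are clamped to zero, the standard
practice.

A note on dynamic range: with 8-bit input the quantization error in OD
grows as the pixel value falls ($\delta od \approx 0.217/I$ per count at
intensity $I$). Joint stain concentrations up to 0.9 OD keep every
channel above ~18 counts and round-trip through 8-bit RGB to within 0.02
concentration units; at joint concentrations near 2 the synthesized
pixel drops below 2 counts and no unmixing can recover the input. The
validation grid therefore covers $[0, 0.9]^2$, which spans the staining
range of the generator and of routine DAB/hematoxylin tissue; the
analytic (unquantized) round trip is verified to $10^{-4}$ on
$[0, 2]^2$.

### Nucleus segmentation

Cells are anchored on their hematoxylin-stained nuclei: Gaussian
smoothing (sigma 1.5 px) of the hematoxylin OD channel, Otsu threshold,
hole filling, morphological opening (radius 1), optional
distance-transform watershed to split touching nuclei, and a minimum
area filter (30 px). This is a conventional counterstain pipeline built
on EBImage; every step is parameterized under the `nuclei:` config
section. Coordinates are 0-based (row, col). Nuclei touching the image
border are kept — clipping is the job of the ROI mask.

### Membrane segmentation: intensity-based spot linking

In brightfield, a stained membrane is a dark curve — a connected pixel
curve of local intensity minima in the DAB image. The pipeline
partitions the image into adjacent spots whose shared borders trace
those mid-lines:

1. **Spot partition.** The negated DAB OD image is smoothed (Gaussian
   sigma 1.0 px, suppressing single-pixel false minima) and every pixel
   is assigned by steepest ascent to the basin of its regional maximum —
   a marker-free watershed in which membranes are the ridge lines
   between basins. Ties on plateaus are broken by (row, col)
   lexicographic order, making the partition deterministic; a constant
   image is a single spot. Border pixels are taken per 4-adjacent
   cross-label pixel pair as the higher-OD member, so the border curve
   sits on the absorbance ridge and is about one pixel wide.
2. **Merging.** False curves arise at minima with no immunoreaction.
   Iteratively to a fixed point: spots smaller than `min_spot_area`
   (25 px) merge into the neighbour with the longest shared dissolvable
   border; dissolvable borders shorter than `min_border_length` (5 px)
   are dissolved. A border is *dissolvable* only while the median DAB OD
   along it is below `protect_min_od` (0.1): borders that trace real
   signal along most of their length must never be merged away, while
   the median (rather than the mean) keeps a false curve dissolvable
   when it merely terminates on a membrane. A second guard keeps any
   short border whose two spots both carry membrane evidence on other
   borders — dissolving such an edge (e.g. across the small gap of a
   nearly complete ring) would fuse two membrane-bounded regions and
   erase the real boundary between them. Both guards were added after
   the plain area/length rules demonstrably destroyed complete-ring
   boundaries on ground-truthed fixtures.
3. **Merging over nuclei.** A membrane mid-line cannot cross a nucleus;
   border edges with more than `over_nucleus_threshold` (0.5) of their
   pixels inside the nucleus mask are dissolved.
4. **Skeleton extraction.** Surviving border pixels are collected,
   pixels inside the nucleus mask are subtracted, pixels whose own DAB
   OD falls below `min_mean_od` (0.1) are dropped (border stretches with
   no signal are false curves regardless of the spots they separate),
   and the remainder is split into 8-connected segments. Segments
   shorter than `min_segment_length` (10 px) or with mean DAB OD below
   `min_mean_od` are disclosed. The mean DAB OD along each retained
   segment — measured on the raw, unsmoothed OD channel — is the
   intensity used for scoring.

The merging order (area before border length, repeated to a fixed
point) and all thresholds are choices of this implementation,
calibrated once on the synthetic fixtures and exposed in the
`membrane:` config section. On images up to 20×20 the partition is
verified against a brute-force per-pixel steepest-ascent oracle.

### Per-cell scoring

Skeleton pixels are attributed to the nearest nucleus (Voronoi regions
of the nucleus label map) within `max_radius_px` (25 px) of the nucleus
boundary. Per cell, the pipeline records the mean DAB OD of its
assigned skeleton, the assigned pixel count (membrane mask area), and
*completeness*: the fraction of 24 equal angular sectors around the
nucleus centroid containing at least one assigned skeleton pixel. An
annular-band intersection would measure the same quantity; angular
coverage was chosen because it is insensitive to the exact membrane
radius.

Classification uses intensity measured in OD units with thresholds
$t_1 = 0.15$, $t_2 = 0.40$, $t_3 = 0.70$ and a completeness cutoff of
0.8 (all configurable; intensity boundaries are left-closed):

| class | rule |
|-------|------|
| 0     | mean OD < $t_1$ |
| 1+    | faint ($t_1 \le$ OD $< t_2$), or stronger but incomplete |
| 2+    | $t_2 \le$ OD $< t_3$ and completeness $\ge$ 0.8 |
| 3+    | OD $\ge t_3$ and completeness $\ge$ 0.8 |

Strong-but-incomplete cells deliberately fall to 1+: circumferential
staining is constitutive of 2+/3+ in the clinical definition. The OD
thresholds are anchored to the synthetic generator's class design
(below); on real material they would be calibrated against control
tissue.

Region scores: the class proportions $p_0..p_3$; the **Field Score**
(3 if $p_3 >$ 30%, else 2 if $p_{\ge 2} \ge$ 10%, else 1 if
$p_{\ge 1} \ge$ 10%, else 0 — the >30% guideline variant is the
default, the 10% variant is a config switch, and neither is asserted to
be the only correct reading of the guidelines); the **H-Score**
$100(p_1 + 2p_2 + 3p_3) \in [0, 300]$; and **LO-CMA**, the total
membrane mask area per class (pixels, µm² when the pixel size is
known). Cores pool the cells of their 1–4 ROIs (cell-weighted) for the
core score; taking the maximum ROI score instead is a config option. A
cell belongs to an ROI iff its nucleus centroid is inside the ROI
polygon (even-odd rule, 0-based (row, col) vertices).

## Agreement statistics

For two ordinal raters over the four classes: Cohen's kappa
$\kappa = (p_o - p_e)/(1 - p_e)$; weighted kappa
$\kappa_w = 1 - \sum(1-w_{ij})p_{ij} / \sum(1-w_{ij})e_{ij}$ with the
quadratic weights $w_{ij} = 1 - (i-j)^2/9$, which print as 1 / 0.89 /
0.56 / 0 for 0-, 1-, 2- and 3-step disagreements; with identity weights
$\kappa_w$ reduces exactly to $\kappa$, which the suite verifies to
$10^{-12}$. Kappa strength is labelled on the Landis–Koch scale.
Confidence intervals default to a seeded nonparametric bootstrap over
cases (2000 percentile resamples); the Fleiss–Cohen asymptotic interval
is an option. Spearman's rho is the Pearson correlation of mid-ranks,
with a t-approximation p-value and a Fisher-z interval
(SE $1/\sqrt{n-3}$). Two-group feature comparison reports per-group
mean, SD, min, max and a two-sided p-value from Welch's t test (the
default — the emulated comparison table reports means and SDs,
suggesting a parametric test) or the Mann–Whitney test. Proportional
"% ratio" features are stored as fractions in [0, 1].

## The synthetic generator

`generate_tile()` emulates one TMA-core field: non-overlapping cells,
each a hematoxylin nucleus disk (radius 7 px, OD 0.7) with a DAB
membrane arc (radius 15 px, half-width 1.2 px) whose OD and angular
completeness follow the class design

| class | membrane OD | completeness |
|-------|-------------|--------------|
| 0     | 0.05        | 0.20 |
| 1+    | 0.25        | 0.50 |
| 2+    | 0.55        | 0.90 |
| 3+    | 0.95        | 0.95 |

RGB is synthesized through the Beer–Lambert relation from the same
stain vectors, with Gaussian noise added in OD space (default sigma
0.03) and 8-bit quantization. Class counts are one multinomial draw
recorded in the ground truth; placement is rejection sampling with a
minimum rim gap of 4 px. Everything is deterministic under the seed.
The default 512×512 px tile stands in for a TMA-core field; full 2 mm
cores are out of test scope. Companion generators produce paired score
vectors with a known population kappa (closed form from the joint
distribution) and small two-group case tables whose group moments are
matched to a published equivocal-cohort comparison; the `"null"` mode
draws both groups from one untruncated Gaussian and is the calibration
mode for type-I-error testing, while the effect mode truncates draws at
zero (ratios capped at 1) for realism.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real tissue: confluent epithelium with shared
membranes (cells here are isolated rings; a confluent mode is a
stretch goal), nuclear pleomorphism and chromatin texture, stromal and
immune cells, uneven illumination, scanner colour response, and
out-of-focus blur. Recovery targets (nucleus precision/recall 1.0,
≥95% of stained membrane pixels within one pixel of the recovered
skeleton, class proportions within ±0.05, ≥95% field-score agreement at
noise sigma 0.03) are defined on this idealized geometry.

## Numerical choices and degenerate inputs

* Flooding ties are broken by (row, col) lexicographic order; a
  constant image yields one spot and no borders.
* Membrane recovery is scored against ground-truth membrane pixels with
  drawn OD ≥ 0.4 (the 2+/3+ design classes): fainter stubs sit below
  the pipeline's own `min_mean_od` retention threshold by design.
  "Within one pixel" is the 8-neighbourhood (Chebyshev distance ≤ 1).
* An all-zero hematoxylin channel yields zero nuclei (not an error);
  scoring an ROI containing no cells records a per-ROI error entry and
  the run continues.
* Kappa is flagged undefined when the expected agreement is 1 (a single
  category on both margins); Spearman's rho when either vector is
  constant; a constant feature in the group comparison is flagged
  degenerate with p = 1.
* All randomized procedures (bootstrap, generators) take explicit
  seeds; the bootstrap default seed is 20130930. Repeated runs with the
  same seed and config are byte-identical.

## Problem sizes of the shipped validation

The validation suite and the acceptance script use: 50 tiles of
512×512 px with 80 cells each for end-to-end recovery; a 64×64 grid of
concentration pairs on $[0, 0.9]^2$ for the deconvolution round trip;
1000 random 4×4 tables for the kappa identity; 1000 null cohorts (9 vs
6 cases) for type-I calibration; 200 simulated rater pairs of 100 cases
with 2000 bootstrap resamples each for CI coverage. These sizes give
stable estimates (binomial SE ≤ 0.7 pp on the calibration fraction)
while keeping a full run in a few minutes on one CPU.

## Known limitations

* The membrane tracer assumes membranes are ridges of the DAB OD
  channel after smoothing; membranes thinner than a pixel or heavily
  blurred will shift the traced mid-line.
* Completeness by angular coverage assumes a star-convex membrane
  around the nucleus centroid; grossly non-convex cells would need the
  annular-band variant.
* Core aggregation by cell pooling weights large ROIs more than the
  max-ROI rule used in some reading protocols; both are provided.
* The per-cell intensity is the mean OD of assigned skeleton pixels;
  chromogen saturation at very high OD compresses differences above
  ~1.5 OD (see the dynamic-range note).
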