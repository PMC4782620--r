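---
title: "Detecting microcalcification clusters: model, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microcalcification clusters: model, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdetect)
```

## The detection problem

A microcalcification cluster (MC) is a group of four or more tiny calcium
deposits — individually 0.05–1 mm across — confined to roughly a
10 × 10 mm² region of a mammogram. Clusters matter clinically (they are an
early sign of breast cancer) and are hard to find: each deposit is a small
bright spot whose contrast against fibroglandular tissue is low, and bright
curvilinear structures (mammary glands, vessels) mimic them locally.

`mcdetect` decomposes the problem into four stages, each with a narrow,
testable contract: **enhance** small bright structures regardless of
orientation, **suppress** the curvilinear mimics by scale, **segment**
candidates, and apply the **spatial clustering rule** that defines an MC.

## Stage models and assumptions

### Multi-structuring-element top-hat

The top-hat transform `f − (f ∘ b)` keeps exactly the bright structures that
cannot contain the structuring element `b`. A single SE cannot serve: a line
SE at one orientation also keeps every elongated structure at the *other*
orientations. The enhancement therefore probes with a bank of eight line SEs
(length 15 px, orientations `k·180°/8`) and subtracts the *pixelwise maximum*
of the openings:

`E = f − max_i (f ∘ b_i)`.

A structure that fits *any* line of the bank survives the maximum and
vanishes from `E`; only compact blobs — smaller than 15 px in every
orientation — remain. Equivalently `E` is the pixelwise *minimum* of the
eight single-SE top-hats, a dual identity the tests assert exactly. At
0.05 mm/px the 15 px footprint spans 0.75 mm, so anything larger than
0.75 × 0.75 mm is removed; this is the scale that separates
"microcalcification-sized" from "mass-sized".

Line SEs are rasterized by stepping along the dominant axis and mirroring
through the centre pixel, so every SE is point-symmetric, contains its
anchor, and has exactly `footprint_px` pixels at every orientation.

*Border policy.* Openings use reflect padding by default (replicate and
constant are available). The image is padded by twice the SE half-width so
the result equals the true opening of the symmetrically extended image —
verified pixel-exactly against a per-pixel sliding-window oracle. One
consequence worth knowing: opening is idempotent exactly in the interior,
but within the border band oblique SEs may differ on a second application,
because reflection does not commute with non-axis-aligned SEs. This is a
property of *any* padding-based border rule (scipy's `grey_opening` behaves
the same way), not of this implementation.

### Wavelet subband zeroing

After enhancement, thin gland and vessel cross-sections (1–2 px) survive
alongside true spots (the top-hat passes both). The denoiser separates them
by scale: a four-level separable symlet-2 decomposition, zeroing (a) the
coarsest approximation — removing residual smooth background and giving the
mid-band zero mean — and (b) the finest detail triplet, which carries pixel
noise and most of the energy of 1–2 px wide ridges, then reconstructing.
Symlet-2 is used for its near-symmetry and two vanishing moments; the
half-point symmetric extension pairs naturally with near-symmetric filters.

The transform is implemented in the package (decomposition keeps the
slightly redundant `floor((n + 3)/2)` coefficients per axis; the inverse is
cropped to the recorded shape at every level), which buys two exact
guarantees the tests assert: perfect reconstruction to < 1e−8 for odd and
even sides in all extension modes, and bit-identical agreement of unselected
subbands under zeroing. Coefficients were cross-checked against an
independent reference implementation (PyWavelets) and a frozen fixture from
that check lives in the test suite.

The selector is fully configurable (`subband_selector`): any subset of
detail levels plus the approximation. Zeroing the two finest triplets was
measured during development and rejected as the default: it suppresses
ridges further but costs small-spot response disproportionately, because
0.2–0.3 mm spots carry substantial energy at the 2–4 px scale.

### Segmentation

The default threshold is **fixed at 0.14** on the denoised scale. Two
alternatives were considered and remain available:

* a *quantile* rule marks a fixed fraction of pixels foreground, which by
  construction fires on cluster-free images — scattered suprathreshold
  specks across 200 px blocks then satisfy the cluster rule, so a low FP
  rate on negatives is impossible under it;
* a *k-sigma* rule adapts to the noise floor but not to the gland-residue
  ceiling, which is what actually limits the threshold from below.

The fixed default was calibrated from the measured stage responses on
default phantoms: after enhancement + denoising, gland-like ridge residue
has 99th percentile ≈ 0.09–0.11 (occasional peaks higher), while spot
responses begin around 0.16; 0.14 sits between the two populations. Otsu
and quantile thresholds are kept for exploratory work, and
`threshold_sweep()` traces the sensitivity/FP trade-off over a suite. An
optional minimum-component-size filter exists but defaults to off.

### Cluster rule

Blocks of 200 × 200 px (10 × 10 mm at 0.05 mm/px) step by 100 px; a block
with more than three component centroids is labeled an MC. Membership is by
centroid inside the half-open block box — unambiguous at block boundaries.
When the pixel spacing differs from 0.05 mm/px, the block side is derived
from the physical 10 mm rule (`round(10 / spacing)` px) and the step stays
at half a block. Overlapping block hits sharing at least one member
component are merged (connected components of the block-sharing graph) into
single cluster detections; merging is idempotent.

### Scoring

Cluster-level true-positive rate and false positives per image. The default
match rule (`center_in_box`) accepts a detection–truth pair if either box's
centre lies in the other box — tolerant of the block grid's 100 px
quantization; IoU matching is available for stricter studies. Each true
cluster is credited once, to its highest-IoU matching detection; one
detection may legitimately claim several truths (a merged box spanning two
clusters detects both); detections matching no truth are false positives.
With zero truths the TPR is reported as `NA`, never as 100%.

## The phantom generator

Clinical mammograms of this kind are not publicly available, so the package
ships a seeded generator (`phantom_spec`/`generate_phantom`) that emulates
the features the method is built around, with exact ground truth:

* **background**: a smooth low-contrast field (base 0.3, amplitude 0.1,
  ~64 px correlation length) standing in for large-scale breast density;
* **spots**: isotropic Gaussians truncated at 3σ (σ = diameter/4),
  diameters 0.2–0.5 mm within the 0.05–1 mm clinical span, contrast
  0.2–0.4 — the positive images model *reported* clusters, i.e.
  calcifications conspicuous enough for a radiologist to flag against
  glandular texture of contrast up to 0.25. A square-profile option exists
  for exact-arithmetic tests;
* **clusters**: 4–10 spots scattered as a truncated Gaussian (σ = extent/5)
  inside a 10 mm extent box. The Gaussian reflects the concentrated
  appearance of clinical clusters, whose quoted 10 × 10 mm² area is an
  upper bound; uniform scatter over the full box remains available and is
  the harder condition (it spreads 4-spot clusters so thin that no aligned
  block may contain four centroids);
* **curvilinear confounders**: quadratic Bezier ridges 1–2 px wide with
  ±20% per-pixel multiplicative jitter — gland/vessel cross-sections
  *narrower than the SE footprint*, so the top-hat passes them and the
  wavelet stage must do the suppression, mirroring the premise that a
  microcalcification is about twice the size of a gland cross-section;
* **acquisition PSF**: Gaussian blur σ = 0.7 px applied to the noiseless
  scene. Real digitized mammograms are band-limited; without the PSF,
  hard-rasterized curved ridges carry single-pixel staircase corners that
  are indistinguishable *in principle* from true 1 px spots — an aliasing
  artifact of drawing, not a feature of tissue;
* **noise**: additive Gaussian, σ = 0.01 on the [0, 1] scale.

Each structural layer draws from its own RNG stream derived from the master
seed, so layers can be varied independently. The benchmark suite
(`default_benchmark_suite`) makes `round(0.1·n)` images positive (at least
one) with 1–2 clusters each and gives every image 2–6 confounder ridges —
the composition of a screening set in which positives are the rare case.

**What the phantom does not model**: anatomical texture (ductal structure,
Cooper's ligaments), X-ray scatter and detector physics, benign-vs-malignant
calcification morphology, pectoral muscle and skin-line. Passing the suite
therefore demonstrates that the pipeline implements its stage contracts and
separates its two structure classes at realistic scales and contrasts — not
clinical-grade performance.

## Numerical choices and test problem sizes

* Working scale is float [0, 1]; readers divide integer images by their type
  maximum. All thresholds are defined on this scale, decoupled from bit
  depth.
* Pixel coordinates are 0-based (row, col), origin top-left; boxes are
  half-open — one convention, asserted everywhere.
* The wavelet inverse crops to recorded shapes, so odd dimensions
  reconstruct exactly; no clipping of negatives before thresholding.
* Component labels are deterministic: raster-scan order of each component's
  first pixel (ties impossible). Default connectivity is 8, the common
  choice for blob-like bright spots.
* Oracle tests run on arrays up to 32 × 32 (exact equality); the end-to-end
  benchmark uses thirty 1024 × 1024 phantoms (51 × 51 mm at 0.05 mm/px), a
  field size that holds the full block grid and several confounders while
  keeping a complete suite run in a couple of minutes on one CPU.
  Full-size (4740 × 3540) clinical frames process in a few minutes each
  through the same code path.

## Known limitations

* **Grid quantization**: a cluster whose surviving component centroids span
  more than one block step (100 px = 5 mm) can straddle all aligned blocks
  so that none holds four centroids — a miss intrinsic to the fixed
  block-grid rule rather than to this implementation. The merge step cannot
  recover what no single block detected.
* **Contrast floor**: spots whose denoised response falls below the fixed
  threshold are lost; for clusters of exactly four spots a single
  sub-threshold spot loses the whole cluster. This is the main miss mode at
  the dim end of the spot-amplitude range.
* **Equal-contrast ambiguity**: subband zeroing attenuates 1–2 px ridges
  about 1.5–2× more than 4–10 px blobs. Ridge segments whose contrast
  exceeds spot contrast by more than that factor will cross the threshold;
  interlacing high-contrast linear structures remain the dominant
  false-positive source, consistent with the method's design premises.
* **No candidate classification**: the pipeline stops at the counting rule;
  no per-component shape or texture features are used to prune false
  positives.
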