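---
title: "Methods: latent-fingerprint processing, feature extraction and core-anchored matching"
author: "lfpmatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent-fingerprint processing, feature extraction and core-anchored matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpmatch)
```

## The problem

A latent fingerprint (LFP) is the invisible sweat/sebum residue a finger
leaves on a surface. Once developed — for instance by dusting with a
fluorescent powder and photographing under 365 nm UV light — it becomes a
ridge image that must be compared against a reference print, typically an
inked rolled impression on a fingerprint card. `lfpmatch` implements the
digital half of that workflow: preprocessing the photographs into binary
ridge models, extracting Galton–Henry feature points (minutiae), and
scoring the developed print against the control with a core-anchored
similarity statistic. Because real case photographs are rarely shareable,
the package also ships a seeded synthetic generator that produces paired
control/sample images with exact ground truth, so every pipeline stage is
testable end to end.

Conventions used throughout: images are numeric matrices with the origin
at the top-left, `x` the column index and `y` the row index, both
1-based; binary images use 1 = ridge once polarity has been asserted;
orientations are ridge directions modulo $\pi$.

## Preprocessing: grayscale, normalization, binarization

The input photograph passes through three phases.

1. **Grayscale.** Rec.601 luma, $0.299R + 0.587G + 0.114B$, rounded.
   The standard colorimetric choice for this kind of imagery; an
   achromatic input maps to its own channel value exactly.
2. **Normalization.** The classic mean/variance normalization: a pixel
   $I$ maps to $m_0 + \sqrt{v_0/v}\,(I - m)$ with $(m, v)$ the image
   mean and population variance and targets $m_0 = 128$, $v_0 = 2000$ by
   default. This removes lighting and exposure differences between the
   two photographs before any thresholding. Variance is the population
   variance (divide by $N$), the usual convention for image moments. A
   constant image raises a degenerate-image error rather than silently
   passing garbage downstream.
3. **Binarization.** Pixels are classified into 0/1 by intensity
   threshold. Three methods are available: global Otsu (the threshold
   maximizing between-class variance over all 256 candidate levels of
   the 8-bit histogram), a fixed threshold, and a block-wise adaptive
   variant (per-tile Otsu on 16 px tiles, falling back to the global
   threshold in near-constant tiles). **The pipeline default is the
   adaptive variant**: on degraded prints, smudges and pressure or
   illumination non-uniformity move local ridge intensity across any
   single global threshold and fragment the ridges, which costs
   extraction precision; the per-tile threshold tracks local contrast
   instead. Global Otsu remains a config switch
   (`imgproc.binarize_method = "otsu"`) and is what the Otsu
   oracle-equivalence test exercises.

Ridge polarity is then asserted per modality: inked controls carry dark
ridges on a light card, powder-developed prints fluoresce so their
ridges are the brighter class. `ensure_ridge_polarity()` compares class
mean intensities and flips if needed; it is idempotent.

## Segmentation, thinning and feature extraction

**Segmentation.** Ridge-bearing image regions carry strong band-pass
energy near the ridge frequency. We high-pass the normalized image
(subtract a $\sigma=6$ Gaussian blur), square, and smooth
($\sigma=4$); pixels above a fixed fraction of the 95th-percentile
energy form the foreground mask, after hole/island cleanup and a small
erosion that pulls the mask boundary back to where energy support really
ends (smoothing bleeds energy a few pixels into dead regions). This
pixel-resolution mask excludes blank background, occluded patches and
heavy smudges; minutiae within a small margin (default 3 px) of the mask
boundary are discarded as unreliable, as are minutiae within 12 px of
the image border.

**Thinning.** Zhang–Suen iterative thinning reduces the ridge mask to a
one-pixel skeleton, preserving 8-connected topology. A short pruning
pass (branches ≤ 3 px, well below any genuine spur) removes the tiny
end-cap forks thinning leaves at rounded ridge endings; without it a
termination frequently reads as a termination-plus-bifurcation pair.

**Crossing-number typing.** At each skeleton pixel,
$CN = \tfrac12\sum_k |p_k - p_{k+1}|$ over the cyclic 8-neighborhood.
$CN=1$ is a ridge ending (termination), $CN=3$ a bifurcation, $CN\ge4$ a
trifurcation/crossover candidate. A graph walk over the skeleton then
re-labels compound Galton–Henry structures: two bifurcations joined by
both arms of a short cycle become an *eye* (enclosure); a short branch
ending free is a *spur*; an isolated short fragment is a *short ridge*;
two bifurcations fused across a very short bridge with four long arms
are a *crossover*. The length scales (`L_eye = 30`, `L_spur = 8`,
`L_short = 15` px) assume the default 9 px ridge period and are
config-exposed. Level-3 sweat pores are detected on the un-thinned mask
as background blobs fully enclosed by ridge with area in $[1, 20]$ px²;
pores are reference data and excluded from the match matrix by default.

**Core detection.** The orientation field is estimated block-wise
(16 px) from the structure tensor of central-difference gradients; ridge
orientation is perpendicular to the dominant gradient direction, and
coherence is the normalized eigenvalue spread. After smoothing doubled
angles, singular points are found by the Poincaré index — the summed
wrapped orientation change around a block's 8-neighborhood, $+1$ at a
whorl core, $+1/2$ at a loop core, $-1/2$ at a delta. Two numerical
details matter: the circuit must follow the positive orientation of the
`atan2` convention (a reversed circuit negates every index), and an
8-sample ring is ambiguous (steps of exactly $\pm\pi/2$) when a whorl
core sits adjacent to a lattice node, so candidate singularities are
confirmed and classified on a denser 16-sample interpolated ring. The
retained core is refined to sub-block accuracy by re-estimating the
field on an 8 px lattice around the coarse detection and fitting the
analytic singularity model — near a singularity of index $s/2$ the
doubled orientation angle follows $2\theta(p) = s\,\arg(p - c) + \beta$
— by minimizing the circular residual over the center $c$ (both the
loop and the whorl winding models are tried, because a noisy whorl often
presents as a split pair of half-index cores whose far field still winds
by $2\pi$). Sub-block core accuracy matters because the match statistic
measures distances from the core. When several singularities
survive, the one with the largest |index| (ties: nearest the coherence
centroid) anchors the match; when none does, the minutiae centroid is
used and flagged.

## The similarity score

Feature-point coordinates become $m \times 2$ matrices: $Z$ for the
sample, $X$ for the control, rows ordered canonically by polar angle
then radius about each image's core $(a, b)$ so the matrix does not
depend on extraction order. Points within $r_{\min} = 3$ px of the core
are excluded to avoid near-singular ratios. For corresponding rows the
score compares squared core-centered Euclidean distances,

$$\rho_i \;=\; \frac{(z_{i1}-a_Z)^2 + (z_{i2}-b_Z)^2}
                   {(x_{i1}-a_X)^2 + (x_{i2}-b_X)^2},
\qquad
P \;=\; \frac1m \sum_{i=1}^m \frac{1}{\lvert \rho_i - 1\rvert + 1},$$

reported also as a percentage $100P$. Each term lies in $(0,1]$; $P = 1$
exactly iff every distance ratio is 1 — in particular whenever the two
matrices and cores coincide — and larger $P$ means closer resemblance.
The score is invariant to rotating the sample about its core and to
translating either image together with its core, and it is deliberately
asymmetric: the direction sample→control is fixed. Published
descriptions of this family of scores are frequently typeset beyond
recovery; the form above is this package's own reconstruction, chosen to
(a) use exactly the named core-anchored Euclidean distances, (b) attain
1 exactly at a perfect match, (c) stay bounded in $(0,1]$, and (d)
produce percentage-scale scores. Measuring each matrix's distances from
its *own* core (rather than one shared anchor) is likewise an
interpretation; it is what makes independently photographed images
comparable.

**Correspondence.** Row $i$ of $Z$ must mean the same physical point as
row $i$ of $X$. Pairing happens in core-centered polar coordinates:
candidates must satisfy $|\Delta r| \le$ `tol_r` (8 px ≈ one ridge
period) and $|\Delta\varphi| \le$ `tol_phi` (0.4 rad, comfortably above
the ±0.1 rad capture rotation the generator models plus core-detection
noise); accepted pairs are chosen greedily by ascending polar distance,
which makes each accepted pair a mutual nearest neighbor among the
points still unpaired, deterministically. Unmatched points are reported.

**Unpaired-point penalty.** By default unpaired points enter the score
as zero-valued terms (`matching.penalize_unpaired = TRUE`). This is a
deliberate design choice: without the penalty, $P$ is the mean of terms
over pairs that already passed the $|\Delta r|$ gate, so even an
impostor's surviving pairs produce terms close to 1 and the score barely
separates genuine from impostor prints, while the *number* of alignable
points — far higher for genuine pairs — carries the real
information. With the penalty the self-match anchor is
untouched (a self-match has no unpaired points, $P = 1$ exactly) and
genuine/impostor distributions separate cleanly. The mean-of-terms
variant remains available by config.

## The synthetic generator

The generator's role is to emulate the *study conditions* of a
powder-development experiment: an inked control and a
fluorescent-powder-developed sample of the same finger, on one of five
substrate archetypes, with known ground truth.

* **Orientation field** — zero-pole construction: a whorl is a single
  index $+1$ singularity (concentric flow), a loop is a $+1/2$ core
  paired with a $-1/2$ delta, an arch is a smooth singularity-free arc
  field.
* **Ridge pattern** — seeded white noise filtered repeatedly (5 passes)
  with Gabor kernels tuned to the local orientation (12 quantized bins,
  per-pixel blending) and to frequency `1/ridge_period`; the pattern
  locks to the requested period (radial-spectrum peak within a few
  percent of $1/9$ px⁻¹).
* **Skeleton and ground truth** — the rendered mask is thinned, cleaned
  (short-branch pruning, minimum component size), and *edited* to plant
  minutiae: a cut removes a 13 px run of ridge, creating two
  terminations; a bridge draws a branch to the neighboring ridge,
  creating two bifurcations (or a bifurcation plus a termination if it
  ends free); spurs are short free branches; pores are punched holes
  with locally widened ridge so the hole stays enclosed. The definitive
  ridge mask is the dilation (width 3 on the 9 px period — powder
  adheres to ridge crests, and the resulting 6 px valleys cannot be
  bridged by rendering blur) of this edited skeleton, so the skeleton's
  crossing-number census *is* the ground truth, planted edits flagged.
  Spontaneous minutiae created by the noise-seeded rendering are genuine
  features of the pattern and are part of the truth.
* **Appearance** — control: ridges at ≈ 55 on a 225 card, σ = 0.8 ink
  blur, low-frequency pressure field, sensor noise. Sample: a rigid
  transform (rotation ± 0.1 rad, translation ± 8 px, bilinear
  anti-aliased resampling), polarity inverted (ridges ≈ 190 × contrast
  on a ≈ 45 substrate), per-substrate background texture (paper
  blotches, metal streaks, plastic sheen, glass noise, wood grain),
  powder granularity (sd 22), optional smudge patches, and occlusion
  discs (radius 10–18 px) placed until the requested area fraction is
  covered. Defaults: 192 px images (~21 ridge periods, a realistic
  core-region crop), 12 planted minutiae, paper substrate, smudge
  probability 0.1, texture amplitude 0.2, contrast 0.9, occlusion 0.1.
* **Determinism** — one seed drives everything through fixed
  per-stage substreams; a fixed seed reproduces the pair bit for bit.

What the generator does *not* model: fluorescence optics and UV
illumination physics, powder-adhesion chemistry, skin elasticity
(non-rigid distortion), wet/dry ridge width variation, sensor demosaic
artifacts. Passing tests on synthetic pairs therefore demonstrate the
pipeline's correctness and its robustness to the modelled degradations —
not performance on real casework imagery.

## Evaluation conventions

Extraction quality is scored by greedy nearest matching at 5 px
tolerance, type labels not compared, both sets restricted to the image
interior (16 px margin). For degraded samples, a 4 px zone around the
occlusion discs is excluded from both sets: a truth point the occluder
erased is unrecoverable in principle, and a ridge ending the occluder
manufactured is a genuine feature of the visible image — counting either
against the extractor would measure the occluder, not the extraction.
`generate_pair()` flags each truth point as visible/occluded for the
same reason.

Study sizes (25 seeds for recovery studies, 50 genuine/impostor pairs,
25 seeds per occlusion level) keep the full suite comfortably fast on a
single CPU while leaving the binomial sign test with plenty of power.

## Numerical and degenerate-input choices

* Constant images error out (`lfp_degenerate_image`) in normalization,
  binarization and orientation estimation instead of returning
  all-background, so silent failures cannot reach the scoring stage.
* Otsu ties resolve toward the smallest maximizing threshold;
  non-8-bit inputs are quantized onto 256 levels between their min and
  max first.
* The canonical feature-matrix ordering breaks ties by radius then
  x/y; duplicate `(x, y, type)` records collapse.
* A feature point exactly on a core raises a degenerate-geometry error
  (the distance ratio would be 0/…); `r_min` keeps near-core points out.
* All randomness is seeded; derived stage seeds stay far below $2^{31}$.

## Known limitations

* Rotation between sample and control must stay within `tol_phi`
  (default 0.4 rad ≈ 23°); there is no global rotation search, by
  design (no affine/TPS registration beyond core anchoring).
* Arches have no core; matching then falls back to the minutiae
  centroid, which is less stable between the two sides.
* The score's discriminative power depends on a consistent core; a
  badly occluded core region degrades genuine scores (visible in the
  occlusion study).
* Compound-structure centroids (eyes especially) can shift a few pixels
  between generator truth and extraction when the cycle is resolved
  slightly differently, which occasionally costs a match at the 5 px
  tolerance.
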