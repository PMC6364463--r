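---
title: "CT texture analysis of tumor heterogeneity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT texture analysis of tumor heterogeneity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nuclear grade of clear-cell renal cell carcinoma (ccRCC) — low (Fuhrman
I–II) versus high (III–IV) — is prognostic but ordinarily requires tissue.
CT texture analysis (CTTA) asks whether the *spatial heterogeneity* of the
lesion on routine contrast-enhanced CT carries the same signal. The
approach quantifies heterogeneity from the voxel-intensity histogram of a
tumor region of interest (ROI), after band-pass filtering that isolates
texture at chosen spatial scales, and then tests which of those
quantities separate the two grades.

`cttar` implements this analysis as a reproducible pipeline:

1. **Channels.** Each volume is analyzed unfiltered and after
   Laplacian-of-Gaussian (LoG) filtering at a fine scale
   ($\sigma = 1.0$) and a coarse scale ($\sigma = 2.5$).
2. **Features.** Over the masked lesion voxels of each channel, five
   first-order histogram statistics: mean gray intensity, standard
   deviation, entropy, skewness, kurtosis.
3. **Inference.** A two-sample comparison of every cell of the
   phase × feature × filter grid (2 × 5 × 3 = 30 tests), with
   Benjamini–Hochberg false-discovery-rate (FDR) adjustment across the
   whole grid, followed by ROC analysis of the surviving cells with
   Youden-optimal cutoffs.
4. **Phantoms.** A synthetic cohort generator with explicit control of
   lesion texture, so every stage can be validated against known truth
   and the pipeline's operating characteristics (power, FDR control) can
   be measured.

## The filtering model

The LoG operator at scale $\sigma$ is
$\nabla^2 G_\sigma * I$ — a zero-mean band-pass filter whose response
peaks for structures of size $\approx \sigma\sqrt2$. Small $\sigma$
passes fine texture, large $\sigma$ coarse texture, and both suppress
the DC component, so filtered masked means are small and legitimately
negative.

Several conventions are not fixed by common CTTA practice; `cttar`
resolves each explicitly, records all of them in the run log, and makes
them configurable:

* **Sigma units**: in-plane voxel units (default) or mm with anisotropy
  correction per axis.
* **Mode**: 2D per-slice filtering by default — with 3 mm slices the
  through-plane sampling is too coarse for a $\sigma = 1$ 3D operator —
  with a 3D mode available.
* **Boundary**: reflect (half-sample symmetric) padding; kernels
  truncated at $4\sigma$.
* **Normalization**: the response carries no $\sigma^2$ scale
  normalization (a flag in the classic sense is deliberately absent: the
  entropy feature, the pipeline's primary marker, is invariant to channel
  scaling anyway).
* **Kernel**: sampled analytic Gaussian second-derivative factors with a
  shared normalizer; the kernel is mean-subtracted so its discrete sum is
  exactly zero and any uniform HU offset maps to exactly zero response.

Filtering is always applied to the **full volume before masking**, so
voxels near the ROI boundary see their true image context; feature
extraction must never pre-zero outside-mask voxels.

## The features

For masked voxel values $x_1,\dots,x_n$:

* mean $\bar x$; sample SD ($n-1$ denominator);
* skewness $m_3/m_2^{3/2}$ and kurtosis $m_4/m_2^2$ from population
  moments, without small-sample bias correction. Kurtosis uses the
  **non-excess** convention (a Gaussian scores 3). The convention is
  stated prominently in the run log because reported CTTA kurtosis values
  are ambiguous between the two conventions.
* entropy $-\sum_i p_i \log_2 p_i$ (bits) over a 256-bin equal-width
  histogram spanning the per-ROI min–max range. Empty bins contribute
  nothing; a constant region has entropy 0; entropy is bounded by
  $\log_2 256 = 8$ bits and attains the bound only for uniform bin
  occupancy.

The 256-bin min–max convention was chosen because it is well defined for
the signed, unbounded filtered channels, it makes entropy invariant under
affine intensity rescaling, and it puts typical unfiltered CT entropies
in the high-6 range, consistent with values reported for abdominal CTTA.
Both the bin count and a fixed-range alternative are configurable.
Degenerate inputs are explicit: an empty mask is a precondition error, a
single-voxel mask leaves dispersion features undefined, and a constant
region reports SD = entropy = 0 with skewness/kurtosis missing (0/0).

## Inference

Each grid cell is tested with Welch's unequal-variance $t$ (the pooled
test is available by flag); the family of all 30 cells is adjusted
jointly by Benjamini–Hochberg, and cells with adjusted $p < 0.05$ are
called significant. Cells with fewer than two usable values per group
are excluded, shrinking the family size accordingly — the family is
always the set of tests actually performed.

ROC analysis treats high grade as the positive class. If a feature is
*lower* in high grade (as entropy is), its sign is flipped so
AUC $\ge 0.5$, and the flip is recorded as `positive_direction`. The AUC
is the trapezoidal area of the empirical curve, which equals the
Mann–Whitney concordance probability with ties counted one half — an
identity the tests assert against an exhaustive pair-count oracle. The
reported cutoff maximizes Youden's $J$; candidate cutoffs are midpoints
between adjacent observed values, and ties in $J$ are resolved toward
the midpoint of the two group medians.

## The phantom model

Each synthetic subject carries one ellipsoidal lesion (semi-axes drawn
from `lesion_radius_range` with ±10% axis jitter) in a
64 × 64 × 24-voxel volume at 1 × 1 × 3 mm spacing, imaged in two
contrast phases that differ only in mean enhancement. The lesion
interior is composed of:

* a **correlated Gaussian texture field**: white noise smoothed to
  correlation length $\ell$ (mm), then rescaled to amplitude
  `texture_field_sd` (HU) — smoothing-then-rescaling decouples amplitude
  (which drives the SD feature) from correlation length (which drives
  the fine-vs-coarse LoG response);
* optional **intermittency**: multiplication by $\exp(aZ)$ with $Z$ an
  independent smooth unit-variance field. This produces patchy,
  heavy-tailed texture (marginal kurtosis $\approx 3e^{4a^2}$ before
  noise) — the phantom's analogue of heterocellular tissue with focal
  necrosis and uneven vascularization. Because the histogram range
  stretches with the tails while the bulk stays concentrated,
  intermittency *lowers* min–max-binned entropy and *raises* kurtosis in
  every channel while leaving mean, SD (enforced by the rescale) and
  skewness (symmetry) essentially untouched;
* an optional **necrotic core**: a central uniform ellipsoid at
  `necrosis_hu_offset` (default −60 HU, liquefied tissue) scaled to
  cover `necrosis_fraction` of the lesion volume. The viable-rim mean is
  raised so the whole-lesion mean still equals the specified
  group/phase enhancement;
* an alternative **discrete texture family** (`texture_dist =
  "discrete3"`): a spatially white three-level field taking 0 and
  $\pm\sqrt3\,$SD with probabilities 2/3, 1/6, 1/6 — tissue made of a
  few discrete attenuation classes. Its first four moments match the
  Gaussian field's exactly, and because its third and fourth *cumulants*
  vanish, every linear filter of it also has skewness 0 and kurtosis 3.
  Only the histogram entropy distinguishes it from Gaussian texture,
  which is precisely what makes it useful for specificity testing;
* i.i.d. Gaussian **acquisition noise** (default 5 HU), independent per
  phase.

Between-subject variability is modeled by per-subject jitter: a
per-phase enhancement offset (SD 30 HU), lognormal jitter of texture
amplitude (CV 0.15) and correlation length (CV 0.10), and uniform jitter
of the necrotic fraction (±0.05). These magnitudes were chosen so that
within-group feature dispersions are of the order reported in abdominal
CTTA cohorts; they are conditions of the phantom, not fitted quantities.

Default group structure: 77 low-grade and 54 high-grade subjects; mean
lesion attenuations 94/84 HU (low, corticomedullary/nephrographic) and
82/76 HU (high); intermittency 0.3 versus 0.8 and necrotic fraction 0.10
versus 0.15. Under these defaults entropy is the dominant discriminator
(lower in high grade, in every channel), kurtosis responds secondarily
(higher in high grade), and mean/SD/skewness differences are weak — the
qualitative pattern such grading studies report. The phantom is *not*
calibrated to reproduce any published cohort's numbers: no quantitative
texture model of real ccRCC is available to calibrate against, so
published AUCs and group means are not reproduction targets.

Reproducibility: every subject draws from its own substream, seeded by a
stable hash of the subject identifier mixed with the run seed, so
enlarging a cohort never reshuffles existing subjects, and identical
(spec, seed) pairs yield byte-identical downstream tables.

### What the phantom does not model

DICOM acquisition physics (beam hardening, reconstruction kernels, dose
dependence), enhancement kinetics, non-ellipsoidal lesion shapes,
multifocal or peripheral necrosis, inter-reader segmentation
variability, and registration error between phases. Passing phantom
tests therefore demonstrates that the *pipeline* is correct and
well-powered under its stated statistical model — not that the pipeline
will reach any particular performance on clinical images.

## Designed validation properties

Three constructions deserve explanation because their design is part of
the method:

* **Necrosis lowers entropy.** The mechanism — a large uniform region
  concentrates histogram mass — holds only when the core is uniform
  *relative to histogram resolution*: with 256 bins over a ~250 HU ROI
  range, one bin is ≈ 1 HU wide, so the mechanism test uses phantoms
  with 2 HU acquisition noise. At 5 HU noise the core bump spans ~30
  bins and the entropy change washes out, while the split of mass into
  two components adds entropy of its own ($+H_2(f)$ bits); the property
  is then genuinely unreliable. This resolution condition is a real
  feature of min–max-binned entropy, not an implementation artifact.
* **Heterogeneity-only recovery.** The power test uses cohorts
  (40 + 40) whose groups share means, texture amplitude, correlation
  length and necrotic fraction and differ only in intermittency
  (0.3 vs 0.8). The pipeline should flag entropy in the fine and coarse
  channels with AUC > 0.7 in at least 90% of replicates, and matched
  null cohorts should yield an empty significant set in at least 90%.
* **Entropy-only specificity.** Gaussian-texture versus
  discrete3-texture groups (white fields, equal moments) differ in
  entropy and in *nothing else* by construction. Even so, a rare
  non-entropy discovery is expected occasionally: with several certain
  entropy discoveries, the BH step-up raises the effective per-cell
  threshold for the remaining 24 truly null cells, and an FDR of 5%
  among ~4–6 discoveries per run implies a false companion in roughly
  one run in ten. The test's ≥ 90% requirement sits deliberately at
  that theoretical boundary.

## Numerical choices and degenerate cases

* Convolution is separable, by dense banded matrices per axis; reflect
  padding is part of the operator definition and is pinned by an
  independent pad-and-shift convolution oracle in the tests.
* Histogram binning uses right-closed intervals with the maximum value
  included in the last bin; bin occupancy, not interpolation, defines
  entropy.
* Tied ROC scores are grouped on single curve vertices (which is what
  makes trapezoidal AUC equal Mann–Whitney with half-ties).
* Lesions must span at least 7 axial slices; specs whose smallest
  possible lesion violates this are rejected at construction, and any
  generated mask violating it aborts generation loudly.
* Degenerate specs (zero-size lesions, fractions outside [0, 1],
  lesions larger than the volume) are rejected with messages.

## Problem sizes used in the shipped checks

The validation suite runs phantom cohorts at 64 × 64 × 24 voxels (the
recovery and null studies, 50 replicates each at n = 40 + 40, and the
necrosis mechanism study, 100 paired lesions) and 48 × 48 × 20 voxels
(the specificity study, 50 replicates at n = 40 + 40); the acceptance
script runs the full default cohort (131 subjects) once, ten replicate
pairs of the recovery/null study, and 50 mechanism pairs. These sizes
were chosen so the full validation
runs comfortably on a laptop-class single core while keeping every
Monte-Carlo estimate's binomial error well inside the asserted margins.

## Known limitations

* Entropy under min–max binning is sensitive to single extreme voxels
  (they stretch the range); clinical use would likely clip the HU range
  first. The fixed-range histogram option exists for that purpose.
* The 2D-per-slice default ignores through-plane texture entirely.
* The Youden cutoff is reported without confidence intervals; no
  DeLong-style AUC inference, multivariable modeling or cross-validation
  is included.
* The FDR family is the full 30-cell grid; per-phase families are a
  defensible alternative the package does not currently offer.
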