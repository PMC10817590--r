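---
title: "Interocular retinal texture asymmetry: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interocular retinal texture asymmetry: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

oculotex asks a narrow question of segmented macular OCT data: do the texture
statistics of a person's right and left retinas differ, and does that
difference depend on sex? The pipeline answers it in four stages: simulate
(or read) segmented OCT volumes, project each neuroretinal layer to a mean
value fundus (MVF) image, reduce each image to grey-level co-occurrence
matrix (GLCM) texture features on a blockwise grid, and test paired
right-eye/left-eye differences per sex group under three multiple-comparison
corrections. This vignette records the scientific model behind each stage
and the conventions and design decisions a reader needs in order to trust,
reproduce, or criticise the results.

## The measurement model

An OCT macular cube is a grid of `n_bscan` cross-sectional B-scans, each
composed of `n_ascan` depth profiles (A-scans). Segmentation provides seven
interface surfaces `z_0 <= z_1 <= ... <= z_6` (fractional voxels) that
delimit six neuroretinal layers: RNFL, GCL, IPL, INL, OPL, ONL. The MVF
image of a layer assigns to each en-face position the depth-wise mean of
the A-scan intensities between the layer's two interfaces. Two conventions
matter:

* **Span rounding.** Fractional interfaces are rounded to the integer voxel
  span `[ceil(z_top), ceil(z_bottom))`. No sub-voxel interpolation is
  attempted: it would imply a precision the segmentation does not have, and
  the half-open span makes adjacent layers partition the A-scan exactly.
* **Zero-thickness pixels.** Where a layer vanishes (the foveal pit), the
  span is empty. Such pixels are masked invalid and carry `NA`. They are
  never silently zero, which would poison every downstream block mean.

Left-eye images are mirrored along the A-scan axis, so the temporal retina
sits on the low-column side of every image and features extracted at the
same position are anatomically comparable between eyes. The block grid
(below) discards the foveal centre anyway, but masking keeps the invariant
"every reported value is an average of measured tissue" independent of the
grid geometry.

## Texture features

The 128 x 512 MVF image is mean-pooled 4:1 along the A-scan axis to a
128 x 128 image with isotropic sampling, quantized to 16 grey levels, and
cut into a 7 x 7 grid of 18 x 18-pixel blocks anchored at the top-left
corner (the last two rows and columns of pixels are unused; a fixed anchor
keeps the grid reproducible). The grid's central row and column overlap the
fovea and are discarded, leaving 36 blocks in four 3 x 3 quadrant groups
(Q1 temporal-superior, Q2 nasal-superior, Q3 temporal-inferior, Q4
nasal-inferior).

Per block, four co-occurrence matrices are accumulated at displacement
d = 1 along 0, 45, 90 and 135 degrees, each pooled with its opposite
direction (180 degrees apart), which makes the matrices symmetric. Pairs
touching invalid pixels are skipped rather than imputed. From each matrix,
21 classical features are computed (autocorrelation, cluster prominence and
shade, contrast, correlation, difference entropy and variance,
dissimilarity, energy, entropy, homogeneity, the two information measures
of correlation, inverse difference and its normalised variants, maximum
probability, sum average, sum entropy, sum of squares-variance, and sum
variance). The per-block value of a feature is its maximum over the four
orientations — an orientation-invariant summary that also makes the block
value exactly invariant under horizontal mirroring, which is what licenses
comparing flipped left eyes with right eyes. Quadrant values are means over
the quadrant's nine blocks; per eye this yields 21 x 6 x 4 = 504 features.

Numerical conventions, fixed and tested rather than left to a library:

* Entropy-family features use base-2 logarithms with `0 * log 0 = 0`.
* Sum Variance is the second moment of the grey-level-sum distribution
  about the **Sum Average**. The original feature list contains a
  well-known misprint (centring on Sum Entropy); the misprinted form is
  available as a configuration switch for comparison with legacy code.
* Difference Variance is the variance of the grey-level-difference
  distribution; its raw second moment is the selectable alternative.
* On a constant block, Correlation, IMC1 and IMC2 have vanishing
  denominators and are defined as 0, keeping quadrant means finite.
* A block with no valid pixel pair at some orientation simply drops that
  orientation from the maximum; a block with no valid orientation carries
  no value and is skipped by the quadrant mean.

### Quantization: fixed-range by default

Grey-level quantization is linear equal-width binning into 16 levels over
the fixed 0-255 reflectivity range. The alternative — per-image min-max
binning — is attractive for real acquisitions because it cancels
brightness and gain differences between scans, and it is available as
`glcm_config(quantization = "per_image")`. It is not the default for a
measured reason: the realized min-max of an image is a single random scale
shared by everything in that image, so per-image binning couples the
features of all four quadrants of a layer (on synthetic cohorts we observe
between-quadrant correlations of r = 0.7-0.85 for entropy-type features,
against r = 0 under fixed binning). That coupling makes the downstream
correlation filter collapse each feature to a single representative per
layer regardless of quadrant, and it lets a strictly quadrant-local effect
bleed into apparent differences at other quadrants of the same layer. On
data without global brightness variation — which includes this package's
simulations — fixed-range binning is the scientifically safer default; on
real device exports the per-image switch (or an upstream intensity
normalisation) should be considered.

## The statistical chain

Within one sex group, each of the features is correlated (Pearson) with
every other feature across participants, separately for right (OD) and left
(OS) eyes. A pair is *redundant* when `|r| >= 0.5` in **both** eyes — a
deliberately conservative rule: a pair that co-varies in one eye only is
evidence of an interocular difference, not of redundancy. Features in no
redundant pair are kept outright. The rest are ranked by their number `n`
of redundant partners, ties broken by the larger explained-variance sum
`sum_i (r_OD,i^2 + r_OS,i^2)`, and the ranked list is traversed once: an
undiscarded feature is kept and all its not-yet-kept partners are
discarded. The kept set is then pairwise non-redundant. Whether the ranks
should be recomputed after each discard is ambiguous in the procedure's
usual verbal statement; both traversals are implemented
(`recompute_after_discard`), produce sound kept sets, and agree on all
worked examples — the single-pass form is the default because it is
deterministic in one sort.

Each kept feature is tested for a right-left difference with a paired test
across the group's participants. The test is chosen by a Shapiro-Wilk gate
at the 10% level — conservative in the sense that it diverts features to
the non-parametric branch more readily than the usual 5% convention. The
gate is applied to the OD and the OS samples (not to the paired
differences; the differences-based gate is the textbook alternative, but
the eye-wise gate is the procedure implemented here, and the choice is
exposed by calling `normality_gate` directly). Gated features take a
paired t-test, others a Wilcoxon signed-rank test with the following fixed
dialect: zero differences dropped, tied ranks averaged, exact distribution
for up to 25 non-zero pairs and a continuity-corrected normal
approximation above that. Identical eyes (all differences zero) are
flagged degenerate with p = 1.

Three corrections are applied to the kept family of m p-values at
alpha = 0.05:

* **Bonferroni**: significant iff `p < alpha / m`.
* **Benjamini-Hochberg**: the largest k with `p_(k) < k * alpha / m`
  declares the k smallest p-values significant.
* **Storey q-values**: `pi0 = #{p > lambda} / (m (1 - lambda))` with
  lambda = 0.5 (the common default; configurable, and lambda = 0
  reproduces BH exactly), `q(p_(i)) = min_(j >= i) pi0 m p_(j) / j`,
  significant iff q < 0.05. The FDR point estimate at t = 0.05 is
  reported alongside.

Every feature ends in exactly one state — redundant (correlated-out),
non-significant, significant before correction only, or significant after
correction — and the per-group state grid plus the count summary are the
pipeline's primary outputs.

## The synthetic cohort generator

The study's real scans are not distributable, so the package ships a
generator whose role is to produce data with the statistical structure the
analysis assumes, under full experimental control. It emulates:

* a sex-balanced cohort (default 49 + 49 participants, both eyes each)
  with ages from a truncated normal (mean 42.5, sd 16.3, range 19-74
  years, sampled by inverse CDF so the truncation is exact);
* per-eye volumes on the 512 x 128 en-face grid with a configurable depth
  (default 64 voxels — depth only matters through the layer averages, so
  the device's native depth would add cost without information);
* seven smooth interface surfaces: mean layer thicknesses of 6, 7, 6, 5,
  5, 10 voxels (RNFL..ONL), perturbed by smoothed-noise fields with a
  20-pixel correlation length, plus a radial Gaussian foveal depression
  (radius 14 B-scan pixels) that multiplicatively thins all layers but the
  ONL, reaching zero thickness at the centre — so the masking and foveal
  exclusion paths are genuinely exercised;
* per-layer reflectivity: a constant layer mean (170, 110, 130, 100, 125,
  90 on the 8-bit scale, bright RNFL over darker nuclear layers) plus a
  stationary texture field — white noise convolved with a Gaussian kernel
  (correlation length 2.5 pixels in isotropic units; the A-scan axis
  kernel is scaled by the 4:1 anisotropy), standardized to mean 0 and sd
  10 — constant along depth within the layer, plus independent voxel noise
  (sd 15). Voxels are rounded and clipped to 0-255; the texture field
  survives depth averaging while the voxel noise is attenuated by the
  layer thickness, which is what makes the MVF texture measurable.

Randomness is organised in substreams keyed by (seed, participant, eye),
so adding participants to a cohort never changes existing volumes, and a
written dataset is bit-reproducible from its configuration.

Injected effects are the generator's experimental handle: an effect
specification names a sex, an eye, a layer and a quadrant, and regenerates
the texture field inside that quadrant's en-face footprint (mirrored for
left eyes) with modified correlation length and/or sd, from its own
substream — volumes outside the footprint stay bit-identical to the
no-effect dataset. A tripled texture sd (`delta_sd = 20`) is the reference
"strong" effect used in the recovery studies.

What the generator does *not* emulate is as important: no speckle physics,
no vasculature or shadowing, no acquisition brightness/gain variation
between scans, no segmentation error, and — critically — all participants
share identical texture parameters, so between-participant variation is
pure sampling noise of the fields. Passing tests on these cohorts
demonstrates that the analysis chain is correct and calibrated (type I
control, locality, recoverability); it does not demonstrate that real
retinas differ between sexes, and the generator's reflectivity statistics
are placeholders, not fitted values.

## Study configurations used by the test suite

The packaged studies run at desk scale, chosen once:

* **Type-I study**: 50 null cohorts of 20 participants/group, three
  mid-retinal layers (GCL, IPL, INL), depth 32 voxels; the mean fraction
  of corrected-significant features must stay within alpha for each
  correction method.
* **Recovery study**: 20 cohorts of 49 participants/group (the full
  cohort size: the correlation filter's choice of clique representative —
  exactly what the recovery question asks about — is unstable in small
  samples), the same three layers as the type-I study, one injected
  left-eye IPL/Q4 effect (`delta_sd = 20`) in the female group. The
  strong effect matters twice: it drives the paired tests, and by
  decorrelating the affected quadrant's left-eye features from their
  weaker partners it also stabilises which feature survives the
  redundancy filter (under the both-eyes rule a pruned left-eye link
  prunes the pair). A run succeeds when Entropy and/or Energy at IPL/Q4
  is corrected-significant in the female group and the male group has
  zero corrected detections. Note the structural ceiling on per-run
  success: in the null (male) group the three corrections jointly allow
  a family-wise false-positive probability of roughly 5-10% per run (the
  Storey estimate of the null proportion is noisy at family sizes of a
  few dozen, and occasionally fires when Benjamini-Hochberg would not),
  so the 90% acceptance threshold sits close to — and in unlucky seed
  blocks below — what any effect size can deliver. The family size is
  one reason the recovery study keeps three layers rather than only the
  affected one.

The acceptance script (`scripts/acceptance.R`) re-runs smaller versions of
both studies (12 null, 8 effect cohorts) plus the structural and oracle
checks, and writes all quantities as JSON.

## Known limitations

* The texture model has one spatial scale and one amplitude per layer;
  real retinal texture is multi-scale and spatially inhomogeneous. The 21
  features are therefore much more mutually redundant here than on real
  data, and the decorrelation step keeps fewer features than reported for
  real cohorts.
* Per-image quantization (the field's common habit) and acquisition
  brightness variation (the reason for that habit) are both absent from
  the default simulation; transferring conclusions between the two
  quantization modes requires care either way.
* The Wilcoxon dialect, the eye-wise normality gate, the single-pass
  selection traversal and lambda = 0.5 are fixed conventions. All are
  configurable, but the defaults are what the tests pin down.
* Interface perturbations are generated on the isotropic 128-grid and
  linearly expanded along A-scans; with a 20-pixel correlation length the
  interpolation error is negligible, but sub-4-pixel interface detail is
  not representable.
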