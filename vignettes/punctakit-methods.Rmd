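---
title: "Quantifying synaptic density and microglial engulfment in 3D: methods and design"
author: "punctakit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic density and microglial engulfment in 3D: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctakit)
```

## The measurement problem

A synapse in tissue appears, under confocal microscopy, as a pair of
diffraction-limited fluorescent spots: a pre-synaptic punctum (e.g.
Vglut1) apposed to a post-synaptic punctum (e.g. Homer1) within roughly
200 nm. Counting synapses therefore reduces to (i) detecting ~0.2 um
puncta in each channel of a 3D z-stack, (ii) counting post-synaptic
puncta that have at least one pre-synaptic punctum strictly within a
200 nm radius, and (iii) expressing the result as puncta per cubic
micrometre, normalized to a reference group of animals. A companion
measurement quantifies microglial engulfment of synaptic material as the
volume of pre-synaptic marker inside lysosomes (CD68) inside microglia
(Iba1), in um^3 per cell.

punctakit implements both measurements as plain, testable voxel and
point-set arithmetic, plus a synthetic phantom generator that provides
exact ground truth so the entire chain can be validated without any raw
imaging data.

## Geometry conventions

All geometry is done in physical micrometres, never voxel indices,
because confocal voxels are anisotropic (0.1 x 0.1 um pixels against
0.125 or 0.5 um z-steps) and the colocalization radius (0.2 um) is
sub-voxel in z. A voxel with 1-based index $i$ along an axis of spacing
$d$ spans $[(i-1)d, id)$ and has its centre at $(i - \tfrac12)d$; the
physical extent of an axis with $n$ voxels is $nd$. Punctum positions
are continuous coordinates, not voxel indices.

## Detection

The tissue path is a scale-matched blob detector:

1. **Filtering.** The channel is smoothed with a Gaussian of physical
   standard deviation $\sigma = d_{\mathrm{punctum}} / (2\sqrt{3})$
   (~0.058 um for 0.2 um puncta), converted to per-axis voxel sigmas.
   The scale-normalized, sign-flipped Laplacian
   $-\sigma^2 \nabla^2 (G_\sigma * I)$ — with each second derivative
   taken in physical units — peaks for bright blobs of the matched
   diameter: for a solid ball of radius $r$, the 3D response is maximal
   at $\sigma = r/\sqrt{3}$, which is how the default maps diameter to
   scale. The convention is configurable (`sigma_um`) because different
   implementations derive $\sigma$ from the diameter differently.
2. **Candidates.** Every voxel whose response is $\ge$ all 26 neighbours
   is a candidate; a connected plateau of equal-valued maxima
   contributes a single candidate at its centroid, keeping the
   candidate set deterministic.
3. **Merging.** Candidates within one punctum width (0.2 um, physical
   distance) are linked and single-linkage components become one
   punctum at the response-weighted centroid. Merging is single-pass:
   this matches the standard definition and is exactly checkable
   against an independent union-find. (A subtlety: the centroids of two
   *different* components can, in adversarial geometries, sit closer
   than the merge radius even though all member-to-member distances
   exceed it. On detector output this does not occur in practice, and
   the property is asserted on detection outputs in the test suite.)
4. **Gating.** Puncta within half a punctum diameter of any physical
   face are discarded (the smallest margin at which a punctum's profile
   is fully sampled — "on the image edge" is not otherwise
   quantifiable), and puncta whose raw intensity falls below the global
   Otsu threshold of the channel's voxel-intensity histogram (256 bins,
   ties toward the lower cut) are discarded. Both filters are pointwise,
   so their order is immaterial.

The culture path (`mode = "dog2d"`) max-projects the stack, applies a
difference of Gaussians with $\sigma_1 = \sigma/\sqrt{1.6}$,
$\sigma_2 = 1.6\,\sigma_1$ and $\sigma = d/(2\sqrt{2})$ (geometric mean
matched to the blob scale, default diameter 0.72 um), and gates on the
detector response — by an explicit `quality_threshold` when configured,
otherwise by Otsu on the response distribution. This replaces
interactively chosen spot-quality cutoffs with a reproducible rule.

### When does the global Otsu gate work?

Otsu's threshold maximizes the between-class variance
$w_0 w_1 (\mu_0 - \mu_1)^2$. With foreground fraction $f$ and
foreground-background contrast $\Delta$, the foreground split scores
about $f \Delta^2$, while the best split *inside* a Gaussian background
of spread $\sigma_b$ scores about $0.64\,\sigma_b^2$. The gate is
therefore reliable only when $f\Delta^2 > 0.64\,\sigma_b^2$: sparse,
dim, or noisy fields push the threshold into the background mode. The
synthetic defaults (below) model a photon-counting-like acquisition
that satisfies this inequality, as the acquisitions this workflow is
designed for must. For data outside this regime the gate is
configurable (`intensity_gate = fixed(value)` or `"none"`).

## Colocalization and density

`count_colocalized` counts reference (post-synaptic) puncta with at
least one target punctum at distance $d < r$ (strict inequality,
following the "<200 nm" convention; default $r = 0.2$ um). The count
is existence-based and asymmetric: one target may satisfy several
references, and the count never exceeds the reference count. Under
independent homogeneous Poisson channels of intensity $\lambda$, the
expected colocalized fraction is $1 - \exp(-\lambda \frac43 \pi r^3)$,
which the test suite uses as a closed-form calibration of chance
colocalization.

Per-punctum local density uses a Gaussian kernel density estimate
$\hat\rho_i = \sum_{j \ne i} (2\pi h^2)^{-3/2}
e^{-\|x_i - x_j\|^2 / 2h^2}$ with default bandwidth $h = 0.4$ um
(twice the punctum diameter), self-term excluded — an isolated punctum
has local density zero — and no boundary correction. The estimator is a
descriptive output with explicit parameters; no headline measurement
depends on the bandwidth choice.

Overall density is count / analyzed volume, where the analyzed volume
is the stack extent minus the edge-exclusion margin on each face, so
the numerator's spatial domain matches the denominator. Group tables
are normalized per measurement and per region to the mean of the
reference group (young wild-type), whose normalized mean is exactly 1.

## Engulfment volumetrics

Surface rendering is replaced by voxel arithmetic: each channel is
optionally smoothed, thresholded (Otsu by default), the cell channel is
labelled into 26-connected components with components below
`min_cell_volume_um3` (default 50 um^3) discarded — an automatic stand-in
for manual cell selection — and for each cell $c$:

* cell volume $= |c| \cdot v$,
* lysosome-in-cell $= |c \wedge L| \cdot v$,
* cargo-in-lysosome $= |c \wedge L \wedge S| \cdot v$,

with $v$ the voxel volume. Cargo outside lysosomes and lysosomal signal
outside cells are ignored (the ignored lysosome fraction is reported as
a diagnostic). The nesting inequality cargo $\le$ lysosome $\le$ cell
holds by construction and is asserted on every result. Voxel counting is
exactly testable: a painted sphere of radius $r$ must report
$(4/3)\pi r^3$ within the voxelization error (<1% at 0.1 um voxels for
a 3 um cell, ~5% for a 0.5 um cargo sphere).

## The synthetic phantom generator

`generate_puncta_field` emulates the synaptic acquisition: a
256 x 256 x 16 grid at 0.1 x 0.1 x 0.125 um (a 2 um stack), 150 puncta
per channel of 0.2 um FWHM, placed by rejection sampling with 0.3 um
minimum separation and an edge margin of one FWHM (so the detector's
edge exclusion never removes a true punctum). A configurable fraction
(default 0.4) of reference puncta receives a paired target punctum
displaced uniformly within a 0.15 um ball — strictly inside the 0.2 um
radius — while unpaired cross-channel puncta are kept at least the
minimum separation apart, so the true colocalized fraction equals the
requested one exactly. The pair count is `round_half_up(n * fraction)`.

Rendering is midpoint evaluation of an isotropic physical-space
Gaussian at voxel centres. The nearest voxel centre can sit half a
voxel diagonal from a punctum centre, so the peak voxel underestimates
the true amplitude by $e^{-d^2/2\sigma^2}$; for the peak to be within
5% the FWHM must span roughly 6.5 voxels per axis, and the photometry
property test uses a 0.02 um grid (FWHM = 10 voxels) accordingly.

Noise is Poisson on (signal + background) in counts of configurable
gain, then additive Gaussian read noise, then clipping at zero; each
component can be switched off for noise-free oracles. The defaults —
amplitude 150 +/- 15% counts, background 3 counts, shot noise only —
describe a photon-counting confocal acquisition with peak SNR
$150/\sqrt{153} \approx 12$. They were chosen, by the regime analysis
above, so the phantom sits where a global Otsu gate is a valid
detector component; brightness statistics of any particular instrument
are otherwise free parameters. What the phantom does **not** emulate:
realistic point-spread functions (Airy/Gibson-Lanni), spectral
bleed-through, autofluorescence, tissue scattering, or uneven
illumination. Passing recovery tests therefore demonstrate the
correctness of the computation, not robustness to every real-world
artefact; the preprocessing stage (rolling ball, percentile
normalization) exists for the latter and is validated separately.

`generate_engulfment_phantom` paints nested spheres or ellipsoids
(defaults 3 / 1.5 / 0.5 um radii at 0.1 um isotropic voxels) at fixed
intensities per compartment and records analytic volumes as ground
truth.

## Preprocessing

Rolling-ball background subtraction is implemented as the grayscale
opening of each z-slice with a ball-shaped structuring element of the
stated pixel radius (default 6), without pre-smoothing. The opening is
everywhere at most the input, so the output is non-negative, and a
linear background is removed exactly in the slice interior. Because the
structuring element is non-flat, the top-hat is idempotent only up to
the ball's one-pixel sag ($r - \sqrt{r^2 - 1} \approx 0.08$ at $r = 6$)
at narrow peaks, and replicated-edge padding perturbs a boundary band
of one radius; both bounds are asserted in the tests.

Percentile normalization maps the 1st and 99th percentiles (for the
default 2% total saturation, split equally across tails) linearly to
[0, 1] with clipping. Quantile scope is configurable: per slice, per
stack, or pooled across the sections of one animal
(`preprocess_section_set`), the last being the default interpretation
of normalizing "across sections"; normalization is per channel. A
degenerate image (coinciding quantiles) returns zeros with a warning
rather than an error, since blank slices occur in practice.

## Statistics

Group comparisons use:

* **one-sample t** against a null level (e.g. normalized uptake against
  1, or chance preference against 50%);
* **ordinary two-way ANOVA** (age group x genotype) with Type II sums
  of squares — on the balanced or mildly unbalanced cohorts this
  package targets, Type II coincides with the textbook decomposition
  while remaining well defined for unequal cell sizes, and the choice
  is stated rather than implicit;
* **repeated-measures two-way ANOVA** for complete-block designs (each
  independent culture experiment observed in every condition), with the
  block entered additively and effects tested against the within-block
  residual; incomplete blocks are an error rather than silently
  dropped.

Post hoc comparisons are the four cell-wise pairs of scientific
interest — each factor compared within every level of the other — with
Bonferroni adjustment over the family actually tested
($p_{adj} = \min(1, m\,p)$), not all six pairwise cells. Tests are
two-sided with significance flagged at 0.05. Degenerate decompositions
follow a fixed convention: an effect with zero sum of squares reports
$F = 0$, $p = 1$ (rather than 0/0), and a saturated fit falls back to
the sequential table, which coincides with Type II in the balanced
cases where this can occur.

## Pipeline, determinism, problem sizes

`run_pipeline` executes simulate/read -> preprocess -> detect (both
synaptic channels) -> colocalize -> aggregate per animal (the animal is
the unit of analysis) -> normalize -> ANOVA, writing per-image puncta
CSVs, a long-format group table, an ANOVA JSON and a run manifest; any
stage failure aborts naming the stage and image. Per-image seeds are
derived from the master seed, outputs carry no timestamps, and two runs
with the same config are byte-identical — asserted in the tests.

Validation problem sizes were chosen to exercise the acquisition-scale
geometry while keeping the full suite fast on one CPU: detection
recovery and colocalized-fraction recovery use the full 256 x 256 x 16
standard phantom over 10 seeds each; oracle-equality checks use
50-100 random instances; the chance-colocalization check uses 200
Poisson fields in a 20 x 20 x 2 um box; the ANOVA null calibration uses
1000 simulated datasets; the determinism check runs the self-check
pipeline twice at 128 x 128 x 12.

## Known limitations

* No sub-voxel Gaussian fitting: localization accuracy is limited to
  the half-voxel scale (median ~0.05 um on the standard phantom), which
  suffices for a 0.2 um colocalization radius but not for
  single-molecule-scale questions.
* The global Otsu gate assumes the bright-sparse regime quantified
  above; very sparse or low-contrast acquisitions need a fixed gate.
* Engulfment volumes depend on the threshold convention; no numeric
  equivalence with any commercial surface-rendering output is claimed,
  only with analytic phantoms.
* The KDE local density has no boundary correction; values within one
  bandwidth of a face are biased low.
* Colocalization is point-based (centre distance), not object-overlap
  (pixel-based Manders/Pearson) colocalization; the two answer
  different questions.
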