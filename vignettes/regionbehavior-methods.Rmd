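---
title: "Methods: regional behavioral analysis of brain ROIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional behavioral analysis of brain ROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionbehavior)
```

## The model

Functional imaging experiments report their activation peaks as
stereotaxic coordinates ("foci"), and each experiment can be classified
into one of 51 behavioral sub-domains grouped into five domains
(Action, Cognition, Emotion, Interoception, Perception). Pooling many
experiments gives, for each sub-domain $b$, a spatial distribution of
where that behavior activates the brain.

`regionbehavior` turns such a coordinate table into a 4-D
**probability-density image**: for sub-domain $b$ with $N_b$ total
in-grid foci,

$$\mathrm{PDF}(x, y, z, b) = \frac{\#\,\text{foci of } b \text{ in voxel } (x,y,z)}{N_b},$$

so every channel sums to exactly 1 and the sum of a channel over any
region of interest (ROI) is the probability $p_o$ that a focus of that
behavior falls inside the ROI.

Under the null hypothesis that foci are spatially uniform within the
brain, that probability would be the ROI-to-brain volume ratio
$p_e = V_\mathrm{ROI} / V_\mathrm{brain}$. The behavioral association
of an ROI with sub-domain $b$ is scored by a two-proportion binomial
effect-size z-statistic:

$$z = \frac{p_o - p_e}{\sqrt{\left(p_o(1-p_o) + p_e(1-p_e)\right) / N_b}}.$$

A **behavior profile** is the 51-row table of these statistics ranked
by descending $z$; sub-domains with $z \ge 3.0$ and positive effect are
flagged significant. The 3.0 default acts as a Bonferroni-style guard
for 51 simultaneous tests at an overall level near 0.05.

### Assumptions behind the z-statistic

- Foci are treated as independent draws; within-experiment spatial
  correlation between peaks is ignored, so $N_b$ overstates the
  effective sample size and z-values are somewhat anti-conservative.
  The stringent 3.0 threshold partly compensates.
- The binomial variance uses both the observed and expected
  proportions; at $p_o = p_e$ it reduces to the usual two-proportion
  score variance.
- $p_e$ assumes uniform density over the brain mask. Real foci
  over-sample gray matter, so whole-brain-scale ROIs drift from this
  null; the statistic is intended for regional ROIs (a few percent of
  brain volume).

### Degenerate inputs

These contracts are exact, not approximate:

- whole-brain ROI: $p_o = 1$ for every populated channel, zero effect,
  $z = 0$;
- empty ROI: $p_o = p_e = 0$, $z = 0$;
- sub-domain with no foci ($N_b = 0$): $z$ is `NA`, never significant;
- zero variance with nonzero effect: $z = \pm\infty$;
- ROI voxels outside the brain mask are excluded from both $p_o$'s
  support and $p_e$'s numerator (with a warning), keeping the two
  consistent.

## Grid conventions

Grids are **node-centered**: the origin is the mm coordinate of the
center of voxel $(1,1,1)$ and voxel $(i,j,k)$ has center
$\mathrm{origin} + (i-1, j-1, k-1) \cdot s$ for spacing $s$. The
default bounding box, $x \in [-90, 90]$, $y \in [-126, 90]$,
$z \in [-72, 108]$ mm, is a generous superset of the atlas brain; at
the default 2-mm spacing it is a $91 \times 109 \times 91$ grid whose
centers include the stereotaxic origin. Axes follow the Talairach
convention: $x < 0$ is left.

A focus is assigned to the voxel whose center is nearest; a coordinate
exactly halfway between two centers rounds **away from zero** per axis.
Rounding away from the stereotaxic origin (rather than "round half up")
keeps the assignment mirror-symmetric across the midline, so
lateralization analyses are not biased toward one hemisphere by the tie
rule.

### 1-mm / 2-mm conversion

The two standard precisions share the bounding box and origin; the
coarse voxel at index $i$ along an axis owns fine voxels $2i-1$ and
$2i$, i.e. exactly 8 children per coarse voxel (clipped only on the
most-positive box faces, which brain masks never reach).
Up-conversion sets every child of a set parent and therefore preserves
ROI volume exactly; down-conversion sets a coarse voxel iff at least
half of its children are set (majority rule, ties set), with an
`"any"`-child alternative for dilation-like behavior.

## Spatial normalization

Internal analysis space is Talairach. Tables tagged `MNI` can be
adjusted with the pooled linear `icbm2tal` transform; both published
variants are built in (`mni_to_tal("fsl")`, the default, and
`mni_to_tal("spm")`), and arbitrary 4×4 affines can be loaded from
plain-text files. Masks are resampled through an affine by
nearest-neighbor pull over the output grid, which preserves the binary
character of ROIs.

## Behavior-specific ROIs and self-consistency

A sub-domain's channel, smoothed with an isotropic Gaussian
(default FWHM 10 mm, $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$,
discrete kernel sampled to $4\sigma$ and renormalized to unit sum,
zero padding at the box edge), approximates a continuous density.
Thresholding at 25 % of the smoothed maximum (relative, so the shape is
invariant to $N_b$) yields that behavior's **behavior-specific ROI**.

The **self-consistency** check runs the full profile analysis on each
behavior-specific ROI and records the rank of every sub-domain: on
well-separated data each sub-domain should rank first on its own ROI
with a large z. Ties in z are broken by sub-domain id, so the rank
matrix is deterministic.

## The synthetic generator

No coordinate database ships with the package, so validation uses a
seeded generator with known ground truth:

- the **brain** is an ellipsoid (default semi-axes 70, 85, 65 mm,
  ≈ 1.6 L, mirror-symmetric in $x$) voxelized on the analysis grid;
- each sub-domain draws its foci from a mixture of isotropic Gaussian
  clusters (truncated to the brain by rejection) and a uniform
  in-brain component;
- an optional hemispheric bias reflects each focus into $x < 0$ with
  probability `left_bias`;
- every focus carries a ground-truth component label.

`known_answer_suite()` builds three canonical test beds: a *recovery*
fixture (one clustered sub-domain among 50 uniform ones; a 12-mm
sphere over the cluster must flag exactly that sub-domain), a
*lateralization* fixture (uniform foci reflected left with probability
0.6), and a *self-consistency* fixture (51 clusters on a lattice with
pairwise separation ≥ 26 mm). The fixture sizes (2000 clustered /
1000-per-channel uniform / 400-per-cluster foci) are package choices
sized so that the expected effects exceed their standard errors by a
wide margin while whole-suite runtime stays in seconds; they emulate
the *structure* of a curated foci database, not its empirical density,
gray-matter weighting, or per-experiment clustering.

## Worked example

```{r example, eval = FALSE}
grid <- grid_spec(2)
brain <- generate_brain_mask(grid)
fix <- known_answer_suite(seed = 42)

pdf <- assemble_pdf4d(fix$a$foci, grid)
profile <- analyze_roi(pdf, fix$a$roi, brain)
head(profile, 3)

symmetry_table(fix$b$foci)

sc <- self_consistency(assemble_pdf4d(fix$c$foci, grid), brain)
table(sc$diag_rank)
```

## Limitations

- The linear MNI adjustment cannot capture nonlinear template
  differences; residual errors of a few mm are expected near the brain
  edge.
- Foci independence is assumed (see above); reported z-values should
  be read as effect sizes with an approximate scale, not exact
  p-values.
- Only isotropic, axis-aligned (RAS+) NIfTI grids are supported;
  rotated or anisotropic images must be reoriented upstream.
- The uniform null ignores gray/white asymmetry; very large ROIs will
  show systematic positive z for well-sampled behaviors.
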