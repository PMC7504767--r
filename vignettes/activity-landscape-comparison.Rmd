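---
title: "Quantitative comparison of 3D activity landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative comparison of 3D activity landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actland)
```

## The problem

Structure-activity relationships (SARs) in a compound dataset can be
*continuous* -- small structural changes cause small potency changes --
or *discontinuous*, where close structural analogs differ strongly in
potency (activity cliffs). A 3D activity landscape (AL) makes this
visible: compounds are placed in a 2D projection of chemical space, and
an interpolated potency surface is added as the third dimension, so
continuous SARs appear as smooth terrain and discontinuous SARs as
rugged peaks and canyons. Visual inspection of such landscapes is
qualitative; `actland` turns landscape topology into a small numeric
feature vector so that two datasets' landscapes can be *compared
quantitatively*.

The pipeline is:

1. **Chemical space.** ECFP4 fingerprints (2048-bit folded circular
   substructure fingerprints) give pairwise Tanimoto distances
   $d = 1 - |a \cap b| / |a \cup b|$; metric multidimensional scaling
   (MDS) embeds the compounds in 2D by minimizing the metric stress
   $\sum_{i<j} (d_{ij} - \lVert x_i - x_j \rVert)^2$.
2. **Potency surface.** A Gaussian process with a Matern
   ($\nu = 3/2$) plus White-noise kernel interpolates pKi over the
   projection, giving a coherent surface.
3. **Heatmap.** The surface is rasterized at 280 x 300 pixels and
   color-coded green-yellow-red over a fixed pKi window with anchors
   3.72 (green), 5.75 (yellow) and 8.75 (red); potencies outside the
   window clamp to the end colors. The per-pixel combined RG intensity
   $(R - G)/255 \in [-1, 1]$ encodes the surface height.
4. **Grid features.** A 56 x 60 grid partitions the image into 3360
   cells of 25 pixels; each cell's mean intensity is assigned to one of
   eight threshold intervals
   $[-1,-0.75), [-0.75,-0.5), \dots, [0.75, 1]$, ordered from deepest
   valleys to highest peaks. The eight cell counts are the landscape's
   feature vector. Because only the global distribution is kept, the
   representation is invariant to image orientation.
5. **Similarity.** Two landscapes are compared by the symmetric
   relative entropy of their smoothed cell-count distributions,
   $\mathrm{RE}(p, q) = \tfrac12\{\mathrm{KLD}(p\|q) +
   \mathrm{KLD}(q\|p)\}$ with
   $\mathrm{KLD}(p\|q)=\sum_i p_i \log(p_i/q_i)$, and by the cosine
   distance $1 - x \cdot y / (\lVert x\rVert\,\lVert y\rVert)$ of the
   raw count vectors. Larger values mean more dissimilar landscape
   topology.

## A worked example

```{r example}
rugged <- generate_dataset(n_compounds = 150, n_series = 8,
                           ruggedness = 0.8, seed = 3)
smooth <- generate_dataset(n_compounds = 150, n_series = 8,
                           ruggedness = 0, seed = 4)
al_r <- activity_landscape(rugged$compounds, seed = 1, id = "rugged")
al_s <- activity_landscape(smooth$compounds, seed = 1, id = "smooth")
al_r
al_compare(al_r, al_s)
```

```{r plot, fig.width = 5, fig.height = 5}
plot(al_r, points = TRUE)
```

## Model details and assumptions

**Fingerprints.** SMILES are converted to 2048-bit ECFP4 fingerprints
by the RDKit backend (bundled helper script; any Python with RDKit on
the PATH works). Because fingerprint computation is the only step that
needs a chemistry toolkit, fingerprints can also be supplied directly
as bit-index files, and all of the package's own testing uses synthetic
fingerprints.

**MDS.** We use SMACOF majorization (Guttman transform) on the raw
metric stress with 4 restarts: the first initialized from classical
scaling, which already solves exactly-Euclidean inputs, the others
random. Iteration stops when the relative stress decrease falls below
1e-6 (at most 500 iterations); the best-stress solution is kept.
Stress is guaranteed non-increasing per iteration. Tanimoto distances
are generally not exactly embeddable in 2D, so the absolute coordinates
depend on the seed; for a fixed seed the projection is fully
deterministic. Rotation/reflection of the projection is arbitrary,
which is harmless downstream because the feature distribution is
orientation-invariant.

**GPR.** Potencies are standardized (mean subtracted, scaled to unit
variance) so the zero-mean, unit-amplitude Matern prior is on the right
scale regardless of a dataset's pKi spread; predictions are transformed
back. The covariance is `Matern(3/2, length_scale) +
noise_level * I`, plus a ridge `alpha` on the training diagonal.
`alpha` is selected from 10 log-spaced candidates in $[10^{-7},
10^{-1}]$ by maximum log marginal likelihood; at each candidate the
length scale is optimized over a 24-point log-spaced grid on
$[10^{-2}, 10^{2}]$ with the noise level profile-optimized exactly in
1D (via a single eigendecomposition per length scale), followed by a
golden-section refinement of the length scale for the winning
candidate. Grid-plus-refine is used instead of a multi-start quasi-
Newton optimizer because the marginal-likelihood surface in the length
scale is multimodal for clustered chemical-space data; the grid makes
the selection reproducible and robust. The per-candidate maximized log
marginal likelihoods are stored on the fitted object so the selection
can be audited.

**Rasterization.** The heatmap is produced by direct evaluation of the
posterior mean on the 280 x 300 pixel grid -- a top-down view of the
landscape -- over the bounding box of the projected compounds expanded
by 5% per side. Pixel centers are evenly spaced; row 1 is the top of
the image.

**Color and intensity conventions.** Anchor colors are pure green
(0,255,0), yellow (255,255,0) and red (255,0,0) with piecewise-linear
interpolation in RGB and half-up rounding of channels; the blue channel
is always zero. These choices make the extreme combined RG intensities
exactly -255/0/+255 before normalization. When external PNG heatmaps
are ingested, near-white pixels (all channels >= 250), which some
renderers use for unpainted surface, are mapped to intensity 0
(yellow-equivalent).

**Binning conventions.** The eight threshold intervals are half-open
and lower-inclusive with the top bin closed at +1, so every intensity
in $[-1, 1]$ belongs to exactly one category; a cell mean of exactly 0
falls in the first positive interval. These boundary rules are
conventions (any consistent rule would do) and are fixed by tests.

**Smoothing.** Probabilities are computed as
$(n_i + \varepsilon) / (N + 8\varepsilon)$ with $\varepsilon = 0.5$
per bin, so the KLD is finite when a category is empty in one
landscape but not the other; raw counts are kept alongside and are
what the cosine distance uses (cosine ignores scale, so smoothing is
unnecessary there). The relative entropy is reported in nats by
default; base-2 is available via `base = 2` (`--log-base 2` on the
command line). Reported RE values therefore depend on this choice of
base and of $\varepsilon$ where categories are sparsely populated.

## What the synthetic generator emulates

`generate_dataset()` stands in for curated activity classes of a few
hundred compounds. Analog series are Gaussian clusters (default 20
series, 700 compounds, cluster sd 0.04 in a unit square, matching the
hundreds-of-compounds scale of typical ChEMBL activity classes); each
series takes its base potency from a smooth random field over chemical
space, which produces SAR continuity; `ruggedness` is the fraction of
series containing an activity cliff, realized as a matched analog
subgroup (a nucleus compound plus its nearest series neighbors,
`cliff_fraction` = 20% of the series) flipped to the opposite extreme
of the potency window (default pKi 4-10). Cliffs are modeled as
subgroups rather than single molecules because substituent-driven
potency flips affect analog subseries, and because a lone discordant
point among dozens of concordant neighbors is statistically
indistinguishable from assay noise -- the marginal-likelihood-optimized
GP would (correctly) absorb it into the White-noise term, leaving no
topological trace at the grid's resolution. `noise_sd` (default 0.2
pKi, a typical inter-assay reproducibility) adds measurement noise. The generator consumes its
random stream in a ruggedness-independent order, so datasets generated
with the same seed but different `ruggedness` are *topology variants*
of one landscape -- identical layout, potencies, noise and
fingerprints with nested cliff sets. Dose-response experiments (mean
dissimilarity as a function of ruggedness) use such variants, which
isolates the topological effect from between-layout variability;
independent seeds are used where genuinely independent datasets are
called for. Synthetic fingerprints
combine disjoint per-series core bits with random-hyperplane locality
bits so that Tanimoto distance grows with latent 2D distance -- the
property MDS needs -- plus a few private noise bits.

What the generator does *not* emulate: real substructure-driven
fingerprint correlations, series of unequal diversity, multiple cliffs
per series, selection biases of curated datasets, or potency
distributions with heavy censoring. Passing tests on synthetic data
therefore demonstrate that the pipeline's machinery behaves as
specified (determinism, invariances, discrimination of constructed
smooth vs. rugged topologies), not that any particular published
dataset's similarity values are reproduced.

## Numerical choices and degenerate inputs

- Tanimoto distance of two empty fingerprints is an error, not 1;
  fingerprints are required non-empty.
- An all-identical coordinate set cannot be fitted (error); an
  all-identical distance matrix projects to a single point.
- Constant potencies give `scale = 1` standardization and a constant
  surface.
- MDS convergence: relative stress decrease below 1e-6; SMACOF cannot
  increase stress, and for exactly-2D-embeddable distances the final
  stress is numerically zero.
- The raster extent must have positive area; images must be divisible
  by the grid (280 x 300 under 56 x 60 by default; both are
  configurable through `al_config()` subject to divisibility).
- Cell means are rounded to 12 decimals, far below the intensity
  resolution (multiples of 1/6375 for 8-bit RG input), so the
  partition is independent of within-block summation order; otherwise
  a block summing to exactly 0 could fall on either side of the 0
  category boundary after an image flip.
- Problem sizes in the test-suite: unit tests run on datasets of 30-150
  compounds; the end-to-end discrimination checks use the generator
  defaults (700 compounds, 20 series) with 20 seeded replicates per
  arm.

## Limitations

- The absolute MDS layout is seed-dependent; only statements that are
  invariant to the projection's orientation (as the cell distribution
  is) should be compared across software.
- The potency surface is an intentionally overfitted visualization
  device, not a QSAR model; it should not be used to predict potencies
  of new compounds.
- RE/CD values are comparable only under identical grid, gradient
  anchors, epsilon and log base; the packaged defaults reproduce the
  standard configuration.
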