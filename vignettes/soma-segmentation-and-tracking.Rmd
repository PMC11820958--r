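---
title: "Unsupervised soma segmentation and tracking in longitudinal 3D microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised soma segmentation and tracking in longitudinal 3D microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somatrack)
```

## The problem

Longitudinal in vivo two-photon fluorescence microscopy produces
four-dimensional data: a 3D volume of the same cortical region acquired at
a series of timepoints, registered so that a cell occupies (nearly) the
same voxels in every session. For glial cells such as oligodendrocytes, the
biological questions are about *fate*: how many cells are present, how many
appear (oligodendrogenesis) and how many disappear (e.g. cuprizone-induced
demyelination) at each timepoint, and how these rates vary with cortical
depth. Manual annotation of such volumes takes hours per image set and is
subject to observer variability.

`somatrack` implements a fully unsupervised pipeline for this task. It
assumes only that somas are compact, bright objects and that the
surrounding processes (myelin sheaths, in the oligodendrocyte case) are
thin, dim and elongated. There is no training step; everything is driven by
per-slice intensity statistics and explicit morphological reasoning.

The pipeline has four stages:

1. **Per-slice binarization** by a two-component beta mixture fitted with
   EM, thresholded where the weighted component densities cross.
2. **Anisotropic binary median filtering** (default window 11 x 11 x 3) to
   remove filamentous structures and impulsive noise.
3. **4D connected-component labeling** (kernel 3 x 3 x 3 x 3) so that one
   component is one tracked cell across space *and* time, followed by a
   temporal split-merge step and a minimum-size filter (30 voxels).
4. **Fate reporting**: per-timepoint totals, new and lost cells, optional
   100-um depth strata, per-cell coordinate tables and per-cell crops for
   visual verification.

## The intensity model

Intensities are bounded (8-bit, \[0, 255\]), and their distribution within a
slice is asymmetric, so a beta mixture on the rescaled unit interval is a
natural model. For a slice (fixed z and t), let $Y$ be the rescaled
intensity of a retained pixel. We model

$$ f(y) = p_0\, f(y;\alpha_0,\beta_0) + p_1\, f(y;\alpha_1,\beta_1),
   \qquad p_1 = 1 - p_0, $$

where $f(y;\alpha,\beta)$ is the beta density. Component 0 is the dim
background and component 1 the bright ROI (somas). Fitting is by EM:
the E-step computes the posterior responsibility of the bright class,
$r_1(y) = p_1 f_1(y) / (p_0 f_0(y) + p_1 f_1(y))$ (in log space); the
M-step updates $p_0$ as the mean background responsibility and each
component's shape parameters by numerically maximizing the weighted beta
log-likelihood over $(\log\alpha, \log\beta)$ with `stats::optim`
(L-BFGS-B, analytic gradients, box constraints $[10^{-3}, 10^3]$). Because
the weighted beta log-likelihood depends on the data only through
$\sum w_i \log y_i$, $\sum w_i \log(1-y_i)$ and $\sum w_i$, each optimizer
evaluation is O(1) after one pass over the data.

Each slice is fitted independently. This is the mechanism by which the
model adapts to depth-dependent attenuation: a dim, deep slice gets its own
threshold, so no global intensity normalization is needed.

### Pre-masking and rescaling

Most pixels in a sparse fluorescence image are background. Before fitting,
pixels strictly below a high percentile of the slice (default the 99th; the
astrocyte preset uses the 98th) are labeled background outright, and only
the retained tail is rescaled (per-slice min-max) to \[0, 1\] and clamped to
$[10^{-6}, 1-10^{-6}]$ — the beta density is unbounded or zero at the
endpoints, so values must stay strictly interior. Percentiles are
*empirical* (inverse ECDF, `quantile` type 1), so every threshold is an
observed intensity value; this matters for heavily quantized 8-bit data,
where ties at the percentile value keep whole saturated structures in the
retained set. Pre-masking operates on raw intensities and rescaling on the
retained values: with per-slice min-max rescaling this is the only
self-consistent order, since rescaling changes as the retained set changes.

### Initialization and why a second start is needed

The classical initialization assigns each value to a random class and
derives starting parameters from the two random halves. That start is
*exchangeable*: both components begin as near-identical fits of the pooled
data, differing only by $O(n^{-1/2})$ noise. Empirically, the EM map for
this model has an attracting fixed point at exactly that configuration
(both components equal to the pooled single-beta fit) — from the random
assignment the iteration settles there even for strongly bimodal data, and
moderate perturbations decay back. `fitBetaMixEM` therefore runs a second
seeded start that splits the data at a random pivot value drawn from the
sample, which breaks the exchangeability, and keeps whichever run attains
the higher final observed log-likelihood. Within each run the ascent
property of EM holds and is checked (the log-likelihood trace is
non-decreasing to $10^{-8}$).

Convergence is declared when the observed log-likelihood changes by less
than `tol` (default $10^{-6}$) or after `maxIter` (200) iterations.

### Thresholding and the single-component fallback

With two detected components the threshold is the crossing point of the
weighted densities: the root of $p_0 f_0(y) = p_1 f_1(y)$ between the two
component means, found by bracketed root finding on the log-density
difference (better conditioned than the difference of densities). If
several sign changes exist between the means, the root nearest their
midpoint is used; if none exists, the slice falls back to the percentile
threshold. Pixels at or above the threshold (and not pre-masked) become
ROI — the boundary pixel is ROI.

A slice is treated as effectively single-component when any of the
following holds:

* the fitted mixing proportion leaves $[\delta, 1-\delta]$
  ($\delta = 0.02$);
* the component means differ by less than 0.02;
* the EM fails to converge from two different seeds;
* a BIC comparison with the single-beta maximum-likelihood fit prefers one
  component ($2\,\Delta\ell < 3 \log n$, three extra parameters).

The first three are cheap heuristics; the BIC rule is the operative model
choice and is what keeps genuinely unimodal slices (uniformly dim, or
uniformly saturated) on the percentile fallback. The fallback threshold is
the 80th percentile of the retained values by default (70th in the
astrocyte preset). Two degenerate cases are distinguished deliberately: a
slice that is constant *before* pre-masking carries no signal and is
labeled entirely background, whereas a retained set that is constant
(e.g. all saturated at 255) is exactly the bright structure we are after
and is labeled entirely ROI via the fallback percentile.

## Denoising

On the binarized stack, a 3D median filter is applied per timepoint. On
binary data the median is a strict majority vote, so the filter preserves
compact shapes and deletes structures thinner than half the window. The
default window of 11 x 11 x 3 voxels is deliberately anisotropic: somas are
roughly isotropic in-plane while z-sampling is coarse, and filaments are
mostly in-plane, so a wide in-plane window removes them while three z-planes
suffice to stabilize the vote. The window volume (363) is odd, so ties are
impossible. Outside-of-volume voxels count as background (zero padding);
this is conservative — the filter can only erode at volume borders, never
create ROI there. A solid sphere wider than the window survives with its
interior intact, eroded by at most the half-window at its surface; a
1-voxel filament of any length vanishes.

## Tracking by 4D connected components

ROI voxels are nodes; two voxels are connected when every coordinate offset
(x, y, z, t) has magnitude at most 1 — the 80-neighborhood of the
3 x 3 x 3 x 3 kernel. A connected component is therefore a single cell
*trajectory*: presence at consecutive timepoints at the same location joins
up automatically, with tolerance to one-voxel drift per timepoint.
Components are labeled deterministically (numbered by their minimal voxel
in (t, z, y, x) order), and the implementation (vectorized neighbor
matching plus union-find) is verified against a breadth-first flood-fill
oracle in the test suite.

**Split-merge.** A timepoint with poor signal splits a cell's component in
two, which would report one lost and one new cell. The merge step joins
components that come within a spatial window (default +/-2 voxels per axis)
of each other at temporal distance up to `gap + 1` (default gap = 1
missing timepoint). Merging is transitive via union-find, hence
order-independent. Setting all spatial half-widths to 0 disables merging
entirely. The right window size depends on registration quality and
acquisition stability, so it is exposed as a tunable; the default is
deliberately small to avoid fusing neighboring cells.

**Size filter.** Components with fewer than 30 voxels *in total across
the whole 4D trajectory* are removed (a 30-voxel component is kept). The
whole-trajectory count follows from treating the component's node set as
one graph; it filters transient speckle while keeping a soma that is
present even at a single timepoint, provided it is large enough.

**Fates.** For each surviving component, the first and last timepoints
with presence define its fate, with the reporting convention that a
component first present at $t+1$ is counted as *new at index* $t$, and one
last present at $t < T$ as *lost at index* $t$. Totals count components
whose $[\mathrm{first}, \mathrm{last}]$ span covers the timepoint —
gap-filled, so a cell bridged across a low-signal timepoint by the merge
step counts as present throughout, and the conservation identity

$$ n_{\mathrm{total}}(t+1) = n_{\mathrm{total}}(t) + n_{\mathrm{new}}(t)
   - n_{\mathrm{lost}}(t) $$

holds exactly on every run. Depth stratification assigns each cell to a
bin (default 100-um increments) by its z-centroid at first presence, with
depth measured from the first z-slice — which reproduces a
micrometres-from-pia convention only if the stack starts at the pial
surface.

## The synthetic-scene generator

There is no public reference dataset for this kind of longitudinal stack,
so validation is against seeded synthetic scenes with known ground truth
(`sceneScript()`, `generateScene()`). A scene emulates:

* background drawn from a Beta(2, 8) on \[0, 255\] (dim, right-skewed);
* somas as solid ellipsoids (default radius 7 voxels in-plane, 2 in z,
  reflecting anisotropic sampling) with a soft 1-voxel edge, intensities
  drawn from Beta(8, 2) scaled by a peak of 600 on the 0-255 scale and
  clipped — so soma cores *saturate* at 255, as bright GFP-filled somas do
  on 8-bit detectors. Saturation is not incidental: ties at 255 are what
  carry a soma through the 99th-percentile pre-mask on small slices, and
  heavily saturated slices are exactly the single-component fallback case
  discussed above;
* per-cell scripted appearance and disappearance timepoints;
* thin (1-2 voxel) straight filaments at intermediate intensity (default
  170), emulating myelin-sheath-like structures that the median filter
  must remove;
* multiplicative depth attenuation $e^{-\lambda(z-1)}$ (default
  $\lambda = 0.01$ per slice);
* optional low-SNR timepoints, rendered by scaling the *fluorescent
  signal* while leaving the background noise floor unchanged. A global
  multiplicative scale would not degrade detection at all — the per-slice
  mixture threshold adapts to any common scale — so contrast itself must
  drop, which is also the physical mechanism (less emission against
  constant autofluorescence and detector noise).

Scene scripts validate that unscripted cells respect a separation margin
(radii plus twice the merge window), so ground-truth components cannot
merge by construction.

The bundled `exampleSceneScript("multifate")` is the end-to-end validation
scene: 64 x 64 x 24 x 6 voxels, 15 cells in two depth layers — 10 stable,
3 appearing at timepoint 4, 2 disappearing after timepoint 2 — plus three
filaments. The acceptance script and test suite run the full pipeline on it
at default parameters and require the recovered fate table to equal the
script exactly. `exampleSceneScript("gap")` scripts one cell with a low-SNR
acquisition at its middle timepoint; without merging the pipeline reports
two components (one lost, one new — the documented failure mode), and the
default merge window repairs it to a single stable cell.

**What the generator does not emulate:** optics (no PSF convolution, no
photon shot noise), registration error (scenes are perfectly aligned, as
the pipeline assumes), touching cells, soma size variability within a
scene, and structured autofluorescence. Passing the synthetic validation
therefore demonstrates the correctness of the algorithmic chain under the
stated model of the data, not performance on real acquisitions — on real
data, registration quality and the pre-mask/fallback percentiles are the
parameters to revisit first.

## Parameters at a glance

| parameter | default (oligodendrocyte) | astrocyte preset | meaning |
|---|---|---|---|
| `premaskPercentile` | 99 | 98 | slice percentile below which pixels are background outright |
| `fallbackPercentile` | 80 | 70 | threshold percentile when one component is detected |
| `minValues` | 50 | 50 | minimum retained pixels to attempt an EM fit |
| `tol`, `maxIter` | 1e-6, 200 | — | EM convergence |
| `medianWindow` | 11 x 11 x 3 | — | denoising window (voxels), odd per axis |
| `cclKernel` | 3 x 3 x 3 x 3 | — | 4D connectivity kernel |
| `mergeHalfwidth`, `mergeGap` | (2, 2, 2), 1 | — | split-merge spatial window and tolerated gap |
| `minComponentSize` | 30 | — | minimum 4D voxel count per cell |
| `depthBinUm` | 100 | — | depth stratification increment (um) |

Problem sizes used in the validation suite (chosen so the full suite runs
comfortably on a single core): EM recovery on 20 seeded draws of n = 10,000
from 0.5 Beta(2,8) + 0.5 Beta(8,2); 50 random intersection-threshold
checks; 20 random 20 x 20 x 6 volumes against the brute-force median
oracle; 50 random stacks up to 15 x 15 x 8 x 5 against the BFS labeling
oracle; 100 random small scenes for fate conservation; and the two bundled
scenes above for end-to-end recovery, split-merge behavior and
byte-identical determinism (including serial vs parallel).

## Known limitations

* Two somas that touch in any frame form one component; there is no
  watershed splitting.
* Cells are not re-identified across registration failures; misalignment
  shows up as spurious lost-then-new pairs.
* The 4D labeling is sequential (the slice fitting and median filtering
  parallelize; the component pass does not).
* Rejecting whole low-quality timepoints is a judgment call left to the
  user; the diagnostics table (per-slice thresholds, component counts,
  fallback usage) is the intended basis for it.
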