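# somatrack

Unsupervised segmentation and tracking of cell bodies (somas) in
longitudinally registered 4D fluorescence microscopy stacks — built for
longitudinal in vivo two-photon imaging of cortical glia (oligodendrocytes,
astrocytes), where the biological readout is cell *fate*: how many cells
are present at each timepoint, how many appear, how many are lost, and how
those counts distribute over cortical depth.

No training data, no GPU. The pipeline is:

1. **Beta-mixture binarization, per 2D slice.** Intensities of each (z, t)
   slice are pre-masked at a high percentile (default 99th), min-max
   rescaled to [0, 1], and modeled as a two-component beta mixture
   `p0·Beta(α0, β0) + p1·Beta(α1, β1)` fitted by EM (M-step via
   `stats::optim` on the weighted beta log-likelihood). The binarization
   threshold is the crossing point of the weighted component densities,
   the root of `p0·f0(y) = p1·f1(y)` between the component means; when
   only one component is supported (BIC vs a single beta, degenerate
   mixing, or non-convergence) the slice falls back to a percentile
   threshold (default 80th). Per-slice fitting is what absorbs
   depth-dependent signal attenuation.
2. **Anisotropic binary median filter** (default window 11 × 11 × 3, per
   timepoint): a strict-majority vote that erases thin filamentous
   structures (myelin sheaths) and impulsive noise while preserving
   compact soma cores.
3. **4D connected-component labeling** (kernel 3 × 3 × 3 × 3, i.e. all 80
   surrounding offsets in x, y, z, t): one component = one tracked cell
   across space and time. A temporal split-merge step (default ±2 voxels,
   1-timepoint gap) rejoins trajectories broken by a low-SNR acquisition,
   and components with fewer than 30 voxels are removed.
4. **Fate reporting.** Per-timepoint totals, new and lost cells (reported
   at the preceding timepoint index), satisfying
   `n_total(t+1) = n_total(t) + n_new(t) − n_lost(t)` exactly; optional
   100-µm depth strata; per-cell CSV (unique id, centroid in voxels and
   µm, size); per-cell cropped TIFF stacks for rapid visual verification.

Because no reference dataset of this kind is public, the package ships a
seeded synthetic-scene generator with exact ground truth (saturating
ellipsoidal somas, scripted appearance/disappearance, filament noise,
depth attenuation, low-SNR timepoints) and validates the whole chain
end-to-end against it. See the vignette
(`vignettes/soma-segmentation-and-tracking.Rmd`) for the model, every
tunable, and the generator's scope and limits.

## Worked example

```r
library(somatrack)

## a synthetic 64 x 64 x 24 x 6 scene with known ground truth:
## 15 cells - 10 stable, 3 appearing at t = 4, 2 disappearing after t = 2
scene <- generateScene(exampleSceneScript("multifate", seed = 1))
scene$stack
#> ImageStack4D: 64 x 64 x 24 voxels, 6 timepoint(s)
#>   voxel size (um): 0.5 x 0.5 x 2
#>   intensity range: [0, 255]

res <- runPipeline(runConfig(outputDir = "out", seed = 1),
                   stack = scene$stack)
res$components
#> CellComponentSet: 15 component(s), 5824 ROI voxel(s), stack 64 x 64 x 24 x 6

res$fates
#>   timepoint n_total n_new n_lost
#> 1         1      12     0      0
#> 2         2      12     0      2
#> 3         3      10     3      0
#> 4         4      13     0      0
#> 5         5      13     0      0
#> 6         6      13     0      0
```

The fate table reads: 12 cells at baseline; the 2 cells lost after t = 2
are reported at index 2 (`n_lost`); the 3 new cells first present at t = 4
are reported at index 3 (`n_new`); totals obey the conservation identity.
Here the recovered table equals the scripted ground truth row for row.

Per-cell records carry unique ids, presence spans, sizes and centroids in
voxels and micrometres:

```r
head(res$cells[, c("cell_id", "first_t", "last_t", "size_total",
                   "x_um", "y_um", "z_um")], 4)
#>   cell_id first_t last_t size_total     x_um      y_um    z_um
#> 1       1       1      6        505  4.53012  4.457831 11.9759
#> 2       2       1      6        506 26.50000  4.500000 12.0000
#> 3       3       1      6        497 15.55063  4.512658 12.0000
#> 4       4       1      6        515 26.50000 15.500000 12.0000
```

`runPipeline()` also writes the denoised binary stack and label stack
(multi-page TIFF), `cells.csv`, `fates.csv`, a per-slice fit diagnostics
CSV and a JSON manifest of the effective parameters into `outputDir`.
Real data enter through `readStack()` (one multi-page TIFF per timepoint,
or a single hyperstack); `exportCrops()` writes per-cell crops for review.
A thin command-line wrapper with `run`, `simulate`, `fit-slice` and
`report` subcommands is installed under `exec/somatrack`.

Presets: `runConfig(preset = "oligodendrocyte")` (pre-mask 99th /
fallback 80th percentile, the default) and `preset = "astrocyte"`
(98th / 70th).

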