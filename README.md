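# speckle4d

Processing pipeline for **burst-mode 4D optical coherence microscopy (OCM)**
time-lapses of multicellular spheroids embedded in collagen gels — the
label-free imaging setting used to watch cancer-cell invasion and the matrix
deformations it causes, en route to volumetric traction-force microscopy.

OCM gives no fluorescent labels. What it does give is coherent speckle, and
speckle carries a clock: over the ~12–15 s between the N = 8 volumes of an
acquisition *burst*, intracellular motion fully rescrambles the speckle of
live cells while the speckle of quasi-static collagen stays frozen. For burst
frames $S_i(x,y,z,t)$ the pipeline computes the per-voxel burst statistics

$$\bar S = \frac{1}{N}\sum_{i=1}^{N}|S_i|, \qquad
S_\sigma = \sqrt{\frac{1}{N-1}\sum_{i=1}^{N}\left(|S_i|-\bar S\right)^2},$$

and from them synthesises a **'cell' channel** ($S_\sigma$, bright where
speckle decorrelates) and a **'collagen' channel** ($\bar S$ with segmented
cell voxels zeroed). Around this core the package implements the full
processing chain:

* **drift correction** — sub-pixel (0.01-voxel) lateral drift from 3D
  cross-correlation of four peripheral sub-volumes, median-combined, applied
  as a spectral phase ramp;
* **channel synthesis** — 768:400 isotropic down-sampling (to the
  (1.88 µm)³ / (2.34 µm)³ voxels of the mono-/co-culture settings) and
  median-based depth-background removal;
* **4D segmentation** — 5×5×5 median filter, Otsu threshold, largest
  connected component at t = 0, then 4D region growing (a component survives
  iff it overlaps the previous cleaned mask);
* **deformation tracking** — multi-resolution Thirion demons registration
  (3 pyramid levels, 100 iterations/level, accumulated-field smoothing
  σ = 2 voxels) of the t = 0 collagen channel onto every later time-point up
  to a 24-h horizon, plus a displacement noise-floor estimator;
* **a synthetic phantom generator** with exact ground truth (Rayleigh
  collagen speckle, AR(1)-decorrelating cell speckle, analytic contraction
  fields, drift, depth background, noise) that makes every stage falsifiable;
* **design/accounting utilities** — the cylindrical-lens rule f²/d for
  coherence-gate-curvature compensation and the raw-data budget
  (≈24 GB/burst, ≈1.75 TB/series).

## Worked example

Simulate a desk-scale phantom (64×64×48 voxels at 1.88 µm, contracting and
drifting, growing spheroid) and run the full pipeline against its ground
truth:

```r
library(speckle4d)

spec <- phantom_spec(grid = voxel_grid(c(64L, 64L, 48L), pitch = 1.88),
                     radius_um = 22, protrusion_length_um = 10,
                     protrusion_width_um = 6,
                     drift_um_per_step = c(1.88, 0),   # 1 voxel/step
                     growth_um_per_step = 0.5, seed = 7)
cfg <- pipeline_config(seed = 7,
                       demons = list(pyramid_levels = 2,
                                     iterations_per_level = 50))
man <- run_pipeline(cfg, phantom = spec, t_points = 3)
print(man)
summarize_run(man)
```

```
<run_manifest> speckle4d 0.1.0 seed 7
stages (s): input=2.1, projections=0.1, drift=0.2, drift_correct=0.1, downsample=0.1,
            background=0.0, segmentation=0.2, collagen_channel=0.0, tracking=1.1, validation=0.0
validation: drift max err 0.010 vox; Dice min 0.879; collagen-on-mask max 0
field RMSE (vox): 0.053, 0.100
  t_min mask_voxels cum_dx_vox cum_dy_vox mean_disp_um      dice
1     0         758       0.00          0     0.000000 0.8798607
2    40         819       1.00          0     1.202850 0.8787554
3    80         959       2.01          0     1.992921 0.9304136
```

Reading the report: the simulated drift of exactly 1 voxel/step is recovered
as 1.00/2.01 cumulative voxels (max error 0.01 voxels); the cleaned cell
mask overlaps the true mask with Dice 0.88–0.93 and grows with the phantom;
the collagen channel is identically zero on the mask; and the demons field
tracks the ramped contraction with 0.05–0.10 voxel RMSE against the true
field, the mean off-mask displacement growing with the contraction schedule.

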