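# cortimap

Multi-scale mapping of cortical bone surface changes from longitudinal
micro-CT.

Longitudinal in vivo µCT studies of the mouse tibia monitor how the
cortical surfaces — the outer periosteum and the inner endosteum — move
between scans. In growing animals two processes are superimposed:
appositional **growth**, which displaces the whole surface smoothly, and
focal **remodelling**, which resorbs and re-forms bone in patches of tens
of micrometres. `cortimap` separates the two by spatial frequency:

1. each scan is smoothed (3D Gaussian, σ = 0.65 voxels, 3×3×3 kernel) and
   segmented with a global Otsu threshold;
2. every closed surface is represented by a signed-distance level-set
   field Φ (positive inside). Because |∇Φ| = 1, the outward-normal
   displacement at a baseline surface voxel v between two time points is
   simply Δ(v) = (Φ_{t+1}(v) − Φ_t(v)) · h, with h the voxel size in µm;
3. the per-surface change field is unwrapped into a 2D map S(θ, z) over
   the angle to the posterior direction and the bone height;
4. S is decomposed with a 2D dual-tree complex wavelet transform
   (4 levels; 14-tap q-shift filters above level 1). The terminal scaling
   band reconstructs the **low-spatial-frequency** (growth-like) pattern;
   the detail bands, soft-thresholded at τ = median(|d*|)/0.6745 (MAD),
   reconstruct the **high-spatial-frequency** (remodelling-like) pattern.
   One coarse coefficient spans 2⁴ rows = 166.4 µm of bone height at
   10.4 µm voxels;
5. accuracy and activity are summarised by RMSD against ground truth,
   activation rates r = A_r/A_s, and spatially averaged profiles.

The package includes a synthetic phantom generator and a four-scenario
accuracy study (null / uniform growth c = 3 voxels / random local activity
with amplitude a = 3 voxels at rate b = 0.3 in a height band / combined)
with exact ground truth, so the whole framework is testable without any
scan data.

## Worked example

```r
library(cortimap)

# a synthetic "combined" scenario: growth of 3 voxels plus local activity
# (a = 3, b = 0.3) in the central third of the bone height, re-voxelised,
# with 5% intensity noise and 0.3-voxel misalignment of the follow-up
spec <- scenario_spec("combined", c = 3, a = 3, b = 0.3, seed = 1,
                      noise_sd = 0.05, misalign_sd = 0.3)
run <- run_scenario(spec)   # default 160 x 160 x 480 tube phantom
run$report
#>   scenario band  rmsd_um      n       q05       q25         q50        q75      q95
#> 1 combined  low 2.184138 132160 -4.010877 -2.698638 -1.50021352 -0.3363193 1.274642
#> 2 combined high 6.339874 132160 -6.819544 -1.648565 -0.09265782  1.8879957 5.116021
c(low_voxels = run$rmsd_low_voxel, high_voxels = run$rmsd_high_voxel)
#>  low_voxels high_voxels
#>   0.2100132   0.6096033
```

The imposed 31.2 µm growth is recovered by the low-frequency pattern to
about a fifth of a voxel RMSD, and the imposed local activity by the
high-frequency pattern to about two thirds of a voxel — inside the ~1.5
and ~0.7 voxel error envelopes established for this class of framework on
real repeated scans (the high-band figure is dominated by the one-voxel
quantisation floor of a surface derived from a segmentation).

Individual stages are exported for direct use: `read_volume()`,
`gaussian_smooth()`, `otsu_segment()`, `rigid_register()`, `select_voi()`,
`label_surfaces()`, `signed_distance()` / `surface_field()`,
`geometry_change()`, `extract_zero_surface()`, `hausdorff_distance()`,
`unwrap_surface()` / `backproject()`, `dtcwt_forward()` / `dtcwt_inverse()`,
`mad_threshold()`, `soft_threshold()`, `synthesize_patterns()`, `rmsd()`,
`activation_rate()`, `spatial_profiles()`, `run_pipeline()`,
`run_evaluation()`. A thin command-line wrapper with `segment`, `track`,
`simulate`, `evaluate` and `profiles` subcommands is installed at
`inst/cli/cortimap.R`.

See the methods vignette (`vignettes/cortimap-methods.Rmd`) for the model,
the filter design, boundary handling, and what the phantom study does and
does not demonstrate about real scans.

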