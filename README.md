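# plaquediff

Automatic comparison of coronary artery plaque thickness between a
baseline and a follow-up acquisition.

Longitudinal studies of coronary artery disease need to know *where* and
*by how much* plaque has progressed or regressed between two CCTA scans.
Comparing scans slice by slice is slow and viewing-angle dependent:
upstream segmentation delivers stacks of paired lumen and vessel-wall
cross-sectional contours per artery, but the two acquisitions live in
different scanner coordinate frames and carry no point correspondence.
`plaquediff` closes that gap for image-analysis researchers working with
contour-level coronary data: it turns the two contour trees into
corresponding smooth surfaces and maps the local thickness change on
every surface point.

## Method

For each branch, plaque thickness at a surface point is the distance from
the lumen surface to the corresponding vessel-wall surface point,
`Thic(v) = || x_wall(v) - x_lumen(v) ||`, and the longitudinal readout is
the per-vertex signed difference

```
DIF_thickness(v) = FU_Thic(v) - BL_Thic(v)      (positive = progression)
```

classified against a clinical threshold (`|DIF| <= 0.5 mm` = no change,
`> 0.5` increase, `< -0.5` decrease). Correspondence — the hard part —
is never searched for; it is constructed:

1. **Subdivision surfaces from one coarse mesh.** Each branch gets a
   coarse mesh of hexagonal rings along its centerline; Loop subdivision
   refines it into a smooth tube, and an iterative fit pushes every
   vertex along its normal by its signed distance to the axially
   interpolated target contour (plus Laplacian regularisation). The
   lumen surface is fitted first and then re-fitted outward to the wall
   contours, so lumen and wall vertices correspond by construction.
2. **Rigid coherent point drift (CPD) registration.** Branch centerlines
   (lumen-contour centroids, cubic-spline resampled at 0.5 mm) of the
   follow-up tree are registered onto the baseline as a pooled point
   cloud; the CPD posterior is resolved into a one-to-one point
   correspondence with per-point residual translation vectors
   `T(x_i) = y_k - x_i'`.
3. **Coarse-mesh transfer.** The follow-up coarse mesh is mapped into
   baseline coordinates ring by ring (`y_k^j = T(x_i) + x_i^j`) and used
   to fit the baseline surfaces, so all four surfaces (BL/FU x
   lumen/wall) share one vertex ancestry and can be differenced
   vertex-wise.

A synthetic module generates multi-branch tubular artery trees with
circular cross-sections, applies plaque edits with known ground truth
(lumen/wall radius changes over an axial window) and rigid pose
perturbations with contour jitter, reproducing the published ten-case
artificial validation suite.

## Worked example

```r
library(plaquediff)

bl <- generate_tree(tree_config())                       # baseline tree
ed <- apply_plaque(bl, plaque_spec("LAD", s0 = 27.5, L = 4,
                                   dR_lumen = -0.5))     # plaque: +0.50 mm
fu <- make_followup(ed$tree, rotation = 10, axis = c(0.2, 1, 0.4),
                    translation = c(5, 3, -2), noise_sd = 0.05, seed = 7)

report <- run_compare(bl, fu, pipeline_config())
#> [plaquediff] rigid CPD              326 FU -> 326 BL points, w=0.1
#> [plaquediff] correspondence         325 pairs, 1 unmatched FU, 1 unmatched BL
#> [plaquediff] fit LAD                RMS residuals (mm): 0.004 0.005 0.004 0.005
#> [plaquediff] difference             mean 0.013 sd 0.086 mm over 31080 vertices
print(report)
#> plaquediff comparison report
#>   registration: 325 pairs, sigma2 0.0002072, 15 EM iterations
#>   DIF_thickness: mean +0.013 sd 0.086 min -0.220 max +0.613 mm (n=31080)
#>   classified: 0.8% increase, 0.0% decrease (threshold 0.50 mm)

region_stats(report$diff, branch = "LAD", window = ed$truth[[1]]$interior)
#> edited region: mean 0.48 +/- 0.06 mm over 552 vertices (created +0.50)
```

The 0.5 mm lumen shrinkage placed on the LAD is recovered as a mean
difference of 0.48 mm confined to the edited window, while the rest of
the tree stays near zero despite the 10 degree / 6 mm pose change and
0.05 mm contour jitter between the two "acquisitions". `run_compare(...,
outdir = "out/")` additionally writes `report.json` plus colored PLY/VTK
meshes (continuous diverging map, and the thresholded red = increase /
yellow = decrease rendering).

A thin command-line front end wraps these functions:

```sh
Rscript inst/cli/plaquediff.R synth   --out data/ --seed 1
Rscript inst/cli/plaquediff.R compare --bl data/case01_bl.json \
        --fu data/case01_fu.json --out out/
Rscript inst/cli/plaquediff.R table2  --out out/
```

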