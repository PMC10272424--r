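# hemomap

Atlas-based mapping of intracerebral hemorrhage (ICH) on brain CT, and
prediction of stroke-associated pneumonia (SAP) from the resulting lesion
features.

Pulmonary infection is a frequent, dangerous complication of hemorrhagic
stroke. Where a hematoma sits in the brain — and how hard it presses on the
surrounding tissue — carries information about a patient's risk of
developing pneumonia, because lesions of structures involved in
consciousness and swallowing compromise airway protection. `hemomap`
implements the full image-analysis chain that turns a brain CT and a binary
hemorrhage segmentation into that risk signal:

1. **Preprocessing** — automatic skull-stripping (bone threshold +
   morphology + connected components), min-max intensity normalization
   `v' = (v - min) / (max - min)`, and resampling onto the atlas grid.
2. **Registration** — alignment of the CT (moving image `I_m`) to a
   reference atlas (fixed image `I_f`) by maximizing the binned mutual
   information
   `MI(X, Y) = Σ_ij p(i,j) log2[ p(i,j) / (p_x(i) p_y(j)) ]`,
   first with a similarity transform (translation, rotation, isotropic
   scale) under a multi-resolution pyramid, then with a cubic B-spline
   free-form deformation: the composite transform is
   `T = T_similarity + T_nonrigid`.
3. **Lesion transfer** — the hemorrhage mask is carried through the same
   composite transform into atlas space with nearest-neighbor
   interpolation.
4. **Features** — for each of the 35 atlas structures *i*, the
   bleeding-distribution feature `Bd_i = BNum_i / AllNum_i` (lesion voxels
   on structure *i* over the structure's size), plus 8 bleeding-extrusion
   features: CSF, parenchyma and hemorrhage volumes (voxel counts from
   Hounsfield windows) and their five mutual ratios.
5. **Prediction** — stratified 10-fold cross-validation of logistic
   regression, an RBF support-vector machine and a random forest on the 43
   features, for two tasks: any pneumonia vs none, and moderate-or-worse vs
   the rest; feature importance from an L1-penalized logistic fit.
6. **Statistical maps** — per-category voxelwise probability maps (the
   fraction of patients in a pneumonia category whose hemorrhage covers a
   voxel), hemisphere mass comparison, and box-plot summaries of the
   hemorrhage/brain-tissue volume ratio.

Because no patient imaging ships with the package, a first-class **phantom
module** generates a fully synthetic study: a 35-structure ellipsoidal
brain atlas, subject CTs derived from it by known random similarity +
smooth deformations with tissue intensities in clinically typical
Hounsfield windows, and category-dependent ellipsoidal hemorrhages (volume
medians increasing with pneumonia severity; severe lesions biased to the
left hemisphere). Every subject stores its ground-truth transform, lesion
footprint and tissue tallies, so registration error, feature fidelity and
classifier recovery are all measurable exactly.

## Worked example

```r
library(hemomap)

# a small synthetic study: 40 subjects on a 32-voxel grid
res <- run_demo(seed = 7, grid_size = 32, n_subjects = 40,
                out_dir = "demo_out")

res$metrics$logistic_sap_any
#> <sap_cv> logistic on sap_any, 10-fold
#>   AUC 0.975 | accuracy 0.855 | sensitivity 0.767 | specificity 0.950

res$ratio_summary[, c("category", "n", "median", "mean")]
#>   category  n     median       mean
#> 1     none 19 0.01551095 0.01787420
#> 2     mild  9 0.03955254 0.04397365
#> 3 moderate  6 0.04422944 0.04932052
#> 4   severe  6 0.11017290 0.14435972
```

The AUC is the 10-fold cross-validated area under the ROC curve for
predicting *any* pneumonia from the 43 lesion features — the planted
volume/location signal is recovered well above chance. The ratio summary
shows the hemorrhage-to-brain-tissue volume ratio increasing monotonically
with pneumonia severity, the trend the box plot visualizes
(`plot(res$ratio_summary)`). Probability maps for each category are written
as NIfTI files (`demo_out/probmap_*.nii.gz`) for overlay in any viewer.

Individual stages are exposed directly: `make_cohort()`, `strip_skull()`,
`minmax_normalize()`, `register_similarity()`, `register_bspline()`,
`apply_to_mask()`, `distribution_features()`, `extrusion_features()`,
`crossval()`, `feature_weights()`, `probability_map()`, `ratio_summary()`.
A thin command-line wrapper lives at `inst/cli/hemomap.R`.

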