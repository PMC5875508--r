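# atlasseg

Hierarchical multi-atlas segmentation of organs at risk on thoracic and
abdominal CT, in R.

Soft-tissue organs of the trunk — liver, spleen, kidneys — are adjacent
and imaged at nearly the same Hounsfield units, so threshold- or
region-based autosegmentation fails on them. `atlasseg` segments them in
two stages:

1. **Bulk localisation by multi-atlas label transfer.** Each
   presegmented reference scan (atlas) is registered to the patient —
   a two-phase affine initialisation (translations first, then full
   affine) followed by masked multi-resolution cubic B-spline
   deformable registration, both driven by Mattes mutual information
   `MI(F, M ∘ T) = Σ p(f,m) log p(f,m) / (p(f) p(m))`, with the metric
   restricted to the atlas organ masks dilated by a 1 cm margin. The
   warped per-atlas organ masks are fused by the **STAPLE** EM
   algorithm, which estimates a voxelwise organ probability `w` together
   with each atlas's sensitivity/specificity, and the probability map is
   thresholded at 0.7.
2. **Per-structure level-set refinement.** The organ HU interval is
   extracted automatically from the fused shape by 125-bin multi-level
   Otsu analysis; a threshold level set
   (`φ_t = −S|∇φ| + 0.5 κ|∇φ|`, 500 iterations) adapts the shape to
   that interval, and a geodesic level set (curvature weight 3,
   30 iterations, edge image `g = 1/(1+|∇G_σ∗I|)`) smooths it and
   recovers weak-edge regions such as motion-blurred organ poles.

Overlap metrics (Dice, symmetric mean surface distance, Hausdorff),
NIfTI I/O, a deterministic synthetic phantom generator with analytic
ground-truth transforms, a directory watch service and a CLI complete
the toolkit. See the methods vignette
(`vignettes/atlasseg-methods.Rmd`) for the models, parameter meanings
and design decisions.

## Worked example

Generate the standard synthetic case — a 64³ CT-like patient at 2.5 mm
voxels with liver/spleen/kidneys/lungs plus three deformed, reposed,
intensity-remapped atlases — and run the full pipeline:

```r
library(atlasseg)

case <- generatePhantom(phantomSpec(seed = 5))
organs <- c("liver", "spleen", "kidney_l", "kidney_r", "lung_l")
res <- segment(case$patient, phantomAtlasLibrary(case), organs,
               config = phantomSegmentationConfig(seed = 2))

reportSummary(res$report)
#>      organ status meanDiceToFused     meanP     meanQ
#> 1    liver     ok       0.9856482 0.9852104 0.9912977
#> 2   spleen     ok       0.9600785 0.9712069 0.9774901
#> 3 kidney_l     ok       0.9280743 0.9119694 0.9806412
#> 4 kidney_r     ok       0.9518011 0.9612153 0.9800475
#> 5   lung_l     ok       0.9874001 0.9825868 0.9956234

for (o in organs)
  cat(sprintf("%s refined dice %.4f msd %.3f\n",
              o, dice(res$masks[[o]], case$truth[[o]]),
              meanSurfaceDistance(res$masks[[o]], case$truth[[o]])))
#> liver refined dice 0.9857 msd 0.264
#> spleen refined dice 0.9974 msd 0.030
#> kidney_l refined dice 0.9703 msd 0.247
#> kidney_r refined dice 0.9402 msd 0.468
#> lung_l refined dice 1.0000 msd 0.000
```

`meanDiceToFused` is each organ's average agreement between the three
warped atlas masks and their STAPLE consensus; `meanP`/`meanQ` are the
EM-estimated atlas sensitivities and specificities. The final lines
score the refined masks against the phantom's ground truth: Dice (1 is
a perfect match) and mean surface distance in mm (0 is ideal). The run
takes about five minutes on one CPU.

A command-line interface wraps the same functions
(`exec/atlasseg segment|fuse|refine|evaluate|phantom|watch`), e.g.

```sh
exec/atlasseg phantom --out ph --seed 7
exec/atlasseg evaluate --auto ph/truth_liver.nii.gz \
                       --manual ph/truth_liver.nii.gz --report r.json
```

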