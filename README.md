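# myostrain

Myocardial strain quantification from short-axis cine cardiac MRI by dense
displacement-field regression.

## What this package does

Clinically, myocardial strain is measured from tagged CMR, but tagging costs
extra acquisitions and specialized post-processing (e.g. sine-wave-modeling
of tag patterns). `myostrain` implements the alternative: spatiotemporal
encoder–decoder networks (**MyoNet** and **ResMyoNet**, five-level U-Nets
with alternating spatial `1×3×3` / temporal `3×1×1` kernels and dilated deep
levels) regress per-frame x/y displacement fields directly from binary
myocardium mask sequences of the cine acquisition. Predicted fields are
mapped back from a bounded normalized scale through an exact inverse affine
transform and converted to strain via the Lagrangian finite-deformation
pipeline:

    F = I + ∇u,   E = ½(FᵀF − I),
    Ecc = e_cᵀ E e_c,   Err = e_rᵀ E e_r,

with gradients by masked central finite differences and segment averaging
over the six AHA sectors. Method agreement is assessed with SSIM, RMSE, mean
endpoint error, ICC(2,1), Pearson r, coefficients of variation, Bland–Altman
limits of agreement, and per-segment paired t-tests with Bonferroni
correction.

Because the original in-vivo rat data are restricted, the package includes a
**synthetic deforming-annulus phantom**: an annular LV wall contracts
radially (endocardium inward, epicardium fixed) and twists rigidly under a
raised-cosine time course, with displacement and per-segment Ecc/Err
available in closed form. The phantom drives the entire test suite — strain
oracle equivalence, rigid-motion nullity, loss exactness, normalization
round trips, scan-level split leakage audits, flip-augmentation invariance,
and a desk-scale end-to-end training/recovery experiment.

The training targets are three losses on the normalized scale (MSE +
smooth-L1 with joint branch condition + a foreground-masked term that
concentrates error where the tagged displacement is defined), optimized with
RMSprop. No deep-learning framework exists in this R stack, so the package
carries its own CNN engine (im2col + BLAS, hand-derived backprop, verified
against numerical gradients in the tests).

## Worked example

```r
library(myostrain)

spec <- phantom_spec()        # 128x128, 20 frames, annulus 6-12 mm @ 0.25 mm/px
spec
#> <phantom_spec> 128px, 20 frames, annulus [6, 12] mm @ 0.25 mm/px,
#>   contraction 0.25, twist 0.1 rad, peak frame 9, seed 1

ph <- make_phantom(spec)
ph$displacement
#> <displacement_sequence> phantom-0001/slice: 20 frames of 128x128, |u| max 1.59 mm

tab <- strain_analysis(ph$displacement)
tab[tab$frame == spec$peak_frame, ][1:6, ]
#>   frame segment n_pixels Ecc_percent Err_percent
#> 1     9 1            906       -7.72        28.9
#> 2     9 2            902       -7.66        29.0
#> 3     9 3            906       -7.72        28.9
#> ...
```

At the peak frame the dense pipeline reports wall-averaged Ecc ≈ −7.7 %
(circumferential shortening) and Err ≈ +28.9 % (radial thickening) per
segment; the closed-form values are −7.69 % and +28.9 %, so the numerical
strain chain agrees with the analytic motion to ≈ 0.1 % strain. A full
phantom → split → train → predict → strain → agreement experiment runs with

```r
res <- run_pipeline(n_scans = 8, variant = "myonet",
                    base_channels = 8, epochs = 30, seed = 1)
res$report
#> <agreement_report>
#>   SSIM x/y: 0.7975 / 0.7348; RMSE x/y: ... mm; EPE 0.529 mm
#>   Ecc: ICC ..., bias 1.94%
#>   ...
```

A thin CLI wraps the same functions (`inst/cli/myostrain phantom|strain|pipeline ...`).

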