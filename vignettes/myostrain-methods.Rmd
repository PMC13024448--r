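---
title: "Methods: displacement-regression strain analysis on a synthetic cardiac phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: displacement-regression strain analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`myostrain` quantifies left-ventricular myocardial strain from short-axis cine
CMR by regressing dense in-plane displacement fields directly from binary
myocardium mask sequences with spatiotemporal convolutional networks, then
converting the fields to circumferential (Ecc) and radial (Err) Green–Lagrange
strain averaged over the six AHA segments. Real rat acquisitions with
tagging-derived (SinMod-style) reference displacement are not redistributable,
so the package ships a synthetic deforming-annulus phantom with closed-form
motion, displacement and strain, and every end-to-end claim in the test suite
is validated against that analytic ground truth.

## The phantom and what it does (and does not) emulate

The phantom is an annular wall of inner radius $R_i$ and outer radius $R_o$
(defaults 6 and 12 mm, 0.25 mm/px on a 128×128 grid, 20 frames) whose material
points move radially and twist rigidly:

$$\varphi_t(r, \theta) = \bigl(r - a(t)\,g(r),\; \theta + \beta(t)\bigr),
\qquad g(r) = R_i\,\tfrac{1}{2}\bigl(1 + \cos \pi s\bigr),\;
s = \tfrac{r - R_i}{R_o - R_i}.$$

Both amplitudes follow a raised-cosine ramp, zero at frame 0 (the
end-diastolic Lagrangian reference), maximal at `peak_frame`, returning to
zero — a smooth systole/diastole surrogate. Because $g(R_i) = R_i$ and
$g(R_o) = 0$, the endocardium contracts by the fraction $a$ while the
epicardium stays fixed: the wall thickens as it contracts, masks visibly
deform (so the motion is learnable from mask input), and the circumferential
and radial stretches have closed forms
$\lambda_c = r'/r$ and $\lambda_r = 1 - a\,g'(r)$, giving
$E_{cc} = (\lambda_c^2 - 1)/2$ and $E_{rr} = (\lambda_r^2 - 1)/2$ pointwise
and, by radial quadrature, exactly per segment. An incompressible radial map
was considered and rejected: its stretches lack convenient closed forms, and
oracle simplicity matters more here than physiological fidelity. The rigid
twist adds realism to the displacement fields while provably contributing
zero strain — a free null test.

Defaults were chosen once as physiologically sensible for a small-animal
short-axis slice: peak endocardial contraction 0.25 (endocardial
$E_{cc} \approx -22\%$, wall-averaged $E_{cc} \approx -7.7\%$,
$E_{rr} \approx +29\%$), twist 0.1 rad, displacement amplitude ≈ 1.5 mm.
Cohorts jitter amplitudes and radii by ±15 % and the center by ±1.5 px to
mimic animal-to-animal variability. The phantom does **not** simulate MR
contrast, tag fading, noise in the cine images, through-plane motion, or
non-annular anatomy; passing tests therefore demonstrate correctness of the
machinery (normalization, networks, losses, strain, statistics) under known
motion, not clinical performance on real data.

## Invertible displacement normalization

Reference displacement fields arrive as signed mm on the frame-0 grid.
For network training they are affinely mapped to 8-bit-style intensities,
$d \mapsto 32 + (d + d_{max})\cdot 223/(2 d_{max})$, divided by 255, with
background fixed at exactly 0. Foreground values therefore live in
$[32/255 \approx 0.1255,\ 1]$; the constant 0.125 separates background from
foreground everywhere downstream (the masked loss and the inverse mapping
use the same threshold). Dividing by 255 (rather than 256) makes the upper
bound exactly 1.0; the often-quoted lower bound 0.125 is the rounded value
of 32/255. One symmetric scale $d_{max}$ is shared by both components —
fitted on the training scans only, padded by a 10 % margin so held-out data
rarely clamps — and stored in a JSON sidecar so the inverse map is exactly
reproducible. The inverse is algebraic; round trips are exact to well below
1e-9 mm.

## Network architectures

Both variants are five-level spatiotemporal U-Nets mapping a
$(1, T, H, W)$ binary mask tensor to a $(2, T, H, W)$ normalized
displacement tensor. Each level pairs a spatial $1{\times}3{\times}3$
convolution with a temporal $3{\times}1{\times}1$ convolution (the
alternating-kernel idea); the two deepest encoder levels dilate them
($1{\times}2{\times}2$ spatially, $2{\times}1{\times}1$ temporally) to widen
the receptive field without losing resolution. Pooling is spatial-only
$1{\times}2{\times}2$: with five levels a 20-frame axis cannot be halved
repeatedly, and temporal context is instead integrated by the temporal
kernels and dilations. The decoder mirrors the encoder with
nearest-neighbor $1{\times}2{\times}2$ upsampling (checkerboard-free,
unlike transposed convolution) and skip concatenation; a final
$1{\times}1{\times}1$ convolution with a sigmoid bounds outputs to the
normalized scale. MyoNet levels are conv–BN–ReLU pairs; ResMyoNet levels
are residual blocks (conv–BN–ReLU–conv–BN main path, identity or
$1{\times}1{\times}1$ projection shortcut, tanh after the sum). The channel
schedule is $16 \to 32 \to 64 \to 128 \to 256$ at full scale (here capped by
`base_channels` 8 for desk-scale runs) — chosen so CPU training is feasible;
the reference description leaves channel widths open.

No deep-learning framework is available in this R stack, so the engine is
part of the package: im2col convolutions over BLAS matrix products with
hand-derived backward passes for every layer (convolution, batch
normalization, activations, pooling, upsampling, concatenation). The test
suite verifies each backward pass against central-difference numerical
gradients, and whole-network gradients were checked the same way during
development. Initialization is Kaiming fan-in with a seeded RNG; builds and
forward passes are bit-reproducible given the configuration seed.

Two readings of "alternating kernels" exist (within-level pairs versus
across levels); the within-level pair is implemented. Dilation is applied
at the two deepest encoder levels, the natural reading of "dilation in
deeper layers".

## Losses

Training minimizes the unweighted sum of three terms on the normalized
scale. Writing $d_x = x - \hat{x}$, $d_y = y - \hat{y}$ per pixel:

* **MSE**: per-frame pixel mean of $d_x^2 + d_y^2$, averaged over frames.
  The source formulation writes per-frame sums; the pixel mean is adopted so
  the loss does not scale with image area.
* **Smooth L1**: $0.5(d_x^2 + d_y^2)$ where both $|d_x| < 1$ and
  $|d_y| < 1$, else $|d_x| + |d_y| - 0.5$, averaged over pixels and frames.
  The branch condition couples the components exactly as printed; the
  formula is continuous where a single component crosses the kink.
* **Masked foreground loss**: squared error restricted to pixels whose
  *target* components both exceed 0.125, normalized by the per-frame
  foreground count $m$ (0 when $m = 0$). Thresholding the target rather
  than the prediction keeps gradients alive precisely where the network is
  wrong — thresholding predictions would zero gradients exactly where
  learning is needed.

All three and their exact sum are tested to 1e-12 against naive double-loop
oracles.

## Training protocol

RMSprop (learning rate $10^{-3}$, smoothing constant 0.99, batch size 4),
100 epochs at full scale with model selection by best validation loss;
desk-scale runs use 30 epochs. No learning-rate schedule is applied: the
protocol names only an initial rate, and a constant rate is the simplest
consistent reading. Splitting is at the scan level (80/10/10 with
`max(1, round(·))` for the small sets so tiny cohorts keep validation and
test scans) — slices of one scan never cross sets, which the suite audits
over a thousand seeded cohorts. Augmentation flips images horizontally or
vertically with probability 0.5 per axis per sample per epoch, negating the
displacement component parallel to the flip on the signed scale through the
affine normalization; joint flips provably leave every loss term invariant.

One initialization refinement proved important at desk scale: the head bias
starts at the logit of the mean training target ("prior matching"), so the
sigmoid output begins at the data's mean level rather than 0.5 and the few
dozen optimization steps of a 30-epoch desk run fit displacement structure
rather than the background level. This roughly halved the desk-scale
training loss at fixed epochs.

Training accuracy is reported as $1 - \mathrm{MSE}$ on the normalized
scale; since that scale has unit dynamic range, the MSE needs no further
normalization.

## Strain computation

Displacements are Lagrangian from frame 0. Per frame: convert mm to pixel
units, differentiate with central differences where both neighbors lie in
the myocardium mask and one-sided differences at mask edges (dropping the
boundary ring instead would discard most of a thin rat wall), assemble
$F = I + \nabla u$ and $E = (F^\top F - I)/2$, and project on the local
radial/circumferential unit vectors about the mask centroid. Central (and
one-sided) differences are exact for affine fields, so rigid motions give
$|E| \le 10^{-9}$ and uniform scaling $\lambda = 1.1$ gives exactly
$E_{cc} = E_{rr} = 0.105$ — both enforced in the suite. Segments are six
60° sectors counterclockwise from a reference angle (default 90°, the image
"up"; the anterior insertion convention for rodent short-axis slices is not
standardized, so the angle is configurable). Per-segment means are reported
in percent with a pixel-weighted global row. The per-segment temporal
reduction is the signed value of maximal magnitude across the cycle
("peak strain"), the quantity conventionally compared between methods;
which frame realizes it is reported alongside.

## Agreement statistics

Displacement agreement uses SSIM (11×11 Gaussian window, σ = 1.5,
population covariances, valid window positions — numerically identical to
the common reference implementation on interior windows), per-component
RMSE and mean endpoint error in mm over the foreground. Strain agreement
uses ICC(2,1) (two-way random effects, absolute agreement — chosen because
both "raters" are fixed methods scoring the same segments, and systematic
offsets should be penalized), Pearson r, per-method coefficients of
variation, Bland–Altman bias with 1.96·SD limits, and per-segment paired
t-tests across slices with Bonferroni correction over the six segments
within each strain family. Degenerate inputs follow conventions stated in
the documentation: identical paired samples give $t = 0$, $p = 1$; zero
variance or zero mean make correlation or CV undefined rather than silently
zero.

## Desk-scale problem sizes

The self-contained experiment the acceptance script and suite run is sized
for a single CPU: 8 phantom scans at 32×32 with 8 frames (same physical
annulus at 1 mm/px), `base_channels` 8, 30 epochs — about a minute per
variant — with one held-out test scan. At that scale MyoNet reaches roughly
an eightfold training-loss reduction, recovers held-out per-segment peak
strains with ICC ≈ 0.88 and r ≈ 0.90 against the closed form, and ResMyoNet
reaches MyoNet's final training loss in roughly a third of the epochs,
mirroring the faster convergence reported for residual variants. Pooled
per-frame per-segment values agree less strongly (ICC ≈ 0.79): near-zero
frames expose a positive noise floor in Err, since the quadratic term of
the Green–Lagrange tensor rectifies gradient noise. That floor is a
property of finite-deformation strain on noisy fields, not of the segment
averaging.

## Known limitations

* The phantom's motion is axisymmetric; segment-resolved *differences* are
  only exercised by the flip/rotation equivariance tests, not by the
  physiology.
* Desk-scale training uses tiny cohorts; nothing here estimates real-data
  performance or replaces validation against tagging.
* Strain is 2D in-plane; no torsion, longitudinal, or through-plane
  components.
* The CNN engine is CPU-bound R/BLAS; full-scale (128×128×20, 100-epoch)
  training is possible but slow, and is not part of the test suite.
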