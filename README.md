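# hepaseg

Joint liver and tumor segmentation for 3D contrast-enhanced CT, built
around three ideas: multi-scale context encoding, a learnable
vector-quantization codebook at the network bottleneck, and a selective
state-space (linear recurrence) module for cross-slice context — trained
with an anatomical *containment* prior that penalizes tumor probability
exceeding liver probability. The package is aimed at researchers who want a
fully inspectable, dependency-light reference implementation of this model
family, runnable and testable end to end on synthetic phantoms without any
external dataset, GPU, or deep-learning framework.

## The model

A 3D U-Net (4 levels, widths 16/32/48/64) whose encoder blocks are
three-branch multi-scale context modules (1x1x1 + 3x3x3; 1x1x1 + dilated
3x3x3 with dilation 2, i.e. a 5x5x5 receptive field; global average pooling
+ 1x1x1), fused by a 1x1x1 convolution. At the bottleneck, features
`Z in R^{C x N}` are vector-quantized against a learnable codebook
`E in R^{K x C}` (K = C = 64):

    d_nk   = ||z_n||^2 + ||e_k||^2 - 2 z_n' e_k
    k*(n)  = argmin_k d_nk,   zhat_n = e_{k*(n)}
    Ztilde = Z + stopgrad(Zhat - Z)                  (straight-through)
    L_VQ   = ||Zhat - Z||^2_[no grad Zhat] + lambda ||Zhat - Z||^2_[no grad Z]

with lambda = 0.25. The quantized volume is flattened depth-major and run
through a gated linear recurrence (state size n = 16, embedding d = 64)

    h_t = a(x_t) * h_{t-1} + W_b x_t,   y_t = C_out h_t,
    a(x_t) = exp(-softplus(W_a x_t + b_a)) in (0,1)^n

with a residual connection. Two sigmoid heads predict the liver *region*
(labels 1 and 2) and the tumor; the objective is

    L = L_seg + alpha L_VQ + beta L_contain,
    L_contain = mean_x max(0, T(x) - L(x)),    alpha = 0.4, beta = 0.6,

where `L_seg` is Dice+BCE per head. Evaluation implements the LiTS metric
suite: Dice, VOE (= 1 - Dice), RVD, and spacing-aware ASD / 95HD surface
distances, plus tumor-size-stratified Dice (bins <10, 10-20, 20-30, 30-50,
>=50 voxels of maximum extent).

Everything — phantoms, preprocessing (HU clip to (-200,200), cubic B-spline
in-plane x0.5 / 1 mm axial resampling, 48-slice liver slabs, min-max
normalization), the network with hand-written backward passes (Rcpp im2col
kernels), Adam training (lr 1e-4, batch 1, seeds 42/57/89 reported as
mean +/- sd), and NIfTI-1 I/O — is implemented in this package. See
`vignettes/methods.Rmd` for every numerical convention and design decision.

## Worked example

```r
library(hepaseg)

# a LiTS-like synthetic case: ellipsoidal liver, two hypodense lesions
cfg <- phantom_config(grid_shape = c(48L, 64L, 64L),
                      spacing_mm = c(1.5, 0.8, 0.8),
                      liver_semiaxes_mm = c(20, 18, 18),
                      n_tumors = 2L, tumor_radius_range_mm = c(5, 9),
                      noise_sd = 10, seed = 42L)
ph <- generate_phantom(cfg)
case <- list(image = minmax_normalize(clip_hu(ph$image)),
             mask  = ph$mask$data)

# overfit the full default model (codebook + state-space bottleneck) on it
run <- train(train_config(epochs = 150L), list(case),
             seed = 42L, max_steps = 150L)
pr  <- predict_volume(run$final_net, case$image)
metric_report(pr$liver, pr$tumor, case$mask, spacing = cfg$spacing_mm)
```

On this machine the run takes ~12 minutes (single CPU core), prints a
decreasing total loss (0.98 at step 10 -> 0.27 at step 150), and the report
gives

```
  structure  dice   voe ...
1     liver 0.981 0.019
2     tumor 0.969 0.031
```

i.e. the full model overfits the phantom: organ and lesions are segmented
nearly perfectly on the training volume. (This demonstrates the mechanics
of the pipeline, not clinical accuracy — see the methods vignette for what
phantom results do and do not establish.) The codebook usage perplexity is
logged per step (`run$log$perplexity`) to monitor prototype collapse.

## Command line

```sh
Rscript inst/cli/hepaseg.R phantoms --n 3 --out data/
Rscript inst/cli/hepaseg.R preprocess --in img.nii.gz --mask lab.nii.gz --out pre/
Rscript inst/cli/hepaseg.R train --manifest data/manifest.csv --out run/
Rscript inst/cli/hepaseg.R evaluate --checkpoint run/checkpoint_seed42.rds \
    --manifest data/manifest.csv --report report.csv
Rscript inst/cli/hepaseg.R replicate --manifest data/manifest.csv --out rep/
```

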