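# progreg — progressive self-calibrating deformable 3D registration

`progreg` is an R package for unsupervised deformable registration of 3D
grayscale volumes (NIfTI), built for the setting where a pair of same-modality
brain volumes has been globally pre-aligned but still carries a large
residual non-linear deformation. It is aimed at image-analysis practitioners
who want a CPU-trainable, fully inspectable implementation of progressive
registration with aggregate-flow composition, plus a phantom generator that
makes the whole pipeline testable without any external data.

## The method

A single shared-weight UNet `G` predicts a displacement vector field (DVF)
`u = G(M, F)` for a moving/fixed pair; the deformation is `phi(x) = x + u(x)`
and warping is backward, `warped(x) = M(x + u(x))`, by trilinear
interpolation. Training minimizes

```
L = -LNCC(M ∘ phi, F) + lambda * ||∇u||²  (mean over voxels)
```

The smoothness term caps how much deformation one prediction can express, so
the network is applied *progressively*: pass `k` registers the previous
pass's output to `F` and yields a small correction `u_k`. Instead of warping
the warped image again (which blurs detail a little more at every pass — the
information-loss problem of sequential cascades), each correction is folded
into a single total field with the aggregate-flow operator

```
u_total(x) = u_k(x) + u_prev(x + u_k(x))
```

so the final image is produced by exactly **one** interpolation of the
primary moving image, no matter how many passes ran. Every result carries an
`interp_count` that the test suite pins to 1. Because pass `k` trains on the
output of pass `k−1`, the network learns to correct its own residual error
(self-calibration), and each added training pass implicitly augments the
training distribution with freshly generated inputs.

A two-scale cascade completes the method: a low-resolution network (2×
average-pooled inputs) handles the coarse deformation; its aggregate is
upsampled (grid doubled, displacements ×2) and used as the initial value of
the full-resolution chain. Training and testing pass counts (`n_train`,
`n_test`) are independent hyperparameters; `grid_search()` reproduces the
pass-count sweep used to select them.

## Worked example

```r
library(progreg)

# a 32^3 labeled template and 12 large-deformation pairs (initial Dice of
# the smallest structure calibrated below 0.6), 8 for training, 4 held out
pspec <- phantom_spec(seed = 1)
pairs <- make_pair_set(12, pspec, severity = "large", seed = 1)
w     <- loss_weights(lambda_smooth = 1, lncc_window = 5)

fit <- train_hierarchical(
  pairs[1:8],
  cfg_low  = train_config(steps = 150, lr = 1e-3, weights = w,
                          schedule = iteration_schedule(3, 3)),
  cfg_orig = train_config(steps = 150, lr = 1e-3, weights = w,
                          schedule = iteration_schedule(3, 2)))

p   <- pairs[[9]]                       # held-out pair
res <- hierarchical_infer(p$moving, p$fixed, fit$net_low, fit$net_orig,
                          iteration_schedule(3, 3), iteration_schedule(3, 2), w)
res
#> <registration_result: 5 passes, final similarity 0.6702, interpolations of the moving image: 1>

dice_report(p$moving_labels, p$fixed_labels)$mean                        # before
#> [1] 0.4734582
dice_report(warp_labels(p$moving_labels, res$total_flow), p$fixed_labels)$mean
#> [1] 0.7104186
```

The held-out pair's mean label overlap rises from 0.47 to 0.71 after
registration, and the warped image was interpolated once (`interp_count` 1);
`cascade_infer()` runs the same model as a conventional sequential cascade
for comparison, accumulating one interpolation per pass and measurably lower
boundary sharpness (`edge_sharpness()`).

## Command line

A thin launcher in `inst/cli/progreg` exposes the same functionality:

```sh
progreg generate --out pair/ --shape 32,32,32 --severity large --seed 1
progreg train --config train.yaml --out-low low.rds --out-orig orig.rds
progreg register --moving pair/moving.nii.gz --fixed pair/fixed.nii.gz \
        --checkpoint orig.rds --checkpoint-low low.rds \
        --out-warped warped.nii.gz --out-flow flow.nii.gz
progreg evaluate --flow flow.nii.gz --moving-labels pair/moving_labels.nii.gz \
        --fixed-labels pair/fixed_labels.nii.gz --out dice.csv
progreg compose a.nii.gz b.nii.gz --out total.nii.gz
```

Volumes and label maps are 3D NIfTI-1; flows are 4D NIfTI with the 4th
dimension of size 3, components ordered as (D, H, W)-axis displacements in
voxel units (recorded in the header description).

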