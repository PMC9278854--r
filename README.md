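# neuriface

Direct interfacing of neural recordings with the layers of a deep
convolutional image classifier.

## The problem

Claims that a brain region "corresponds" to a layer of a deep convolutional
network (DCNN) conventionally rest on shared variance: activity in the region
correlates with, or can be predicted from, activity in the layer. But shared
variance need not be task-relevant variance — a region can covary with a
layer without being able to play the layer's functional role. `neuriface`
implements the stricter test: learn a linear translation from recordings
(fMRI voxels, multiunit spike counts, trials × features) into a layer's
activation space, substitute the translated activity for the layer's
activations, resume the forward pass, and score how well the substituted
network performs its object recognition task. Good correspondence means the
region's activity, and nothing else, can drive the network to the right
decision.

For an image matrix `D_i` with predictions `P_i = f(D_i)` and recordings
`D_r`, the forward pass decomposes at any layer `q` as `f = g'_q ∘ g_q`. The
translation `W` (linear, no bias, no nonlinearity) is fitted on training
folds so that `g_q(D_i) ≈ W D̃_r` (`D̃_r` centered/column-scaled), and the
interfaced predictions `P_r = g'_q(W D̃_r)` on held-out rows are scored by:

* **multiclass AUC** (Hand–Till): every class pair's two directed
  Mann–Whitney AUCs (ties = 1/2) averaged, then averaged over pairs; chance
  is 0.5 for any number of classes;
* **KL divergence** of the interfaced from the image-driven predictions,
  row-wise (lower = closer correspondence).

The package also provides: bin-wise temporal interfacing yielding per-trial
KL time series and a directional Granger-causal comparison of two regions
(likelihood-ratio tests on pooled trial-masked lagged regressions, BIC lag
selection, expanding-window onset timelines); a perturbation
(noise-attenuation) analysis; conventional baselines (MVPA classifiers,
PCA+PLS neural predictivity, pixel-PCA interfacing); and a synthetic-data
module (labeled images, simulated region recordings as noisy linear layer
readouts, two-region feedforward/feedback dynamics) so every analysis runs
end to end on one CPU with no downloads. Since no deep-learning framework is
assumed, the package includes its own miniature VGG-style classifier
(vectorized im2col convolutions, batch-norm, SGD with Nesterov momentum)
with exact activation extraction and injection at every named layer.

## A worked example

```r
library(neuriface)

imgs <- generate_images(m = 10, n_per_class = 200, size = c(32, 32), seed = 101)
net  <- train_net(net_spec(), imgs, hyper = list(max_epochs = 10), seed = 202)
net$final_val_acc
#> [1] 0.95

# a synthetic "region": a noisy 128-feature linear readout of the late
# dense layer
rec <- simulate_region(net, imgs, "fc1", d = 128, noise_sd = 0.5, seed = 3)

grid <- run_interface_grid(
  net, imgs, rec,
  layers    = c("conv1a", "conv2a", "conv3a", "conv3b", "fc1"),
  fold_plan = make_fold_plan(imgs$labels, k = 8, seed = 4),
  seed      = 5)
grid$grid
#> # A tibble: 5 × 5
#>   region layer    auc mean_kl auc_image
#>   <chr>  <chr>  <dbl>   <dbl>     <dbl>
#> 1 fc1    conv1a 0.823  3.02       0.999
#> 2 fc1    conv2a 0.950  1.18       0.999
#> 3 fc1    conv3a 0.996  0.105      0.999
#> 4 fc1    conv3b 0.996  0.104      0.999
#> 5 fc1    fc1    0.998  0.0284     0.999
best_layer(grid)$layer
#> [1] "fc1"
autoplot(grid)
```

The grid shows the method doing its job: recordings simulated as a readout
of the late dense layer (`fc1`) interface poorly into the earliest conv
layer (AUC 0.82, large KL against the image-driven outputs) and recover the
image-driven level — AUC 0.998, lowest KL — at the source layer.
`auc_image` is the image-driven reference (0.999 on this synthetic task),
and chance AUC is 0.5.

Temporal analysis on the two-region simulator:

```r
spec   <- dynamics_spec()   # 30 x 10 ms bins, feedforward lag 2, feedback lag 3
trials <- imgs[sample(2000, 200, replace = TRUE)]
two    <- simulate_two_region_dynamics(net, trials, spec, seed = 6)
diss   <- granger_dissociation(net, trials, two, spec, seed = 7)
diss$rate
#> <granger_timeline> V4 vs IT: onset V4->IT at bin 10; IT->V4 at bin never
diss$kl
#> <granger_timeline> V4 vs IT: onset V4->IT at bin never; IT->V4 at bin 13
```

Raw firing rates show causality from the early region to the late region
first (the stimulus-driven feedforward sweep), while the task-relevant
signal — each region's bin-wise ability to drive the classifier, measured
as a KL time series — shows the late region driving the early one first
(the feedback of class information).

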