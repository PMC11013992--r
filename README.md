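# dfseg — dynamic fusion segmentation of orchard point clouds

Orchard management robots (spraying, scouting, navigation) perceive their
surroundings through solid-state LiDAR. To act on a scan they need *semantic
segmentation*: a class label for every 3D point — leaves, trunks, cultivation
pots, support scaffolds, ground, and in busier scenes people, indicator signs
and other obstacles. `dfseg` is a self-contained R implementation of a
dynamic fusion segmentation network for this task, together with the
surrounding tooling: point-cloud I/O, preprocessing, segmentation metrics,
ablation harnesses and a synthetic orchard-scene generator for benchmarking
without field data.

## The method

**Local feature aggregation (LFA), training-free.** Raw coordinates are
embedded by a trigonometric positional encoder: per axis `a` and channel
pair `t`,

```
f[2t] = sin(mu * a / nu^(6t/FI)),   f[2t+1] = cos(mu * a / nu^(6t/FI)),
```

concatenated over x, y, z into an N × FI map (FI = 144, mu = 1000,
nu = 100 by default). Three set-abstraction stages then each keep half of
the points (farthest point sampling), group k = 64 neighbours (exact k-NN),
encode neighbour coordinates relative to their centroid, and pool each
group by max + average pooling, doubling the feature width per stage
(cascade N → 0.5N → 0.25N → 0.125N). All levels are propagated back to
full resolution by inverse-distance-weighted interpolation and
concatenated, giving per-point features of width

```
f = FI + 2FI + 4FI + 8FI = 2160   (defaults).
```

**Dynamic segmentation layers, learnable.** Each layer's fusion
segmentation (Fus-Seg) module applies two Seg blocks (shared per-point
perceptrons `f -> f/2 -> C`) to its two input layers, pairs the
L2-normalized per-point class scores in a C × C multi-embedding space
`M(n)[i,j] = F_i(n) S_j(n)`, max-pools `M(n)` into a per-point label vector,
and uses the resulting N × C label matrix as per-class weights to expand
the features (N × f → N × f × C) before a learned C → 1 contraction and an
inverted residual block (f → 2f → f with a skip connection). A final fully
connected layer yields N × C scores. Training minimizes per-point
cross-entropy plus a 0.1-weighted pairing loss that pushes the diagonal of
each `M(n)` to dominate, with AdamW (lr 0.001, betas (0.9, 0.999),
eps 1e-8, weight decay 1e-4). Forward, backward and optimizer are
implemented in base R; a finite-difference suite verifies every gradient.

**Metrics.** Point accuracy `trace(S)/N` and mean intersection-over-union
`mIoU = mean_i S_ii / (Σ_j S_ij + Σ_j S_ji − S_ii)` over a C × C confusion
matrix `S`.

See the vignette `vignettes/dynamic-fusion-segmentation.Rmd` for the full
account of the model, the synthetic-scene generator and the design choices.

## Worked example

```r
library(dfseg)

## a labelled synthetic scene, written the way field scenes are stored
cfg   <- scene_config(n_trees = 2, points_per_scene = 20000,
                      class_set = "simple", seed = 7)
scene <- generate_scene(cfg, name = "demo")
scene
#> <point_cloud> demo: 18227 points, 5 classes present
#>   extent: x [0.00, 10.01]  y [0.00, 10.02]  z [0.00, 3.90] m
table(class = scene$labels)
#> class
#>     0     1     2     3     4
#>  6692   189    90    30 11226

## a reduced network on 3 collapsed classes (canopy / trunk-like / ground-like)
net <- build_network(network_config(n_points = 1024, class_set = NULL, C = 3,
                                    n_dynamic_layers = 1, FI = 12, k = 16,
                                    seed = 42))
net
#> <dfs_network> C = 3, 1 dynamic layer(s), f = 180, fps sampler, k = 16
#>   295,573 learnable parameters

train_scenes <- lapply(1:10, function(i) {
  sc <- generate_scene(scene_config(n_trees = 2, points_per_scene = 8000,
                                    class_set = "simple", seed = 100 + i))
  sc$labels <- c(0L, 1L, 2L, 1L, 2L)[sc$labels + 1L]
  subsample(sc, 1024, seed = i)
})
run <- train_network(net, train_scenes[1:8],
                     train_config(epochs = 20, batch_size = 2, seed = 42))
tail(run$log[, c("epoch", "loss", "acc")], 3)
#>    epoch      loss       acc
#> 18    18 0.2065100 0.9727783
#> 19    19 0.1994245 0.9752197
#> 20    20 0.1926548 0.9759521

ev <- evaluate_network(run$model, train_scenes[9:10])
sprintf("held-out Acc: %.2f%%  mIoU: %.2f%%", 100 * ev$acc, 100 * ev$miou)
#> [1] "held-out Acc: 88.38%  mIoU: 51.14%"
round(ev$per_class_iou, 3)
#>     0     1     2
#> 0.678 0.000 0.856
```

The log shows the network memorizing its training scenes (97.6% point
accuracy after 20 epochs) and generalizing to held-out scenes at 88% point
accuracy; the per-class IoU table shows the usual imbalanced-class picture —
large surfaces (canopy, ground) segment well, the thin trunk class is hard
at this reduced scale and short schedule. The recovery benchmark in
`tests/testthat/test-acceptance.R` runs the same experiment at 30 epochs
and 20 scenes, where training accuracy passes 99%.

A command-line front end wrapping these functions (simulate / train /
predict / evaluate / ablate) is installed at
`system.file("cli", "dfseg.R", package = "dfseg")`.

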