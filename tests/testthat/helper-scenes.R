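# Shared fixtures: random clouds and the reduced synthetic benchmark used by
# the training/ablation tests.

random_cloud <- function(n, seed = 1, labeled = FALSE, C = 3L) {
  with_seed_test(seed, {
    point_cloud(matrix(stats::runif(n * 3, 0, 5), ncol = 3),
                labels = if (labeled) sample(0:(C - 1L), n, replace = TRUE) else NULL,
                name = sprintf("rnd%d", seed))
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Easy 3-class benchmark: simple orchard scenes with the thin/adjacent
# classes merged into their geometric neighbours (canopy / trunk-like /
# ground-like), so classes are separated by much more than the noise scale.
make_easy_scenes <- function(n, n_pts = 1024L, seed = 1L) {
  lapply(seq_len(n), function(i) {
    cfg <- scene_config(n_trees = 2, points_per_scene = 8000,
                        class_set = "simple", noise_sd = 0.01,
                        seed = seed * 1000L + i)
    sc <- generate_scene(cfg, name = sprintf("easy_%02d_%d", i, seed))
    sc$labels <- c(0L, 1L, 2L, 1L, 2L)[sc$labels + 1L]
    subsample(sc, n_pts, seed = i)
  })
}
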