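# End-to-end network behaviour on small configurations. The reduced
# benchmark (3 collapsed classes, small encoder) keeps runtimes short while
# exercising every code path of the full architecture.

small_cfg <- function(...) {
  network_config(n_points = 256L, class_set = NULL, C = 3L,
                 n_dynamic_layers = 1L, FI = 12L, k = 8L, ...)
}

test_that("build_network is seeded and reports its parameter count", {
  a <- build_network(small_cfg(seed = 5))
  b <- build_network(small_cfg(seed = 5))
  expect_identical(a$params, b$params)
  expect_gt(a$n_params, 0)
  d <- build_network(small_cfg(seed = 6))
  expect_false(identical(a$params, d$params))
})

test_that("forward output is N x C regardless of depth; N is conserved", {
  for (N in c(512L, 1024L)) {
    cloud <- subsample(generate_scene(scene_config(points_per_scene = 3000,
                                                   seed = N)), N, seed = 1)
    for (L in c(1L, 3L)) {
      cfg <- network_config(n_points = N, class_set = NULL, C = 4L,
                            n_dynamic_layers = L, FI = 12L, k = 8L)
      net <- build_network(cfg)
      pred <- predict(net, cloud)
      expect_equal(n_points(pred), N)
      expect_equal(dim(attr(pred, "scores")), c(N, 4L))
      expect_true(all(pred$labels %in% 0:3))
    }
  }
})

test_that("prediction is deterministic and incompatible sizes are subsampled", {
  cloud <- subsample(generate_scene(scene_config(points_per_scene = 3000,
                                                 seed = 3)), 256, seed = 2)
  net <- build_network(small_cfg(seed = 2))
  p1 <- predict(net, cloud)
  p2 <- predict(net, cloud)
  expect_identical(p1$labels, p2$labels)
  odd <- subsample(cloud, 255, seed = 1)     # 255 not divisible by 8
  p3 <- predict(net, odd)
  expect_equal(n_points(p3), 256L)           # padded back to the configured size
})

test_that("training reduces the loss and logs per-epoch accuracy", {
  scenes <- make_easy_scenes(4, n_pts = 256L, seed = 21)
  net <- build_network(small_cfg(seed = 7))
  tr <- train_network(net, scenes, train_config(epochs = 8, batch_size = 2, seed = 7))
  expect_equal(nrow(tr$log), 8L)
  expect_lt(tr$log$loss[8], tr$log$loss[1])
  expect_true(all(tr$log$acc >= 0 & tr$log$acc <= 1))
  # the trained model beats the untrained one on its own training data
  ev0 <- evaluate_network(net, scenes)
  ev1 <- evaluate_network(tr$model, scenes)
  expect_gt(ev1$acc, ev0$acc)
})

test_that("lambda = 0 reduces the objective to plain cross-entropy", {
  scenes <- make_easy_scenes(2, n_pts = 256L, seed = 31)
  cfg <- small_cfg(seed = 3, lambda = 0)
  net <- build_network(cfg)
  X0 <- dfseg:::lfa_features(cfg, scenes[[1]]$coords, seed = 1)
  fwd <- dfseg:::head_fwd(net$params, X0, labels = scenes[[1]]$labels, lambda = 0)
  expect_identical(fwd$loss, fwd$xent)
})

test_that("training rejects invalid inputs with clear errors", {
  net <- build_network(small_cfg())
  expect_error(train_network(net, list(), train_config(epochs = 1)), "at least one")
  unlab <- point_cloud(matrix(runif(768), 256, 3))
  expect_error(train_network(net, list(unlab), train_config(epochs = 1)), "labelled")
  bad <- point_cloud(matrix(runif(768), 256, 3),
                     labels = rep(5L, 256))     # outside 0..C-1
  expect_error(train_network(net, list(bad), train_config(epochs = 1)), "outside")
  odd <- point_cloud(matrix(runif(300), 100, 3), labels = rep(0L, 100))
  expect_error(train_network(net, list(odd), train_config(epochs = 1)), "divisible")
})

test_that("yaml configs round-trip into network and training settings", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("network:", "  n_points: 256", "  class_set: ~", "  C: 3",
               "  FI: 12", "  k: 8", "  n_dynamic_layers: 2",
               "training:", "  epochs: 5", "  lr: 0.01", "  batch_size: 2"), f)
  cfg <- config_from_yaml(f)
  expect_equal(cfg$network$C, 3L)
  expect_equal(cfg$network$n_dynamic_layers, 2L)
  expect_equal(cfg$network$f, 12L * 15L)
  expect_equal(cfg$training$epochs, 5L)
  expect_equal(cfg$training$lr, 0.01)
})
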