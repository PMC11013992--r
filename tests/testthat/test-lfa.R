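test_that("pose_encode matches its closed form at the origin and on the unit circle", {
  cfg <- pose_config(FI = 12, mu = 1000, nu = 100)
  at0 <- pose_encode(matrix(0, 3, 3), cfg)
  expect_equal(unname(at0[, seq(1, 12, 2)]), matrix(0, 3, 6))  # sines
  expect_equal(unname(at0[, seq(2, 12, 2)]), matrix(1, 3, 6))  # cosines
  with_seed_test(3, {
    x <- matrix(rnorm(3000), ncol = 3)
    enc <- pose_encode(x, cfg)
    pairs <- enc[, seq(1, 12, 2)]^2 + enc[, seq(2, 12, 2)]^2
    expect_true(all(abs(pairs - 1) < 1e-9))
    expect_true(all(enc >= -1 & enc <= 1))
  })
})

test_that("pose_encode equals the scalar-loop formula evaluation", {
  pt <- matrix(c(0.3, -1.2, 2.0), 1, 3)
  expect_equal(pose_encode(pt, pose_config(12, 1000, 100)),
               pose_oracle(pt, 12, 1000, 100), tolerance = 1e-12)
  with_seed_test(9, {
    x <- matrix(rnorm(30), ncol = 3)
    expect_equal(pose_encode(x, pose_config(36, 7, 13)),
                 pose_oracle(x, 36, 7, 13), tolerance = 1e-12)
  })
})

test_that("pose_config rejects dimensions not divisible by 6", {
  expect_error(pose_config(FI = 10), "divisible by 6")
  expect_error(pose_config(FI = 12, mu = -1), "positive")
})

test_that("fps handles the base cases", {
  x <- cbind(c(0, 1, 10), 0, 0)
  expect_equal(fps(x, 1, start_index = 1), 1L)
  expect_equal(fps(x, 2, start_index = 1), c(1L, 3L))  # farthest from 0 is 10
  expect_error(fps(x, 4), "exceeds")
})

test_that("fps equals the brute-force greedy selection on random instances", {
  for (s in 1:200) {
    with_seed_test(s, {
      N <- sample(2:64, 1)
      x <- matrix(runif(N * 3), ncol = 3)
      m <- sample.int(N, 1)
      start <- sample.int(N, 1)
      expect_identical(fps(x, m, start), as.integer(fps_oracle(x, m, start)))
    })
  }
})

test_that("random_sample is seeded, exhaustive at m = N, and uniform", {
  x <- matrix(runif(12), 4, 3)
  expect_setequal(random_sample(x, 4, seed = 1), 1:4)
  expect_identical(random_sample(x, 2, seed = 9), random_sample(x, 2, seed = 9))
  draws <- vapply(1:10000, function(s) random_sample(x, 1, seed = s), 0L)
  freq <- tabulate(draws, 4) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("knn_group matches hand-computed neighbourhoods", {
  x <- cbind(c(0, 1, 3), 0, 0)
  expect_equal(knn_group(x, 1L, 2)[1, ], c(1L, 2L))
  all_self <- knn_group(x, 1:3, 1)
  expect_equal(as.vector(all_self), 1:3)   # k = 1: each centroid is its own group
  expect_error(knn_group(x, 1L, 5), "exceeds")
})

test_that("knn_group equals brute-force distance-table sorting", {
  for (s in 1:100) {
    with_seed_test(s, {
      N <- sample(4:128, 1)
      x <- matrix(runif(N * 3), ncol = 3)
      m <- sample.int(N, 1)
      ci <- sample.int(N, m)
      k <- sample.int(min(N, 16), 1)
      expect_identical(knn_group(x, ci, k), knn_oracle(x, ci, k))
    })
  }
})

test_that("sa_stage honours its shape contract and doubles the feature width", {
  with_seed_test(4, {
    x <- matrix(runif(96), 32, 3)
    f <- pose_encode(x, pose_config(12))
    st <- sa_stage(x, f, n_centroids = 16, k = 8, config = pose_config(12))
    expect_equal(dim(st$coords), c(16L, 3L))
    expect_equal(dim(st$features), c(16L, 24L))
    expect_length(st$indices, 16L)
  })
})

test_that("sa_stage features are translation invariant", {
  # FPS and k-NN depend only on pairwise distances and the encoder sees only
  # relative coordinates, so translating the cloud changes nothing
  with_seed_test(5, {
    x <- matrix(runif(96), 32, 3)
    f <- pose_encode(x, pose_config(12))  # use the same input features
    a <- sa_stage(x, f, 16, k = 8, config = pose_config(12))
    b <- sa_stage(x + matrix(c(3, -2, 7), 32, 3, byrow = TRUE), f, 16, k = 8,
                  config = pose_config(12))
    expect_identical(a$indices, b$indices)
    expect_equal(a$features, b$features, tolerance = 1e-9)
  })
})

test_that("sa_stage is permutation equivariant given the matching start point", {
  with_seed_test(6, {
    x <- matrix(runif(96), 32, 3)
    f <- pose_encode(x, pose_config(12))
    perm <- sample(32)
    a <- sa_stage(x, f, 16, k = 8, config = pose_config(12), start_index = 1)
    b <- sa_stage(x[perm, ], f[perm, ], 16, k = 8, config = pose_config(12),
                  start_index = which(perm == 1))
    expect_equal(a$coords, b$coords)
    expect_equal(a$features, b$features)
  })
})

test_that("max and average pooling agree on a degenerate cloud of identical points", {
  x <- matrix(1, 8, 3)
  f <- matrix(0.5, 8, 4)
  st <- sa_stage(x, f, 4, k = 4, config = pose_config(12))
  # every group member is identical, so max == avg and features are constant
  expect_equal(st$features, matrix(st$features[1, ], 4, 8, byrow = TRUE))
})

test_that("lfa_forward follows the halving cascade and dimension schedule", {
  with_seed_test(7, {
    x <- matrix(runif(128 * 3), ncol = 3)
    out <- lfa_forward(x, n_stages = 3, config = pose_config(12), k = 8)
    expect_equal(dim(out), c(128L, 12L * 15L))
    expect_equal(attr(out, "stage_sizes"), c(64L, 32L, 16L))
    expect_equal(attr(out, "level_dims"), c(12L, 24L, 48L, 96L))
    # empty cascade degenerates to the raw embedding
    expect_equal(lfa_forward(x, n_stages = 0, config = pose_config(12))[, 1:12],
                 pose_encode(x, pose_config(12)))
    expect_error(lfa_forward(x[1:100, ], n_stages = 3, config = pose_config(12)),
                 "divisible")
  })
})

test_that("lfa_forward samples the same hierarchy after a rigid translation", {
  # FPS, k-NN and the reconstruction weights depend only on pairwise
  # distances; only the stage-0 embedding sees absolute coordinates
  with_seed_test(8, {
    x <- matrix(runif(64 * 3), ncol = 3)
    xt <- sweep(x, 2, c(5, -1, 2), "+")
    f <- pose_encode(x, pose_config(12))
    for (s in c(1L, 2L)) {
      a <- sa_stage(x, f, 64 %/% 2^s, k = 8, config = pose_config(12))
      b <- sa_stage(xt, f, 64 %/% 2^s, k = 8, config = pose_config(12))
      expect_identical(a$indices, b$indices)
      expect_equal(a$features, b$features, tolerance = 1e-9)
    }
  })
})
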