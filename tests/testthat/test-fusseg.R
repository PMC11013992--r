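test_that("seg_block is a shared per-point map with the contracted shape", {
  with_seed_test(1, {
    X <- matrix(rnorm(40), 10, 4)
    p <- seg_params(4, 3, seed = 2)
    out <- seg_block(X, p)
    expect_equal(dim(out), c(10L, 3L))
    perm <- sample(10)
    expect_equal(seg_block(X[perm, ], p), out[perm, ], tolerance = 1e-9)
    expect_error(seg_block(matrix(0, 5, 7), p), "does not match")
  })
})

test_that("seg_block with identity weights and no normalization is the identity", {
  p <- seg_params(3, 3, hidden = 3, bn = FALSE, seed = 1)
  p$W1 <- diag(3); p$b1 <- rep(0, 3)
  p$W2 <- diag(3); p$b2 <- rep(0, 3)
  X <- matrix(abs(rnorm(30)), 10, 3)  # nonnegative so ReLU passes through
  expect_equal(seg_block(X, p), X)
})

test_that("embedding_space reproduces hand-computed pairings", {
  # raw mode: F = (1, 2), S = (3, 4) -> outer product [[3, 4], [6, 8]]
  M <- embedding_space(matrix(c(1, 2), 1), matrix(c(3, 4), 1), normalize = FALSE)
  expect_equal(M[1, , ], rbind(c(3, 4), c(6, 8)))
  # normalized mode equals the scalar cosine-term computation
  a <- matrix(c(1, 2), 1); b <- matrix(c(3, 4), 1)
  an <- a / sqrt(sum(a^2)); bn <- b / sqrt(sum(b^2))
  expect_equal(embedding_space(a, b)[1, , ], outer(drop(an), drop(bn)),
               tolerance = 1e-12)
})

test_that("one-hot pre-labels give a single diagonal pairing", {
  for (C in c(2, 5, 8)) {
    oh <- matrix(0, 4, C)
    oh[cbind(1:4, rep_len(seq_len(C), 4))] <- 1
    M <- embedding_space(oh, oh)
    for (n in 1:4) {
      cl <- rep_len(seq_len(C), 4)[n]
      expected <- matrix(0, C, C)
      expected[cl, cl] <- 1
      expect_equal(M[n, , ], expected)
    }
    # and the one-hots survive pooling unchanged
    expect_equal(pool_labels(M), oh)
  }
})

test_that("pairing spaces of swapped inputs are transposes of each other", {
  with_seed_test(3, {
    a <- matrix(rnorm(12), 3, 4)
    b <- matrix(rnorm(12), 3, 4)
    Mab <- embedding_space(a, b)
    Mba <- embedding_space(b, a)
    for (n in 1:3) expect_equal(Mab[n, , ], t(Mba[n, , ]), tolerance = 1e-12)
  })
})

test_that("pool_labels takes column-wise maxima over the first layer's axis", {
  M <- array(0, c(1, 2, 2))
  M[1, , ] <- rbind(c(3, 4), c(6, 8))
  expect_equal(pool_labels(M), matrix(c(6, 8), 1))
  with_seed_test(4, {
    M <- array(rnorm(5 * 3 * 3), c(5, 3, 3))
    tag <- pool_labels(M)
    for (j in 1:3) expect_true(all(tag[, j] >= M[, , j] - 1e-15))
  })
})

test_that("expand_features is the per-point outer product", {
  out <- expand_features(matrix(c(1, 2), 1), matrix(c(3, 4), 1))
  expect_equal(out[1, , ], rbind(c(3, 4), c(6, 8)))
  expect_equal(dim(out), c(1L, 2L, 2L))
  with_seed_test(5, {
    feats <- matrix(rnorm(12), 4, 3)
    onehot <- matrix(0, 4, 2); onehot[, 2] <- 1
    sel <- expand_features(feats, onehot)
    expect_equal(sel[, , 2], feats)           # selector column carries the feature
    expect_equal(sel[, , 1], matrix(0, 4, 3))
    uni <- expand_features(feats, matrix(1, 4, 2))
    for (c in 1:2) expect_equal(uni[, , c], feats)
  })
})

test_that("inverted_residual keeps shape, doubles internally, and zeroes to identity", {
  with_seed_test(6, {
    X <- matrix(rnorm(40), 8, 5)
    p <- ir_params(5, seed = 3)
    expect_equal(dim(inverted_residual(X, p)), dim(X))
    expect_equal(nrow(p$W2), 10L)             # expansion width 2f
    expect_equal(inverted_residual(X, ir_params(5, init = "zero")), X)
  })
})

test_that("dynamic_layer composes without shape change and stacks", {
  with_seed_test(7, {
    N <- 16; f <- 8; C <- 3
    X <- matrix(rnorm(N * f), N, f)
    p <- dynamic_params(f, C, seed = 1)
    r <- dynamic_layer(X, X, p)
    expect_equal(dim(r$features), c(N, f))
    expect_equal(dim(r$pre_labels_1), c(N, C))
    expect_equal(dim(r$embedding), c(N, C, C))
    expect_equal(dim(r$tags), c(N, C))
    # three stacked layers preserve the width
    run <- X
    for (l in 1:3) run <- dynamic_layer(run, run, dynamic_params(f, C, seed = l))$features
    expect_equal(dim(run), c(N, f))
  })
})

test_that("dynamic_layer is permutation equivariant over points", {
  with_seed_test(8, {
    N <- 12; f <- 6; C <- 3
    X <- matrix(rnorm(N * f), N, f)
    p <- dynamic_params(f, C, seed = 2)
    perm <- sample(N)
    a <- dynamic_layer(X, X, p)$features
    b <- dynamic_layer(X[perm, ], X[perm, ], p)$features
    expect_equal(b, a[perm, ], tolerance = 1e-9)
  })
})

test_that("gradients reach both Seg blocks (finite differences on a toy)", {
  with_seed_test(9, {
    N <- 4; f <- 6; C <- 2; lambda <- 0.1
    X <- matrix(rnorm(N * f), N, f)
    labels <- c(0L, 1L, 0L, 1L)
    params <- list(layers = list(dynamic_params(f, C, seed = 5)),
                   out = list(W = dfseg:::init_mat(f, C), b = numeric(C)))
    loss_fn <- function(p) dfseg:::head_fwd(p, X, labels = labels, lambda = lambda)$loss
    fwd <- dfseg:::head_fwd(params, X, labels = labels, lambda = lambda)
    gr <- dfseg:::head_bwd(params, fwd, lambda = lambda)
    bump <- function(tree, path, i, d) {
      if (length(path) == 0) { tree[i] <- tree[i] + d; return(tree) }
      tree[[path[[1]]]] <- bump(tree[[path[[1]]]], path[-1], i, d)
      tree
    }
    for (path in list(list("layers", 1L, "segA", "W1"),
                      list("layers", 1L, "segB", "W1"),
                      list("layers", 1L, "segA", "W2"),
                      list("layers", 1L, "segB", "W2"),
                      list("layers", 1L, "w"),
                      list("layers", 1L, "ir", "W1"))) {
      g <- gr; p <- params
      for (k in path) { g <- g[[k]]; p <- p[[k]] }
      expect_gt(sum(abs(g)), 0)               # gradient actually flows
      for (i in seq_len(min(3, length(p)))) {
        num <- (loss_fn(bump(params, path, i, 1e-5)) -
                  loss_fn(bump(params, path, i, -1e-5))) / 2e-5
        expect_equal(g[i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("the pairing loss rewards diagonal dominance", {
  oh <- matrix(0, 6, 3)
  oh[cbind(1:6, rep_len(1:3, 6))] <- 5
  aligned <- pairing_loss(embedding_space(oh, oh))
  with_seed_test(10, {
    r <- matrix(rnorm(18), 6, 3)
    shuffled <- pairing_loss(embedding_space(r, matrix(rnorm(18), 6, 3)))
  })
  expect_lt(aligned, shuffled)
})
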