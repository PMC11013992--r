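# Fusion segmentation: Seg blocks producing per-point pre-labels, the C x C
# multi-embedding pairing space of two layers, its max-pooled label matrix,
# feature expansion/contraction, and the inverted residual block. Exported
# functions are the user-facing forward operations; the *_fwd/*_bwd pairs
# carry the caches used by training.

#' Parameters of a Seg block
#'
#' A Seg block is a shared per-point two-layer perceptron `f -> hidden -> C`
#' (hidden defaults to `f/2`) with batch normalization and ReLU after the
#' first layer. The same map is applied to every point.
#'
#' @param f input feature width.
#' @param C number of classes.
#' @param hidden hidden width (default `max(C, f/2)`).
#' @param bn include the normalization layer (default `TRUE`).
#' @param seed optional seed for the random initialization.
#' @return a parameter list usable with [seg_block()].
#' @export
seg_params <- function(f, C, hidden = NULL, bn = TRUE, seed = NULL) {
  f <- check_count(f, "f"); C <- check_count(C, "C")
  if (is.null(hidden)) hidden <- max(C, f %/% 2L)
  hidden <- check_count(hidden, "hidden")
  with_seed(seed, list(
    W1 = init_mat(f, hidden), b1 = numeric(hidden),
    bn1 = if (bn) list(gamma = rep(1, hidden), beta = numeric(hidden)) else NULL,
    W2 = init_mat(hidden, C, scale = sqrt(1 / hidden)), b2 = numeric(C)
  ))
}

seg_fwd <- function(X, p) {
  l1 <- nn_linear_fwd(X, p$W1, p$b1)
  h <- l1$out
  bn <- NULL
  if (!is.null(p$bn1)) {
    bn <- nn_bn_fwd(h, p$bn1$gamma, p$bn1$beta)
    h <- bn$out
  }
  r <- nn_relu_fwd(h)
  l2 <- nn_linear_fwd(r$out, p$W2, p$b2)
  list(out = l2$out, cache = list(l1 = l1$cache, bn = bn$cache, relu = r$cache,
                                  l2 = l2$cache, has_bn = !is.null(p$bn1)))
}

seg_bwd <- function(dY, cache) {
  g2 <- nn_linear_bwd(dY, cache$l2)
  dh <- nn_relu_bwd(g2$dX, cache$relu)
  bn1 <- NULL
  if (cache$has_bn) {
    gb <- nn_bn_bwd(dh, cache$bn)
    dh <- gb$dX
    bn1 <- list(gamma = gb$dgamma, beta = gb$dbeta)
  }
  g1 <- nn_linear_bwd(dh, cache$l1)
  list(dX = g1$dX,
       grads = list(W1 = g1$dW, b1 = g1$db, bn1 = bn1, W2 = g2$dW, b2 = g2$db))
}

#' Apply a Seg block to per-point features
#'
#' @param features N x f feature matrix.
#' @param params a [seg_params()] list.
#' @return N x C matrix of per-point class scores (pre-labels).
#' @export
seg_block <- function(features, params) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(params$W1)) {
    stop_dfseg("feature width %d does not match Seg block input %d",
               ncol(features), nrow(params$W1))
  }
  seg_fwd(features, params)$out
}

#' Multi-embedding pairing space of two pre-label sets
#'
#' For each point n, a C x C matrix `M[i, j] = F_i(n) * S_j(n)` pairing the
#' class scores of two layers. With `normalize = TRUE` (default) the
#' per-point score vectors are L2-normalized first, so entries are the terms
#' of a cosine similarity: diagonal entries are the real pairings, the
#' off-diagonal ones the incorrect pairings.
#'
#' @param a,b N x C pre-label matrices from two Seg blocks.
#' @param normalize L2-normalize the per-point vectors first.
#' @return N x C x C array.
#' @export
embedding_space <- function(a, b, normalize = TRUE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop_dfseg("pre-label shapes differ")
  if (normalize) {
    a <- nn_l2norm_fwd(a)$out
    b <- nn_l2norm_fwd(b)$out
  }
  N <- nrow(a); C <- ncol(a)
  M <- array(0, c(N, C, C))
  for (i in seq_len(C)) M[, i, ] <- a[, i] * b
  M
}

#' Max-pool a pairing space into per-point label vectors
#'
#' Reduces over the first layer's class axis, so row n of the result is the
#' column-wise maximum of `M(n)` and lives in the second layer's class
#' coordinates.
#'
#' @param space N x C x C array from [embedding_space()].
#' @return N x C label matrix.
#' @export
pool_labels <- function(space) {
  stopifnot(length(dim(space)) == 3L, dim(space)[2L] == dim(space)[3L])
  C <- dim(space)[2L]
  tag <- space[, 1L, , drop = TRUE]
  if (is.null(dim(tag))) tag <- matrix(tag, nrow = dim(space)[1L])
  if (C > 1L) for (i in 2:C) {
    cand <- space[, i, , drop = TRUE]
    if (is.null(dim(cand))) cand <- matrix(cand, nrow = dim(space)[1L])
    tag <- pmax(tag, cand)
  }
  tag
}

# pooling with argmax bookkeeping, for backprop
pool_labels_fwd <- function(M) {
  N <- dim(M)[1L]; C <- dim(M)[2L]
  tag <- matrix(M[, 1L, ], N, C)
  amax <- matrix(1L, N, C)
  if (C > 1L) for (i in 2:C) {
    cand <- matrix(M[, i, ], N, C)
    upd <- cand > tag                       # strict: ties keep the lowest i
    tag[upd] <- cand[upd]
    amax[upd] <- i
  }
  list(tag = tag, amax = amax)
}

#' Expand per-point features by their label vector
#'
#' The outer product `feature(n) %o% tag(n)` turns an N x f feature map into
#' an N x f x C volume; the label vector acts as per-class weights on the
#' feature channels.
#'
#' @param features N x f feature matrix (Layer 2's features).
#' @param tags N x C label matrix from [pool_labels()].
#' @return N x f x C array.
#' @export
expand_features <- function(features, tags) {
  features <- as.matrix(features); tags <- as.matrix(tags)
  if (nrow(features) != nrow(tags)) stop_dfseg("features/tags row mismatch")
  N <- nrow(features); f <- ncol(features); C <- ncol(tags)
  out <- array(0, c(N, f, C))
  for (c in seq_len(C)) out[, , c] <- features * tags[, c]
  out
}

#' Parameters of an inverted residual block
#'
#' @param f feature width.
#' @param init `"he"` for random initialization or `"zero"` (the block is
#'   then exactly the identity map).
#' @param seed optional seed.
#' @return parameter list usable with [inverted_residual()].
#' @export
ir_params <- function(f, init = c("he", "zero"), seed = NULL) {
  f <- check_count(f, "f")
  init <- match.arg(init)
  f2 <- 2L * f
  if (init == "zero") {
    return(list(W1 = matrix(0, f, f2), b1 = numeric(f2),
                bn1 = list(gamma = numeric(f2), beta = numeric(f2)),
                W2 = matrix(0, f2, f2), b2 = numeric(f2),
                bn2 = list(gamma = numeric(f2), beta = numeric(f2)),
                W3 = matrix(0, f2, f), b3 = numeric(f)))
  }
  with_seed(seed, list(
    W1 = init_mat(f, f2), b1 = numeric(f2),
    bn1 = list(gamma = rep(1, f2), beta = numeric(f2)),
    W2 = init_mat(f2, f2), b2 = numeric(f2),
    bn2 = list(gamma = rep(1, f2), beta = numeric(f2)),
    # small projection so a freshly built block starts near the identity
    W3 = init_mat(f2, f, scale = 0.01), b3 = numeric(f)
  ))
}

ir_fwd <- function(X, p) {
  l1 <- nn_linear_fwd(X, p$W1, p$b1)
  n1 <- nn_bn_fwd(l1$out, p$bn1$gamma, p$bn1$beta)
  r1 <- nn_relu_fwd(n1$out)
  l2 <- nn_linear_fwd(r1$out, p$W2, p$b2)
  n2 <- nn_bn_fwd(l2$out, p$bn2$gamma, p$bn2$beta)
  r2 <- nn_relu_fwd(n2$out)
  l3 <- nn_linear_fwd(r2$out, p$W3, p$b3)
  list(out = l3$out + X,
       cache = list(l1 = l1$cache, n1 = n1$cache, r1 = r1$cache,
                    l2 = l2$cache, n2 = n2$cache, r2 = r2$cache, l3 = l3$cache))
}

ir_bwd <- function(dY, cache) {
  g3 <- nn_linear_bwd(dY, cache$l3)
  d <- nn_relu_bwd(g3$dX, cache$r2)
  gb2 <- nn_bn_bwd(d, cache$n2)
  g2 <- nn_linear_bwd(gb2$dX, cache$l2)
  d <- nn_relu_bwd(g2$dX, cache$r1)
  gb1 <- nn_bn_bwd(d, cache$n1)
  g1 <- nn_linear_bwd(gb1$dX, cache$l1)
  list(dX = g1$dX + dY,                 # residual path
       grads = list(W1 = g1$dW, b1 = g1$db,
                    bn1 = list(gamma = gb1$dgamma, beta = gb1$dbeta),
                    W2 = g2$dW, b2 = g2$db,
                    bn2 = list(gamma = gb2$dgamma, beta = gb2$dbeta),
                    W3 = g3$dW, b3 = g3$db))
}

#' Inverted residual block
#'
#' Per-point expand-transform-project map `f -> 2f -> 2f -> f` (each step a
#' shared linear layer, the first two followed by normalization and ReLU)
#' with a skip connection adding the input. With all-zero parameters the
#' block is exactly the identity.
#'
#' @param features N x f feature matrix.
#' @param params an [ir_params()] list.
#' @return N x f feature matrix.
#' @export
inverted_residual <- function(features, params) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(params$W1)) {
    stop_dfseg("feature width %d does not match block input %d",
               ncol(features), nrow(params$W1))
  }
  ir_fwd(features, params)$out
}

#' Parameters of a full dynamic segmentation layer
#'
#' Two Seg blocks (one per input layer), the learned `C -> 1` contraction
#' over the class axis (`w`, `b0`), and an inverted residual block.
#'
#' @param f feature width of the running features (layer 2).
#' @param f1 feature width of layer 1 (default `f`).
#' @param C number of classes.
#' @param seed optional seed.
#' @return parameter list usable with [dynamic_layer()].
#' @export
dynamic_params <- function(f, C, f1 = f, seed = NULL) {
  with_seed(seed, list(
    segA = seg_params(f1, C),
    segB = seg_params(f, C),
    w = rep(1, C), b0 = 0,
    ir = ir_params(f)
  ))
}

# pairing objective: per point, each row of M should be largest on the
# diagonal; softmax cross-entropy of row i against target i, averaged
pairing_loss_fwd <- function(M) {
  N <- dim(M)[1L]; C <- dim(M)[2L]
  loss <- 0
  dM <- array(0, dim(M))
  for (i in seq_len(C)) {
    row <- matrix(M[, i, ], N, C)
    sx <- softmax_xent(row, rep(i, N))
    loss <- loss + sx$loss
    dM[, i, ] <- sx$dlogits
  }
  list(loss = loss / C, dM = dM / C)
}

#' Auxiliary pairing loss of an embedding space
#'
#' Diagonal-dominance objective: for every point, each row of the C x C
#' pairing matrix is scored by softmax cross-entropy against its diagonal
#' index, encouraging real pairings to dominate incorrect ones.
#'
#' @param space N x C x C array from [embedding_space()].
#' @return scalar loss (mean over points and rows).
#' @export
pairing_loss <- function(space) pairing_loss_fwd(space)$loss

dyn_fwd <- function(l1, l2, p) {
  sa <- seg_fwd(l1, p$segA)
  sb <- seg_fwd(l2, p$segB)
  na <- nn_l2norm_fwd(sa$out)
  nb <- nn_l2norm_fwd(sb$out)
  Fh <- na$out; Sh <- nb$out
  N <- nrow(Fh); C <- ncol(Fh)
  M <- array(0, c(N, C, C))
  for (i in seq_len(C)) M[, i, ] <- Fh[, i] * Sh
  pl <- pool_labels_fwd(M)
  s <- drop(pl$tag %*% p$w)
  E <- l2 * s + p$b0
  ir <- ir_fwd(E, p$ir)
  list(out = ir$out, F = sa$out, S = sb$out, M = M, tag = pl$tag,
       cache = list(segA = sa$cache, segB = sb$cache, na = na$cache,
                    nb = nb$cache, Fh = Fh, Sh = Sh, amax = pl$amax,
                    tag = pl$tag, s = s, l2 = l2, ir = ir$cache))
}

# dM_extra carries the (already weighted) pairing-loss gradient on M
dyn_bwd <- function(dout, cache, p, dM_extra = NULL) {
  g_ir <- ir_bwd(dout, cache$ir)
  dE <- g_ir$dX
  dl2 <- dE * cache$s
  ds <- rowSums(dE * cache$l2)
  db0 <- sum(dE)
  dw <- drop(crossprod(cache$tag, ds))
  dtag <- outer(ds, p$w)
  N <- nrow(dtag); C <- ncol(dtag)
  dM <- if (is.null(dM_extra)) array(0, c(N, C, C)) else dM_extra
  for (j in seq_len(C)) {
    dM[cbind(seq_len(N), cache$amax[, j], j)] <-
      dM[cbind(seq_len(N), cache$amax[, j], j)] + dtag[, j]
  }
  Fh <- cache$Fh; Sh <- cache$Sh
  dFh <- matrix(0, N, C); dSh <- matrix(0, N, C)
  for (i in seq_len(C)) {
    Mi <- matrix(dM[, i, ], N, C)
    dFh[, i] <- rowSums(Mi * Sh)
    dSh <- dSh + Mi * Fh[, i]
  }
  dF <- nn_l2norm_bwd(dFh, cache$na)
  dS <- nn_l2norm_bwd(dSh, cache$nb)
  ga <- seg_bwd(dF, cache$segA)
  gb <- seg_bwd(dS, cache$segB)
  list(dl1 = ga$dX, dl2 = dl2 + gb$dX,
       grads = list(segA = ga$grads, segB = gb$grads, w = dw, b0 = db0,
                    ir = g_ir$grads))
}

#' One dynamic segmentation layer
#'
#' Composes the fusion segmentation module with an inverted residual block:
#' Seg blocks on the two input layers produce pre-labels, their pairing
#' space is max-pooled into a label matrix, the label matrix expands Layer
#' 2's features (`N x f -> N x f x C`), a learned `C -> 1` combination over
#' the class axis contracts the volume back to width f, and the inverted
#' residual block transforms the result. The expansion and contraction are
#' fused algebraically (the contraction of `feature %o% tag` by weights `w`
#' equals `feature * sum(tag * w)`), which avoids materializing the volume.
#'
#' @param layer1_features N x f1 features of the first input layer.
#' @param layer2_features N x f features of the second input layer (these
#'   are the features that flow onward).
#' @param params a [dynamic_params()] list.
#' @return list with `features` (N x f output), `pre_labels_1`,
#'   `pre_labels_2` (the two N x C Seg outputs, used by the auxiliary
#'   pairing loss), `embedding` (N x C x C pairing space) and `tags`
#'   (N x C label matrix).
#' @export
dynamic_layer <- function(layer1_features, layer2_features, params) {
  l1 <- as.matrix(layer1_features); l2 <- as.matrix(layer2_features)
  if (nrow(l1) != nrow(l2)) stop_dfseg("layer inputs disagree on N")
  r <- dyn_fwd(l1, l2, params)
  list(features = r$out, pre_labels_1 = r$F, pre_labels_2 = r$S,
       embedding = r$M, tags = r$tag)
}
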