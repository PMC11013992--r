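# Differentiable building blocks. Each primitive has a forward returning
# (output, cache) and a backward mapping upstream gradients to input and
# parameter gradients; the chain is assembled by hand in fusseg.R/network.R.
# Normalization layers use the statistics of the points of the current cloud
# (the cloud is the batch) in both training and inference, so every forward
# pass is a pure function of its input.

nn_linear_fwd <- function(X, W, b) {
  Y <- X %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(out = Y, cache = list(X = X, W = W))
}

nn_linear_bwd <- function(dY, cache) {
  list(dX = dY %*% t(cache$W),
       dW = crossprod(cache$X, dY),
       db = colSums(dY))
}

nn_bn_fwd <- function(X, gamma, beta, eps = 1e-5) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  v <- colMeans(Xc * Xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(Xc, 2L, istd, "*")
  Y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = Y, cache = list(xhat = xhat, istd = istd, gamma = gamma))
}

nn_bn_bwd <- function(dY, cache) {
  n <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- sweep(dY, 2L, cache$gamma, "*")
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dX <- sweep(dxhat, 2L, s1 / n, "-") - sweep(xhat, 2L, s2 / n, "*")
  dX <- sweep(dX, 2L, cache$istd, "*")
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

nn_relu_fwd <- function(X) list(out = pmax(X, 0), cache = X > 0)
nn_relu_bwd <- function(dY, cache) dY * cache

# L2-normalize rows; backward projects out the radial component
nn_l2norm_fwd <- function(X, eps = 1e-12) {
  nrm <- sqrt(rowSums(X * X))
  nrm <- pmax(nrm, eps)
  list(out = X / nrm, cache = list(X = X, nrm = nrm))
}

nn_l2norm_bwd <- function(dY, cache) {
  X <- cache$X; nrm <- cache$nrm
  dY / nrm - X * (rowSums(dY * X) / nrm^3)
}

# -- parameter trees ----------------------------------------------------------

# apply f elementwise over the numeric leaves of (possibly several) nested
# lists with identical structure
tree_map <- function(f, tree, ...) {
  others <- list(...)
  if (is.list(tree)) {
    out <- vector("list", length(tree))
    names(out) <- names(tree)
    for (i in seq_along(tree)) {
      out[[i]] <- do.call(tree_map, c(list(f, tree[[i]]), lapply(others, `[[`, i)))
    }
    out
  } else if (is.null(tree)) {
    NULL
  } else {
    do.call(f, c(list(tree), others))
  }
}

tree_zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

tree_sum <- function(f, tree) {
  tot <- 0
  walk <- function(t) {
    if (is.list(t)) for (el in t) walk(el)
    else if (!is.null(t)) tot <<- tot + f(t)
  }
  walk(tree)
  tot
}

n_parameters <- function(params) tree_sum(length, params)

# He-style initialization
init_mat <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  matrix(stats::rnorm(n_in * n_out, sd = scale), n_in, n_out)
}

# -- AdamW --------------------------------------------------------------------

adamw_state <- function(params) {
  list(m = tree_zeros_like(params), v = tree_zeros_like(params), t = 0L)
}

# decoupled weight decay, applied to weight matrices only (biases and
# normalization parameters are exempt, the usual convention)
adamw_step <- function(params, grads, state, lr = 1e-3, betas = c(0.9, 0.999),
                       eps = 1e-8, weight_decay = 1e-4) {
  state$t <- state$t + 1L
  b1 <- betas[1L]; b2 <- betas[2L]
  state$m <- tree_map(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map(function(v, g) b2 * v + (1 - b2) * g * g, state$v, grads)
  c1 <- 1 / (1 - b1^state$t)
  c2 <- 1 / (1 - b2^state$t)
  params <- tree_map(function(p, m, v) {
    upd <- lr * (c1 * m) / (sqrt(c2 * v) + eps)
    if (is.matrix(p)) upd <- upd + lr * weight_decay * p
    p - upd
  }, params, state$m, state$v)
  list(params = params, state = state)
}

# softmax cross-entropy over rows; targets are 1-based class indices.
# returns mean loss and gradient wrt logits
softmax_xent <- function(logits, targets) {
  n <- nrow(logits)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  Z <- rowSums(ex)
  P <- ex / Z
  loss <- mean(log(Z) + mx - logits[cbind(seq_len(n), targets)])
  dlogits <- P
  dlogits[cbind(seq_len(n), targets)] <- dlogits[cbind(seq_len(n), targets)] - 1
  list(loss = loss, dlogits = dlogits / n, probs = P)
}
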