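# Local feature aggregation: training-free trigonometric positional encoding,
# sampling/grouping, the set-abstraction cascade, and reconstruction back to
# full resolution. Everything here is deterministic given the sampler seed;
# no learnable parameters are involved.

#' Configuration of the trigonometric positional encoder
#'
#' The encoder maps raw coordinates to a high-dimensional vector without any
#' learnable map. Each axis contributes `FI/3` channels arranged in
#' sine/cosine pairs indexed by `t = 0 .. FI/6 - 1`:
#' `sin(mu * a / nu^(6t/FI))`, `cos(mu * a / nu^(6t/FI))`, so `mu` scales the
#' magnitude and `nu` sets the wavelength progression across channels.
#'
#' @param FI output dimension, divisible by 6 (default 144).
#' @param mu magnitude scale (default 1000).
#' @param nu wavelength base (default 100).
#' @return a `pose_config` list.
#' @export
pose_config <- function(FI = 144L, mu = 1000, nu = 100) {
  FI <- check_count(FI, "FI", min = 6L)
  if (FI %% 6L != 0L) stop_dfseg("`FI` must be divisible by 6, got %d", FI)
  if (mu <= 0 || nu <= 0) stop_dfseg("`mu` and `nu` must be positive")
  structure(list(FI = FI, mu = mu, nu = nu), class = "pose_config")
}

#' Trigonometric positional encoding of 3D coordinates
#'
#' @param coords N x 3 coordinate matrix.
#' @param config a [pose_config()].
#' @return N x FI feature matrix: the per-axis encodings concatenated in
#'   x, y, z order.
#' @export
pose_encode <- function(coords, config = pose_config()) {
  stopifnot(inherits(config, "pose_config"))
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop_dfseg("`coords` must be N x 3")
  FI <- config$FI
  n_pair <- FI %/% 6L
  freq <- config$mu / config$nu^(6 * (seq_len(n_pair) - 1L) / FI)
  out <- matrix(0, nrow(coords), FI)
  odd <- seq(1L, FI %/% 3L, by = 2L)
  for (ax in 1:3) {
    ang <- outer(coords[, ax], freq)        # N x FI/6
    block <- matrix(0, nrow(coords), FI %/% 3L)
    block[, odd] <- sin(ang)
    block[, odd + 1L] <- cos(ang)
    out[, (ax - 1L) * (FI %/% 3L) + seq_len(FI %/% 3L)] <- block
  }
  out
}

#' Farthest point sampling
#'
#' Greedy centroid selection: starting from `start_index`, repeatedly pick
#' the point whose minimum Euclidean distance to the already-selected set is
#' largest (ties broken by lowest index). Depends only on pairwise
#' distances, so the selection is invariant under rigid motions of the cloud.
#'
#' @param coords N x 3 coordinate matrix.
#' @param m number of centroids, `1 <= m <= N`.
#' @param start_index index of the first centroid (1-based, default 1).
#' @return integer vector of `m` centroid indices in selection order.
#' @export
fps <- function(coords, m, start_index = 1L) {
  coords <- as.matrix(coords)
  N <- nrow(coords)
  m <- check_count(m, "m")
  if (m > N) stop_dfseg("m = %d exceeds the number of points (%d)", m, N)
  start_index <- check_count(start_index, "start_index")
  stopifnot(start_index <= N)
  sel <- integer(m)
  sel[1L] <- start_index
  if (m == 1L) return(sel)
  mind <- sqdist_to(coords, coords[start_index, ])
  for (i in 2:m) {
    j <- which.max(mind)              # first max = lowest index on ties
    sel[i] <- j
    mind <- pmin(mind, sqdist_to(coords, coords[j, ]))
  }
  sel
}

#' Random centroid sampling
#'
#' @param coords N x 3 coordinate matrix.
#' @param m number of centroids, `1 <= m <= N`.
#' @param seed integer seed; fixed seed gives identical draws.
#' @return integer vector of `m` distinct indices, uniform without
#'   replacement.
#' @export
random_sample <- function(coords, m, seed = NULL) {
  N <- nrow(as.matrix(coords))
  m <- check_count(m, "m")
  if (m > N) stop_dfseg("m = %d exceeds the number of points (%d)", m, N)
  with_seed(seed, sample.int(N, m))
}

#' k-nearest-neighbour grouping around centroids
#'
#' For each centroid, the k points of the cloud with smallest Euclidean
#' distance to it. Rows are sorted by ascending distance; ties are broken by
#' lowest index, except that the centroid itself (distance 0) always comes
#' first among its ties, so it is always a member of its own group.
#'
#' @param coords N x 3 coordinate matrix.
#' @param centroid_indices integer vector of m centroid indices (1-based).
#' @param k neighbourhood size, `1 <= k <= N`.
#' @return m x k integer matrix of neighbour indices.
#' @export
knn_group <- function(coords, centroid_indices, k) {
  coords <- as.matrix(coords)
  N <- nrow(coords)
  k <- check_count(k, "k")
  if (k > N) stop_dfseg("k = %d exceeds the number of points (%d)", k, N)
  ci <- as.integer(centroid_indices)
  stopifnot(all(ci >= 1L), all(ci <= N))
  out <- matrix(0L, length(ci), k)
  idx <- seq_len(N)
  for (r in seq_along(ci)) {
    d <- sqdist_to(coords, coords[ci[r], ])
    out[r, ] <- order(d, idx != ci[r], idx)[seq_len(k)]
  }
  out
}

#' One set-abstraction stage
#'
#' Samples `n_centroids` centroids (FPS or RS), groups `k` neighbours per
#' centroid, encodes each neighbour's coordinates *relative to its centroid*
#' with the trigonometric encoder, combines them with the group features
#' (neighbour feature concatenated with the centroid feature, then modulated
#' by the relative-position encoding: `(g + p) * p`), and aggregates each
#' group by the sum of element-wise max pooling and average pooling. The
#' output feature width is twice the input width.
#'
#' @param coords N x 3 coordinates of the current hierarchy level.
#' @param features N x d feature matrix of the current level.
#' @param n_centroids number of centroids to keep.
#' @param k neighbourhood size (default 64).
#' @param sampler `"fps"` or `"rs"`.
#' @param config a [pose_config()] used for the relative encodings.
#' @param seed seed for the RS sampler (ignored for FPS).
#' @param start_index FPS start point (ignored for RS).
#' @return list with `coords` (n_centroids x 3), `features`
#'   (n_centroids x 2d) and `indices` (the sampled centroid indices).
#' @export
sa_stage <- function(coords, features, n_centroids, k = 64L,
                     sampler = c("fps", "rs"), config = pose_config(),
                     seed = NULL, start_index = 1L) {
  sampler <- match.arg(sampler)
  coords <- as.matrix(coords)
  features <- as.matrix(features)
  if (nrow(features) != nrow(coords)) stop_dfseg("features/coords row mismatch")
  k <- check_count(k, "k")
  ci <- if (sampler == "fps") fps(coords, n_centroids, start_index)
        else random_sample(coords, n_centroids, seed)
  nbr <- knn_group(coords, ci, k)
  m <- length(ci)
  flat <- as.vector(t(nbr))                       # group-major, k rows per centroid
  ctr <- rep(ci, each = k)
  rel <- coords[flat, , drop = FALSE] - coords[ctr, , drop = FALSE]
  d_in <- ncol(features)
  d_out <- 2L * d_in
  P <- pose_encode(rel, config)
  P <- P[, ((seq_len(d_out) - 1L) %% config$FI) + 1L, drop = FALSE]
  G <- cbind(features[flat, , drop = FALSE], features[ctr, , drop = FALSE])
  H <- (G + P) * P
  grp <- rep(seq_len(m), each = k)
  avg <- rowsum(H, grp, reorder = FALSE) / k
  mx <- H[seq(1L, by = k, length.out = m), , drop = FALSE]
  if (k > 1L) for (j in 2:k) {
    mx <- pmax(mx, H[seq(j, by = k, length.out = m), , drop = FALSE])
  }
  feat <- mx + avg
  dimnames(feat) <- NULL
  list(coords = coords[ci, , drop = FALSE], features = feat, indices = ci)
}

# inverse-distance-weighted propagation of centroid features to query points
# (power 2, over the `n_neighbors` nearest centroids)
idw_propagate <- function(query, ref_coords, ref_feats, n_neighbors = 3L) {
  nq <- nrow(query)
  m <- nrow(ref_coords)
  nn <- min(n_neighbors, m)
  D <- matrix(0, nq, m)
  for (j in seq_len(m)) D[, j] <- sqdist_to(query, ref_coords[j, ])
  idx <- matrix(0L, nq, nn)
  w <- matrix(0, nq, nn)
  for (h in seq_len(nn)) {
    idx[, h] <- max.col(-D, ties.method = "first")
    d <- D[cbind(seq_len(nq), idx[, h])]
    w[, h] <- 1 / (d + 1e-12)                  # d is squared: power-2 IDW
    D[cbind(seq_len(nq), idx[, h])] <- Inf
  }
  w <- w / rowSums(w)
  out <- w[, 1L] * ref_feats[idx[, 1L], , drop = FALSE]
  if (nn > 1L) for (h in 2:nn) {
    out <- out + w[, h] * ref_feats[idx[, h], , drop = FALSE]
  }
  out
}

#' Full local feature aggregation forward pass
#'
#' Runs the full-resolution trigonometric embedding (stage 0), then
#' `n_stages` set-abstraction stages that halve the point count and double
#' the feature width (cascade `N -> 0.5N -> 0.25N -> 0.125N` for the default
#' three stages), reconstructs every stage back to full resolution by
#' inverse-distance-weighted interpolation over the 3 nearest centroids, and
#' concatenates all hierarchy levels. With the defaults (`FI = 144`, three
#' stages) the per-point feature dimension is
#' `144 + 288 + 576 + 1152 = 2160`.
#'
#' @param cloud a `point_cloud` or an N x 3 coordinate matrix; N must be
#'   divisible by `2^n_stages`.
#' @param n_stages number of set-abstraction stages (default 3).
#' @param config a [pose_config()].
#' @param k neighbourhood size (default 64). With `grouping = FALSE` the
#'   neighbourhood collapses to the centroid itself (k = 1), the
#'   "sampling-without-grouping" ablation arm.
#' @param sampler `"fps"` or `"rs"`.
#' @param seed seed for the RS sampler.
#' @param grouping logical; `FALSE` disables k-NN grouping.
#' @return N x f feature matrix, `f = FI * (2^(n_stages+1) - 1)`; the
#'   per-stage centroid counts are attached as `attr(, "stage_sizes")` and
#'   the per-level dimensions as `attr(, "level_dims")`.
#' @export
lfa_forward <- function(cloud, n_stages = 3L, config = pose_config(),
                        k = 64L, sampler = c("fps", "rs"), seed = NULL,
                        grouping = TRUE) {
  sampler <- match.arg(sampler)
  coords <- if (inherits(cloud, "point_cloud")) cloud$coords else as.matrix(cloud)
  n_stages <- check_count(n_stages, "n_stages", min = 0L)
  N <- nrow(coords)
  if (n_stages > 0L && N %% 2L^n_stages != 0L) {
    stop_dfseg("N = %d is not divisible by 2^%d; subsample the cloud first", N, n_stages)
  }
  if (!grouping) k <- 1L
  X0 <- pose_encode(coords, config)
  if (n_stages == 0L) {
    attr(X0, "stage_sizes") <- integer(0)
    attr(X0, "level_dims") <- config$FI
    return(X0)
  }
  levels <- vector("list", n_stages)
  cur_coords <- coords
  cur_feat <- X0
  for (s in seq_len(n_stages)) {
    st <- sa_stage(cur_coords, cur_feat, n_centroids = N %/% 2L^s,
                   k = min(k, nrow(cur_coords)), sampler = sampler,
                   config = config,
                   seed = if (is.null(seed)) NULL else seed + s)
    cur_coords <- st$coords
    cur_feat <- st$features
    levels[[s]] <- st
  }
  parts <- vector("list", n_stages + 1L)
  parts[[1L]] <- X0
  for (s in seq_len(n_stages)) {
    parts[[s + 1L]] <- idw_propagate(coords, levels[[s]]$coords, levels[[s]]$features)
  }
  out <- do.call(cbind, parts)
  attr(out, "stage_sizes") <- vapply(levels, function(l) nrow(l$coords), 0L)
  attr(out, "level_dims") <- vapply(parts, ncol, 0L)
  out
}
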