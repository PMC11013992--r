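# Independent brute-force oracles, written against the stated definitions
# (not the package internals) and kept deliberately naive.

# greedy farthest point sampling, O(N^2 m): recompute every candidate's
# minimum distance to the selected set at each step; ties -> lowest index
fps_oracle <- function(coords, m, start_index = 1L) {
  sel <- start_index
  while (length(sel) < m) {
    best <- -1; best_i <- NA_integer_
    for (i in seq_len(nrow(coords))) {
      di <- min(sqrt(colSums((t(coords[sel, , drop = FALSE]) - coords[i, ])^2)))
      if (di > best) { best <- di; best_i <- i }
    }
    sel <- c(sel, best_i)
  }
  sel
}

# k nearest neighbours by full distance-table sort; ascending distance,
# ties by lowest index with the centroid first among its ties
knn_oracle <- function(coords, centroid_indices, k) {
  out <- matrix(0L, length(centroid_indices), k)
  for (r in seq_along(centroid_indices)) {
    ci <- centroid_indices[r]
    d <- sqrt(colSums((t(coords) - coords[ci, ])^2))
    rank_tbl <- data.frame(d = d, not_self = seq_along(d) != ci, i = seq_along(d))
    ord <- with(rank_tbl, order(d, not_self, i))
    out[r, ] <- ord[seq_len(k)]
  }
  out
}

# scalar-loop evaluation of the trigonometric encoding
pose_oracle <- function(coords, FI, mu, nu) {
  n_pair <- FI / 6
  out <- matrix(0, nrow(coords), FI)
  for (n in seq_len(nrow(coords))) {
    for (ax in 1:3) {
      for (t in 0:(n_pair - 1)) {
        val <- mu * coords[n, ax] / nu^(6 * t / FI)
        base <- (ax - 1) * (FI / 3)
        out[n, base + 2 * t + 1] <- sin(val)
        out[n, base + 2 * t + 2] <- cos(val)
      }
    }
  }
  out
}

# per-point counting oracles for the segmentation metrics
confusion_oracle <- function(truth, pred, C) {
  cm <- matrix(0, C, C)
  for (n in seq_along(truth)) {
    cm[truth[n] + 1, pred[n] + 1] <- cm[truth[n] + 1, pred[n] + 1] + 1
  }
  cm
}

accuracy_oracle <- function(truth, pred) mean(truth == pred)

miou_oracle <- function(truth, pred, C) {
  ious <- c()
  for (cl in 0:(C - 1)) {
    inter <- sum(truth == cl & pred == cl)
    union <- sum(truth == cl | pred == cl)
    if (union > 0) ious <- c(ious, inter / union)
  }
  mean(ious)
}

# nearest-neighbour classifier for the scene-separability property
nn1_classify <- function(train_coords, train_labels, test_coords) {
  vapply(seq_len(nrow(test_coords)), function(i) {
    d <- colSums((t(train_coords) - test_coords[i, ])^2)
    train_labels[which.min(d)]
  }, integer(1))
}
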