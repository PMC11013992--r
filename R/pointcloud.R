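# Point-cloud container, class taxonomies and geometric preprocessing.

#' Construct a point cloud
#'
#' The universal currency of the package: an N x 3 matrix of coordinates in
#' meters with optional per-point integer class labels. Labels use the raw
#' on-disk values (0-based), matching the XYZL file format.
#'
#' @param coords numeric matrix with N rows and 3 columns (X, Y, Z), meters.
#' @param labels optional integer vector of length N with per-point class
#'   values; `NULL` for unlabeled clouds.
#' @param name scene identifier string.
#' @return an object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(matrix(runif(30), ncol = 3), labels = rep(0L, 10))
#' n_points(pc)
#' @export
point_cloud <- function(coords, labels = NULL, name = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop_dfseg("`coords` must have 3 columns, got %d", ncol(coords))
  if (nrow(coords) < 1L) stop_dfseg("a point cloud needs at least one point")
  if (!all(is.finite(coords))) stop_dfseg("`coords` contain non-finite values")
  dimnames(coords) <- NULL
  if (!is.null(labels)) {
    if (length(labels) != nrow(coords)) {
      stop_dfseg("length(labels) == %d but cloud has %d points", length(labels), nrow(coords))
    }
    if (any(!is.finite(labels)) || any(labels != round(labels))) {
      stop_dfseg("`labels` must be integers")
    }
    labels <- as.integer(labels)
  }
  structure(list(coords = coords, labels = labels, name = as.character(name)[1L]),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a `point_cloud`.
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$coords)

#' @export
print.point_cloud <- function(x, ...) {
  lab <- if (is.null(x$labels)) "unlabeled" else {
    sprintf("%d classes present", length(unique(x$labels)))
  }
  rng <- apply(x$coords, 2L, range)
  cat(sprintf("<point_cloud> %s: %d points, %s\n",
              if (nzchar(x$name)) x$name else "(unnamed)", n_points(x), lab))
  cat(sprintf("  extent: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f] m\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Label taxonomy of an orchard scene
#'
#' Two taxonomies are supported. The complex one (C = 8) covers scenes with
#' bystanders and clutter: leaves = 0, trunks = 1, pots = 2, scaffolds = 3,
#' grounds = 4, people = 5, indicators = 6, others = 7. The simple one
#' (C = 5) keeps the first five classes. Label values are contiguous 0..C-1.
#'
#' @param class_set `"simple"` or `"complex"`.
#' @return a `class_map`: list with `mapping` (named integer vector,
#'   name -> value) and `C` (number of classes).
#' @export
class_map <- function(class_set = c("simple", "complex")) {
  class_set <- match.arg(class_set)
  nm <- c("leaves", "trunks", "pots", "scaffolds", "grounds",
          "people", "indicators", "others")
  C <- if (class_set == "simple") 5L else 8L
  mapping <- stats::setNames(seq_len(C) - 1L, nm[seq_len(C)])
  structure(list(mapping = mapping, C = C, class_set = class_set),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat(sprintf("<class_map> %s taxonomy, C = %d\n", x$class_set, x$C))
  cat(paste(sprintf("  %d = %s", x$mapping, names(x$mapping)), collapse = "\n"), "\n")
  invisible(x)
}

#' @noRd
check_labels_in_map <- function(cloud, map) {
  if (!is.null(cloud$labels) && !all(cloud$labels %in% map$mapping)) {
    bad <- setdiff(unique(cloud$labels), map$mapping)
    stop_dfseg("labels outside the %s taxonomy: %s", map$class_set,
               paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Translate a scene so its bounding-box corner sits at the origin
#'
#' Scene coordinates are re-expressed relative to the minimum corner of the
#' axis-aligned bounding box ("lower left point of the box"), the convention
#' used when working scenes are cut from a larger scan. The operation is a
#' pure translation: labels and all pairwise distances are unchanged, and it
#' is idempotent.
#'
#' @param cloud a `point_cloud`.
#' @return the translated `point_cloud`.
#' @export
normalize_scene <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  mins <- apply(cloud$coords, 2L, min)
  cloud$coords <- sweep(cloud$coords, 2L, mins, "-")
  cloud
}

#' Randomly subsample a cloud to a fixed number of points
#'
#' Fixed-size inputs are required by the network (default 4096 points).
#' Sampling is uniform without replacement when the cloud has at least
#' `n_points` points and with replacement otherwise, so the result always
#' has exactly `n_points` rows. Labels follow their points.
#'
#' @param cloud a `point_cloud`.
#' @param n_points target point count.
#' @param seed integer seed; fixed seed gives identical output.
#' @return a `point_cloud` with `n_points` points.
#' @export
subsample <- function(cloud, n_points = 4096L, seed = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  n_points <- check_count(n_points, "n_points")
  N <- nrow(cloud$coords)
  idx <- with_seed(seed, sample.int(N, n_points, replace = N < n_points))
  point_cloud(cloud$coords[idx, , drop = FALSE],
              labels = if (is.null(cloud$labels)) NULL else cloud$labels[idx],
              name = cloud$name)
}

#' Split scene identifiers into train and test sets
#'
#' Default train fraction is 2/3, the proportion used when a scene corpus is
#' split for network training (e.g. 206 of 309 scenes).
#'
#' @param scenes character vector of scene identifiers.
#' @param train_fraction fraction of scenes assigned to training.
#' @param seed integer seed.
#' @return list with `train`, `test` (disjoint, covering all scenes) and `seed`.
#' @export
split_scenes <- function(scenes, train_fraction = 2 / 3, seed = 1L) {
  scenes <- as.character(scenes)
  if (anyDuplicated(scenes)) stop_dfseg("scene identifiers must be unique")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_dfseg("`train_fraction` must be in (0, 1)")
  }
  n_train <- max(1L, min(length(scenes) - 1L, round(length(scenes) * train_fraction)))
  tr <- with_seed(seed, sample(scenes, n_train))
  list(train = sort(tr), test = sort(setdiff(scenes, tr)), seed = as.integer(seed))
}
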