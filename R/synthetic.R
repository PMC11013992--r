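# Synthetic labelled orchard scenes.
#
# Emulates the working-scene corpus used for network training: 2-3 potted
# trees per scene, some trunks supported by slanted wooden stakes, ground
# plane, and (in the complex taxonomy) people, indicator signs and clutter.
# Points are sampled on primitive surfaces in proportion to surface area
# (LiDAR returns come from surfaces, not volumes), perturbed by isotropic
# Gaussian noise, and thinned by an angular occlusion sector per tree to
# mimic a single-viewpoint scanner.

#' Configuration of a synthetic orchard scene
#'
#' @param n_trees number of trees (2 or 3 when `NULL`, drawn per scene).
#' @param extent numeric length-3 scene box (x, y, z) in meters.
#' @param points_per_scene total surface samples before occlusion; when
#'   `NULL`, drawn uniformly from 10,000..60,000 per scene, the typical size
#'   of a working scene cut from a full scan.
#' @param class_set `"simple"` (C = 5) or `"complex"` (C = 8).
#' @param noise_sd isotropic Gaussian noise, meters (default 0.01, about the
#'   ranging noise of a solid-state scanner at close range).
#' @param occlusion_fraction fraction of each tree's azimuth hidden from the
#'   virtual scanner, in `[0, 1)`.
#' @param seed integer seed; scenes are deterministic per seed.
#' @return a `scene_config` list.
#' @export
scene_config <- function(n_trees = NULL, extent = c(10, 10, 6),
                         points_per_scene = NULL,
                         class_set = c("simple", "complex"),
                         noise_sd = 0.01, occlusion_fraction = 0.2,
                         seed = 1L) {
  class_set <- match.arg(class_set)
  if (!is.null(points_per_scene)) {
    points_per_scene <- check_count(points_per_scene, "points_per_scene", min = 1000L)
  }
  if (!is.null(n_trees)) n_trees <- check_count(n_trees, "n_trees")
  stopifnot(length(extent) == 3L, all(extent > 0))
  if (noise_sd < 0) stop_dfseg("`noise_sd` must be >= 0")
  if (occlusion_fraction < 0 || occlusion_fraction >= 1) {
    stop_dfseg("`occlusion_fraction` must be in [0, 1)")
  }
  structure(list(n_trees = n_trees, extent = as.numeric(extent),
                 points_per_scene = points_per_scene, class_set = class_set,
                 noise_sd = noise_sd, occlusion_fraction = occlusion_fraction,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# surface area of an ellipsoid (Thomsen's approximation, p = 1.6075)
ellipsoid_area <- function(a, b, c) {
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

sample_ellipsoid_shell <- function(n, center, axes) {
  v <- matrix(stats::rnorm(3L * n), ncol = 3L)
  v <- v / sqrt(rowSums(v * v))
  sweep(v %*% diag(axes), 2L, center, "+")
}

sample_cylinder <- function(n, center_xy, radius, z0, z1) {
  th <- stats::runif(n, 0, 2 * pi)
  cbind(center_xy[1L] + radius * cos(th),
        center_xy[2L] + radius * sin(th),
        stats::runif(n, z0, z1))
}

# thin cylinder along an arbitrary segment p0 -> p1
sample_tube <- function(n, p0, p1, radius) {
  ax <- p1 - p0
  len <- sqrt(sum(ax * ax))
  u <- ax / len
  # orthonormal frame around u
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1 * e1))
  e2 <- c(u[2L] * e1[3L] - u[3L] * e1[2L],
          u[3L] * e1[1L] - u[1L] * e1[3L],
          u[1L] * e1[2L] - u[2L] * e1[1L])
  t <- stats::runif(n, 0, len)
  th <- stats::runif(n, 0, 2 * pi)
  outer(t, u) + radius * (outer(cos(th), e1) + outer(sin(th), e2)) +
    matrix(p0, n, 3L, byrow = TRUE)
}

sample_cone_frustum <- function(n, center_xy, r_base, r_top, z0, h) {
  z <- stats::runif(n, 0, h)
  r <- r_base + (r_top - r_base) * z / h
  th <- stats::runif(n, 0, 2 * pi)
  cbind(center_xy[1L] + r * cos(th), center_xy[2L] + r * sin(th), z0 + z)
}

sample_rect_xy <- function(n, ex, ey) {
  cbind(stats::runif(n, 0, ex), stats::runif(n, 0, ey), 0)
}

place_trunks <- function(n_trees, extent, min_spacing = 2) {
  margin <- 1
  lo <- c(margin, margin)
  hi <- c(extent[1L] - margin, extent[2L] - margin)
  if (any(hi <= lo)) stop_dfseg("extent too small to place %d trees at >= %g m spacing",
                                n_trees, min_spacing)
  for (try in 1:500) {
    pos <- cbind(stats::runif(n_trees, lo[1L], hi[1L]),
                 stats::runif(n_trees, lo[2L], hi[2L]))
    if (n_trees == 1L) return(pos)
    d <- as.matrix(stats::dist(pos))
    if (min(d[upper.tri(d)]) >= min_spacing) return(pos)
  }
  stop_dfseg("extent too small to place %d trees at >= %g m spacing",
             n_trees, min_spacing)
}

#' Generate one labelled synthetic orchard scene
#'
#' Builds a parametric recipe (ground plane, trunks, ellipsoidal canopy
#' shells, pots, stakes and -- in the complex taxonomy -- a person, an
#' indicator sign and clutter blobs), samples points on primitive surfaces
#' proportional to area, adds Gaussian noise, removes an angular occlusion
#' sector per tree, and normalizes the scene with [normalize_scene()].
#' Every point carries the label of its generating primitive. The geometric
#' recipe (translated to the normalized frame) is attached as
#' `attr(cloud, "recipe")` so tests can assert label-geometry consistency.
#'
#' @param config a [scene_config()].
#' @param name scene identifier.
#' @return a labelled `point_cloud`.
#' @export
generate_scene <- function(config = scene_config(), name = "scene") {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, generate_scene_impl(config, name))
}

generate_scene_impl <- function(config, name) {
  ex <- config$extent[1L]; ey <- config$extent[2L]
  map <- class_map(config$class_set)
  lab <- map$mapping
  n_trees <- if (is.null(config$n_trees)) sample(2:3, 1L) else config$n_trees
  n_total <- if (is.null(config$points_per_scene)) sample(10000:60000, 1L) else config$points_per_scene

  centers <- place_trunks(n_trees, config$extent)
  prims <- list()
  add <- function(label, area, tree, sampler, recipe = NULL) {
    prims[[length(prims) + 1L]] <<- list(label = label, area = area,
                                         tree = tree, sampler = sampler,
                                         recipe = recipe)
  }

  add(lab[["grounds"]], ex * ey, NA_integer_,
      function(n) sample_rect_xy(n, ex, ey))

  pot_h <- 0.3
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    cxy <- centers[i, ]
    r_tr <- stats::runif(1L, 0.05, 0.15)
    h_tr <- stats::runif(1L, 1.5, 3)
    z_base <- pot_h            # trunk emerges from the pot rim
    z_top <- z_base + h_tr
    local({
      cxy <- cxy; r_tr <- r_tr; z_base <- z_base; z_top <- z_top
      add(lab[["trunks"]], 2 * pi * r_tr * h_tr, i,
          function(n) sample_cylinder(n, cxy, r_tr, z_base, z_top))
    })
    # canopy: 2-4 ellipsoidal shells around the trunk top
    n_shell <- sample(2:4, 1L)
    for (s in seq_len(n_shell)) {
      ctr <- c(cxy[1L] + stats::runif(1L, -0.3, 0.3),
               cxy[2L] + stats::runif(1L, -0.3, 0.3),
               z_top + stats::runif(1L, -0.3, 0.3))
      axes <- c(stats::runif(2L, 0.6, 1.2), stats::runif(1L, 0.5, 1.0))
      local({
        ctr <- ctr; axes <- axes
        add(lab[["leaves"]], ellipsoid_area(axes[1L], axes[2L], axes[3L]), i,
            function(n) sample_ellipsoid_shell(n, ctr, axes))
      })
    }
    r_pb <- 0.3; r_pt <- 0.22
    slant <- sqrt((r_pb - r_pt)^2 + pot_h^2)
    local({
      cxy <- cxy
      add(lab[["pots"]], pi * (r_pb + r_pt) * slant, i,
          function(n) sample_cone_frustum(n, cxy, r_pb, r_pt, 0, pot_h))
    })
    has_stake <- i == 1L || stats::runif(1L) < 0.7
    stake <- NULL
    if (has_stake) {
      phi <- stats::runif(1L, 0, 2 * pi)
      foot <- c(cxy + 0.5 * c(cos(phi), sin(phi)), 0)
      top <- c(cxy, z_base + 0.6 * h_tr)
      local({
        foot <- foot; top <- top
        add(lab[["scaffolds"]], 2 * pi * 0.02 * sqrt(sum((top - foot)^2)), i,
            function(n) sample_tube(n, foot, top, 0.02))
      })
      stake <- list(foot = foot, top = top, radius = 0.02)
    }
    trees[[i]] <- list(center = cxy, trunk_radius = r_tr,
                       trunk_base_z = z_base, trunk_top_z = z_top,
                       pot = list(r_base = r_pb, r_top = r_pt, height = pot_h),
                       stake = stake)
  }

  if (config$class_set == "complex") {
    free_spot <- function() {
      for (try in 1:200) {
        p <- c(stats::runif(1L, 0.5, ex - 0.5), stats::runif(1L, 0.5, ey - 0.5))
        if (min(sqdist_to(cbind(centers, 0), c(p, 0))) > 1.5^2) return(p)
      }
      p
    }
    # person: capsule (cylinder trunk + hemispherical cap budgeted by area)
    pp <- free_spot()
    r_p <- stats::runif(1L, 0.15, 0.22)
    h_p <- stats::runif(1L, 1.0, 1.4)
    a_cyl <- 2 * pi * r_p * h_p; a_cap <- 4 * pi * r_p^2
    local({
      pp <- pp; r_p <- r_p; h_p <- h_p; a_cyl <- a_cyl; a_cap <- a_cap
      add(lab[["people"]], a_cyl + a_cap, NA_integer_, function(n) {
        n_cap <- stats::rbinom(1L, n, a_cap / (a_cyl + a_cap))
        body <- sample_cylinder(n - n_cap, pp, r_p, 0, h_p)
        head <- sample_ellipsoid_shell(n_cap, c(pp, h_p), rep(r_p, 3L))
        head <- head[head[, 3L] >= 0, , drop = FALSE]
        rbind(body, head)
      })
    })
    # indicator: thin post plus a planar sign
    ip <- free_spot()
    sign_w <- 0.4; sign_h <- 0.3; post_h <- 1.2
    th_s <- stats::runif(1L, 0, 2 * pi)
    local({
      ip <- ip; th_s <- th_s
      add(lab[["indicators"]],
          2 * pi * 0.02 * post_h + sign_w * sign_h, NA_integer_, function(n) {
        n_sign <- stats::rbinom(1L, n, (sign_w * sign_h) /
                                  (2 * pi * 0.02 * post_h + sign_w * sign_h))
        post <- sample_tube(n - n_sign, c(ip, 0), c(ip, post_h), 0.02)
        u <- stats::runif(n_sign, -sign_w / 2, sign_w / 2)
        v <- stats::runif(n_sign, 0, sign_h)
        sgn <- cbind(ip[1L] + u * cos(th_s), ip[2L] + u * sin(th_s), post_h + v)
        rbind(post, sgn)
      })
    })
    # others: 1-2 convex clutter blobs resting on the ground
    for (b in seq_len(sample(1:2, 1L))) {
      bp <- free_spot()
      axes_b <- stats::runif(3L, 0.1, 0.4)
      local({
        bp <- bp; axes_b <- axes_b
        add(lab[["others"]], ellipsoid_area(axes_b[1L], axes_b[2L], axes_b[3L]),
            NA_integer_, function(n) {
          pts <- sample_ellipsoid_shell(n, c(bp, axes_b[3L]), axes_b)
          pts[pts[, 3L] < 0, 3L] <- 0
          pts
        })
      })
    }
  }

  # allocate points proportional to surface area, with a floor per primitive
  areas <- vapply(prims, `[[`, 0, "area")
  n_i <- pmax(30L, round(n_total * areas / sum(areas)))
  n_i[which.max(n_i)] <- n_i[which.max(n_i)] + (n_total - sum(n_i))

  coords <- vector("list", length(prims))
  for (j in seq_along(prims)) coords[[j]] <- prims[[j]]$sampler(n_i[j])
  n_i <- vapply(coords, nrow, 0L)           # samplers may trim (e.g. capsule cap)
  coords <- do.call(rbind, coords)
  labels <- rep(vapply(prims, `[[`, 0L, "label"), n_i)
  tree_of <- rep(vapply(prims, `[[`, 0L, "tree"), n_i)

  if (config$noise_sd > 0) {
    coords <- coords + matrix(stats::rnorm(length(coords), sd = config$noise_sd),
                              ncol = 3L)
  }

  # single-viewpoint occlusion: hide an azimuth sector of each tree
  if (config$occlusion_fraction > 0) {
    keep <- rep(TRUE, nrow(coords))
    width <- 2 * pi * config$occlusion_fraction
    for (i in seq_len(n_trees)) {
      own <- which(!is.na(tree_of) & tree_of == i)
      if (!length(own)) next
      phi0 <- stats::runif(1L, 0, 2 * pi)
      az <- atan2(coords[own, 2L] - centers[i, 2L],
                  coords[own, 1L] - centers[i, 1L]) %% (2 * pi)
      keep[own] <- ((az - phi0) %% (2 * pi)) > width
    }
    coords <- coords[keep, , drop = FALSE]
    labels <- labels[keep]
  }

  cloud <- normalize_scene(point_cloud(coords, labels = labels, name = name))
  shift <- apply(coords, 2L, min)
  for (i in seq_len(n_trees)) {
    trees[[i]]$center <- trees[[i]]$center - shift[1:2]
    trees[[i]]$trunk_base_z <- trees[[i]]$trunk_base_z - shift[3L]
    trees[[i]]$trunk_top_z <- trees[[i]]$trunk_top_z - shift[3L]
    if (!is.null(trees[[i]]$stake)) {
      trees[[i]]$stake$foot <- trees[[i]]$stake$foot - shift
      trees[[i]]$stake$top <- trees[[i]]$stake$top - shift
    }
  }
  attr(cloud, "recipe") <- list(trees = trees, extent = config$extent,
                                class_set = config$class_set,
                                ground_z = -shift[3L], translation = -shift)
  cloud
}

#' Generate a dataset of synthetic scenes on disk
#'
#' Writes `n_scenes` XYZL files plus a split manifest (`manifest.txt`,
#' train fraction 2/3) into `out_dir`. Per-scene seeds are derived from the
#' master seed in `config`, so the dataset is reproducible as a whole.
#'
#' @param n_scenes number of scenes (>= 2).
#' @param config a [scene_config()]; its `seed` is the master seed.
#' @param out_dir output directory (created if missing).
#' @return the split list from [split_scenes()], with an extra `dir` element.
#' @export
generate_dataset <- function(n_scenes, config = scene_config(), out_dir) {
  n_scenes <- check_count(n_scenes, "n_scenes", min = 2L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- with_seed(config$seed, sample.int(2147483647L, n_scenes))
  names <- sprintf("scene_%03d", seq_len(n_scenes))
  for (i in seq_len(n_scenes)) {
    cfg_i <- config
    cfg_i$seed <- seeds[i]
    write_xyzl(generate_scene(cfg_i, name = names[i]),
               file.path(out_dir, paste0(names[i], ".txt")))
  }
  split <- split_scenes(names, seed = config$seed)
  write_manifest(split, file.path(out_dir, "manifest.txt"))
  split$dir <- out_dir
  split
}
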