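# The full dynamic fusion segmentation network: input layer -> local feature
# aggregation -> stacked dynamic segmentation layers -> fully connected
# output. The LFA encoder is training-free; all learnable parameters live in
# the dynamic layers and the output layer, and are trained with hand-written
# backpropagation and AdamW.

#' Network configuration
#'
#' @param n_points points per input cloud (default 4096; clouds are
#'   subsampled to this size).
#' @param class_set `"simple"` (C = 5), `"complex"` (C = 8) or `NULL` to use
#'   a custom `C` (synthetic benchmarks).
#' @param C number of classes; derived from `class_set` when given.
#' @param n_dynamic_layers number of dynamic segmentation layers, 1..3
#'   (default 3).
#' @param FI,mu,nu trigonometric encoder settings (see [pose_config()]).
#' @param n_stages set-abstraction stages (default 3; the cascade keeps
#'   1/2, 1/4, 1/8 of the points).
#' @param k neighbourhood size for grouping (default 64).
#' @param sampler `"fps"` or `"rs"` centroid sampling.
#' @param grouping `FALSE` disables k-NN grouping (ablation arm).
#' @param lambda weight of the auxiliary pairing loss (default 0.1).
#' @param seed seed for parameter initialization.
#' @return a `network_config` list; `f` is the LFA output width
#'   `FI * (2^(n_stages+1) - 1)` (2160 at the defaults).
#' @export
network_config <- function(n_points = 4096L, class_set = "complex", C = NULL,
                           n_dynamic_layers = 3L, FI = 144L, mu = 1000,
                           nu = 100, n_stages = 3L, k = 64L,
                           sampler = c("fps", "rs"), grouping = TRUE,
                           lambda = 0.1, seed = 1L) {
  sampler <- match.arg(sampler)
  if (!is.null(class_set)) C <- class_map(class_set)$C
  C <- check_count(C, "C", min = 2L)
  n_dynamic_layers <- check_count(n_dynamic_layers, "n_dynamic_layers")
  if (n_dynamic_layers > 3L) stop_dfseg("`n_dynamic_layers` must be 1..3")
  pc <- pose_config(FI, mu, nu)
  n_stages <- check_count(n_stages, "n_stages", min = 0L)
  structure(list(n_points = check_count(n_points, "n_points"),
                 class_set = class_set, C = C,
                 n_dynamic_layers = n_dynamic_layers, pose = pc,
                 n_stages = n_stages, k = check_count(k, "k"),
                 sampler = sampler, grouping = isTRUE(grouping),
                 lambda = lambda, seed = as.integer(seed),
                 f = pc$FI * (2L^(n_stages + 1L) - 1L)),
            class = "network_config")
}

#' Training hyperparameters
#'
#' Defaults follow the standard AdamW recipe used for this architecture:
#' learning rate 0.001, betas (0.9, 0.999), epsilon 1e-8, weight decay 1e-4,
#' 150 epochs.
#'
#' @param lr learning rate.
#' @param betas AdamW momentum coefficients.
#' @param eps AdamW epsilon.
#' @param weight_decay decoupled weight decay on weight matrices.
#' @param epochs training epochs.
#' @param batch_size scenes per gradient step (default 8).
#' @param optimizer `"adamw"` (default) or `"sgd"`.
#' @param seed shuffling seed.
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 0.001, betas = c(0.9, 0.999), eps = 1e-8,
                         weight_decay = 1e-4, epochs = 150L, batch_size = 8L,
                         optimizer = c("adamw", "sgd"), seed = 1L,
                         verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr > 0, all(betas > 0), eps > 0, weight_decay >= 0)
  structure(list(lr = lr, betas = betas, eps = eps,
                 weight_decay = weight_decay,
                 epochs = check_count(epochs, "epochs"),
                 batch_size = check_count(batch_size, "batch_size"),
                 optimizer = optimizer, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Build a dynamic fusion segmentation network
#'
#' @param config a [network_config()].
#' @return a `dfs_network`: configuration plus initialized parameters.
#'   Forward maps an N x 3 cloud to N x C class scores.
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  f <- config$f
  params <- with_seed(config$seed, {
    layers <- lapply(seq_len(config$n_dynamic_layers), function(i) {
      dynamic_params(f, config$C)
    })
    out <- list(W = init_mat(f, config$C, scale = sqrt(1 / f)),
                b = numeric(config$C))
    list(layers = layers, out = out)
  })
  structure(list(config = config, params = params,
                 n_params = n_parameters(params)),
            class = "dfs_network")
}

#' @export
print.dfs_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<dfs_network> C = %d, %d dynamic layer(s), f = %d, %s sampler%s\n",
              cfg$C, cfg$n_dynamic_layers, cfg$f, cfg$sampler,
              if (cfg$grouping) sprintf(", k = %d", cfg$k) else ", no grouping"))
  cat(sprintf("  %s learnable parameters\n", format(x$n_params, big.mark = ",")))
  invisible(x)
}

# LFA features for one cloud under a network configuration (training-free)
lfa_features <- function(config, coords, seed = NULL) {
  lfa_forward(coords, n_stages = config$n_stages, config = config$pose,
              k = config$k, sampler = config$sampler, seed = seed,
              grouping = config$grouping)
}

# head forward: X0 are the LFA features. Returns scores, per-layer caches
# and pairing spaces. Loss terms are added when labels (0-based) are given.
head_fwd <- function(params, X0, labels = NULL, lambda = 0.1) {
  run <- X0
  L <- length(params$layers)
  caches <- vector("list", L)
  pair <- vector("list", L)
  pair_loss <- 0
  for (l in seq_len(L)) {
    r <- dyn_fwd(run, run, params$layers[[l]])
    caches[[l]] <- r$cache
    if (lambda != 0) {
      pl <- pairing_loss_fwd(r$M)
      pair_loss <- pair_loss + pl$loss
      pair[[l]] <- pl$dM
    }
    run <- r$out
  }
  fo <- nn_linear_fwd(run, params$out$W, params$out$b)
  # the auxiliary term is the mean pairing loss over fusion modules, so its
  # weight does not grow with network depth
  res <- list(scores = fo$out, caches = caches, out_cache = fo$cache,
              pair = pair, pair_loss = pair_loss / max(1L, L))
  if (!is.null(labels)) {
    sx <- softmax_xent(fo$out, labels + 1L)
    res$loss <- sx$loss + lambda * res$pair_loss
    res$xent <- sx$loss
    res$dscores <- sx$dlogits
  }
  res
}

head_bwd <- function(params, fwd, lambda = 0.1) {
  go <- nn_linear_bwd(fwd$dscores, fwd$out_cache)
  drun <- go$dX
  L <- length(params$layers)
  layer_grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    dM <- if (lambda != 0) fwd$pair[[l]] * (lambda / L) else NULL
    gb <- dyn_bwd(drun, fwd$caches[[l]], params$layers[[l]], dM_extra = dM)
    layer_grads[[l]] <- gb$grads
    drun <- gb$dl1 + gb$dl2
  }
  list(layers = layer_grads, out = list(W = go$dW, b = go$db))
}

#' Predict per-point labels for a cloud
#'
#' Runs the LFA encoder and the trained head; each point gets the argmax
#' class (ties broken by lowest class value). Clouds whose size is
#' incompatible with the set-abstraction cascade are subsampled to the
#' configured input size first.
#'
#' @param object a trained `dfs_network`.
#' @param cloud a `point_cloud` (labels, if any, are ignored).
#' @param ... unused.
#' @return the input `point_cloud` with predicted labels (0-based class
#'   values); per-point scores are attached as `attr(, "scores")`.
#' @export
predict.dfs_network <- function(object, cloud, ...) {
  cfg <- object$config
  coords <- if (inherits(cloud, "point_cloud")) cloud$coords else as.matrix(cloud)
  name <- if (inherits(cloud, "point_cloud")) cloud$name else ""
  if (nrow(coords) %% 2L^cfg$n_stages != 0L) {
    sub <- subsample(point_cloud(coords, name = name), cfg$n_points, seed = cfg$seed)
    coords <- sub$coords
  }
  X0 <- lfa_features(cfg, coords, seed = cfg$seed)
  fwd <- head_fwd(object$params, X0, lambda = 0)
  pred <- max.col(fwd$scores, ties.method = "first") - 1L
  out <- point_cloud(coords, labels = pred, name = name)
  attr(out, "scores") <- fwd$scores
  out
}

#' Train a network on labelled scenes
#'
#' Minimizes per-point softmax cross-entropy plus the lambda-weighted
#' auxiliary pairing loss of every dynamic layer. The training-free LFA
#' features of each scene are computed once and cached; gradients flow
#' through the dynamic layers and output layer and are applied with AdamW
#' (or plain SGD). Scenes should be normalized and subsampled beforehand.
#'
#' @param model a `dfs_network` from [build_network()].
#' @param scenes list of labelled `point_cloud`s; labels must lie in
#'   `0..C-1` and each scene size must be divisible by `2^n_stages`.
#' @param config a [train_config()].
#' @return list with `model` (trained), `log` (data.frame: epoch, loss,
#'   xent, pair, acc) and `seconds` (wall time).
#' @export
train_network <- function(model, scenes, config = train_config()) {
  stopifnot(inherits(model, "dfs_network"), inherits(config, "train_config"))
  if (length(scenes) < 1L) stop_dfseg("need at least one training scene")
  cfg <- model$config
  for (sc in scenes) {
    stopifnot(inherits(sc, "point_cloud"))
    if (is.null(sc$labels)) stop_dfseg("training scenes must be labelled")
    if (any(sc$labels < 0L | sc$labels >= cfg$C)) {
      stop_dfseg("scene '%s' has labels outside 0..%d", sc$name, cfg$C - 1L)
    }
    if (n_points(sc) %% 2L^cfg$n_stages != 0L) {
      stop_dfseg("scene '%s' size %d is not divisible by 2^%d; subsample first",
                 sc$name, n_points(sc), cfg$n_stages)
    }
  }
  t0 <- proc.time()[["elapsed"]]
  X0s <- lapply(seq_along(scenes), function(i) {
    lfa_features(cfg, scenes[[i]]$coords, seed = cfg$seed + i)
  })
  labs <- lapply(scenes, `[[`, "labels")
  params <- model$params
  state <- adamw_state(params)
  n_sc <- length(scenes)
  log <- data.frame(epoch = integer(), loss = double(), xent = double(),
                    pair = double(), acc = double())
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(config$seed + ep, sample.int(n_sc))
    ep_loss <- 0; ep_xent <- 0; ep_pair <- 0; n_hit <- 0; n_tot <- 0
    for (b0 in seq(1L, n_sc, by = config$batch_size)) {
      batch <- ord[b0:min(b0 + config$batch_size - 1L, n_sc)]
      grads <- NULL
      for (i in batch) {
        fwd <- head_fwd(params, X0s[[i]], labels = labs[[i]], lambda = cfg$lambda)
        if (!is.finite(fwd$loss)) {
          stop_dfseg("non-finite loss at epoch %d (scene '%s')", ep, scenes[[i]]$name)
        }
        g <- head_bwd(params, fwd, lambda = cfg$lambda)
        grads <- if (is.null(grads)) g else tree_map(`+`, grads, g)
        ep_loss <- ep_loss + fwd$loss
        ep_xent <- ep_xent + fwd$xent
        ep_pair <- ep_pair + fwd$pair_loss
        pred <- max.col(fwd$scores, ties.method = "first") - 1L
        n_hit <- n_hit + sum(pred == labs[[i]])
        n_tot <- n_tot + length(pred)
      }
      grads <- tree_map(function(g) g / length(batch), grads)
      if (config$optimizer == "adamw") {
        st <- adamw_step(params, grads, state, lr = config$lr,
                         betas = config$betas, eps = config$eps,
                         weight_decay = config$weight_decay)
        params <- st$params
        state <- st$state
      } else {
        params <- tree_map(function(p, g) p - config$lr * g, params, grads)
      }
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n_sc,
                                 xent = ep_xent / n_sc, pair = ep_pair / n_sc,
                                 acc = n_hit / n_tot))
    if (config$verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                      ep_loss / n_sc, n_hit / n_tot))
    }
  }
  model$params <- params
  list(model = model, log = log,
       seconds = proc.time()[["elapsed"]] - t0)
}

#' Evaluate a trained network on labelled scenes
#'
#' @param model a trained `dfs_network`.
#' @param scenes list of labelled `point_cloud`s.
#' @return list with `acc`, `miou`, `per_class_iou`, `confusion` and
#'   `ms_per_cloud` (mean forward wall time per scene, milliseconds).
#' @export
evaluate_network <- function(model, scenes) {
  C <- model$config$C
  cm <- matrix(0, C, C)
  t0 <- proc.time()[["elapsed"]]
  for (sc in scenes) {
    pred <- predict(model, sc)
    truth <- sc$labels
    if (n_points(pred) != length(truth)) truth <- truth[seq_len(n_points(pred))]
    cm <- cm + confusion(truth, pred$labels, C)
  }
  ms <- 1000 * (proc.time()[["elapsed"]] - t0) / length(scenes)
  list(acc = accuracy(cm), miou = miou(cm),
       per_class_iou = per_class_iou(cm), confusion = cm, ms_per_cloud = ms)
}

#' Layer-count ablation harness
#'
#' Trains otherwise-identical networks with 1..3 dynamic segmentation layers
#' and evaluates each on held-out scenes, reproducing the depth experiment
#' design (accuracy, mIoU and iterate speed per layer count).
#'
#' @param train_scenes,test_scenes lists of labelled `point_cloud`s.
#' @param config base [network_config()].
#' @param tc a [train_config()].
#' @param layers layer counts to compare (default 1:3).
#' @param seeds one or more seeds; results are reported per seed.
#' @return data.frame with columns layers, seed, acc, miou, ms_per_cloud.
#' @export
ablate_layers <- function(train_scenes, test_scenes, config, tc,
                          layers = 1:3, seeds = 1L) {
  res <- list()
  for (L in layers) for (sd in seeds) {
    cfg <- config
    cfg$n_dynamic_layers <- as.integer(L)
    cfg$seed <- as.integer(sd)
    tc$seed <- as.integer(sd)
    tr <- train_network(build_network(cfg), train_scenes, tc)
    ev <- evaluate_network(tr$model, test_scenes)
    res[[length(res) + 1L]] <- data.frame(layers = L, seed = sd, acc = ev$acc,
                                          miou = ev$miou,
                                          ms_per_cloud = ev$ms_per_cloud)
  }
  do.call(rbind, res)
}

#' Sampling/grouping-strategy ablation harness
#'
#' Compares the three sampling arms of the set-abstraction cascade:
#' FPS without grouping, RS + k-NN, and FPS + k-NN.
#'
#' @param train_scenes,test_scenes lists of labelled `point_cloud`s.
#' @param config base [network_config()].
#' @param tc a [train_config()].
#' @param arms subset of `c("fps-nogroup", "rs", "fps")`.
#' @param seeds one or more seeds.
#' @return data.frame with columns arm, seed, acc, miou, ms_per_cloud.
#' @export
ablate_sampling <- function(train_scenes, test_scenes, config, tc,
                            arms = c("fps-nogroup", "rs", "fps"), seeds = 1L) {
  arms <- match.arg(arms, c("fps-nogroup", "rs", "fps"), several.ok = TRUE)
  res <- list()
  for (arm in arms) for (sd in seeds) {
    cfg <- config
    cfg$sampler <- if (arm == "rs") "rs" else "fps"
    cfg$grouping <- arm != "fps-nogroup"
    cfg$seed <- as.integer(sd)
    tc$seed <- as.integer(sd)
    tr <- train_network(build_network(cfg), train_scenes, tc)
    ev <- evaluate_network(tr$model, test_scenes)
    res[[length(res) + 1L]] <- data.frame(arm = arm, seed = sd, acc = ev$acc,
                                          miou = ev$miou,
                                          ms_per_cloud = ev$ms_per_cloud)
  }
  do.call(rbind, res)
}

#' Read network and training configuration from a YAML file
#'
#' Top-level keys `network:` and `training:` map onto the arguments of
#' [network_config()] and [train_config()].
#'
#' @param path YAML file.
#' @return list with `network` and `training` configs.
#' @export
config_from_yaml <- function(path) {
  if (!file.exists(path)) stop_dfseg("file not found: %s", path)
  y <- yaml::read_yaml(path)
  net <- do.call(network_config, as.list(y$network %||% list()))
  tc <- do.call(train_config, as.list(y$training %||% list()))
  list(network = net, training = tc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
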