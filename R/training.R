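#' Training configuration
#'
#' The reference recipe: SGD with momentum 0.9 and weight decay 5e-4,
#' batch of 8 random 64-cube crops, initial learning rate 0.01 under
#' cyclic polynomial decay that reinitializes every 5000 iterations,
#' Gaussian N(0, 0.01^2) weight initialization, and a deeply supervised
#' auxiliary loss.
#'
#' @param batch_size Crops per iteration.
#' @param base_lr Initial learning rate of each decay cycle.
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty applied to convolution/mapping weights
#'   (not biases or normalization parameters).
#' @param power Polynomial-decay exponent.
#' @param restart_every Cycle length of the learning-rate schedule, in
#'   iterations.
#' @param max_iter Total training iterations.
#' @param aux_weight Weight of the auxiliary (skip-branch) cross-entropy.
#' @param init_std Weight-initialization standard deviation.
#' @param lr_schedule `"cyclic"` (reinitialize each cycle) or `"global"`
#'   (single decay over `max_iter`).
#' @param class_weights Optional per-class loss weights (default none).
#' @param val_every Evaluate training Dice every this many iterations (0
#'   disables); used for logging and early stopping.
#' @param early_stop_dice Stop when every foreground class reaches this
#'   training Dice (NULL: never stop early).
#' @param checkpoint_every Save a checkpoint every this many iterations
#'   (0: only at the end).
#' @param seed RNG seed governing initialization, crop sampling,
#'   augmentation, and dropout.
#' @return An `svn_train_config`.
#' @export
train_config <- function(batch_size = 8L, base_lr = 0.01, momentum = 0.9,
                         weight_decay = 5e-4, power = 0.9,
                         restart_every = 5000L, max_iter = 8000L,
                         aux_weight = 0.5, init_std = 0.01,
                         lr_schedule = c("cyclic", "global"),
                         class_weights = NULL, val_every = 500L,
                         early_stop_dice = NULL, checkpoint_every = 0L,
                         seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(batch_size >= 1, base_lr > 0, momentum >= 0, weight_decay >= 0,
            power > 0, restart_every >= 1, max_iter >= 1,
            restart_every <= max_iter, aux_weight >= 0)
  structure(list(batch_size = as.integer(batch_size), base_lr = base_lr,
                 momentum = momentum, weight_decay = weight_decay,
                 power = power, restart_every = as.integer(restart_every),
                 max_iter = as.integer(max_iter), aux_weight = aux_weight,
                 init_std = init_std, lr_schedule = lr_schedule,
                 class_weights = class_weights,
                 val_every = as.integer(val_every),
                 early_stop_dice = early_stop_dice,
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "svn_train_config")
}

#' Learning rate at an iteration
#'
#' Cyclic polynomial decay: within each cycle of `restart_every`
#' iterations, `base_lr * (1 - local/restart_every)^power` where `local`
#' is the iteration index inside the cycle; the rate resets to `base_lr`
#' at every cycle start. The `"global"` schedule decays once over
#' `max_iter` without restarts.
#'
#' @param iteration 0-based iteration counter (scalar or vector).
#' @param config An `svn_train_config`.
#' @return Learning rate(s).
#' @export
lr_at <- function(iteration, config = train_config()) {
  stopifnot(all(iteration >= 0))
  if (config$lr_schedule == "global") {
    frac <- pmin(iteration / config$max_iter, 1)
  } else {
    frac <- (iteration %% config$restart_every) / config$restart_every
  }
  config$base_lr * (1 - frac)^config$power
}

# Apply f(name, value) to every trainable parameter leaf of a network,
# rebuilding the structure from f's return values.
map_params <- function(net, f) {
  for (nm in names(net$layers)) {
    l <- net$layers[[nm]]
    if (is.null(l)) next
    if (inherits(l, "svn_sparse_block")) {
      for (i in seq_along(l$units))
        l$units[[i]]$params <- lapply_named(l$units[[i]]$params, f)
    } else {
      l$params <- lapply_named(l$params, f)
    }
    net$layers[[nm]] <- l
  }
  net
}

lapply_named <- function(params, f) {
  for (pn in names(params)) {
    if (is.null(params[[pn]])) next
    params[[pn]] <- f(pn, params[[pn]])
  }
  params
}

#' Initialize network weights
#'
#' Every convolution/deconvolution/mapping weight is redrawn from
#' N(0, `std`^2); biases are set to zero, batch-norm scales to one and
#' shifts to zero. Deterministic for a given seed.
#'
#' @param net A `sparsevoxnet`.
#' @param std Gaussian standard deviation.
#' @param seed Integer seed.
#' @return The reinitialized network.
#' @export
init_weights <- function(net, std = 0.01, seed = 1L) {
  stopifnot(inherits(net, "sparsevoxnet"))
  set.seed(seed)
  map_params(net, function(nm, v) {
    if (nm %in% c("W", "Wt", "Wp", "Wg", "Wo")) {
      array(stats::rnorm(length(v), 0, std), dim = dim(v))
    } else if (nm == "gamma") {
      rep(1, length(v))
    } else {
      numeric(length(v))  # biases and beta
    }
  })
}

#' Dual-head segmentation loss
#'
#' Voxel-mean softmax cross-entropy of the main head plus `aux_weight`
#' times the same for the auxiliary head.
#'
#' @param output List with `main_logits` and `aux_logits` (5-D arrays).
#' @param labels Integer array over \{0, ..., num_classes - 1\} matching
#'   the logits' spatial/batch extents.
#' @param aux_weight Auxiliary-head weight.
#' @param need_grad Also return gradients w.r.t. both logit arrays.
#' @return List with `loss`, `main`, `aux`, and (optionally) `d_main`,
#'   `d_aux`.
#' @export
svn_loss <- function(output, labels, aux_weight = 0.5, need_grad = FALSE) {
  main <- softmax_ce(output$main_logits, labels, need_grad)
  aux <- softmax_ce(output$aux_logits, labels, need_grad)
  out <- list(loss = main$loss + aux_weight * aux$loss,
              main = main$loss, aux = aux$loss)
  if (need_grad) {
    out$d_main <- main$grad
    out$d_aux <- if (aux_weight > 0) aux_weight * aux$grad else
      array(0, dim = dim(output$aux_logits))
  }
  out
}

# One SGD step with momentum and decoupled-from-bias weight decay.
# Velocity buffers mirror the gradient structure; lr = 0 changes nothing.
sgd_step <- function(net, grads, vel, lr, momentum, weight_decay) {
  upd_params <- function(params, g, v) {
    if (is.null(v)) v <- list()
    for (pn in names(g)) {
      if (is.null(g[[pn]])) next
      gr <- g[[pn]]
      if (weight_decay > 0 && pn %in% c("W", "Wt", "Wp", "Wg", "Wo"))
        gr <- gr + weight_decay * params[[pn]]
      v[[pn]] <- if (is.null(v[[pn]])) gr else momentum * v[[pn]] + gr
      params[[pn]] <- params[[pn]] - lr * v[[pn]]
    }
    list(params = params, vel = v)
  }
  if (is.null(vel)) vel <- list()
  for (nm in names(grads)) {
    l <- net$layers[[nm]]
    if (inherits(l, "svn_sparse_block")) {
      if (is.null(vel[[nm]])) vel[[nm]] <- vector("list", length(l$units))
      for (i in seq_along(grads[[nm]])) {
        r <- upd_params(l$units[[i]]$params, grads[[nm]][[i]], vel[[nm]][[i]])
        l$units[[i]]$params <- r$params
        vel[[nm]][[i]] <- r$vel
      }
    } else {
      r <- upd_params(l$params, grads[[nm]], vel[[nm]])
      l$params <- r$params
      vel[[nm]] <- r$vel
    }
    net$layers[[nm]] <- l
  }
  list(net = net, vel = vel)
}

# Assemble a (1, c, c, c, B) input and (c, c, c, B) label batch from crops.
batch_from_crops <- function(crops) {
  cs <- dim(crops[[1]]$image)
  B <- length(crops)
  x <- array(0, dim = c(1L, cs, B))
  lab <- array(0L, dim = c(cs, B))
  for (b in seq_len(B)) {
    x[1L, , , , b] <- crops[[b]]$image
    lab[, , , b] <- crops[[b]]$label
  }
  list(x = x, labels = lab)
}

# Per-class training Dice over a list of crops: evaluation mode (no
# dropout) with per-batch normalization statistics, main head.
eval_crop_dice <- function(net, crops, num_classes) {
  batch <- batch_from_crops(crops)
  f <- svn_fwd(net, batch$x, train = FALSE, need_cache = FALSE,
               bn_batch = TRUE)
  prob <- softmax_volume(f$main_logits)
  pm <- matrix(prob, num_classes, length(prob) / num_classes)
  pred <- max.col(t(pm), ties.method = "first") - 1L
  vapply(seq_len(num_classes) - 1L, function(cl) {
    denom <- sum(pred == cl) + sum(batch$labels == cl)
    if (denom == 0) 1 else 2 * sum(pred == cl & as.vector(batch$labels) == cl) / denom
  }, numeric(1))
}

#' Train a SparseVoxNet
#'
#' SGD training on random augmented crops: each iteration samples a
#' training volume uniformly, draws a batch of random cubic crops,
#' applies a random 90-degree rotation to each, and takes one SGD step on
#' the dual-head cross-entropy at the scheduled learning rate. Fully
#' reproducible for a fixed seed.
#'
#' @param net A `sparsevoxnet` (it is reinitialized with
#'   `config$init_std` and `config$seed` unless `reinit = FALSE`).
#' @param data Training data: either a manifest path / data.frame (see
#'   [read_manifest()]; only `split == "train"` rows are used) or a list
#'   of samples, each a list with `image` and `label` 3-D arrays. Images
#'   are z-score normalized on load.
#' @param config An `svn_train_config`.
#' @param crop_size Training crop edge (defaults to the network config).
#' @param checkpoint_dir Directory for checkpoints (NULL: no files
#'   written).
#' @param reinit Reinitialize weights before training.
#' @param verbose Print a progress line every `val_every` iterations.
#' @return An `svn_fit`: list with the trained `net`, the iteration `log`
#'   (data.frame of iteration, lr, loss, main/aux terms), the final
#'   `dice` estimate per class, and the `config`s.
#' @export
svn_train <- function(net, data, config = train_config(),
                      crop_size = NULL, checkpoint_dir = NULL,
                      reinit = TRUE, verbose = FALSE) {
  stopifnot(inherits(net, "sparsevoxnet"), inherits(config, "svn_train_config"))
  if (is.null(crop_size)) crop_size <- net$config$crop_size
  samples <- load_training_samples(data)
  if (reinit) net <- init_weights(net, config$init_std, config$seed)
  set.seed(config$seed + 1L)
  # fixed held-in crops for Dice monitoring, drawn before training starts
  monitor <- unlist(lapply(samples, function(s)
    sample_crops(s$image, s$label, crop_size, 2L)), recursive = FALSE)
  vel <- NULL
  nlog <- 0L
  log_rows <- vector("list", config$max_iter)
  dice_now <- rep(NA_real_, net$config$num_classes)
  stop_iter <- config$max_iter
  for (it in seq_len(config$max_iter) - 1L) {
    vi <- sample.int(length(samples), 1L)
    crops <- sample_crops(samples[[vi]]$image, samples[[vi]]$label,
                          crop_size, config$batch_size)
    crops <- lapply(crops, augment_crop)
    batch <- batch_from_crops(crops)
    fwd <- svn_fwd(net, batch$x, train = TRUE)
    net <- fwd$net
    ls <- svn_loss(list(main_logits = fwd$main_logits,
                        aux_logits = fwd$aux_logits),
                   batch$labels, config$aux_weight, need_grad = TRUE)
    if (!is.finite(ls$loss))
      stop(sprintf("training diverged at iteration %d (loss %s)", it, ls$loss))
    grads <- svn_bwd(net, fwd$caches, ls$d_main, ls$d_aux)
    lr <- lr_at(it, config)
    st <- sgd_step(net, grads, vel, lr, config$momentum, config$weight_decay)
    net <- st$net
    vel <- st$vel
    nlog <- nlog + 1L
    log_rows[[nlog]] <- data.frame(iteration = it, lr = lr, loss = ls$loss,
                                   main = ls$main, aux = ls$aux)
    if (config$val_every > 0 && (it + 1L) %% config$val_every == 0L) {
      dice_now <- eval_crop_dice(net, monitor, net$config$num_classes)
      if (verbose)
        message(sprintf("iter %d  lr %.5f  loss %.4f  dice %s", it, lr,
                        ls$loss, paste(sprintf("%.3f", dice_now), collapse = "/")))
      if (!is.null(config$early_stop_dice) &&
          all(dice_now[-1L] >= config$early_stop_dice)) {
        stop_iter <- it + 1L
        break
      }
    }
    if (!is.null(checkpoint_dir) && config$checkpoint_every > 0 &&
        (it + 1L) %% config$checkpoint_every == 0L)
      save_checkpoint(net, list(vel = vel, iteration = it + 1L, config = config),
                      file.path(checkpoint_dir, sprintf("iter_%06d.rds", it + 1L)))
  }
  fit <- structure(list(net = net, log = do.call(rbind, log_rows[seq_len(nlog)]),
                        dice = dice_now, iterations = stop_iter,
                        train_config = config),
                   class = "svn_fit")
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    save_checkpoint(net, list(vel = vel, iteration = stop_iter, config = config),
                    file.path(checkpoint_dir, "final.rds"))
  }
  fit
}

load_training_samples <- function(data) {
  if (is.character(data)) data <- read_manifest(data)
  if (is.data.frame(data)) {
    rows <- data[data$split == "train", , drop = FALSE]
    if (nrow(rows) == 0L) stop("manifest has no rows with split == 'train'")
    samples <- lapply(seq_len(nrow(rows)), function(i) {
      v <- read_volume(rows$image[i])
      l <- read_labels(rows$label[i])
      list(image = normalize_volume(v$data), label = l$data)
    })
    return(samples)
  }
  stopifnot(is.list(data), length(data) >= 1L)
  lapply(data, function(s) {
    stopifnot(!is.null(s$image), !is.null(s$label))
    list(image = normalize_volume(s$image), label = s$label)
  })
}

#' @export
print.svn_fit <- function(x, ...) {
  cat(sprintf("SparseVoxNet fit: %d iterations, final loss %.4f\n",
              x$iterations, utils::tail(x$log$loss, 1)))
  if (!all(is.na(x$dice)))
    cat(sprintf("Training Dice (bg/myo/pool): %s\n",
                paste(sprintf("%.3f", x$dice), collapse = " / ")))
  invisible(x)
}

#' Save a training checkpoint
#'
#' Stores the network (weights, running statistics, config) and optimizer
#' state; reloading continues the trajectory bit-exactly.
#'
#' @param net A `sparsevoxnet`.
#' @param state List with optimizer state (`vel`), `iteration`, and the
#'   training `config`.
#' @param path Output file (RDS).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, state, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(net = net, state = state), path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return List with `net` and `state`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  readRDS(path)
}

#' Recalibrate batch-normalization statistics
#'
#' With small batches the exponential running estimates used in evaluation
#' mode lag the statistics the network was actually trained under.
#' This standard post-training pass recomputes the running mean/variance of
#' every batch-norm stage by streaming training crops through the network
#' in training mode (no parameter updates), leaving evaluation-mode
#' predictions calibrated.
#'
#' @param net A `sparsevoxnet`.
#' @param crops List of crop samples (`image`/`label`), e.g. from
#'   [sample_crops()].
#' @param batch_size Crops per forward pass.
#' @param passes Number of streaming passes over the crops.
#' @return The network with updated running statistics.
#' @export
recalibrate_bn <- function(net, crops, batch_size = 2L, passes = 2L) {
  stopifnot(inherits(net, "sparsevoxnet"), length(crops) >= 1L)
  for (p in seq_len(passes)) {
    idx <- seq_along(crops)
    for (start in seq(1L, length(idx), by = batch_size)) {
      take <- idx[start:min(start + batch_size - 1L, length(idx))]
      b <- batch_from_crops(crops[take])
      f <- svn_fwd(net, b$x, train = TRUE, need_cache = FALSE)
      net <- f$net
    }
  }
  net
}
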