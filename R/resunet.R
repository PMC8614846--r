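# Architecture constructor for the residual encoder-decoder segmentation
# network. The encoder is the standard 18-layer residual topology (basic
# blocks 2-2-2-2, widths w,2w,4w,8w); a 50-layer bottleneck variant
# (3-4-6-3) is available for comparison. The decoder upsamples by nearest
# 2x, concatenates the matching encoder stage and applies a 3x3
# conv-BN-ReLU whose width mirrors that stage; a final 1x1 convolution
# with independent sigmoid channels produces the four class maps.

resunet_build_graph <- function(depth = 18L, base_width = 64L,
                                in_channels = 1L, n_classes = 4L) {
  g <- graph_builder()
  shapes <- list()
  conv <- function(prev, cin, cout, k, stride, pad, pname, bias = FALSE) {
    shapes[[paste0(pname, ".W")]] <<- c(k * k * cin, cout)
    if (bias) shapes[[paste0(pname, ".b")]] <<- cout
    g$add("conv", prev, k = k, stride = stride, pad = pad,
          cin = cin, cout = cout, bias = bias, pname = pname)
  }
  bn <- function(prev, c, pname) {
    shapes[[paste0(pname, ".gamma")]] <<- c
    shapes[[paste0(pname, ".beta")]] <<- c
    g$add("bn", prev, channels = c, pname = pname)
  }
  cbr <- function(prev, cin, cout, k, stride, pad, pname) {
    id <- conv(prev, cin, cout, k, stride, pad, paste0(pname, ".conv"))
    id <- bn(id, cout, paste0(pname, ".bn"))
    g$add("relu", id)
  }
  basic_block <- function(prev, cin, cout, stride, pname) {
    id <- conv(prev, cin, cout, 3, stride, 1, paste0(pname, ".conv1"))
    id <- bn(id, cout, paste0(pname, ".bn1"))
    id <- g$add("relu", id)
    id <- conv(id, cout, cout, 3, 1, 1, paste0(pname, ".conv2"))
    id <- bn(id, cout, paste0(pname, ".bn2"))
    sc <- prev
    if (stride != 1 || cin != cout) {
      sc <- conv(prev, cin, cout, 1, stride, 0, paste0(pname, ".down.conv"))
      sc <- bn(sc, cout, paste0(pname, ".down.bn"))
    }
    g$add("relu", g$add("add", c(id, sc)))
  }
  bottleneck_block <- function(prev, cin, cout, stride, pname) {
    mid <- cout %/% 4L
    id <- conv(prev, cin, mid, 1, 1, 0, paste0(pname, ".conv1"))
    id <- bn(id, mid, paste0(pname, ".bn1"))
    id <- g$add("relu", id)
    id <- conv(id, mid, mid, 3, stride, 1, paste0(pname, ".conv2"))
    id <- bn(id, mid, paste0(pname, ".bn2"))
    id <- g$add("relu", id)
    id <- conv(id, mid, cout, 1, 1, 0, paste0(pname, ".conv3"))
    id <- bn(id, cout, paste0(pname, ".bn3"))
    sc <- prev
    if (stride != 1 || cin != cout) {
      sc <- conv(prev, cin, cout, 1, stride, 0, paste0(pname, ".down.conv"))
      sc <- bn(sc, cout, paste0(pname, ".down.bn"))
    }
    g$add("relu", g$add("add", c(id, sc)))
  }
  stage <- function(prev, n_blocks, cin, cout, stride_first, block, pname) {
    id <- block(prev, cin, cout, stride_first, paste0(pname, ".b1"))
    for (b in seq_len(n_blocks - 1L))
      id <- block(id, cout, cout, 1, paste0(pname, ".b", b + 1L))
    id
  }

  if (depth == 18L) {
    block <- basic_block; nb <- c(2L, 2L, 2L, 2L); exp <- 1L
  } else if (depth == 50L) {
    block <- bottleneck_block; nb <- c(3L, 4L, 6L, 3L); exp <- 4L
  } else stop("depth must be 18 or 50")
  w <- as.integer(base_width)
  cw <- w * exp * c(1L, 2L, 4L, 8L)  # stage output widths

  inp <- g$add("input")
  stem <- cbr(inp, in_channels, w, 7, 2, 3, "stem")           # H/2
  mp <- g$add("maxpool", stem, k = 3L, stride = 2L, pad = 1L)  # H/4
  e1 <- stage(mp, nb[1], w, cw[1], 1, block, "enc1")
  e2 <- stage(e1, nb[2], cw[1], cw[2], 2, block, "enc2")       # H/8
  e3 <- stage(e2, nb[3], cw[2], cw[3], 2, block, "enc3")       # H/16
  e4 <- stage(e3, nb[4], cw[3], cw[4], 2, block, "enc4")       # H/32

  dec <- function(prev, skip, cin, cskip, pname) {
    id <- g$add("up2", prev)
    id <- g$add("concat", c(id, skip))
    cbr(id, cin + cskip, cskip, 3, 1, 1, pname)
  }
  d3 <- dec(e4, e3, cw[4], cw[3], "dec3")  # H/16
  d2 <- dec(d3, e2, cw[3], cw[2], "dec2")  # H/8
  d1 <- dec(d2, e1, cw[2], cw[1], "dec1")  # H/4
  d0 <- dec(d1, stem, cw[1], w, "dec0")    # H/2
  up <- g$add("up2", d0)                   # H
  out <- conv(up, w, n_classes, 1, 1, 0, "head", bias = TRUE)

  list(nodes = g$get_nodes(), shapes = shapes, out = out,
       depth = depth, base_width = w, in_channels = in_channels,
       n_classes = n_classes)
}

#' Build the ResU-Net-18 segmentation network
#'
#' Constructs the four-class bone segmentation network: an 18-layer
#' residual encoder (basic blocks 2-2-2-2) with a skip-connected decoder
#' whose stage widths mirror the encoder, and a 4-channel head of
#' independent sigmoids (one probability map per class; channels are
#' deliberately not constrained to sum to 1). Accepts single-channel
#' square inputs whose side is divisible by 32.
#'
#' Output channel `c` corresponds to mask class `c - 1`
#' (background, femur, tibia, fibula).
#'
#' @param base_width encoder width of the first stage (64 for the
#'   standard topology; smaller values give proportionally lighter
#'   networks for experimentation).
#' @param depth 18 (basic blocks) or 50 (bottleneck variant, mainly for
#'   capacity comparison).
#' @param seed seed for the He-normal weight initialization.
#' @return An object of class `kj_resunet`.
#' @export
build_resunet18 <- function(base_width = 64L, depth = 18L, seed = 1L) {
  arch <- resunet_build_graph(depth = depth, base_width = base_width)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  params <- list(); buffers <- list()
  for (nm in names(arch$shapes)) {
    sh <- arch$shapes[[nm]]
    if (endsWith(nm, ".W")) {
      params[[nm]] <- matrix(rnorm(prod(sh), 0, sqrt(2 / sh[1])),
                             sh[1], sh[2])
    } else if (endsWith(nm, ".b") || endsWith(nm, ".beta")) {
      params[[nm]] <- numeric(sh)
    } else if (endsWith(nm, ".gamma")) {
      params[[nm]] <- rep(1, sh)
    }
  }
  for (node in arch$nodes) {
    if (node$op == "bn") {
      buffers[[paste0(node$pname, ".mean")]] <- numeric(node$channels)
      buffers[[paste0(node$pname, ".var")]] <- rep(1, node$channels)
    }
  }
  structure(list(graph = arch$nodes, params = params, buffers = buffers,
                 out = arch$out, depth = arch$depth,
                 base_width = arch$base_width,
                 n_classes = arch$n_classes),
            class = "kj_resunet")
}

#' Number of trainable parameters of a network construction
#'
#' Computed from the parameter shapes alone (no allocation), so the
#' 18- and 50-layer variants can be compared cheaply.
#'
#' @inheritParams build_resunet18
#' @return Integer parameter count.
#' @export
resunet_param_count <- function(depth = 18L, base_width = 64L) {
  arch <- resunet_build_graph(depth = depth, base_width = base_width)
  sum(vapply(arch$shapes, prod, 0.0))
}

#' @export
print.kj_resunet <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<kj_resunet> depth %d, base width %d, %d nodes, %s parameters\n",
              x$depth, x$base_width, length(x$graph),
              format(n_par, big.mark = ",")))
  invisible(x)
}

#' Training configuration
#'
#' Defaults follow the training recipe used throughout the package:
#' Adam with learning rate 0.001 and weight decay 1e-5, early stopping
#' after 10 epochs without validation-loss improvement (any strict
#' decrease counts as improvement), and augmentation by rotation within
#' +/- 5 degrees, shifts within +/- 10% of the image size, horizontal
#' flips, and +/- 10% multiplicative contrast/brightness jitter.
#' Batch size and epoch budget are implementation defaults.
#'
#' @param learning_rate Adam learning rate (> 0).
#' @param weight_decay L2 penalty added to the gradients (>= 0).
#' @param early_stop_patience epochs without improvement before stopping.
#' @param max_epochs epoch budget.
#' @param batch_size minibatch size.
#' @param rotation_deg augmentation rotation range (degrees).
#' @param shift_frac augmentation shift range (fraction of side).
#' @param hflip enable horizontal-flip augmentation.
#' @param jitter contrast/brightness jitter amplitude.
#' @param augment enable augmentation.
#' @param seed integer seed controlling shuffling and augmentation.
#' @return An object of class `kj_train_config`.
#' @export
training_config <- function(learning_rate = 0.001, weight_decay = 1e-5,
                            early_stop_patience = 10L, max_epochs = 300L,
                            batch_size = 4L, rotation_deg = 5,
                            shift_frac = 0.10, hflip = TRUE, jitter = 0.10,
                            augment = TRUE, seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, early_stop_patience >= 1,
            max_epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 rotation_deg = rotation_deg, shift_frac = shift_frac,
                 hflip = isTRUE(hflip), jitter = jitter,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "kj_train_config")
}

# Random rotation/shift/flip/jitter of an image-mask pair; bilinear
# resampling for the image, nearest for the mask, background fill.
augment_pair <- function(image, mask, cfg) {
  H <- nrow(image); W <- ncol(image)
  ang <- runif(1, -cfg$rotation_deg, cfg$rotation_deg) * pi / 180
  dr <- runif(1, -cfg$shift_frac, cfg$shift_frac) * H
  dc <- runif(1, -cfg$shift_frac, cfg$shift_frac) * W
  flip <- cfg$hflip && runif(1) < 0.5
  cf <- 1 + runif(1, -cfg$jitter, cfg$jitter)   # contrast
  bf <- 1 + runif(1, -cfg$jitter, cfg$jitter)   # brightness/saturation gain

  ctr_r <- (H + 1) / 2; ctr_c <- (W + 1) / 2
  tgt_r <- rep(seq_len(H), W)
  tgt_c <- rep(seq_len(W), each = H)
  ca <- cos(-ang); sa <- sin(-ang)
  rr <- tgt_r - ctr_r - dr; cc <- tgt_c - ctr_c - dc
  src_r <- ctr_r + ca * rr - sa * cc
  src_c <- ctr_c + sa * rr + ca * cc
  if (flip) src_c <- W + 1 - src_c

  # nearest for the mask
  ri <- round(src_r); ci <- round(src_c)
  ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  mv <- integer(H * W)
  mv[ok] <- unclass(mask)[cbind(ri[ok], ci[ok])]
  # bilinear for the image
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  pick <- function(r, c) {
    v <- numeric(H * W)
    okk <- r >= 1 & r <= H & c >= 1 & c <= W
    v[okk] <- image[cbind(r[okk], c[okk])]
    v
  }
  iv <- (1 - fr) * (1 - fc) * pick(r0, c0) +
    (1 - fr) * fc * pick(r0, c0 + 1) +
    fr * (1 - fc) * pick(r0 + 1, c0) +
    fr * fc * pick(r0 + 1, c0 + 1)
  iv <- pmin(pmax((iv - mean(iv)) * cf + mean(iv) * bf, 0), 1)
  list(image = matrix(iv, H, W), mask = matrix(mv, H, W))
}

dataset_check <- function(ds, name) {
  if (length(ds) == 0L) stop(name, " dataset is empty")
  for (s in ds) {
    if (is.null(s$image) || is.null(s$mask))
      stop(name, " samples need $image and $mask")
    if (!all(dim(s$image) == dim(s$mask)))
      stop(name, ": image/mask shape mismatch")
  }
  invisible(TRUE)
}

eval_loss <- function(model, ds, batch_size) {
  total <- 0
  n_pix <- 0
  for (chunk in split(seq_along(ds), ceiling(seq_along(ds) / batch_size))) {
    xt <- images_to_tensor(lapply(ds[chunk], `[[`, "image"))
    yt <- masks_to_onehot(lapply(ds[chunk], `[[`, "mask"))
    fw <- nn_forward(model, xt, train = FALSE)
    z <- fw$vals[[model$out]]$x
    total <- total + bce_with_logits(z, yt)$loss * length(z)
    n_pix <- n_pix + length(z)
  }
  total / n_pix
}

model_mean_iou <- function(model, ds) {
  ious <- vapply(ds, function(s) {
    pred <- predict_mask(model, s$image)
    mean_iou(pred, label_mask(s$mask))
  }, 0.0)
  mean(ious)
}

#' Train the segmentation network
#'
#' Minibatch Adam training with the configured augmentation, per-channel
#' BCE-with-logits loss, and early stopping on the validation loss: when
#' the validation loss has not strictly improved for
#' `early_stop_patience` epochs, training stops and the weights from the
#' best validation epoch are returned. All randomness (shuffling,
#' augmentation) flows through `cfg$seed`, so runs repeat bit-identically
#' in single-threaded BLAS conditions.
#'
#' @param model a [build_resunet18()] network.
#' @param train_set,val_set lists of samples, each `list(image =, mask =)`
#'   with `image` a numeric matrix in `[0, 1]` and `mask` an integer
#'   matrix with labels 0-3.
#' @param cfg a [training_config()].
#' @param target_train_iou optional early exit: when set, the mean IoU on
#'   the (un-augmented) training set is evaluated each epoch and training
#'   stops once it reaches the target, returning the current weights.
#'   Intended for controlled overfitting runs.
#' @param verbose print per-epoch losses.
#' @return The trained model, with a `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`, `train_iou`) and `best_epoch`
#'   attached.
#' @export
train <- function(model, train_set, val_set, cfg = training_config(),
                  target_train_iou = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "kj_resunet"), inherits(cfg, "kj_train_config"))
  dataset_check(train_set, "training")
  dataset_check(val_set, "validation")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  adam_m <- list(); adam_v <- list(); step <- 0L
  best_val <- Inf; best_params <- model$params; best_buffers <- model$buffers
  best_epoch <- 0L; since_best <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), train_iou = numeric())

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample(length(train_set))
    ep_loss <- 0; ep_n <- 0
    for (chunk in split(perm, ceiling(seq_along(perm) / cfg$batch_size))) {
      pairs <- lapply(train_set[chunk], function(s) {
        if (cfg$augment) augment_pair(s$image, s$mask, cfg)
        else s
      })
      xt <- images_to_tensor(lapply(pairs, `[[`, "image"))
      yt <- masks_to_onehot(lapply(pairs, `[[`, "mask"))
      fw <- nn_forward(model, xt, train = TRUE)
      model$buffers <- fw$buffers
      z <- fw$vals[[model$out]]$x
      l <- bce_with_logits(z, yt)
      if (!is.finite(l$loss))
        stop("training aborted: non-finite loss at epoch ", epoch,
             " (learning rate too high or corrupt inputs?)")
      ep_loss <- ep_loss + l$loss * length(z); ep_n <- ep_n + length(z)
      grads <- nn_backward(model, fw, l$dz)
      step <- step + 1L
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      for (nm in names(grads)) {
        g <- grads[[nm]] + cfg$weight_decay * model$params[[nm]]
        if (is.null(adam_m[[nm]])) {
          adam_m[[nm]] <- g * 0; adam_v[[nm]] <- g * 0
        }
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g * g
        mhat <- adam_m[[nm]] / (1 - b1^step)
        vhat <- adam_v[[nm]] / (1 - b2^step)
        model$params[[nm]] <- model$params[[nm]] -
          cfg$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    train_loss <- ep_loss / ep_n
    val_loss <- eval_loss(model, val_set, cfg$batch_size)
    train_iou <- if (!is.null(target_train_iou))
      model_mean_iou(model, train_set) else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                   val_loss = val_loss,
                                   train_iou = train_iou))
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f%s", epoch,
                      train_loss, val_loss,
                      if (is.na(train_iou)) ""
                      else sprintf("  iou %.3f", train_iou)))
    if (val_loss < best_val) {
      best_val <- val_loss; best_epoch <- epoch; since_best <- 0L
      best_params <- model$params; best_buffers <- model$buffers
    } else {
      since_best <- since_best + 1L
    }
    if (!is.null(target_train_iou) && train_iou >= target_train_iou) {
      # controlled-overfit exit: keep the current weights
      best_params <- model$params; best_buffers <- model$buffers
      best_epoch <- epoch
      break
    }
    if (since_best >= cfg$early_stop_patience) break
  }
  model$params <- best_params
  model$buffers <- best_buffers
  attr(model, "history") <- hist
  attr(model, "best_epoch") <- best_epoch
  model
}

#' Per-pixel probability maps for a radiograph
#'
#' Evaluation-mode forward pass; channel `c` is the sigmoid probability
#' of class `c - 1` (background, femur, tibia, fibula). Channels are
#' independent sigmoids and need not sum to 1.
#'
#' @param model a (trained) [build_resunet18()] network.
#' @param image a normalized [radiograph()] or a numeric matrix in
#'   `[0, 1]`, square with side divisible by 32.
#' @return `H x W x 4` array of probabilities in `[0, 1]`.
#' @export
predict_prob_maps <- function(model, image) {
  px <- if (inherits(image, "kj_radiograph")) image$pixels else image
  stopifnot(is.matrix(px))
  xt <- images_to_tensor(list(px))
  fw <- nn_forward(model, xt, train = FALSE)
  p <- plogis(fw$vals[[model$out]]$x)
  array(p, dim = c(nrow(px), ncol(px), ncol(p)))
}

#' Segment a radiograph into a label mask
#'
#' Each pixel takes the class of its highest-probability channel; exact
#' ties go to the lowest class index.
#'
#' @inheritParams predict_prob_maps
#' @return A [label_mask()].
#' @export
predict_mask <- function(model, image) {
  p <- predict_prob_maps(model, image)
  maps_to_mask(p)
}

#' Collapse probability maps to a label mask
#'
#' @param maps `H x W x 4` probability array, channel `c` = class `c - 1`.
#' @return A [label_mask()]; ties resolve to the lowest class index.
#' @export
maps_to_mask <- function(maps) {
  stopifnot(length(dim(maps)) == 3L)
  d <- dim(maps)
  m <- matrix(maps, d[1] * d[2], d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  label_mask(matrix(lab, d[1], d[2]))
}

#' Binary cross-entropy over probability maps
#'
#' Mean over all pixels and channels of
#' `-(y log p + (1 - y) log(1 - p))`, with predictions clipped to
#' `[eps, 1 - eps]`, `eps = 1e-7`. Equals `ln 2` when `p = 0.5`
#' everywhere, regardless of the targets.
#'
#' @param pred probabilities in `[0, 1]` (array or matrix).
#' @param target one-hot targets of the same shape.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(pred, target) {
  if (!all(dim(pred) == dim(target))) stop("shape mismatch")
  eps <- 1e-7
  p <- pmin(pmax(pred, eps), 1 - eps)
  mean(-(target * log(p) + (1 - target) * log(1 - p)))
}

#' Intersection-over-union of a predicted mask
#'
#' `iou` computes the IoU of one class; `mean_iou` averages over the
#' classes present in prediction or truth (a class absent from both is
#' excluded from the mean).
#'
#' @param pred,truth [label_mask()] objects (or integer matrices) of the
#'   same shape.
#' @param class_id class code 0-3.
#' @param classes classes considered by `mean_iou`.
#' @return IoU in `[0, 1]`; `iou` returns `NaN` for a class absent from
#'   both masks.
#' @export
iou <- function(pred, truth, class_id) {
  p <- unclass(pred); t_ <- unclass(truth)
  if (!all(dim(p) == dim(t_))) stop("shape mismatch")
  pi_ <- p == class_id; ti <- t_ == class_id
  un <- sum(pi_ | ti)
  if (un == 0L) return(NaN)
  sum(pi_ & ti) / un
}

#' @rdname iou
#' @export
mean_iou <- function(pred, truth, classes = 0:3) {
  vals <- vapply(classes, function(cl) iou(pred, truth, cl), 0.0)
  mean(vals[!is.nan(vals)])
}

#' Overfitting score from validation and training losses
#'
#' `(val_loss - train_loss) / val_loss`: the relative generalization gap,
#' 0 when training and validation losses coincide and approaching 1 when
#' the training loss collapses far below the validation loss.
#'
#' @param val_loss validation loss (> 0).
#' @param train_loss training loss.
#' @return The overfitting score.
#' @export
overfitting_score <- function(val_loss, train_loss) {
  if (any(val_loss <= 0)) stop("val_loss must be > 0")
  (val_loss - train_loss) / val_loss
}
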