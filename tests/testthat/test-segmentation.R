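test_that("BCE loss matches its analytic values", {
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  p_half <- matrix(0.5, 2, 2)
  expect_equal(bce_loss(p_half, y), log(2), tolerance = 1e-12)
  # ln 2 at p = 0.5 regardless of the targets
  expect_equal(bce_loss(p_half, matrix(c(0, 0, 1, 1), 2, 2)), log(2),
               tolerance = 1e-12)
  expect_equal(bce_loss(matrix(0.25), matrix(1)), -log(0.25),
               tolerance = 1e-12)
  expect_lt(bce_loss(y, y), 1.1e-7)  # perfect prediction, clipped
  expect_error(bce_loss(matrix(0.5, 2, 2), matrix(1, 3, 2)), "mismatch")
})

test_that("logits-path BCE agrees with the probability-path definition", {
  set.seed(5)
  z <- matrix(rnorm(200, 0, 2), 50, 4)
  y <- matrix(rbinom(200, 1, 0.5), 50, 4)
  l <- kneejsw:::bce_with_logits(z, y)
  expect_equal(l$loss, bce_loss(plogis(z), y), tolerance = 1e-9)
})

test_that("overfitting score is the relative validation-training gap", {
  expect_equal(overfitting_score(0.5, 0.5), 0)
  expect_equal(overfitting_score(0.2, 0.05), 0.75)
  expect_error(overfitting_score(0, 0.1), "> 0")
  expect_error(overfitting_score(-1, 0.1), "> 0")
})

test_that("IoU counts pixel overlap per class", {
  a <- label_mask(matrix(0L, 20, 20))
  expect_equal(iou(a, a, 0), 1.0)
  b <- unclass(a); b[1:10, 1:10] <- 1L
  c_ <- unclass(a); c_[1:10, 6:15] <- 1L
  expect_equal(iou(label_mask(b), label_mask(c_), 1), 50 / 150)
  expect_equal(iou(label_mask(b), label_mask(c_), 1),
               iou(label_mask(c_), label_mask(b), 1))  # symmetry
  # invariance under simultaneous horizontal flip
  expect_equal(iou(flip_horizontal(label_mask(b)),
                   flip_horizontal(label_mask(c_)), 1), 50 / 150)
  d <- unclass(a); d[15:20, 15:20] <- 1L
  expect_equal(iou(label_mask(b), label_mask(d), 1), 0)
  # class absent from both masks is excluded from the mean
  expect_true(is.nan(iou(label_mask(b), label_mask(c_), 3)))
  expect_equal(mean_iou(label_mask(b), label_mask(b)), 1.0)
  expect_error(iou(label_mask(b), label_mask(matrix(0L, 5, 5)), 1),
               "mismatch")
})

test_that("probability maps collapse to labels with low-class tie-breaking", {
  maps <- array(0, dim = c(1, 2, 4))
  maps[1, 1, ] <- c(0.1, 0.9, 0.2, 0.3)   # class 1 (femur) wins
  maps[1, 2, ] <- c(0.5, 0.5, 0.1, 0.1)   # tie: lowest class index wins
  m <- maps_to_mask(maps)
  expect_identical(as.vector(unclass(m)), c(1L, 0L))
  # all-background maps give an all-zero mask
  bg <- array(rep(c(0.9, 0.1, 0.1, 0.1), each = 6), dim = c(2, 3, 4))
  expect_true(all(unclass(maps_to_mask(bg)) == 0L))
})

test_that("network forward pass honours shape and range contracts", {
  net <- build_resunet18(base_width = 8, seed = 1)
  ph <- make_phantom(phantom_spec(height = 64L, width = 64L, seed = 3))
  p <- predict_prob_maps(net, ph$radiograph)
  expect_equal(dim(p), c(64L, 64L, 4L))
  expect_true(all(p >= 0 & p <= 1))
  # deterministic in evaluation mode
  expect_identical(p, predict_prob_maps(net, ph$radiograph))
  expect_error(predict_prob_maps(net, matrix(0.5, 60, 60)),
               "divisible by 32")
})

test_that("the 18-layer encoder is strictly smaller than the 50-layer one", {
  expect_lt(resunet_param_count(18), resunet_param_count(50))
})

test_that("analytic gradients match finite differences", {
  set.seed(3)
  net <- build_resunet18(base_width = 4, seed = 2)
  H <- 64
  img <- matrix(runif(H * H), H, H)
  msk <- matrix(sample(0:3, H * H, TRUE), H, H)
  xt <- kneejsw:::images_to_tensor(list(img))
  yt <- kneejsw:::masks_to_onehot(list(msk))
  fw <- kneejsw:::nn_forward(net, xt, train = TRUE)
  l <- kneejsw:::bce_with_logits(fw$vals[[net$out]]$x, yt)
  grads <- kneejsw:::nn_backward(net, fw, l$dz)
  loss_of <- function(m) {
    f <- kneejsw:::nn_forward(m, xt, train = TRUE)
    kneejsw:::bce_with_logits(f$vals[[m$out]]$x, yt)$loss
  }
  eps <- 1e-5
  for (nm in c("stem.conv.W", "enc2.b1.down.conv.W", "dec2.conv.W",
               "enc3.b2.bn2.gamma", "head.W", "head.b")) {
    ii <- sample(length(net$params[[nm]]), 3)
    for (i in ii) {
      m1 <- net; m1$params[[nm]][i] <- m1$params[[nm]][i] + eps
      m2 <- net; m2$params[[nm]][i] <- m2$params[[nm]][i] - eps
      fd <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
      an <- grads[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-8, abs(fd), abs(an)), 1e-4)
    }
  }
})

test_that("training stops early and returns the best-validation weights", {
  ds_train <- list(training_phantom(1))
  # adversarial validation pair: labels swapped, so validation worsens as
  # the network fits the training mask
  bad <- ds_train[[1]]
  sw <- bad$mask
  bad$mask[sw == 1L] <- 2L
  bad$mask[sw == 2L] <- 1L
  cfg <- training_config(max_epochs = 30, early_stop_patience = 3,
                         batch_size = 1, augment = FALSE, seed = 5)
  net <- build_resunet18(base_width = 4, seed = 4)
  tr <- train(net, ds_train, list(bad), cfg)
  h <- attr(tr, "history")
  best <- which.min(h$val_loss)
  expect_lte(nrow(h), best + cfg$early_stop_patience)
  expect_identical(attr(tr, "best_epoch"), best)
  # returned weights reproduce the recorded minimum validation loss
  expect_equal(kneejsw:::eval_loss(tr, list(bad), 1), min(h$val_loss),
               tolerance = 1e-12)
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- list(training_phantom(2))
  cfg <- training_config(max_epochs = 2, batch_size = 1, seed = 9)
  h1 <- attr(train(build_resunet18(4, seed = 8), ds, ds, cfg), "history")
  h2 <- attr(train(build_resunet18(4, seed = 8), ds, ds, cfg), "history")
  expect_identical(h1, h2)
})

test_that("training rejects empty datasets and malformed samples", {
  net <- build_resunet18(base_width = 4, seed = 1)
  ds <- list(training_phantom(1))
  expect_error(train(net, list(), ds), "empty")
  expect_error(train(net, ds, list(list(image = matrix(0, 4, 4),
                                        mask = matrix(0L, 8, 8)))),
               "mismatch")
})
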