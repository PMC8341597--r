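test_that("network parameter count matches a layer-by-layer hand count", {
  # depth 2, base 4, 1 input channel, 5 classes, 3x3 kernels:
  #   enc1 conv1 1->4:   9*1*4  + 4 =  40
  #   enc1 conv2 4->4:   9*4*4  + 4 = 148
  #   enc2 conv1 4->8:   9*4*8  + 8 = 296
  #   enc2 conv2 8->8:   9*8*8  + 8 = 584
  #   dec1 conv1 12->4:  9*12*4 + 4 = 436   (8 upsampled + 4 skip channels)
  #   dec1 conv2 4->4:   9*4*4  + 4 = 148
  #   head 1x1   4->5:   1*4*5  + 5 =  25
  set.seed(1)
  m <- build_unet(net_config(depth = 2, base_filters = 4, input_size = 8))
  expect_identical(n_params(m), 40L + 148L + 296L + 584L + 436L + 148L + 25L)
  expect_identical(n_skip_connections(m), 1L)
})

test_that("forward pass yields a per-pixel softmax over 5 classes at input resolution", {
  set.seed(2)
  m <- build_unet(net_config(depth = 4, base_filters = 4, input_size = 64))
  expect_identical(n_skip_connections(m), 3L)
  x <- matrix(runif(64 * 64), 64, 64)
  pr <- predict(m, x, pixel_spacing = 0.08)
  expect_identical(dim(pr$mask$labels), c(64L, 64L))
  expect_identical(dim(pr$probs), c(64L, 64L, 5L))
  sums <- apply(pr$probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(pr$probs >= 0 & pr$probs <= 1))
  # labels are the argmax with ties toward the lower class index
  first_argmax <- apply(pr$probs, c(1, 2), which.max) - 1L
  expect_identical(pr$mask$labels, matrix(as.integer(first_argmax), 64, 64))

  expect_error(net_config(depth = 4, input_size = 60), "divisible")
  expect_error(predict(m, matrix(0, 63, 63)), "square|incompatible")
  expect_error(predict(m, matrix(0, 36, 36)), "incompatible")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(3)
  cfg <- net_config(depth = 2, base_filters = 3, input_size = 8,
                    dropout_rate = 0)
  m <- build_unet(cfg)
  # jitter all parameters (in particular the zero-initialized biases) so no
  # pre-activation sits exactly on the ReLU kink, where the analytic
  # subgradient and a central finite difference legitimately disagree
  m$params <- lapply(m$params, function(p) p + rnorm(length(p), sd = 0.05))
  cfgv <- ivusseg:::cpp_cfg(cfg, 8L, 8L)
  x <- matrix(runif(64), nrow = 1)
  y <- as.integer(sample(0:4, 64, TRUE))
  cw <- rep(1, 5)
  g <- ivusseg:::cpp_unet_grad(m$params, cfgv, x, y, 0, 1, cw)
  eps <- 1e-6
  for (pi in seq_along(m$params)) {
    for (ix in sample(length(m$params[[pi]]), min(3, length(m$params[[pi]])))) {
      p <- m$params
      p[[pi]][ix] <- p[[pi]][ix] + eps
      lp <- ivusseg:::cpp_unet_loss(p, cfgv, x, y, cw)
      p[[pi]][ix] <- p[[pi]][ix] - 2 * eps
      lm <- ivusseg:::cpp_unet_loss(p, cfgv, x, y, cw)
      num <- (lp - lm) / (2 * eps)
      expect_equal(g$grads[[pi]][ix], num, tolerance = 1e-3)
    }
  }
})

test_that("training overfits a two-frame set and checkpoints the best validation loss", {
  set.seed(4)
  # dropout off: this probes optimizer + capacity, not regularization
  cfg <- net_config(depth = 2, base_filters = 8, input_size = 32,
                    dropout_rate = 0)
  m <- build_unet(cfg)
  g <- test_geometry(image_size = 32, pixel_spacing = 0.16)
  mk <- rasterize_mask(g)
  set.seed(5)
  frames <- list(render_bmode(g, 0.4), render_bmode(g, 0.4))
  masks <- list(mk, mk)
  tc <- train_config(batch_size = 2, max_epochs = 200, early_stop_patience = 200,
                     augment = FALSE)
  fit <- train_unet(m, frames, masks, tc)
  expect_lte(nrow(fit$history), 200)
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            0.10 * fit$history$train_loss[1])

  # explicit validation pair: returned weights are the argmin of val loss
  set.seed(6)
  m2 <- build_unet(cfg)
  tc2 <- train_config(batch_size = 2, max_epochs = 8, early_stop_patience = 8,
                      augment = FALSE)
  fit2 <- train_unet(m2, frames, masks, tc2, frames[1], masks[1])
  expect_identical(fit2$best_epoch,
                   which.min(fit2$history$val_loss))

  expect_error(train_unet(m, list(), list(), tc), "empty training set")
})

test_that("training is reproducible under a fixed seed", {
  cfg <- net_config(depth = 2, base_filters = 4, input_size = 32)
  g <- test_geometry(image_size = 32, pixel_spacing = 0.16)
  mk <- rasterize_mask(g)
  run <- function() {
    set.seed(42)
    m <- build_unet(cfg)
    set.seed(43)
    fr <- list(render_bmode(g, 0.4), render_bmode(g, 0.4))
    set.seed(44)
    train_unet(m, fr, list(mk, mk),
               train_config(max_epochs = 3, augment = TRUE))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
})

test_that("augmentation transforms frame and mask jointly and exactly", {
  withr::local_seed(7)
  g <- test_geometry(image_size = 32, pixel_spacing = 0.16,
                     struts_deg = c(10, 200))
  mk <- rasterize_mask(g)
  fr <- render_bmode(g, 0.3)

  # flips are involutions
  once <- apply_augmentation(fr, mk, flip_h = TRUE)
  twice <- apply_augmentation(once$frame, once$mask, flip_h = TRUE)
  expect_identical(twice$frame, fr)
  expect_identical(twice$mask$labels, mk$labels)

  # 90-degree rotations permute pixels: per-class counts unchanged
  rot <- apply_augmentation(fr, mk, rot90_k = 1)
  expect_identical(tabulate(rot$mask$labels + 1L, 5),
                   tabulate(mk$labels + 1L, 5))
  # four quarter-turns are the identity
  r4 <- apply_augmentation(fr, mk, rot90_k = 4)
  expect_identical(r4$mask$labels, mk$labels)

  # random augmentation keeps the class set within the input's
  for (i in 1:5) {
    a <- augment(fr, mk)
    expect_true(all(unique(as.integer(a$mask$labels)) %in%
                      unique(as.integer(mk$labels))))
  }
  expect_error(apply_augmentation(fr[1:10, 1:10], mk), "sizes differ")
})

test_that("splits are patient-disjoint with 20% frame-wise validation", {
  man <- data.frame(patient_id = rep(sprintf("P%02d", 1:24), each = 10))
  set.seed(8)
  sp <- make_split(man, test_n_patients = 2)
  expect_length(sp$test_patients, 2)
  expect_length(sp$train_patients, 22)
  expect_length(intersect(sp$train_patients, sp$test_patients), 0)
  # no frame of a test patient appears in train or validation
  expect_false(any(man$patient_id[c(sp$train_idx, sp$validation_idx)] %in%
                     sp$test_patients))
  # validation size is round(0.2 * training frames), drawn from train patients
  expect_equal(length(sp$validation_idx), round(0.2 * 220))
  expect_true(all(man$patient_id[sp$validation_idx] %in% sp$train_patients))
  # reproducible
  set.seed(8)
  sp2 <- make_split(man, 2)
  expect_identical(sp, sp2)
  expect_error(make_split(man, 24), "at least")
})
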