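#' Training configuration
#'
#' The optimization recipe: batch size 2, categorical cross-entropy loss,
#' Adam with learning rate 0.001, 20 percent of training frames held out
#' for validation, and augmentation by horizontal/vertical flips and
#' rotations. Epoch budget and early stopping (patience on validation loss)
#' are explicit knobs. Optional per-class loss weights exist because pixel
#' imbalance (tiny stent blobs vs large background) is the known failure
#' mode of this task; they default to off.
#'
#' @param batch_size Frames per gradient step (>= 1).
#' @param learning_rate Adam learning rate.
#' @param validation_fraction Fraction of training frames reserved for
#'   validation, in (0, 1).
#' @param max_epochs Epoch budget.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param augment Apply random flip/rotation augmentation each epoch.
#' @param class_weights Optional numeric vector of 5 per-class loss weights.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 2L, learning_rate = 0.001,
                         validation_fraction = 0.2, max_epochs = 30L,
                         early_stop_patience = 10L, augment = TRUE,
                         class_weights = NULL) {
  cfg <- structure(list(batch_size = as.integer(batch_size),
                        learning_rate = as.numeric(learning_rate),
                        validation_fraction = as.numeric(validation_fraction),
                        max_epochs = as.integer(max_epochs),
                        early_stop_patience = as.integer(early_stop_patience),
                        augment = isTRUE(augment),
                        class_weights = class_weights,
                        loss = "categorical_crossentropy", optimizer = "adam"),
                   class = "train_config")
  if (cfg$batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (cfg$validation_fraction <= 0 || cfg$validation_fraction >= 1)
    stop("validation_fraction must lie in (0, 1)", call. = FALSE)
  if (!is.null(class_weights) && length(class_weights) != 5L)
    stop("class_weights must have length 5", call. = FALSE)
  cfg
}

#' Patient-level train/validation/test split
#'
#' Test frames are split by patient, never by frame: `test_n_patients`
#' whole pullbacks are held out, and no patient contributes to both sides.
#' Validation frames are then drawn frame-wise from the training patients
#' only, `round(validation_fraction * n_training_frames)` of them.
#'
#' Uses R's RNG stream; the same seed reproduces the same split.
#'
#' @param manifest Data frame with one row per frame and a `patient_id`
#'   column (as written by [generate_dataset()]), or the sequence list from
#'   [simulate_pullbacks()].
#' @param test_n_patients Number of whole patients held out for testing.
#' @param validation_fraction Fraction of training frames for validation.
#' @return A `split_plan`: `train_patients`, `test_patients`, and the row
#'   index vectors `train_idx`, `validation_idx`, `test_idx` into the
#'   manifest.
#' @export
make_split <- function(manifest, test_n_patients, validation_fraction = 0.2) {
  if (is.list(manifest) && !is.data.frame(manifest))
    manifest <- manifest_skeleton(manifest)
  pats <- unique(manifest$patient_id)
  if (length(pats) < test_n_patients + 1L)
    stop("argument error: need at least test_n_patients + 1 patients", call. = FALSE)
  test_patients <- sample(pats, test_n_patients)
  train_patients <- setdiff(pats, test_patients)
  test_idx <- which(manifest$patient_id %in% test_patients)
  pool <- which(manifest$patient_id %in% train_patients)
  n_val <- round(validation_fraction * length(pool))
  validation_idx <- sort(sample(pool, n_val))
  train_idx <- setdiff(pool, validation_idx)
  structure(list(train_patients = train_patients,
                 test_patients = test_patients,
                 train_idx = train_idx, validation_idx = validation_idx,
                 test_idx = test_idx),
            class = "split_plan")
}

# flat frame table (patient_id, patient number, frame index) for a sequence
# list, mirroring the manifest layout
manifest_skeleton <- function(sequences) {
  do.call(rbind, lapply(seq_along(sequences), function(p) {
    data.frame(patient_id = sequences[[p]]$patient_id,
               patient = p, frame_index = seq_along(sequences[[p]]$frames),
               stringsAsFactors = FALSE)
  }))
}

#' Apply a fixed geometric augmentation to a frame/mask pair
#'
#' The identical transform is applied to both grids, so labels stay aligned
#' with intensities. Flips and 90-degree rotation multiples permute pixels,
#' hence per-class pixel counts are preserved and masks stay exact.
#'
#' @param frame Numeric matrix.
#' @param mask `ivus_mask` or integer matrix of the same size.
#' @param flip_h,flip_v Apply horizontal (left-right) / vertical (up-down)
#'   flip.
#' @param rot90_k Number of clockwise 90-degree rotations (0-3).
#' @return List `frame`, `mask` (same types as the inputs).
#' @export
apply_augmentation <- function(frame, mask, flip_h = FALSE, flip_v = FALSE,
                               rot90_k = 0L) {
  lab <- if (inherits(mask, "ivus_mask")) mask$labels else mask
  if (!all(dim(frame) == dim(lab)))
    stop("argument error: frame and mask sizes differ", call. = FALSE)
  tf <- function(m) {
    if (flip_h) m <- m[, ncol(m):1, drop = FALSE]
    if (flip_v) m <- m[nrow(m):1, , drop = FALSE]
    k <- rot90_k %% 4L
    while (k > 0L) { m <- t(m[nrow(m):1, , drop = FALSE]); k <- k - 1L }
    m
  }
  out_lab <- tf(lab)
  out_mask <- if (inherits(mask, "ivus_mask"))
    label_mask(out_lab, mask$pixel_spacing) else out_lab
  list(frame = tf(frame), mask = out_mask)
}

#' Randomly augment a frame/mask pair
#'
#' Samples horizontal and vertical flips (probability 1/2 each) and a
#' uniform 90-degree rotation multiple from R's RNG stream, then applies
#' them jointly via [apply_augmentation()].
#'
#' @inheritParams apply_augmentation
#' @return List `frame`, `mask`.
#' @export
augment <- function(frame, mask) {
  apply_augmentation(frame, mask,
                     flip_h = runif(1) < 0.5, flip_v = runif(1) < 0.5,
                     rot90_k = sample(0:3, 1))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    params[[i]] <- params[[i]] -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  list(params = params, state = state)
}

mask_to_y <- function(mask) {
  lab <- if (inherits(mask, "ivus_mask")) mask$labels else mask
  as.integer(lab)
}

frame_to_x <- function(frame) matrix(as.numeric(frame), nrow = 1L)

#' Train a U-Net on frame/mask pairs
#'
#' Mini-batch Adam on the per-pixel categorical cross-entropy, with optional
#' on-the-fly flip/rotation augmentation. After every epoch the validation
#' loss is computed (dropout off); the weights achieving the minimum
#' validation loss are kept and returned, and training stops early after
#' `early_stop_patience` epochs without improvement. When no validation
#' pair is supplied the epoch training loss drives checkpointing instead.
#'
#' Randomness (shuffling, augmentation, dropout) derives from R's RNG
#' stream, so a fixed `set.seed()` reproduces the run.
#'
#' @param model An `ivus_unet` from [build_unet()].
#' @param frames List of square numeric matrices (training inputs).
#' @param masks List of `ivus_mask` or integer label matrices, same length.
#' @param config A [train_config()].
#' @param val_frames,val_masks Optional validation pairs.
#' @param verbose Print per-epoch losses.
#' @return The model with trained `params`, a `history` data frame
#'   (epoch, train_loss, val_loss) and `best_epoch`.
#' @export
train_unet <- function(model, frames, masks, config = train_config(),
                       val_frames = NULL, val_masks = NULL, verbose = FALSE) {
  if (length(frames) == 0L)
    stop("argument error: empty training set", call. = FALSE)
  if (length(frames) != length(masks))
    stop("argument error: frames and masks lengths differ", call. = FALSE)
  cw <- if (is.null(config$class_weights)) rep(1, model$config$n_classes)
        else as.numeric(config$class_weights)
  h <- nrow(frames[[1]])
  cfgv <- cpp_cfg(model$config, h, h)
  params <- model$params
  state <- adam_init(params)
  has_val <- !is.null(val_frames) && length(val_frames) > 0L

  val_loss_of <- function(p) {
    mean(vapply(seq_along(val_frames), function(i) {
      cpp_unet_loss(p, cfgv, frame_to_x(val_frames[[i]]),
                    mask_to_y(val_masks[[i]]), cw)
    }, numeric(1)))
  }

  n <- length(frames)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  stall <- 0L
  for (ep in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_losses <- numeric(0)
    b <- 1L
    while (b <= n) {
      ids <- ord[b:min(b + config$batch_size - 1L, n)]
      gsum <- NULL; lsum <- 0
      for (i in ids) {
        fr <- frames[[i]]; mk <- masks[[i]]
        if (config$augment) {
          aug <- augment(fr, mk); fr <- aug$frame; mk <- aug$mask
        }
        seed <- floor(runif(1) * 2^31)
        g <- cpp_unet_grad(params, cfgv, frame_to_x(fr), mask_to_y(mk),
                           model$config$dropout_rate, seed, cw)
        lsum <- lsum + g$loss
        gsum <- if (is.null(gsum)) g$grads else
          mapply(`+`, gsum, g$grads, SIMPLIFY = FALSE)
      }
      k <- length(ids)
      if (k > 1L) gsum <- lapply(gsum, function(x) x / k)
      up <- adam_step(params, gsum, state, config$learning_rate)
      params <- up$params; state <- up$state
      ep_losses <- c(ep_losses, lsum / k)
      b <- b + config$batch_size
    }
    tr_loss <- mean(ep_losses)
    vl <- if (has_val) val_loss_of(params) else tr_loss
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                   val_loss = if (has_val) vl else NA_real_))
    if (verbose)
      message(sprintf("epoch %d  train %.4f  val %s", ep, tr_loss,
                      if (has_val) sprintf("%.4f", vl) else "-"))
    if (vl < best$loss) {
      best <- list(loss = vl, params = params, epoch = ep)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stop_patience) break
    }
  }
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}
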