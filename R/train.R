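# Training protocol: SGD with Nesterov momentum and polynomial learning-rate
# decay, forced-foreground batch sampling against class imbalance, per-epoch
# validation with best-Dice checkpointing, deterministic given the seed.

#' Training configuration
#'
#' Defaults follow the nnU-Net-style protocol: initial learning rate 0.001,
#' weight decay 3e-5, batch size 4, 250 iterations per epoch, 300 epochs, and
#' a forced-foreground sampling probability of 0.33.
#'
#' @param lr initial learning rate.
#' @param weight_decay L2 weight decay.
#' @param batch_size samples per step (>= 2; batch norm needs a batch).
#' @param iters_per_epoch optimizer steps per epoch.
#' @param epochs total epochs.
#' @param fg_sample_ratio probability that a batch slot is forced to a sample
#'   containing foreground, in (0, 1].
#' @param fold validation fold index in 0..4, or `NA` to train on everything
#'   and validate on the training set (desk-scale overfitting runs).
#' @param seed RNG seed for sampling.
#' @param momentum,nesterov,lr_power optimizer settings.
#' @export
train_config <- function(lr = 0.001, weight_decay = 3e-5, batch_size = 4L,
                         iters_per_epoch = 250L, epochs = 300L,
                         fg_sample_ratio = 0.33, fold = NA_integer_,
                         seed = 1L, momentum = 0.99, nesterov = TRUE,
                         lr_power = 0.9) {
  if (fg_sample_ratio <= 0 || fg_sample_ratio > 1)
    stop("fg_sample_ratio must be in (0, 1]")
  if (batch_size < 2L) stop("batch_size must be >= 2 (batch normalization)")
  structure(list(lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 iters_per_epoch = as.integer(iters_per_epoch),
                 epochs = as.integer(epochs),
                 fg_sample_ratio = fg_sample_ratio,
                 fold = fold, seed = as.integer(seed),
                 momentum = momentum, nesterov = nesterov,
                 lr_power = lr_power),
            class = "train_config")
}

#' Sample one batch of ids with forced-foreground slots
#'
#' Each slot is independently forced with probability `ratio` to draw from the
#' foreground-containing ids; otherwise it draws uniformly from all ids.
#'
#' @param ids all sample ids; `fg_ids` the subset containing foreground.
#' @param batch_size slots; `ratio` forcing probability.
#' @return data.frame with `id` and logical `forced`.
#' @export
sample_batch_ids <- function(ids, fg_ids, batch_size, ratio) {
  forced <- stats::runif(batch_size) < ratio & length(fg_ids) > 0
  id <- character(batch_size)
  for (j in seq_len(batch_size)) {
    id[j] <- if (forced[j]) fg_ids[sample.int(length(fg_ids), 1L)]
             else ids[sample.int(length(ids), 1L)]
  }
  data.frame(id = id, forced = forced, stringsAsFactors = FALSE)
}

# stack samples into (b, 3, h, w) in [0,1] and (b, h, w) targets
batch_tensors <- function(samples) {
  b <- length(samples)
  d <- dim(samples[[1]]$image)
  x <- array(0, dim = c(b, 3L, d[1], d[2]))
  y <- array(0, dim = c(b, d[1], d[2]))
  for (j in seq_len(b)) {
    x[j, , , ] <- aperm(samples[[j]]$image / 255, c(3, 1, 2))
    y[j, , ] <- samples[[j]]$mask
  }
  list(x = x, y = y)
}

mean_train_dice <- function(model, samples) {
  set_training(FALSE)
  on.exit(set_training(TRUE))
  dice <- vapply(samples, function(s) {
    pred <- predict_mask(model, s$image)
    v <- ratio_metrics(confusion(pred, s$mask))$dice
    if (is.na(v)) 0 else v
  }, numeric(1))
  mean(dice)
}

#' Segment one image with a trained model
#'
#' @param model an `ntsm_model`; `image` h x w x 3 array (8-bit integers or
#'   \[0,1\] reals).
#' @return binary mask matrix (argmax over classes at the finest scale).
#' @export
predict_mask <- function(model, image) {
  if (max(image) > 1) image <- image / 255
  x <- array(aperm(image, c(3, 1, 2)), dim = c(1L, 3L, nrow(image), ncol(image)))
  old <- set_training(FALSE)
  on.exit(set_training(old))
  out <- ntsm_forward(model, x)
  lg <- out$logits[[1]]$value
  (lg[1, dim(lg)[2], , ] > lg[1, 1, , ]) * 1
}

#' Train an NTSM model
#'
#' Runs `epochs * iters_per_epoch` optimizer steps of the joint
#' deep-supervision loss with polynomial learning-rate decay, validating after
#' every epoch and keeping the checkpoint with the best validation Dice.
#' Aborts with a diagnostic if the loss diverges to NaN.
#'
#' @param samples list of `image_sample`s (e.g. from [load_dataset()]).
#' @param config an [ntsm_config()].
#' @param train a [train_config()].
#' @param loss_cfg a [loss_config()]; level count must match
#'   `config$deep_supervision_levels`.
#' @param out_dir directory for `checkpoint_best.ckpt` and `train_log.csv`,
#'   or `NULL` to keep everything in memory.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-validation weights restored), `log`
#'   (data.frame epoch/train_loss/val_loss/val_dice), `losses` (per-step),
#'   and `checkpoint` path (or NULL).
#' @export
ntsm_train <- function(samples, config = ntsm_config(), train = train_config(),
                       loss_cfg = NULL, out_dir = NULL, verbose = FALSE) {
  if (is.null(loss_cfg))
    loss_cfg <- loss_config(level_weights = 0.5^(seq_len(config$deep_supervision_levels) - 1))
  ids <- vapply(samples, `[[`, character(1), "id")
  names(samples) <- ids
  if (!is.na(train$fold)) {
    folds <- make_folds(ids, k = 5L, seed = train$seed)
    val_ids <- ids[folds == train$fold]
    tr_ids <- setdiff(ids, val_ids)
    if (length(val_ids) == 0 || length(tr_ids) == 0)
      stop("fold ", train$fold, " leaves an empty train or validation set")
  } else {
    tr_ids <- ids; val_ids <- ids
  }
  fg_ids <- tr_ids[vapply(samples[tr_ids], function(s) sum(s$mask) > 0, logical(1))]
  model <- build_ntsm(config)
  params <- collect_params(model)
  opt <- new_sgd(params, lr = train$lr, momentum = train$momentum,
                 nesterov = train$nesterov, weight_decay = train$weight_decay)
  total_steps <- train$epochs * train$iters_per_epoch
  set.seed(train$seed + 1L)
  set_training(TRUE)
  on.exit(set_training(FALSE))
  losses <- numeric(total_steps)
  log_rows <- vector("list", train$epochs)
  best <- list(dice = -Inf, params = NULL, stats = NULL)
  step <- 0L
  for (ep in seq_len(train$epochs)) {
    ep_loss <- 0
    for (it in seq_len(train$iters_per_epoch)) {
      step <- step + 1L
      opt$lr <- poly_lr(train$lr, step - 1L, total_steps, train$lr_power)
      bids <- sample_batch_ids(tr_ids, fg_ids, train$batch_size, train$fg_sample_ratio)
      bt <- batch_tensors(samples[bids$id])
      out <- ntsm_forward(model, bt$x)
      loss <- deep_supervision_loss(out, bt$y, loss_cfg)
      lv <- as.numeric(loss$value)
      if (!is.finite(lv))
        stop("training diverged: loss is ", lv, " at step ", step,
             " (epoch ", ep, "); lower the learning rate")
      losses[step] <- lv
      ep_loss <- ep_loss + lv
      ag_zero_grad(params)
      ag_backward(loss)
      sgd_step(opt)
    }
    # per-epoch validation: full held-out set
    set_training(FALSE)
    val <- vapply(samples[val_ids], function(s) {
      outv <- ntsm_forward(model, batch_tensors(list(s))$x)
      lossv <- deep_supervision_loss(outv, array(s$mask, dim = c(1L, dim(s$mask))), loss_cfg)
      pred <- predict_mask(model, s$image)
      dv <- ratio_metrics(confusion(pred, s$mask))$dice
      c(as.numeric(lossv$value), if (is.na(dv)) 0 else dv)
    }, numeric(2))
    set_training(TRUE)
    val_loss <- mean(val[1, ]); val_dice <- mean(val[2, ])
    log_rows[[ep]] <- data.frame(epoch = ep,
                                 train_loss = ep_loss / train$iters_per_epoch,
                                 val_loss = val_loss, val_dice = val_dice)
    if (val_dice > best$dice) {
      best$dice <- val_dice
      best$params <- lapply(params, function(p) p$value)
      best$stats <- lapply(collect_stats(model), function(s) list(rm = s$rm, rv = s$rv))
    }
    if (verbose)
      message(sprintf("epoch %d/%d  train %.4f  val %.4f  dice %.4f",
                      ep, train$epochs, ep_loss / train$iters_per_epoch,
                      val_loss, val_dice))
  }
  # restore best weights
  for (i in seq_along(params)) params[[i]]$value <- best$params[[i]]
  st <- collect_stats(model)
  for (i in seq_along(st)) { st[[i]]$rm <- best$stats[[i]]$rm; st[[i]]$rv <- best$stats[[i]]$rv }
  log <- do.call(rbind, log_rows)
  ckpt <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ckpt <- file.path(out_dir, "checkpoint_best.ckpt")
    save_checkpoint(model, ckpt)
    utils::write.csv(log, file.path(out_dir, "train_log.csv"), row.names = FALSE)
  }
  list(model = model, log = log, losses = losses, best_val_dice = best$dice,
       checkpoint = ckpt)
}

#' Evaluate a model on a dataset
#'
#' @param model an `ntsm_model` or a checkpoint path.
#' @param samples list of `image_sample`s or a preprocessed dataset directory.
#' @param csv optional CSV path for the per-image report.
#' @return data.frame (id, sen, spe, dice, hd95) with a `mean` summary row.
#' @export
ntsm_evaluate <- function(model, samples, csv = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.character(samples)) samples <- load_dataset(samples)
  rows <- do.call(rbind, lapply(samples, function(s) {
    pred <- predict_mask(model, s$image)
    m <- segmentation_metrics(pred, s$mask)
    data.frame(id = s$id, sen = m$sen, spe = m$spe, dice = m$dice, hd95 = m$hd95)
  }))
  write_metrics_csv(rows, csv)
}

#' Predict masks for image files
#'
#' Writes `<stem>_mask.png` ({0,1} raw values) and a red-overlay
#' `<stem>_overlay.png` per input image.
#'
#' @param model an `ntsm_model` or checkpoint path; `image_paths` PNG/JPG
#'   files; `out_dir` destination.
#' @return character vector of written mask paths.
#' @export
ntsm_predict <- function(model, image_paths, out_dir) {
  if (is.character(model)) model <- load_checkpoint(model)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vapply(image_paths, function(f) {
    img <- read_image_any(f)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
    img <- img[, , 1:3]
    pred <- predict_mask(model, round(img * 255))
    stem <- strip_chan(strip_ext(f))
    mask_path <- file.path(out_dir, paste0(stem, "_mask.png"))
    png::writePNG(pred / 255, mask_path)
    ov <- img
    r <- ov[, , 1]; r[pred == 1] <- 0.6 * r[pred == 1] + 0.4
    g <- ov[, , 2]; g[pred == 1] <- 0.6 * g[pred == 1]
    b <- ov[, , 3]; b[pred == 1] <- 0.6 * b[pred == 1]
    ov[, , 1] <- r; ov[, , 2] <- g; ov[, , 3] <- b
    png::writePNG(ov, file.path(out_dir, paste0(stem, "_overlay.png")))
    mask_path
  }, character(1))
}

#' Profile a model configuration
#'
#' @param config an [ntsm_config()]; `input_size` (h, w) for the FLOP count.
#' @return an `efficiency_report`: `params` (learnable scalars), `flops`
#'   (2 x MACs for one forward), `memory_bytes` (serialized checkpoint size).
#' @export
ntsm_profile <- function(config, input_size = c(64L, 64L)) {
  model <- build_ntsm(config)
  structure(list(params = count_params(model),
                 flops = estimate_flops(model, input_size),
                 memory_bytes = checkpoint_bytes(model)),
            class = "efficiency_report")
}

#' Write an efficiency report as key-value text
#' @param report an `efficiency_report`; `path` destination.
#' @export
write_efficiency_report <- function(report, path) {
  writeLines(c(paste0("params: ", report$params),
               paste0("flops: ", format(report$flops, scientific = FALSE)),
               paste0("memory_bytes: ", report$memory_bytes)), path)
  invisible(path)
}
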