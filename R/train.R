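# Training/prediction orchestration: deterministic dataset splitting, SGD
# with momentum and weight decay over the dual-head composite loss, random
# crops + augmentation per epoch, per-epoch validation Dice with
# best-checkpoint retention and early stopping, JSONL step logs.

#' Deterministic train/val/test split of a dataset manifest
#'
#' @param manifest data.frame from [generate_dataset()] / [read_manifest()]
#' @param fractions length-3 fractions summing to 1
#' @param seed shuffle seed
#' @return list(train, val, test) manifests; disjoint, union = input
#' @export
split_dataset <- function(manifest, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- nrow(manifest)
  if (n < 3) stop("dataset must contain at least 3 items, got ", n)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  if (n_train == 0) n_train <- 1L
  if (n_val == 0 && fractions[2] > 0) n_val <- 1L
  idx_train <- ord[seq_len(n_train)]
  idx_val <- ord[n_train + seq_len(n_val)]
  idx_test <- ord[-seq_len(n_train + n_val)]
  keep_dir <- function(m) { attr(m, "dir") <- attr(manifest, "dir"); m }
  list(train = keep_dir(manifest[idx_train, , drop = FALSE]),
       val = keep_dir(manifest[idx_val, , drop = FALSE]),
       test = keep_dir(manifest[idx_test, , drop = FALSE]))
}

load_sample <- function(manifest, i, dir = attr(manifest, "dir")) {
  list(image = read_image_rgb(file.path(dir, manifest$image[i])),
       mask = read_mask_png(file.path(dir, manifest$mask[i])),
       boundary = read_mask_png(file.path(dir, manifest$boundary[i])))
}

random_crop <- function(sample, crop) {
  H <- dim(sample$image)[1]; W <- dim(sample$image)[2]
  if (H < crop || W < crop) {
    stop("image ", H, "x", W, " smaller than crop ", crop)
  }
  r0 <- if (H == crop) 1L else sample.int(H - crop + 1L, 1)
  c0 <- if (W == crop) 1L else sample.int(W - crop + 1L, 1)
  rr <- r0:(r0 + crop - 1L); cc <- c0:(c0 + crop - 1L)
  list(image = sample$image[rr, cc, , drop = FALSE],
       mask = sample$mask[rr, cc], boundary = sample$boundary[rr, cc])
}

# pad H x W x 3 image (white) to sides divisible by 2^(levels-1)
pad_to_divisible <- function(image, levels) {
  d <- 2L^(levels - 1L)
  H <- dim(image)[1]; W <- dim(image)[2]
  Hp <- as.integer(ceiling(H / d) * d); Wp <- as.integer(ceiling(W / d) * d)
  if (Hp == H && Wp == W) {
    return(list(image = image, offset = c(0L, 0L), size = c(H, W)))
  }
  out <- array(1, c(Hp, Wp, dim(image)[3]))
  out[seq_len(H), seq_len(W), ] <- image
  list(image = out, offset = c(0L, 0L), size = c(H, W))
}

sgd_step <- function(model, grads, vel, lr, momentum, weight_decay) {
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g + weight_decay * model$params[[nm]]
    vel[[nm]] <- momentum * vel[[nm]] - lr * g
    model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
  }
  list(model = model, vel = vel)
}

batch_array <- function(samples, field) {
  a1 <- samples[[1]][[field]]
  if (length(dim(a1)) == 3L) {
    out <- array(0, c(dim(a1), length(samples)))
    for (i in seq_along(samples)) out[, , , i] <- samples[[i]][[field]]
  } else {
    out <- array(0, c(dim(a1), 1L, length(samples)))
    for (i in seq_along(samples)) out[, , 1L, i] <- samples[[i]][[field]]
  }
  out
}

# Precise-BN re-estimation: with weights fixed, replace the EMA running
# statistics by the exact average of batch statistics over a few training
# batches, so eval-mode forwards match the trained regime even after short
# runs where the EMA (momentum 0.99) has not caught up.
reestimate_bn_stats <- function(model, batches) {
  for (s in model$bn) {
    s$running_mean <- s$running_mean * 0
    s$running_var <- s$running_var * 0
  }
  for (i in seq_along(batches)) {
    mi <- model
    mi$bn_momentum <- (i - 1) / i   # cumulative mean of batch stats
    mi$encoder_cfg$dropout_rate <- 0  # stats reflect the inference path
    P <- wrap_params(mi)
    invisible(cunet_graph(P, ag_const(batches[[i]]), mi, training = TRUE,
                          tape = NULL))
  }
  model
}

validation_dice <- function(model, val_manifest, threshold = 0.5) {
  ds <- numeric(nrow(val_manifest))
  for (i in seq_len(nrow(val_manifest))) {
    s <- load_sample(val_manifest, i)
    pad <- pad_to_divisible(s$image, model$encoder_cfg$levels)
    out <- cunet_forward(model, pad$image, training = FALSE)
    seg <- out$seg_prob[seq_len(pad$size[1]), seq_len(pad$size[2]), 1]
    ds[i] <- dice_coefficient(binarize(seg, threshold), s$mask)
  }
  mean(ds)
}

#' Train a C-UNet model
#'
#' SGD with momentum and weight decay over the dual-head loss
#' (focal Tversky + w_seg (Dice+BCE) on the segmentation head, focal
#' Tversky + w_bou combo on the boundary head). Each epoch draws a random
#' square crop (and optional augmentation) per training image; validation
#' Dice is computed every epoch and the best-validation checkpoint is
#' retained. Stops when `early_stop_patience` epochs pass without
#' improvement. Fully seeded and reproducible.
#'
#' @param train_manifest,val_manifest manifests from [split_dataset()]
#' @param model a `cunet_model` (or NULL to build one from `model_cfg`)
#' @param model_cfg list(encoder, csfi, wcu) configuration blocks
#' @param loss_cfg a [loss_config()]
#' @param train_cfg a [train_config()]
#' @param out_dir directory for checkpoint and logs
#' @param augment_policy optional [augmentation_policy()] applied per crop
#' @return list(checkpoint, log, history, model, best_val_dice)
#' @export
train_cunet <- function(train_manifest, val_manifest, model = NULL,
                        model_cfg = NULL, loss_cfg = loss_config(),
                        train_cfg, out_dir = tempfile("cunet_run"),
                        augment_policy = NULL) {
  stopifnot(nrow(train_manifest) > 0, nrow(val_manifest) > 0,
            inherits(train_cfg, "train_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(model)) {
    model_cfg <- model_cfg %||% list()
    model <- cunet_model(
      encoder_cfg = model_cfg$encoder %||% encoder_config(),
      csfi_cfg = model_cfg$csfi %||% csfi_config(),
      wcu_cfg = model_cfg$wcu %||% wcu_config(),
      seed = train_cfg$seed)
  }
  model$bn_momentum <- train_cfg$bn_momentum
  check_divisible(train_cfg$train_crop, train_cfg$train_crop,
                  model$encoder_cfg$levels)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old), add = TRUE)
  set.seed(train_cfg$seed)

  vel <- lapply(model$params, function(p) p * 0)
  log_path <- file.path(out_dir, "train_log.jsonl")
  ckpt_path <- file.path(out_dir, "checkpoint.rds")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)

  best_val <- -Inf
  since_improve <- 0L
  history <- list()
  step <- 0L
  n_train <- nrow(train_manifest)

  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample.int(n_train)
    b0 <- 1L
    while (b0 <= n_train) {
      idx <- ord[b0:min(b0 + train_cfg$batch_size - 1L, n_train)]
      b0 <- b0 + train_cfg$batch_size
      samples <- lapply(idx, function(i) {
        s <- random_crop(load_sample(train_manifest, i), train_cfg$train_crop)
        if (!is.null(augment_policy)) {
          pol <- augment_policy
          pol$seed <- sample.int(.Machine$integer.max, 1)
          a <- augment_pair(s$image, list(mask = s$mask, boundary = s$boundary),
                            pol)
          s <- list(image = a$image, mask = a$targets$mask,
                    boundary = a$targets$boundary)
        }
        s
      })
      x <- batch_array(samples, "image")
      mask <- batch_array(samples, "mask")
      boundary <- batch_array(samples, "boundary")

      tape <- ag_tape()
      P <- wrap_params(model, tape)
      out <- cunet_graph(P, ag_const(x), model, training = TRUE, tape = tape)
      loss_node <- total_loss_graph(out$seg_prob, out$boundary_prob,
                                    mask, boundary, loss_cfg, tape)
      step <- step + 1L
      if (!is.finite(loss_node$value)) {
        stop("training diverged: non-finite loss at step ", step)
      }
      ag_backward(tape, loss_node)
      grads <- lapply(P, function(p) p$grad)
      upd <- sgd_step(model, grads, vel, train_cfg$learning_rate,
                      train_cfg$momentum, train_cfg$weight_decay)
      model <- upd$model; vel <- upd$vel
      writeLines(jsonlite::toJSON(
        list(step = step, epoch = epoch, loss = loss_node$value),
        auto_unbox = TRUE, digits = NA), log_con)
    }
    # refresh BN running stats at fixed weights before eval-mode validation,
    # using full padded training images so the statistics match the
    # inference geometry rather than the training-crop geometry
    bn_idx <- ord[seq_len(min(n_train, 8L))]
    bn_batches <- lapply(bn_idx, function(i) {
      img <- pad_to_divisible(load_sample(train_manifest, i)$image,
                              model$encoder_cfg$levels)$image
      array(img, c(dim(img), 1L))
    })
    model <- reestimate_bn_stats(model, bn_batches)
    val_dice <- validation_dice(model, val_manifest)
    history[[epoch]] <- list(epoch = epoch, val_dice = val_dice)
    improved <- val_dice > best_val
    if (improved) {
      best_val <- val_dice
      since_improve <- 0L
      save_checkpoint(model, ckpt_path, extra = list(
        val_dice = val_dice, epoch = epoch,
        loss_cfg = loss_cfg, train_cfg = train_cfg))
    } else {
      since_improve <- since_improve + 1L
    }
    if (since_improve >= train_cfg$early_stop_patience) break
  }
  list(checkpoint = ckpt_path, log = log_path, history = history,
       model = model, best_val_dice = best_val)
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint carries every parameter, the batch-norm running
#' statistics, all configuration blocks and the initialization seed, so
#' reloading reproduces forward passes exactly.
#'
#' @param model a `cunet_model`
#' @param path file path
#' @param extra named list stored alongside the model
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  bn_values <- lapply(model$bn, function(s)
    list(running_mean = s$running_mean, running_var = s$running_var))
  saveRDS(list(params = model$params, bn = bn_values,
               encoder_cfg = model$encoder_cfg, csfi_cfg = model$csfi_cfg,
               wcu_cfg = model$wcu_cfg, seed = model$seed,
               bn_momentum = model$bn_momentum %||% 0.99,
               extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- structure(list(params = ck$params, bn = list(),
                          encoder_cfg = ck$encoder_cfg,
                          csfi_cfg = ck$csfi_cfg, wcu_cfg = ck$wcu_cfg,
                          seed = ck$seed, bn_momentum = ck$bn_momentum),
                     class = "cunet_model")
  model$bn <- lapply(ck$bn, function(s) {
    e <- new.env(parent = emptyenv())
    e$running_mean <- s$running_mean
    e$running_var <- s$running_var
    e
  })
  attr(model, "extra") <- ck$extra
  model
}

#' Predict segmentation masks for a directory of images
#'
#' Runs the eval-mode forward pass on every PNG under `image_dir`, padding
#' each image (white fill, offsets recorded in the metadata JSON) so its
#' sides divide by the encoder's pooling factor — never silently cropping —
#' then writes thresholded masks (and optional probability TIFFs) with the
#' input's original size.
#'
#' @param checkpoint path to a checkpoint or a `cunet_model`
#' @param image_dir directory of input PNG images
#' @param out_dir output directory
#' @param threshold binarization threshold
#' @param write_prob also write the probability map as TIFF
#' @return data.frame of written files, invisibly
#' @export
predict_cunet <- function(checkpoint, image_dir, out_dir, threshold = 0.5,
                          write_prob = FALSE) {
  model <- if (inherits(checkpoint, "cunet_model")) checkpoint else
    load_checkpoint(checkpoint)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- sort(list.files(image_dir, pattern = "^image_.*\\.png$|^.*\\.png$"))
  files <- files[!grepl("^(mask|boundary)_", files)]
  if (length(files) == 0) stop("no PNG images under ", image_dir)
  rows <- vector("list", length(files))
  for (i in seq_along(files)) {
    img <- read_image_rgb(file.path(image_dir, files[i]))
    pad <- pad_to_divisible(img, model$encoder_cfg$levels)
    out <- cunet_forward(model, pad$image, training = FALSE)
    seg <- out$seg_prob[seq_len(pad$size[1]), seq_len(pad$size[2]), 1]
    mask_name <- sub("^image_", "mask_", files[i])
    write_mask_png(binarize(seg, threshold), file.path(out_dir, mask_name))
    meta <- list(source = files[i], mask = mask_name,
                 pad_offset = pad$offset, original_size = pad$size,
                 threshold = threshold)
    if (write_prob) {
      prob_name <- sub("\\.png$", ".tiff", sub("^image_", "prob_", files[i]))
      tiff::writeTIFF(seg, file.path(out_dir, prob_name),
                      bits.per.sample = 16L, compression = "none")
      meta$prob <- prob_name
    }
    jsonlite::write_json(meta, file.path(
      out_dir, sub("\\.png$", ".json", mask_name)), auto_unbox = TRUE)
    rows[[i]] <- data.frame(source = files[i], mask = mask_name)
  }
  invisible(do.call(rbind, rows))
}
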