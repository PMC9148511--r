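# End-to-end orchestration: the published training recipe (SGDM, batch 16,
# lr 0.01, momentum 0.9, L2 5e-3, weighted cross-entropy), prediction,
# evaluation and checkpointing.

#' Training configuration
#'
#' Defaults follow the published recipe: input 192x256x3, batch size 16,
#' learning rate 0.01, momentum 0.9, L2 regularization 0.005, weighted
#' cross-entropy loss, SGDM optimizer. The epoch count (not published) and
#' seed are exposed; class weights default to inverse pixel frequency over
#' the training masks, normalized to mean 1.
#'
#' @param input_size integer `(height, width)` working resolution.
#' @param batch_size mini-batch size.
#' @param learning_rate SGDM step size alpha.
#' @param momentum SGDM momentum coefficient.
#' @param l2 L2 regularization coefficient (applied to convolution weights).
#' @param epochs number of training epochs.
#' @param seed integer seed driving shuffling and any internal draws.
#' @param class_weight_mode `"inverse_frequency"` or `"uniform"`.
#' @param validation_split fraction held out for validation when no
#'   validation set is supplied (the 7:3 convention).
#' @return object of class `train_config`.
#' @export
train_config <- function(input_size = c(192L, 256L), batch_size = 16L,
                         learning_rate = 0.01, momentum = 0.9, l2 = 0.005,
                         epochs = 30L, seed = 1L,
                         class_weight_mode = c("inverse_frequency", "uniform"),
                         validation_split = 0.3) {
  class_weight_mode <- match.arg(class_weight_mode)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (learning_rate < 0) stop("learning_rate must be nonnegative")
  structure(list(input_size = as.integer(input_size),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 l2 = l2, epochs = as.integer(epochs),
                 seed = as.integer(seed),
                 class_weight_mode = class_weight_mode,
                 validation_split = validation_split,
                 loss = "weighted cross entropy", optimizer = "SGDM"),
            class = "train_config")
}

#' @export
print.train_config <- function(x, ...) {
  cat("Training configuration\n")
  cat("  Input image size :", paste(c(x$input_size, 3L), collapse = "x"), "\n")
  cat("  Batch size       :", x$batch_size, "\n")
  cat("  Learning rate    :", x$learning_rate, "\n")
  cat("  L2 regularization:", x$l2, "\n")
  cat("  Momentum         :", x$momentum, "\n")
  cat("  Loss function    :", x$loss, "\n")
  cat("  Optimiser        :", x$optimizer, "\n")
  cat("  Epochs           :", x$epochs, "  Seed:", x$seed, "\n")
  invisible(x)
}

# inverse pixel-frequency class weights over the training masks,
# normalized to mean 1 (index 1 = background, 2 = lesion)
inverse_frequency_weights <- function(masks) {
  f_lesion <- mean(vapply(masks, mean, 0))
  f <- pmax(c(1 - f_lesion, f_lesion), 1e-6)
  w <- 1 / f
  w / mean(w)
}

prepare_set <- function(samples, input_size) {
  lapply(samples, function(s) {
    d <- dim(s$mask)
    if (!identical(as.integer(d), as.integer(input_size)))
      s <- resize_sample(s, input_size)
    s
  })
}

# one-hot target matrix ((H*W*N) x 2) from a list of masks
target_matrix <- function(masks) {
  m <- unlist(lapply(masks, as.numeric), use.names = FALSE)
  cbind(1 - m, m)
}

# batched mask prediction for a list of equally sized images
# (inference-mode forward in chunks; argmax with ties to background)
predict_masks_batched <- function(net, images, batch_size = 16L) {
  d <- dim(images[[1]])
  H <- d[1]; W <- d[2]
  out <- vector("list", length(images))
  for (s0 in seq(1L, length(images), by = batch_size)) {
    ids <- s0:min(s0 + batch_size - 1L, length(images))
    X <- stack_images(images[ids])
    fw <- nn_forward(net, X, H, W, length(ids), training = FALSE)
    P <- softmax_rows(fw$logits)
    lesion <- P[, 2] > P[, 1]
    for (j in seq_along(ids)) {
      rows <- (j - 1L) * H * W + seq_len(H * W)
      out[[ids[j]]] <- matrix(lesion[rows] * 1L, H, W)
    }
  }
  out
}

#' Train the network
#'
#' Minimizes the weighted cross-entropy loss over mini-batches with SGD plus
#' classical momentum and L2 regularization on the convolution weights.
#' Mini-batch statistics are used in batch normalization during training and
#' accumulated into running statistics (momentum 0.9) for inference. The
#' per-iteration training loss and per-epoch validation Jaccard index are
#' recorded, and the checkpoint with the best validation Jaccard is
#' returned.
#'
#' @param net a `dilated_net` from [build_network()].
#' @param train_set list of `image_sample` objects (resized to the working
#'   resolution if needed).
#' @param val_set optional validation list; when `NULL`, `train_set` is
#'   split 7:3 (seeded).
#' @param config a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-validation network), `history`
#'   (per-iteration `loss`, per-epoch `val_jac`, `best_epoch`) and
#'   `class_weights`.
#' @export
train <- function(net, train_set, val_set = NULL, config = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(net, "dilated_net"), inherits(config, "train_config"))
  if (length(train_set) == 0L) stop("training set is empty")
  set.seed(config$seed)
  if (is.null(val_set)) {
    n <- length(train_set)
    n_val <- max(1L, floor(config$validation_split * n))
    if (n - n_val < 1L) stop("training set too small to split")
    idx <- sample.int(n)
    val_set <- train_set[idx[seq_len(n_val)]]
    train_set <- train_set[idx[-seq_len(n_val)]]
  }
  hw <- config$input_size
  train_set <- prepare_set(train_set, hw)
  val_set <- prepare_set(val_set, hw)
  H <- hw[1]; W <- hw[2]

  w_class <- switch(config$class_weight_mode,
                    inverse_frequency =
                      inverse_frequency_weights(lapply(train_set, `[[`, "mask")),
                    uniform = c(1, 1))

  velocity <- lapply(net$layers, function(ly) {
    v <- list(W = ly$W * 0, b = ly$b * 0)
    if (ly$bn) { v$gamma <- ly$gamma * 0; v$beta <- ly$beta * 0 }
    v
  })
  lr <- config$learning_rate; mom <- config$momentum; l2 <- config$l2

  n_train <- length(train_set)
  loss_hist <- numeric(0)
  val_jac <- numeric(config$epochs)
  best <- list(jac = -Inf, layers = net$layers, epoch = 0L)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n_train)
    starts <- seq(1L, n_train, by = config$batch_size)
    for (s0 in starts) {
      ids <- ord[s0:min(s0 + config$batch_size - 1L, n_train)]
      N <- length(ids)
      X <- stack_images(lapply(train_set[ids], `[[`, "image"))
      Tm <- target_matrix(lapply(train_set[ids], `[[`, "mask"))
      fw <- nn_forward(net, X, H, W, N, training = TRUE, keep_cache = TRUE)
      net$layers <- fw$layers               # running BN statistics
      # fused softmax + weighted CE + gradient wrt logits
      sg <- softmax_wce_grad(fw$logits, as.integer(Tm[, 2]), w_class,
                             PROB_CLAMP)
      loss <- sg$loss
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; consider lowering the learning rate")
      loss_hist <- c(loss_hist, loss)
      bw <- nn_backward(net, fw$cache, sg$grad, H, W, N)
      for (i in seq_along(net$layers)) {
        g <- bw$grads[[i]]
        v <- velocity[[i]]
        v$W <- mom * v$W - lr * (g$dW + l2 * net$layers[[i]]$W)
        net$layers[[i]]$W <- net$layers[[i]]$W + v$W
        v$b <- mom * v$b - lr * g$db
        net$layers[[i]]$b <- net$layers[[i]]$b + v$b
        if (net$layers[[i]]$bn) {
          v$gamma <- mom * v$gamma - lr * g$dgamma
          net$layers[[i]]$gamma <- net$layers[[i]]$gamma + v$gamma
          v$beta <- mom * v$beta - lr * g$dbeta
          net$layers[[i]]$beta <- net$layers[[i]]$beta + v$beta
        }
        velocity[[i]] <- v
      }
    }
    # held-out Jaccard with the current running statistics
    preds <- predict_masks_batched(net, lapply(val_set, `[[`, "image"),
                                   config$batch_size)
    if (any(vapply(preds, anyNA, TRUE)))
      stop("training diverged (non-finite predictions) at epoch ", epoch,
           "; consider lowering the learning rate")
    jacs <- vapply(seq_along(val_set), function(j) {
      seg_score(confusion_from_masks(preds[[j]], val_set[[j]]$mask))[["JAC"]]
    }, 0)
    val_jac[epoch] <- mean(jacs)
    if (val_jac[epoch] >= best$jac) {
      best <- list(jac = val_jac[epoch], layers = net$layers, epoch = epoch)
    }
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  val JAC %.4f", epoch,
                      config$epochs, mean(utils::tail(loss_hist, length(starts))),
                      val_jac[epoch]))
  }
  net$layers <- best$layers
  list(model = net,
       history = list(loss = loss_hist, val_jac = val_jac,
                      best_epoch = best$epoch, best_val_jac = best$jac,
                      iterations_per_epoch = length(seq(1L, n_train,
                                                        by = config$batch_size))),
       class_weights = w_class, config = config)
}

#' Predict a binary lesion mask
#'
#' Runs the network on one image (nearest-neighbor-resized to the model's
#' working resolution if needed) and takes the per-pixel argmax over the two
#' softmax channels. Ties at probability 0.5/0.5 resolve to background.
#' `model` may also be a plain function `image -> mask`, which allows
#' oracle predictors in evaluation.
#'
#' @param model a `dilated_net` (or a function of the image).
#' @param image `H x W x 3` array or an `image_sample`.
#' @return integer matrix mask (1 = lesion) at the working resolution.
#' @export
predict_mask <- function(model, image) {
  if (inherits(image, "image_sample")) image <- image$image
  if (is.function(model)) return(model(image))
  stopifnot(inherits(model, "dilated_net"))
  d <- dim(image)
  if (!identical(as.integer(d[1:2]), model$input_size))
    image <- resize_nearest(image, model$input_size)
  p <- forward_probs(model, image)[[1]]
  (p[, , 2] > p[, , 1]) * 1L
}

#' Evaluate a model on a test set
#'
#' Predicts a mask per image, tallies the pixel confusion matrix against the
#' ground truth, scores ACC/JAC/DICE per image and averages over images.
#' Items without a ground-truth mask are skipped with a message.
#'
#' @param model a `dilated_net` or a predictor function.
#' @param test_set non-empty list of `image_sample` objects with masks.
#' @param batch_size forward-pass batch size for network models.
#' @return object of class `eval_report`: list with `per_image` (data frame
#'   id/ACC/JAC/DICE), `mean`, `n`, `n_skipped`, `seconds_per_image`.
#' @export
evaluate <- function(model, test_set, batch_size = 16L) {
  if (length(test_set) == 0L) stop("test set is empty")
  rows <- list()
  skipped <- 0L
  t0 <- proc.time()[["elapsed"]]
  has_mask <- !vapply(test_set, function(s) is.null(s$mask), TRUE)
  preds <- NULL
  if (inherits(model, "dilated_net") && any(has_mask)) {
    usable <- prepare_set(test_set[has_mask], model$input_size)
    preds <- predict_masks_batched(model, lapply(usable, `[[`, "image"),
                                   batch_size)
    preds_idx <- cumsum(has_mask)
  }
  for (i in seq_along(test_set)) {
    s <- test_set[[i]]
    if (is.null(s$mask)) {
      message("evaluate: skipping item ", s$meta$id %||% i, " (no mask)")
      skipped <- skipped + 1L
      next
    }
    pred <- if (is.null(preds)) predict_mask(model, s$image) else
      preds[[preds_idx[i]]]
    truth <- s$mask
    if (!identical(dim(pred), dim(truth)))
      truth <- resize_nearest(truth, dim(pred))
    sc <- seg_score(confusion_from_masks(pred, truth))
    rows[[length(rows) + 1L]] <-
      data.frame(id = s$meta$id %||% sprintf("img_%04d", i),
                 ACC = sc[["ACC"]], JAC = sc[["JAC"]], DICE = sc[["DICE"]],
                 stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no evaluable items (all lacked masks)")
  elapsed <- proc.time()[["elapsed"]] - t0
  per_image <- do.call(rbind, rows)
  agg <- aggregate_scores(per_image[, c("ACC", "JAC", "DICE")])
  structure(list(per_image = per_image, mean = agg$mean, n = agg$n,
                 n_skipped = skipped,
                 seconds_per_image = elapsed / agg$n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d images: ACC %.4f  JAC %.4f  DICE %.4f\n",
              x$n, x$mean[["ACC"]], x$mean[["JAC"]], x$mean[["DICE"]]))
  if (x$n_skipped > 0L) cat("  (", x$n_skipped, "items skipped )\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are RDS files embedding the architecture specification, the
#' working resolution and all parameters (including batch-norm running
#' statistics), so a reloaded model reproduces evaluation reports exactly.
#'
#' @param model a `dilated_net`.
#' @param path file path.
#' @param extra optional list stored alongside (e.g. training history).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `dilated_net` (with any `extra` attached as attribute
#'   `extra`).
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  stopifnot(inherits(model, "dilated_net"))
  saveRDS(list(format = "dilatedskinnet-checkpoint-1",
               spec = model$spec, input_size = model$input_size,
               layers = model$layers, slope = model$slope, eps = model$eps,
               seed = model$seed, extra = extra), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "dilatedskinnet-checkpoint-1"))
    stop("not a recognised checkpoint file: ", path)
  net <- structure(list(spec = ck$spec, input_size = ck$input_size,
                        layers = ck$layers, slope = ck$slope, eps = ck$eps,
                        seed = ck$seed),
                   class = "dilated_net")
  attr(net, "extra") <- ck$extra
  net
}
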