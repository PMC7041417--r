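#' Training configuration
#'
#' Defaults reproduce the optimization schedule used for the full-scale
#' network: initial learning rate 0.001 held for 60 epochs then stepped down
#' by a factor of 10, 100 epochs total, batch size 8, SGD with momentum 0.9,
#' and a smoothed multi-class soft Dice loss.
#'
#' @param learning_rate initial learning rate.
#' @param decay_epoch last epoch trained at the initial rate.
#' @param decay_factor multiplicative step applied after `decay_epoch`.
#' @param epochs total training epochs.
#' @param batch_size patches per mini-batch.
#' @param momentum SGD momentum coefficient.
#' @param loss_smooth smoothing constant of the soft Dice loss.
#' @param seed root RNG seed for shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, decay_epoch = 60L,
                         decay_factor = 0.1, epochs = 100L, batch_size = 8L,
                         momentum = 0.9, loss_smooth = 1e-5, seed = 1L) {
  stopifnot(learning_rate > 0, decay_factor > 0, decay_factor < 1,
            decay_epoch < epochs, epochs >= 1L, batch_size >= 1L,
            momentum >= 0, momentum < 1, loss_smooth > 0)
  structure(list(learning_rate = learning_rate,
                 decay_epoch = as.integer(decay_epoch),
                 decay_factor = decay_factor, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 loss_smooth = loss_smooth, seed = as.integer(seed)),
            class = "train_config")
}

#' Stepped learning-rate schedule
#'
#' The learning rate stays at its initial value through `decay_epoch`
#' (default: 0.001 through epoch 60) and is multiplied by `decay_factor`
#' (default 0.1, giving 0.0001) for all later epochs.
#'
#' @param epoch 1-based epoch index in `1..epochs`.
#' @param config a [train_config()].
#' @return The learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config) {
  if (epoch < 1L || epoch > config$epochs)
    stop("epoch out of range 1..", config$epochs)
  if (epoch <= config$decay_epoch) config$learning_rate
  else config$learning_rate * config$decay_factor
}

one_hot_classes <- function(labels, n_classes = 4L) {
  cls <- labels_to_classes(as.integer(labels))
  d <- dim(labels)
  out <- array(0, c(d, n_classes))
  n <- prod(d)
  out[seq_len(n) + n * cls] <- 1
  out
}

#' Multi-class soft Dice loss
#'
#' `1 - mean_c (2 sum(p_c t_c) + eps) / (sum(p_c) + sum(t_c) + eps)` over the
#' four classes, for probability maps `p` and one-hot truth `t`. Lies in
#' `[0, 1]`; 0 at a perfect prediction, approaching 1 at a total miss.
#'
#' @param probs `(s, s, s, 4)` class-probability array.
#' @param truth `(s, s, s, 4)` one-hot array (or an `(s, s, s)` integer label
#'   array in the file convention, converted internally).
#' @param smooth smoothing constant `eps`.
#' @return Scalar loss.
#' @export
dice_loss <- function(probs, truth, smooth = 1e-5) {
  if (length(dim(truth)) == 3L) truth <- one_hot_classes(truth)
  if (!identical(dim(probs), dim(truth)))
    stop("probs/truth shape mismatch")
  nc <- dim(probs)[4]
  pm <- matrix(probs, ncol = nc)
  tm <- matrix(truth, ncol = nc)
  num <- 2 * colSums(pm * tm) + smooth
  den <- colSums(pm) + colSums(tm) + smooth
  1 - mean(num / den)
}

# Gradient of dice_loss with respect to the probabilities.
dice_loss_grad <- function(probs, truth, smooth = 1e-5) {
  nc <- dim(probs)[4]
  pm <- matrix(probs, ncol = nc)
  tm <- matrix(truth, ncol = nc)
  num <- 2 * colSums(pm * tm) + smooth
  den <- colSums(pm) + colSums(tm) + smooth
  # d/dp_c of -(1/nc) * num_c/den_c
  g <- -(1 / nc) * (2 * sweep(tm, 2L, den, `*`) -
                      matrix(num, nrow(tm), nc, byrow = TRUE)) /
    matrix(den^2, nrow(tm), nc, byrow = TRUE)
  array(g, dim(probs))
}

# Chain the Dice gradient through the softmax: dL/dz_i = p_i (g_i - sum_j g_j p_j).
softmax_backprop <- function(probs, dprobs) {
  nc <- dim(probs)[4]
  pm <- matrix(probs, ncol = nc)
  gm <- matrix(dprobs, ncol = nc)
  dot <- rowSums(gm * pm)
  array(pm * (gm - dot), dim(probs))
}

#' Train a 3D U-Net on a patch set
#'
#' Mini-batch SGD with momentum under the soft Dice loss. Patches are
#' reshuffled every epoch; shuffling, dropout and initialization all flow
#' from `config$seed`, so runs are bit-reproducible on CPU. The velocity
#' update is `v <- momentum * v - lr * grad; w <- w + v`, a temporally
#' averaged gradient that damps the optimization velocity.
#'
#' @param patches a `patch_set` with label patches
#'   (see [build_training_patches()]).
#' @param config a [unet_config()] describing the architecture, or an
#'   already-built `unet3d` model to continue training.
#' @param train a [train_config()].
#' @param verbose print per-epoch loss.
#' @return An object of class `unet3d_fit`: the trained model plus a history
#'   data frame (`epoch`, `lr`, `loss`). Supports `print()`, `summary()`,
#'   `plot()`, `coef()` and `predict()`.
#' @export
unet_train <- function(patches, config = unet_config(), train = train_config(),
                       verbose = FALSE) {
  stopifnot(inherits(patches, "patch_set"))
  n <- length(patches)
  if (n == 0L) stop("empty patch set")
  if (is.null(patches$labels)) stop("patch set carries no labels")
  model <- if (inherits(config, "unet3d")) config
           else build_unet(config, init_seed = train$seed)
  truth <- lapply(patches$labels, one_hot_classes)
  velocity <- lapply(model$params, function(pp)
    list(w = array(0, dim(pp$w)), b = numeric(length(pp$b))))
  history <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0))

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(train$seed)

  for (epoch in seq_len(train$epochs)) {
    lr <- lr_schedule(epoch, train)
    order <- sample.int(n)
    batch_losses <- numeric(0)
    b0 <- 1L
    while (b0 <= n) {
      idx <- order[b0:min(b0 + train$batch_size - 1L, n)]
      b0 <- b0 + train$batch_size
      grad_sum <- NULL
      loss_sum <- 0
      for (i in idx) {
        fwd <- unet_forward(model, patches$images[[i]], training = TRUE,
                            keep_cache = TRUE)
        probs <- softmax4(fwd$logits)
        loss_sum <- loss_sum + dice_loss(probs, truth[[i]], train$loss_smooth)
        dprobs <- dice_loss_grad(probs, truth[[i]], train$loss_smooth)
        dlogits <- softmax_backprop(probs, dprobs)
        g <- unet_backward(model, fwd$cache, dlogits)
        if (is.null(grad_sum)) grad_sum <- g
        else for (nm in names(g)) {
          grad_sum[[nm]]$w <- grad_sum[[nm]]$w + g[[nm]]$w
          grad_sum[[nm]]$b <- grad_sum[[nm]]$b + g[[nm]]$b
        }
      }
      nb <- length(idx)
      for (nm in names(model$params)) {
        velocity[[nm]]$w <- train$momentum * velocity[[nm]]$w -
          lr * grad_sum[[nm]]$w / nb
        velocity[[nm]]$b <- train$momentum * velocity[[nm]]$b -
          lr * grad_sum[[nm]]$b / nb
        model$params[[nm]]$w <- model$params[[nm]]$w + velocity[[nm]]$w
        model$params[[nm]]$b <- model$params[[nm]]$b + velocity[[nm]]$b
      }
      batch_losses <- c(batch_losses, loss_sum / nb)
    }
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         loss = mean(batch_losses)))
    if (verbose)
      message(sprintf("epoch %3d | lr %.5f | dice loss %.4f",
                      epoch, lr, mean(batch_losses)))
  }
  structure(list(model = model, history = history, train_config = train,
                 n_patches = n,
                 patch_origins = table(patches$specs$origin)),
            class = "unet3d_fit")
}

#' @export
print.unet3d_fit <- function(x, ...) {
  cat("Fitted 3D U-Net segmentation model\n")
  print(x$model)
  cat(sprintf("  trained on %d patches for %d epochs; final Dice loss %.4f\n",
              x$n_patches, nrow(x$history), tail(x$history$loss, 1)))
  invisible(x)
}

#' @export
summary.unet3d_fit <- function(object, ...) {
  h <- object$history
  cat("Training summary\n")
  cat(sprintf("  patches: %d (%s)\n", object$n_patches,
              paste(sprintf("%s %d", names(object$patch_origins),
                            object$patch_origins), collapse = ", ")))
  cat(sprintf("  epochs: %d | batch size %d | momentum %.2f\n",
              nrow(h), object$train_config$batch_size,
              object$train_config$momentum))
  cat(sprintf("  Dice loss: first %.4f -> best %.4f (epoch %d) -> final %.4f\n",
              h$loss[1], min(h$loss), which.min(h$loss),
              tail(h$loss, 1)))
  invisible(object$history)
}

#' @export
plot.unet3d_fit <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "mean Dice loss",
       main = "Training loss", ...)
  invisible(x)
}

#' @export
coef.unet3d_fit <- function(object, ...) object$model$params

#' Predict from a fitted U-Net
#'
#' `newdata` may be a normalized [mc_volume()] (tiled full-volume inference)
#' or a single `(s, s, s, 4)` patch array.
#'
#' @param object a `unet3d_fit`.
#' @param newdata volume or patch to segment.
#' @param ... unused.
#' @return A [label_volume()] for volumes; a list `(probs, labels)` for
#'   patches.
#' @export
predict.unet3d_fit <- function(object, newdata, ...) {
  if (inherits(newdata, "mc_volume")) predict_volume(object$model, newdata)
  else predict_patch(object$model, newdata)
}

#' Write a training history as CSV
#'
#' @param fit a `unet3d_fit`.
#' @param path output CSV path (columns epoch, lr, loss).
#' @return Invisibly, `path`.
#' @export
write_history <- function(fit, path) {
  write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
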