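#' 3D U-Net architecture configuration
#'
#' Defaults match the segmentation network used throughout this package:
#' three resolution levels with 48/96/192 feature maps, two zero-padded 3^3
#' convolutions (each followed by ReLU) per block, 2^3 max-pool downsampling,
#' nearest-neighbour upsampling followed by a 3^3 convolution, encoder-to-
#' decoder skip concatenation, and a final 1^3 convolution to 4 class maps
#' fused by per-voxel softmax. Dropout (rate 0.25) is applied after each
#' encoder block during training only.
#'
#' @param levels number of resolution levels.
#' @param features feature maps per level (strictly increasing,
#'   `length(features) == levels`).
#' @param convs_per_block convolutions per encoder/decoder block.
#' @param kernel convolution kernel edge (odd).
#' @param in_channels input channels (4 MR sequences).
#' @param out_classes output classes (4: background, necrosis, edema,
#'   enhancing).
#' @param dropout dropout rate after encoder blocks (training only).
#' @param patch_size expected input patch edge; must be divisible by
#'   `2^(levels - 1)`.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(levels = 3L, features = c(48L, 96L, 192L),
                        convs_per_block = 2L, kernel = 3L, in_channels = 4L,
                        out_classes = 4L, dropout = 0.25, patch_size = 64L) {
  stopifnot(levels >= 1L, convs_per_block >= 1L, dropout >= 0, dropout < 1)
  if (kernel != 3L)
    stop("only 3^3 convolution kernels are supported")
  if (length(features) != levels)
    stop("features must list one width per level")
  if (levels > 1L && any(diff(features) <= 0))
    stop("features must be strictly increasing across levels")
  if (out_classes != 4L)
    stop("out_classes must be 4 (background, necrosis, edema, enhancing)")
  div <- 2L^(levels - 1L)
  if (patch_size %% div != 0L)
    stop("patch_size must be divisible by 2^(levels-1) = ", div)
  structure(list(levels = as.integer(levels), features = as.integer(features),
                 convs_per_block = as.integer(convs_per_block),
                 kernel = as.integer(kernel),
                 in_channels = as.integer(in_channels),
                 out_classes = as.integer(out_classes),
                 dropout = dropout, patch_size = as.integer(patch_size)),
            class = "unet_config")
}

# Ordered description of every convolution layer implied by a config.
conv_plan <- function(config) {
  L <- config$levels; f <- config$features; nb <- config$convs_per_block
  k <- config$kernel
  plan <- list()
  cin <- config$in_channels
  for (l in seq_len(L)) {
    for (j in seq_len(nb)) {
      plan[[sprintf("enc%d_%d", l, j)]] <-
        list(cin = if (j == 1L) cin else f[l], cout = f[l], k = k)
    }
    cin <- f[l]
  }
  if (L > 1L) for (l in (L - 1L):1L) {
    plan[[sprintf("up%d", l)]] <- list(cin = f[l + 1L], cout = f[l], k = k)
    for (j in seq_len(nb)) {
      plan[[sprintf("dec%d_%d", l, j)]] <-
        list(cin = if (j == 1L) 2L * f[l] else f[l], cout = f[l], k = k)
    }
  }
  plan[["out"]] <- list(cin = f[1L], cout = config$out_classes, k = 1L)
  plan
}

#' Build a 3D U-Net
#'
#' Instantiates the network of [unet_config()] with He-initialized weights
#' (seeded, so builds are reproducible). The parameter count is a pure
#' function of the configuration.
#'
#' @param config a [unet_config()].
#' @param init_seed RNG seed for weight initialization.
#' @return An object of class `unet3d` (config + named parameter list).
#' @export
build_unet <- function(config, init_seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  plan <- conv_plan(config)
  params <- with_seed(init_seed, lapply(plan, function(p) {
    nw <- p$k^3 * p$cin * p$cout
    list(w = array(rnorm(nw, 0, sqrt(2 / (p$k^3 * p$cin))),
                   c(p$k, p$k, p$k, p$cin, p$cout)),
         b = numeric(p$cout))
  }))
  structure(list(config = config, params = params), class = "unet3d")
}

#' Number of trainable parameters
#'
#' @param model a `unet3d` model.
#' @return Integer parameter count (weights + biases).
#' @export
n_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$w) + length(p$b), numeric(1)))
}

#' @export
print.unet3d <- function(x, ...) {
  cfg <- x$config
  cat("3D U-Net\n")
  cat(sprintf("  levels %d | features %s | %d conv/block (k=%d) | dropout %.2f\n",
              cfg$levels, paste(cfg$features, collapse = "/"),
              cfg$convs_per_block, cfg$kernel, cfg$dropout))
  cat(sprintf("  input %d^3 x %d -> output %d^3 x %d class maps\n",
              cfg$patch_size, cfg$in_channels, cfg$patch_size, cfg$out_classes))
  cat(sprintf("  parameters: %s\n", format(n_params(x), big.mark = ",")))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

concat_channels <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1:3], d[4] + dim(b)[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}

# Forward pass over halo-padded activations (one-voxel zero halo, which the
# compiled kernels exploit to run convolutions as offset GEMMs). Takes and
# returns ordinary unpadded arrays. With keep_cache = TRUE, stores everything
# the backward pass needs (conv inputs, ReLU activations, pool argmax,
# dropout masks). Dropout draws from the current RNG stream when training.
unet_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  L <- cfg$levels; nb <- cfg$convs_per_block
  p <- model$params
  cache <- if (keep_cache) list(conv_in = list(), act = list(),
                                pool_arg = list(), pool_dim = list(),
                                drop = list()) else NULL
  conv_step <- function(a, nm, act = TRUE) {
    if (keep_cache) cache$conv_in[[nm]] <<- a
    out <- if (dim(p[[nm]]$w)[1] == 1L) .conv1p_fwd(a, p[[nm]]$w, p[[nm]]$b)
           else .convp_fwd(a, p[[nm]]$w, p[[nm]]$b)
    if (act) out <- relu(out)
    if (keep_cache) cache$act[[nm]] <<- out
    out
  }
  a <- .pad_halo(x)
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    for (j in seq_len(nb)) a <- conv_step(a, sprintf("enc%d_%d", l, j))
    if (training && cfg$dropout > 0) {
      mask <- array((runif(length(a)) >= cfg$dropout) / (1 - cfg$dropout),
                    dim(a))
      a <- a * mask
      if (keep_cache) cache$drop[[sprintf("enc%d", l)]] <- mask
    }
    if (l < L) {
      skips[[l]] <- a
      pooled <- .poolp_fwd(a)
      if (keep_cache) {
        cache$pool_arg[[l]] <- pooled$argmax
        cache$pool_dim[[l]] <- dim(a)
      }
      a <- pooled$y
    }
  }
  if (L > 1L) for (l in (L - 1L):1L) {
    a <- .upsamplep_fwd(a)
    a <- conv_step(a, sprintf("up%d", l))
    a <- concat_channels(a, skips[[l]])
    for (j in seq_len(nb)) a <- conv_step(a, sprintf("dec%d_%d", l, j))
  }
  logits <- conv_step(a, "out", act = FALSE)
  list(logits = .unpad_halo(logits), cache = cache)
}

# Per-voxel softmax over the last (class) dimension of a 4-D array.
softmax4 <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, ncol = d[4])
  mx <- Reduce(pmax, lapply(seq_len(d[4]), function(j) m[, j]))
  e <- exp(m - mx)
  array(e / rowSums(e), d)
}

# Backward pass mirroring unet_forward. dlogits is unpadded; returns
# gradients named like params.
unet_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  L <- cfg$levels; nb <- cfg$convs_per_block
  p <- model$params
  grads <- list()
  conv_back <- function(nm, da, act = TRUE) {
    if (act) da <- da * (cache$act[[nm]] > 0)
    g <- if (dim(p[[nm]]$w)[1] == 1L)
      .conv1p_bwd(cache$conv_in[[nm]], p[[nm]]$w, da)
    else .convp_bwd(cache$conv_in[[nm]], p[[nm]]$w, da)
    grads[[nm]] <<- list(w = g$dw, b = g$db)
    g$dx
  }
  da <- conv_back("out", .pad_halo(dlogits), act = FALSE)
  # the decoder ran l = (L-1)..1, so its reverse runs l = 1..(L-1)
  dskips <- vector("list", L)
  if (L > 1L) for (l in seq_len(L - 1L)) {
    for (j in rev(seq_len(nb))) da <- conv_back(sprintf("dec%d_%d", l, j), da)
    nf <- cfg$features[l]
    d_up <- da[, , , seq_len(nf), drop = FALSE]
    dskips[[l]] <- da[, , , nf + seq_len(nf), drop = FALSE]
    d_up <- conv_back(sprintf("up%d", l), d_up)
    da <- .upsamplep_bwd(d_up)
  }
  # after the decoder loop `da` is the gradient at the bottleneck output
  for (l in rev(seq_len(L))) {
    if (l < L)
      da <- .poolp_bwd(cache$pool_arg[[l]], da, cache$pool_dim[[l]]) +
        dskips[[l]]
    dmask <- cache$drop[[sprintf("enc%d", l)]]
    if (!is.null(dmask)) da <- da * dmask
    for (j in rev(seq_len(nb))) da <- conv_back(sprintf("enc%d_%d", l, j), da)
  }
  grads
}

#' Predict class probabilities and labels for one patch
#'
#' Runs the network (dropout inactive) and fuses the four per-voxel softmax
#' probability maps by argmax; ties break to the lowest class index. Class
#' indices map to file labels as 0/1/2/3 -> 0/1/2/4.
#'
#' @param model a `unet3d` model.
#' @param patch a `(s, s, s, 4)` array matching the model's `patch_size`.
#' @return List with `probs` (`(s, s, s, 4)` array summing to 1 per voxel)
#'   and `labels` (`(s, s, s)` integer array, file convention).
#' @export
predict_patch <- function(model, patch) {
  cfg <- model$config
  ps <- cfg$patch_size
  if (!identical(dim(patch), as.integer(c(ps, ps, ps, cfg$in_channels))))
    stop(sprintf("patch shape mismatch: expected (%d,%d,%d,%d), got (%s)",
                 ps, ps, ps, cfg$in_channels,
                 paste(dim(patch), collapse = ",")))
  logits <- unet_forward(model, patch, training = FALSE)$logits
  probs <- softmax4(logits)
  cls <- max.col(matrix(probs, ncol = cfg$out_classes),
                 ties.method = "first") - 1L
  labels <- array(classes_to_labels(cls), dim(patch)[1:3])
  list(probs = probs, labels = labels)
}

#' Predict a full label volume by non-overlapping tiling
#'
#' Tiles the (already normalized) volume into non-overlapping patches over
#' the zero-padded grid, predicts each tile, reassembles, and crops back to
#' the input shape. Deterministic for fixed weights.
#'
#' @param model a `unet3d` model.
#' @param volume a normalized [mc_volume()].
#' @return A [label_volume()] of the input shape.
#' @export
predict_volume <- function(model, volume) {
  stopifnot(inherits(volume, "mc_volume"))
  shape <- dim(volume$data)[1:3]
  ps <- model$config$patch_size
  tiles <- seed_grid(shape, ps, ps)
  tiles$origin <- "inference-tile"
  pset <- extract_patches(volume, tiles)
  preds <- lapply(pset$images, function(img) predict_patch(model, img)$labels)
  pset$labels <- preds
  out <- assemble_prediction(pset, shape)
  out$spacing <- volume$spacing
  out$reference <- volume$reference
  out
}

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file of the weights next to a JSON sidecar
#' recording the architecture configuration; the sidecar is validated on
#' reload.
#'
#' @param model a `unet3d` model.
#' @param path checkpoint path (`.rds`).
#' @return `save_checkpoint`: invisibly, `path`. `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, path)
  sidecar <- sub("\\.rds$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(unclass(model$config), sidecar, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  sidecar <- sub("\\.rds$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    cfg <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    stored <- unclass(model$config)
    for (nm in names(cfg)) {
      if (!isTRUE(all.equal(unname(unlist(stored[[nm]])),
                            unname(unlist(cfg[[nm]])))))
        stop("checkpoint sidecar disagrees with stored config on '", nm, "'")
    }
  }
  stopifnot(inherits(model, "unet3d"))
  model
}
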