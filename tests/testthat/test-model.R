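tiny_cfg <- function(drop = 0, ps = 16L)
  unet_config(levels = 2L, features = c(2L, 4L), convs_per_block = 2L,
              dropout = drop, patch_size = ps)

test_that("config validation enforces architecture invariants", {
  expect_error(unet_config(levels = 2, features = c(8, 8), patch_size = 16),
               "strictly increasing")
  expect_error(unet_config(levels = 3, features = c(8, 16), patch_size = 16),
               "one width per level")
  expect_error(unet_config(levels = 3, features = c(8, 16, 32),
                           patch_size = 30), "divisible")
  expect_error(unet_config(out_classes = 3), "out_classes")
})

test_that("the network preserves spatial shape and emits 4 probability maps", {
  model <- build_unet(tiny_cfg(), init_seed = 2)
  x <- array(rnorm(16^3 * 4), c(16, 16, 16, 4))
  out <- predict_patch(model, x)
  expect_identical(dim(out$probs), c(16L, 16L, 16L, 4L))
  expect_identical(dim(out$labels), c(16L, 16L, 16L))
  sums <- rowSums(matrix(out$probs, ncol = 4))
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(out$probs >= 0 & out$probs <= 1))
  expect_error(predict_patch(model, array(0, c(8, 8, 8, 4))),
               "shape mismatch")
})

test_that("parameter count is a pure function of the configuration", {
  m1 <- build_unet(tiny_cfg(), init_seed = 1)
  m2 <- build_unet(tiny_cfg(), init_seed = 99)
  expect_identical(n_params(m1), n_params(m2))
  m3 <- build_unet(tiny_cfg(), init_seed = 1)
  expect_identical(m1$params, m3$params)  # seeded init reproducibility
})

test_that("forward passes are bit-reproducible with dropout inactive", {
  model <- build_unet(tiny_cfg(drop = 0.25), init_seed = 3)
  x <- array(rnorm(16^3 * 4), c(16, 16, 16, 4))
  p1 <- predict_patch(model, x)
  p2 <- predict_patch(model, x)
  expect_identical(p1$probs, p2$probs)
  expect_identical(p1$labels, p2$labels)
})

test_that("argmax fusion breaks ties toward the lowest class index", {
  model <- build_unet(tiny_cfg(), init_seed = 1)
  for (nm in names(model$params)) {
    model$params[[nm]]$w[] <- 0
    model$params[[nm]]$b[] <- 0
  }
  x <- array(rnorm(16^3 * 4), c(16, 16, 16, 4))
  out <- predict_patch(model, x)
  expect_true(all(abs(out$probs - 0.25) < 1e-12))  # exact 4-way tie
  expect_true(all(out$labels == 0L))               # lowest class wins
})

test_that("the padded-GEMM convolution agrees with the im2col path", {
  set.seed(8)
  x <- array(rnorm(6 * 7 * 5 * 3), c(6, 7, 5, 3))
  w <- array(rnorm(27 * 3 * 2), c(3, 3, 3, 3, 2))
  b <- rnorm(2)
  ref <- gliomaseg:::.conv3d_fwd(x, w, b)$y
  padded <- gliomaseg:::.convp_fwd(gliomaseg:::.pad_halo(x), w, b)
  expect_equal(gliomaseg:::.unpad_halo(padded), ref, tolerance = 1e-12)
})

test_that("full-volume prediction tiles, assembles and crops correctly", {
  model <- build_unet(tiny_cfg(), init_seed = 4)
  ph <- small_phantom(seed = 6)
  mask <- derive_brain_mask(ph$volume)
  nv <- zscore_normalize(ph$volume, mask)
  pred <- predict_volume(model, nv)
  expect_identical(dim(pred), dim(nv))

  # constant-background model yields an all-zero label volume
  zero_model <- model
  for (nm in names(zero_model$params)) {
    zero_model$params[[nm]]$w[] <- 0
    zero_model$params[[nm]]$b[] <- 0
  }
  zero_model$params$out$b <- c(10, 0, 0, 0)  # background logit dominates
  p0 <- predict_volume(zero_model, nv)
  expect_true(all(p0$labels == 0L))

  p1 <- predict_volume(model, nv)
  expect_identical(pred$labels, p1$labels)  # determinism
})

test_that("checkpoints round trip with a validated config sidecar", {
  model <- build_unet(tiny_cfg(), init_seed = 5)
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_checkpoint(model, path)
  expect_true(file.exists(sub("rds$", "json", path)))
  back <- load_checkpoint(path)
  expect_identical(back$params, model$params)
  expect_identical(unclass(back$config), unclass(model$config))
})
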