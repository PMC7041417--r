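test_that("dice loss hits its limits at perfect and total-miss predictions", {
  lab <- array(sample(c(0L, 1L, 2L, 4L), 6^3, TRUE), c(6, 6, 6))
  truth <- gliomaseg:::one_hot_classes(lab)
  expect_lt(dice_loss(truth, lab), 1e-4)
  wrong <- truth[, , , c(2, 1, 4, 3)]  # every voxel assigned a wrong class
  expect_gt(dice_loss(wrong, lab), 0.99)
  expect_error(dice_loss(truth[, , 1:3, ], lab), "shape mismatch")
})

test_that("dice loss matches the brute-force summation oracle", {
  set.seed(21)
  for (i in 1:20) {
    logits <- array(rnorm(8^3 * 4), c(8, 8, 8, 4))
    probs <- gliomaseg:::softmax4(logits)
    lab <- array(sample(c(0L, 1L, 2L, 4L), 8^3, TRUE,
                        prob = c(0.7, 0.1, 0.1, 0.1)), c(8, 8, 8))
    truth <- gliomaseg:::one_hot_classes(lab)
    l1 <- dice_loss(probs, truth)
    l2 <- oracle_dice_loss(probs, truth)
    expect_lt(abs(l1 - l2), 1e-6)
    expect_gte(l1, 0)
    expect_lte(l1, 1)
  }
  # uniform probabilities on a single-class patch
  probs <- array(0.25, c(8, 8, 8, 4))
  lab0 <- array(0L, c(8, 8, 8))
  t0 <- gliomaseg:::one_hot_classes(lab0)
  expect_lt(abs(dice_loss(probs, t0) - oracle_dice_loss(probs, t0)), 1e-6)
})

test_that("the analytic loss gradient matches finite differences", {
  set.seed(5)
  logits <- array(rnorm(4^3 * 4), c(4, 4, 4, 4))
  lab <- array(sample(c(0L, 1L, 2L, 4L), 4^3, TRUE), c(4, 4, 4))
  truth <- gliomaseg:::one_hot_classes(lab)
  probs <- gliomaseg:::softmax4(logits)
  dlog <- gliomaseg:::softmax_backprop(
    probs, gliomaseg:::dice_loss_grad(probs, truth, 1e-5))
  eps <- 1e-6
  for (i in sample(length(logits), 8)) {
    lp <- logits; lp[i] <- lp[i] + eps
    lm <- logits; lm[i] <- lm[i] - eps
    num <- (dice_loss(gliomaseg:::softmax4(lp), truth) -
              dice_loss(gliomaseg:::softmax4(lm), truth)) / (2 * eps)
    expect_lt(abs(num - dlog[i]), 1e-5 * max(1, abs(num)))
  }
})

test_that("learning rate steps down by a factor of 10 after epoch 60", {
  cfg <- train_config()
  expect_identical(lr_schedule(1, cfg), 0.001)
  expect_identical(lr_schedule(60, cfg), 0.001)
  expect_equal(lr_schedule(61, cfg), 1e-4)
  expect_equal(lr_schedule(100, cfg), 1e-4)
  expect_error(lr_schedule(0, cfg), "out of range")
  expect_error(lr_schedule(101, cfg), "out of range")
})

test_that("training reduces the loss and is reproducible under a fixed seed", {
  ph <- small_phantom(seed = 7)
  mask <- derive_brain_mask(ph$volume)
  nv <- zscore_normalize(ph$volume, mask)
  patches <- build_training_patches(nv, ph$labels, mask, patch_size = 16L,
                                    stride = 8L, max_boundary = 16,
                                    seed = 3)
  ucfg <- unet_config(levels = 2L, features = c(4L, 8L), convs_per_block = 1L,
                      dropout = 0.1, patch_size = 16L)
  tcfg <- train_config(learning_rate = 0.02, decay_epoch = 2L, epochs = 3L,
                       batch_size = 8L, seed = 11)
  fit1 <- unet_train(patches, ucfg, tcfg)
  expect_identical(nrow(fit1$history), 3L)
  expect_lt(tail(fit1$history$loss, 1), fit1$history$loss[1])
  fit2 <- unet_train(patches, ucfg, tcfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)

  expect_error(unet_train(structure(list(specs = data.frame(), images = list(),
                                         labels = list(), seed = 1),
                                    class = "patch_set"), ucfg, tcfg),
               "empty patch set")
})

test_that("fit objects expose the standard modelling methods", {
  ph <- small_phantom(seed = 7)
  mask <- derive_brain_mask(ph$volume)
  nv <- zscore_normalize(ph$volume, mask)
  patches <- build_training_patches(nv, ph$labels, mask, patch_size = 16L,
                                    max_boundary = 8, seed = 3)
  fit <- unet_train(patches,
                    unet_config(levels = 2L, features = c(2L, 4L),
                                convs_per_block = 1L, dropout = 0,
                                patch_size = 16L),
                    train_config(learning_rate = 0.01, decay_epoch = 1L,
                                 epochs = 2L, seed = 1))
  expect_output(print(fit), "Fitted 3D U-Net")
  expect_output(summary(fit), "Dice loss")
  expect_named(coef(fit)[["out"]], c("w", "b"))
  pred <- predict(fit, nv)
  expect_s3_class(pred, "label_volume")
  expect_identical(dim(pred), dim(nv))
  tmp <- file.path(withr::local_tempdir(), "hist.csv")
  write_history(fit, tmp)
  expect_identical(nrow(utils::read.csv(tmp)), 2L)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
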