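test_that("seed grid lays the expected lattice over the padded volume", {
  g1 <- seed_grid(c(64, 64, 64), 64, 64)
  expect_identical(nrow(g1), 1L)
  expect_identical(unlist(g1[1, c("x", "y", "z")], use.names = FALSE),
                   c(1L, 1L, 1L))

  g2 <- seed_grid(c(240, 240, 155), 64, 64)
  expect_identical(nrow(g2), 48L)  # 4 x 4 x 3 tiles on the padded 256^2 x 192
  expect_identical(padded_shape(c(240, 240, 155), 64), c(256L, 256L, 192L))

  g3 <- seed_grid(c(128, 128, 128), 64, 32)
  expect_identical(nrow(g3), 27L)  # 3 overlapping seeds per axis
})

test_that("brain-fraction filter keeps patches strictly above the threshold", {
  mask <- array(FALSE, c(64, 64, 64))
  mask[1:32, , ] <- TRUE  # fraction exactly 0.5
  spec <- seed_grid(c(64, 64, 64), 64, 64)
  expect_identical(nrow(brain_fraction_filter(spec, mask, 0.6)), 0L)
  expect_identical(nrow(brain_fraction_filter(spec, mask, 0.4)), 1L)

  mask60 <- array(FALSE, c(10, 10, 10))
  mask60[, , 1:6] <- TRUE  # fraction exactly 0.60 -> rejected ("more than")
  s10 <- seed_grid(c(10, 10, 10), 10, 10)
  expect_identical(nrow(brain_fraction_filter(s10, mask60, 0.6)), 0L)

  full <- array(TRUE, c(64, 64, 64))
  expect_identical(nrow(brain_fraction_filter(spec, full, 0.6)), 1L)
})

test_that("brain-fraction filter is monotone in the threshold", {
  set.seed(71)
  mask <- random_mask(c(48, 48, 48), p = 0.5)
  specs <- seed_grid(c(48, 48, 48), 16, 16)
  counts <- vapply(seq(0, 0.9, by = 0.1), function(th)
    nrow(brain_fraction_filter(specs, mask, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("WT boundary is the thick 6-connected interface", {
  lab <- array(0L, c(9, 9, 9))
  lab[5, 5, 5] <- 2L
  b <- wt_boundary_voxels(lab)
  expect_identical(nrow(b), 7L)  # the voxel plus its 6 face neighbours
  expect_true(any(apply(b, 1, identical, c(x = 5L, y = 5L, z = 5L))))

  cube <- array(0L, c(9, 9, 9))
  cube[4:6, 4:6, 4:6] <- 4L
  b2 <- wt_boundary_voxels(cube)
  expect_identical(nrow(b2), 80L)  # 26-voxel shell + 54 exterior face voxels
  expect_false(any(b2[, 1] == 5 & b2[, 2] == 5 & b2[, 3] == 5))

  expect_warning(b0 <- wt_boundary_voxels(array(0L, c(5, 5, 5))), "no tumor")
  expect_identical(nrow(b0), 0L)
})

test_that("boundary sampling draws round(fraction * n) seeded patches", {
  set.seed(12)
  boundary <- cbind(x = sample(1:90, 100, TRUE), y = sample(1:90, 100, TRUE),
                    z = sample(1:90, 100, TRUE))
  s <- sample_boundary_patches(boundary, c(96, 96, 96), 0.3, 32, seed = 9)
  expect_identical(nrow(s), 30L)
  expect_identical(unique(s$origin), "boundary-weighted")
  s2 <- sample_boundary_patches(boundary, c(96, 96, 96), 0.3, 32, seed = 9)
  expect_identical(s, s2)
  s3 <- sample_boundary_patches(boundary, c(96, 96, 96), 0.3, 32, seed = 10)
  expect_false(identical(s, s3))
})

test_that("boundary patch corners are clipped into the padded grid", {
  boundary <- cbind(x = 3L, y = 3L, z = 3L)  # near the low corner
  s <- sample_boundary_patches(boundary, c(240, 240, 240), 1, 64, seed = 1)
  expect_identical(unlist(s[1, c("x", "y", "z")], use.names = FALSE),
                   c(1L, 1L, 1L))
  high <- cbind(x = 239L, y = 239L, z = 239L)
  s2 <- sample_boundary_patches(high, c(240, 240, 240), 1, 64, seed = 1)
  expect_true(all(unlist(s2[1, c("x", "y", "z")]) + 64L - 1L <= 256L))
})

test_that("extracted patches reproduce sub-blocks and zero padding", {
  ph <- small_phantom(seed = 5)
  spec <- data.frame(x = 9L, y = 5L, z = 13L, size = 16L, origin = "grid-seed")
  ps <- extract_patches(ph$volume, spec, labels = ph$labels)
  expect_equal(ps$images[[1]][, , , 2],
               ph$volume$data[9:24, 5:20, 13:28, 2], ignore_attr = TRUE)
  expect_identical(ps$labels[[1]], ph$labels$labels[9:24, 5:20, 13:28])

  # patch reaching into the padded margin (48 -> 60 for size 20) is zero there
  spec2 <- data.frame(x = 41L, y = 41L, z = 41L, size = 20L,
                      origin = "grid-seed")
  p2 <- extract_patches(ph$volume, spec2)$images[[1]]
  expect_true(all(p2[9:20, , , ] == 0))  # beyond voxel 48 on x

  bad <- data.frame(x = 60L, y = 1L, z = 1L, size = 16L, origin = "grid-seed")
  expect_error(extract_patches(ph$volume, bad), "outside padded bounds")
})

test_that("tiling then assembling is the identity", {
  set.seed(33)
  for (shape in list(c(48L, 48L, 48L), c(40L, 56L, 24L))) {
    lab <- random_labels(shape)
    vol <- mc_volume(array(rnorm(prod(shape) * 4), c(shape, 4L)))
    tiles <- seed_grid(shape, 16, 16)
    ps <- extract_patches(vol, tiles, labels = lab)
    out <- assemble_prediction(ps, shape)
    expect_identical(out$labels, lab)
  }
})

test_that("assembly rejects missing or duplicated tiles", {
  shape <- c(32L, 32L, 32L)
  vol <- mc_volume(array(1, c(shape, 4L)))
  lab <- array(0L, shape)
  ps <- extract_patches(vol, seed_grid(shape, 16, 16), labels = lab)
  broken <- ps
  broken$specs <- broken$specs[-3, ]
  broken$images <- broken$images[-3]
  broken$labels <- broken$labels[-3]
  expect_error(assemble_prediction(broken, shape), "cover the padded grid")
})

test_that("training inventory combines filtered grid seeds and boundary patches", {
  ph <- small_phantom(seed = 5)
  mask <- derive_brain_mask(ph$volume)
  nv <- zscore_normalize(ph$volume, mask)
  inv <- build_training_patches(nv, ph$labels, mask, patch_size = 16L,
                                max_boundary = 10, seed = 2)
  origins <- table(inv$specs$origin)
  expect_identical(unname(origins["boundary-weighted"]), 10L)
  expect_gt(origins["grid-seed"], 0L)
  # reproducible given the seed
  inv2 <- build_training_patches(nv, ph$labels, mask, patch_size = 16L,
                                 max_boundary = 10, seed = 2)
  expect_identical(inv$specs, inv2$specs)
})

test_that("patch sets survive a disk round trip with manifest", {
  ph <- small_phantom(seed = 5)
  mask <- derive_brain_mask(ph$volume)
  inv <- build_training_patches(ph$volume, ph$labels, mask, patch_size = 16L,
                                max_boundary = 4, seed = 2)
  dir <- withr::local_tempdir()
  write_patch_set(inv, dir)
  back <- read_patch_set(dir)
  expect_equal(back$specs$x, inv$specs$x)
  expect_equal(back$images[[1]], inv$images[[1]], ignore_attr = TRUE)
  expect_identical(back$labels[[2]], inv$labels[[2]])
})
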