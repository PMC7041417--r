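test_that("phantoms are bit-reproducible given a seed", {
  a <- generate_phantom(phantom_config(shape = c(40, 40, 40), seed = 13))
  b <- generate_phantom(phantom_config(shape = c(40, 40, 40), seed = 13))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$labels, b$labels$labels)
  c2 <- generate_phantom(phantom_config(shape = c(40, 40, 40), seed = 14))
  expect_false(identical(a$labels$labels, c2$labels$labels))
})

test_that("label topology is nested and inside the brain", {
  ph <- small_phantom(seed = 9)
  r <- derive_regions(ph$labels)
  expect_true(all(r$TC[r$ET]))
  expect_true(all(r$WT[r$TC]))
  brain <- derive_brain_mask(ph$volume)
  expect_true(all(brain[ph$labels$labels != 0L]))
  expect_true(all(c(1L, 2L, 4L) %in% ph$labels$labels))
})

test_that("noiseless phantoms reproduce the intensity table exactly", {
  cfg <- phantom_config(shape = c(40, 40, 40), noise_sd = 0, seed = 2)
  ph <- generate_phantom(cfg)
  it <- cfg$intensities
  brain <- derive_brain_mask(ph$volume)
  lab <- ph$labels$labels
  picks <- list(healthy = brain & lab == 0L, necrosis = lab == 1L,
                edema = lab == 2L, enhancing = lab == 4L)
  for (tissue in names(picks)) {
    for (ci in 1:4) {
      vals <- ph$volume$data[, , , ci][picks[[tissue]]]
      expect_true(all(vals == it[tissue, ci]),
                  label = sprintf("%s intensities on %s", tissue,
                                  colnames(it)[ci]))
    }
  }
  expect_true(all(ph$volume$data[, , , 1][!brain] == 0))
})

test_that("tumor voxel counts track the analytic spheroid volumes", {
  cfg <- phantom_config(seed = 3)  # default 96^3
  ph <- generate_phantom(cfg)
  wt_vox <- sum(ph$labels$labels != 0L)
  analytic <- 4 / 3 * pi * cfg$radii[3]^3
  expect_gt(wt_vox, 0.5 * analytic)
  expect_lt(wt_vox, 1.5 * analytic)
})

test_that("imbalance profile counts class fractions", {
  expect_identical(unname(imbalance_profile(array(0L, c(5, 5, 4)))),
                   c(1, 0, 0, 0))
  lab <- array(0L, c(10, 10, 1))
  lab[1, 1, 1] <- 2L
  expect_equal(imbalance_profile(lab)[["2"]], 0.01)
})

test_that("a full-size phantom is dominated by non-tumor voxels", {
  ph <- generate_phantom(phantom_config(shape = c(240, 240, 155), seed = 1,
                                        noise_sd = 0))
  prof <- imbalance_profile(ph$labels)
  expect_gt(prof[["0"]], 0.95)
  expect_true(all(prof[c("1", "2", "4")] > 0))
})

test_that("two-focus phantoms contain two disjoint WT components", {
  ph2 <- small_phantom(seed = 10, n_foci = 2L)
  cc <- gliomaseg:::.label_components_3d(ph2$labels$labels != 0L, 26L)
  expect_identical(length(cc$sizes), 2L)
  expect_gt(max(cc$sizes), min(cc$sizes))  # unequal focus sizes
})

test_that("invalid geometry and intensity tables are rejected", {
  expect_error(phantom_config(radii = c(10, 9, 15)), "strictly increasing")
  expect_error(phantom_config(shape = c(40, 40, 40),
                              radii = c(10, 14, 19)), "fit inside")
  it <- gliomaseg:::default_intensity_table()
  it["edema", "FLAIR"] <- 0.1
  expect_error(phantom_config(intensities = it), "edema")
  it2 <- gliomaseg:::default_intensity_table()
  it2["necrosis", "T1ce"] <- 0.95
  expect_error(phantom_config(intensities = it2), "necrosis")
})
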