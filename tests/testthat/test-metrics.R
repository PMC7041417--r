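test_that("region derivation follows the nested ET/TC/WT definitions", {
  lab <- array(0L, c(10, 10, 10))
  lab[1:10, 1, 1] <- 1L                     # 10 necrosis
  lab[1:10, 2:3, 1] <- 2L                   # 20 edema
  lab[1:5, 4, 1] <- 4L                      # 5 enhancing
  r <- derive_regions(lab)
  expect_identical(sum(r$ET), 5L)
  expect_identical(sum(r$TC), 15L)
  expect_identical(sum(r$WT), 35L)
  expect_true(all(r$TC[r$ET]))
  expect_true(all(r$WT[r$TC]))

  empty <- derive_regions(array(0L, c(4, 4, 4)))
  expect_false(any(empty$ET) || any(empty$TC) || any(empty$WT))
})

test_that("dice, sensitivity and specificity follow their definitions", {
  t1 <- array(FALSE, c(6, 6, 6)); t1[1:4, 1, 1] <- TRUE
  p_same <- t1
  expect_identical(dice_score(p_same, t1), 1)
  expect_identical(sensitivity(p_same, t1), 1)
  expect_identical(specificity(p_same, t1), 1)

  p_disj <- array(FALSE, c(6, 6, 6)); p_disj[1:4, 3, 3] <- TRUE
  expect_identical(dice_score(p_disj, t1), 0)

  p2 <- array(FALSE, c(6, 6, 6)); p2[1:2, 1, 1] <- TRUE
  expect_equal(dice_score(p2, t1), 2 * 2 / (2 + 4))
  expect_equal(sensitivity(p2, t1), 0.5)

  none <- array(FALSE, c(6, 6, 6))
  expect_identical(sensitivity(none, t1), 0)
  expect_identical(specificity(none, t1), 1)
  expect_true(is.na(dice_score(none, none)))
  expect_true(is.na(sensitivity(none, none)))
  expect_error(dice_score(t1, array(FALSE, c(5, 5, 5))), "shapes differ")
})

test_that("HD95 reproduces closed-form cases and honors spacing", {
  m <- array(FALSE, c(10, 10, 10)); m[3:6, 3:6, 3:6] <- TRUE
  expect_identical(hausdorff95(m, m), 0)

  a <- array(FALSE, c(10, 10, 10)); a[2, 5, 5] <- TRUE
  b <- array(FALSE, c(10, 10, 10)); b[5, 5, 5] <- TRUE
  expect_equal(hausdorff95(a, b), 3)
  expect_equal(hausdorff95(a, b, spacing = c(2, 1, 1)), 6)
  expect_equal(hausdorff95(a, b), hausdorff95(b, a))  # symmetric

  none <- array(FALSE, c(10, 10, 10))
  expect_true(is.na(hausdorff95(none, b)))
})

test_that("dice equals the F1 score computed from precision and recall", {
  set.seed(17)
  for (i in 1:25) {
    p <- random_mask(c(8, 8, 8), p = runif(1, 0.1, 0.6))
    t <- random_mask(c(8, 8, 8), p = runif(1, 0.1, 0.6))
    if (!any(p) || !any(t) || !any(p & t)) next
    prec <- sum(p & t) / sum(p)
    rec <- sum(p & t) / sum(t)
    f1 <- 2 * prec * rec / (prec + rec)
    expect_equal(dice_score(p, t), f1, tolerance = 1e-12)
  }
})

test_that("growing the prediction toward the truth never lowers dice", {
  set.seed(23)
  t1 <- random_mask(c(8, 8, 8), p = 0.4)
  p <- array(FALSE, c(8, 8, 8))
  missing <- which(t1 & !p)
  last_d <- dice_score(p, t1); last_s <- 0
  for (step in 1:5) {
    add <- missing[seq_len(min(20, length(missing)))]
    missing <- setdiff(missing, add)
    p[add] <- TRUE
    d <- dice_score(p, t1); s <- sensitivity(p, t1)
    expect_gte(d, ifelse(is.na(last_d), 0, last_d))
    expect_gte(s, last_s)
    last_d <- d; last_s <- s
  }
})

test_that("per-case evaluation reports all regions and metrics", {
  ph <- small_phantom(seed = 8)
  rep <- evaluate_segmentation(ph$labels, ph$labels, case = "self")
  expect_identical(rep$region, c("ET", "TC", "WT"))
  expect_true(all(rep$dice == 1))
  expect_true(all(rep$hd95 == 0))
  expect_true(all(rep$specificity > 0.99))
})

test_that("cohort summaries aggregate with the declared statistics", {
  mk <- function(d) data.frame(case = "c", region = "WT", dice = d,
                               sensitivity = d, specificity = 1, hd95 = 1)
  single <- summarize_cohort(mk(0.7))
  wt_dice <- single[single$metric == "dice", ]
  expect_equal(wt_dice$mean, 0.7)
  expect_equal(wt_dice$median, 0.7)
  expect_equal(wt_dice$sd, 0)

  three <- summarize_cohort(do.call(rbind, lapply(c(0.6, 0.8, 1.0), mk)))
  d3 <- three[three$metric == "dice", ]
  expect_equal(d3$mean, 0.8)
  expect_equal(d3$median, 0.8)
  expect_equal(d3$sd, sd(c(0.6, 0.8, 1.0)))
  expect_equal(d3$q25, 0.7)
  expect_equal(d3$q75, 0.9)
  expect_true(d3$q25 <= d3$median && d3$median <= d3$q75)

  # undefined dice scores as zero by default, is dropped under "exclude"
  withna <- do.call(rbind, lapply(c(0.6, 0.8, NA), mk))
  z <- summarize_cohort(withna)
  expect_equal(z[z$metric == "dice", "mean"], mean(c(0.6, 0.8, 0)))
  ex <- summarize_cohort(withna, undefined = "exclude")
  expect_equal(ex[ex$metric == "dice", "mean"], 0.7)
  # undefined HD95 is always excluded
  expect_equal(z[z$metric == "hd95", "n"], 3L)
  expect_error(summarize_cohort(list()), "no reports")
})
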