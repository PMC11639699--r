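# Segmentation metrics and efficiency indicators.  The brute-force
# Hausdorff oracles live in helper-oracles.R.

test_that("confusion counts match an exhaustive pixel loop and handle edge cases", {
  ones <- matrix(1, 4, 4)
  c1 <- confusion(ones, ones)
  expect_identical(c(c1$tp, c1$fp, c1$fn, c1$tn), c(16L, 0L, 0L, 0L))
  c2 <- confusion(1 - ones, ones)
  expect_identical(c(c2$tp, c2$tn), c(0L, 0L))
  set.seed(0)
  p <- matrix(rbinom(64, 1, 0.4), 8, 8)
  t <- matrix(rbinom(64, 1, 0.4), 8, 8)
  cc <- confusion(p, t)
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in 1:8) for (j in 1:8) {
    if (p[i, j] == 1 && t[i, j] == 1) tp <- tp + 1L
    if (p[i, j] == 1 && t[i, j] == 0) fp <- fp + 1L
    if (p[i, j] == 0 && t[i, j] == 1) fn <- fn + 1L
    if (p[i, j] == 0 && t[i, j] == 0) tn <- tn + 1L
  }
  expect_identical(c(cc$tp, cc$fp, cc$fn, cc$tn), c(tp, fp, fn, tn))
  expect_identical(cc$tp + cc$fp + cc$fn + cc$tn, 64L)
  expect_error(confusion(p, t[1:4, ]), "shapes")
  expect_error(confusion(p * 2, t), "binary")
})

test_that("ratio metrics match direct substitution and flag zero denominators", {
  r <- ratio_metrics(list(tp = 2, fp = 1, fn = 1, tn = 12))
  expect_equal(r$dice, 4 / 6, tolerance = 1e-15)
  expect_equal(r$sen, 2 / 3, tolerance = 1e-15)
  expect_equal(r$spe, 12 / 13, tolerance = 1e-15)
  perfect <- ratio_metrics(confusion(matrix(c(1, 0), 2, 2), matrix(c(1, 0), 2, 2)))
  expect_equal(unlist(perfect), c(sen = 1, spe = 1, dice = 1))
  und <- ratio_metrics(list(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_true(is.na(und$sen) && is.na(und$dice) && !is.na(und$spe))
})

test_that("hd95 agrees with the all-pairs brute-force oracle", {
  a <- matrix(0, 8, 8); a[1, 1] <- 1
  b <- matrix(0, 8, 8); b[1, 6] <- 1
  expect_equal(hd95(a, b), 5.0, tolerance = 1e-12)
  expect_equal(hd95(a, a), 0, tolerance = 0)
  for (s in 1:8) {
    A <- random_blob_mask(32, 100 + s)
    B <- random_blob_mask(32, 200 + s)
    expect_equal(hd95(A, B), brute_hd(A, B), tolerance = 1e-9)
    # the percentile variant is bounded by the exact Hausdorff distance
    expect_lte(hd95(A, B), hd95(A, B, percentile = 100) + 1e-12)
    expect_equal(hd95(A, B, percentile = 100),
                 max(max(brute_directed(A, B)), max(brute_directed(B, A))),
                 tolerance = 1e-9)
  }
  expect_true(is.na(hd95(matrix(0, 4, 4), a[1:4, 1:4])))
})

test_that("Sen/Spe/Dice are invariant under simultaneous transposition", {
  A <- random_blob_mask(16, 1); B <- random_blob_mask(16, 2)
  expect_identical(unlist(ratio_metrics(confusion(A, B))),
                   unlist(ratio_metrics(confusion(t(A), t(B)))))
})

test_that("binary Dice equals 1 minus the Dice-loss term at zero smoothing", {
  set.seed(3)
  pred <- matrix(rbinom(64, 1, 0.5), 8, 8)
  truth <- matrix(rbinom(64, 1, 0.5), 8, 8)
  probs <- array(0, c(1, 2, 8, 8))
  probs[1, 2, , ] <- pred; probs[1, 1, , ] <- 1 - pred
  # isolate the Dice-loss term by differencing two dice weights:
  # loss(k) = BCE + k * (1 - dice)  =>  dice = 1 - (loss(k2) - loss(k1)) / (k2 - k1)
  lk <- function(k) as.numeric(bce_dice_level_loss(
    probs, truth, loss_config(level_weights = 1, dice_weight = k, smooth = 1e-12))$value)
  dice_from_loss <- 1 - (lk(2) - lk(1))
  expect_equal(dice_from_loss, ratio_metrics(confusion(pred, truth))$dice,
               tolerance = 1e-6)
})

test_that("parameter counting matches closed forms for plain convolutions", {
  c11 <- ntsm:::new_conv2d(1L, 1L, 1L)
  expect_identical(count_params(c11), 2)
  for (C in 1:8)
    expect_identical(count_params(ntsm:::new_conv2d(C, C, 3L)), 9 * C^2 + C)
})

test_that("metrics CSV report appends a mean row and tracks undefined entries", {
  rows <- data.frame(id = c("a", "b"), sen = c(1, NA), spe = c(1, 0.5),
                     dice = c(1, 0.8), hd95 = c(0, 2))
  f <- tempfile(fileext = ".csv")
  out <- write_metrics_csv(rows, f)
  expect_true(file.exists(f))
  re <- read.csv(f)
  expect_identical(re$id[3], "mean")
  expect_equal(re$sen[3], 1)       # NA excluded from the mean
  expect_identical(attr(out, "n_undefined_sen"), 1L)
})
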