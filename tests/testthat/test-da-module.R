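# Difference-association module: LCE contrast operator, LCD and LSA
# submodules.

test_that("LCE contrast is zero for equal inputs and per-plane constant offsets", {
  a <- rand_arr(c(2, 3, 5, 5), 1)
  expect_equal(lce_contrast(a, a)$value, array(0, dim(a)), tolerance = 0)
  shifted <- a
  set.seed(2)
  for (b in 1:2) for (c in 1:3) shifted[b, c, , ] <- a[b, c, , ] + rnorm(1)
  # instance normalization removes the per-plane mean, so a spatially constant
  # difference collapses to (numerically) zero
  expect_lt(max(abs(lce_contrast(shifted, a)$value)), 1e-10)
})

test_that("LCE matches a scalar-loop instance-norm oracle and rejects mismatched shapes", {
  x1 <- rand_arr(c(1, 3, 6, 6), 3)
  x2 <- rand_arr(c(1, 3, 6, 6), 4)
  expect_equal(lce_contrast(x1, x2)$value, oracle_lce(x1, x2), tolerance = 1e-10)
  expect_error(lce_contrast(x1, rand_arr(c(1, 3, 6, 5), 5)), "shape mismatch")
})

test_that("LCE output has zero spatial mean per plane before the activation", {
  x1 <- rand_arr(c(2, 4, 7, 7), 6)
  x2 <- rand_arr(c(2, 4, 7, 7), 7)
  pre <- ntsm:::ag_instancenorm(ntsm:::ag_sub(ntsm:::ag_tensor(x1), ntsm:::ag_tensor(x2)))$value
  for (b in 1:2) for (c in 1:4) expect_lt(abs(mean(pre[b, c, , ])), 1e-12)
})

test_that("LCD preserves spatial extent and maps zero weights to zero output", {
  set.seed(8)
  lcd <- new_lcd(3L, da_config(out_channels = 8L))
  x <- rand_arr(c(2, 3, 16, 16), 9)
  out <- lcd_forward(lcd, x)$value
  expect_identical(dim(out), c(2L, 8L, 16L, 16L))
  for (p in collect_params(lcd)) p$value[] <- 0
  expect_equal(lcd_forward(lcd, x)$value, array(0, c(2, 8, 16, 16)), tolerance = 0)
})

test_that("LCD branch influence is bounded by the dilated kernel span per axis", {
  set.seed(10)
  lcd <- new_lcd(3L, da_config(out_channels = 4L))
  randomize_norm_layers(lcd, 11)
  x <- rand_arr(c(1, 3, 32, 32), 12)
  u <- lcd$unit_a
  branch <- function(xx) lfe_forward(u$lfe_context,
                                     ntsm:::fw_conv2d(u$conv_context, ntsm:::as_ag(xx)))$value
  base <- branch(x)
  xp <- x; xp[1, 2, 5, 5] <- xp[1, 2, 5, 5] + 1
  delta <- apply(abs(branch(xp) - base), c(3, 4), max)
  # the context receptor is a 3x3 convolution at dilation 4 (reach 8 pixels);
  # the pooled LFE gates then spread influence along the touched rows and
  # columns, so cells outside BOTH the row band and the column band are exact
  # zeros while nearby cells move
  untouched <- delta[abs(seq_len(32) - 5) > 8, abs(seq_len(32) - 5) > 8]
  expect_equal(max(untouched), 0, tolerance = 0)
  expect_gt(max(delta[abs(seq_len(32) - 5) <= 8, abs(seq_len(32) - 5) <= 8]), 0)
  # the subsequent contrast step is instance-normalized over the whole plane,
  # which deliberately couples all positions (plane statistics shift)
  full <- lcd_forward(lcd, x)$value
  fullp <- lcd_forward(lcd, xp)$value
  expect_gt(max(abs(full - fullp)), 0)
})

test_that("LSA preserves shape, matches its sequential oracle, zeroes with zero weights", {
  set.seed(13)
  cfg <- da_config(out_channels = 8L)
  lsa <- new_lsa(cfg)
  randomize_norm_layers(lsa, 14)
  x <- rand_arr(c(1, 8, 9, 9), 15)
  out <- lsa_forward(lsa, x)$value
  expect_identical(dim(out), c(1L, 8L, 9L, 9L))
  expect_equal(out, oracle_lsa(lsa, x), tolerance = 1e-10)
  expect_error(lsa_forward(lsa, rand_arr(c(1, 4, 9, 9), 16)), "channels")
  for (p in collect_params(lsa)) p$value[] <- 0
  # zero convolutions and zero batch-norm affine terms collapse every branch
  expect_equal(lsa_forward(lsa, x)$value, array(0, c(1, 8, 9, 9)), tolerance = 0)
})

test_that("LSA branches 3 and 4 have independent weights that diverge under training", {
  set.seed(17)
  da <- new_da(3L, da_config(out_channels = 4L))
  w3 <- da$lsa$b3[[2]]$conv$w; w4 <- da$lsa$b4[[2]]$conv$w
  expect_false(identical(w3$value, w4$value))
  # one gradient step on random data keeps them apart even if started equal
  w4$value <- w3$value
  params <- collect_params(da)
  set_training(TRUE)
  on.exit(set_training(FALSE))
  out <- da_forward(da, rand_arr(c(2, 3, 16, 16), 18))
  ntsm:::ag_backward(ntsm:::ag_mean(ntsm:::ag_mul(out, out)))
  opt <- ntsm:::new_sgd(params, lr = 0.1, momentum = 0, nesterov = FALSE, weight_decay = 0)
  ntsm:::sgd_step(opt)
  expect_false(identical(w3$value, w4$value))
})

test_that("end-to-end DA preserves (batch, out_channels, h, w) including odd extents", {
  set.seed(19)
  da <- new_da(3L, da_config(out_channels = 4L))
  for (ext in c(16L, 33L)) {
    out <- da_forward(da, rand_arr(c(1, 3, ext, ext), ext))$value
    expect_identical(dim(out), c(1L, 4L, ext, ext))
    expect_true(all(is.finite(out)))
  }
})

test_that("da_config validates its arguments", {
  expect_error(da_config(out_channels = 2L), ">= 4")
  expect_error(da_config(lcd_context_dilations = c(0L, 8L)), "dilations")
})
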