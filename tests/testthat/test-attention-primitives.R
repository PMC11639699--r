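# LFE (dual 1-D pooled gating attention) and HPA (bilinear-resized learnable
# gate with depthwise convolution).

test_that("LFE with zeroed gate convolutions scales the input by exactly 0.25", {
  set.seed(1)
  lfe <- new_lfe(8L)
  for (l in list(lfe$gate_h, lfe$gate_w)) { l$w$value[] <- 0; l$b$value[] <- 0 }
  x <- rand_arr(c(2, 8, 5, 6), 2)
  expect_equal(lfe_forward(lfe, x)$value, 0.25 * x, tolerance = 0)
})

test_that("LFE preserves shape and is contractive (gates lie in (0,1))", {
  set.seed(3)
  for (case in list(c(1, 2, 8, 8), c(2, 8, 1, 9), c(1, 4, 9, 1), c(3, 16, 5, 7))) {
    lfe <- new_lfe(case[2])
    x <- rand_arr(case, sum(case))
    out <- lfe_forward(lfe, x)$value
    expect_identical(dim(out), as.integer(case))
    expect_true(all(abs(out) <= abs(x) + 1e-12))
    expect_true(all(is.finite(out)))
  }
})

test_that("LFE matches the scalar-loop oracle on seeded tensors", {
  set.seed(4)
  lfe <- new_lfe(4L)
  randomize_norm_layers(lfe, seed = 5)
  x <- rand_arr(c(1, 4, 5, 5), 6)
  expect_equal(lfe_forward(lfe, x)$value, oracle_lfe(lfe, x), tolerance = 1e-10)
  lfe2 <- new_lfe(8L)
  randomize_norm_layers(lfe2, seed = 7)
  x2 <- rand_arr(c(2, 8, 9, 7), 8)
  expect_equal(lfe_forward(lfe2, x2)$value, oracle_lfe(lfe2, x2), tolerance = 1e-10)
})

test_that("LFE rejects malformed inputs", {
  lfe <- new_lfe(4L)
  expect_error(lfe_forward(lfe, array(1, c(4, 5, 5))), "rank-4")
  expect_error(lfe_forward(lfe, array(1, c(1, 3, 5, 5))), "channels")
})

test_that("HPA gate contrivances give exact identity and constant scaling", {
  set.seed(9)
  hpa <- new_hpa(c(4L, 4L), n_slices = 3L)
  # p constant 2, centered-delta kernel of weight 1/2 -> gate is exactly 1
  hpa$p$value[] <- 2
  hpa$dw$w$value[] <- 0
  hpa$dw$w$value[, 1, 2, 2] <- 0.5
  hpa$dw$b$value[] <- 0
  x <- rand_arr(c(2, 3, 7, 5), 10)
  expect_equal(hpa_forward(x, hpa)$value, x, tolerance = 0)
  # centered delta of weight 1 -> gate = p = 2 everywhere
  hpa$dw$w$value[, 1, 2, 2] <- 1
  expect_equal(hpa_forward(x, hpa)$value, 2 * x, tolerance = 0)
})

test_that("HPA matches the loop-based bilinear+convolution+product oracle", {
  set.seed(11)
  hpa <- new_hpa(c(4L, 4L), n_slices = 4L)
  x <- rand_arr(c(2, 4, 7, 5), 12)
  expect_equal(hpa_forward(x, hpa)$value, oracle_hpa(hpa, x), tolerance = 1e-10)
  hpa1 <- new_hpa(c(5L, 3L), n_slices = 1L)
  x1 <- rand_arr(c(1, 6, 9, 9), 13)
  expect_equal(hpa_forward(x1, hpa1)$value, oracle_hpa(hpa1, x1), tolerance = 1e-10)
})

test_that("HPA is linear in x for fixed p and preserves shape", {
  set.seed(14)
  hpa <- new_hpa(c(16L, 16L), n_slices = 2L)
  for (ext in list(c(1, 2, 1, 1), c(2, 2, 9, 3), c(1, 2, 4, 9))) {
    x <- rand_arr(ext, sum(ext))
    y <- hpa_forward(x, hpa)$value
    expect_identical(dim(y), as.integer(ext))
    y3 <- hpa_forward(3 * x, hpa)$value
    expect_equal(y3, 3 * y, tolerance = 1e-5)
  }
})

test_that("HPA configuration guards reject degenerate grids", {
  expect_error(new_hpa(c(1L, 4L)), ">= 2")
  expect_error(new_hpa(c(4L, 4L), init_std = 0), "positive")
})

test_that("gradients flow through both attention primitives to their parameters", {
  set.seed(15)
  lfe <- new_lfe(4L)
  hpa <- new_hpa(c(4L, 4L), n_slices = 4L)
  x <- ntsm:::ag_tensor(rand_arr(c(2, 4, 6, 6), 16), requires_grad = TRUE)
  out <- hpa_forward(lfe_forward(lfe, x), hpa)
  ntsm:::ag_backward(ntsm:::ag_sum(ntsm:::ag_mul(out, out)))
  for (p in collect_params(list(lfe, hpa))) {
    expect_false(is.null(p$grad))
    expect_true(any(p$grad != 0))
  }
})
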