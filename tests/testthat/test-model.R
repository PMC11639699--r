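# NTSM assembly: pinned encoder-decoder backbone, DA fusion, FHPA
# substitution, deep supervision, checkpointing.

test_that("default-shaped forward yields halving deep-supervision logit maps", {
  m <- build_ntsm(tiny_ntsm_config())
  out <- ntsm_forward(m, rand_arr(c(2, 3, 64, 64), 1))
  expect_length(out$logits, 2L)
  expect_identical(dim(out$logits[[1]]$value), c(2L, 2L, 64L, 64L))
  expect_identical(dim(out$logits[[2]]$value), c(2L, 2L, 32L, 32L))
})

test_that("build is deterministic given the seed and checkpoints round-trip bit-exactly", {
  m1 <- build_ntsm(tiny_ntsm_config(seed = 21L))
  m2 <- build_ntsm(tiny_ntsm_config(seed = 21L))
  p1 <- collect_params(m1); p2 <- collect_params(m2)
  expect_true(all(mapply(function(a, b) identical(a$value, b$value), p1, p2)))
  ck <- tempfile(fileext = ".ckpt")
  save_checkpoint(m1, ck)
  expect_true(file.exists(paste0(ck, ".yaml")))
  m3 <- load_checkpoint(ck)
  p3 <- collect_params(m3)
  expect_true(all(mapply(function(a, b) identical(a$value, b$value), p1, p3)))
  x <- rand_arr(c(1, 3, 32, 32), 2)
  expect_identical(ntsm_forward(m1, x)$logits[[1]]$value,
                   ntsm_forward(m3, x)$logits[[1]]$value)
})

test_that("inference forward is bit-deterministic on repeat", {
  m <- build_ntsm(tiny_ntsm_config())
  x <- rand_arr(c(1, 3, 32, 32), 3)
  o1 <- ntsm_forward(m, x)$logits[[1]]$value
  o2 <- ntsm_forward(m, x)$logits[[1]]$value
  expect_identical(o1, o2)
})

test_that("disabling DA on a weight-sharing copy changes the logits", {
  m <- build_ntsm(tiny_ntsm_config(use_da = TRUE))
  m_noda <- m
  m_noda$config$use_da <- FALSE   # same parameter tensors, DA path skipped
  x <- rand_arr(c(1, 3, 32, 32), 4)
  expect_gt(max(abs(ntsm_forward(m, x)$logits[[1]]$value -
                    ntsm_forward(m_noda, x)$logits[[1]]$value)), 0)
})

test_that("FHPA substitution never changes activation shapes anywhere", {
  base <- tiny_ntsm_config()
  plain <- base; plain$fhpa_encoder_stages <- integer(0); plain$fhpa_decoder_stages <- integer(0)
  x <- rand_arr(c(1, 3, 32, 32), 5)
  o1 <- ntsm_forward(build_ntsm(base), x)
  o2 <- ntsm_forward(build_ntsm(plain), x)
  for (l in seq_along(o1$logits))
    expect_identical(dim(o1$logits[[l]]$value), dim(o2$logits[[l]]$value))
})

test_that("invalid configurations and inputs are rejected with informative errors", {
  expect_error(ntsm_config(stage_channels = c(8L, 16L, 30L),
                           fhpa_encoder_stages = 3L, fhpa_decoder_stages = integer(0),
                           deep_supervision_levels = 2L,
                           da = da_config(out_channels = 8L)),
               "divisible by 4")
  expect_error(ntsm_config(stage_channels = c(8L, 16L, 32L),
                           fhpa_encoder_stages = 7L,
                           da = da_config(out_channels = 8L)),
               "invalid fhpa_encoder_stages")
  expect_error(ntsm_config(stage_channels = c(8L, 16L, 32L),
                           fhpa_encoder_stages = 2L, fhpa_decoder_stages = 1L,
                           deep_supervision_levels = 3L,
                           da = da_config(out_channels = 8L)),
               "deep_supervision_levels")
  m <- build_ntsm(tiny_ntsm_config())
  expect_error(ntsm_forward(m, rand_arr(c(1, 3, 30, 32), 6)), "divisible by 4")
  expect_error(ntsm_forward(m, rand_arr(c(1, 4, 32, 32), 7)), "3-channel")
})

test_that("a plain backbone (no DA, no FHPA) builds and runs", {
  cfg <- ntsm_config(stage_channels = c(8L, 16L, 32L),
                     fhpa_encoder_stages = integer(0),
                     fhpa_decoder_stages = integer(0),
                     use_da = FALSE, deep_supervision_levels = 2L,
                     da = da_config(out_channels = 8L))
  out <- ntsm_forward(build_ntsm(cfg), rand_arr(c(1, 3, 32, 32), 8))
  expect_identical(dim(out$logits[[1]]$value), c(1L, 2L, 32L, 32L))
})
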