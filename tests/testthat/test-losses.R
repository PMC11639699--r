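# Joint BCE + Dice deep-supervision loss.

prob_stack <- function(fg) {
  d <- dim(fg)
  p <- array(0, c(d[1], 2L, d[2], d[3]))
  p[, 2, , ] <- fg
  p[, 1, , ] <- 1 - fg
  p
}

test_that("perfect one-hot prediction gives (near-)zero loss", {
  t <- matrix(c(1, 1, 0, 0, 1, 0, 0, 0, 0), 3, 3)
  fg <- array(t, c(1, 3, 3))
  l <- bce_dice_level_loss(prob_stack(fg), t, loss_config(level_weights = 1))
  expect_lt(as.numeric(l$value), 1e-4)
  expect_gte(as.numeric(l$value), 0)
})

test_that("uniform 0.5 prediction has BCE exactly ln 2 per pixel", {
  set.seed(1)
  t <- (matrix(runif(16), 4, 4) > 0.5) * 1
  fg <- array(0.5, c(1, 4, 4))
  cfg <- loss_config(level_weights = 1, dice_weight = 1, smooth = 0)
  l <- as.numeric(bce_dice_level_loss(prob_stack(fg), t, cfg)$value)
  dice <- 2 * sum(0.5 * t) / (sum(fg) + sum(t))
  expect_equal(l, log(2) + (1 - dice), tolerance = 1e-9)
})

test_that("fixed 2x2 example matches hand arithmetic", {
  fg <- array(0, c(1, 2, 2))
  fg[1, , ] <- matrix(c(0.9, 0.8, 0.1, 0.2), 2, 2)
  t <- matrix(c(1, 1, 0, 0), 2, 2)
  for (k in c(1, 2.5)) {
    cfg <- loss_config(level_weights = 1, dice_weight = k, smooth = 0)
    bce <- -mean(log(c(0.9, 0.8, 0.9, 0.8)))
    dice <- 2 * 1.7 / (2 + 2)    # 2*sum(p*t) / (sum(p) + sum(t))
    expect_equal(as.numeric(bce_dice_level_loss(prob_stack(fg), t, cfg)$value),
                 bce + k * (1 - dice), tolerance = 1e-12)
  }
})

test_that("non-binary targets are rejected", {
  fg <- array(0.5, c(1, 2, 2))
  expect_error(bce_dice_level_loss(prob_stack(fg), matrix(c(0, 1, 2, 0), 2, 2)),
               "\\{0, 1\\}")
})

test_that("deep-supervision loss composes weighted per-level losses", {
  set.seed(2)
  t <- (matrix(runif(64), 8, 8) > 0.6) * 1
  lg0 <- ntsm:::ag_tensor(rand_arr(c(1, 2, 8, 8), 3))
  lg1 <- ntsm:::ag_tensor(rand_arr(c(1, 2, 4, 4), 4))
  out <- list(logits = list(lg0, lg1))
  cfg <- loss_config(level_weights = c(0.7, 0.3))
  l01 <- as.numeric(deep_supervision_loss(out, t, cfg)$value)
  pl <- function(lg, tt) as.numeric(bce_dice_level_loss(
    ntsm:::ag_softmax_ch(lg), tt, cfg)$value)
  t1 <- t[seq(1, 8, 2), seq(1, 8, 2)]
  expect_equal(l01, 0.7 * pl(lg0, t) + 0.3 * pl(lg1, t1), tolerance = 1e-10)
  # degenerate weights select the finest level alone
  cfg10 <- loss_config(level_weights = c(1, 0))
  expect_equal(as.numeric(deep_supervision_loss(out, t, cfg10)$value),
               pl(lg0, t), tolerance = 1e-10)
  expect_error(deep_supervision_loss(out, t, loss_config(level_weights = c(1, 1, 1))),
               "levels")
})

test_that("loss is non-negative and zero only at the (smoothed) target", {
  set.seed(5)
  for (i in 1:5) {
    t <- (matrix(runif(25), 5, 5) > runif(1)) * 1
    fg <- array(runif(25), c(1, 5, 5))
    l <- as.numeric(bce_dice_level_loss(prob_stack(fg), t, loss_config(level_weights = 1))$value)
    expect_gte(l, 0)
  }
})

test_that("corrupting more target pixels never decreases the Dice-loss term", {
  set.seed(6)
  fg <- array(0, c(1, 8, 8))
  fg[1, , ] <- matrix(runif(64, 0.6, 0.95), 8, 8)   # confident foreground
  t <- matrix(1, 8, 8)
  cfg <- loss_config(level_weights = 1, dice_weight = 1, smooth = 0)
  p <- fg[1, , ]
  # package Dice-loss term isolated by subtracting the hand-computed BCE
  pkg_dice_term <- function(tt) {
    full <- as.numeric(bce_dice_level_loss(prob_stack(fg), tt, cfg)$value)
    bce <- -(sum(log(p)[tt == 1]) + sum(log(1 - p)[tt == 0])) / 64
    full - bce
  }
  prev <- -Inf
  order_px <- sample(64)
  for (k in c(0, 8, 16, 32, 64)) {
    tt <- t
    tt[order_px[seq_len(k)]] <- 0
    cur <- pkg_dice_term(tt)
    expect_equal(cur, 1 - 2 * sum(p * tt) / (sum(p) + sum(tt)), tolerance = 1e-9)
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
})
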