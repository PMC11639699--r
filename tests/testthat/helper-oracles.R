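# Independent scalar-loop reference implementations ("oracles").  These are
# deliberately written as straight-line nested loops over array indices --
# no im2col, no vectorization, no shared code with the engine -- so that
# agreement with the package's compiled/vectorized path is meaningful.

EPS <- 1e-5

oracle_conv2d <- function(x, w, b = NULL, stride = 1, dil = 1, pad = 0, groups = 1) {
  dx <- dim(x); dw <- dim(w)
  B <- dx[1]; C <- dx[2]; H <- dx[3]; W <- dx[4]
  Co <- dw[1]; Cipg <- dw[2]; kh <- dw[3]; kw <- dw[4]
  oh <- (H + 2 * pad - dil * (kh - 1) - 1) %/% stride + 1
  ow <- (W + 2 * pad - dil * (kw - 1) - 1) %/% stride + 1
  cog <- Co / groups
  y <- array(0, c(B, Co, oh, ow))
  for (bb in 1:B) for (co in 1:Co) {
    g <- (co - 1) %/% cog
    for (i in 1:oh) for (j in 1:ow) {
      s <- if (is.null(b)) 0 else b[co]
      for (ci in 1:Cipg) for (ki in 1:kh) for (kj in 1:kw) {
        hi <- (i - 1) * stride - pad + (ki - 1) * dil + 1
        wi <- (j - 1) * stride - pad + (kj - 1) * dil + 1
        if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
          s <- s + x[bb, g * Cipg + ci, hi, wi] * w[co, ci, ki, kj]
      }
      y[bb, co, i, j] <- s
    }
  }
  y
}

oracle_bn_eval <- function(x, gamma, beta, rm, rv) {
  d <- dim(x)
  y <- x
  for (bb in 1:d[1]) for (c in 1:d[2]) for (i in 1:d[3]) for (j in 1:d[4])
    y[bb, c, i, j] <- (x[bb, c, i, j] - rm[c]) / sqrt(rv[c] + EPS) * gamma[c] + beta[c]
  y
}

oracle_instancenorm <- function(x) {
  d <- dim(x)
  y <- x
  for (bb in 1:d[1]) for (c in 1:d[2]) {
    v <- c()
    for (i in 1:d[3]) for (j in 1:d[4]) v <- c(v, x[bb, c, i, j])
    mu <- sum(v) / length(v)
    va <- sum((v - mu)^2) / length(v)
    for (i in 1:d[3]) for (j in 1:d[4])
      y[bb, c, i, j] <- (x[bb, c, i, j] - mu) / sqrt(va + EPS)
  }
  y
}

oracle_groupnorm <- function(x, gamma, beta, groups) {
  d <- dim(x); cpg <- d[2] %/% groups
  y <- x
  for (bb in 1:d[1]) for (g in 1:groups) {
    v <- c()
    for (c in ((g - 1) * cpg + 1):(g * cpg))
      for (i in 1:d[3]) for (j in 1:d[4]) v <- c(v, x[bb, c, i, j])
    mu <- mean(v); va <- sum((v - mu)^2) / length(v)
    for (c in ((g - 1) * cpg + 1):(g * cpg))
      for (i in 1:d[3]) for (j in 1:d[4])
        y[bb, c, i, j] <- (x[bb, c, i, j] - mu) / sqrt(va + EPS) * gamma[c] + beta[c]
  }
  y
}

# half-pixel bilinear resize of a matrix, one output cell at a time
oracle_bilinear_mat <- function(m, oh, ow) {
  ih <- nrow(m); iw <- ncol(m)
  out <- matrix(0, oh, ow)
  samp1d <- function(n_in, k, n_out) {
    if (n_in == 1) return(list(i0 = 1, i1 = 1, f = 0))
    s <- (k - 0.5) * n_in / n_out - 0.5
    s <- min(max(s, 0), n_in - 1)
    i0 <- floor(s)
    list(i0 = i0 + 1, i1 = min(i0 + 1, n_in - 1) + 1, f = s - i0)
  }
  for (i in 1:oh) for (j in 1:ow) {
    a <- samp1d(ih, i, oh); b <- samp1d(iw, j, ow)
    out[i, j] <- (1 - a$f) * (1 - b$f) * m[a$i0, b$i0] +
      (1 - a$f) * b$f * m[a$i0, b$i1] +
      a$f * (1 - b$f) * m[a$i1, b$i0] +
      a$f * b$f * m[a$i1, b$i1]
  }
  out
}

sigm <- function(v) 1 / (1 + exp(-v))
gelu_ref <- function(v) v * pnorm(v)
leaky_ref <- function(v, s = 0.01) ifelse(v > 0, v, s * v)

# --- module-level oracles: straight-line loop compositions ------------------

oracle_lfe <- function(lfe, x) {
  d <- dim(x); B <- d[1]; C <- d[2]; h <- d[3]; w <- d[4]
  mid <- lfe$mid
  # pooled strips, stacked (h then w) on the third axis
  strip <- array(0, c(B, C, h + w, 1))
  for (bb in 1:B) for (c in 1:C) {
    for (i in 1:h) strip[bb, c, i, 1] <- sum(x[bb, c, i, ]) / w
    for (j in 1:w) strip[bb, c, h + j, 1] <- sum(x[bb, c, , j]) / h
  }
  sq <- oracle_conv2d(strip, lfe$squeeze$w$value, lfe$squeeze$b$value)
  sq <- oracle_bn_eval(sq, lfe$bn$gamma$value, lfe$bn$beta$value,
                       lfe$bn$stats$rm, lfe$bn$stats$rv)
  sq <- sq * sigm(sq)   # swish
  mh <- sq[, , 1:h, , drop = FALSE]
  mw <- sq[, , h + (1:w), , drop = FALSE]
  gh <- sigm(oracle_conv2d(mh, lfe$gate_h$w$value, lfe$gate_h$b$value))
  gw <- sigm(oracle_conv2d(mw, lfe$gate_w$w$value, lfe$gate_w$b$value))
  y <- x
  for (bb in 1:B) for (c in 1:C) for (i in 1:h) for (j in 1:w)
    y[bb, c, i, j] <- x[bb, c, i, j] * gh[bb, c, i, 1] * gw[bb, c, j, 1]
  y
}

oracle_lce <- function(a, b, slope = 0.01) leaky_ref(oracle_instancenorm(a - b), slope)

oracle_hpa <- function(hpa, x) {
  d <- dim(x)
  np <- hpa$n_slices
  gate <- array(0, c(np, d[3], d[4]))
  for (s in 1:np)
    gate[s, , ] <- oracle_bilinear_mat(hpa$p$value[1, s, , ], d[3], d[4])
  # depthwise 3x3, zero pad 1, one filter per slice
  conv_gate <- gate
  for (s in 1:np) for (i in 1:d[3]) for (j in 1:d[4]) {
    acc <- hpa$dw$b$value[s]
    for (ki in 1:3) for (kj in 1:3) {
      hi <- i + ki - 2; wi <- j + kj - 2
      if (hi >= 1 && hi <= d[3] && wi >= 1 && wi <= d[4])
        acc <- acc + gate[s, hi, wi] * hpa$dw$w$value[s, 1, ki, kj]
    }
    conv_gate[s, i, j] <- acc
  }
  y <- x
  for (bb in 1:d[1]) for (c in 1:d[2]) for (i in 1:d[3]) for (j in 1:d[4])
    y[bb, c, i, j] <- x[bb, c, i, j] * conv_gate[if (np == 1) 1 else c, i, j]
  y
}

oracle_cbg <- function(l, x, gelu = TRUE) {
  k <- dim(l$conv$w$value)[3]
  dil <- l$conv$dilation
  y <- oracle_conv2d(x, l$conv$w$value, l$conv$b$value,
                     dil = dil, pad = dil * (k - 1) %/% 2)
  y <- oracle_bn_eval(y, l$bn$gamma$value, l$bn$beta$value, l$bn$stats$rm, l$bn$stats$rv)
  if (gelu) gelu_ref(y) else y
}

oracle_lsa <- function(lsa, x) {
  y1 <- oracle_cbg(lsa$b1, x, gelu = FALSE)
  run_branch <- function(br, x) {
    n <- length(br)
    for (i in seq_len(n)) x <- oracle_cbg(br[[i]], x, gelu = i < n)
    x
  }
  y2 <- run_branch(lsa$b2, x)
  y3 <- run_branch(lsa$b3, x)
  y4 <- run_branch(lsa$b4, x)
  d <- dim(y1)
  ft <- array(0, c(d[1], 4 * d[2], d[3], d[4]))
  ft[, 1:d[2], , ] <- y1
  ft[, d[2] + 1:d[2], , ] <- y2
  ft[, 2 * d[2] + 1:d[2], , ] <- y3
  ft[, 3 * d[2] + 1:d[2], , ] <- y4
  fused <- oracle_cbg(lsa$fuse, ft, gelu = FALSE)
  short <- oracle_cbg(lsa$shortcut, x, gelu = FALSE)
  leaky_ref(fused + short, lsa$cfg$negative_slope)
}

oracle_fhpa <- function(fb, x) {
  cfg <- fb$cfg; C <- cfg$channels; c4 <- C %/% 4
  g <- oracle_groupnorm(x, fb$gn_in$gamma$value, fb$gn_in$beta$value, cfg$gn_groups)
  xs <- lapply(0:3, function(k) g[, k * c4 + 1:c4, , , drop = FALSE])
  d <- dim(xs[[1]])
  y1 <- oracle_hpa(fb$hpa_xy, xs[[1]])
  # zx: gate over the (group-channel, height) plane, broadcast over b and w
  p2 <- oracle_bilinear_mat(fb$hpa_zx$p$value[1, 1, , ], c4, d[3])
  g2 <- p2
  for (i in 1:c4) for (j in 1:d[3]) {
    acc <- fb$hpa_zx$dw$b$value[1]
    for (ki in 1:3) for (kj in 1:3) {
      ci <- i + ki - 2; hj <- j + kj - 2
      if (ci >= 1 && ci <= c4 && hj >= 1 && hj <= d[3])
        acc <- acc + p2[ci, hj] * fb$hpa_zx$dw$w$value[1, 1, ki, kj]
    }
    g2[i, j] <- acc
  }
  y2 <- xs[[2]]
  for (bb in 1:d[1]) for (c in 1:c4) for (i in 1:d[3]) for (j in 1:d[4])
    y2[bb, c, i, j] <- xs[[2]][bb, c, i, j] * g2[c, i]
  # zy: gate over (group-channel, width), broadcast over b and h
  p3 <- oracle_bilinear_mat(fb$hpa_zy$p$value[1, 1, , ], c4, d[4])
  g3 <- p3
  for (i in 1:c4) for (j in 1:d[4]) {
    acc <- fb$hpa_zy$dw$b$value[1]
    for (ki in 1:3) for (kj in 1:3) {
      ci <- i + ki - 2; wj <- j + kj - 2
      if (ci >= 1 && ci <= c4 && wj >= 1 && wj <= d[4])
        acc <- acc + p3[ci, wj] * fb$hpa_zy$dw$w$value[1, 1, ki, kj]
    }
    g3[i, j] <- acc
  }
  y3 <- xs[[3]]
  for (bb in 1:d[1]) for (c in 1:c4) for (i in 1:d[3]) for (j in 1:d[4])
    y3[bb, c, i, j] <- xs[[3]][bb, c, i, j] * g3[c, j]
  y4 <- oracle_conv2d(xs[[4]], fb$pw4$w$value, fb$pw4$b$value)
  y4 <- gelu_ref(y4)
  y4 <- oracle_conv2d(y4, fb$dw4$w$value, fb$dw4$b$value, pad = 1, groups = c4)
  cat4 <- array(0, dim(x))
  cat4[, 1:c4, , ] <- y1
  cat4[, c4 + 1:c4, , ] <- y2
  cat4[, 2 * c4 + 1:c4, , ] <- y3
  cat4[, 3 * c4 + 1:c4, , ] <- y4
  z <- oracle_groupnorm(cat4, fb$gn_mid$gamma$value, fb$gn_mid$beta$value, cfg$gn_groups)
  z <- oracle_conv2d(z, fb$dw_out$w$value, fb$dw_out$b$value, pad = 1, groups = C)
  z <- gelu_ref(z)
  oracle_conv2d(z, fb$pw_out$w$value, fb$pw_out$b$value)
}

# brute-force all-pairs directed nearest-neighbour distances between the
# foreground pixel sets of two masks (0-based coordinates, pixel units)
brute_directed <- function(A, B) {
  fa <- which(A == 1, arr.ind = TRUE) - 1
  fb <- which(B == 1, arr.ind = TRUE) - 1
  apply(fa, 1, function(a) sqrt(min((fb[, 1] - a[1])^2 + (fb[, 2] - a[2])^2)))
}

brute_hd <- function(A, B, percentile = 95) {
  q <- percentile / 100
  max(quantile(brute_directed(A, B), q, type = 7, names = FALSE),
      quantile(brute_directed(B, A), q, type = 7, names = FALSE))
}

random_blob_mask <- function(n, seed, p = 0.1) {
  set.seed(seed)
  m <- matrix(0L, n, n)
  m[sample(n * n, max(3, rbinom(1, n * n, p)))] <- 1L
  m
}

# --- shared fixtures --------------------------------------------------------

# give every batch-norm layer non-trivial running moments and affine terms so
# that eval-mode oracle comparisons exercise them
randomize_norm_layers <- function(module, seed = 1) {
  set.seed(seed)
  walk <- function(x) {
    if (is.list(x) && !inherits(x, "ag_tensor")) {
      if (!is.null(x$kind) && x$kind %in% c("bn", "gn")) {
        n <- length(x$gamma$value)
        x$gamma$value[] <- runif(n, 0.5, 1.5)
        x$beta$value[] <- rnorm(n, sd = 0.3)
        if (x$kind == "bn") {
          x$stats$rm <- rnorm(n, sd = 0.3)
          x$stats$rv <- runif(n, 0.5, 1.5)
        }
      }
      for (el in x) if (!is.null(el)) walk(el)
    }
  }
  walk(module)
  invisible(module)
}

rand_arr <- function(dims, seed) {
  set.seed(seed)
  array(rnorm(prod(dims)), dims)
}

tiny_ntsm_config <- function(seed = 3L, use_da = TRUE) {
  ntsm_config(stage_channels = c(8L, 16L, 32L), fhpa_encoder_stages = c(2L, 3L),
              fhpa_decoder_stages = 1L, deep_supervision_levels = 2L,
              use_da = use_da, da = da_config(out_channels = 8L), seed = seed)
}

make_synthetic_samples <- function(n, delta = 0.1, seed = 11L, size = 64L, i0 = 0L) {
  cfg <- synthetic_config(image_size = c(size, size), contrast_delta = delta,
                          seed = seed)
  lapply(seq_len(n), function(i) generate_sample(cfg, i0 + i))
}
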