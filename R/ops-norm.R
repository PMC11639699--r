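# Normalization ops.  All use biased (population) variance and eps = 1e-5.

norm_eps <- 1e-5

# channel-major matrix view: rows are (b,h,w) samples, one column per channel
to_cm <- function(v) {
  d <- dim(v)
  matrix(aperm(v, c(1, 3, 4, 2)), ncol = d[2])
}
from_cm <- function(m, d) {
  aperm(array(m, dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
}

#' Batch normalization (autograd)
#'
#' Normalizes per channel over (batch, height, width).  In training mode uses
#' batch moments and updates the running moments held in `stats` (an
#' environment with `rm`, `rv`); in inference mode uses the running moments.
#'
#' @param x input `ag_tensor` (b, C, h, w); `gamma`, `beta` per-channel affine
#'   parameters; `stats` environment; `momentum` running-moment update rate.
#' @keywords internal
ag_batchnorm <- function(x, gamma, beta, stats, momentum = 0.1) {
  v <- x$value; d <- dim(v); C <- d[2]
  gv <- as.numeric(gamma$value); bv <- as.numeric(beta$value)
  n <- d[1] * d[3] * d[4]
  if (the$training) {
    mo <- .cpp_channel_moments(v)
    mu <- mo[, 1]; va <- mo[, 2]
    stats$rm <- (1 - momentum) * stats$rm + momentum * mu
    stats$rv <- (1 - momentum) * stats$rv + momentum * va
  } else {
    mu <- stats$rm
    va <- stats$rv
  }
  inv <- 1 / sqrt(va + norm_eps)
  xhat <- .cpp_channel_affine(v, inv, -mu * inv)
  y <- .cpp_channel_affine(xhat, gv, bv)
  training <- the$training
  ag_node(y, list(x, gamma, beta), function(g) {
    dgamma <- .cpp_channel_dot(g, xhat)
    dbeta <- .cpp_channel_dot(g, NULL)
    if (training) {
      # dx = inv * gamma * (g - mean(g) - xhat * mean(g * xhat)) per channel
      dx <- .cpp_channel_affine(g, gv * inv, -dbeta * gv * inv / n) -
        .cpp_channel_affine(xhat, dgamma * gv * inv / n, rep(0, C))
    } else {
      dx <- .cpp_channel_affine(g, gv * inv, rep(0, C))
    }
    list(dx, array(dgamma, dim = C), array(dbeta, dim = C))
  })
}

#' Instance normalization (autograd, no affine terms)
#'
#' Normalizes each (batch, channel) plane over its spatial extent.
#' @keywords internal
ag_instancenorm <- function(x) {
  v <- x$value; d <- dim(v)
  nr <- d[1] * d[2]
  xm <- matrix(v, nrow = nr)           # rows: (b,c) planes, cols: h*w
  mu <- rowMeans(xm)
  va <- rowMeans(xm^2) - mu^2
  inv <- 1 / sqrt(va + norm_eps)
  xhat <- (xm - mu) * inv
  ag_node(array(xhat, dim = d), list(x), function(g) {
    gm <- matrix(g, nrow = nr)
    t1 <- gm - rowMeans(gm)
    t2 <- xhat * rowMeans(gm * xhat)
    list(array((t1 - t2) * inv, dim = d))
  })
}

#' Group normalization (autograd)
#'
#' Normalizes over (channels-in-group, height, width) per batch item and group;
#' per-channel affine parameters.
#' @keywords internal
ag_groupnorm <- function(x, gamma, beta, groups) {
  v <- x$value; d <- dim(v); C <- d[2]
  stopifnot(C %% groups == 0)
  cpg <- C %/% groups
  gv <- as.numeric(gamma$value); bv <- as.numeric(beta$value)
  # (b, cpg, G, h, w) -> (b, G, cpg, h, w) -> rows (b,G)
  va5 <- aperm(array(v, dim = c(d[1], cpg, groups, d[3], d[4])), c(1, 3, 2, 4, 5))
  nr <- d[1] * groups
  xm <- matrix(va5, nrow = nr)
  mu <- rowMeans(xm)
  sg2 <- rowMeans(xm^2) - mu^2
  inv <- 1 / sqrt(sg2 + norm_eps)
  xhat_m <- (xm - mu) * inv
  xhat <- array(aperm(array(xhat_m, dim = c(d[1], groups, cpg, d[3], d[4])),
                      c(1, 3, 2, 4, 5)), dim = d)
  gfull <- bcast_to(array(gv, dim = c(1L, C, 1L, 1L)), d)
  bfull <- bcast_to(array(bv, dim = c(1L, C, 1L, 1L)), d)
  ag_node(xhat * gfull + bfull, list(x, gamma, beta), function(g) {
    dgamma <- bias_grad(g * xhat)
    dbeta <- bias_grad(g)
    dxh <- g * gfull
    dm <- matrix(aperm(array(dxh, dim = c(d[1], cpg, groups, d[3], d[4])),
                       c(1, 3, 2, 4, 5)), nrow = nr)
    t1 <- dm - rowMeans(dm)
    t2 <- xhat_m * rowMeans(dm * xhat_m)
    dxm <- (t1 - t2) * inv
    dx <- array(aperm(array(dxm, dim = c(d[1], groups, cpg, d[3], d[4])),
                      c(1, 3, 2, 4, 5)), dim = d)
    list(dx, array(dgamma, dim = C), array(dbeta, dim = C))
  })
}
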