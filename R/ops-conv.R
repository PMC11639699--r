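# Autograd wrappers around the compiled convolution kernels, plus transposed
# convolution (built from the adjoint kernels) and bilinear resizing.

#' 2-D convolution (autograd)
#'
#' @param x `ag_tensor` of shape (b, Ci, h, w).
#' @param w `ag_tensor` weight of shape (Co, Ci/groups, kh, kw).
#' @param b optional `ag_tensor` bias of length Co.
#' @param stride,dilation,padding,groups integer convolution hyper-parameters.
#' @keywords internal
ag_conv2d <- function(x, w, b = NULL, stride = 1L, dilation = 1L,
                      padding = 0L, groups = 1L) {
  xv <- x$value; wv <- w$value
  dx <- dim(xv); dw <- dim(wv)
  stopifnot(length(dx) == 4L, dx[2] == dw[2] * groups)
  bv <- if (!is.null(b)) as.numeric(b$value) else NULL
  y <- .cpp_conv2d_fw(xv, wv, bv, as.integer(stride), as.integer(dilation),
                      as.integer(padding), as.integer(groups))
  dy <- dim(y)
  prof_add(prod(dy) * dw[2] * dw[3] * dw[4])
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(y, parents, function(g) {
    gx <- .cpp_conv2d_bw_input(g, wv, dx[3], dx[4], as.integer(stride),
                               as.integer(dilation), as.integer(padding),
                               as.integer(groups))
    gw <- .cpp_conv2d_bw_weight(xv, g, dw[3], dw[4], as.integer(stride),
                                as.integer(dilation), as.integer(padding),
                                as.integer(groups))
    gb <- if (!is.null(b)) array(bias_grad(g), dim = dim(b$value)) else NULL
    if (is.null(b)) list(gx, gw) else list(gx, gw, gb)
  })
}

# sum an output gradient over (batch, h, w) per channel
bias_grad <- function(g) {
  d <- dim(g)
  colSums(matrix(aperm(g, c(1, 3, 4, 2)), ncol = d[2]))
}

#' Transposed 2-D convolution (autograd)
#'
#' Weight shape follows the (in, out, kh, kw) convention.  Used for x2
#' upsampling in the decoder (kernel = stride, no padding).
#' @keywords internal
ag_conv_transpose2d <- function(x, w, b = NULL, stride = 2L) {
  xv <- x$value; wv <- w$value
  dx <- dim(xv); dw <- dim(wv)
  stopifnot(dx[2] == dw[1])
  oh <- (dx[3] - 1L) * stride + dw[3]
  ow <- (dx[4] - 1L) * stride + dw[4]
  y <- .cpp_conv2d_bw_input(xv, wv, oh, ow, as.integer(stride), 1L, 0L, 1L)
  prof_add(prod(dx) * dw[2] * dw[3] * dw[4])
  if (!is.null(b)) {
    bv <- as.numeric(b$value)
    y <- y + bcast_to(array(bv, dim = c(1L, dw[2], 1L, 1L)), dim(y))
  }
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(y, parents, function(g) {
    gx <- .cpp_conv2d_fw(g, wv, NULL, as.integer(stride), 1L, 0L, 1L)
    gw <- .cpp_conv2d_bw_weight(g, xv, dw[3], dw[4], as.integer(stride), 1L, 0L, 1L)
    gb <- if (!is.null(b)) array(bias_grad(g), dim = dim(b$value)) else NULL
    if (is.null(b)) list(gx, gw) else list(gx, gw, gb)
  })
}

# Interpolation weight matrix (out_n x in_n) for 1-D bilinear resizing with
# half-pixel alignment (align_corners = FALSE convention).
bilinear_matrix <- function(in_n, out_n) {
  M <- matrix(0, out_n, in_n)
  if (in_n == 1L) { M[, 1] <- 1; return(M) }
  src <- (seq_len(out_n) - 0.5) * in_n / out_n - 0.5
  src <- pmin(pmax(src, 0), in_n - 1)
  i0 <- floor(src)
  fr <- src - i0
  i1 <- pmin(i0 + 1, in_n - 1)
  for (k in seq_len(out_n)) {
    M[k, i0[k] + 1] <- M[k, i0[k] + 1] + (1 - fr[k])
    M[k, i1[k] + 1] <- M[k, i1[k] + 1] + fr[k]
  }
  M
}

#' Bilinear resize of the two trailing axes (autograd)
#'
#' Half-pixel (align_corners = FALSE) sampling; exact adjoint backward.
#' @keywords internal
ag_bilinear_resize <- function(x, out_h, out_w) {
  v <- x$value; d <- dim(v)
  stopifnot(out_h >= 1L, out_w >= 1L)
  if (d[3] == out_h && d[4] == out_w) return(ag_node(v, list(x), function(g) list(g)))
  Mh <- bilinear_matrix(d[3], out_h)
  Mw <- bilinear_matrix(d[4], out_w)
  nbc <- d[1] * d[2]
  # (b*C, h, w) slabs; out = Mh %*% slab %*% t(Mw)
  vm <- array(v, dim = c(nbc, d[3], d[4]))
  out <- array(0, dim = c(nbc, out_h, out_w))
  for (k in seq_len(nbc)) out[k, , ] <- Mh %*% matrix(vm[k, , ], d[3], d[4]) %*% t(Mw)
  prof_add(4 * nbc * out_h * out_w)
  ag_node(array(out, dim = c(d[1], d[2], out_h, out_w)), list(x), function(g) {
    gm <- array(g, dim = c(nbc, out_h, out_w))
    gx <- array(0, dim = c(nbc, d[3], d[4]))
    for (k in seq_len(nbc)) gx[k, , ] <- t(Mh) %*% matrix(gm[k, , ], out_h, out_w) %*% Mw
    list(array(gx, dim = d))
  })
}
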