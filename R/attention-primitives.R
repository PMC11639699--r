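# Attention primitives: the low-level feature extractor (LFE) -- a dual
# 1-D-pooled coordinate-gating attention -- and Hadamard-product attention
# (HPA) -- a learnable grid, bilinearly resized to the input extent, passed
# through a depthwise convolution and multiplied elementwise onto the input.

as_ag <- function(x) if (is_ag(x)) x else ag_tensor(x)

check_rank4 <- function(x, what = "input") {
  d <- dim(x$value)
  if (length(d) != 4L)
    stop(what, " must be a rank-4 (batch, channel, height, width) tensor, got rank ", length(d))
  if (d[3] < 1L || d[4] < 1L)
    stop(what, " spatial extents must be >= 1, got (", d[3], ", ", d[4], ")")
  invisible(d)
}

#' Build a low-level feature extractor (LFE)
#'
#' The LFE pools its input along each spatial axis separately, mixes the two
#' pooled strips through a shared 1x1 bottleneck (batch norm + swish), and
#' turns each strip into a sigmoid gate that rescales the input -- a
#' coordinate-attention style operator.
#'
#' @param channels input/output channel count.
#' @param reduction bottleneck reduction ratio; bottleneck width is
#'   `max(channels / reduction, 4)`.
#' @return an LFE module usable with [lfe_forward()].
#' @export
new_lfe <- function(channels, reduction = 8L) {
  mid <- max(channels %/% reduction, 4L)
  m <- list(kind = "lfe", channels = as.integer(channels), mid = mid,
            squeeze = new_conv2d(channels, mid, 1L),
            bn = new_batchnorm(mid),
            gate_h = new_conv2d(mid, channels, 1L),
            gate_w = new_conv2d(mid, channels, 1L))
  class(m) <- c("ntsm_lfe", "ntsm_module")
  m
}

#' LFE forward pass
#'
#' @param lfe module from [new_lfe()].
#' @param x rank-4 tensor (array or `ag_tensor`) of shape (b, C, h, w) with
#'   C = `lfe$channels`.
#' @return `ag_tensor` of the same shape: `x * g_h * g_w` with one gate per
#'   spatial axis, each in (0, 1).
#' @export
lfe_forward <- function(lfe, x) {
  x <- as_ag(x)
  d <- check_rank4(x)
  if (d[2] != lfe$channels)
    stop("LFE built for ", lfe$channels, " channels, input has ", d[2])
  h <- d[3]; w <- d[4]
  ph <- ag_pool_w(x)                                  # (b, C, h, 1)
  pw <- ag_permute(ag_pool_h(x), c(1, 2, 4, 3))       # (b, C, w, 1)
  mid <- ag_swish(fw_batchnorm(lfe$bn, fw_conv2d(lfe$squeeze, ag_concat(list(ph, pw), 3L))))
  mh <- ag_slice(mid, 3L, seq_len(h))                 # (b, mid, h, 1)
  mw <- ag_permute(ag_slice(mid, 3L, h + seq_len(w)), c(1, 2, 4, 3))  # (b, mid, 1, w)
  gh <- ag_sigmoid(fw_conv2d(lfe$gate_h, mh))
  gw <- ag_sigmoid(fw_conv2d(lfe$gate_w, mw))
  ag_bmul(ag_bmul(x, gh), gw)
}

#' Build a Hadamard-product attention (HPA) operator
#'
#' Stores a learnable grid `p` of extent `nominal_grid` (with `n_slices`
#' independent slices) plus a depthwise 3x3 convolution, one filter per slice.
#' At each forward call `p` is bilinearly resized to the input's two trailing
#' axes, convolved, and multiplied onto the input (broadcast over leading
#' axes).
#'
#' @param nominal_grid integer pair, stored extent of `p` (each >= 2, bilinear
#'   resizing needs two support points per axis).
#' @param n_slices number of independent `p` slices / depthwise filters; must
#'   equal the input's second extent, or 1 to share one gate across it.
#' @param init_std standard deviation of the truncated-normal initialization.
#' @return an HPA module usable with [hpa_forward()].
#' @export
new_hpa <- function(nominal_grid = c(16L, 16L), n_slices = 1L, init_std = 0.02) {
  if (any(nominal_grid < 2L)) stop("nominal_grid extents must be >= 2")
  if (init_std <= 0) stop("init_std must be positive")
  m <- list(kind = "hpa",
            nominal_grid = as.integer(nominal_grid),
            n_slices = as.integer(n_slices),
            p = ag_tensor(trunc_normal(c(1L, n_slices, nominal_grid[1], nominal_grid[2]),
                                       init_std), TRUE),
            dw = new_conv2d(n_slices, n_slices, 3L, groups = n_slices))
  class(m) <- c("ntsm_hpa", "ntsm_module")
  m
}

#' HPA forward pass
#'
#' @param x rank-4 tensor; axes 3 and 4 are the attended axes; axis 2 must
#'   match `hpa$n_slices` (or `n_slices` is 1 and the single gate broadcasts).
#' @param hpa module from [new_hpa()].
#' @return `ag_tensor`, same shape as `x`: `DW(BI(p)) ⊙ x`.
#' @export
hpa_forward <- function(x, hpa) {
  x <- as_ag(x)
  d <- check_rank4(x, "HPA input")
  if (hpa$n_slices != 1L && d[2] != hpa$n_slices)
    stop("HPA built with ", hpa$n_slices, " slices, input axis-2 extent is ", d[2])
  gate <- ag_bilinear_resize(hpa$p, d[3], d[4])
  gate <- fw_conv2d(hpa$dw, gate)                     # (1, n_slices, A1, A2)
  ag_bmul(x, gate)
}
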