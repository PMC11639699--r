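# Feature-hierarchy pyramid attention (FHPA): group-normalize, chunk the
# channels into four equal groups, apply Hadamard-product attention to three
# of them along different axis pairs (height-width, channel-height,
# channel-width), run the fourth through a depthwise-separable path, then
# re-fuse.  Replaces a standard 3x3 convolution block at far lower parameter
# cost for wide stages.

#' FHPA block configuration
#'
#' @param channels channel width; must be divisible by 4 (the block chunks the
#'   channels into four equal groups).
#' @param nominal_grid stored extent of each learnable attention grid.
#' @param init_std initialization std of the grids.
#' @param gn_groups group count of the two group-normalization layers; must
#'   divide `channels`.
#' @export
fhpa_config <- function(channels, nominal_grid = c(16L, 16L), init_std = 0.02,
                        gn_groups = 4L) {
  if (channels %% 4L != 0L)
    stop("FHPA channels must be divisible by 4, got ", channels)
  if (channels %% gn_groups != 0L)
    stop("gn_groups (", gn_groups, ") must divide channels (", channels, ")")
  structure(list(channels = as.integer(channels),
                 nominal_grid = as.integer(nominal_grid),
                 init_std = init_std, gn_groups = as.integer(gn_groups)),
            class = "fhpa_config")
}

#' Build an FHPA block
#' @param cfg a [fhpa_config()].
#' @export
new_fhpa <- function(cfg) {
  C <- cfg$channels; c4 <- C %/% 4L
  m <- list(kind = "fhpa", cfg = cfg,
            gn_in = new_groupnorm(C, cfg$gn_groups),
            # height-width attention: one grid slice + filter per group channel
            hpa_xy = new_hpa(cfg$nominal_grid, n_slices = c4, init_std = cfg$init_std),
            # channel-height / channel-width attention: the attended plane is
            # (group-channel, h) resp. (group-channel, w); batch and the spare
            # spatial axis broadcast, so a single grid slice + filter suffices
            hpa_zx = new_hpa(cfg$nominal_grid, n_slices = 1L, init_std = cfg$init_std),
            hpa_zy = new_hpa(cfg$nominal_grid, n_slices = 1L, init_std = cfg$init_std),
            # group 4: pointwise -> GeLU -> depthwise 3x3
            pw4 = new_conv2d(c4, c4, 1L),
            dw4 = new_conv2d(c4, c4, 3L, groups = c4),
            gn_mid = new_groupnorm(C, cfg$gn_groups),
            # fusion: depthwise 3x3 -> GeLU -> pointwise
            dw_out = new_conv2d(C, C, 3L, groups = C),
            pw_out = new_conv2d(C, C, 1L))
  class(m) <- c("ntsm_fhpa", "ntsm_module")
  m
}

#' FHPA forward pass
#'
#' @param fhpa module from [new_fhpa()].
#' @param x rank-4 tensor (b, channels, h, w).
#' @return `ag_tensor` of the same shape.
#' @export
fhpa_forward <- function(fhpa, x) {
  x <- as_ag(x)
  d <- check_rank4(x)
  C <- fhpa$cfg$channels
  if (d[2] != C) stop("FHPA built for ", C, " channels, input has ", d[2])
  c4 <- C %/% 4L
  g <- fw_groupnorm(fhpa$gn_in, x)
  xs <- lapply(0:3, function(k) ag_slice(g, 2L, k * c4 + seq_len(c4)))
  y1 <- hpa_forward(xs[[1]], fhpa$hpa_xy)
  # zx: attend the (group-channel, height) plane; width becomes batch-like
  x2p <- ag_permute(xs[[2]], c(1, 4, 2, 3))
  y2 <- ag_permute(hpa_forward(x2p, fhpa$hpa_zx), c(1, 3, 4, 2))
  # zy: attend the (group-channel, width) plane; height becomes batch-like
  x3p <- ag_permute(xs[[3]], c(1, 3, 2, 4))
  y3 <- ag_permute(hpa_forward(x3p, fhpa$hpa_zy), c(1, 3, 2, 4))
  y4 <- fw_conv2d(fhpa$dw4, ag_gelu(fw_conv2d(fhpa$pw4, xs[[4]])))
  cat4 <- ag_concat(list(y1, y2, y3, y4), 2L)
  fw_conv2d(fhpa$pw_out, ag_gelu(fw_conv2d(fhpa$dw_out, fw_groupnorm(fhpa$gn_mid, cat4))))
}

#' Closed-form learnable-scalar count of an FHPA block
#'
#' Counts group-norm affine terms, the three attention grids, and all
#' depthwise/pointwise kernels and biases, without building the block.
#' Sub-quadratic in the channel width: the only quadratic terms are the two
#' pointwise convolutions, against `9 C^2 + C` for the 3x3 convolution the
#' block replaces.
#'
#' @param cfg a [fhpa_config()].
#' @return integer parameter count, equal to `count_params(new_fhpa(cfg))`.
#' @export
fhpa_param_count <- function(cfg) {
  C <- cfg$channels; c4 <- C %/% 4L
  g <- prod(cfg$nominal_grid)
  2L * C +                      # gn_in
    c4 * g + (9L * c4 + c4) +   # hpa_xy: grids + depthwise filters + bias
    2L * (g + 9L + 1L) +        # hpa_zx, hpa_zy
    (c4 * c4 + c4) +            # pw4
    (9L * c4 + c4) +            # dw4
    2L * C +                    # gn_mid
    (9L * C + C) +              # dw_out
    (C * C + C)                 # pw_out
}
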