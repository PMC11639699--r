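# Difference-association (DA) module: the local-context-difference (LCD)
# submodule -- pairs of dilated "local vs context" branches whose instance-
# normalized difference sharpens low-level contrast -- and the logical-
# semantic-association (LSA) submodule -- four dilated convolutional branches
# fused with a shortcut, meant to separate true lesions from high-contrast
# distractors such as teeth.

#' DA module configuration
#'
#' @param out_channels channel width of the DA output (>= 4).
#' @param lcd_context_dilations dilations of the two context branches
#'   (default 4 and 8).
#' @param lcd_local_dilation dilation of the local branches (default 1).
#' @param lsa_final_dilation dilation of the final 3x3 convolutions in the LSA
#'   branches and fusion (default 7).
#' @param negative_slope LeakyReLU negative-side slope.
#' @param lcd_fusion how the two contrast maps merge into `F_c`:
#'   `"concat"` (channel concatenation + 1x1 reduction, the default) or
#'   `"sum"`.
#' @return a `da_config` list.
#' @export
da_config <- function(out_channels = 32L,
                      lcd_context_dilations = c(4L, 8L),
                      lcd_local_dilation = 1L,
                      lsa_final_dilation = 7L,
                      negative_slope = 0.01,
                      lcd_fusion = c("concat", "sum")) {
  lcd_fusion <- match.arg(lcd_fusion)
  if (out_channels < 4L) stop("out_channels must be >= 4")
  if (any(c(lcd_context_dilations, lcd_local_dilation, lsa_final_dilation) < 1L))
    stop("dilations must be >= 1")
  structure(list(out_channels = as.integer(out_channels),
                 lcd_context_dilations = as.integer(lcd_context_dilations),
                 lcd_local_dilation = as.integer(lcd_local_dilation),
                 lsa_final_dilation = as.integer(lsa_final_dilation),
                 negative_slope = negative_slope,
                 lcd_fusion = lcd_fusion),
            class = "da_config")
}

#' Low-level comparison extractor (LCE) contrast operator
#'
#' `LeakyReLU(InstanceNorm(F_local - F_context))`: the per-plane normalized
#' difference between a local-receptive-field feature and a wider-context
#' feature.  Zero wherever the difference is spatially constant per plane.
#'
#' @param f_local,f_context rank-4 tensors of identical shape.
#' @param negative_slope LeakyReLU slope.
#' @return `ag_tensor` of the same shape.
#' @export
lce_contrast <- function(f_local, f_context, negative_slope = 0.01) {
  f_local <- as_ag(f_local); f_context <- as_ag(f_context)
  dl <- dim(f_local$value); dc <- dim(f_context$value)
  if (!identical(dl, dc))
    stop("shape mismatch in lce_contrast: local is (", paste(dl, collapse = ","),
         "), context is (", paste(dc, collapse = ","), ")")
  ag_leakyrelu(ag_instancenorm(ag_sub(f_local, f_context)), negative_slope)
}

# one LCE unit: dilated local + context branches, each conv -> LFE
new_lce_unit <- function(in_ch, out_ch, local_dil, context_dil) {
  list(conv_local = new_conv2d(in_ch, out_ch, 3L, dilation = local_dil),
       lfe_local = new_lfe(out_ch),
       conv_context = new_conv2d(in_ch, out_ch, 3L, dilation = context_dil),
       lfe_context = new_lfe(out_ch))
}

#' Build the LCD submodule
#'
#' Two LCE units (context dilations 4 and 8 by default), fused into a single
#' contrast map of `cfg$out_channels` channels.
#'
#' @param in_channels input channel count (3 when run on the raw RGB image).
#' @param cfg a [da_config()].
#' @export
new_lcd <- function(in_channels, cfg = da_config()) {
  oc <- cfg$out_channels
  m <- list(kind = "lcd", cfg = cfg, in_channels = as.integer(in_channels),
            unit_a = new_lce_unit(in_channels, oc, cfg$lcd_local_dilation,
                                  cfg$lcd_context_dilations[1]),
            unit_b = new_lce_unit(in_channels, oc, cfg$lcd_local_dilation,
                                  cfg$lcd_context_dilations[2]),
            fuse = if (cfg$lcd_fusion == "concat") new_conv2d(2L * oc, oc, 1L) else NULL)
  class(m) <- c("ntsm_lcd", "ntsm_module")
  m
}

lce_unit_forward <- function(u, x, slope) {
  f_local <- lfe_forward(u$lfe_local, fw_conv2d(u$conv_local, x))
  f_context <- lfe_forward(u$lfe_context, fw_conv2d(u$conv_context, x))
  lce_contrast(f_local, f_context, slope)
}

#' LCD forward pass
#'
#' @param lcd module from [new_lcd()].
#' @param x rank-4 input (b, in_channels, h, w).
#' @return `ag_tensor` `F_c` of shape (b, out_channels, h, w).
#' @export
lcd_forward <- function(lcd, x) {
  x <- as_ag(x)
  d <- check_rank4(x)
  if (d[2] != lcd$in_channels)
    stop("LCD built for ", lcd$in_channels, " input channels, got ", d[2])
  slope <- lcd$cfg$negative_slope
  ca <- lce_unit_forward(lcd$unit_a, x, slope)
  cb <- lce_unit_forward(lcd$unit_b, x, slope)
  if (lcd$cfg$lcd_fusion == "concat") {
    fw_conv2d(lcd$fuse, ag_concat(list(ca, cb), 2L))
  } else {
    ag_add(ca, cb)
  }
}

# conv + BN (+ optional GeLU) helper for LSA branches
new_cbg <- function(in_ch, out_ch, k, dilation = 1L) {
  list(conv = new_conv2d(in_ch, out_ch, k, dilation = dilation),
       bn = new_batchnorm(out_ch))
}
fw_cbg <- function(l, x, gelu = TRUE) {
  y <- fw_batchnorm(l$bn, fw_conv2d(l$conv, x))
  if (gelu) ag_gelu(y) else y
}

#' Build the LSA submodule
#'
#' Four branches over `F_c`: (1) 1x1; (2) 1x1 -> 7x7 -> dilated 3x3;
#' (3) and (4) 1x1 -> 7x7 -> 7x7 -> dilated 3x3 with independent weights.
#' Batch norm after every convolution, GeLU after all but the last of each
#' branch.  The concatenated branches pass a dilated 3x3 fusion and are added
#' to a 1x1 shortcut of the input, then LeakyReLU.
#'
#' @param cfg a [da_config()]; all branch widths equal `cfg$out_channels`.
#' @export
new_lsa <- function(cfg = da_config()) {
  oc <- cfg$out_channels
  fd <- cfg$lsa_final_dilation
  deep_branch <- function() list(new_cbg(oc, oc, 1L), new_cbg(oc, oc, 7L),
                                 new_cbg(oc, oc, 7L), new_cbg(oc, oc, 3L, dilation = fd))
  m <- list(kind = "lsa", cfg = cfg,
            b1 = new_cbg(oc, oc, 1L),
            b2 = list(new_cbg(oc, oc, 1L), new_cbg(oc, oc, 7L),
                      new_cbg(oc, oc, 3L, dilation = fd)),
            b3 = deep_branch(),
            b4 = deep_branch(),
            fuse = new_cbg(4L * oc, oc, 3L, dilation = fd),
            shortcut = new_cbg(oc, oc, 1L))
  class(m) <- c("ntsm_lsa", "ntsm_module")
  m
}

lsa_branch_forward <- function(branch, x) {
  n <- length(branch)
  for (i in seq_len(n)) x <- fw_cbg(branch[[i]], x, gelu = i < n)
  x
}

#' LSA forward pass
#'
#' @param lsa module from [new_lsa()].
#' @param f_c rank-4 input with `cfg$out_channels` channels (the LCD output).
#' @return `ag_tensor` `F_s`, same shape as the input.
#' @export
lsa_forward <- function(lsa, f_c) {
  f_c <- as_ag(f_c)
  d <- check_rank4(f_c)
  oc <- lsa$cfg$out_channels
  if (d[2] != oc)
    stop("LSA expects ", oc, " input channels, got ", d[2])
  y1 <- fw_cbg(lsa$b1, f_c, gelu = FALSE)
  y2 <- lsa_branch_forward(lsa$b2, f_c)
  y3 <- lsa_branch_forward(lsa$b3, f_c)
  y4 <- lsa_branch_forward(lsa$b4, f_c)
  f_t <- ag_concat(list(y1, y2, y3, y4), 2L)
  fused <- fw_cbg(lsa$fuse, f_t, gelu = FALSE)
  short <- fw_cbg(lsa$shortcut, f_c, gelu = FALSE)
  ag_leakyrelu(ag_add(fused, short), lsa$cfg$negative_slope)
}

#' Build the full DA module (LCD followed by LSA)
#'
#' @param in_channels input channel count.
#' @param cfg a [da_config()].
#' @export
new_da <- function(in_channels, cfg = da_config()) {
  m <- list(kind = "da", cfg = cfg,
            lcd = new_lcd(in_channels, cfg),
            lsa = new_lsa(cfg))
  class(m) <- c("ntsm_da", "ntsm_module")
  m
}

#' DA forward pass: `F_s = LSA(LCD(x))`
#' @param da module from [new_da()]; `x` rank-4 input.
#' @export
da_forward <- function(da, x) lsa_forward(da$lsa, lcd_forward(da$lcd, x))
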