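# NTSM assembly: difference-association module on the raw image, a pinned
# nnU-Net-style 2-D encoder-decoder (two 3x3 conv blocks per stage, strided
# downsampling, transposed-conv upsampling, skip concatenation), FHPA blocks
# substituted for the second conv block of configured stages, and 1x1
# deep-supervision heads.

#' NTSM model configuration
#'
#' @param stage_channels channel widths of the encoder stages, shallow to
#'   deep; the decoder mirrors them.
#' @param fhpa_encoder_stages encoder stage indices (1-based from the
#'   shallowest) whose second conv block is replaced by FHPA; default the last
#'   three of the five stages.
#' @param fhpa_decoder_stages decoder stage indices (1-based from the deepest)
#'   replaced by FHPA; default the first.
#' @param use_da run the difference-association module on the input image and
#'   fuse its output with the stem features.
#' @param da a [da_config()]; its `out_channels` is forced to
#'   `stage_channels[1]`.
#' @param deep_supervision_levels number of supervised decoder scales
#'   (finest first); at most the number of decoder stages.
#' @param num_classes output classes (2: background/lesion).
#' @param seed RNG seed for weight initialization.
#' @param hpa_nominal_grid,gn_groups forwarded to [fhpa_config()].
#' @param negative_slope LeakyReLU slope of the backbone conv blocks.
#' @return an `ntsm_config` list.
#' @export
ntsm_config <- function(stage_channels = c(32L, 64L, 128L, 256L, 512L),
                        fhpa_encoder_stages = tail(seq_along(stage_channels), 3L),
                        fhpa_decoder_stages = 1L,
                        use_da = TRUE,
                        da = da_config(out_channels = stage_channels[1]),
                        deep_supervision_levels = 3L,
                        num_classes = 2L,
                        seed = 1L,
                        hpa_nominal_grid = c(16L, 16L),
                        gn_groups = 4L,
                        negative_slope = 0.01) {
  S <- length(stage_channels)
  if (S < 2L) stop("need at least 2 stages")
  if (num_classes < 1L) stop("num_classes must be positive")
  fhpa_encoder_stages <- as.integer(fhpa_encoder_stages)
  fhpa_decoder_stages <- as.integer(fhpa_decoder_stages)
  bad <- setdiff(fhpa_encoder_stages, seq_len(S))
  if (length(bad)) stop("invalid fhpa_encoder_stages: ", paste(bad, collapse = ", "))
  bad <- setdiff(fhpa_decoder_stages, seq_len(S - 1L))
  if (length(bad)) stop("invalid fhpa_decoder_stages: ", paste(bad, collapse = ", "))
  for (s in fhpa_encoder_stages)
    if (stage_channels[s] %% 4L != 0L)
      stop("FHPA encoder stage ", s, " has width ", stage_channels[s],
           ", not divisible by 4")
  for (d in fhpa_decoder_stages)
    if (stage_channels[S - d] %% 4L != 0L)
      stop("FHPA decoder stage ", d, " has width ", stage_channels[S - d],
           ", not divisible by 4")
  if (deep_supervision_levels > S - 1L)
    stop("deep_supervision_levels (", deep_supervision_levels,
         ") exceeds the ", S - 1L, " decoder stages")
  da$out_channels <- as.integer(stage_channels[1])
  structure(list(stage_channels = as.integer(stage_channels),
                 fhpa_encoder_stages = fhpa_encoder_stages,
                 fhpa_decoder_stages = fhpa_decoder_stages,
                 use_da = isTRUE(use_da), da = da,
                 deep_supervision_levels = as.integer(deep_supervision_levels),
                 num_classes = as.integer(num_classes),
                 seed = as.integer(seed),
                 hpa_nominal_grid = as.integer(hpa_nominal_grid),
                 gn_groups = as.integer(gn_groups),
                 negative_slope = negative_slope),
            class = "ntsm_config")
}

new_conv_block <- function(in_ch, out_ch, stride = 1L) {
  list(conv = new_conv2d(in_ch, out_ch, 3L, stride = stride),
       bn = new_batchnorm(out_ch))
}
fw_conv_block <- function(blk, x, slope) {
  ag_leakyrelu(fw_batchnorm(blk$bn, fw_conv2d(blk$conv, x)), slope)
}

stage_block2 <- function(cfg, ch, is_fhpa) {
  if (is_fhpa)
    new_fhpa(fhpa_config(ch, nominal_grid = cfg$hpa_nominal_grid,
                         gn_groups = if (ch %% cfg$gn_groups == 0L) cfg$gn_groups else 1L))
  else new_conv_block(ch, ch)
}
fw_block2 <- function(blk, x, slope) {
  if (inherits(blk, "ntsm_fhpa")) fhpa_forward(blk, x) else fw_conv_block(blk, x, slope)
}

#' Build an NTSM model
#'
#' Deterministic given `config$seed`: two builds from an equal config have
#' identical parameter tensors.
#'
#' @param config an [ntsm_config()].
#' @return an `ntsm_model` list (config + module tree).
#' @export
build_ntsm <- function(config) {
  stopifnot(inherits(config, "ntsm_config"))
  set.seed(config$seed)
  ch <- config$stage_channels
  S <- length(ch)
  enc <- vector("list", S)
  for (s in seq_len(S)) {
    in_ch <- if (s == 1L) 3L else ch[s - 1L]
    enc[[s]] <- list(block1 = new_conv_block(in_ch, ch[s], stride = if (s == 1L) 1L else 2L),
                     block2 = stage_block2(config, ch[s], s %in% config$fhpa_encoder_stages))
  }
  da <- NULL; da_fuse <- NULL
  if (config$use_da) {
    da <- new_da(3L, config$da)
    da_fuse <- new_conv2d(2L * ch[1], ch[1], 1L)
  }
  dec <- vector("list", S - 1L)
  for (d in seq_len(S - 1L)) {
    cin <- ch[S - d + 1L]; cout <- ch[S - d]
    dec[[d]] <- list(up = new_conv_transpose2d(cin, cout),
                     block1 = new_conv_block(2L * cout, cout),
                     block2 = stage_block2(config, cout, d %in% config$fhpa_decoder_stages))
  }
  heads <- vector("list", config$deep_supervision_levels)
  for (l in seq_len(config$deep_supervision_levels)) {
    # level l (finest first) hangs off decoder stage S - l
    heads[[l]] <- new_conv2d(ch[l], config$num_classes, 1L)
  }
  m <- list(config = config, encoder = enc, da = da, da_fuse = da_fuse,
            decoder = dec, heads = heads)
  class(m) <- c("ntsm_model", "ntsm_module")
  m
}

#' NTSM forward pass
#'
#' @param model an `ntsm_model`.
#' @param image rank-4 tensor (b, 3, h, w); `h` and `w` must be divisible by
#'   `2^(n_stages - 1)`.
#' @return a `segmentation_output`: list with `logits`, a list of `ag_tensor`
#'   class-logit maps, finest scale first, each half the extent of the
#'   previous.
#' @export
ntsm_forward <- function(model, image) {
  x <- as_ag(image)
  d <- check_rank4(x, "image")
  cfg <- model$config
  if (d[2] != 3L) stop("expected a 3-channel image, got ", d[2], " channels")
  S <- length(cfg$stage_channels)
  div <- 2L^(S - 1L)
  if (d[3] %% div != 0L || d[4] %% div != 0L)
    stop("spatial extents (", d[3], ", ", d[4], ") must be divisible by ",
         div, " (2^(stages-1))")
  slope <- cfg$negative_slope
  skips <- vector("list", S)
  h <- fw_conv_block(model$encoder[[1]]$block1, x, slope)
  if (cfg$use_da) {
    fs <- da_forward(model$da, x)
    h <- fw_conv2d(model$da_fuse, ag_concat(list(h, fs), 2L))
  }
  h <- fw_block2(model$encoder[[1]]$block2, h, slope)
  skips[[1]] <- h
  for (s in 2:S) {
    h <- fw_conv_block(model$encoder[[s]]$block1, h, slope)
    h <- fw_block2(model$encoder[[s]]$block2, h, slope)
    skips[[s]] <- h
  }
  dec_out <- vector("list", S - 1L)       # deepest first
  for (dd in seq_len(S - 1L)) {
    up <- fw_conv_transpose2d(model$decoder[[dd]]$up, h)
    h <- ag_concat(list(up, skips[[S - dd]]), 2L)
    h <- fw_conv_block(model$decoder[[dd]]$block1, h, slope)
    h <- fw_block2(model$decoder[[dd]]$block2, h, slope)
    dec_out[[dd]] <- h
  }
  logits <- vector("list", cfg$deep_supervision_levels)
  for (l in seq_len(cfg$deep_supervision_levels)) {
    logits[[l]] <- fw_conv2d(model$heads[[l]], dec_out[[S - l]])
  }
  structure(list(logits = logits), class = "segmentation_output")
}

# ---------------------------------------------------------------------------
# Checkpointing: parameter values + batch-norm running moments, restored onto
# a freshly built model.  The config is also written as a YAML sidecar.
# ---------------------------------------------------------------------------

#' Save model weights to a checkpoint file
#'
#' Writes the parameter tensors and batch-norm running moments (RDS format)
#' plus a human-readable YAML sidecar of the config.  Round-trips bit-exactly.
#'
#' @param model an `ntsm_model`; `path` destination file.
#' @export
save_checkpoint <- function(model, path) {
  params <- lapply(collect_params(model), function(p) p$value)
  stats <- lapply(collect_stats(model), function(s) list(rm = s$rm, rv = s$rv))
  saveRDS(list(config = model$config, params = params, stats = stats),
          path, compress = FALSE)
  yaml::write_yaml(unclass_rec(model$config), paste0(path, ".yaml"))
  invisible(path)
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else unclass(x)
}

#' Load a model from a checkpoint file
#' @param path file written by [save_checkpoint()].
#' @return an `ntsm_model` with restored weights and running moments.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_ntsm(ck$config)
  ps <- collect_params(model)
  if (length(ps) != length(ck$params))
    stop("checkpoint/config mismatch: ", length(ck$params),
         " stored parameter tensors vs ", length(ps), " in the built model")
  for (i in seq_along(ps)) ps[[i]]$value <- ck$params[[i]]
  ss <- collect_stats(model)
  for (i in seq_along(ss)) { ss[[i]]$rm <- ck$stats[[i]]$rm; ss[[i]]$rv <- ck$stats[[i]]$rv }
  model
}
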