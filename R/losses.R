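# Joint deep-supervision loss: per-scale binary cross-entropy on the
# foreground probability plus weighted soft-Dice, summed over decoder scales
# with normalized level weights.

#' Loss configuration
#'
#' @param level_weights per-scale weights, finest first; normalized to sum 1.
#' @param dice_weight weight `k` of the Dice term relative to BCE.  The
#'   default 2 makes the Dice term's foreground pull dominate early training
#'   on whole images, where lesions occupy a few percent of pixels and the
#'   pixel-mean BCE is background-dominated.
#' @param smooth additive smoothing of the soft-Dice numerator/denominator.
#' @export
loss_config <- function(level_weights = c(1, 0.5, 0.25), dice_weight = 2.0,
                        smooth = 1e-5) {
  if (any(level_weights < 0) || sum(level_weights) <= 0)
    stop("level_weights must be non-negative with positive sum")
  if (dice_weight <= 0) stop("dice_weight must be positive")
  structure(list(level_weights = level_weights / sum(level_weights),
                 dice_weight = dice_weight, smooth = smooth),
            class = "loss_config")
}

check_binary_target <- function(target) {
  u <- unique(as.vector(target))
  if (!all(u %in% c(0, 1)))
    stop("target mask must contain only {0, 1}; found ",
         paste(utils::head(setdiff(u, c(0, 1)), 5), collapse = ", "))
  invisible(target)
}

# target broadcast to (b, 1, h, w)
target_arr <- function(target, b) {
  if (length(dim(target)) == 2L)
    target <- array(rep(as.numeric(target), each = b),
                    dim = c(b, 1L, dim(target)))
  else if (length(dim(target)) == 3L)
    target <- array(as.numeric(target), dim = c(dim(target)[1], 1L, dim(target)[2:3]))
  target
}

#' BCE + Dice loss at one scale
#'
#' `mean(BCE(p_fg, y)) + k * (1 - softDice(p_fg, y))` where `p_fg` is the
#' foreground-class probability map and soft Dice is
#' `(2 * sum(p*y) + smooth) / (sum(p) + sum(y) + smooth)`.
#'
#' @param pred_probs class probabilities (b, num_classes, h, w), rows summing
#'   to 1 over classes; foreground is the last class channel.
#' @param target binary mask, (h, w) or (b, h, w).
#' @param cfg a [loss_config()].
#' @return scalar `ag_tensor` (non-negative).
#' @export
bce_dice_level_loss <- function(pred_probs, target, cfg = loss_config()) {
  pred_probs <- as_ag(pred_probs)
  d <- check_rank4(pred_probs, "pred_probs")
  check_binary_target(target)
  t <- target_arr(target, d[1])
  if (!identical(dim(t)[c(1, 3, 4)], d[c(1, 3, 4)]))
    stop("prediction (", paste(d, collapse = ","), ") and target (",
         paste(dim(t), collapse = ","), ") extents disagree")
  p <- ag_slice(pred_probs, 2L, d[2])       # foreground channel
  eps <- 1e-7
  pc <- ag_clamp(p, eps, 1 - eps)
  one_m <- ag_add_const(ag_scale(pc, -1), 1)
  bce_map <- ag_scale(ag_add(ag_mul(ag_log(pc), ag_tensor(t)),
                             ag_mul(ag_log(one_m), ag_tensor(1 - t))), -1)
  bce <- ag_mean(bce_map)
  inter <- ag_sum(ag_mul(p, ag_tensor(t)))
  denom <- ag_add_const(ag_add(ag_sum(p), ag_tensor(sum(t))), cfg$smooth)
  dice <- ag_div(ag_add_const(ag_scale(inter, 2), cfg$smooth), denom)
  ag_add(bce, ag_scale(ag_add_const(ag_scale(dice, -1), 1), cfg$dice_weight))
}

# Logit-space variant used inside training: BCE through log-softmax (per-
# pixel gradient p - t, which never saturates, unlike clamped log(p)), Dice
# on the softmax foreground probability.  Same value as bce_dice_level_loss
# up to the clamp.
bce_dice_logit_loss <- function(logits, target, cfg) {
  d <- dim(logits$value)
  t <- target_arr(target, d[1])
  ls <- ag_logsoftmax_ch(logits)
  ls_fg <- ag_slice(ls, 2L, d[2])
  ls_bg <- ag_slice(ls, 2L, 1L)
  bce <- ag_scale(ag_mean(ag_add(ag_mul(ls_fg, ag_tensor(t)),
                                 ag_mul(ls_bg, ag_tensor(1 - t)))), -1)
  p <- ag_slice(ag_softmax_ch(logits), 2L, d[2])
  inter <- ag_sum(ag_mul(p, ag_tensor(t)))
  denom <- ag_add_const(ag_add(ag_sum(p), ag_tensor(sum(t))), cfg$smooth)
  dice <- ag_div(ag_add_const(ag_scale(inter, 2), cfg$smooth), denom)
  ag_add(bce, ag_scale(ag_add_const(ag_scale(dice, -1), 1), cfg$dice_weight))
}

# nearest-neighbour (top-left) downsampling of a mask by an integer factor
downsample_mask <- function(target, factor) {
  if (factor == 1L) return(target)
  if (length(dim(target)) == 2L) {
    target[seq(1L, nrow(target), by = factor), seq(1L, ncol(target), by = factor)]
  } else {
    target[, seq(1L, dim(target)[2], by = factor), seq(1L, dim(target)[3], by = factor),
           drop = FALSE]
  }
}

#' Deep-supervision loss over all supervised scales
#'
#' `sum_i lambda_i * bce_dice_level_loss(softmax(logits_i), downsample(y, 2^i))`
#' with nearest-neighbour target downsampling (preserves binarity).
#'
#' @param output a `segmentation_output` from [ntsm_forward()] (or a list with
#'   a `logits` list, finest first).
#' @param target binary mask at the finest scale.
#' @param cfg a [loss_config()]; `level_weights` must match the number of
#'   logit levels.
#' @return scalar `ag_tensor`.
#' @export
deep_supervision_loss <- function(output, target, cfg = loss_config()) {
  logits <- output$logits
  if (length(logits) != length(cfg$level_weights))
    stop("got ", length(logits), " logit levels but ",
         length(cfg$level_weights), " level weights")
  check_binary_target(target)
  total <- NULL
  for (i in seq_along(logits)) {
    t_i <- downsample_mask(target, 2L^(i - 1L))
    check_binary_target(t_i)
    term <- ag_scale(bce_dice_logit_loss(as_ag(logits[[i]]), t_i, cfg),
                     cfg$level_weights[i])
    total <- if (is.null(total)) term else ag_add(total, term)
  }
  total
}
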