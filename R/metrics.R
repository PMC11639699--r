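# Segmentation metrics (sensitivity, specificity, Dice, 95th-percentile
# Hausdorff distance) and model-efficiency indicators (parameter count, FLOPs,
# checkpoint size).
#
# Coordinate convention: masks are matrices indexed (row, col); point sets are
# pixel centers at 0-based (row, col) coordinates; distances in pixel units.

check_mask_pair <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("mask shapes disagree: (", paste(dim(pred), collapse = ","), ") vs (",
         paste(dim(truth), collapse = ","), ")")
  vals <- unique(c(as.vector(pred), as.vector(truth)))
  if (!all(vals %in% c(0, 1)))
    stop("masks must be binary {0,1}; found ",
         paste(utils::head(setdiff(vals, c(0, 1)), 5), collapse = ", "))
  invisible(NULL)
}

#' Pixel confusion counts between two binary masks
#'
#' @param pred,truth binary matrices of identical shape, values in {0, 1}.
#' @return a `confusion_counts` list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, truth) {
  check_mask_pair(pred, truth)
  p <- as.vector(pred) == 1; t <- as.vector(truth) == 1
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 fn = sum(!p & t), tn = sum(!p & !t)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and Dice from confusion counts
#'
#' `Sen = TP/(TP+FN)`, `Spe = TN/(TN+FP)`, `Dice = 2TP/(FP+2TP+FN)`.  A metric
#' whose denominator is zero is undefined and reported as `NA` rather than
#' `NaN`.
#'
#' @param counts a `confusion_counts` (or list with tp/fp/fn/tn).
#' @return list with `sen`, `spe`, `dice` (each in \[0,1\] or `NA`).
#' @export
ratio_metrics <- function(counts) {
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sen = safe(counts$tp, counts$tp + counts$fn),
       spe = safe(counts$tn, counts$tn + counts$fp),
       dice = safe(2 * counts$tp, counts$fp + 2 * counts$tp + counts$fn))
}

# exact Euclidean distance of every pixel to the nearest foreground pixel of m
dist_to_set <- function(m) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    EBImage::imageData(EBImage::distmap(1 - m, metric = "euclidean"))
  } else stop("EBImage is required for distance transforms")
}

#' Percentile Hausdorff distance between two binary masks
#'
#' Treats each mask as the set of its foreground pixel centers.  Each directed
#' distance multiset (nearest-neighbour Euclidean distances from every point
#' of one set to the other set) is reduced to its `percentile`-th percentile
#' (linear interpolation); the two directed values combine by `max`.  With
#' `percentile = 100` this is the exact Hausdorff distance.
#'
#' @param a,b binary matrices of identical shape.
#' @param percentile percentile in (0, 100\]; default 95.
#' @return distance in pixel units; `NA` if either mask is empty.
#' @export
hd95 <- function(a, b, percentile = 95) {
  check_mask_pair(a, b)
  if (sum(a) == 0 || sum(b) == 0) return(NA_real_)
  db <- dist_to_set(b)   # distance of every pixel to the set B
  da <- dist_to_set(a)
  q <- percentile / 100
  d_ab <- stats::quantile(db[a == 1], q, type = 7, names = FALSE)
  d_ba <- stats::quantile(da[b == 1], q, type = 7, names = FALSE)
  max(d_ab, d_ba)
}

#' All four segmentation metrics for one mask pair
#' @param pred,truth binary matrices.
#' @return list with `sen`, `spe`, `dice`, `hd95`.
#' @export
segmentation_metrics <- function(pred, truth) {
  r <- ratio_metrics(confusion(pred, truth))
  r$hd95 <- hd95(pred, truth)
  r
}

#' Write a per-image metrics report as CSV
#'
#' One row per image (id, sen, spe, dice, hd95) plus a `mean` summary row;
#' undefined (`NA`) values are excluded from the means and their counts
#' reported in `n_undefined_*` attributes of the returned data frame.
#'
#' @param rows data.frame with columns id, sen, spe, dice, hd95.
#' @param path CSV destination, or `NULL` to skip writing.
#' @export
write_metrics_csv <- function(rows, path = NULL) {
  mean_row <- data.frame(id = "mean",
                         sen = mean(rows$sen, na.rm = TRUE),
                         spe = mean(rows$spe, na.rm = TRUE),
                         dice = mean(rows$dice, na.rm = TRUE),
                         hd95 = mean(rows$hd95, na.rm = TRUE))
  out <- rbind(rows, mean_row)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  for (m in c("sen", "spe", "dice", "hd95"))
    attr(out, paste0("n_undefined_", m)) <- sum(is.na(rows[[m]]))
  out
}

# ---------------------------------------------------------------------------
# Efficiency indicators
# ---------------------------------------------------------------------------

#' Estimate floating-point operations of one forward pass
#'
#' Counts multiply-accumulate operations of every convolution, bilinear
#' interpolation and Hadamard product during a profiled inference forward at
#' the stated input size, and reports `2 * MACs`.
#'
#' @param model an `ntsm_model`.
#' @param input_size integer pair (h, w).
#' @return FLOP count (double).
#' @export
estimate_flops <- function(model, input_size = c(512L, 512L)) {
  old <- set_training(FALSE)
  on.exit(set_training(old))
  the$prof_on <- TRUE
  the$prof_macs <- 0
  on.exit(the$prof_on <- FALSE, add = TRUE)
  x <- array(0, dim = c(1L, 3L, input_size[1], input_size[2]))
  invisible(ntsm_forward(model, x))
  2 * the$prof_macs
}

#' Serialized checkpoint size in bytes
#' @param model an `ntsm_model`.
#' @export
checkpoint_bytes <- function(model) {
  f <- tempfile(fileext = ".ckpt")
  on.exit(unlink(c(f, paste0(f, ".yaml"))))
  save_checkpoint(model, f)
  as.integer(file.size(f))
}
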