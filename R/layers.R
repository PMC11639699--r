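# Layer constructors.  A layer/module is a plain list whose learnable pieces
# are `ag_tensor` environments (shared by reference), so the optimizer mutates
# them in place.  Batch-norm running moments live in a nested environment.

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

trunc_normal <- function(dims, std) {
  n <- prod(dims)
  z <- stats::rnorm(n, sd = std)
  bad <- abs(z) > 2 * std
  while (any(bad)) {
    z[bad] <- stats::rnorm(sum(bad), sd = std)
    bad <- abs(z) > 2 * std
  }
  array(z, dim = dims)
}

same_pad <- function(k, dilation) as.integer(dilation * (k - 1) %/% 2)

#' @keywords internal
new_conv2d <- function(in_ch, out_ch, k, stride = 1L, dilation = 1L,
                       padding = NULL, groups = 1L, bias = TRUE) {
  if (is.null(padding)) padding <- same_pad(k, dilation)
  fan_in <- (in_ch %/% groups) * k * k
  l <- list(kind = "conv2d",
            w = ag_tensor(he_init(c(out_ch, in_ch %/% groups, k, k), fan_in), TRUE),
            b = if (bias) ag_tensor(array(0, out_ch), TRUE) else NULL,
            stride = as.integer(stride), dilation = as.integer(dilation),
            padding = as.integer(padding), groups = as.integer(groups))
  class(l) <- c("ntsm_conv2d", "ntsm_layer")
  l
}

fw_conv2d <- function(l, x) {
  ag_conv2d(x, l$w, l$b, l$stride, l$dilation, l$padding, l$groups)
}

#' @keywords internal
new_conv_transpose2d <- function(in_ch, out_ch, k = 2L, stride = 2L, bias = TRUE) {
  l <- list(kind = "convT2d",
            w = ag_tensor(he_init(c(in_ch, out_ch, k, k), in_ch * k * k), TRUE),
            b = if (bias) ag_tensor(array(0, out_ch), TRUE) else NULL,
            stride = as.integer(stride))
  class(l) <- c("ntsm_convT2d", "ntsm_layer")
  l
}

fw_conv_transpose2d <- function(l, x) ag_conv_transpose2d(x, l$w, l$b, l$stride)

#' @keywords internal
new_batchnorm <- function(ch, momentum = 0.1) {
  st <- new.env(parent = emptyenv())
  st$rm <- rep(0, ch)
  st$rv <- rep(1, ch)
  l <- list(kind = "bn",
            gamma = ag_tensor(array(1, ch), TRUE),
            beta = ag_tensor(array(0, ch), TRUE),
            stats = st, momentum = momentum)
  class(l) <- c("ntsm_bn", "ntsm_layer")
  l
}

fw_batchnorm <- function(l, x) ag_batchnorm(x, l$gamma, l$beta, l$stats, l$momentum)

#' @keywords internal
new_groupnorm <- function(ch, groups) {
  stopifnot(ch %% groups == 0)
  l <- list(kind = "gn",
            gamma = ag_tensor(array(1, ch), TRUE),
            beta = ag_tensor(array(0, ch), TRUE),
            groups = as.integer(groups))
  class(l) <- c("ntsm_gn", "ntsm_layer")
  l
}

fw_groupnorm <- function(l, x) ag_groupnorm(x, l$gamma, l$beta, l$groups)

# ---------------------------------------------------------------------------
# Parameter and state traversal.  Walks nested lists in deterministic order.
# ---------------------------------------------------------------------------

#' Collect learnable parameter tensors of a module tree
#' @param module nested list of layers.
#' @return list of `ag_tensor` leaves with `requires_grad`.
#' @keywords internal
collect_params <- function(module) {
  out <- list()
  walk <- function(x) {
    if (is_ag(x)) {
      if (x$rg) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) if (!is.null(el)) walk(el)
    }
  }
  walk(module)
  out
}

# batch-norm statistics environments, in traversal order
collect_stats <- function(module) {
  out <- list()
  walk <- function(x) {
    if (is.list(x) && !is_ag(x)) {
      if (!is.null(x$kind) && identical(x$kind, "bn")) out[[length(out) + 1L]] <<- x$stats
      for (el in x) if (!is.null(el)) walk(el)
    }
  }
  walk(module)
  out
}

#' Total learnable scalar count of a module tree
#' @param module a built module/model.
#' @return integer number of learnable scalars.
#' @export
count_params <- function(module) {
  sum(vapply(collect_params(module), function(p) length(p$value), numeric(1)))
}

# ---------------------------------------------------------------------------
# SGD with Nesterov momentum, decoupled-from-nothing classic L2 weight decay,
# as used by nnU-Net-style trainers.
# ---------------------------------------------------------------------------

#' @keywords internal
new_sgd <- function(params, lr = 0.001, momentum = 0.99, nesterov = TRUE,
                    weight_decay = 3e-5) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$v <- lapply(params, function(p) array(0, dim = dim(p$value)))
  opt$lr <- lr; opt$momentum <- momentum
  opt$nesterov <- nesterov; opt$wd <- weight_decay
  opt
}

sgd_step <- function(opt) {
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad + opt$wd * p$value
    opt$v[[i]] <- opt$momentum * opt$v[[i]] + g
    step <- if (opt$nesterov) g + opt$momentum * opt$v[[i]] else opt$v[[i]]
    p$value <- p$value - opt$lr * step
  }
  invisible(NULL)
}

poly_lr <- function(base_lr, step, total, power = 0.9) {
  base_lr * (1 - step / total)^power
}
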