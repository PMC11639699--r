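#' @useDynLib ntsm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Reverse-mode automatic differentiation over dense arrays.
#
# A tensor node is an environment holding `value` (a numeric array), `grad`
# (accumulated during backward), `parents` (list of parent nodes) and `backfn`
# (maps the node's output gradient to a list of parent gradients, aligned with
# `parents`).  Nodes form a DAG built eagerly during the forward pass; leaves
# created with requires_grad = TRUE are the learnable parameters.
# ---------------------------------------------------------------------------

# mutable package-level state: training flag + FLOP profiler
the <- new.env(parent = emptyenv())
the$training <- FALSE
the$prof_on <- FALSE
the$prof_macs <- 0

#' Create a tensor node
#'
#' Wraps a numeric array (any rank; scalars become length-1 arrays) as a node
#' of the autodiff graph.
#'
#' @param value numeric array or vector.
#' @param requires_grad should gradients be accumulated into this leaf?
#' @return an `ag_tensor` environment with fields `value` and (after
#'   [ag_backward()]) `grad`.
#' @keywords internal
ag_tensor <- function(value, requires_grad = FALSE) {
  if (is.null(dim(value))) value <- array(as.numeric(value), dim = length(value))
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$backfn <- NULL
  e$rg <- isTRUE(requires_grad)
  class(e) <- "ag_tensor"
  e
}

is_ag <- function(x) inherits(x, "ag_tensor")

# Internal node constructor: tracks gradients only if some parent does.
ag_node <- function(value, parents, backfn) {
  e <- ag_tensor(value)
  e$rg <- any(vapply(parents, function(p) p$rg, logical(1)))
  if (e$rg) {
    e$parents <- parents
    e$backfn <- backfn
  }
  e
}

#' Run backpropagation from a node
#'
#' Accumulates gradients into every reachable leaf with `requires_grad`.
#'
#' @param node an `ag_tensor`, typically a scalar loss.
#' @param grad seed gradient; defaults to ones of the node's shape.
#' @keywords internal
ag_backward <- function(node, grad = NULL) {
  if (is.null(grad)) grad <- array(1, dim = dim(node$value))
  # topological order by DFS (iterative; graphs can be deep)
  topo <- vector("list", 256L); nt <- 0L
  stack <- list(list(n = node, i = 0L)); ns <- 1L
  while (ns > 0L) {
    fr <- stack[[ns]]
    n <- fr$n
    if (fr$i == 0L && !is.null(n$.visited)) { ns <- ns - 1L; next }
    n$.visited <- TRUE
    if (fr$i < length(n$parents)) {
      stack[[ns]]$i <- fr$i + 1L
      p <- n$parents[[fr$i + 1L]]
      if (p$rg && is.null(p$.visited)) {
        ns <- ns + 1L
        stack[[ns]] <- list(n = p, i = 0L)
      }
    } else {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- n
      ns <- ns - 1L
    }
  }
  node$grad <- grad
  for (k in seq_len(nt)) {
    n <- topo[[nt - k + 1L]]
    rm(".visited", envir = n)
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    for (j in seq_along(n$parents)) {
      p <- n$parents[[j]]
      if (!p$rg || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    if (!identical(n, node)) n$grad <- NULL  # free intermediate grads
  }
  invisible(node)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

#' Switch the engine between training and inference behaviour
#'
#' Controls whether batch-norm layers use batch statistics (and update running
#' moments) or the stored running moments.
#' @param on logical.
#' @return the previous value, invisibly.
#' @export
set_training <- function(on) {
  old <- the$training
  the$training <- isTRUE(on)
  invisible(old)
}

prof_add <- function(macs) {
  if (the$prof_on) the$prof_macs <- the$prof_macs + macs
  invisible(NULL)
}

# --- elementwise arithmetic -------------------------------------------------

ag_add <- function(a, b) {
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  prof_add(length(av))
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scale <- function(a, s) {
  ag_node(a$value * s, list(a), function(g) list(g * s))
}

ag_add_const <- function(a, k) {
  ag_node(a$value + k, list(a), function(g) list(g))
}

# a / b for scalar (length-1) nodes
ag_div <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_node(av / bv, list(a, b), function(g) list(g / bv, -g * av / bv^2))
}

ag_log <- function(a) {
  av <- a$value
  ag_node(log(av), list(a), function(g) list(g / av))
}

ag_clamp <- function(a, lo, hi) {
  av <- a$value
  mask <- (av >= lo & av <= hi) * 1
  ag_node(pmin(pmax(av, lo), hi), list(a), function(g) list(g * mask))
}

# Broadcast-multiply x (full shape) by gate g whose dims are 1 where x's are
# not; used by gating attention.  Gradient of the gate sums over broadcast axes.
ag_bmul <- function(x, gate) {
  xd <- dim(x$value); gd <- dim(gate$value)
  stopifnot(length(xd) == length(gd), all(gd == xd | gd == 1L))
  ge <- bcast_to(gate$value, xd)
  xv <- x$value
  prof_add(length(xv))
  ag_node(xv * ge, list(x, gate), function(g) {
    gg <- g * xv
    bax <- which(gd == 1L & xd > 1L)
    if (length(bax)) gg <- sum_over_axes(gg, bax)
    list(g * ge, gg)
  })
}

bcast_to <- function(a, dims) {
  ad <- dim(a)
  if (all(ad == dims)) return(a)
  for (ax in seq_along(dims)) {
    if (ad[ax] == dims[ax]) next
    perm <- c(setdiff(seq_along(dims), ax), ax)
    m <- aperm(a, perm)
    m <- array(rep(as.vector(m), dims[ax]), dim = c(dim(a)[perm[-length(perm)]], dims[ax]))
    a <- aperm(m, order(perm))
    ad <- dim(a)
  }
  a
}

# sum an array over the given axes, keeping them as singleton dims
sum_over_axes <- function(a, axes) {
  d <- dim(a)
  keep <- setdiff(seq_along(d), axes)
  if (length(keep) == 0) return(array(sum(a), dim = rep(1L, length(d))))
  s <- apply(a, keep, sum)
  nd <- d; nd[axes] <- 1L
  out <- array(0, dim = nd)
  perm <- c(keep, axes)
  array(aperm(array(s, dim = c(d[keep], rep(1L, length(axes)))), order(perm)), dim = nd)
}

# --- reductions -------------------------------------------------------------

ag_sum <- function(a) {
  d <- dim(a$value)
  ag_node(sum(a$value), list(a), function(g) list(array(as.numeric(g), dim = d)))
}

ag_mean <- function(a) {
  d <- dim(a$value); n <- length(a$value)
  ag_node(mean(a$value), list(a), function(g) list(array(as.numeric(g) / n, dim = d)))
}

# --- activations ------------------------------------------------------------

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_node(s, list(a), function(g) list(g * s * (1 - s)))
}

#' @keywords internal
ag_swish <- function(a) {
  av <- a$value
  s <- 1 / (1 + exp(-av))
  ag_node(av * s, list(a), function(g) list(g * (s + av * s * (1 - s))))
}

# exact Gaussian-CDF GeLU
ag_gelu <- function(a) {
  av <- a$value
  ph <- stats::pnorm(av)
  ag_node(av * ph, list(a), function(g) list(g * (ph + av * stats::dnorm(av))))
}

ag_leakyrelu <- function(a, slope = 0.01) {
  av <- a$value
  pos <- (av > 0)
  d <- pos + slope * (1 - pos)
  ag_node(av * d, list(a), function(g) list(g * d))
}

# --- shape ops --------------------------------------------------------------

ag_permute <- function(a, perm) {
  ag_node(aperm(a$value, perm), list(a), function(g) list(aperm(g, order(perm))))
}

ag_reshape <- function(a, dims) {
  d0 <- dim(a$value)
  ag_node(array(a$value, dim = dims), list(a), function(g) list(array(g, dim = d0)))
}

# concatenate along axis `ax`; all other extents must agree
ag_concat <- function(tensors, ax) {
  vals <- lapply(tensors, function(t) t$value)
  dims <- lapply(vals, dim)
  sizes <- vapply(dims, function(d) d[ax], numeric(1))
  nd <- dims[[1]]; nd[ax] <- sum(sizes)
  out <- array(0, dim = nd)
  idx <- lapply(nd, seq_len)
  off <- 0
  for (k in seq_along(vals)) {
    sel <- idx; sel[[ax]] <- off + seq_len(sizes[k])
    out <- do.call(`[<-`, c(list(out), sel, list(value = vals[[k]])))
    off <- off + sizes[k]
  }
  ag_node(out, tensors, function(g) {
    gs <- vector("list", length(tensors))
    off <- 0
    for (k in seq_along(tensors)) {
      sel <- idx; sel[[ax]] <- off + seq_len(sizes[k])
      gs[[k]] <- do.call(`[`, c(list(g), sel, list(drop = FALSE)))
      off <- off + sizes[k]
    }
    gs
  })
}

# slice `idx` (an integer vector) from axis `ax`
ag_slice <- function(a, ax, idx) {
  d <- dim(a$value)
  sel <- lapply(d, seq_len); sel[[ax]] <- idx
  val <- do.call(`[`, c(list(a$value), sel, list(drop = FALSE)))
  ag_node(val, list(a), function(g) {
    gx <- array(0, dim = d)
    gx <- do.call(`[<-`, c(list(gx), sel, list(value = g)))
    list(gx)
  })
}

# --- pooling ----------------------------------------------------------------

# mean over width -> (b, C, h, 1)
ag_pool_w <- function(a) {
  v <- a$value; d <- dim(v)
  m <- rowMeans(v, dims = 3)
  ag_node(array(m, dim = c(d[1:3], 1L)), list(a), function(g) {
    list(array(rep(as.vector(g) / d[4], d[4]), dim = d))
  })
}

# mean over height -> (b, C, 1, w)
ag_pool_h <- function(a) {
  v <- a$value; d <- dim(v)
  m <- colMeans(aperm(v, c(3, 1, 2, 4)))          # (b, C, w)
  ag_node(array(m, dim = c(d[1:2], 1L, d[4])), list(a), function(g) {
    ge <- bcast_to(g, d)
    list(ge / d[3])
  })
}

# --- softmax over the channel axis (dim 2) ----------------------------------

ag_logsoftmax_ch <- function(a) {
  v <- a$value; d <- dim(v)
  mx <- apply(v, c(1, 3, 4), max)
  mxb <- bcast_to(array(mx, dim = c(d[1], 1L, d[3], d[4])), d)
  ex <- exp(v - mxb)
  ss <- rowSums(aperm(ex, c(1, 3, 4, 2)), dims = 3)      # (b,h,w)
  lse <- bcast_to(array(log(ss), dim = c(d[1], 1L, d[3], d[4])), d) + mxb
  y <- v - lse
  sm <- exp(y)
  ag_node(y, list(a), function(g) {
    gs <- rowSums(aperm(g, c(1, 3, 4, 2)), dims = 3)
    list(g - sm * bcast_to(array(gs, dim = c(d[1], 1L, d[3], d[4])), d))
  })
}

ag_softmax_ch <- function(a) {
  v <- a$value; d <- dim(v)
  mx <- apply(v, c(1, 3, 4), max)
  ex <- exp(v - bcast_to(array(mx, dim = c(d[1], 1L, d[3], d[4])), d))
  ss <- rowSums(aperm(ex, c(1, 3, 4, 2)), dims = 3)   # (b,h,w)
  y <- ex / bcast_to(array(ss, dim = c(d[1], 1L, d[3], d[4])), d)
  ag_node(y, list(a), function(g) {
    dot <- rowSums(aperm(g * y, c(1, 3, 4, 2)), dims = 3)
    list(y * (g - bcast_to(array(dot, dim = c(d[1], 1L, d[3], d[4])), d)))
  })
}
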