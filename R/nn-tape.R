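# Minimal reverse-mode automatic differentiation over image tensors.
#
# Tensors are R arrays with layout [H, W, C, N] (column-major, H fastest);
# scalar nodes hold a length-1 numeric. Each node is an environment with
#   val     the forward value
#   parents list of parent nodes
#   bwd     function(g) -> list of gradients, one per parent (NULL allowed
#           for parents that do not require grad)
#   req     TRUE if any ancestor is a tracked leaf
#   grad    accumulated gradient (filled by nnBackward)
# The graph is dynamic: it is rebuilt on every forward pass, and
# nnBackward() topologically sorts it by depth-first search from the loss.

.nnCounter <- new.env(parent = emptyenv())
.nnCounter$id <- 0L

nnNode <- function(val, parents = list(), bwd = NULL, req = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$parents <- parents
  n$bwd <- bwd
  n$req <- if (!is.null(req)) req else any(vapply(parents, function(p) p$req,
                                                  logical(1)))
  n$grad <- NULL
  .nnCounter$id <- .nnCounter$id + 1L
  n$id <- .nnCounter$id
  class(n) <- "nnNode"
  n
}

tpConst <- function(val) nnNode(val, req = FALSE)
tpLeaf <- function(val) nnNode(val, req = TRUE)

# reverse-mode sweep: seeds d(loss)/d(loss) = 1 and accumulates into
# node$grad for every node with req = TRUE
nnBackward <- function(loss) {
  stopifnot(length(loss$val) == 1L)
  # iterative DFS post-order over req-subgraph
  order <- vector("list", 256L); no <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L)); ns <- 1L
  while (ns > 0L) {
    top <- stack[[ns]]
    nd <- top$node
    key <- as.character(nd$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) { ns <- ns - 1L; next }
      seen[[key]] <- TRUE
      stack[[ns]]$stage <- 2L
      for (p in nd$parents) if (p$req && is.null(seen[[as.character(p$id)]])) {
        ns <- ns + 1L
        stack[[ns]] <- list(node = p, stage = 1L)
      }
    } else {
      no <- no + 1L
      if (no > length(order)) order <- c(order, vector("list", length(order)))
      order[[no]] <- nd
      ns <- ns - 1L
    }
  }
  loss$grad <- 1
  for (i in seq(no, 1L)) {
    nd <- order[[i]]
    if (is.null(nd$grad) || is.null(nd$bwd)) next
    gs <- nd$bwd(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (!p$req || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(loss)
}

# ---- tensor ops ---------------------------------------------------------

tpConv <- function(x, w, b, pad) {
  wd <- dim(w$val)
  # direct stencil path for small-channel 3x3 convolutions, im2col + GEMM
  # otherwise
  direct <- wd[1] == 3L && wd[2] == 3L && wd[3] * wd[4] <= 1024
  out <- if (direct) conv3_fwd_cpp(x$val, w$val, b$val)
         else conv2d_fwd_cpp(x$val, w$val, b$val, as.integer(pad))
  nnNode(out, list(x, w, b), function(g) {
    r <- if (direct) conv3_bwd_cpp(x$val, w$val, g)
         else conv2d_bwd_cpp(x$val, w$val, g, as.integer(pad))
    list(r$gx, r$gw, r$gb)
  })
}

tpReLU <- function(x) {
  nnNode(relu_fwd_cpp(x$val), list(x), function(g)
    list(relu_bwd_cpp(g, x$val)))
}

# fixed symmetric separable kernel (e.g. Gaussian window), same zero padding
tpConvSep <- function(x, k1d) {
  nnNode(sepconv2_cpp(x$val, k1d), list(x), function(g)
    list(sepconv2_cpp(g, k1d)))
}

tpMaxPool <- function(x) {
  r <- maxpool2_fwd_cpp(x$val)
  xd <- dim(x$val)
  nnNode(r$out, list(x), function(g)
    list(maxpool2_bwd_cpp(g, r$argmax, as.integer(xd))))
}

tpUpsample <- function(x) {
  nnNode(upsample2_fwd_cpp(x$val), list(x), function(g)
    list(upsample2_bwd_cpp(g)))
}

# zero-insertion 2x upsample (stride-2 transposed-convolution front end):
# input pixels land at odd positions, all other outputs are zero
tpZeroUp <- function(x) {
  d <- dim(x$val)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  ri <- seq(1, 2 * d[1], by = 2); ci <- seq(1, 2 * d[2], by = 2)
  out[ri, ci, , ] <- x$val
  nnNode(out, list(x), function(g) list(g[ri, ci, , , drop = FALSE]))
}

tpAvgPool <- function(x) {
  nnNode(avgpool2_fwd_cpp(x$val), list(x), function(g)
    list(avgpool2_bwd_cpp(g)))
}

tpConcatC <- function(xs) {
  dims <- lapply(xs, function(x) dim(x$val))
  cs <- vapply(dims, function(d) d[3], numeric(1))
  d0 <- dims[[1]]
  out <- array(0, c(d0[1], d0[2], sum(cs), d0[4]))
  at <- 0L
  for (x in xs) {
    cc <- dim(x$val)[3]
    out[, , at + seq_len(cc), ] <- x$val
    at <- at + cc
  }
  ofs <- cumsum(c(0, cs[-length(cs)]))
  nnNode(out, xs, function(g) {
    lapply(seq_along(xs), function(k)
      g[, , ofs[k] + seq_len(cs[k]), , drop = FALSE])
  })
}

tpAdd <- function(a, b) nnNode(a$val + b$val, list(a, b),
                               function(g) list(g, g))
tpSub <- function(a, b) nnNode(a$val - b$val, list(a, b),
                               function(g) list(g, -g))
tpMul <- function(a, b) nnNode(a$val * b$val, list(a, b),
                               function(g) list(g * b$val, g * a$val))
tpScale <- function(x, s) nnNode(x$val * s, list(x), function(g) list(g * s))
tpDiv <- function(a, b) nnNode(a$val / b$val, list(a, b), function(g)
  list(g / b$val, -g * a$val / b$val^2))
tpAbs <- function(x) {
  sg <- sign(x$val)
  nnNode(abs(x$val), list(x), function(g) list(g * sg))
}

tpMean <- function(x) {
  n <- length(x$val)
  d <- dim(x$val)
  nnNode(mean(x$val), list(x), function(g) list(array(g / n, d)))
}

tpCropBorder <- function(x, m) {
  d <- dim(x$val)
  ri <- (m + 1):(d[1] - m); ci <- (m + 1):(d[2] - m)
  nnNode(x$val[ri, ci, , , drop = FALSE], list(x), function(g) {
    gx <- array(0, d)
    gx[ri, ci, , ] <- g
    list(gx)
  })
}

tpDropout <- function(x, p, training) {
  if (!training || p <= 0) return(x)
  mask <- array(stats::rbinom(length(x$val), 1L, 1 - p) / (1 - p),
                dim(x$val))
  nnNode(x$val * mask, list(x), function(g) list(g * mask))
}

# ---- scalar ops ---------------------------------------------------------

tpScalarMul <- function(a, b) nnNode(a$val * b$val, list(a, b),
                                     function(g) list(g * b$val, g * a$val))
tpScalarAdd <- function(a, b) nnNode(a$val + b$val, list(a, b),
                                     function(g) list(g, g))
tpScalarAffine <- function(x, mul, add)
  nnNode(x$val * mul + add, list(x), function(g) list(g * mul))
tpScalarPow <- function(x, k) {
  v <- x$val
  nnNode(v^k, list(x), function(g) list(g * k * v^(k - 1)))
}
tpClampMin <- function(x, lo) {
  keep <- x$val > lo
  nnNode(max(x$val, lo), list(x), function(g) list(g * keep))
}

# ---- batch normalisation -------------------------------------------------

# Running statistics are warm-started from the first batch (instead of the
# conventional mean 0 / var 1) so that evaluation-mode passes are faithful
# even after very short training runs, then tracked with momentum 0.1.
updateRunningStats <- function(state, mu, va, m) {
  vaU <- va * m / max(1, m - 1)
  if (is.null(state$initialized)) {
    state$mean <- mu
    state$var <- vaU
    state$initialized <- TRUE
  } else {
    state$mean <- 0.9 * state$mean + 0.1 * mu
    state$var <- 0.9 * state$var + 0.1 * vaU
  }
}

# fused BatchNorm + ReLU (the workhorse of every convolutional block);
# xhat is recomputed from x in the backward pass instead of being stored
tpBNReLU <- function(x, gamma, beta, state, training, eps = 1e-5) {
  d <- dim(x$val)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- chan_mean_cpp(x$val)
    va <- pmax(chan_dot_mean_cpp(x$val, x$val) - mu^2, 0)
    inv <- 1 / sqrt(va + eps)
    updateRunningStats(state, mu, va, m)
  } else {
    mu <- state$mean
    inv <- 1 / sqrt(state$var + eps)
  }
  y <- bnrelu_fwd_cpp(x$val, mu, inv, gamma$val, beta$val)
  nnNode(y, list(x, gamma, beta), function(g) {
    r <- bnrelu_bwd_cpp(g, y, x$val, mu, inv, gamma$val, training)
    list(r$gx, r$gGamma, r$gBeta)
  })
}

# Batch normalisation over (H, W, N) per channel. `state` is an environment
# holding running mean/var (updated in training mode with momentum 0.1).
tpBatchNorm <- function(x, gamma, beta, state, training, eps = 1e-5) {
  d <- dim(x$val)
  m <- d[1] * d[2] * d[4]
  if (training) {
    mu <- chan_mean_cpp(x$val)
    va <- chan_dot_mean_cpp(x$val, x$val) - mu^2
    va <- pmax(va, 0)
    inv <- 1 / sqrt(va + eps)
    xhat <- bn_norm_cpp(x$val, mu, inv)
    updateRunningStats(state, mu, va, m)
    out <- bn_affine_cpp(xhat, gamma$val, beta$val)
    nnNode(out, list(x, gamma, beta), function(g) {
      gMean <- chan_mean_cpp(g)
      gxhMean <- chan_dot_mean_cpp(g, xhat)
      gx <- bn_bwd_cpp(g, xhat, gamma$val * inv, gMean, gxhMean)
      list(gx, gxhMean * m, gMean * m)
    })
  } else {
    inv <- 1 / sqrt(state$var + eps)
    xhat <- bn_norm_cpp(x$val, state$mean, inv)
    out <- bn_affine_cpp(xhat, gamma$val, beta$val)
    nnNode(out, list(x, gamma, beta), function(g) {
      list(bn_affine_cpp(g, gamma$val * inv, numeric(length(inv))),
           chan_dot_mean_cpp(g, xhat) * m,
           chan_mean_cpp(g) * m)
    })
  }
}
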