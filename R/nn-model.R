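#' Network configuration
#'
#' Architecture hyperparameters of the dense-skip encoder-decoder
#' super-resolution network. The encoder has four convolutional stages
#' (the fourth is the bottleneck) separated by three 2x2 max-pools; the
#' decoder mirrors it with three upsampling stages whose skip connections
#' pass through dense-connection blocks, and a 2x output block maps the
#' final features to the doubled-grid image.
#'
#' @param encoderWidths four integers, the channel widths of the encoder
#'   stages (default `c(32, 64, 128, 256)`; the first width is also the
#'   channel count entering the output block).
#' @param denseConfigs list of three `list(L =, k =)` dense-connection
#'   settings, ordered deepest skip first (defaults `{L=0}`,
#'   `{L=3, k=32}`, `{L=5, k=8}`). `L` is the number of bottleneck layers,
#'   `k` the growth rate.
#' @param dropoutP dropout probability between upsampling stages.
#' @param skipMode `"dense"` (dense-connection skips), `"concat"` (plain
#'   U-net concatenation) or `"residual"` (residual block on the skip).
#' @param upsampleMode `"nearest"` (nearest-neighbor x2 followed by a 1x1
#'   channel-halving convolution) or `"transposed"` (stride-2 transposed
#'   convolution).
#' @param useBn,useDropout ablation toggles for batch normalisation and
#'   dropout.
#' @return a validated config list.
#' @export
networkConfig <- function(encoderWidths = c(32L, 64L, 128L, 256L),
                          denseConfigs = list(list(L = 0L),
                                              list(L = 3L, k = 32L),
                                              list(L = 5L, k = 8L)),
                          dropoutP = 0.5,
                          skipMode = c("dense", "concat", "residual"),
                          upsampleMode = c("nearest", "transposed"),
                          useBn = TRUE, useDropout = TRUE) {
  stopIfNot(length(encoderWidths) == 4, "need exactly 4 encoder widths")
  stopIfNot(length(denseConfigs) == 3, "need exactly 3 dense configs")
  for (dc in denseConfigs)
    if (dc$L > 0 && is.null(dc$k))
      stop("dense config with L > 0 requires a growth rate k", call. = FALSE)
  stopIfNot(dropoutP >= 0 && dropoutP < 1, "dropoutP must be in [0, 1)")
  list(encoderWidths = as.integer(encoderWidths),
       denseConfigs = denseConfigs, dropoutP = dropoutP,
       skipMode = match.arg(skipMode), upsampleMode = match.arg(upsampleMode),
       useBn = useBn, useDropout = useDropout)
}

#' Compact network configuration for desk-scale studies
#'
#' A narrow variant of the default architecture (encoder widths 4-32,
#' shallow dense skips with growth rates 8 and 4, no dropout) used by the
#' package's scaled-down training studies: the same topology — four
#' encoder stages, three dense-skip decoder stages, 2x output block — at
#' a computational cost suited to minutes-long single-CPU training runs.
#' Dropout is disabled because the short schedules these studies use
#' leave no room for heavy regularisation.
#'
#' @return a [networkConfig()] list.
#' @export
compactNetworkConfig <- function() {
  networkConfig(encoderWidths = c(4L, 8L, 16L, 32L),
                denseConfigs = list(list(L = 0L), list(L = 1L, k = 8L),
                                    list(L = 2L, k = 4L)),
                useDropout = FALSE)
}

#' MsimModel: the super-resolution network
#'
#' Holds the architecture config and a mutable state environment with the
#' parameter arrays, batch-normalisation running statistics and the dataset
#' normalisation constant. Parameters are created lazily on the first
#' forward pass with a seeded He-normal initialisation.
#'
#' @slot config a [networkConfig()] list.
#' @slot state environment with `params`, `bn`, `normConst`, `seed`.
#' @export
setClass("MsimModel", representation(config = "list", state = "environment"))

#' Create a super-resolution network model
#'
#' @param config a [networkConfig()].
#' @param seed integer seed for weight initialisation.
#' @return an [MsimModel-class].
#' @export
msimNetwork <- function(config = networkConfig(), seed = 1L) {
  st <- new.env(parent = emptyenv())
  st$params <- new.env(parent = emptyenv())
  st$bn <- new.env(parent = emptyenv())
  st$normConst <- 1
  st$seed <- as.integer(seed)
  st$nParamsCreated <- 0L
  new("MsimModel", config = config, state = st)
}

setMethod("show", "MsimModel", function(object) {
  cfg <- object@config
  cat(sprintf("MsimModel: widths [%s], skips %s, %s upsampling, BN=%s dropout=%s\n",
              paste(cfg$encoderWidths, collapse = ","), cfg$skipMode,
              cfg$upsampleMode, cfg$useBn, cfg$useDropout))
  cat(sprintf("  %d parameter tensors (%d values), normConst=%.4g\n",
              length(ls(object@state$params)),
              nParameters(object), object@state$normConst))
})

#' Number of trainable parameter values in a model
#'
#' @param model an [MsimModel-class] that has run at least one forward pass.
#' @return integer count of scalar parameters.
#' @export
nParameters <- function(model) {
  sum(vapply(ls(model@state$params),
             function(nm) length(model@state$params[[nm]]), numeric(1)))
}

# fetch-or-create a parameter array; creation is seeded and deterministic
getParam <- function(st, name, dims, init = c("he", "zero", "one")) {
  if (!is.null(st$params[[name]])) return(st$params[[name]])
  init <- match.arg(init)
  st$nParamsCreated <- st$nParamsCreated + 1L
  v <- withSeed(st$seed * 1000L + st$nParamsCreated, {
    switch(init,
      he = array(stats::rnorm(prod(dims), 0,
                              sqrt(2 / prod(dims[seq_len(length(dims) - 1)]))),
                 dims),
      zero = array(0, dims),
      one = array(1, dims))
  })
  if (length(dims) == 1) v <- as.numeric(v)
  st$params[[name]] <- v
  v
}

# ---- forward-pass building blocks ---------------------------------------
# `ctx` carries the model state, the training flag, and the per-pass map of
# parameter nodes (name -> leaf node) used to read gradients after backward.

pnode <- function(ctx, name, dims, init = "he") {
  v <- getParam(ctx$st, name, dims, init)
  if (!ctx$track) return(tpConst(v))
  nd <- tpLeaf(v)
  ctx$pnodes[[name]] <- nd
  nd
}

opConv <- function(ctx, name, x, cout, k = 3L) {
  cin <- dim(x$val)[3]
  w <- pnode(ctx, paste0(name, ".w"), c(k, k, cin, cout))
  b <- pnode(ctx, paste0(name, ".b"), cout, "zero")
  tpConv(x, w, b, (k - 1L) %/% 2L)
}

opBN <- function(ctx, name, x) {
  if (!ctx$cfg$useBn) return(x)
  cc <- dim(x$val)[3]
  gamma <- pnode(ctx, paste0(name, ".g"), cc, "one")
  beta <- pnode(ctx, paste0(name, ".be"), cc, "zero")
  if (is.null(ctx$st$bn[[name]])) {
    e <- new.env(parent = emptyenv())
    e$mean <- rep(0, cc); e$var <- rep(1, cc)
    ctx$st$bn[[name]] <- e
  }
  tpBatchNorm(x, gamma, beta, ctx$st$bn[[name]], ctx$training)
}

# BN -> ReLU (fused kernel when batch normalisation is enabled)
opBNReLU <- function(ctx, name, x) {
  if (!ctx$cfg$useBn) return(tpReLU(x))
  cc <- dim(x$val)[3]
  gamma <- pnode(ctx, paste0(name, ".g"), cc, "one")
  beta <- pnode(ctx, paste0(name, ".be"), cc, "zero")
  if (is.null(ctx$st$bn[[name]])) {
    e <- new.env(parent = emptyenv())
    e$mean <- rep(0, cc); e$var <- rep(1, cc)
    ctx$st$bn[[name]] <- e
  }
  tpBNReLU(x, gamma, beta, ctx$st$bn[[name]], ctx$training)
}

# Conv -> BN -> ReLU
opCBR <- function(ctx, name, x, cout, k = 3L)
  opBNReLU(ctx, name, opConv(ctx, name, x, cout, k))

# the two-convolution encoder/decoder block
opDoubleConv <- function(ctx, name, x, cout)
  opCBR(ctx, paste0(name, ".c2"), opCBR(ctx, paste0(name, ".c1"), x, cout),
        cout)

# dense connection on a skip path (identity when L = 0)
opDense <- function(ctx, name, x, L, k) {
  if (ctx$cfg$skipMode == "concat") return(x)
  cin <- dim(x$val)[3]
  if (ctx$cfg$skipMode == "residual") {
    h <- opCBR(ctx, paste0(name, ".r1"), x, cin)
    h <- opBN(ctx, paste0(name, ".r2"), opConv(ctx, paste0(name, ".r2"), h, cin))
    return(tpReLU(tpAdd(h, x)))
  }
  if (L == 0L) return(x)
  feats <- list(opCBR(ctx, paste0(name, ".init"), x, cin))
  for (l in seq_len(L)) {
    inp <- if (length(feats) == 1) feats[[1]] else tpConcatC(feats)
    # bottleneck: BN-ReLU-Conv(1x1, 4k) - BN-ReLU-Conv(3x3, k)
    h <- opBNReLU(ctx, sprintf("%s.l%d.bn1", name, l), inp)
    h <- opConv(ctx, sprintf("%s.l%d.c1", name, l), h, 4L * k, 1L)
    h <- opBNReLU(ctx, sprintf("%s.l%d.bn2", name, l), h)
    h <- opConv(ctx, sprintf("%s.l%d.c2", name, l), h, k, 3L)
    feats <- c(feats, list(h))
  }
  allf <- tpConcatC(feats)
  # transition: BN-ReLU-Conv(1x1 back to input channels)-BN-ReLU
  h <- opBNReLU(ctx, paste0(name, ".t.bn1"), allf)
  h <- opConv(ctx, paste0(name, ".t.c1"), h, cin, 1L)
  opBNReLU(ctx, paste0(name, ".t.bn2"), h)
}

# spatial x2 upsampling with channel halving
opUp <- function(ctx, name, x) {
  cin <- dim(x$val)[3]
  if (ctx$cfg$upsampleMode == "nearest")
    opConv(ctx, paste0(name, ".half"), tpUpsample(x), cin %/% 2L, 1L)
  else
    opConv(ctx, paste0(name, ".tconv"), tpZeroUp(x), cin %/% 2L, 3L)
}

# full network graph; x is a node holding [H, W, 1, N]
netForward <- function(ctx, x) {
  wdt <- ctx$cfg$encoderWidths
  d <- list()
  h <- x
  for (i in 1:4) {
    h <- opDoubleConv(ctx, sprintf("enc%d", i), h, wdt[i])
    d[[i]] <- h
    if (i < 4) h <- tpMaxPool(h)
  }
  u <- d[[4]]
  for (i in 1:3) {
    dc <- ctx$cfg$denseConfigs[[i]]
    skip <- opDense(ctx, sprintf("skip%d", i), d[[4 - i]], dc$L,
                    if (is.null(dc$k)) 0L else dc$k)
    up <- opUp(ctx, sprintf("dec%d", i), u)
    u <- opDoubleConv(ctx, sprintf("dec%d", i), tpConcatC(list(skip, up)),
                      wdt[4 - i])
    if (i < 3 && ctx$cfg$useDropout)
      u <- tpDropout(u, ctx$cfg$dropoutP, ctx$training)
  }
  # output block: nearest x2, then 3x3 and 1x1 conv blocks down to 1 channel
  stopIfNot(dim(u$val)[3] == wdt[1],
            "output block expects the first encoder width in channels")
  h <- tpUpsample(u)
  h <- opCBR(ctx, "out.c1", h, wdt[1], 3L)
  h <- opConv(ctx, "out.c2", h, 1L, 1L)
  tpReLU(h)
}

#' Forward pass of the super-resolution network
#'
#' Maps a batch of raw multifocal frames (`[H, W, 1, N]` array, values in
#' `[0, 1]`, `H` and `W` divisible by 8) to `[2H, 2W, 1, N]`
#' super-resolution predictions. In evaluation mode (the default) dropout
#' is inactive, batch normalisation uses running statistics, and the pass
#' is deterministic.
#'
#' @param model an [MsimModel-class].
#' @param x input array `[H, W, 1, N]`, or a matrix for a single frame.
#' @param training logical; enables batch statistics and dropout and
#'   returns a graph node for [nnBackward()].
#' @return in eval mode, the output array; in training mode, a list with
#'   `out` (the output node) and `ctx` (parameter-node map).
#' @export
msimForward <- function(model, x, training = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L, 1L))
  d <- dim(x)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0)
    stop("input spatial dimensions must be divisible by 8 (three pooling stages); pad the input",
         call. = FALSE)
  ctx <- new.env(parent = emptyenv())
  ctx$st <- model@state
  ctx$cfg <- model@config
  ctx$training <- training
  ctx$track <- training
  ctx$pnodes <- new.env(parent = emptyenv())
  out <- netForward(ctx, tpConst(x))
  if (training) list(out = out, ctx = ctx) else out$val
}
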