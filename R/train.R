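#' Training configuration
#'
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs number of epochs (default 50).
#' @param batch batch size (default 8).
#' @param seed integer seed for shuffling, dropout and batch statistics.
#' @param lossCfg a [lossConfig()].
#' @return a validated config list.
#' @export
trainConfig <- function(lr = 1e-3, epochs = 50L, batch = 8L, seed = 1L,
                        lossCfg = lossConfig()) {
  stopIfNot(batch >= 1, "batch must be >= 1")
  stopIfNot(epochs >= 1, "epochs must be >= 1")
  list(lr = lr, epochs = as.integer(epochs), batch = as.integer(batch),
       seed = as.integer(seed), lossCfg = lossCfg)
}

# mean composite loss of a model over dataset indices, evaluation mode
evalLoss <- function(model, dataset, idx, lossCfg, batch = 8L) {
  tot <- 0
  for (b in split(idx, ceiling(seq_along(idx) / batch))) {
    out <- msimForward(model, dataset$input[, , , b, drop = FALSE])
    tot <- tot + length(b) *
      msimLoss(out, dataset$target[, , , b, drop = FALSE], lossCfg)
  }
  tot / length(idx)
}

#' Train the super-resolution network
#'
#' Adam optimisation of the composite MS-SSIM + weighted-L1 loss over the
#' dataset's training split, with the validation loss evaluated every
#' epoch and the best-validation parameter set retained in the returned
#' model. The dataset normalisation constant is stored in the model and
#' reapplied at inference. Aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param model an [MsimModel-class] (modified in place and returned).
#' @param dataset a dataset from [makeTrainingPairs()] and friends.
#' @param cfg a [trainConfig()].
#' @param verbose print per-epoch losses.
#' @return list with `model` and `history` (data.frame of epoch, training
#'   loss, validation loss; epoch 0 is the pre-training validation loss).
#' @export
trainNetwork <- function(model, dataset, cfg = trainConfig(),
                         verbose = FALSE) {
  st <- model@state
  st$normConst <- dataset$normConst
  lossCfg <- cfg$lossCfg
  # materialise parameters with one training-mode forward (no update)
  withSeed(cfg$seed, {
    msimForward(model, dataset$input[, , , dataset$trainIdx[1],
                                     drop = FALSE], training = TRUE)
  })
  adam <- new.env(parent = emptyenv())
  adam$t <- 0
  valLoss0 <- evalLoss(model, dataset, dataset$valIdx, lossCfg, cfg$batch)
  history <- data.frame(epoch = 0L, trainLoss = NA_real_,
                        valLoss = valLoss0)
  best <- list(val = valLoss0, params = as.list(st$params),
               bn = snapshotBN(st$bn))
  withSeed(cfg$seed * 2654435L + 97L, {
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample(dataset$trainIdx)
      epLoss <- 0
      for (b in split(idx, ceiling(seq_along(idx) / cfg$batch))) {
        fw <- msimForward(model, dataset$input[, , , b, drop = FALSE],
                          training = TRUE)
        lossNode <- msimLossNode(fw$out,
                                 tpConst(dataset$target[, , , b,
                                                        drop = FALSE]),
                                 lossCfg)
        if (!is.finite(lossNode$val))
          stop(sprintf("non-finite loss at epoch %d: aborting", ep),
               call. = FALSE)
        nnBackward(lossNode)
        adamStep(st, fw$ctx$pnodes, adam, cfg$lr)
        epLoss <- epLoss + lossNode$val * length(b)
      }
      epLoss <- epLoss / length(idx)
      vl <- evalLoss(model, dataset, dataset$valIdx, lossCfg, cfg$batch)
      history <- rbind(history,
                       data.frame(epoch = ep, trainLoss = epLoss,
                                  valLoss = vl))
      if (verbose)
        message(sprintf("epoch %d: train %.5f val %.5f", ep, epLoss, vl))
      if (vl < best$val)
        best <- list(val = vl, params = as.list(st$params),
                     bn = snapshotBN(st$bn))
    }
  })
  # restore the best-validation checkpoint
  for (nm in names(best$params)) st$params[[nm]] <- best$params[[nm]]
  restoreBN(st$bn, best$bn)
  list(model = model, history = history)
}

snapshotBN <- function(bn) {
  out <- list()
  for (nm in ls(bn)) out[[nm]] <- list(mean = bn[[nm]]$mean,
                                       var = bn[[nm]]$var)
  out
}

restoreBN <- function(bn, snap) {
  for (nm in names(snap)) {
    bn[[nm]]$mean <- snap[[nm]]$mean
    bn[[nm]]$var <- snap[[nm]]$var
  }
}

adamStep <- function(st, pnodes, adam, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  adam$t <- adam$t + 1
  for (nm in ls(pnodes)) {
    g <- pnodes[[nm]]$grad
    if (is.null(g)) next
    if (is.null(adam[[nm]]))
      adam[[nm]] <- list(m = 0 * g, v = 0 * g)
    s <- adam[[nm]]
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    adam[[nm]] <- s
    mhat <- s$m / (1 - beta1^adam$t)
    vhat <- s$v / (1 - beta2^adam$t)
    st$params[[nm]] <- st$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
}

#' Reconstruct a stack with the trained network
#'
#' Feeds every raw frame (normalised by the training constant) through the
#' network in evaluation mode and sums the per-frame super-resolution
#' outputs. Frames whose dimensions are not divisible by 8 are zero-padded
#' and the output cropped, with a warning.
#'
#' @param model a trained [MsimModel-class].
#' @param stack a [RawStack-class].
#' @param batch frames per forward pass (default 8).
#' @return an [SRImage-class] with provenance `"deep"`.
#' @export
inferStack <- function(model, stack, batch = 8L) {
  fr <- stackFrames(stack)
  d <- dim(fr)
  padH <- (8 - d[1] %% 8) %% 8; padW <- (8 - d[2] %% 8) %% 8
  if (padH > 0 || padW > 0)
    warning(sprintf("padding %dx%d frames to divisibility by 8", d[1], d[2]))
  nc <- model@state$normConst
  acc <- matrix(0, 2 * d[1], 2 * d[2])
  for (b in split(seq_len(d[3]), ceiling(seq_len(d[3]) / batch))) {
    x <- array(0, c(d[1] + padH, d[2] + padW, 1L, length(b)))
    x[seq_len(d[1]), seq_len(d[2]), 1, ] <- fr[, , b] / nc
    out <- msimForward(model, x)
    for (k in seq_along(b))
      acc <- acc + out[seq_len(2 * d[1]), seq_len(2 * d[2]), 1, k]
  }
  new("SRImage", image = pmax(acc * nc, 0),
      pixelSizeNm = stack@pixelSizeNm / 2, provenance = "deep",
      nFramesUsed = d[3])
}

#' Save or load a model checkpoint
#'
#' The checkpoint embeds the architecture config, all parameter arrays,
#' batch-normalisation running statistics and the dataset normalisation
#' constant, so a reloaded model reproduces the saved model's outputs
#' exactly.
#'
#' @param model an [MsimModel-class].
#' @param path file path (RDS).
#' @return `loadModel` returns the restored [MsimModel-class].
#' @export
saveModel <- function(model, path) {
  st <- model@state
  saveRDS(list(config = model@config, params = as.list(st$params),
               bn = snapshotBN(st$bn), normConst = st$normConst,
               seed = st$seed, nParamsCreated = st$nParamsCreated),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  ck <- readRDS(path)
  model <- msimNetwork(ck$config, seed = ck$seed)
  st <- model@state
  for (nm in names(ck$params)) st$params[[nm]] <- ck$params[[nm]]
  for (nm in names(ck$bn)) {
    e <- new.env(parent = emptyenv())
    e$mean <- ck$bn[[nm]]$mean; e$var <- ck$bn[[nm]]$var
    e$initialized <- TRUE
    st$bn[[nm]] <- e
  }
  st$normConst <- ck$normConst
  st$nParamsCreated <- ck$nParamsCreated
  model
}
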