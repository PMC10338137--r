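#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 1e-4,
#' batch size 64, up to 100 epochs, early stopping with patience 5 on the
#' validation loss, InfoNCE temperature 0.5. The perturbation magnitude
#' `epsilon` (not stated in the protocol) defaults to 0.1.
#'
#' @param learningRate Adam step size.
#' @param batchSize minibatch size M.
#' @param maxEpochs maximum number of epochs.
#' @param patience epochs without validation improvement before stopping;
#'   `Inf` disables early stopping.
#' @param tau InfoNCE temperature.
#' @param epsilon node-perturbation norm for the contrastive view.
#' @param seed integer seed driving all training randomness.
#' @param contrastive include the InfoNCE regulariser (TRUE) or train on the
#'   supervised loss alone (FALSE).
#' @param verbose print one line per epoch.
#' @return named list of settings.
#' @export
trainConfig <- function(learningRate = 1e-4, batchSize = 64, maxEpochs = 100,
                        patience = 5, tau = 0.5, epsilon = 0.1, seed = NULL,
                        contrastive = TRUE, verbose = FALSE) {
  stopifnot(learningRate > 0, batchSize >= 1, maxEpochs >= 1,
            patience >= 1, tau > 0, epsilon > 0)
  list(learningRate = learningRate, batchSize = batchSize,
       maxEpochs = maxEpochs, patience = patience, tau = tau,
       epsilon = epsilon, seed = seed, contrastive = contrastive,
       verbose = verbose)
}

# forward a batch; optionally with gradients. Returns losses, predictions,
# and (with grad) accumulated parameter gradients.
batchPass <- function(params, mcfg, graphs, Y, tc, grad = TRUE) {
  M <- length(graphs)
  C <- mcfg$nTerms
  D <- mcfg$hiddenDim
  fws <- lapply(graphs, function(g)
    forwardCached(params, mcfg, g@X, g@A))
  Z <- do.call(rbind, lapply(fws, function(f) f$pool$z))
  Yhat <- do.call(rbind, lapply(fws, function(f) f$head$yhat))
  sup <- bceLoss(Y, Yhat)

  nce <- NULL
  pcaches <- NULL
  if (tc$contrastive) {
    pcaches <- vector("list", M)
    Zp <- matrix(0, M, D)
    for (m in seq_len(M)) {
      Hp <- perturbEmbeddings(fws[[m]]$enc$H, tc$epsilon)
      pcaches[[m]] <- if (mcfg$pooling == "hgt") {
        hgtForward(params$hgt, Hp, fws[[m]]$S)
      } else maxPoolForward(Hp)
      Zp[m, ] <- pcaches[[m]]$z
    }
    # cosine similarity (hence InfoNCE) is undefined on a zero-norm view,
    # which a ReLU max-pool can produce early in training; such a batch
    # trains on the supervised loss alone
    if (min(rowNorms(Z)) < 1e-12 || min(rowNorms(Zp)) < 1e-12) {
      nce <- NULL
    } else {
      nce <- infoNCE(Z, Zp, tc$tau, grad = grad)
    }
  }
  contrOn <- tc$contrastive && !is.null(nce)
  reg <- if (contrOn) (if (grad) nce$loss else nce) else 0
  out <- list(sup = sup, reg = reg, loss = totalLoss(sup, reg), Yhat = Yhat)
  if (!grad) return(out)

  dlogits <- (Yhat - Y) / (M * C)
  gT <- zeroLike(params)
  for (m in seq_len(M)) {
    fw <- fws[[m]]
    gb <- graphBackward(params, mcfg, fw,
                        dlogits = dlogits[m, , drop = FALSE],
                        dzExtra = if (contrOn) nce$dZ[m, ] else NULL,
                        poolOnly = TRUE)
    dH <- gb$dH
    gT$head <- addNested(gT$head, gb$grads$head)
    if (mcfg$pooling == "hgt") gT$hgt <- addNested(gT$hgt, gb$grads$hgt)
    if (contrOn) {
      vb <- viewBackward(params, mcfg, pcaches[[m]], fw$S, nce$dZprime[m, ])
      dH <- dH + vb$dH      # perturbation is an additive view: identity pullback
      if (mcfg$pooling == "hgt") gT$hgt <- addNested(gT$hgt, vb$grads)
    }
    gT$gcn <- addNested(gT$gcn, encBackward(params, fw$enc, fw$S, dH))
  }
  out$grads <- gT
  out
}

#' Train a model with Adam, BCE and contrastive regularisation
#'
#' Each minibatch is forwarded to hidden node embeddings; a perturbed copy of
#' the embeddings ([perturbEmbeddings()]) is pooled through the same
#' hierarchical-attention parameters to give a second view; predictions come
#' from the unperturbed branch. The optimiser steps on the unit-weight sum of
#' the BCE loss and the InfoNCE loss between the paired views. Training stops
#' early when the validation loss has not improved for `patience` epochs, and
#' the best-validation parameters are returned.
#'
#' @param model a freshly initialised (or warm) [FunPredModel-class].
#' @param graphs list of [ProteinGraph-class] training graphs.
#' @param labels M x C binary label matrix, rows aligned with `graphs`.
#' @param validGraphs,validLabels optional validation set; when absent the
#'   training loss is used for early stopping.
#' @param config a [trainConfig()] list.
#' @return list with `model` (best parameters), `history` (data.frame with
#'   epoch, train_loss, valid_loss, lr) and `stoppedEarly`.
#' @export
trainModel <- function(model, graphs, labels, validGraphs = NULL,
                       validLabels = NULL, config = trainConfig()) {
  stopifnot(is(model, "FunPredModel"))
  if (length(graphs) == 0L) stop("empty training set")
  labels <- as.matrix(labels)
  stopifnot(nrow(labels) == length(graphs),
            ncol(labels) == model@config$nTerms)
  if (!is.null(config$seed)) set.seed(config$seed)
  mcfg <- model@config
  params <- model@params
  tc <- config

  theta <- flattenParams(params)
  mAdam <- theta * 0; vAdam <- theta * 0; tAdam <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  M <- length(graphs)
  best <- Inf; bestTheta <- theta; wait <- 0L
  hist <- vector("list", tc$maxEpochs)
  stopped <- FALSE

  for (epoch in seq_len(tc$maxEpochs)) {
    ord <- sample.int(M)
    starts <- seq(1L, M, by = tc$batchSize)
    epochLoss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + tc$batchSize - 1L, M)]
      bp <- batchPass(params, mcfg, graphs[idx],
                      labels[idx, , drop = FALSE], tc, grad = TRUE)
      g <- flattenParams(bp$grads)
      tAdam <- tAdam + 1L
      mAdam <- b1 * mAdam + (1 - b1) * g
      vAdam <- b2 * vAdam + (1 - b2) * g * g
      theta <- theta - tc$learningRate *
        (mAdam / (1 - b1^tAdam)) / (sqrt(vAdam / (1 - b2^tAdam)) + eps)
      params <- unflattenParams(theta, model@params)
      epochLoss <- epochLoss + bp$loss * length(idx)
    }
    trainLoss <- epochLoss / M

    validLoss <- if (!is.null(validGraphs) && length(validGraphs)) {
      evalLoss(params, mcfg, validGraphs, as.matrix(validLabels), tc)
    } else trainLoss

    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = trainLoss,
                                valid_loss = validLoss,
                                lr = tc$learningRate)
    if (tc$verbose)
      message(sprintf("epoch %3d  train %.5f  valid %.5f", epoch,
                      trainLoss, validLoss))

    if (validLoss < best - 1e-12) {
      best <- validLoss; bestTheta <- theta; wait <- 0L
    } else {
      wait <- wait + 1L
      if (is.finite(tc$patience) && wait >= tc$patience) {
        stopped <- TRUE
        break
      }
    }
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  new("FunPredModel", config = mcfg,
      params = unflattenParams(bestTheta, model@params)) -> bestModel
  list(model = bestModel, history = history, stoppedEarly = stopped)
}

# loss on a dataset, batched like training (InfoNCE is batch-composed).
# The contrastive view is drawn from a fixed RNG substream so that the
# validation loss is comparable across epochs (otherwise early stopping
# would track perturbation noise instead of model improvement).
evalLoss <- function(params, mcfg, graphs, labels, tc) {
  if (tc$contrastive) {
    if (exists(".Random.seed", envir = globalenv())) {
      oldSeed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
    }
    set.seed((tc$seed %||% 0) + 777L)
  }
  M <- length(graphs)
  starts <- seq(1L, M, by = tc$batchSize)
  tot <- 0
  for (s in starts) {
    idx <- s:min(s + tc$batchSize - 1L, M)
    bp <- batchPass(params, mcfg, graphs[idx],
                    labels[idx, , drop = FALSE], tc, grad = FALSE)
    tot <- tot + bp$loss * length(idx)
  }
  tot / M
}

#' Predict term scores for a list of graphs
#'
#' @param model a [FunPredModel-class].
#' @param graphs list of [ProteinGraph-class].
#' @return M x C matrix of probabilities; rownames are protein ids, colnames
#'   the model's term names when available.
#' @export
predictDataset <- function(model, graphs) {
  stopifnot(is(model, "FunPredModel"))
  out <- do.call(rbind, lapply(graphs, function(g) predictGraph(model, g)$yhat))
  rownames(out) <- vapply(graphs, function(g) g@proteinId, character(1))
  if (!is.null(model@config$termNames)) colnames(out) <- model@config$termNames
  out
}
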