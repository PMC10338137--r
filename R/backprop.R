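# Reverse-mode gradients for the network, written against the cached
# forward passes in model.R. Every routine returns parameter gradients in
# the same nested shape as the parameter list, so they can be accumulated
# and fed to the optimiser. Correctness is pinned to central finite
# differences in the test suite.

zeroLike <- function(p) rapply(p, function(x) x * 0, how = "replace")

addNested <- function(a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- addNested(a[[nm]], b[[nm]])
    a
  } else a + b
}

scaleNested <- function(a, s) rapply(a, function(x) x * s, how = "replace")

flattenParams <- function(p) unlist(p, use.names = FALSE)

unflattenParams <- function(v, skeleton) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- v[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  fill(skeleton)
}

# encoder backward: dH is the gradient at the encoder output
encBackward <- function(params, enc, S, dH) {
  N <- length(params$gcn)
  dW <- vector("list", N)
  for (n in rev(seq_len(N))) {
    dZ <- dH * (enc$Zs[[n]] > 0)
    SdZ <- S %*% dZ
    Hprev <- if (n == 1L) enc$X else enc$Hs[[n - 1L]]
    dW[[n]] <- t(Hprev) %*% SdZ
    dH <- SdZ %*% t(params$gcn[[n]])
  }
  dW
}

# prediction-head backward: dlogits is 1 x C; returns grads and dz (1 x D)
headBackward <- function(hp, cache, dlogits) {
  dW2 <- t(cache$h1) %*% dlogits
  db2 <- drop(dlogits)
  dh1 <- dlogits %*% t(hp$W2)
  dh1pre <- dh1 * (cache$h1pre > 0)
  dW1 <- t(cache$z) %*% dh1pre
  db1 <- drop(dh1pre)
  dz <- dh1pre %*% t(hp$W1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dz = dz)
}

# hierarchical-attention backward: dz is 1 x D; returns grads and dH (L x D)
hgtBackward <- function(hp, cache, S, dz) {
  D <- ncol(hp$Q)
  U <- cache$U; a <- cache$a; M <- cache$M
  da <- dz %*% t(M)                       # 1 x K
  dM <- t(a) %*% dz                       # K x D
  dU <- dM %*% t(hp$pool$Vp)
  dVp <- t(U) %*% dM
  ds <- a * (da - sum(da * a))            # softmax (single row) backward
  dQp <- (ds %*% cache$Kpm) / sqrt(D)
  dKpm <- (t(ds) %*% hp$pool$Qp) / sqrt(D)
  dU <- dU + dKpm %*% t(hp$pool$Kp)
  dKp <- t(U) %*% dKpm

  # per-super-node MLP
  dW2f <- t(cache$U1) %*% dU
  db2f <- colSums(dU)
  dU1 <- dU %*% t(hp$fc1$W2)
  dU1pre <- dU1 * (cache$U1pre > 0)
  dW1f <- t(cache$G) %*% dU1pre
  db1f <- colSums(dU1pre)
  dG <- dU1pre %*% t(hp$fc1$W1)           # K x (H*D)

  H <- cache$H
  dH <- matrix(0, nrow(H), ncol(H))
  dQ <- hp$Q * 0
  nH <- length(hp$heads)
  gheads <- vector("list", nH)
  for (h in seq_len(nH)) {
    ch <- cache$heads[[h]]
    dGh <- dG[, ((h - 1L) * D + 1L):(h * D), drop = FALSE]
    dAh <- dGh %*% t(ch$Vh)               # K x L
    dVh <- t(ch$Ah) %*% dGh               # L x D
    dsc <- ch$Ah * (dAh - rowSums(dAh * ch$Ah))   # row-softmax backward
    dQ <- dQ + (dsc %*% ch$Kh) / sqrt(D)
    dKh <- (t(dsc) %*% hp$Q) / sqrt(D)
    dKpre <- dKh * (ch$Kpre > 0)
    dVpre <- dVh * (ch$Vpre > 0)
    SdK <- S %*% dKpre
    SdV <- S %*% dVpre
    gheads[[h]] <- list(Wk = t(H) %*% SdK, Wv = t(H) %*% SdV)
    dH <- dH + SdK %*% t(hp$heads[[h]]$Wk) + SdV %*% t(hp$heads[[h]]$Wv)
  }
  list(grads = list(Q = dQ, heads = gheads,
                    fc1 = list(W1 = dW1f, b1 = db1f, W2 = dW2f, b2 = db2f),
                    pool = list(Qp = dQp, Kp = dKp, Vp = dVp)),
       dH = dH)
}

maxPoolBackward <- function(cache, dz) {
  dH <- matrix(0, cache$L, length(dz))
  dH[cbind(cache$idx, seq_along(dz))] <- dz
  dH
}

# full backward for one graph given the cached forward `fw`.
#   dlogits : 1 x C gradient at the pre-sigmoid logits (may be zero)
#   dzExtra : 1 x D extra gradient arriving at the graph embedding (InfoNCE)
# Returns parameter gradients; `dH` gives the gradient at the encoder output
# (before the pooling module), used by grad-CAM.
graphBackward <- function(params, config, fw, dlogits,
                          dzExtra = NULL, poolOnly = FALSE) {
  hb <- headBackward(params$head, fw$head, dlogits)
  dz <- hb$dz
  if (!is.null(dzExtra)) dz <- dz + matrix(dzExtra, nrow = 1)
  grads <- list(gcn = NULL, head = hb$grads)
  if (config$pooling == "hgt") {
    pb <- hgtBackward(params$hgt, fw$pool, fw$S, dz)
    grads$hgt <- pb$grads
    dH <- pb$dH
  } else {
    dH <- maxPoolBackward(fw$pool, drop(dz))
  }
  if (poolOnly) return(list(grads = grads, dH = dH))
  grads$gcn <- encBackward(params, fw$enc, fw$S, dH)
  list(grads = grads, dH = dH)
}

# gradient of the pooled branch only, for a perturbed view: the view shares
# the encoder, so its encoder-output gradient passes through unchanged.
viewBackward <- function(params, config, poolCache, S, dzView) {
  if (config$pooling == "hgt") {
    pb <- hgtBackward(params$hgt, poolCache, S, matrix(dzView, nrow = 1))
    list(grads = pb$grads, dH = pb$dH)
  } else {
    list(grads = NULL, dH = maxPoolBackward(poolCache, dzView))
  }
}
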