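# independent literal oracles: every routine here restates the defining
# formula with explicit loops or dense algebra, sharing no code with the
# implementation it checks

# one graph-convolution layer, dense and literal
oracleGCN <- function(Hin, A, W) {
  L <- nrow(A)
  At <- A + diag(L)
  Dt <- diag(rowSums(At))
  S <- solve(sqrt(Dt)) %*% At %*% solve(sqrt(Dt))
  Z <- S %*% Hin %*% W
  pmax(Z, 0)
}

# super-node attention, element by element
oracleSuperNode <- function(hp, H, A) {
  D <- ncol(hp$Q)
  K <- nrow(hp$Q)
  L <- nrow(H)
  gammas <- list()
  for (h in seq_along(hp$heads)) {
    Kh <- oracleGCN(H, A, hp$heads[[h]]$Wk)
    Vh <- oracleGCN(H, A, hp$heads[[h]]$Wv)
    G <- matrix(0, K, D)
    for (k in seq_len(K)) {
      sc <- numeric(L)
      for (i in seq_len(L)) sc[i] <- sum(hp$Q[k, ] * Kh[i, ]) / sqrt(D)
      w <- exp(sc - max(sc)); w <- w / sum(w)
      for (j in seq_len(D)) G[k, j] <- sum(w * Vh[, j])
    }
    gammas[[h]] <- G
  }
  Gcat <- do.call(cbind, gammas)
  U <- matrix(0, K, D)
  for (k in seq_len(K)) {
    u1 <- pmax(as.numeric(Gcat[k, ] %*% hp$fc1$W1) + hp$fc1$b1, 0)
    U[k, ] <- as.numeric(u1 %*% hp$fc1$W2) + hp$fc1$b2
  }
  U
}

oraclePool <- function(pp, U) {
  D <- ncol(U)
  K <- nrow(U)
  sc <- numeric(K)
  for (k in seq_len(K))
    sc[k] <- sum(pp$Qp[1, ] * as.numeric(U[k, ] %*% pp$Kp)) / sqrt(D)
  w <- exp(sc - max(sc)); w <- w / sum(w)
  z <- numeric(D)
  for (k in seq_len(K)) z <- z + w[k] * as.numeric(U[k, ] %*% pp$Vp)
  z
}

# InfoNCE by double loop over the minibatch
oracleInfoNCE <- function(Z, Zp, tau) {
  M <- nrow(Z)
  cosSim <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  tot <- 0
  for (m in seq_len(M)) {
    num <- exp(cosSim(Z[m, ], Zp[m, ]) / tau)
    den <- 0
    for (mp in seq_len(M)) den <- den + exp(cosSim(Z[m, ], Zp[mp, ]) / tau)
    tot <- tot - log(num / den)
  }
  tot / M
}

oracleBCE <- function(Y, Yhat) {
  tot <- 0
  for (i in seq_len(nrow(Y)))
    for (j in seq_len(ncol(Y))) {
      p <- min(max(Yhat[i, j], 1e-7), 1 - 1e-7)
      tot <- tot - (Y[i, j] * log(p) + (1 - Y[i, j]) * log(1 - p))
    }
  tot / (nrow(Y) * ncol(Y))
}

# protein-centric Fmax by exhaustive per-threshold loops
oracleFmax <- function(truth, scores, step = 0.01) {
  grid <- seq(0, 1, by = step)
  bestF <- 0; bestT <- grid[1]
  for (t in grid) {
    precs <- c(); recs <- c()
    for (i in seq_len(nrow(truth))) {
      pred <- which(scores[i, ] >= t & scores[i, ] > 0)
      true <- which(truth[i, ] == 1)
      if (length(pred))
        precs <- c(precs, length(intersect(pred, true)) / length(pred))
      if (length(true))
        recs <- c(recs, length(intersect(pred, true)) / length(true))
    }
    p <- if (length(precs)) mean(precs) else NA
    r <- mean(recs)
    f <- if (!is.na(p) && p + r > 0) 2 * p * r / (p + r) else 0
    if (f > bestF + 1e-15) { bestF <- f; bestT <- t }
  }
  list(fmax = bestF, threshold = bestT)
}

oracleSmin <- function(truth, scores, ic, step = 0.01) {
  grid <- seq(0, 1, by = step)
  bestS <- Inf
  for (t in grid) {
    rus <- c(); mis <- c()
    for (i in seq_len(nrow(truth))) {
      pred <- which(scores[i, ] >= t & scores[i, ] > 0)
      true <- which(truth[i, ] == 1)
      rus <- c(rus, sum(ic[setdiff(true, pred)]))
      mis <- c(mis, sum(ic[setdiff(pred, true)]))
    }
    s <- sqrt(mean(rus)^2 + mean(mis)^2)
    if (s < bestS) bestS <- s
  }
  bestS
}

# micro AUPR by a literal rank walk with tie blocks
oracleAUPR <- function(y, s) {
  o <- order(s, decreasing = TRUE)
  y <- y[o]; s <- s[o]
  nPos <- sum(y)
  tp <- 0; fp <- 0; lastRec <- 0; area <- 0
  i <- 1
  while (i <= length(y)) {
    j <- i
    while (j < length(y) && s[j + 1] == s[i]) j <- j + 1
    tp <- tp + sum(y[i:j]); fp <- fp + sum(1 - y[i:j])
    prec <- tp / (tp + fp); rec <- tp / nPos
    area <- area + (rec - lastRec) * prec
    lastRec <- rec
    i <- j + 1
  }
  area
}

# ancestral closure by boolean reachability matrix powers
oraclePropagate <- function(terms, dag) {
  n <- length(dag@terms)
  R <- matrix(FALSE, n, n, dimnames = list(dag@terms, dag@terms))
  for (t in names(dag@parents)) R[t, dag@parents[[t]]] <- TRUE
  reach <- R
  for (k in seq_len(n)) reach <- reach | (reach %*% R > 0)
  out <- terms
  for (t in terms) {
    anc <- dag@terms[reach[t, ]]
    anc <- anc[dag@namespace[anc] == dag@namespace[[t]]]
    out <- union(out, anc)
  }
  sort(out)
}

# brute-force contact map
oracleContacts <- function(coords, cutoff) {
  L <- nrow(coords)
  A <- matrix(0, L, L)
  for (i in seq_len(L))
    for (j in seq_len(L))
      if (i != j &&
          sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff) A[i, j] <- 1
  A
}

# AUROC as normalised Mann-Whitney U with half credit for ties
oracleAUROC <- function(scores, mask) {
  pos <- scores[mask]; neg <- scores[!mask]
  u <- 0
  for (a in pos)
    for (b in neg)
      u <- u + (a > b) + 0.5 * (a == b)
  u / (length(pos) * length(neg))
}
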