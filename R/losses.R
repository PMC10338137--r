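#' Same-direction perturbation of node embeddings
#'
#' Produces a second "view" of a graph by adding noise to every node
#' embedding without flipping any coordinate's sign: for each node a noise
#' vector of Euclidean norm `epsilon` is drawn uniformly on the sphere and
#' its elementwise absolute value is added along `sign(h)`. Coordinates that
#' are exactly zero stay zero, so the perturbation preserves the sparsity
#' pattern left by the ReLU encoder.
#'
#' @param H L x D node embedding matrix.
#' @param epsilon positive perturbation norm.
#' @return perturbed L x D matrix (uses the current RNG stream).
#' @export
perturbEmbeddings <- function(H, epsilon) {
  if (epsilon <= 0) stop("epsilon must be positive")
  D <- ncol(H)
  noise <- t(vapply(seq_len(nrow(H)), function(i) abs(runifSphere(D)),
                    numeric(D)))
  H + epsilon * noise * sign(H)
}

#' InfoNCE contrastive loss over paired graph embeddings
#'
#' For a minibatch of M graphs with two views each (rows of `Z` and `Zprime`
#' paired by index), computes
#' \deqn{-\frac1M \sum_m \log \frac{\exp(\cos(z_m, z'_m)/\tau)}
#'   {\sum_{m'} \exp(\cos(z_m, z'_{m'})/\tau)}}
#' pulling each graph's two views together and pushing other graphs' views
#' apart. Cosine similarity makes the loss invariant to positive rescaling
#' of any embedding.
#'
#' @param Z,Zprime M x D matrices of graph embeddings, rows paired.
#' @param tau temperature (default 0.5).
#' @param grad if TRUE also return gradients with respect to `Z`, `Zprime`.
#' @return the loss (nonnegative scalar); with `grad = TRUE` a list
#'   `(loss, dZ, dZprime)`.
#' @export
infoNCE <- function(Z, Zprime, tau = 0.5, grad = FALSE) {
  Z <- as.matrix(Z); Zprime <- as.matrix(Zprime)
  stopifnot(nrow(Z) == nrow(Zprime), ncol(Z) == ncol(Zprime), tau > 0)
  M <- nrow(Z)
  nz <- rowNorms(Z); nzp <- rowNorms(Zprime)
  if (any(nz < 1e-12) || any(nzp < 1e-12))
    stop("zero-norm embedding: cosine similarity undefined")
  Zn <- Z / nz; Zpn <- Zprime / nzp
  Cs <- Zn %*% t(Zpn)                      # M x M cosine similarities
  logits <- Cs / tau
  mx <- apply(logits, 1L, max)
  lse <- mx + log(rowSums(exp(logits - mx)))
  loss <- -mean(diag(logits) - lse)
  if (!grad) return(loss)
  P <- exp(logits - lse)                   # row-softmax
  G <- -(diag(M) - P) / (M * tau)          # dloss/dCs
  dZn <- G %*% Zpn
  dZpn <- t(G) %*% Zn
  # through row normalisation: d(z/|z|) pullback
  dZ <- (dZn - Zn * rowSums(dZn * Zn)) / nz
  dZp <- (dZpn - Zpn * rowSums(dZpn * Zpn)) / nzp
  list(loss = loss, dZ = dZ, dZprime = dZp)
}

#' Binary cross-entropy over a minibatch
#'
#' Mean over all M x C (protein, term) entries of
#' \eqn{-[y \log\hat y + (1-y)\log(1-\hat y)]}, with predictions clamped to
#' `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param Y M x C binary ground-truth matrix.
#' @param Yhat M x C predicted probabilities.
#' @return nonnegative scalar loss.
#' @export
bceLoss <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat))) stop("shape mismatch between Y and Yhat")
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  p <- pmin(pmax(Yhat, 1e-7), 1 - 1e-7)
  -mean(Y * log(p) + (1 - Y) * log(1 - p))
}

#' Total training loss
#'
#' Unit-weight sum of the supervised (BCE) and contrastive (InfoNCE) losses.
#'
#' @param sup supervised loss.
#' @param reg contrastive regularisation loss.
#' @return `sup + reg`.
#' @export
totalLoss <- function(sup, reg) {
  stopifnot(is.finite(sup), is.finite(reg))
  sup + reg
}
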