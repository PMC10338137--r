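CHECKPOINT_FORMAT <- 1L

glorotMat <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

#' Construct a function-prediction model
#'
#' Builds the network: `nGcnLayers` graph-convolution layers mapping the
#' F-dimensional node features to a D-dimensional hidden embedding, a
#' hierarchical attention module with `nSuperNodes` learnable super-node
#' queries and `nHeads` attention heads that pools residues into a single
#' graph vector, and a two-layer sigmoid MLP head scoring `nTerms` GO terms.
#' Weights are Glorot-uniform initialised from the current RNG state (pass
#' `seed` for reproducibility).
#'
#' @param inputDim node feature width F (21 for one-hot-only features).
#' @param nTerms number of GO terms C.
#' @param hiddenDim hidden width D (default 512).
#' @param nGcnLayers number of graph-convolution layers N (default 4).
#' @param nSuperNodes number of learnable super-node queries K (default 8).
#' @param nHeads number of attention heads H (default 4).
#' @param pooling `"hgt"` for the hierarchical attention pooling, `"max"`
#'   for the elementwise max-pool ablation.
#' @param termNames optional character vector of term ids (length `nTerms`).
#' @param seed optional integer seed for initialisation.
#' @param quiet suppress the construction log line.
#' @return A [FunPredModel-class].
#' @export
funPredModel <- function(inputDim, nTerms, hiddenDim = 512, nGcnLayers = 4,
                         nSuperNodes = 8, nHeads = 4,
                         pooling = c("hgt", "max"), termNames = NULL,
                         seed = NULL, quiet = FALSE) {
  pooling <- match.arg(pooling)
  stopifnot(inputDim >= 1, nTerms >= 1, hiddenDim >= 1, nGcnLayers >= 1,
            nSuperNodes >= 1, nHeads >= 1)
  if (!is.null(termNames)) stopifnot(length(termNames) == nTerms)
  if (!is.null(seed)) set.seed(seed)
  D <- hiddenDim; K <- nSuperNodes; H <- nHeads; C <- nTerms
  config <- list(inputDim = inputDim, hiddenDim = D, nGcnLayers = nGcnLayers,
                 nSuperNodes = K, nHeads = H, nTerms = C, pooling = pooling,
                 termNames = termNames, format = CHECKPOINT_FORMAT)
  params <- list(
    gcn = lapply(seq_len(nGcnLayers), function(i)
      glorotMat(if (i == 1) inputDim else D, D)),
    head = list(W1 = glorotMat(D, D), b1 = numeric(D),
                W2 = glorotMat(D, C), b2 = numeric(C))
  )
  if (pooling == "hgt") {
    params$hgt <- list(
      Q = glorotMat(K, D),
      heads = lapply(seq_len(H), function(h)
        list(Wk = glorotMat(D, D), Wv = glorotMat(D, D))),
      fc1 = list(W1 = glorotMat(H * D, D), b1 = numeric(D),
                 W2 = glorotMat(D, D), b2 = numeric(D)),
      pool = list(Qp = glorotMat(1, D), Kp = glorotMat(D, D),
                  Vp = glorotMat(D, D))
    )
  }
  if (!quiet)
    message(sprintf(
      "model: F=%d D=%d N=%d K=%d H=%d C=%d pooling=%s", inputDim, D,
      nGcnLayers, K, H, C, pooling))
  new("FunPredModel", config = config, params = params)
}

#' One graph-convolution layer
#'
#' Computes `ReLU(S Hin W)` where `S` is the symmetrically normalised
#' adjacency with self-loops added ([normalizedAdjacency()]). The input
#' adjacency must be the raw contact map (zero diagonal); self-loops are added
#' here, inside the layer.
#'
#' @param Hin L x d input node embeddings.
#' @param A L x L symmetric binary adjacency, zero diagonal.
#' @param W d x d' weight matrix.
#' @return L x d' activated node embeddings.
#' @export
gcnLayer <- function(Hin, A, W) {
  if (ncol(Hin) != nrow(W)) stop("dimension mismatch: ncol(Hin) != nrow(W)")
  if (nrow(Hin) != nrow(A)) stop("dimension mismatch: nrow(Hin) != nrow(A)")
  relu(normalizedAdjacency(A) %*% Hin %*% W)
}

# cached encoder forward: returns pre-activations and activations per layer
encForward <- function(params, X, S) {
  N <- length(params$gcn)
  Hs <- vector("list", N)
  Zs <- vector("list", N)
  Hcur <- X
  for (n in seq_len(N)) {
    Zs[[n]] <- S %*% (Hcur %*% params$gcn[[n]])
    Hcur <- relu(Zs[[n]])
    Hs[[n]] <- Hcur
  }
  list(H = Hcur, Hs = Hs, Zs = Zs, X = X)
}

#' Encode a graph into hidden node embeddings
#'
#' Applies the model's stack of graph-convolution layers (the first maps
#' F to D, the rest D to D) to produce the L x D hidden embedding matrix that
#' the pooling module and grad-CAM both consume.
#'
#' @param model a [FunPredModel-class].
#' @param X L x F node features.
#' @param A L x L adjacency.
#' @return L x D matrix of node embeddings.
#' @export
encodeGraph <- function(model, X, A) {
  stopifnot(is(model, "FunPredModel"))
  encForward(model@params, X, normalizedAdjacency(A))$H
}

# cached hierarchical-attention forward from hidden embeddings H
hgtForward <- function(hp, H, S) {
  D <- ncol(hp$Q)
  nH <- length(hp$heads)
  heads <- vector("list", nH)
  for (h in seq_len(nH)) {
    ph <- hp$heads[[h]]
    Kpre <- S %*% (H %*% ph$Wk)
    Vpre <- S %*% (H %*% ph$Wv)
    Kh <- relu(Kpre); Vh <- relu(Vpre)
    scores <- (hp$Q %*% t(Kh)) / sqrt(D)       # K x L
    Ah <- rowSoftmax(scores)
    heads[[h]] <- list(Kpre = Kpre, Vpre = Vpre, Kh = Kh, Vh = Vh,
                       Ah = Ah, G = Ah %*% Vh)
  }
  G <- do.call(cbind, lapply(heads, `[[`, "G"))  # K x (H*D)
  U1pre <- sweep(G %*% hp$fc1$W1, 2, hp$fc1$b1, "+")
  U1 <- relu(U1pre)
  U <- sweep(U1 %*% hp$fc1$W2, 2, hp$fc1$b2, "+")
  # attention pooling over super-nodes
  Kpm <- U %*% hp$pool$Kp                         # K x D
  s <- (hp$pool$Qp %*% t(Kpm)) / sqrt(D)          # 1 x K
  a <- rowSoftmax(s)
  M <- U %*% hp$pool$Vp                           # K x D
  z <- a %*% M                                    # 1 x D
  list(heads = heads, G = G, U1pre = U1pre, U1 = U1, U = U,
       Kpm = Kpm, a = a, M = M, z = z, H = H)
}

maxPoolForward <- function(H) {
  idx <- max.col(t(H), ties.method = "first")     # argmax node per dimension
  list(z = matrix(H[cbind(idx, seq_len(ncol(H)))], 1), idx = idx,
       L = nrow(H))
}

# z -> predictions (cached)
headForward <- function(hp, z) {
  h1pre <- sweep(z %*% hp$W1, 2, hp$b1, "+")
  h1 <- relu(h1pre)
  logits <- sweep(h1 %*% hp$W2, 2, hp$b2, "+")
  list(h1pre = h1pre, h1 = h1, logits = logits,
       yhat = sigmoid(logits), z = z)
}

#' Super-node attention: pool residues into K super-node embeddings
#'
#' Each learnable super-node query attends over all residues; keys and values
#' are graph-convolved transforms of the hidden embeddings, so attention
#' weights respect graph topology. Per head h the attention output is
#' `softmax(Q K_h' / sqrt(D)) V_h`, with the softmax taken over residues so
#' each super-node's weights sum to one; head outputs are concatenated and
#' mixed by a per-super-node two-layer MLP.
#'
#' @param model a [FunPredModel-class] with `pooling = "hgt"`.
#' @param H L x D hidden node embeddings.
#' @param A L x L adjacency.
#' @return K x D super-node embedding matrix; the per-head attention
#'   matrices (each K x L) are attached as attribute `"attention"`.
#' @export
superNodeAttention <- function(model, H, A) {
  stopifnot(is(model, "FunPredModel"), model@config$pooling == "hgt")
  fw <- hgtForward(model@params$hgt, H, normalizedAdjacency(A))
  structure(fw$U, attention = lapply(fw$heads, `[[`, "Ah"))
}

#' Attention pooling of super-nodes into one graph embedding
#'
#' A single learnable query scores the K super-node embeddings
#' (`softmax(Qp (U Kp)' / sqrt(D))`) and the graph embedding is the weighted
#' sum of value-transformed super-nodes.
#'
#' @param model a [FunPredModel-class] with `pooling = "hgt"`.
#' @param U K x D super-node embeddings.
#' @return length-D graph embedding with the length-K pooling weights as
#'   attribute `"weights"`.
#' @export
attentionPool <- function(model, U) {
  stopifnot(is(model, "FunPredModel"), model@config$pooling == "hgt")
  hp <- model@params$hgt$pool
  D <- ncol(U)
  s <- (hp$Qp %*% t(U %*% hp$Kp)) / sqrt(D)
  a <- rowSoftmax(s)
  structure(drop(a %*% (U %*% hp$Vp)), weights = drop(a))
}

#' Score GO terms from a graph embedding
#'
#' Two-layer MLP with ReLU then an elementwise sigmoid; outputs are strictly
#' inside (0, 1).
#'
#' @param model a [FunPredModel-class].
#' @param z length-D graph embedding (or 1 x D matrix).
#' @return length-C vector of term probabilities.
#' @export
predictHead <- function(model, z) {
  stopifnot(is(model, "FunPredModel"))
  drop(headForward(model@params$head, matrix(z, nrow = 1))$yhat)
}

# full cached forward used by training / saliency
forwardCached <- function(params, config, X, A) {
  S <- normalizedAdjacency(A)
  enc <- encForward(params, X, S)
  if (config$pooling == "hgt") {
    pool <- hgtForward(params$hgt, enc$H, S)
  } else {
    pool <- maxPoolForward(enc$H)
  }
  head <- headForward(params$head, pool$z)
  list(S = S, enc = enc, pool = pool, head = head)
}

#' Forward pass over one protein graph
#'
#' Runs encoder, hierarchical pooling and prediction head, returning the term
#' probabilities together with the intermediate node embeddings and graph
#' embedding used by training and saliency.
#'
#' @param model a [FunPredModel-class].
#' @param graph a [ProteinGraph-class].
#' @return list with `yhat` (length-C probabilities), `H` (L x D node
#'   embeddings) and `z` (length-D graph embedding).
#' @export
predictGraph <- function(model, graph) {
  stopifnot(is(model, "FunPredModel"), is(graph, "ProteinGraph"))
  if (ncol(graph@X) != model@config$inputDim)
    stop("graph feature width ", ncol(graph@X),
         " does not match model inputDim ", model@config$inputDim)
  fw <- forwardCached(model@params, model@config, graph@X, graph@A)
  list(yhat = drop(fw$head$yhat), H = fw$enc$H, z = drop(fw$pool$z))
}

#' Save / load model checkpoints
#'
#' Checkpoints are versioned containers holding the architecture
#' configuration and all parameters; loading refuses a file whose format
#' version or configuration is incompatible.
#'
#' @param model a [FunPredModel-class].
#' @param path checkpoint file path (`.rds`).
#' @return `saveCheckpoint` the path invisibly; `loadCheckpoint` the model.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "FunPredModel"))
  saveRDS(list(format = CHECKPOINT_FORMAT,
               package = "profun",
               config = model@config, params = model@params), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$package, "profun") || is.null(obj$format))
    stop("not a recognised checkpoint: ", path)
  if (obj$format != CHECKPOINT_FORMAT)
    stop("checkpoint format ", obj$format, " is incompatible with this ",
         "version (expects ", CHECKPOINT_FORMAT, ")")
  new("FunPredModel", config = obj$config, params = obj$params)
}
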