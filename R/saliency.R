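#' Grad-CAM residue saliency for one (protein, term) pair
#'
#' Treats the encoder output (the last graph-convolution layer's activations,
#' an L x D matrix `F`) as the feature map, takes the gradient `W = dy/dF` of
#' the term output by reverse-mode differentiation, and scores residue i as
#' `ReLU(sum_j W[i,j] F[i,j] / D)`. By default the derivative is taken with
#' respect to the pre-sigmoid logit, which keeps gradients informative when
#' the predicted probability saturates; set `target = "probability"` for the
#' sigmoid output itself.
#'
#' @param model a [FunPredModel-class].
#' @param graph a [ProteinGraph-class].
#' @param termIndex 1-based column of the term to explain.
#' @param target differentiate the `"logit"` (default) or `"probability"`.
#' @param numbering optional author residue numbering for reporting.
#' @return A [SaliencyMap-class] with raw and 0-100 scaled scores.
#' @export
gradCAM <- function(model, graph, termIndex,
                    target = c("logit", "probability"), numbering = NULL) {
  target <- match.arg(target)
  stopifnot(is(model, "FunPredModel"), is(graph, "ProteinGraph"))
  C <- model@config$nTerms
  if (termIndex < 1 || termIndex > C)
    stop("termIndex out of range 1..", C)
  fw <- forwardCached(model@params, model@config, graph@X, graph@A)
  dlogits <- matrix(0, 1, C)
  dlogits[1, termIndex] <- if (target == "logit") 1 else {
    y <- fw$head$yhat[1, termIndex]
    y * (1 - y)
  }
  W <- graphBackward(model@params, model@config, fw, dlogits,
                     poolOnly = TRUE)$dH
  Fmap <- fw$enc$H
  raw <- relu(rowSums(W * Fmap) / ncol(Fmap))
  termId <- if (!is.null(model@config$termNames))
    model@config$termNames[termIndex] else paste0("term", termIndex)
  if (is.null(numbering)) numbering <- as.character(seq_len(nrow(Fmap)))
  new("SaliencyMap", proteinId = graph@proteinId, termId = termId,
      raw = as.numeric(raw), scaled = scaleScores(raw),
      numbering = numbering)
}

#' Min-max scale saliency scores to 0-100
#'
#' Constant input (no contrast to display) maps to all zeros by convention.
#'
#' @param raw nonnegative numeric vector.
#' @return numeric vector in `[0, 100]`.
#' @export
scaleScores <- function(raw) {
  if (any(raw < 0)) stop("raw saliency must be nonnegative")
  rng <- range(raw)
  if (diff(rng) < 1e-300) return(rep(0, length(raw)))
  (raw - rng[1]) / diff(rng) * 100
}

#' AUROC of saliency scores against a binding-site mask
#'
#' Mann-Whitney (midrank) AUROC: the probability that a random site residue
#' outscores a random non-site residue, with ties counted half. Invariant to
#' any strictly increasing transform of the scores.
#'
#' @param scores per-residue saliency scores.
#' @param siteMask logical vector, TRUE at site residues; needs at least one
#'   TRUE and one FALSE.
#' @return AUROC in `[0, 1]`.
#' @export
saliencyAUC <- function(scores, siteMask) {
  stopifnot(length(scores) == length(siteMask))
  siteMask <- as.logical(siteMask)
  n1 <- sum(siteMask); n0 <- sum(!siteMask)
  if (n1 == 0 || n0 == 0)
    stop("degenerate mask: need both site and non-site residues")
  r <- rank(scores)   # midranks
  (sum(r[siteMask]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Read a binding-site mask file
#'
#' Simple TSV of `protein_id residue_number`; returns, for one protein, a
#' logical mask over the chain's author numbering.
#'
#' @param path TSV path.
#' @param proteinId protein to extract.
#' @param numbering the chain's author residue numbering.
#' @return logical vector aligned with `numbering`.
#' @export
readSiteMask <- function(path, proteinId, numbering) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  df <- df[df[[1]] == proteinId, , drop = FALSE]
  numbering %in% as.character(df[[2]])
}

#' Export a saliency map
#'
#' `writeSaliencyTSV` writes one row per residue (protein_id, term_id,
#' residue_number, raw, scaled). `writeSaliencyPDB` writes the chain as a
#' C-alpha PDB with the scaled scores in the B-factor column so the map can
#' be coloured in a structure viewer.
#'
#' @param map a [SaliencyMap-class].
#' @param path output path.
#' @param chain the [ResidueChain-class] the map belongs to.
#' @return the path, invisibly.
#' @export
writeSaliencyTSV <- function(map, path) {
  stopifnot(is(map, "SaliencyMap"))
  df <- data.frame(protein_id = map@proteinId, term_id = map@termId,
                   residue_number = map@numbering,
                   raw = map@raw, scaled = round(map@scaled, 4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSaliencyTSV
#' @export
writeSaliencyPDB <- function(map, chain, path) {
  stopifnot(is(map, "SaliencyMap"), is(chain, "ResidueChain"),
            length(map@raw) == length(chain))
  writeChainPDB(chain, path, bfactor = map@scaled)
}
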