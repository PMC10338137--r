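#' One-letter residue alphabet used for feature encoding
#'
#' The 20 standard amino acids in alphabetical one-letter order, followed by
#' `"X"` for unknown or non-standard residues. Column order of every one-hot
#' feature block.
#'
#' @export
RESIDUE_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' ResidueChain: one protein chain as sequence plus C-alpha trace
#'
#' The raw structural record consumed by the rest of the package: a one-letter
#' sequence, an L x 3 matrix of C-alpha coordinates in Angstrom, a mask of
#' residues whose coordinate is actually resolved, and the author residue
#' numbering (with insertion codes) kept for reporting.
#'
#' @slot proteinId protein identifier.
#' @slot chainId chain identifier within the source structure.
#' @slot sequence one-letter residue string of length L.
#' @slot coords L x 3 numeric matrix of C-alpha coordinates (Angstrom).
#' @slot resolvedMask logical length L; TRUE where a C-alpha exists.
#' @slot numbering character length L; author residue numbers (may carry
#'   insertion codes), used for 1-based reporting in exports.
#'
#' @exportClass ResidueChain
setClass("ResidueChain",
  representation(
    proteinId = "character",
    chainId = "character",
    sequence = "character",
    coords = "matrix",
    resolvedMask = "logical",
    numbering = "character"
  )
)

setValidity("ResidueChain", function(object) {
  L <- nchar(object@sequence)
  if (length(object@sequence) != 1L) return("sequence must be a single string")
  if (nrow(object@coords) != L) return("coords rows must equal sequence length")
  if (ncol(object@coords) != 3L) return("coords must have 3 columns")
  if (length(object@resolvedMask) != L) return("resolvedMask length mismatch")
  if (length(object@numbering) != L) return("numbering length mismatch")
  if (any(!is.finite(object@coords[object@resolvedMask, , drop = FALSE])))
    return("coordinates must be finite where resolved")
  TRUE
})

#' Construct a ResidueChain
#'
#' @param proteinId,chainId identifiers.
#' @param sequence one-letter residue string.
#' @param coords L x 3 numeric matrix of C-alpha coordinates.
#' @param resolvedMask logical length L (default all TRUE).
#' @param numbering author residue numbering (default `1:L`).
#' @return A [ResidueChain-class] object.
#' @export
residueChain <- function(proteinId, sequence, coords,
                         chainId = "A",
                         resolvedMask = rep(TRUE, nchar(sequence)),
                         numbering = as.character(seq_len(nchar(sequence)))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  new("ResidueChain", proteinId = proteinId, chainId = chainId,
      sequence = sequence, coords = coords,
      resolvedMask = resolvedMask, numbering = numbering)
}

#' ContactGraph: binary residue contact map
#'
#' Symmetric binary adjacency over residues of one chain: an edge joins two
#' resolved residues whose C-alpha distance is strictly below the cutoff.
#' Self-loops are absent here; they are added inside the graph-convolution
#' layer where the propagation operator is formed.
#'
#' @slot adjacency L x L binary matrix, symmetric, zero diagonal.
#' @slot cutoff contact cutoff in Angstrom.
#' @slot distances L x L matrix of pairwise C-alpha distances (NA where a
#'   residue is unresolved), kept for edge-list export.
#'
#' @exportClass ContactGraph
setClass("ContactGraph",
  representation(adjacency = "matrix", cutoff = "numeric",
                 distances = "matrix")
)

setValidity("ContactGraph", function(object) {
  A <- object@adjacency
  if (nrow(A) != ncol(A)) return("adjacency must be square")
  if (!all(A %in% c(0, 1))) return("adjacency must be binary")
  if (any(A != t(A))) return("adjacency must be symmetric")
  if (any(diag(A) != 0)) return("adjacency diagonal must be zero")
  if (object@cutoff <= 0) return("cutoff must be positive")
  TRUE
})

#' ProteinGraph: the model input for one protein
#'
#' Node-feature matrix (one-hot residue identity, optionally concatenated
#' with per-residue embeddings) plus the binary contact adjacency.
#'
#' @slot proteinId protein identifier.
#' @slot X L x F node-feature matrix.
#' @slot A L x L binary adjacency (no self-loops).
#' @slot blocks named list of feature-block widths, in column order.
#'
#' @exportClass ProteinGraph
setClass("ProteinGraph",
  representation(proteinId = "character", X = "matrix", A = "matrix",
                 blocks = "list")
)

setValidity("ProteinGraph", function(object) {
  if (nrow(object@X) != nrow(object@A)) return("X and A row mismatch")
  if (nrow(object@A) != ncol(object@A)) return("A must be square")
  if (any(object@A != t(object@A))) return("A must be symmetric")
  if (any(diag(object@A) != 0)) return("A diagonal must be zero")
  bw <- sum(unlist(object@blocks))
  if (length(object@blocks) && bw != ncol(object@X))
    return("block widths must sum to ncol(X)")
  TRUE
})

#' GODag: a Gene Ontology directed acyclic graph
#'
#' Terms, their parents via `is_a`/`part_of`, and the namespace of each term
#' (MF, BP or CC).
#'
#' @slot terms character vector of term ids.
#' @slot parents named list: term id -> character vector of parent ids.
#' @slot namespace named character: term id -> one of "MF", "BP", "CC".
#'
#' @exportClass GODag
setClass("GODag",
  representation(terms = "character", parents = "list",
                 namespace = "character")
)

setValidity("GODag", function(object) {
  if (!all(names(object@parents) %in% object@terms))
    return("parents keys must be terms")
  if (!all(object@terms %in% names(object@namespace)))
    return("every term needs a namespace")
  TRUE
})

#' AnnotationStore: protein-to-term assignments with information content
#'
#' Holds ancestor-propagated GO assignments per protein, per-term counts in
#' the reference (training) set, and the derived information content in bits.
#'
#' @slot assignments named list: protein id -> character vector of term ids.
#' @slot termCounts named numeric: term id -> count of annotated proteins.
#' @slot ic named numeric: term id -> information content (bits).
#' @slot nProteins number of proteins the counts refer to.
#'
#' @exportClass AnnotationStore
setClass("AnnotationStore",
  representation(assignments = "list", termCounts = "numeric",
                 ic = "numeric", nProteins = "numeric")
)

#' FunPredModel: network configuration plus parameters
#'
#' The trained (or freshly initialised) predictor: a GCN encoder, the
#' hierarchical super-node attention pooling, and a sigmoid MLP head.
#'
#' @slot config named list of architecture settings (see [funPredModel()]).
#' @slot params nested named list of parameter matrices.
#'
#' @exportClass FunPredModel
setClass("FunPredModel",
  representation(config = "list", params = "list")
)

#' SaliencyMap: per-residue grad-CAM attribution for one (protein, term)
#'
#' @slot proteinId protein identifier.
#' @slot termId GO term (or synthetic term) identifier.
#' @slot raw nonnegative length-L vector of raw class-activation scores.
#' @slot scaled length-L vector min-max scaled to `[0, 100]`.
#' @slot numbering author residue numbering for reporting.
#'
#' @exportClass SaliencyMap
setClass("SaliencyMap",
  representation(proteinId = "character", termId = "character",
                 raw = "numeric", scaled = "numeric", numbering = "character")
)

setValidity("SaliencyMap", function(object) {
  if (any(object@raw < 0)) return("raw saliency must be nonnegative")
  if (any(object@scaled < -1e-9 | object@scaled > 100 + 1e-9))
    return("scaled saliency must lie in [0, 100]")
  if (length(object@raw) != length(object@scaled))
    return("raw/scaled length mismatch")
  TRUE
})

## ------------------------------------------------------------------ accessors

#' @describeIn ResidueChain-class sequence accessor
#' @param x object.
#' @export
setGeneric("chainSequence", function(x) standardGeneric("chainSequence"))

#' @export
setMethod("chainSequence", "ResidueChain", function(x) x@sequence)

#' @describeIn ResidueChain-class C-alpha coordinate accessor
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' @export
setMethod("caCoords", "ResidueChain", function(x) x@coords)

#' @describeIn ResidueChain-class number of residues
#' @export
setMethod("length", "ResidueChain", function(x) nchar(x@sequence))

#' Adjacency accessor
#' @param x a [ContactGraph-class] or [ProteinGraph-class].
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @export
setMethod("adjacency", "ContactGraph", function(x) x@adjacency)

#' @export
setMethod("adjacency", "ProteinGraph", function(x) x@A)

#' Node-feature accessor
#' @param x a [ProteinGraph-class].
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))

#' @export
setMethod("nodeFeatures", "ProteinGraph", function(x) x@X)

#' Model configuration accessor
#' @param x a [FunPredModel-class].
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @export
setMethod("modelConfig", "FunPredModel", function(x) x@config)

#' Model parameter accessor
#' @param x a [FunPredModel-class].
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @export
setMethod("modelParams", "FunPredModel", function(x) x@params)

#' Raw saliency accessor
#' @param x a [SaliencyMap-class].
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))

#' @export
setMethod("rawScores", "SaliencyMap", function(x) x@raw)

#' Scaled (0-100) saliency accessor
#' @param x a [SaliencyMap-class].
#' @export
setGeneric("scaledScores", function(x) standardGeneric("scaledScores"))

#' @export
setMethod("scaledScores", "SaliencyMap", function(x) x@scaled)

## ----------------------------------------------------------------- show methods

setMethod("show", "ResidueChain", function(object) {
  cat(sprintf("ResidueChain %s/%s: %d residues (%d resolved)\n",
              object@proteinId, object@chainId, length(object),
              sum(object@resolvedMask)))
})

setMethod("show", "ContactGraph", function(object) {
  cat(sprintf("ContactGraph: %d residues, %d contacts, cutoff %.1f A\n",
              nrow(object@adjacency), sum(object@adjacency) / 2,
              object@cutoff))
})

setMethod("show", "ProteinGraph", function(object) {
  cat(sprintf("ProteinGraph %s: L=%d, F=%d (%s), %d contacts\n",
              object@proteinId, nrow(object@X), ncol(object@X),
              paste(sprintf("%s:%d", names(object@blocks),
                            unlist(object@blocks)), collapse = "+"),
              sum(object@A) / 2))
})

setMethod("show", "GODag", function(object) {
  ns <- table(object@namespace[object@terms])
  cat(sprintf("GODag: %d terms (%s)\n", length(object@terms),
              paste(sprintf("%s:%d", names(ns), as.integer(ns)),
                    collapse = ", ")))
})

setMethod("show", "AnnotationStore", function(object) {
  cat(sprintf(
    "AnnotationStore: %d proteins, %d annotated terms, IC for %d terms\n",
    length(object@assignments), length(object@termCounts),
    length(object@ic)))
})

setMethod("show", "FunPredModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "FunPredModel: F=%d -> D=%d (%d GCN layers), K=%d super-nodes, H=%d heads, C=%d terms, pooling=%s\n",
    cfg$inputDim, cfg$hiddenDim, cfg$nGcnLayers, cfg$nSuperNodes,
    cfg$nHeads, cfg$nTerms, cfg$pooling))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap %s / %s: %d residues, max raw %.4g\n",
              object@proteinId, object@termId, length(object@raw),
              if (length(object@raw)) max(object@raw) else NA_real_))
})
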