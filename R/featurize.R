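#' One-hot encode a residue sequence
#'
#' Encodes a one-letter sequence over the 21-symbol alphabet
#' ([RESIDUE_ALPHABET]: 20 standard residues plus `"X"`). Any symbol outside
#' the standard 20 maps to the `"X"` column, so each row has exactly one 1.
#'
#' @param sequence non-empty one-letter residue string (or character vector
#'   of single letters).
#' @param alphabet encoding alphabet; the last symbol is the unknown bucket.
#' @return L x length(alphabet) binary matrix with alphabet column names.
#' @export
oneHotEncode <- function(sequence, alphabet = RESIDUE_ALPHABET) {
  chars <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  if (length(chars) == 0L) stop("empty sequence")
  idx <- match(chars, alphabet)
  idx[is.na(idx)] <- length(alphabet)   # unknown bucket
  X <- matrix(0, nrow = length(chars), ncol = length(alphabet),
              dimnames = list(NULL, alphabet))
  X[cbind(seq_along(idx), idx)] <- 1
  X
}

#' Embedding providers
#'
#' An embedding provider supplies precomputed per-residue embeddings (for
#' example from a protein language model) as an L x dim matrix per protein id.
#' Providers are plain lists with fields `name`, `dim` and `lookup(proteinId,
#' L)`; the language model itself is never run here.
#'
#' `fileEmbeddingProvider` reads whitespace-delimited matrix files named
#' `<proteinId>.tsv` from a directory. `constantEmbeddingProvider` returns a
#' constant matrix and is intended for tests and ablations.
#'
#' @param dir directory holding `<proteinId>.tsv` matrix files.
#' @param dim embedding dimension (rows are residues, columns dimensions).
#' @param value fill value for the constant provider.
#' @param name provider label recorded in the feature blocks.
#' @return A provider list with fields `name`, `dim`, `lookup`.
#' @export
fileEmbeddingProvider <- function(dir, dim, name = "embedding") {
  stopifnot(dir.exists(dir), dim >= 1)
  list(
    name = name, dim = as.integer(dim),
    lookup = function(proteinId, L) {
      f <- file.path(dir, paste0(proteinId, ".tsv"))
      if (!file.exists(f)) stop("no embedding file for '", proteinId, "'")
      m <- as.matrix(utils::read.table(f, header = FALSE))
      dimnames(m) <- NULL
      storage.mode(m) <- "double"
      if (ncol(m) != dim)
        stop("embedding for '", proteinId, "' has ", ncol(m),
             " columns, expected ", dim)
      m
    }
  )
}

#' @rdname fileEmbeddingProvider
#' @export
constantEmbeddingProvider <- function(dim, value = 0, name = "mock") {
  stopifnot(dim >= 1)
  list(name = name, dim = as.integer(dim),
       lookup = function(proteinId, L) matrix(value, nrow = L, ncol = dim))
}

#' Build node features for a chain
#'
#' Column-concatenates the one-hot residue encoding with the provider's
#' embedding block (if a provider is given). The block layout is recorded so
#' downstream code can address feature groups.
#'
#' @param chain a [ResidueChain-class].
#' @param provider an embedding provider (see [fileEmbeddingProvider()]) or
#'   `NULL` for one-hot-only features.
#' @return list with `X` (L x F matrix) and `blocks` (named widths).
#' @export
buildNodeFeatures <- function(chain, provider = NULL) {
  stopifnot(is(chain, "ResidueChain"))
  X <- oneHotEncode(chain@sequence)
  blocks <- list(one_hot = ncol(X))
  if (!is.null(provider)) {
    E <- provider$lookup(chain@proteinId, length(chain))
    if (nrow(E) != length(chain))
      stop("provider returned ", nrow(E), " rows for '", chain@proteinId,
           "', chain has ", length(chain), " residues")
    X <- cbind(X, E)
    blocks[[provider$name]] <- ncol(E)
  }
  dimnames(X) <- NULL
  list(X = X, blocks = blocks)
}

#' Assemble the model input graph for one chain
#'
#' Convenience constructor: contact map plus node features in one
#' [ProteinGraph-class].
#'
#' @param chain a [ResidueChain-class].
#' @param provider optional embedding provider.
#' @param cutoff contact cutoff in Angstrom (default 10).
#' @return A [ProteinGraph-class].
#' @export
buildProteinGraph <- function(chain, provider = NULL, cutoff = 10) {
  cm <- contactMap(chain, cutoff = cutoff)
  nf <- buildNodeFeatures(chain, provider)
  new("ProteinGraph", proteinId = chain@proteinId, X = nf$X,
      A = cm@adjacency, blocks = nf$blocks)
}
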