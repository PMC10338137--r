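#' @keywords internal
"_PACKAGE"

#' @import methods
NULL

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) {
  # numerically stable elementwise logistic
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

# row-wise softmax of a matrix (each row sums to 1)
rowSoftmax <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

rowNorms <- function(m) sqrt(rowSums(m * m))

#' Symmetrically normalised adjacency with self-loops
#'
#' Computes \eqn{\tilde D^{-1/2} (A + I) \tilde D^{-1/2}}, the propagation
#' operator used by every graph-convolution layer in the network.
#'
#' @param A square symmetric binary adjacency matrix with zero diagonal.
#' @return Dense L x L propagation matrix.
#' @export
normalizedAdjacency <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

# uniform random point on the unit sphere in `d` dimensions
runifSphere <- function(d) {
  repeat {
    v <- stats::rnorm(d)
    n <- sqrt(sum(v * v))
    if (n > 1e-12) return(v / n)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
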