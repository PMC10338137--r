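# CAFA-style evaluation. Truth is a binary protein x term matrix, scores a
# numeric matrix of the same shape; both sides are assumed
# ancestor-propagated over the same term universe before they get here.
# A term is "predicted" at threshold t when its score is >= t and > 0 (a
# zero score is the absence of a prediction, so an all-zero score matrix
# predicts nothing at any threshold).

predictedAt <- function(scores, t) scores >= t & scores > 0

checkEval <- function(truth, scores) {
  truth <- as.matrix(truth); scores <- as.matrix(scores)
  if (!all(dim(truth) == dim(scores))) stop("truth/scores shape mismatch")
  if (nrow(truth) == 0L) stop("empty protein set")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  list(truth = truth == 1, scores = scores)
}

#' Protein-centric Fmax
#'
#' Sweeps thresholds `t = 0, step, ..., 1`; at each t, precision is averaged
#' over proteins with at least one predicted term and recall over all
#' proteins, and `F1 = 2pr/(p+r)`. Returns the grid maximum and the lowest
#' threshold attaining it. With no predictions anywhere Fmax is 0 by
#' convention.
#'
#' @param truth binary protein x term matrix (ancestor-propagated).
#' @param scores numeric protein x term score matrix in `[0, 1]`.
#' @param step threshold grid step (default 0.01).
#' @return list with `fmax`, `threshold`, and the per-threshold `table`
#'   (t, precision, recall, f1).
#' @export
computeFmax <- function(truth, scores, step = 0.01) {
  ce <- checkEval(truth, scores)
  truth <- ce$truth; scores <- ce$scores
  ntrue <- rowSums(truth)
  if (any(ntrue == 0))
    warning(sum(ntrue == 0), " protein(s) without true terms excluded ",
            "from recall averaging")
  grid <- seq(0, 1, by = step)
  tab <- data.frame(t = grid, precision = NA_real_, recall = NA_real_,
                    f1 = 0)
  for (i in seq_along(grid)) {
    P <- predictedAt(scores, grid[i])
    npred <- rowSums(P)
    tp <- rowSums(P & truth)
    hasPred <- npred > 0
    prec <- if (any(hasPred)) mean(tp[hasPred] / npred[hasPred]) else NA_real_
    rec <- mean((tp / ntrue)[ntrue > 0])
    f1 <- if (!is.na(prec) && (prec + rec) > 0)
      2 * prec * rec / (prec + rec) else 0
    tab$precision[i] <- prec; tab$recall[i] <- rec; tab$f1[i] <- f1
  }
  best <- which.max(tab$f1)   # first maximum -> lowest threshold
  list(fmax = tab$f1[best], threshold = grid[best], table = tab)
}

#' Semantic-distance minimum (Smin)
#'
#' At each threshold, `ru` is the average (over proteins) information content
#' of false-negative terms (remaining uncertainty) and `mi` the average IC of
#' false-positive terms (misinformation); the semantic distance is
#' `sqrt(ru^2 + mi^2)` and Smin its grid minimum.
#'
#' @param truth,scores as in [computeFmax()].
#' @param ic named numeric information content covering every column; terms
#'   without IC (zero training count) must be dropped beforehand.
#' @param step threshold grid step.
#' @return list with `smin`, `threshold`, and the per-threshold `table`
#'   (t, ru, mi, s).
#' @export
computeSmin <- function(truth, scores, ic, step = 0.01) {
  ce <- checkEval(truth, scores)
  truth <- ce$truth; scores <- ce$scores
  termIds <- colnames(scores)
  icv <- if (!is.null(termIds)) {
    if (!all(termIds %in% names(ic)))
      stop("missing IC for term(s): ",
           paste(utils::head(setdiff(termIds, names(ic)), 5), collapse = ", "))
    unname(ic[termIds])
  } else {
    if (length(ic) != ncol(scores)) stop("ic length must match columns")
    unname(ic)
  }
  if (any(!is.finite(icv))) stop("non-finite IC for a scored term")
  grid <- seq(0, 1, by = step)
  tab <- data.frame(t = grid, ru = NA_real_, mi = NA_real_, s = NA_real_)
  for (i in seq_along(grid)) {
    P <- predictedAt(scores, grid[i])
    ru <- mean((truth & !P) %*% icv)
    mi <- mean((P & !truth) %*% icv)
    tab$ru[i] <- ru; tab$mi[i] <- mi; tab$s[i] <- sqrt(ru^2 + mi^2)
  }
  best <- which.min(tab$s)
  list(smin = tab$s[best], threshold = grid[best], table = tab)
}

#' Function-centric AUPR
#'
#' Micro-averaged area under the precision-recall curve over all pooled
#' (protein, term) pairs, integrated by the step-wise rule; pairs with equal
#' score enter the curve as one block, so a constant classifier scores the
#' positive prevalence. `average = "macro"` instead averages per-term AUPRs
#' over terms with at least one positive.
#'
#' @param truth,scores as in [computeFmax()].
#' @param average `"micro"` (default) or `"macro"`.
#' @return scalar AUPR in `[0, 1]`.
#' @export
computeAUPR <- function(truth, scores, average = c("micro", "macro")) {
  average <- match.arg(average)
  ce <- checkEval(truth, scores)
  truth <- ce$truth; scores <- ce$scores
  if (average == "macro") {
    hasPos <- colSums(truth) > 0
    if (!any(hasPos)) stop("no positive (protein, term) pairs")
    return(mean(vapply(which(hasPos), function(j)
      auprPairs(truth[, j], scores[, j]), numeric(1))))
  }
  auprPairs(as.vector(truth), as.vector(scores))
}

auprPairs <- function(y, s) {
  nPos <- sum(y)
  if (nPos == 0) stop("no positive (protein, term) pairs")
  o <- order(s, decreasing = TRUE)
  y <- y[o]; s <- s[o]
  blockEnd <- cumsum(rle(s)$lengths)   # last index of each tie block
  tp <- cumsum(y)[blockEnd]
  n <- blockEnd
  prec <- tp / n
  rec <- tp / nPos
  sum(diff(c(0, rec)) * prec)
}

#' Propagate prediction scores up a DAG
#'
#' CAFA convention: an ancestor's score is the maximum score of any of its
#' descendants (or its own). Columns missing from the matrix are treated as
#' score zero.
#'
#' @param scores protein x term matrix with term-id column names.
#' @param dag a [GODag-class].
#' @return matrix over the same columns with ancestor scores raised.
#' @export
propagateScores <- function(scores, dag) {
  stopifnot(is(dag, "GODag"), !is.null(colnames(scores)))
  out <- scores
  for (term in colnames(scores)) {
    if (!term %in% dag@terms) next
    anc <- setdiff(propagateTerms(term, dag), term)
    anc <- intersect(anc, colnames(scores))
    for (a in anc) out[, a] <- pmax(out[, a], scores[, term])
  }
  out
}

#' Full CAFA-style evaluation
#'
#' Computes Fmax, Smin and micro-AUPR on one term universe. When a DAG is
#' supplied, truth sets and scores are ancestor-propagated first and
#' namespace roots are excluded from the computation (a root annotates
#' everything, so it is trivially predicted).
#'
#' @param truth binary protein x term matrix (column names are term ids).
#' @param scores numeric protein x term matrix, same shape.
#' @param ic named IC vector; when `NULL`, Smin is skipped (`NA`).
#' @param dag optional [GODag-class] for propagation / root exclusion.
#' @param excludeRoots drop root terms before evaluating (default TRUE,
#'   only applies when `dag` is given).
#' @param step threshold grid step.
#' @return list with `fmax`, `fmax_threshold`, `smin`, `smin_threshold`,
#'   `aupr`, and the merged per-threshold `table`.
#' @export
evaluateAnnotations <- function(truth, scores, ic = NULL, dag = NULL,
                                excludeRoots = TRUE, step = 0.01) {
  truth <- as.matrix(truth); scores <- as.matrix(scores)
  if (!is.null(dag)) {
    scores <- propagateScores(scores, dag)
    truth <- propagateScores(truth, dag)  # closure of binary sets
    if (excludeRoots) {
      keep <- setdiff(colnames(scores), rootTerms(dag))
      truth <- truth[, keep, drop = FALSE]
      scores <- scores[, keep, drop = FALSE]
    }
  }
  if (!is.null(ic)) {
    known <- colnames(scores) %in% names(ic)
    if (!is.null(colnames(scores)) && any(!known)) {
      warning(sum(!known), " term(s) without IC dropped from Smin")
      sm <- computeSmin(truth[, known, drop = FALSE],
                        scores[, known, drop = FALSE], ic, step)
    } else sm <- computeSmin(truth, scores, ic, step)
  } else sm <- NULL
  fm <- computeFmax(truth, scores, step)
  au <- computeAUPR(truth, scores)
  tab <- fm$table
  if (!is.null(sm)) {
    tab$ru <- sm$table$ru; tab$mi <- sm$table$mi
  }
  list(fmax = fm$fmax, fmax_threshold = fm$threshold,
       smin = if (is.null(sm)) NA_real_ else sm$smin,
       smin_threshold = if (is.null(sm)) NA_real_ else sm$threshold,
       aupr = au, table = tab)
}

#' Binary annotation matrix from assignment lists
#'
#' @param assignments named list: protein id -> term ids.
#' @param proteins row universe (default: names of `assignments`).
#' @param terms column universe (default: all assigned terms).
#' @return binary matrix with protein rows and term columns.
#' @export
annotationMatrix <- function(assignments,
                             proteins = names(assignments),
                             terms = sort(unique(unlist(assignments)))) {
  m <- matrix(0, length(proteins), length(terms),
              dimnames = list(proteins, terms))
  for (p in intersect(proteins, names(assignments))) {
    tt <- intersect(assignments[[p]], terms)
    m[p, tt] <- 1
  }
  m
}

#' Read and write CAFA-style prediction files
#'
#' Lines of `protein_id term_id score`, whitespace-separated, scores printed
#' with five decimals and sorted by protein then descending score.
#'
#' @param scores protein x term score matrix with dimnames.
#' @param path file path.
#' @param floor scores at or below this value are not written (default 0.01).
#' @return `writeCAFA` the path invisibly; `readCAFA` a score matrix.
#' @export
writeCAFA <- function(scores, path, floor = 0.01) {
  stopifnot(!is.null(rownames(scores)), !is.null(colnames(scores)))
  rows <- list()
  for (p in rownames(scores)) {
    s <- scores[p, ]
    keep <- which(s >= floor)
    if (!length(keep)) next
    keep <- keep[order(s[keep], decreasing = TRUE)]
    rows[[p]] <- data.frame(protein = p, term = colnames(scores)[keep],
                            score = sprintf("%.5f", s[keep]))
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(protein = character(0),
                                    term = character(0), score = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeCAFA
#' @param proteins,terms optional universes for the returned matrix (defaults
#'   to those present in the file).
#' @export
readCAFA <- function(path, proteins = NULL, terms = NULL) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE),
    error = function(e) data.frame())
  if (!nrow(df)) {
    m <- matrix(0, length(proteins %||% character(0)),
                length(terms %||% character(0)),
                dimnames = list(proteins, terms))
    return(m)
  }
  names(df)[1:3] <- c("protein", "term", "score")
  proteins <- proteins %||% unique(df$protein)
  terms <- terms %||% sort(unique(df$term))
  m <- matrix(0, length(proteins), length(terms),
              dimnames = list(proteins, terms))
  keep <- df$protein %in% proteins & df$term %in% terms
  df <- df[keep, , drop = FALSE]
  m[cbind(df$protein, df$term)] <- as.numeric(df$score)
  m
}

#' Bootstrap confidence interval for an evaluation statistic
#'
#' Resamples proteins with replacement and recomputes a metric; a thin
#' utility for reporting variability over test proteins.
#'
#' @param truth,scores as in [computeFmax()].
#' @param statistic function(truth, scores) -> scalar.
#' @param nBoot number of bootstrap iterations (default 10).
#' @return numeric vector of bootstrap statistic values.
#' @export
bootstrapMetric <- function(truth, scores, statistic, nBoot = 10) {
  n <- nrow(truth)
  vapply(seq_len(nBoot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    statistic(truth[idx, , drop = FALSE], scores[idx, , drop = FALSE])
  }, numeric(1))
}

#' Group terms into information-content bins
#'
#' Helper for IC-stratified reporting: assigns each term to a bin such as
#' `[0,5)`, `[5,10)`, `[10,Inf)`.
#'
#' @param ic named IC vector.
#' @param breaks bin boundaries (default `c(0, 5, 10, Inf)`).
#' @return named factor of bin labels.
#' @export
icBins <- function(ic, breaks = c(0, 5, 10, Inf)) {
  cut(ic, breaks = breaks, right = FALSE, include.lowest = TRUE)
}
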