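test_that("Fmax limits: perfect predictions and empty predictions", {
  truth <- matrix(c(1, 0, 1, 1, 0, 1), 2, 3,
                  dimnames = list(c("p1", "p2"), c("a", "b", "c")))
  expect_equal(computeFmax(truth, truth * 1.0)$fmax, 1)
  expect_equal(computeFmax(truth, truth * 0)$fmax, 0)
  expect_error(computeFmax(truth[0, ], truth[0, ]), "empty")
})

test_that("Fmax equals the exhaustive per-threshold oracle", {
  set.seed(51)
  for (rep in 1:3) {
    truth <- matrix(rbinom(200, 1, 0.3), 20, 10)
    truth[rowSums(truth) == 0, 1] <- 1    # every protein annotated
    scores <- matrix(round(runif(200), 2), 20, 10)
    got <- computeFmax(truth, scores)
    want <- oracleFmax(truth, scores)
    expect_equal(got$fmax, want$fmax, tolerance = 1e-6)
    expect_equal(got$threshold, want$threshold, tolerance = 1e-9)
  }
})

test_that("Smin limits, the hand case, and the grid oracle", {
  truth <- matrix(c(1, 0, 1, 1, 0, 1), 2, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  ic <- c(a = 1, b = 2, c = 3)
  expect_equal(computeSmin(truth, truth * 1.0, ic)$smin, 0)

  # single protein, truth {a} with IC 2, empty prediction -> S = 2 always
  t1 <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("a", "b")))
  sm <- computeSmin(t1, t1 * 0, c(a = 2, b = 1))
  expect_equal(sm$smin, 2)
  expect_true(all(abs(sm$table$s - 2) < 1e-12))

  set.seed(52)
  truth <- matrix(rbinom(60, 1, 0.4), 10, 6,
                  dimnames = list(NULL, letters[1:6]))
  scores <- matrix(round(runif(60), 2), 10, 6,
                   dimnames = list(NULL, letters[1:6]))
  ic <- setNames(runif(6, 0.5, 4), letters[1:6])
  expect_equal(computeSmin(truth, scores, ic)$smin,
               oracleSmin(truth, scores, setNames(ic, NULL)),
               tolerance = 1e-6)
  expect_error(computeSmin(truth, scores, ic[1:3]), "missing IC")
})

test_that("AUPR limits and rank-walk oracle agree to 1e-9", {
  truth <- matrix(c(1, 1, 0, 0), 2, 2)
  perfect <- matrix(c(0.9, 0.8, 0.2, 0.1), 2, 2)
  expect_equal(computeAUPR(truth, perfect), 1)

  # constant scores: single PR point at prevalence
  expect_equal(computeAUPR(truth, matrix(0.5, 2, 2)), 0.5)

  set.seed(53)
  truth <- matrix(rbinom(200, 1, 0.25), 20, 10)
  scores <- matrix(sample(seq(0, 1, 0.05), 200, replace = TRUE), 20, 10)
  expect_equal(computeAUPR(truth, scores),
               oracleAUPR(as.vector(truth == 1), as.vector(scores)),
               tolerance = 1e-9)
  expect_error(computeAUPR(truth * 0, scores), "no positive")

  # macro averaging stays in [0, 1]
  expect_gte(computeAUPR(truth, scores, average = "macro"), 0)
  expect_lte(computeAUPR(truth, scores, average = "macro"), 1)
})

test_that("Fmax and Smin are invariant to a monotone transform of scores and grid", {
  # the grid-quantile transform t -> t^2 is strictly monotone on [0, 1];
  # transforming both the scores and the threshold grid leaves every
  # thresholded prediction set unchanged
  set.seed(54)
  truth <- matrix(rbinom(60, 1, 0.4), 10, 6,
                  dimnames = list(NULL, letters[1:6]))
  truth[rowSums(truth) == 0, 1] <- 1
  grid <- seq(0, 1, 0.01)
  scores <- matrix(sample(grid, 60, replace = TRUE), 10, 6,
                   dimnames = list(NULL, letters[1:6]))
  f0 <- computeFmax(truth, scores)$fmax
  ic <- setNames(runif(6, 0.5, 3), letters[1:6])
  s0 <- computeSmin(truth, scores, ic)$smin

  fT <- vapply(grid^2, function(t) {
    P <- scores^2 >= t & scores^2 > 0
    npred <- rowSums(P); tp <- rowSums(P & (truth == 1))
    prec <- if (any(npred > 0)) mean((tp / npred)[npred > 0]) else NA
    rec <- mean(tp / rowSums(truth))
    if (!is.na(prec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }, numeric(1))
  expect_equal(max(fT), f0, tolerance = 1e-12)

  sT <- vapply(grid^2, function(t) {
    P <- scores^2 >= t & scores^2 > 0
    ru <- mean(((truth == 1) & !P) %*% unname(ic))
    mi <- mean((P & !(truth == 1)) %*% unname(ic))
    sqrt(ru^2 + mi^2)
  }, numeric(1))
  expect_equal(min(sT), s0, tolerance = 1e-12)
})

test_that("adding a correct prediction at fixed FP never lowers F1", {
  set.seed(55)
  truth <- matrix(rbinom(40, 1, 0.5), 8, 5)
  truth[rowSums(truth) == 0, 1] <- 1
  scores <- matrix(runif(40, 0.2, 0.9), 8, 5) * (1 - truth)  # only FPs scored
  f0 <- computeFmax(truth, scores)$table$f1
  scores2 <- scores
  miss <- which(truth == 1 & scores == 0)
  scores2[miss[1]] <- 1                      # one extra true positive
  f1 <- computeFmax(truth, scores2)$table$f1
  expect_true(all(f1 - f0 >= -1e-12))
})

test_that("score propagation lifts ancestors to the max descendant score", {
  dag <- tinyDag()
  sc <- matrix(c(0.9, 0.1, 0, 0.3), 1, 4,
               dimnames = list("p", c("GO:0004", "GO:0002", "GO:0003",
                                      "GO:0001")))
  out <- propagateScores(sc, dag)
  expect_equal(out["p", "GO:0002"], 0.9)
  expect_equal(out["p", "GO:0003"], 0.9)
  expect_equal(out["p", "GO:0001"], 0.9)
})

test_that("evaluateAnnotations excludes roots and reproduces the metric calls", {
  dag <- tinyDag()
  anno <- list(p1 = c("GO:0004"), p2 = c("GO:0002"), p3 = c("GO:0003"))
  anno <- lapply(anno, propagateTerms, dag = dag)
  terms <- sort(unique(unlist(anno)))
  truth <- annotationMatrix(anno, terms = terms)
  ev <- evaluateAnnotations(truth, truth * 0.9,
                            ic = annotationStore(anno)@ic, dag = dag)
  expect_equal(ev$fmax, 1)
  expect_equal(ev$smin, 0)
  expect_equal(ev$aupr, 1)
  expect_false("GO:0001" %in% colnames(ev$table))
})

test_that("CAFA files round-trip at five decimals, sorted", {
  set.seed(56)
  sc <- matrix(runif(12), 3, 4,
               dimnames = list(paste0("p", 1:3), paste0("GO:000", 1:4)))
  f <- withr::local_tempfile(fileext = ".txt")
  writeCAFA(sc, f, floor = 0)
  df <- read.table(f)
  # sorted by protein then descending score
  expect_true(!is.unsorted(df$V1))
  for (p in unique(df$V1))
    expect_true(!is.unsorted(rev(df$V3[df$V1 == p])))
  back <- readCAFA(f, proteins = rownames(sc), terms = colnames(sc))
  expect_equal(back, sc, tolerance = 1e-5)

  # floor drops low scores
  writeCAFA(sc, f, floor = 0.5)
  back2 <- readCAFA(f, proteins = rownames(sc), terms = colnames(sc))
  expect_true(all(back2[sc < 0.5] == 0))
})

test_that("bootstrap metric and IC bins behave", {
  set.seed(57)
  truth <- matrix(rbinom(40, 1, 0.5), 8, 5)
  truth[rowSums(truth) == 0, 1] <- 1
  sc <- matrix(runif(40), 8, 5)
  b <- bootstrapMetric(truth, sc, function(t, s) computeFmax(t, s)$fmax,
                       nBoot = 5)
  expect_length(b, 5)
  expect_true(all(b >= 0 & b <= 1))
  bins <- icBins(c(a = 2, b = 7, c = 12))
  expect_equal(as.character(bins),
               c("[0,5)", "[5,10)", "[10,Inf]"))
})
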