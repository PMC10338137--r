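test_that("gcnLayer matches the literal dense formula and its limits", {
  # isolated node: normalisation collapses to identity
  h <- matrix(c(1, -2), 1, 2)
  W <- matrix(c(0.5, 0, 0, -1), 2, 2)
  expect_equal(gcnLayer(h, matrix(0, 1, 1), W), pmax(h %*% W, 0))

  # entrywise-negative propagation gives the zero matrix
  expect_equal(gcnLayer(matrix(1, 3, 1), randomAdjacency(3),
                        matrix(-1, 1, 4)),
               matrix(0, 3, 4))

  # 4-node path graph vs dense oracle
  set.seed(21)
  A <- matrix(0, 4, 4)
  for (i in 1:3) A[i, i + 1] <- A[i + 1, i] <- 1
  Hin <- matrix(rnorm(4 * 3), 4, 3)
  W <- matrix(rnorm(3 * 5), 3, 5)
  expect_lt(max(abs(gcnLayer(Hin, A, W) - oracleGCN(Hin, A, W))), 1e-6)

  expect_error(gcnLayer(Hin, A, matrix(0, 4, 2)), "mismatch")
})

test_that("the encoder composes layers and is permutation-equivariant", {
  set.seed(22)
  g <- randomGraph(8, Fdim = 5)
  m1 <- tinyModel(Fdim = 5, N = 1)
  H1 <- encodeGraph(m1, nodeFeatures(g), adjacency(g))
  expect_equal(H1, gcnLayer(nodeFeatures(g), adjacency(g),
                            modelParams(m1)$gcn[[1]]))

  m4 <- tinyModel(Fdim = 5, N = 4, D = 7)
  H <- encodeGraph(m4, nodeFeatures(g), adjacency(g))
  expect_equal(dim(H), c(8L, 7L))

  pi_ <- sample(8)
  Hp <- encodeGraph(m4, nodeFeatures(g)[pi_, ], adjacency(g)[pi_, pi_])
  expect_equal(Hp, H[pi_, ], tolerance = 1e-12)
})

test_that("super-node attention normalises over residues and matches the loop oracle", {
  set.seed(23)
  mdl <- tinyModel(Fdim = 5, D = 4, K = 2, H = 2, N = 1)
  g <- randomGraph(6, Fdim = 5)
  H <- encodeGraph(mdl, nodeFeatures(g), adjacency(g))
  U <- superNodeAttention(mdl, H, adjacency(g))
  att <- attr(U, "attention")
  for (a in att) expect_equal(unname(rowSums(a)), rep(1, 2), tolerance = 1e-6)

  # oracle equivalence on a random small instance (L=6, K=2, H=2, D=4)
  Uo <- oracleSuperNode(modelParams(mdl)$hgt, H, adjacency(g))
  expect_lt(max(abs(U - Uo)), 1e-6)

  # identical key rows (zero key weights) -> unweighted mean of value rows
  p2 <- modelParams(mdl)
  p2$hgt$heads[[1]]$Wk <- p2$hgt$heads[[1]]$Wk * 0
  fw <- profun:::hgtForward(p2$hgt, H, profun:::normalizedAdjacency(adjacency(g)))
  expect_equal(unname(fw$heads[[1]]$G[1, ]),
               unname(colMeans(fw$heads[[1]]$Vh)), tolerance = 1e-9)
})

test_that("attention pooling weights sum to one and K=1 collapses to a linear map", {
  set.seed(24)
  mdl <- tinyModel(Fdim = 5, D = 4, K = 3)
  U <- matrix(rnorm(3 * 4), 3, 4)
  z <- attentionPool(mdl, U)
  expect_equal(sum(attr(z, "weights")), 1, tolerance = 1e-9)
  expect_lt(max(abs(as.numeric(z) - oraclePool(modelParams(mdl)$hgt$pool, U))),
            1e-6)

  m1 <- tinyModel(Fdim = 5, D = 4, K = 1)
  u <- matrix(rnorm(4), 1, 4)
  z1 <- attentionPool(m1, u)
  expect_equal(attr(z1, "weights"), 1)
  expect_equal(as.numeric(z1),
               as.numeric(u %*% modelParams(m1)$hgt$pool$Vp),
               tolerance = 1e-9)
})

test_that("the prediction head is a sigmoid MLP", {
  mdl <- tinyModel(Fdim = 5, D = 2, C = 2)
  p <- modelParams(mdl)
  p$head$W1 <- p$head$W1 * 0; p$head$W2 <- p$head$W2 * 0
  m0 <- new("FunPredModel", config = modelConfig(mdl), params = p)
  expect_equal(unname(predictHead(m0, c(1, -1))), c(0.5, 0.5))

  # hand-set tiny head: z=(1,2), W1=I, b1=0, W2, b2 known
  p$head$W1 <- diag(2); p$head$b1 <- c(0, 0)
  p$head$W2 <- matrix(c(0.3, -0.2, 0.1, 0.4), 2, 2)
  p$head$b2 <- c(0.05, -0.05)
  mh <- new("FunPredModel", config = modelConfig(mdl), params = p)
  z <- c(1, 2)
  hand <- 1 / (1 + exp(-(pmax(z, 0) %*% p$head$W2 + p$head$b2)))
  expect_equal(unname(predictHead(mh, z)), as.numeric(hand), tolerance = 1e-12)

  set.seed(25)
  y <- predictHead(tinyModel(), rnorm(6))
  expect_true(all(y > 0 & y < 1))
})

test_that("forward returns contract shapes, is node-permutation invariant and deterministic", {
  set.seed(26)
  mdl <- tinyModel(Fdim = 5, C = 4, D = 6, N = 3, K = 2, H = 2)
  g <- randomGraph(9, Fdim = 5)
  out <- predictGraph(mdl, g)
  expect_length(out$yhat, 4L)
  expect_equal(dim(out$H), c(9L, 6L))
  expect_length(out$z, 6L)

  pi_ <- sample(9)
  gp <- new("ProteinGraph", proteinId = "g", X = nodeFeatures(g)[pi_, ],
            A = adjacency(g)[pi_, pi_], blocks = g@blocks)
  outP <- predictGraph(mdl, gp)
  expect_equal(outP$yhat, out$yhat, tolerance = 1e-5)
  expect_equal(outP$z, out$z, tolerance = 1e-5)
  expect_equal(outP$H, out$H[pi_, ], tolerance = 1e-5)

  expect_identical(predictGraph(mdl, g), out)  # bitwise determinism
})

test_that("checkpoints round-trip and refuse incompatible files", {
  mdl <- tinyModel(C = 3)
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(mdl, f)
  back <- loadCheckpoint(f)
  expect_identical(modelParams(back), modelParams(mdl))
  expect_identical(modelConfig(back), modelConfig(mdl))

  saveRDS(list(something = 1), f)
  expect_error(loadCheckpoint(f), "not a recognised checkpoint")
  saveRDS(list(package = "profun", format = 999L, config = list(),
               params = list()), f)
  expect_error(loadCheckpoint(f), "incompatible")

  # using a model on a graph with the wrong feature width is refused
  g <- randomGraph(5, Fdim = 7)
  expect_error(predictGraph(mdl, g), "inputDim")
})
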