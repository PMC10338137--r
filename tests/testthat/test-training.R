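test_that("perturbation keeps direction, norm epsilon, and zero coordinates", {
  set.seed(31)
  H <- matrix(rnorm(6 * 4), 6, 4)
  H[H == 0] <- 0.1              # make sign-definite
  Hp <- perturbEmbeddings(H, 0.3)
  expect_equal(unname(sqrt(rowSums((Hp - H)^2))), rep(0.3, 6),
               tolerance = 1e-6)
  expect_true(all(sign(Hp) == sign(H)))

  H0 <- H; H0[2, 3] <- 0
  Hp0 <- perturbEmbeddings(H0, 0.5)
  expect_equal(Hp0[2, 3], 0)

  # epsilon -> 0 limit
  expect_equal(perturbEmbeddings(H, 1e-12), H, tolerance = 1e-10)
  expect_error(perturbEmbeddings(H, 0), "positive")
})

test_that("InfoNCE analytic limits and oracle equivalence hold", {
  set.seed(32)
  z1 <- matrix(rnorm(8), 1, 8)
  expect_equal(infoNCE(z1, z1 * 2, tau = 0.5), 0)

  # all 2M embeddings identical at M=4 -> ln 4
  Z <- matrix(rep(rnorm(8), 4), 4, 8, byrow = TRUE)
  expect_equal(infoNCE(Z, Z, tau = 0.5), log(4), tolerance = 1e-12)

  # all 2M embeddings identical: every similarity is 1, softmax uniform
  for (M in c(1, 2, 5, 9)) {
    Zm <- matrix(rep(rnorm(6), M), M, 6, byrow = TRUE)
    expect_equal(infoNCE(Zm, Zm, tau = 0.5), log(M), tolerance = 1e-9)
  }

  Z <- matrix(rnorm(4 * 8), 4, 8)
  Zp <- matrix(rnorm(4 * 8), 4, 8)
  expect_lt(abs(infoNCE(Z, Zp, 0.5) - oracleInfoNCE(Z, Zp, 0.5)), 1e-6)

  # invariant to positive rescaling of any row (cosine similarity)
  Zs <- Z * c(3, 0.2, 7, 1)
  expect_equal(infoNCE(Zs, Zp, 0.5), infoNCE(Z, Zp, 0.5), tolerance = 1e-9)

  Z0 <- Z; Z0[2, ] <- 0
  expect_error(infoNCE(Z0, Zp, 0.5), "zero-norm")
})

test_that("BCE matches its limits and the scalar-loop oracle", {
  Y <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(bceLoss(Y, matrix(0.5, 2, 2)), log(2), tolerance = 1e-12)
  expect_lt(bceLoss(Y, Y), 1e-6 * abs(log(1e-7)))

  set.seed(33)
  Y <- matrix(rbinom(12, 1, 0.5), 3, 4)
  Yhat <- matrix(runif(12), 3, 4)
  expect_equal(bceLoss(Y, Yhat), oracleBCE(Y, Yhat), tolerance = 1e-12)
  expect_error(bceLoss(Y, Yhat[, 1:2]), "shape")

  expect_equal(totalLoss(0.5, 0.25), 0.75)
  expect_equal(totalLoss(1.3, 0), 1.3)
})

test_that("analytic training gradients match central finite differences", {
  set.seed(34)
  mdl <- tinyModel(Fdim = 4, C = 2, D = 5, N = 2, K = 2, H = 2)
  graphs <- list(randomGraph(6, 4, "a"), randomGraph(7, 4, "b"),
                 randomGraph(5, 4, "c"))
  Y <- matrix(rbinom(6, 1, 0.5), 3, 2)
  tc <- trainConfig(learningRate = 1e-3, seed = 99, epsilon = 0.15)

  set.seed(1234)
  bp <- profun:::batchPass(modelParams(mdl), modelConfig(mdl), graphs, Y,
                           tc, grad = TRUE)
  theta <- profun:::flattenParams(modelParams(mdl))
  gflat <- profun:::flattenParams(bp$grads)
  lossAt <- function(v) {
    set.seed(1234)   # same perturbation draws as the analytic pass
    profun:::batchPass(profun:::unflattenParams(v, modelParams(mdl)),
                       modelConfig(mdl), graphs, Y, tc, grad = FALSE)$loss
  }
  h <- 1e-5
  idx <- sample(length(theta), 40)
  num <- vapply(idx, function(i) {
    vp <- theta; vp[i] <- vp[i] + h
    vm <- theta; vm[i] <- vm[i] - h
    (lossAt(vp) - lossAt(vm)) / (2 * h)
  }, numeric(1))
  relErr <- abs(num - gflat[idx]) / pmax(abs(num), 1e-6)
  expect_lt(stats::median(relErr), 1e-5)
  # a coordinate whose +/- h step crosses a ReLU kink or a sign boundary of
  # the perturbation is non-differentiable there; almost all must agree
  expect_gte(mean(relErr < 1e-3), 0.9)
})

test_that("early stopping fires after patience epochs without improvement", {
  set.seed(35)
  mdl <- tinyModel(Fdim = 4, C = 2, D = 4, N = 1, K = 2, H = 1)
  graphs <- list(randomGraph(5, 4, "a"), randomGraph(6, 4, "b"))
  Y <- matrix(c(1, 0, 0, 1), 2, 2)
  # vanishing learning rate freezes the parameters -> validation loss
  # cannot improve after the first epoch
  fit <- trainModel(mdl, graphs, Y, graphs, Y,
                    trainConfig(learningRate = 1e-30, maxEpochs = 50,
                                patience = 1, seed = 5,
                                contrastive = FALSE))
  expect_equal(nrow(fit$history), 2L)
  expect_true(fit$stoppedEarly)

  expect_error(trainModel(mdl, list(), Y), "empty")
})

test_that("training is reproducible given the seed", {
  set.seed(36)
  mdl <- tinyModel(Fdim = 4, C = 2, D = 4, N = 2, K = 2, H = 1)
  graphs <- lapply(1:4, function(i) randomGraph(5, 4, paste0("g", i)))
  Y <- matrix(rbinom(8, 1, 0.5), 4, 2)
  tc <- trainConfig(learningRate = 1e-3, maxEpochs = 4, patience = Inf,
                    seed = 77)
  f1 <- trainModel(mdl, graphs, Y, config = tc)
  f2 <- trainModel(mdl, graphs, Y, config = tc)
  expect_equal(f1$history, f2$history, tolerance = 1e-6)
  expect_equal(modelParams(f1$model), modelParams(f2$model),
               tolerance = 1e-12)
})

test_that("the contrastive objective aligns paired views", {
  set.seed(37)
  spec <- syntheticSpec(nProteins = 24, lengthRange = c(30, 40),
                        labelNoise = 0, seed = 912)
  ds <- generateDataset(spec)
  mdl <- funPredModel(21, 3, hiddenDim = 16, nGcnLayers = 2,
                      nSuperNodes = 2, nHeads = 2, seed = 8, quiet = TRUE)
  fit <- trainModel(mdl, ds$graphs, ds$labels,
                    config = trainConfig(learningRate = 3e-3,
                                         maxEpochs = 15, patience = Inf,
                                         batchSize = 12, seed = 8))
  # embed both views with the trained parameters
  p <- modelParams(fit$model); cfg <- modelConfig(fit$model)
  set.seed(99)
  Z <- NULL; Zp <- NULL
  for (g in ds$graphs[1:12]) {
    fw <- profun:::forwardCached(p, cfg, nodeFeatures(g), adjacency(g))
    Hp <- perturbEmbeddings(fw$enc$H, 0.1)
    zp <- profun:::hgtForward(p$hgt, Hp, fw$S)$z
    Z <- rbind(Z, fw$pool$z); Zp <- rbind(Zp, zp)
  }
  Zn <- Z / sqrt(rowSums(Z^2)); Zpn <- Zp / sqrt(rowSums(Zp^2))
  Cs <- Zn %*% t(Zpn)
  expect_gt(mean(diag(Cs)), mean(Cs[row(Cs) != col(Cs)]))
})

test_that("every training loss stays finite across seeds", {
  for (sd in 1:5) {
    set.seed(sd)
    spec <- syntheticSpec(nProteins = 10, lengthRange = c(30, 36),
                          seed = 100 + sd)
    ds <- generateDataset(spec)
    mdl <- funPredModel(21, 3, hiddenDim = 8, nGcnLayers = 2,
                        nSuperNodes = 2, nHeads = 1, seed = sd,
                        quiet = TRUE)
    fit <- trainModel(mdl, ds$graphs, ds$labels,
                      config = trainConfig(learningRate = 3e-3,
                                           maxEpochs = 3, patience = Inf,
                                           batchSize = 5, seed = sd))
    expect_true(all(is.finite(fit$history$train_loss)))
  }
})
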