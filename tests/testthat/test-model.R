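test_that("branch shape arithmetic reaches the contracted flatten and fusion sizes", {
  net <- buildFusionNet(fusionNetConfig(nClasses = 12))
  expect_equal(net@net$flatten[["scattering"]], 3000)
  expect_equal(net@net$flatten[["spectrum"]], 800)
  expect_equal(net@net$flatten[["lifetime"]], 400)
  expect_equal(ncol(net@net$head$params$W), 155)
  # misconfigured channel counts fail at build time, naming the branch
  expect_error(buildFusionNet(fusionNetConfig(
    scatteringChannels = c(10, 21))), "scattering")
  expect_error(buildFusionNet(fusionNetConfig(
    spectrumChannels = c(50, 99))), "spectrum")
  expect_error(buildFusionNet(fusionNetConfig(
    lifetimeChannels = c(70, 140, 190))), "lifetime")
  expect_error(buildFusionNet(fusionNetConfig(perModalityReduced = 40)),
               "fused")
})

test_that("forward passes emit normalized log-probabilities", {
  fx <- tinyTrainedModel()
  logp <- forwardPass(fx$model, fx$clean[1:9])
  expect_equal(dim(logp), c(4, 9))
  expect_equal(colSums(exp(logp)), rep(1, 9), tolerance = 1e-6)
  expect_equal(rownames(logp), classOrder(fx$model))
})

test_that("an untrained model (zero-initialized head) is uniform over classes", {
  model <- builtModel()
  clean <- smallCleanSet(n = 4, seed = 2)
  logp <- forwardPass(model, clean[1:3])
  expect_equal(as.numeric(logp), rep(-log(4), 12), tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences through the whole network", {
  clean <- smallCleanSet(n = 4, seed = 2)
  model <- buildFusionNet(fusionNetConfig(
    nClasses = 4, dropoutRate = 0, seed = 11), classOrder(builtModel()))
  net <- model@net
  idx <- 1:6
  batch <- pollenfuse:::.batchTensors(clean, idx)
  tgt <- rep(1:4, length.out = 6)
  lossOf <- function(net) {
    fw <- pollenfuse:::.netForward(net, batch, train = TRUE)
    pollenfuse:::.nllLoss(fw$logp, tgt)
  }
  fw <- pollenfuse:::.netForward(net, batch, train = TRUE)
  dLogp <- matrix(0, 4, 6)
  dLogp[cbind(tgt, 1:6)] <- -1 / 6
  bk <- pollenfuse:::.netBackward(net, fw, dLogp)
  eps <- 1e-5
  checks <- list(
    list(\(n, v) { n$head$params$W[2, 30] <- v; n },
         \(g) g$head$W[2, 30], \(n) n$head$params$W[2, 30]),
    list(\(n, v) { n$reduce$spectrum$params$W[7, 100] <- v; n },
         \(g) g$reduce$spectrum$W[7, 100],
         \(n) n$reduce$spectrum$params$W[7, 100]),
    list(\(n, v) { n$branches$scattering[[2]]$params$W[3, 1, 2, 2] <- v; n },
         \(g) g$branches$scattering[[2]]$W[3, 1, 2, 2],
         \(n) n$branches$scattering[[2]]$params$W[3, 1, 2, 2]),
    list(\(n, v) { n$branches$lifetime[[12]]$params$W[5, 10, 1, 2] <- v; n },
         \(g) g$branches$lifetime[[12]]$W[5, 10, 1, 2],
         \(n) n$branches$lifetime[[12]]$params$W[5, 10, 1, 2]),
    list(\(n, v) { n$branches$spectrum[[1]]$params$gamma[1] <- v; n },
         \(g) g$branches$spectrum[[1]]$gamma[1],
         \(n) n$branches$spectrum[[1]]$params$gamma[1]),
    list(\(n, v) { n$auxBN$params$beta[5] <- v; n },
         \(g) g$auxBN$beta[5], \(n) n$auxBN$params$beta[5]))
  for (chk in checks) {
    v0 <- chk[[3]](net)
    num <- (lossOf(chk[[1]](net, v0 + eps)) -
              lossOf(chk[[1]](net, v0 - eps))) / (2 * eps)
    expect_equal(chk[[2]](bk$grads), num, tolerance = 1e-4)
  }
})

test_that("training history is deterministic for a fixed seed and loss decreases", {
  clean <- smallCleanSet(n = 30, seed = 7)
  cfg <- fusionNetConfig(nClasses = 4, trainPerClass = 24, perClassBatch = 6,
                         maxEpochs = 5, patience = 6, seed = 21)
  m1 <- trainFusionNet(clean, cfg)
  m2 <- trainFusionNet(clean, cfg)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  h <- trainingHistory(m1)
  expect_lt(h$train_loss[5], h$train_loss[1])
})

test_that("the split respects the balanced training protocol", {
  fx <- tinyTrainedModel()
  sp <- trainTestSplit(fx$model)
  lab <- sampleLabels(fx$clean)
  cfg <- modelConfig(fx$model)
  nVal <- round(cfg$validationFraction * cfg$trainPerClass)
  expect_true(all(table(lab[sp$train]) == cfg$trainPerClass - nVal))
  expect_true(all(table(lab[sp$validation]) == nVal))
  # everything not drawn for training is test
  expect_equal(sort(c(sp$train, sp$validation, sp$test)),
               seq_along(lab))
  expect_length(sp$test, length(lab) - 4 * cfg$trainPerClass)
  expect_error(trainFusionNet(fx$clean,
                              fusionNetConfig(trainPerClass = 10000)),
               "fewer than trainPerClass")
})

test_that("the network can overfit a tiny sample set", {
  clean <- smallCleanSet(n = 10, seed = 19)
  cfg <- fusionNetConfig(nClasses = 4, trainPerClass = 8, perClassBatch = 4,
                         maxEpochs = 150, patience = 150, seed = 2)
  m <- trainFusionNet(clean, cfg)
  sp <- trainTestSplit(m)
  trainAcc <- mean(predictClasses(m, clean[sp$train]) ==
                     sampleLabels(clean)[sp$train])
  expect_gte(trainAcc, 0.95)
})

test_that("evaluateModel reports accuracy and a row-normalized confusion matrix", {
  fx <- tinyTrainedModel()
  sp <- trainTestSplit(fx$model)
  ev <- evaluateModel(fx$model, fx$clean[sp$test])
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_equal(unname(rowSums(ev$confusion)), rep(1, 4), tolerance = 1e-6)
  expect_equal(sum(ev$counts), length(sp$test))
})

test_that("model checkpoints round-trip with identical predictions", {
  fx <- tinyTrainedModel()
  ck <- withr::local_tempfile(fileext = ".rds")
  writeFusionNet(fx$model, ck)
  back <- readFusionNet(ck)
  expect_identical(forwardPass(back, fx$clean[1:5]),
                   forwardPass(fx$model, fx$clean[1:5]))
  expect_error(readFusionNet(writeParticles(fx$clean, ck)), "FusionNet")
})
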