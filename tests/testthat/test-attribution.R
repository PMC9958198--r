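test_that("the Riemann core is exact for a linear model at any step count", {
  # f(x) = sum w * x with zero baseline: the gradient is constant along the
  # path, so IG_i must equal w_i * x_i exactly, for any M.
  set.seed(8)
  x <- list(a = stats::rnorm(5), b = matrix(stats::rnorm(6), 2, 3))
  w <- list(a = stats::rnorm(5), b = matrix(stats::rnorm(6), 2, 3))
  base <- list(a = numeric(5), b = matrix(0, 2, 3))
  gradSum <- function(alphas)
    lapply(w, function(wi) as.numeric(wi) * length(alphas))
  for (M in c(1, 7, 300)) {
    ig <- pollenfuse:::.igRiemann(gradSum, x, base, M)
    expect_equal(ig$a, w$a * x$a, tolerance = 1e-12)
    expect_equal(ig$b, as.numeric(w$b) * as.numeric(x$b),
                 tolerance = 1e-12)
  }
})

test_that("a baseline input receives exactly zero attribution", {
  model <- builtModel()
  zero <- new("CleanSampleSet", scattering = array(0, c(20, 120, 1)),
              spectrum = array(0, c(4, 32, 1)),
              lifetime = array(0, c(4, 24, 1)),
              ltFeatures = matrix(0, 4, 1), sizeFeature = 0,
              labels = NA_character_)
  att <- integratedGradients(model, zero, steps = 10)
  expect_true(all(scatteringArray(att) == 0))
  expect_true(all(spectrumArray(att) == 0))
  expect_true(all(lifetimeArray(att) == 0))
  expect_true(all(ltFeatureMatrix(att) == 0))
  expect_equal(sizeFeatureVector(att), 0)
  expect_equal(completenessGap(att), 0)
})

test_that("the completeness gap shrinks as the step count grows", {
  fx <- tinyTrainedModel()
  sub <- fx$clean[trainTestSplit(fx$model)$test][1:4]
  g10 <- completenessGap(integratedGradients(fx$model, sub, steps = 10))
  g500 <- completenessGap(integratedGradients(fx$model, sub, steps = 500))
  expect_true(all(g500 <= g10))
})

test_that("attributions sum to the score difference from the baseline", {
  fx <- tinyTrainedModel()
  sub <- fx$clean[trainTestSplit(fx$model)$test][1:6]
  att <- integratedGradients(fx$model, sub, steps = 300)
  logp <- forwardPass(fx$model, sub)
  zeroS <- new("CleanSampleSet", scattering = array(0, c(20, 120, 1)),
               spectrum = array(0, c(4, 32, 1)),
               lifetime = array(0, c(4, 24, 1)),
               ltFeatures = matrix(0, 4, 1), sizeFeature = 0,
               labels = NA_character_)
  f0 <- forwardPass(fx$model, zeroS)[, 1]
  for (i in 1:6) {
    tgt <- match(targetClasses(att)[i], classOrder(fx$model))
    diff <- abs(logp[tgt, i] - f0[tgt])
    expect_lte(completenessGap(att)[i], 0.01 * diff)
  }
})

test_that("the M = 1000 Riemann sum matches a trapezoidal path integral", {
  fx <- tinyTrainedModel()
  sub <- fx$clean[trainTestSplit(fx$model)$test][1]
  att <- integratedGradients(fx$model, sub, steps = 1000)
  x <- pollenfuse:::.sampleInputs(sub, 1)
  base <- pollenfuse:::.zeroBaseline()
  tgt <- match(targetClasses(att)[1], classOrder(fx$model))
  net <- fx$model@net
  sumGrad <- function(alphas) {
    out <- NULL
    for (ch in split(alphas, ceiling(seq_along(alphas) / 100))) {
      g <- pollenfuse:::.gradAlongPath(
        net, pollenfuse:::.pathBatch(x, base, ch), tgt)
      g <- unlist(g[c("scattering", "spectrum", "lifetime", "ltFeatures",
                      "sizeFeature")])
      out <- if (is.null(out)) g else out + g
    }
    out
  }
  M <- 1000
  # trapezoid = average of the left- and right-endpoint Riemann sums
  left <- sumGrad((0:(M - 1)) / M)
  right <- sumGrad((1:M) / M)
  dx <- unlist(lapply(x, as.numeric)) - unlist(lapply(base, as.numeric))
  trap <- dx * (left + right) / (2 * M)
  ig <- c(as.numeric(scatteringArray(att)), as.numeric(spectrumArray(att)),
          as.numeric(lifetimeArray(att)), as.numeric(ltFeatureMatrix(att)),
          sizeFeatureVector(att))
  expect_lt(sqrt(sum((ig - trap)^2)) / sqrt(sum(trap^2)), 1e-3)
})

test_that("instance explanations target the predicted class and pair all modalities", {
  fx <- tinyTrainedModel()
  sub <- fx$clean[trainTestSplit(fx$model)$test]
  ex <- explainInstance(fx$model, sub, which = 2, steps = 25)
  logp <- forwardPass(fx$model, sub[2])
  expect_equal(predictedClasses(ex$attribution),
               classOrder(fx$model)[which.max(logp)])
  expect_identical(predictedClasses(ex$attribution),
                   targetClasses(ex$attribution))
  expect_length(ex$pairs, 5)
  for (p in ex$pairs)
    expect_equal(dim(as.matrix(p$input)), dim(as.matrix(p$attribution)))
})

test_that("attribution targets can be the true label or a fixed class", {
  fx <- tinyTrainedModel()
  sub <- fx$clean[trainTestSplit(fx$model)$test][1:3]
  attT <- integratedGradients(fx$model, sub, steps = 10, target = "true")
  expect_identical(targetClasses(attT), sampleLabels(sub))
  attC <- integratedGradients(fx$model, sub, steps = 10, target = "Carex")
  expect_true(all(targetClasses(attC) == "Carex"))
  expect_error(integratedGradients(fx$model, sub, steps = 10,
                                   target = "Betula"), "unknown target")
  expect_error(integratedGradients(fx$model, sub, steps = 0), "steps")
})
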