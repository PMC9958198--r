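# Shared fixtures: hand-built records with known properties and a small
# trained model cached for the whole test session.

.fixtureCache <- new.env(parent = emptyenv())

## instrument wavelength grid, recomputed independently of the package
gridWl <- function() 350 + (0:31) * 14.51

## a raw record that passes all four filter predicates:
## spectrum peak at grid index 5 (max 4000 > 2500) in all acquisitions,
## lifetime maximum at bin 20 (inside [10, 44]), 200 scattering columns.
goodRecord <- function(peakIdx = 5L, lifetimePeakBin = 20L, nCols = 200L) {
  sp <- outer(0.5^(0:7), 4000 * exp(-(0:31 - peakIdx)^2 / 8))
  lt <- matrix(0, 4, 64)
  for (b in 1:4)
    lt[b, ] <- 3000 * ifelse(0:63 >= lifetimePeakBin,
                             exp(-(0:63 - lifetimePeakBin) / (2 + b)),
                             exp(-(lifetimePeakBin - 0:63)^2 / 2))
  sc <- outer(exp(-(1:24 - 12)^2 / 50),
              exp(-(seq_len(nCols) - nCols / 2)^2 / (2 * (nCols / 5)^2)))
  list(scattering = 300 * sc, spectrum = sp, lifetime = lt)
}

rawSetFrom <- function(records, labels = rep(NA_character_,
                                             length(records))) {
  new("RawParticleSet", records = records, labels = labels,
      corrupt = logical())
}

## independent re-statement of the four filter predicates (test oracle)
oraclePasses <- function(r) {
  max(r$spectrum) > 2500 &&
    ncol(r$scattering) < 450 &&
    {
      bin <- (which.max(r$lifetime) - 1) %/% 4
      bin >= 10 && bin <= 44
    } &&
    all(vapply(1:4, function(i) {
      j <- which.max(r$spectrum[i, ]) - 1
      j >= 3 && j <= 10
    }, logical(1)))
}

## small clean sample set from the default study conditions
smallCleanSet <- function(n = 12, seed = 7) {
  key <- paste0("clean", n, "_", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- preprocessParticles(suppressWarnings(
      generateParticles(defaultClassSpecs(), n, seed = seed)))
  .fixtureCache[[key]]
}

## a quickly trained small model on the default four classes, cached
tinyTrainedModel <- function() {
  if (is.null(.fixtureCache$model)) {
    clean <- smallCleanSet(n = 30, seed = 7)
    cfg <- fusionNetConfig(nClasses = 4, trainPerClass = 24,
                           perClassBatch = 6, maxEpochs = 6, patience = 6,
                           seed = 3)
    .fixtureCache$model <- trainFusionNet(clean, cfg)
    .fixtureCache$modelData <- clean
  }
  list(model = .fixtureCache$model, clean = .fixtureCache$modelData)
}

## a built (untrained) four-class model matching the default class order
builtModel <- function(seed = 5) {
  classes <- sort(vapply(defaultClassSpecs(), function(s) s@className, ""))
  buildFusionNet(fusionNetConfig(nClasses = 4, seed = seed), classes)
}

## hand-built AttributionSet: values planted in chosen coordinates
attributionSetFrom <- function(perRecord, predicted,
                               trueLab = predicted) {
  n <- length(perRecord)
  sc <- array(0, c(20, 120, n)); sp <- array(0, c(4, 32, n))
  lt <- array(0, c(4, 24, n)); ltf <- matrix(0, 4, n); sz <- numeric(n)
  for (i in seq_len(n)) {
    r <- perRecord[[i]]
    if (!is.null(r$scattering)) sc[, , i] <- r$scattering
    if (!is.null(r$spectrum)) sp[, , i] <- r$spectrum
    if (!is.null(r$lifetime)) lt[, , i] <- r$lifetime
    if (!is.null(r$ltFeatures)) ltf[, i] <- r$ltFeatures
    if (!is.null(r$sizeFeature)) sz[i] <- r$sizeFeature
  }
  new("AttributionSet", scattering = sc, spectrum = sp, lifetime = lt,
      ltFeatures = ltf, sizeFeature = sz, predictedClass = predicted,
      targetClass = predicted, logProb = numeric(n),
      completenessGap = numeric(n), trueLabel = trueLab)
}
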