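test_that("each filter predicate rejects exactly the records that violate it", {
  good <- goodRecord()
  dim_spec <- goodRecord(); dim_spec$spectrum <- dim_spec$spectrum *
    (2400 / max(dim_spec$spectrum))
  long_sc <- goodRecord(nCols = 460)
  early_lt <- goodRecord(lifetimePeakBin = 5)
  off_peak <- goodRecord(); off_peak$spectrum[2, 25] <-
    2 * max(off_peak$spectrum)
  raw <- rawSetFrom(list(dim_spec, long_sc, early_lt, off_peak, good))
  res <- filterParticles(raw)
  expect_length(res$kept, 1)
  counts <- stats::setNames(res$report$rejected, res$report$rule)
  expect_equal(counts[["spectrum_max"]], 1)
  expect_equal(counts[["scattering_cols"]], 1)
  expect_equal(counts[["lifetime_argmax"]], 1)
  expect_equal(counts[["spectrum_argmax"]], 1)
  expect_equal(counts[["total_kept"]], 1)
  # independently check every record against the predicate oracle
  expect_equal(vapply(particleRecords(raw), oraclePasses, logical(1)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("spectrum-max rule uses a strict threshold of 2500", {
  r <- goodRecord()
  r$spectrum <- r$spectrum * (2400 / max(r$spectrum))
  expect_length(filterParticles(rawSetFrom(list(r)))$kept, 0)
  r$spectrum <- r$spectrum * (2501 / max(r$spectrum))
  expect_length(filterParticles(rawSetFrom(list(r)))$kept, 1)
})

test_that("filtering an empty set yields an empty result and zero counts", {
  res <- filterParticles(rawSetFrom(list()))
  expect_length(res$kept, 0)
  expect_true(all(res$report$rejected == 0))
})

test_that("filtering is idempotent and pass rate equals one minus the corrupt fraction", {
  raw <- suppressWarnings(
    generateParticles(defaultClassSpecs(), 40, corruptFraction = 0.25,
                      seed = 13))
  res <- filterParticles(raw)
  expect_equal(length(res$kept) / length(raw), 0.75)
  again <- filterParticles(res$kept)
  expect_length(again$kept, length(res$kept))
  expect_true(all(again$report$rejected[1:4] == 0))
})

test_that("scattering crop centres on the global maximum with zero-fill at edges", {
  # unique maximum at 0-based column 150 of a 24 x 300 image
  m <- matrix(seq(0, 1, length.out = 24 * 300), 24, 300)
  m[10, 151] <- 10
  out <- centerCropScattering(m)
  expect_equal(dim(out), c(20, 120))
  expect_equal(out, m[3:22, 91:210])  # 0-based columns 90..209

  # exact fit: max at 0-based column 60 of 120 columns
  m2 <- matrix(1, 24, 120); m2[12, 61] <- 5
  expect_equal(centerCropScattering(m2), m2[3:22, ])

  # max near the left edge: first 50 output columns are zero-padding
  m3 <- matrix(1, 24, 120); m3[12, 11] <- 5
  out3 <- centerCropScattering(m3)
  expect_true(all(out3[, 1:50] == 0))
  expect_equal(out3[, 51:120], m3[3:22, 1:70])

  expect_warning(z <- centerCropScattering(matrix(0, 24, 50)), "all-zero")
  expect_equal(dim(z), c(20, 120))
})

test_that("lifetime alignment places the global maximum at time index 4", {
  # already at 0-based bin 4: first 24 bins unchanged
  m <- matrix(0, 4, 64); m[2, 5] <- 10; m[2, 6:20] <- 5
  expect_equal(alignLifetime(m), m[, 1:24])

  # max at 0-based bin 10: output bin j = input bin j + 6
  m2 <- matrix(stats::runif(4 * 64), 4, 64); m2[3, 11] <- 50
  out <- alignLifetime(m2)
  expect_equal(out, m2[, 7:30])

  # property: argmax lands at index 4 for random traces
  set.seed(42)
  for (k in 1:25) {
    peak <- sample(5:60, 1)
    mk <- matrix(stats::runif(4 * 64), 4, 64)
    mk[sample(4, 1), peak + 1] <- 100
    out <- alignLifetime(mk)
    expect_equal((which.max(out) - 1) %/% 4, 4)
    expect_equal(dim(out), c(4, 24))
  }
  expect_error(alignLifetime(matrix(0, 4, 64)), "all-zero")
})

test_that("spectrum stacking keeps the first four acquisitions unchanged", {
  m <- matrix(seq_len(8 * 32), 8, 32)
  out <- stackSpectrum(m)
  expect_equal(dim(out), c(4, 32))
  expect_equal(out, m[1:4, ])
  expect_equal(stackSpectrum(matrix(0, 8, 32)), matrix(0, 4, 32))
  expect_error(stackSpectrum(matrix(0, 6, 32)), "8 acquisition rows")
})

test_that("lifetime features are noise-corrected band sums normalized by their maximum", {
  # construct bands with zero pre-rise noise and known sums 10/20/40/30
  lt <- matrix(0, 4, 24)
  lt[1, 5] <- 10; lt[2, 5] <- 20; lt[3, 5] <- 40; lt[4, 5] <- 30
  expect_equal(deriveLifetimeFeatures(lt), c(0.25, 0.5, 1, 0.75))

  # identical bands give all ones
  lt2 <- matrix(rep(c(0, 0, 1, 5, 9, 5, 3, 2, 1, rep(0, 15)), each = 4),
                4, 24)
  expect_equal(deriveLifetimeFeatures(lt2), rep(1, 4))

  # noise estimate subtracts the mean of the first two bins
  lt3 <- matrix(2, 4, 24)          # constant = all noise, no signal
  expect_warning(f <- deriveLifetimeFeatures(lt3), "no positive")
  expect_equal(f, rep(0, 4))

  # property: max feature is exactly 1 whenever any band has signal
  set.seed(1)
  for (k in 1:20) {
    ltk <- matrix(stats::runif(4 * 24), 4, 24)
    expect_equal(max(deriveLifetimeFeatures(ltk)), 1)
  }
})

test_that("the size feature is the log of total image intensity", {
  expect_equal(deriveSizeFeature(matrix(1, 20, 120)), log(2400))
  img <- matrix(stats::runif(2400), 20, 120)
  expect_equal(deriveSizeFeature(2 * img),
               deriveSizeFeature(img) + log(2), tolerance = 1e-12)
  expect_error(deriveSizeFeature(matrix(0, 20, 120)), "zero-sum")
})

test_that("the size feature increases monotonically with planted diameter", {
  sizes <- seq(15, 60, length.out = 10)
  feats <- vapply(sizes, function(s) {
    spec <- classSpec("x", 451, 10, 4000, rep(3, 4), sizeMu = s,
                      sizeSigma = 0, roughness = 0, noiseSd = 0)
    r <- particleRecords(generateParticles(list(spec), 1, seed = 5))[[1]]
    deriveSizeFeature(centerCropScattering(r$scattering))
  }, numeric(1))
  expect_false(is.unsorted(feats, strictly = TRUE))
})

test_that("preprocessing yields the exact clean-sample shape contract", {
  raw <- suppressWarnings(
    generateParticles(defaultClassSpecs(), 5, corruptFraction = 0.2,
                      seed = 3))
  clean <- preprocessParticles(raw)
  n <- length(clean)
  expect_equal(n, 16)  # 4 classes x (5 - round(0.2 * 5)) survivors
  expect_equal(dim(scatteringArray(clean)), c(20, 120, n))
  expect_equal(dim(spectrumArray(clean)), c(4, 32, n))
  expect_equal(dim(lifetimeArray(clean)), c(4, 24, n))
  expect_equal(dim(ltFeatureMatrix(clean)), c(4, n))
  expect_length(sizeFeatureVector(clean), n)
  # aligned lifetime argmax at index 4 and normalized features for all
  for (i in seq_len(n)) {
    expect_equal((which.max(lifetimeArray(clean)[, , i]) - 1) %/% 4, 4)
    expect_equal(max(ltFeatureMatrix(clean)[, i]), 1)
  }
  expect_s3_class(attr(clean, "filterReport"), "data.frame")
})
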