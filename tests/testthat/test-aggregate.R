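test_that("summary statistics and sign levels follow the cutoff table", {
  # two records of one class, +1/+1 in one spectrum cell, +1/-1 in another
  r1 <- list(spectrum = matrix(0, 4, 32)); r1$spectrum[1, 4] <- 1
  r1$spectrum[2, 10] <- 1
  r2 <- list(spectrum = matrix(0, 4, 32)); r2$spectrum[1, 4] <- 1
  r2$spectrum[2, 10] <- -1
  su <- summarizeAttributions(attributionSetFrom(list(r1, r2),
                                                 c("A", "A")))
  tab <- summaryTable(su)
  sp <- tab[tab$modality == "spectrum", ]
  consistent <- sp[sp$row == 0 & sp$col == 3, ]   # feature at (t=0, wl=3)
  expect_equal(consistent$mean, 1)
  expect_equal(consistent$mean_abs, 1)
  expect_equal(consistent$sign_level, "strong_positive")
  mixed <- sp[sp$row == 1 & sp$col == 9, ]
  expect_equal(mixed$mean, 0)
  expect_equal(mixed$mean_abs, 1)
  expect_equal(mixed$sign_level, "mixed")
})

test_that("sign levels handle the exact cutoff boundaries", {
  sl <- pollenfuse:::.signLevel
  expect_equal(sl(0.76, 1), "strong_positive")
  expect_equal(sl(0.75, 1), "positive")      # s > 0.75 is strict
  expect_equal(sl(0.26, 1), "positive")
  expect_equal(sl(0.25, 1), "mixed")         # |s| <= 0.25 is mixed
  expect_equal(sl(-0.25, 1), "mixed")
  expect_equal(sl(-0.26, 1), "negative")
  expect_equal(sl(-0.75, 1), "negative")
  expect_equal(sl(-0.76, 1), "strong_negative")
  expect_equal(sl(0, 0), "mixed")            # no signal at all
})

test_that("mean absolute attribution bounds the absolute mean everywhere", {
  set.seed(3)
  recs <- lapply(1:6, function(i)
    list(spectrum = matrix(stats::rnorm(128), 4, 32),
         lifetime = matrix(stats::rnorm(96), 4, 24),
         ltFeatures = stats::rnorm(4), sizeFeature = stats::rnorm(1)))
  su <- summarizeAttributions(
    attributionSetFrom(recs, rep(c("A", "B"), 3)))
  tab <- summaryTable(su)
  expect_true(all(tab$mean_abs >= abs(tab$mean) - 1e-12))
  # ranks form a permutation within each class and modality
  for (cl in unique(tab$class)) {
    for (mod in unique(tab$modality)) {
      r <- tab$rank[tab$class == cl & tab$modality == mod]
      expect_identical(sort(r), seq_along(r))
    }
  }
})

test_that("pooling is linear in record counts and order-invariant", {
  set.seed(4)
  recs <- lapply(1:9, function(i)
    list(spectrum = matrix(stats::rnorm(128), 4, 32)))
  labels <- rep("A", 9)
  full <- attributionSetFrom(recs, labels)
  m_full <- summaryTable(summarizeAttributions(full))
  m1 <- summaryTable(summarizeAttributions(full[1:3]))
  m2 <- summaryTable(summarizeAttributions(full[4:9]))
  expect_equal(m_full$mean, (3 * m1$mean + 6 * m2$mean) / 9,
               tolerance = 1e-12)
  expect_equal(m_full$mean_abs, (3 * m1$mean_abs + 6 * m2$mean_abs) / 9,
               tolerance = 1e-12)
  shuffled <- summaryTable(summarizeAttributions(full[sample(9)]))
  expect_equal(shuffled$mean, m_full$mean, tolerance = 1e-12)
})

test_that("pooling can use the true label and restrict to correct predictions", {
  recs <- lapply(1:4, function(i) list(sizeFeature = i))
  att <- attributionSetFrom(recs, predicted = c("A", "A", "B", "B"),
                            trueLab = c("A", "B", "B", "B"))
  byPred <- summaryTable(summarizeAttributions(att, poolBy = "predicted"))
  byTrue <- summaryTable(summarizeAttributions(att, poolBy = "true"))
  szP <- byPred[byPred$modality == "size_feature", ]
  szT <- byTrue[byTrue$modality == "size_feature", ]
  expect_equal(szP$mean[szP$class == "A"], 1.5)   # records 1, 2
  expect_equal(szT$mean[szT$class == "A"], 1)     # record 1 only
  expect_equal(szT$mean[szT$class == "B"], 3)     # records 2, 3, 4
  onlyOk <- summaryTable(summarizeAttributions(att, onlyCorrect = TRUE))
  szO <- onlyOk[onlyOk$modality == "size_feature", ]
  expect_equal(szO$mean[szO$class == "B"], 3.5)   # records 3, 4
})

test_that("top-k ranking returns the k largest mean-absolute features per class", {
  set.seed(5)
  recs <- lapply(1:4, function(i)
    list(spectrum = matrix(stats::rnorm(128), 4, 32)))
  su <- summarizeAttributions(attributionSetFrom(recs, rep(c("A", "B"), 2)))
  top <- topFeatures(su, "spectrum", 10)
  expect_equal(nrow(top), 20)  # 10 per class
  expect_true(all(table(top$class) == 10))
  for (cl in c("A", "B")) {
    sub <- summaryTable(su)
    sub <- sub[sub$modality == "spectrum" & sub$class == cl, ]
    expect_equal(sort(top$mean_abs[top$class == cl], decreasing = TRUE),
                 sort(sub$mean_abs, decreasing = TRUE)[1:10])
  }
  one <- topFeatures(su, "spectrum", 1)
  for (cl in c("A", "B")) {
    sub <- summaryTable(su)
    sub <- sub[sub$modality == "spectrum" & sub$class == cl, ]
    expect_equal(one$mean_abs[one$class == cl], max(sub$mean_abs))
  }
  expect_warning(allf <- topFeatures(su, "lt_features", 10), "exceeds")
  expect_equal(nrow(allf), 8)  # 4 features x 2 classes
})

test_that("scattering maps honour the row-major feature index contract", {
  img <- matrix(stats::rnorm(2400), 20, 120)
  su <- summarizeAttributions(
    attributionSetFrom(list(list(scattering = img)), "A"))
  maps <- scatteringMap(su)
  expect_length(maps, 1)
  expect_equal(maps[["A"]], img, tolerance = 1e-12)
  tab <- summaryTable(su)
  sc <- tab[tab$modality == "scattering", ]
  # feature_id r*120 + c maps back to image position [r, c]
  for (k in sample(nrow(sc), 20)) {
    r <- sc$feature_id[k] %/% 120
    cc <- sc$feature_id[k] %% 120
    expect_equal(maps[["A"]][r + 1, cc + 1], sc$mean[k])
    expect_equal(sc$row[k], r)
    expect_equal(sc$col[k], cc)
  }
})

test_that("summary CSV export round-trips", {
  recs <- lapply(1:2, function(i) list(ltFeatures = c(i, 0, 0, 1)))
  su <- summarizeAttributions(attributionSetFrom(recs, c("A", "A")))
  csv <- withr::local_tempfile(fileext = ".csv")
  writeSummary(su, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(summaryTable(su)))
  expect_equal(back$mean, summaryTable(su)$mean, tolerance = 1e-12)
})
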