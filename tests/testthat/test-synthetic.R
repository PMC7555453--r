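lib <- markerLibrary()

test_that("default profiles encode the species-dominant ion structure", {
  pr <- defaultProfiles()
  expect_equal(nrow(pr$panel), 40L)
  expect_true(all(vapply(pr$means, function(m) all(m > 1000), logical(1))))
  top3 <- function(s) names(sort(pr$means[[s]], decreasing = TRUE))[1:3]
  expect_setequal(top3("chicken"), c("C 50:2", "C 52:3", "C 54:4"))
  expect_setequal(top3("pork"), c("C 50:1", "C 52:2", "C 54:3"))
  expect_setequal(top3("beef"), c("C 50:1", "C 52:2", "C 54:2"))
  ## cross-species contrasts behind the fingerprint differences
  expect_gt(pr$means$chicken[["C 52:3"]], pr$means$chicken[["C 52:2"]])
  expect_gt(pr$means$beef[["C 54:2"]], pr$means$chicken[["C 54:2"]])
  ## filler ions stay off the marker list and inside the mass window
  filler <- pr$panel[!pr$panel$is_marker, ]
  expect_equal(nrow(filler), 25L)
  expect_false(any(filler$label %in% lib$label))
  expect_true(all(filler$mz > 800 & filler$mz < 1000))
})

test_that("generation is seed-reproducible and respects the noise model", {
  a <- generatePure("chicken", 3, seed = 1)
  b <- generatePure("chicken", 3, seed = 1)
  expect_identical(lapply(a, peakTable), lapply(b, peakTable))
  expect_false(identical(peakTable(a[[1]]),
                         peakTable(generatePure("chicken", 1, seed = 2)[[1]])))
  ## noise-free limit reproduces the profile means exactly
  pr0 <- defaultProfiles(cv = 0, scaleSigma = 0, mzJitterPpm = 0)
  pk <- generatePure("pork", 1, seed = 1, pr0)[[1]]
  expect_equal(peakTable(pk)$intensity,
               unname(pr0$means$pork[order(pr0$panel$mz)]))
  expect_equal(peakTable(pk)$mz, sort(pr0$panel$mz))
})

test_that("per-ion sample means converge to the profile means", {
  pr <- defaultProfiles()
  pks <- generatePure("pork", 100, seed = 2, pr)
  ints <- vapply(pks, function(p) peakTable(p)$intensity,
                 numeric(nrow(pr$panel)))
  mu <- pr$means$pork[order(pr$panel$mz)]
  ## lognormal-noise standard error: sd/sqrt(n) per ion, 3-sigma band
  s2 <- log(1 + pr$cv)^2 + pr$scaleSigma^2
  se <- mu * sqrt(exp(s2) - 1) / sqrt(length(pks))
  expect_true(all(abs(rowMeans(ints) - mu) < 3.5 * se))
})

test_that("generated m/z stay within 5 ppm of their panel annotation", {
  pr <- defaultProfiles()
  mzRef <- sort(pr$panel$mz)
  pks <- generatePure("beef", 50, seed = 3, pr)
  for (p in pks)
    expect_true(all(abs(ppmError(peakTable(p)$mz, mzRef)) < 5))
})

test_that("product means are convex combinations of species profiles", {
  pr0 <- defaultProfiles(cv = 0, scaleSigma = 0, mzJitterPpm = 0)
  fr <- c(beef = 0.7, pork = 0.2, chicken = 0.1)
  pk <- generateProduct(list(fractions = fr), 1, seed = 1, pr0)[[1]]
  expected <- (0.7 * pr0$means$beef + 0.2 * pr0$means$pork +
                 0.1 * pr0$means$chicken)[order(pr0$panel$mz)]
  expect_equal(peakTable(pk)$intensity, unname(expected))
  ## degenerate single-species recipe equals the pure generator
  expect_equal(peakTable(generateProduct(list(fractions = c(pork = 1)),
                                         2, seed = 9)[[2]]),
               peakTable(generatePure("pork", 2, seed = 9)[[2]]))
  expect_error(generateProduct(list(fractions = c(pork = 0.7)), 1, 1),
               "sum to 1")
  expect_error(generateProduct(list(fractions = c(pork = 1.2, beef = -0.2)),
                               1, 1), "non-negative")
})

test_that("component decomposition sums exactly to the blend spectrum", {
  pk <- generateProduct(list(fractions = c(pork = 0.8, chicken = 0.2)),
                        1, seed = 5, keepComponents = TRUE)[[1]]
  comp <- attr(pk, "components")
  expect_equal(rownames(comp), c("pork", "chicken"))
  panelInt <- peakTable(pk)$intensity
  expect_equal(unname(colSums(comp)[order(defaultProfiles()$panel$mz)]),
               panelInt)
})

test_that("pure species separate almost perfectly in marker space", {
  ## held-out nearest-centroid check on 210 seeded samples
  pr <- defaultProfiles()
  pks <- c(generatePure("beef", 70, 11, pr),
           generatePure("chicken", 70, 12, pr),
           generatePure("pork", 70, 13, pr))
  fm <- buildFeatureMatrix(annotateSamples(pks, lib))
  m <- intensityMatrix(rowSumNormalize(fm))
  labels <- sub("_[0-9]+$", "", rownames(m))
  train <- as.logical(seq_along(labels) %% 2)
  centroids <- do.call(rbind, lapply(unique(labels), function(cl)
    colMeans(m[train & labels == cl, , drop = FALSE])))
  rownames(centroids) <- unique(labels)
  pred <- apply(m[!train, ], 1, function(v)
    rownames(centroids)[which.min(colSums((t(centroids) - v)^2))])
  expect_gte(mean(pred == labels[!train]), 0.99)
})

test_that("acquisition sequences interleave QC pools as prescribed", {
  pks <- generatePure("pork", 25, seed = 21)
  seqn <- buildSequence(pks, qcPeriod = 10, seed = 22)
  roles <- seqn$order$role
  ## blank, lead QC, 10 samples, QC, 10 samples, QC, 5 samples, blank
  qcPos <- which(roles == "QC")
  expect_equal(qcPos, c(2L, 13L, 24L))
  expect_equal(roles[c(1, length(roles))], c("blank", "blank"))
  expect_equal(sum(roles == "sample"), 25L)
  ## same seed, same permutation; different seed differs
  seqn2 <- buildSequence(pks, qcPeriod = 10, seed = 22)
  expect_identical(seqn$order, seqn2$order)
  expect_false(identical(seqn$order,
                         buildSequence(pks, qcPeriod = 10, seed = 23)$order))
  expect_error(buildSequence(pks, qcPeriod = 0, seed = 1), "qcPeriod")
})

test_that("the QC pool is the arithmetic mean spectrum of the samples", {
  pks <- generatePure("beef", 8, seed = 31)
  seqn <- buildSequence(pks, qcPeriod = 10, seed = 1)
  qc <- seqn$peakLists[[which(seqn$order$role == "QC")[1]]]
  ints <- vapply(pks, function(p) peakTable(p)$intensity,
                 numeric(length(pks[[1]])))
  expect_equal(peakTable(qc)$intensity, unname(rowMeans(ints)))
})

test_that("synthetic PCR datasets honour the discrepancy rate", {
  d0 <- generatePcrDataset(40, 0, seed = 1)
  expect_identical(d0$mpcr[, c("pork", "chicken", "beef")],
                   d0$mqpcr[, c("pork", "chicken", "beef")])
  expect_identical(generatePcrDataset(15, 0.4, seed = 2),
                   generatePcrDataset(15, 0.4, seed = 2))
  d1 <- generatePcrDataset(60, 1, seed = 3)
  fatRich <- d1$declarations$product_type %in% c("luncheon", "natural_juices")
  disagree <- rowSums(d1$mpcr[, 3:5] != d1$mqpcr[, 3:5]) > 0
  expect_true(all(disagree[fatRich]))
  expect_false(any(disagree[!fatRich]))
  expect_error(generatePcrDataset(10, 1.5, seed = 1), "0, 1")
})
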