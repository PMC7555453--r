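lib <- markerLibrary()

test_that("feature matrices are assembled from annotation tables", {
  pks <- c(generatePure("beef", 3, 1), generatePure("chicken", 3, 2),
           generatePure("pork", 3, 3))
  tabs <- annotateSamples(pks, lib)
  fm <- buildFeatureMatrix(tabs)
  expect_s4_class(fm, "TagFeatureMatrix")
  expect_equal(dim(intensityMatrix(fm)), c(9L, 15L))
  expect_equal(featureState(fm), "raw")
  ## single-ion subset gives a column vector
  one <- buildFeatureMatrix(tabs, ionSubset = "C 52:3")
  expect_equal(dim(intensityMatrix(one)), c(9L, 1L))
  expect_error(buildFeatureMatrix(tabs, ionSubset = "C 99:9"), "unknown ion")
})

test_that("ions missing from a sample enter as zero, not as an error", {
  full <- stickSpectrum(lib)
  partial <- PeakList("partial", lib$annotated_mz[-3],
                      rep(1e4, nrow(lib) - 1))
  fm <- buildFeatureMatrix(annotateSamples(list(a = full, b = partial), lib))
  m <- intensityMatrix(fm)
  expect_equal(unname(m["b", lib$label[3]]), 0)
  expect_true(all(m["a", ] == 1e4))
})

test_that("row-sum normalization rescales each sample to unit total", {
  fm <- matrixFromValues(rbind(s1 = c(2, 3, 5), s2 = c(10, 30, 60)))
  nm <- rowSumNormalize(fm)
  expect_equal(unname(intensityMatrix(nm)["s1", ]), c(0.2, 0.3, 0.5))
  expect_equal(featureState(nm), "normalized")
  ## invariance to per-sample global scale (the normalization's purpose)
  fmScaled <- matrixFromValues(rbind(s1 = 7 * c(2, 3, 5),
                                     s2 = 0.1 * c(10, 30, 60)))
  expect_equal(intensityMatrix(rowSumNormalize(fmScaled)),
               intensityMatrix(nm))
  ## degenerate mass on one ion
  deg <- rowSumNormalize(matrixFromValues(rbind(s1 = c(1, 0, 0),
                                                s2 = c(1, 1, 0))))
  expect_equal(unname(intensityMatrix(deg)["s1", ]), c(1, 0, 0))
  ## idempotence
  expect_equal(intensityMatrix(rowSumNormalize(nm)), intensityMatrix(nm))
  ## all-zero row names the offending sample
  expect_error(rowSumNormalize(matrixFromValues(rbind(bad = c(0, 0, 0),
                                                      ok = c(1, 2, 3)))),
               "bad")
})

test_that("Pareto scaling centers and sqrt-sd-scales each ion", {
  ## hand check: column (1, 3) -> mean 2, sd sqrt(2), divisor 2^(1/4)
  fit <- tagprint:::.paretoFit(matrix(c(1, 3), ncol = 1))
  scaled <- tagprint:::.paretoApply(matrix(c(1, 3), ncol = 1), fit)
  expect_equal(as.numeric(scaled), c(-0.8409, 0.8409), tolerance = 1e-4)
  ## public pipeline: column means 0, constant columns map to zeros
  fm <- rowSumNormalize(matrixFromValues(
    rbind(s1 = c(1, 1, 2), s2 = c(2, 1, 1), s3 = c(3, 1, 4))))
  ps <- paretoScale(fm)
  expect_equal(featureState(ps), "pareto")
  expect_true(all(abs(colMeans(intensityMatrix(ps))) < 1e-12))
  params <- scalingParams(ps)
  expect_equal(length(params$centers), 3L)
  expect_error(paretoScale(rowSumNormalize(matrixFromValues(
    matrix(c(1, 2), 1, 2, dimnames = list("s1", NULL))))), "2 samples")
})

test_that("a constant ion scales to exactly zero", {
  vals <- rbind(s1 = c(4, 1), s2 = c(4, 3), s3 = c(4, 5))
  vals <- vals / rowSums(vals)
  vals[, 1] <- 0.5; vals[, 2] <- 0.5       # both ions constant across samples
  fm <- rowSumNormalize(matrixFromValues(vals * 2))
  ps <- paretoScale(fm)
  expect_true(all(intensityMatrix(ps) == 0))
})

test_that("the pretreatment order raw -> normalized -> pareto is enforced", {
  fm <- matrixFromValues(rbind(s1 = c(2, 3, 5), s2 = c(1, 1, 2)))
  expect_error(paretoScale(fm), "normalized")
  ps <- paretoScale(rowSumNormalize(fm))
  expect_error(rowSumNormalize(ps), "Pareto")
  expect_error(paretoScale(ps), "normalized")
})

test_that("stored parameters reproduce the training scaling on new data", {
  fm <- matrixFromValues(rbind(s1 = c(2, 3, 5), s2 = c(1, 4, 5),
                               s3 = c(3, 3, 4)))
  ps <- paretoScale(rowSumNormalize(fm))
  projected <- applyPretreatment(fm, ps)
  expect_equal(projected, intensityMatrix(ps))
  expect_error(applyPretreatment(fm, rowSumNormalize(fm)), "no Pareto")
})
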