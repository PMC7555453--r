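lib <- markerLibrary()

test_that("the first PLS component matches the eigen-decomposition oracle", {
  set.seed(9)
  for (rep in 1:5) {
    X <- scale(matrix(rnorm(4 * 3), 4, 3), scale = FALSE)
    labels <- stats::setNames(c("a", "a", "b", "b"), paste0("s", 1:4))
    model <- suppressWarnings(fitPlsda(X, labels, nComponents = 1))
    ## brute force: w1 is the dominant eigenvector of X' Yc Yc' X
    Yc <- scale(tagprint:::.dummyY(labels), scale = FALSE)
    M <- t(X) %*% Yc %*% t(Yc) %*% X
    w <- eigen(M, symmetric = TRUE)$vectors[, 1]
    expect_equal(abs(model@weights[, 1]), abs(w), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("NIPALS agrees with an independent PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(10)
  X <- scale(matrix(rnorm(10 * 6), 10, 6), scale = FALSE)
  labels <- stats::setNames(rep(c("a", "b"), each = 5), paste0("s", 1:10))
  model <- fitPlsda(X, labels, nComponents = 2)
  ref <- mixOmics::plsda(X, factor(labels), ncomp = 2, scale = FALSE)
  for (a in 1:2) {
    w <- model@weights[, a] / sqrt(sum(model@weights[, a]^2))
    rw <- ref$loadings$X[, a] / sqrt(sum(ref$loadings$X[, a]^2))
    expect_equal(abs(w), abs(rw), tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("the three-species synthetic model is fully recognized", {
  fm <- pureMeatMatrix(3, seed = 1)
  fmp <- paretoScale(rowSumNormalize(fm))
  model <- fitPlsda(fmp)
  expect_equal(model@nComponents, 2L)
  expect_true(model@R2X >= 0 && model@R2X <= 1)
  expect_true(model@R2Y >= 0 && model@R2Y <= 1)
  expect_equal(recognitionAbility(model, fmp), 100)
  ## duplicating every sample leaves the fit invariant
  dup <- rbind(intensityMatrix(fmp), intensityMatrix(fmp))
  rownames(dup) <- make.unique(rownames(dup))
  labels2 <- rep(classLabels(fm), 2)
  names(labels2) <- rownames(dup)
  model2 <- fitPlsda(dup, labels2)
  expect_equal(model2@R2X, model@R2X, tolerance = 1e-9)
  expect_equal(model2@R2Y, model@R2Y, tolerance = 1e-9)
})

test_that("degenerate fits are rejected", {
  X <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  expect_error(fitPlsda(X, rep("a", 4)), "2 classes")
  expect_error(fitPlsda(X, c("a", "b", "b", "b")), "2 samples")
  X0 <- matrix(0, 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  expect_error(fitPlsda(X0, c("a", "a", "b", "b")), "zero variance")
})

test_that("classification follows the argmax rule with deterministic ties", {
  fm <- pureMeatMatrix(3, seed = 1)
  fmp <- paretoScale(rowSumNormalize(fm))
  model <- fitPlsda(fmp)
  cls <- classifySamples(model, fmp)
  expect_equal(cls$predicted, unname(classLabels(fm)))
  expect_true(all(cls$margin > 0))
  ## balanced classes: the all-zero projection ties every dummy response
  tie <- classifySamples(
    fitPlsda(scale(matrix(rnorm(12, sd = 1), 4, 3), scale = FALSE),
             stats::setNames(c("a", "a", "b", "b"), paste0("s", 1:4)),
             nComponents = 1) -> m2,
    matrix(0, 1, 3))
  expect_equal(tie$predicted, sort(m2@classes)[1])
  expect_equal(tie$margin, 0)
})

test_that("identical samples with conflicting labels cannot both be right", {
  x0 <- c(1, 2, 3); x1 <- c(4, 1, 0); x2 <- c(0, 5, 1)
  X <- rbind(s1 = x0, s2 = x1, s3 = x0, s4 = x2)
  X <- scale(X, scale = FALSE)
  labels <- stats::setNames(c("a", "a", "b", "b"), rownames(X))
  model <- fitPlsda(X, labels, nComponents = 2)
  cls <- classifySamples(model, X)
  expect_equal(cls$predicted[1], cls$predicted[3])   # same x, same call
  expect_lte(100 * mean(cls$predicted[c(1, 3)] == c("a", "b")), 50)
})

test_that("a mislabeled chicken sample stays with the chicken cluster", {
  fm <- chickenPorkMatrix(10, nProducts = 0, seed = 13)
  labels <- classLabels(fm)
  labels[["chicken_1"]] <- "pork"          # deliberate mislabel
  fmp <- paretoScale(rowSumNormalize(fm))
  model <- fitPlsda(fmp, labels)
  cls <- classifySamples(model, fmp)
  expect_equal(cls$predicted[cls$sample_id == "chicken_1"], "chicken")
  ## in score space the sample sits with the chicken cloud, not the pork one
  sc <- modelScores(model)
  dist2 <- function(centroid) sum((sc["chicken_1", ] - centroid)^2)
  chickenC <- colMeans(sc[grepl("^chicken_", rownames(sc)) &
                            rownames(sc) != "chicken_1", , drop = FALSE])
  porkC <- colMeans(sc[grepl("^pork_", rownames(sc)), , drop = FALSE])
  expect_lt(dist2(chickenC), dist2(porkC))
})

test_that("Q2 from k = n folds equals a brute-force leave-one-out loop", {
  fm <- pureMeatMatrix(3, seed = 4)
  m <- intensityMatrix(rowSumNormalize(fm))
  labels <- as.character(classLabels(fm))
  n <- nrow(m)
  q2 <- q2Cv(fm, k = n, seed = 99)
  ## independent LOO loop written against the same definitions
  Y <- tagprint:::.dummyY(stats::setNames(labels, rownames(m)))
  press <- 0
  for (i in seq_len(n)) {
    tr <- m[-i, , drop = FALSE]
    ctr <- colMeans(tr); div <- sqrt(apply(tr, 2, sd))
    sc <- function(z) {
      out <- sweep(z, 2, ctr)
      ok <- div > 0
      out[, ok] <- sweep(out[, ok, drop = FALSE], 2, div[ok], "/")
      out[, !ok] <- 0
      out
    }
    fit <- tagprint:::.nipalsPls(sc(tr), Y[-i, , drop = FALSE], 2)
    yhat <- sweep(sc(m[i, , drop = FALSE]) %*% fit$B, 2, -fit$yMeans)
    press <- press + sum((Y[i, ] - yhat)^2)
  }
  ss <- sum(sweep(Y, 2, colMeans(Y))^2)
  expect_equal(q2, 1 - press / ss, tolerance = 1e-10)
})

test_that("Q2 is high for intact labels and collapses under permutation", {
  fm <- pureMeatMatrix(10, seed = 2)
  q2 <- q2Cv(fm, k = 7, seed = 3)
  expect_gt(q2, 0.5)
  labels <- as.character(classLabels(fm))
  worse <- vapply(1:20, function(i) {
    set.seed(100 + i)
    q2Cv(fm, sample(labels), k = 7, seed = 3) < q2
  }, logical(1))
  expect_true(all(worse))
  expect_error(q2Cv(fm, k = 1, seed = 1), ">= 2")
})

test_that("cross-validated metrics are bit-reproducible under a seed", {
  fm <- pureMeatMatrix(4, seed = 6)
  expect_identical(q2Cv(fm, k = 7, seed = 5), q2Cv(fm, k = 7, seed = 5))
  expect_identical(predictionAbility(fm, k = 7, seed = 5),
                   predictionAbility(fm, k = 7, seed = 5))
  p1 <- permutationTest(fm, nPerm = 20, seed = 5)
  p2 <- permutationTest(fm, nPerm = 20, seed = 5)
  expect_identical(p1$permutedQ2, p2$permutedQ2)
  expect_identical(p1$pValue, p2$pValue)
})

test_that("the permutation test calibrates against chance labelings", {
  fm <- pureMeatMatrix(4, seed = 20)
  pt <- permutationTest(fm, nPerm = 49, seed = 21)
  expect_lte(pt$pValue, 0.02)
  expect_equal(length(pt$permutedQ2), 49L)
  expect_true(pt$pValue > 0 && pt$pValue <= 1)
  expect_error(permutationTest(fm, nPerm = 10, seed = 1), ">= 20")
  ## labels already random: p should usually not be small
  m <- intensityMatrix(rowSumNormalize(fm))
  ps <- vapply(1:10, function(i) {
    set.seed(200 + i)
    rl <- sample(rep(c("a", "b", "c"), 4))
    names(rl) <- rownames(m)
    permutationTest(m, rl, nComponents = 2, nPerm = 20, seed = i)$pValue
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("VIP scores satisfy their algebraic identity and rank markers", {
  fm <- pureMeatMatrix(10, seed = 42)
  model <- fitPlsda(paretoScale(rowSumNormalize(fm)))
  vip <- vipScores(model)
  expect_equal(mean(vip^2), 1, tolerance = 1e-9)
  expect_true(all(vip >= 0))
  ## the main printed per-species discriminators carry VIP > 1
  expect_true(all(vip[c("C 50:2", "C 52:3", "C 50:1", "C 52:2",
                        "C 54:3", "C 54:2")] > 1))
  ## at least six of the seven species-dominant ions exceed 1
  dom <- c("C 50:2", "C 52:3", "C 54:4", "C 50:1", "C 52:2",
           "C 54:3", "C 54:2")
  expect_gte(sum(vip[dom] > 1), 6)
  ## single-ion model: VIP is identically 1
  X1 <- matrix(c(-1, -2, 1, 2), 4, 1,
               dimnames = list(paste0("s", 1:4), "ion"))
  m1 <- suppressWarnings(fitPlsda(X1, stats::setNames(c("a", "a", "b", "b"),
                                                      rownames(X1)),
                                  nComponents = 1))
  expect_equal(unname(vipScores(m1)), 1)
})

test_that("the S-plot places markers at the extremes with bounded correlation", {
  fm <- chickenPorkMatrix(10, nProducts = 5, seed = 7)
  fmp <- paretoScale(rowSumNormalize(fm))
  model <- fitPlsda(fmp)
  sp <- sPlot(model, fmp)
  expect_true(all(abs(sp$pcorr1) <= 1 + 1e-12))
  expect_equal(sum(sp$marker), 4L)
  flagged <- sp$label[sp$marker]
  expect_true(all(c("C 52:3", "C 50:2", "C 52:2") %in% flagged))
  ## chicken markers and the pork marker sit on opposite sides
  side <- stats::setNames(sign(sp$pcorr1), sp$label)
  expect_equal(side[["C 52:3"]], side[["C 50:2"]])
  expect_equal(side[["C 52:3"]], -side[["C 52:2"]])
  ## an ion equal to the first score has correlation exactly 1
  Xs <- intensityMatrix(fmp)
  t1 <- tagprint:::.projectScores(model, Xs)[, 1]
  Xaug <- cbind(Xs, synthetic_t1 = t1)
  modelAug <- fitPlsda(Xaug, classLabels(fm), nComponents = 2)
  spAug <- sPlot(modelAug, Xaug)
  tAug <- tagprint:::.projectScores(modelAug, Xaug)[, 1]
  expect_equal(abs(stats::cor(tAug, Xaug[, "synthetic_t1"])),
               abs(spAug$pcorr1[spAug$label == "synthetic_t1"]),
               tolerance = 1e-10)
  ## zero-variance ions get correlation 0 by convention
  Xz <- cbind(Xs, dead_ion = 0)
  spZ <- sPlot(fitPlsda(Xz, classLabels(fm), nComponents = 2), Xz)
  expect_equal(spZ$pcorr1[spZ$label == "dead_ion"], 0)
})

test_that("variable line plots reproduce the printed marker direction", {
  fm <- chickenPorkMatrix(8, nProducts = 0, seed = 15)
  byClass <- function(ion) {
    d <- variableLinePlot(fm, ion = ion)
    tapply(d$value, d$class, mean)
  }
  v874 <- byClass("C 52:3")
  expect_gt(v874[["chicken"]], v874[["pork"]])
  v876 <- byClass("C 52:2")
  expect_gt(v876[["pork"]], v876[["chicken"]])
  v848 <- byClass("C 50:2")
  expect_gt(v848[["chicken"]], v848[["pork"]])
  expect_error(variableLinePlot(fm, ion = "C 99:9"), "unknown ion")
  ## one-class input returns a single series without error
  one <- fm[, grepl("^pork", colnames(fm))]
  d <- variableLinePlot(one, ion = "C 52:2")
  expect_equal(unique(d$class), "pork")
})

test_that("scores are invariant to sample order up to reordering", {
  fm <- pureMeatMatrix(3, seed = 30)
  fmp <- paretoScale(rowSumNormalize(fm))
  model <- fitPlsda(fmp)
  m <- intensityMatrix(fmp)
  set.seed(31)
  perm <- sample(nrow(m))
  model2 <- fitPlsda(m[perm, ], classLabels(fm)[perm])
  expect_equal(model2@scores[rownames(m), ], model@scores, tolerance = 1e-9)
  expect_equal(model2@R2Y, model@R2Y, tolerance = 1e-12)
})
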