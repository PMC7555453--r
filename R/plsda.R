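#' PlsdaModel: NIPALS partial least squares discriminant analysis
#'
#' PLS2 regression of the Pareto-scaled ion matrix onto class indicator
#' (dummy) columns, extracted component-wise by NIPALS with deflation.
#' Carries the model-quality apparatus used in fingerprint authentication:
#' cumulative explained X-variance (R2X) and dummy-Y variance (R2Y), VIP
#' scores, and the stored pretreatment parameters needed to project unknown
#' samples.
#'
#' @slot weights ions x components X-weight matrix W (unit columns).
#' @slot xLoadings ions x components loading matrix P.
#' @slot yLoadings classes x components Y-loading matrix C.
#' @slot scores samples x components training score matrix T.
#' @slot coefficients ions x classes regression matrix B (centered spaces).
#' @slot classes character, sorted class levels.
#' @slot yMeans numeric, dummy-column means (uncentering term).
#' @slot nComponents integer.
#' @slot R2X,R2Y cumulative explained fractions in [0, 1].
#' @slot ssyPerComponent dummy-Y sum of squares explained per component.
#' @slot vip per-ion variable importance in projection.
#' @slot scaling stored pretreatment (Pareto centers / scale divisors).
#' @slot labels training labels, named by sample.
#' @exportClass PlsdaModel
setClass("PlsdaModel",
  representation(weights = "matrix", xLoadings = "matrix",
                 yLoadings = "matrix", scores = "matrix",
                 coefficients = "matrix", classes = "character",
                 yMeans = "numeric", nComponents = "integer",
                 R2X = "numeric", R2Y = "numeric",
                 ssyPerComponent = "numeric", vip = "numeric",
                 scaling = "list", labels = "character"))

setValidity("PlsdaModel", function(object) {
  msg <- character(0)
  if (object@R2X < -1e-9 || object@R2X > 1 + 1e-9)
    msg <- c(msg, "R2X must be in [0, 1]")
  if (object@R2Y < -1e-9 || object@R2Y > 1 + 1e-9)
    msg <- c(msg, "R2Y must be in [0, 1]")
  if (length(object@vip) && any(object@vip < 0))
    msg <- c(msg, "VIP scores must be non-negative")
  if (length(object@vip) &&
      abs(mean(object@vip^2) - 1) > 1e-9)
    msg <- c(msg, "mean squared VIP must equal 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlsdaModel", function(object) {
  cat("PlsdaModel: ", length(object@classes), " classes (",
      paste(object@classes, collapse = ", "), "), ",
      object@nComponents, " components\n",
      sprintf("  R2X = %.3f, R2Y = %.3f\n", object@R2X, object@R2Y),
      sep = "")
})

#' @export
setMethod("modelScores", "PlsdaModel", function(object) object@scores)

#' @export
setMethod("modelLoadings", "PlsdaModel", function(object) object@xLoadings)

## class labels -> n x g dummy indicator matrix over sorted class levels
.dummyY <- function(labels, classes = sort(unique(labels))) {
  y <- outer(labels, classes, `==`) * 1
  dimnames(y) <- list(names(labels), classes)
  y
}

## NIPALS PLS2 on a centered X and uncentered dummy Y; Y is centered inside
.nipalsPls <- function(X, Y, nComponents, tol = 1e-12, maxit = 500L) {
  n <- nrow(X); p <- ncol(X); g <- ncol(Y)
  yMeans <- colMeans(Y)
  E <- X
  F <- sweep(Y, 2, yMeans)
  ssX <- sum(E^2); ssY <- sum(F^2)
  if (ssX <= 0) stop("X has zero variance")
  W <- matrix(0, p, nComponents)
  P <- matrix(0, p, nComponents)
  C <- matrix(0, g, nComponents)
  Tm <- matrix(0, n, nComponents)
  ssyExplained <- numeric(nComponents)
  a <- 0L
  while (a < nComponents) {
    ssFprev <- sum(F^2)
    u <- F[, which.max(colSums(F^2))]
    if (sum(u^2) < .Machine$double.eps * ssY) break
    w <- NULL
    for (it in seq_len(maxit)) {
      w <- crossprod(E, u)[, 1]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- w / nw
      tt <- E %*% w
      cc <- crossprod(F, tt)[, 1] / sum(tt^2)
      uNew <- (F %*% cc)[, 1] / sum(cc^2)
      if (sum((uNew - u)^2) < tol * max(sum(uNew^2), .Machine$double.eps)) {
        u <- uNew
        break
      }
      u <- uNew
    }
    tt <- E %*% w
    stt <- sum(tt^2)
    if (stt < 1e-12 * ssX) break
    cc <- crossprod(F, tt)[, 1] / stt
    pp <- crossprod(E, tt)[, 1] / stt
    ## deterministic sign: largest |w| element positive
    i <- which.max(abs(w))
    if (w[i] < 0) { w <- -w; tt <- -tt; cc <- -cc; pp <- -pp }
    a <- a + 1L
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; Tm[, a] <- tt
    E <- E - tt %*% t(pp)
    F <- F - tt %*% t(cc)
    ssyExplained[a] <- ssFprev - sum(F^2)
  }
  if (a < nComponents) {
    warning("extracted only ", a, " of ", nComponents,
            " requested components (rank limit)")
    W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
    C <- C[, seq_len(a), drop = FALSE]; Tm <- Tm[, seq_len(a), drop = FALSE]
    ssyExplained <- ssyExplained[seq_len(a)]
  }
  B <- W %*% solve(crossprod(P, W), t(C))
  dimnames(W) <- list(colnames(X), paste0("comp", seq_len(ncol(W))))
  dimnames(P) <- dimnames(W)
  dimnames(C) <- list(colnames(Y), colnames(W))
  dimnames(Tm) <- list(rownames(X), colnames(W))
  dimnames(B) <- list(colnames(X), colnames(Y))
  list(W = W, P = P, C = C, T = Tm, B = B, yMeans = yMeans,
       R2X = 1 - sum(E^2) / ssX,
       R2Y = if (ssY > 0) 1 - sum(F^2) / ssY else NA_real_,
       ssyExplained = ssyExplained, nComponents = a)
}

.vipFromFit <- function(fit) {
  p <- nrow(fit$W)
  ssy <- fit$ssyExplained
  wNorm <- sweep(fit$W, 2, sqrt(colSums(fit$W^2)), "/")  # unit already, kept explicit
  vip <- sqrt(p * as.numeric(wNorm^2 %*% ssy) / sum(ssy))
  names(vip) <- rownames(fit$W)
  vip
}

#' Fit a PLS-DA model
#'
#' @param x A [TagFeatureMatrix-class] in state \code{"pareto"} (fitted with
#'   its stored scaling), or an already-centered samples x ions matrix (no
#'   scaling is stored in that case).
#' @param labels Class labels, one per sample; default: the matrix's
#'   \code{class_label} column. At least 2 classes, each with >= 2 samples.
#' @param nComponents Number of latent components; default
#'   \code{max(nClasses - 1, 2)}.
#' @return A [PlsdaModel-class].
#' @examples
#' pk <- c(generatePure("pork", 3, 1), generatePure("chicken", 3, 2),
#'         generatePure("beef", 3, 3))
#' fm <- buildFeatureMatrix(annotateSamples(pk, markerLibrary()),
#'                          classLabels = sub("_[0-9]+$", "", names(pk)))
#' model <- fitPlsda(paretoScale(rowSumNormalize(fm)))
#' @export
fitPlsda <- function(x, labels = NULL, nComponents = NULL) {
  scaling <- list()
  if (methods::is(x, "TagFeatureMatrix")) {
    if (featureState(x) != "pareto")
      stop("fitPlsda expects a Pareto-scaled matrix")
    if (is.null(labels)) labels <- classLabels(x)
    scaling <- scalingParams(x)
    m <- intensityMatrix(x)
  } else {
    m <- as.matrix(x)
    if (is.null(labels)) stop("labels are required for a plain matrix")
  }
  labels <- stats::setNames(as.character(labels), rownames(m))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2)) stop("each class needs at least 2 samples")
  if (is.null(nComponents)) nComponents <- max(length(classes) - 1L, 2L)
  fit <- .nipalsPls(m, .dummyY(labels, classes), nComponents)
  methods::new("PlsdaModel",
    weights = fit$W, xLoadings = fit$P, yLoadings = fit$C, scores = fit$T,
    coefficients = fit$B, classes = classes, yMeans = fit$yMeans,
    nComponents = as.integer(fit$nComponents),
    R2X = fit$R2X, R2Y = fit$R2Y, ssyPerComponent = fit$ssyExplained,
    vip = .vipFromFit(fit), scaling = scaling, labels = labels)
}

## dummy-response predictions for samples already in the model's scaled space
.predictDummy <- function(model, Xs) {
  sweep(Xs %*% model@coefficients, 2, -model@yMeans)
}

## scores for samples in the model's scaled space (x-rotation)
.projectScores <- function(model, Xs) {
  R <- model@weights %*% solve(crossprod(model@xLoadings, model@weights))
  Xs %*% R
}

#' Classify samples with a PLS-DA model
#'
#' Predicted class is the argmax of the predicted dummy responses; the
#' margin is the gap between the best and second-best response. Exact ties
#' resolve to the first class in sorted order (margin 0).
#'
#' @param model A [PlsdaModel-class].
#' @param x A [TagFeatureMatrix-class] (raw or normalized: projected with
#'   the model's stored pretreatment) or a samples x ions matrix already in
#'   the model's scaled space.
#' @return \code{data.frame} with \code{sample_id}, \code{predicted},
#'   \code{margin}; the full dummy-prediction matrix is attached as
#'   attribute \code{"dummy"}.
#' @export
classifySamples <- function(model, x) {
  Xs <- if (methods::is(x, "TagFeatureMatrix")) {
    if (featureState(x) == "pareto") intensityMatrix(x)
    else applyPretreatment(x, model)
  } else as.matrix(x)
  if (ncol(Xs) != nrow(model@coefficients))
    stop("sample ion set does not match the model")
  yhat <- .predictDummy(model, Xs)
  pred <- character(nrow(yhat)); margin <- numeric(nrow(yhat))
  for (i in seq_len(nrow(yhat))) {
    o <- order(yhat[i, ], decreasing = TRUE)
    ## ties -> first class in sorted order
    top <- which(yhat[i, ] == yhat[i, o[1]])
    pred[i] <- model@classes[min(top)]
    margin[i] <- if (length(top) > 1) 0
                 else yhat[i, o[1]] - yhat[i, o[2]]
  }
  out <- data.frame(
    sample_id = if (!is.null(rownames(Xs))) rownames(Xs)
                else sprintf("sample_%d", seq_len(nrow(Xs))),
    predicted = pred, margin = margin, stringsAsFactors = FALSE)
  attr(out, "dummy") <- yhat
  out
}

## seeded (stratified when possible) fold assignment
.makeFolds <- function(labels, k, seed) {
  n <- length(labels)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k cannot exceed the number of samples")
  .withSeed(seed, {
    fold <- integer(n)
    if (min(table(labels)) >= k) {
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample(n)] <- rep_len(seq_len(k), n)
    }
    fold
  })
}

## shared CV engine: per fold, re-derive Pareto scaling on the training
## rows (leakage-free), fit, predict held-out dummy responses
.cvPredict <- function(mNorm, labels, nComponents, k, seed) {
  classes <- sort(unique(labels))
  Y <- .dummyY(labels, classes)
  fold <- .makeFolds(labels, k, seed)
  yhat <- matrix(NA_real_, nrow(mNorm), length(classes),
                 dimnames = list(rownames(mNorm), classes))
  for (f in sort(unique(fold))) {
    test <- fold == f
    fit <- .paretoFit(mNorm[!test, , drop = FALSE])
    Xtr <- .paretoApply(mNorm[!test, , drop = FALSE], fit)
    Xte <- .paretoApply(mNorm[test, , drop = FALSE], fit)
    pls <- .nipalsPls(Xtr, Y[!test, , drop = FALSE], nComponents)
    yhat[test, ] <- sweep(Xte %*% pls$B, 2, -pls$yMeans)
  }
  list(Y = Y, yhat = yhat, fold = fold, classes = classes)
}

## accept TagFeatureMatrix (raw/normalized) or plain raw matrix; return the
## row-sum normalized samples x ions matrix
.asNormalizedMatrix <- function(x) {
  if (methods::is(x, "TagFeatureMatrix")) {
    if (featureState(x) == "pareto")
      stop("cross-validation re-derives scaling internally; ",
           "supply a raw or normalized matrix")
    m <- intensityMatrix(x)
    if (featureState(x) == "raw") m <- .rowSumNorm(m)
    m
  } else .rowSumNorm(as.matrix(x))
}

#' Cross-validated predictive ability Q2
#'
#' Q2 = 1 - PRESS/SS, where PRESS accumulates squared dummy-response
#' prediction errors over held-out folds of a seeded, stratified k-fold
#' split (Pareto scaling re-derived inside each training fold), and SS is
#' the total centered dummy sum of squares.
#'
#' @param x A [TagFeatureMatrix-class] (state raw or normalized) or a raw
#'   samples x ions matrix. Row-sum normalization is per-sample and is
#'   applied up front; scaling is re-derived per fold.
#' @param labels Class labels (default: the matrix's class labels).
#' @param nComponents Latent components (default
#'   \code{max(nClasses - 1, 2)}).
#' @param k Folds (default 7); \code{k = n} gives leave-one-out.
#' @param seed Integer seed for the fold split.
#' @return Q2, a scalar \code{<= 1}.
#' @export
q2Cv <- function(x, labels = NULL, nComponents = NULL, k = 7, seed = 1) {
  if (is.null(labels) && methods::is(x, "TagFeatureMatrix"))
    labels <- classLabels(x)
  labels <- as.character(labels)
  if (is.null(nComponents))
    nComponents <- max(length(unique(labels)) - 1L, 2L)
  m <- .asNormalizedMatrix(x)
  cv <- .cvPredict(m, labels, nComponents, k, seed)
  press <- sum((cv$Y - cv$yhat)^2)
  ss <- sum(sweep(cv$Y, 2, colMeans(cv$Y))^2)
  1 - press / ss
}

#' Recognition ability: percent of training samples correctly classified
#'
#' @param model A [PlsdaModel-class].
#' @param x Training data ([TagFeatureMatrix-class] or scaled matrix);
#'   default: classify from the model's stored training scores space is not
#'   possible, so \code{x} is required.
#' @param labels True labels (default: the model's training labels).
#' @return Percent correct in [0, 100].
#' @export
recognitionAbility <- function(model, x, labels = NULL) {
  if (is.null(labels)) labels <- model@labels
  cls <- classifySamples(model, x)
  100 * mean(cls$predicted == as.character(labels))
}

#' Prediction ability: pooled percent correct over k-fold held-out samples
#'
#' @inheritParams q2Cv
#' @return Percent correct in [0, 100].
#' @export
predictionAbility <- function(x, labels = NULL, nComponents = NULL, k = 7,
                              seed = 1) {
  if (is.null(labels) && methods::is(x, "TagFeatureMatrix"))
    labels <- classLabels(x)
  labels <- as.character(labels)
  if (is.null(nComponents))
    nComponents <- max(length(unique(labels)) - 1L, 2L)
  m <- .asNormalizedMatrix(x)
  cv <- .cvPredict(m, labels, nComponents, k, seed)
  pred <- cv$classes[apply(cv$yhat, 1, which.max)]
  100 * mean(pred == labels)
}

#' Permutation test of the cross-validated Q2
#'
#' Recomputes Q2 under \code{nPerm} seeded random permutations of the class
#' labels and reports the empirical p-value
#' \code{(1 + #\{permuted Q2 >= observed\}) / (nPerm + 1)}.
#'
#' @inheritParams q2Cv
#' @param nPerm Number of permutations (>= 20).
#' @return List of class \code{"PermutationResult"}: \code{observedQ2},
#'   \code{observedR2Y}, \code{permutedQ2}, \code{permutedR2Y},
#'   \code{pValue}, \code{nPerm}, \code{seed}.
#' @export
permutationTest <- function(x, labels = NULL, nComponents = NULL,
                            nPerm = 200, seed = 1) {
  if (nPerm < 20) stop("nPerm must be >= 20")
  if (is.null(labels) && methods::is(x, "TagFeatureMatrix"))
    labels <- classLabels(x)
  labels <- as.character(labels)
  if (is.null(nComponents))
    nComponents <- max(length(unique(labels)) - 1L, 2L)
  m <- .asNormalizedMatrix(x)
  obsQ2 <- q2Cv(m, labels, nComponents, k = min(7, nrow(m)), seed = seed)
  fitFull <- .nipalsPls(.paretoApply(m, .paretoFit(m)), .dummyY(labels),
                        nComponents)
  permQ2 <- numeric(nPerm); permR2Y <- numeric(nPerm)
  for (i in seq_len(nPerm)) {
    pl <- .withSeed(seed + i, sample(labels))
    permQ2[i] <- q2Cv(m, pl, nComponents, k = min(7, nrow(m)), seed = seed + i)
    permR2Y[i] <- .nipalsPls(.paretoApply(m, .paretoFit(m)), .dummyY(pl),
                             nComponents)$R2Y
  }
  structure(list(observedQ2 = obsQ2, observedR2Y = fitFull$R2Y,
                 permutedQ2 = permQ2, permutedR2Y = permR2Y,
                 pValue = (1 + sum(permQ2 >= obsQ2)) / (nPerm + 1),
                 nPerm = nPerm, seed = seed),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed Q2 = %.3f (R2Y = %.3f), %d permutations\n",
    x$observedQ2, x$observedR2Y, x$nPerm))
  cat(sprintf("  max permuted Q2 = %.3f, empirical p = %.4g\n",
              max(x$permutedQ2), x$pValue))
  invisible(x)
}

#' Variable importance in projection
#'
#' \eqn{VIP_j = \sqrt{p \sum_a (w_{ja}/\|w_a\|)^2\, SSY_a / \sum_a SSY_a}}
#' with \eqn{p} ions and \eqn{SSY_a} the dummy-Y sum of squares explained by
#' component \eqn{a}. Mean squared VIP is identically 1; ions with VIP > 1
#' are conventionally selected as markers.
#'
#' @param model A [PlsdaModel-class].
#' @return Named numeric vector of VIP scores.
#' @export
vipScores <- function(model) model@vip

#' S-plot coordinates for component 1
#'
#' For each ion: \code{p1} = cov(t1, x_j) and \code{pcorr1} = cor(t1, x_j)
#' against the first latent score, on the model-scaled data. Ions with zero
#' variance get correlation 0. The \code{topK} most remote ions (largest
#' combined rank of |p1| and |pcorr1|) are flagged as candidate markers.
#'
#' @param model A fitted [PlsdaModel-class] (two-class use is typical).
#' @param x The data to plot ([TagFeatureMatrix-class] or scaled matrix);
#'   usually the training matrix.
#' @param topK Number of extreme ions to flag (default 4).
#' @return \code{data.frame} with \code{label}, \code{p1}, \code{pcorr1},
#'   \code{marker} (logical).
#' @export
sPlot <- function(model, x, topK = 4) {
  Xs <- if (methods::is(x, "TagFeatureMatrix")) {
    if (featureState(x) == "pareto") intensityMatrix(x)
    else applyPretreatment(x, model)
  } else as.matrix(x)
  t1 <- .projectScores(model, Xs)[, 1]
  n <- nrow(Xs)
  p1 <- as.numeric(crossprod(sweep(Xs, 2, colMeans(Xs)),
                             t1 - mean(t1))) / (n - 1)
  sdx <- apply(Xs, 2, stats::sd)
  pcorr <- ifelse(sdx > 0, p1 / (sdx * stats::sd(t1)), 0)
  remoteness <- rank(abs(p1)) + rank(abs(pcorr))
  out <- data.frame(label = colnames(Xs), p1 = p1, pcorr1 = pcorr,
                    marker = rank(-remoteness, ties.method = "first") <= topK,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-class intensity series for one ion (variable line plot)
#'
#' Returns the row-sum-normalized intensities of one ion, grouped by class
#' and ordered class-by-class — the data behind the "variable line plot"
#' used to confirm marker ions.
#'
#' @param x A [TagFeatureMatrix-class] (raw or normalized).
#' @param labels Class labels (default from the matrix).
#' @param ion Ion label present in the matrix.
#' @return \code{data.frame} with \code{sample_id}, \code{class},
#'   \code{value}, ordered by class.
#' @export
variableLinePlot <- function(x, labels = NULL, ion) {
  if (is.null(labels) && methods::is(x, "TagFeatureMatrix"))
    labels <- classLabels(x)
  m <- .asNormalizedMatrix(x)
  if (!ion %in% colnames(m)) stop("unknown ion '", ion, "'")
  out <- data.frame(sample_id = rownames(m), class = as.character(labels),
                    value = m[, ion], stringsAsFactors = FALSE)
  out <- out[order(out$class), , drop = FALSE]
  rownames(out) <- NULL
  out
}
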