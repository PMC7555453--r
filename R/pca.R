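#' PcaModel: principal component analysis of a scaled feature matrix
#'
#' @slot loadings ions x components orthonormal loading matrix.
#' @slot scores samples x components score matrix (X %*% loadings).
#' @slot explainedVariance fraction of total variance per component
#'   (non-increasing, sums to <= 1).
#' @slot nComponents integer.
#' @exportClass PcaModel
setClass("PcaModel",
  representation(loadings = "matrix", scores = "matrix",
                 explainedVariance = "numeric", nComponents = "integer"))

setValidity("PcaModel", function(object) {
  msg <- character(0)
  g <- crossprod(object@loadings)
  if (max(abs(g - diag(ncol(g)))) > 1e-8)
    msg <- c(msg, "loadings must be orthonormal")
  ev <- object@explainedVariance
  if (any(diff(ev) > 1e-12) || sum(ev) > 1 + 1e-8)
    msg <- c(msg, "explained fractions must be non-increasing and sum to <= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PcaModel", function(object) {
  cat("PcaModel:", object@nComponents, "components;",
      "explained variance:",
      paste(sprintf("%.1f%%", 100 * object@explainedVariance), collapse = ", "),
      "\n")
})

## fix loading signs so the largest-|magnitude| element is positive
.fixSigns <- function(loadings, scores = NULL) {
  for (a in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, a]))
    if (loadings[i, a] < 0) {
      loadings[, a] <- -loadings[, a]
      if (!is.null(scores)) scores[, a] <- -scores[, a]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Fit a PCA model
#'
#' Singular value decomposition of the Pareto-scaled matrix (already
#' column-centered by the scaling). Deterministic sign convention: in each
#' loading vector the largest-magnitude element is positive. Requesting more
#' components than the matrix rank truncates with a warning.
#'
#' @param x A [TagFeatureMatrix-class] in state \code{"pareto"}, or a
#'   column-centered samples x ions matrix.
#' @param nComponents Number of components (default
#'   \code{min(n - 1, p, 2)}).
#' @return A [PcaModel-class].
#' @export
fitPca <- function(x, nComponents = NULL) {
  m <- if (methods::is(x, "TagFeatureMatrix")) {
    if (featureState(x) != "pareto")
      stop("fitPca expects a Pareto-scaled matrix")
    intensityMatrix(x)
  } else as.matrix(x)
  n <- nrow(m); p <- ncol(m)
  if (is.null(nComponents)) nComponents <- min(n - 1L, p, 2L)
  sv <- svd(m)
  tol <- max(dim(m)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (nComponents > rank) {
    warning("requested ", nComponents, " components but rank is ", rank,
            "; truncating")
    nComponents <- rank
  }
  idx <- seq_len(nComponents)
  loadings <- sv$v[, idx, drop = FALSE]
  scores <- m %*% loadings
  fx <- .fixSigns(loadings, scores)
  totVar <- sum(sv$d^2)
  dimnames(fx$loadings) <- list(colnames(m), paste0("PC", idx))
  dimnames(fx$scores) <- list(rownames(m), paste0("PC", idx))
  methods::new("PcaModel",
    loadings = fx$loadings, scores = fx$scores,
    explainedVariance = sv$d[idx]^2 / totVar,
    nComponents = as.integer(nComponents))
}

#' @describeIn PcaModel-class sample scores
#' @param object A \code{PcaModel} (or \code{PlsdaModel}).
#' @export
setGeneric("modelScores", function(object) standardGeneric("modelScores"))

#' @export
setMethod("modelScores", "PcaModel", function(object) object@scores)

#' @describeIn PcaModel-class loadings
#' @export
setGeneric("modelLoadings", function(object) standardGeneric("modelLoadings"))

#' @export
setMethod("modelLoadings", "PcaModel", function(object) object@loadings)

#' @describeIn PcaModel-class explained-variance fractions
#' @export
setGeneric("explainedVariance", function(object) standardGeneric("explainedVariance"))

#' @export
setMethod("explainedVariance", "PcaModel", function(object) object@explainedVariance)
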