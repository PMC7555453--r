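#' TagFeatureMatrix: samples-by-ions intensity matrix with pretreatment state
#'
#' An S4 container extending
#' \linkS4class{SummarizedExperiment}
#' (ions as rows, samples as columns, assay \code{"intensity"}) that tracks
#' the pretreatment state of the data: \code{"raw"} (annotated intensities,
#' cps), \code{"normalized"} (constant row sum: each sample's intensities
#' divided by their per-sample total) or \code{"pareto"} (ion-wise centered
#' and divided by the square root of the ion standard deviation). The
#' pipeline order raw -> normalized -> pareto is enforced; Pareto centers and
#' scale divisors are stored so unknown samples can be projected with the
#' training parameters.
#'
#' @slot state character: \code{"raw"}, \code{"normalized"} or
#'   \code{"pareto"}.
#' @slot centers,scaleDivisors numeric per-ion Pareto parameters (empty
#'   until scaling).
#' @exportClass TagFeatureMatrix
setClass("TagFeatureMatrix",
  contains = "SummarizedExperiment",
  representation(state = "character",
                 centers = "numeric",
                 scaleDivisors = "numeric"),
  prototype(state = "raw", centers = numeric(0), scaleDivisors = numeric(0))
)

setValidity("TagFeatureMatrix", function(object) {
  msg <- character(0)
  if (!object@state %in% c("raw", "normalized", "pareto"))
    msg <- c(msg, "state must be raw, normalized or pareto")
  a <- SummarizedExperiment::assay(object)
  if (object@state == "normalized") {
    s <- colSums(a)
    if (any(abs(s - 1) > 1e-9))
      msg <- c(msg, "normalized state requires every sample to sum to 1")
  }
  if (object@state == "pareto") {
    if (any(abs(rowMeans(a)) > 1e-8))
      msg <- c(msg, "pareto state requires every ion mean to be 0")
    if (length(object@centers) != nrow(a))
      msg <- c(msg, "pareto state requires stored scaling parameters")
  }
  if (length(msg)) msg else TRUE
})

#' Build a feature matrix from annotated ion tables
#'
#' Assembles the samples x ions raw-intensity matrix from per-sample
#' annotation tables ([annotatePeaks()] output), restricted to an ion
#' subset (default: every ion of the first table, i.e. the full library the
#' tables were annotated against). Ions a sample did not match contribute 0.
#'
#' @param tables Named list of annotated ion tables over a common library.
#' @param ionSubset Character vector of ion labels to keep (default all);
#'   unknown labels are an error.
#' @param classLabels Named character vector (sample id -> class) or
#'   unnamed vector in table order; optional.
#' @param roles Optional named character vector of acquisition roles.
#' @return A [TagFeatureMatrix-class] in state \code{"raw"}.
#' @examples
#' lib <- markerLibrary()
#' pk <- generatePure("pork", 2, seed = 1)
#' fm <- buildFeatureMatrix(annotateSamples(pk, lib),
#'                          classLabels = c(pork_1 = "pork", pork_2 = "pork"))
#' dim(fm)   # 15 ions x 2 samples
#' @export
buildFeatureMatrix <- function(tables, ionSubset = NULL, classLabels = NULL,
                               roles = NULL) {
  if (!length(tables)) stop("no annotation tables supplied")
  ids <- names(tables)
  if (is.null(ids))
    ids <- vapply(tables, function(t) attr(t, "sample_id"), character(1))
  ions <- tables[[1]]$label
  if (is.null(ionSubset)) ionSubset <- ions
  bad <- setdiff(ionSubset, ions)
  if (length(bad))
    stop("unknown ion label(s): ", paste(bad, collapse = ", "))
  mat <- vapply(tables, function(t) {
    v <- t$intensity[match(ionSubset, t$label)]
    v[is.na(v)] <- 0
    v
  }, numeric(length(ionSubset)))
  mat <- matrix(mat, nrow = length(ionSubset), ncol = length(tables),
                dimnames = list(ionSubset, ids))
  t1 <- tables[[1]]
  rowDat <- S4Vectors::DataFrame(
    label = ionSubset,
    annotated_mz = t1$annotated_mz[match(ionSubset, t1$label)],
    theoretical_mz = t1$theoretical_mz[match(ionSubset, t1$label)],
    row.names = ionSubset)
  cls <- rep(NA_character_, length(ids))
  if (!is.null(classLabels)) {
    cls <- if (!is.null(names(classLabels))) unname(classLabels[ids])
           else as.character(classLabels)
  }
  rl <- rep("sample", length(ids))
  if (!is.null(roles) && !is.null(names(roles))) {
    hit <- !is.na(roles[ids])
    rl[hit] <- unname(roles[ids][hit])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = mat),
    rowData = rowDat,
    colData = S4Vectors::DataFrame(sample_id = ids, class_label = cls,
                                   role = rl, row.names = ids))
  methods::new("TagFeatureMatrix", se, state = "raw")
}

#' @describeIn TagFeatureMatrix-class pretreatment state of the matrix
#' @param object A \code{TagFeatureMatrix}.
#' @export
setGeneric("featureState", function(object) standardGeneric("featureState"))

#' @export
setMethod("featureState", "TagFeatureMatrix", function(object) object@state)

#' @describeIn TagFeatureMatrix-class stored Pareto parameters
#'   (list with \code{centers} and \code{scaleDivisors}) or \code{NULL}
#' @export
setGeneric("scalingParams", function(object) standardGeneric("scalingParams"))

#' @export
setMethod("scalingParams", "TagFeatureMatrix", function(object) {
  if (!length(object@centers)) return(NULL)
  list(centers = object@centers, scaleDivisors = object@scaleDivisors)
})

#' @describeIn TagFeatureMatrix-class the intensity matrix in statistical
#'   orientation (samples x ions)
#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))

#' @export
setMethod("intensityMatrix", "TagFeatureMatrix", function(object)
  t(SummarizedExperiment::assay(object, "intensity")))

#' @describeIn TagFeatureMatrix-class per-sample class labels
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @export
setMethod("classLabels", "TagFeatureMatrix", function(object)
  stats::setNames(SummarizedExperiment::colData(object)$class_label,
                  colnames(object)))

setMethod("show", "TagFeatureMatrix", function(object) {
  cat("TagFeatureMatrix: ", nrow(object), " ions x ", ncol(object),
      " samples, state '", object@state, "'\n", sep = "")
  cl <- classLabels(object)
  if (!all(is.na(cl))) {
    tab <- table(cl, useNA = "no")
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

## ---- internal matrix-level pretreatment (samples x ions) ----

.rowSumNorm <- function(x) {
  s <- rowSums(x)
  if (any(s <= 0)) {
    bad <- rownames(x)[s <= 0]
    stop("sample(s) with non-positive total intensity: ",
         paste(bad, collapse = ", "))
  }
  x / s
}

.paretoFit <- function(x) {
  centers <- colMeans(x)
  sds <- apply(x, 2, stats::sd)           # sample sd, n-1
  list(centers = centers, scaleDivisors = sqrt(sds))
}

.paretoApply <- function(x, fit) {
  out <- sweep(x, 2, fit$centers)
  div <- fit$scaleDivisors
  pos <- div > 0
  out[, pos] <- sweep(out[, pos, drop = FALSE], 2, div[pos], "/")
  out[, !pos] <- 0                        # zero-variance ions map to zero
  out
}

#' Constant row-sum normalization
#'
#' Divides each sample's ion intensities by their per-sample total, removing
#' the global intensity scale that DART acquisition imposes (no internal
#' standard). Normalizing an already-normalized matrix is the identity;
#' normalizing a Pareto-scaled matrix is rejected (the pipeline order is
#' raw -> normalized -> pareto).
#'
#' @param x A [TagFeatureMatrix-class] in state \code{"raw"} (or
#'   \code{"normalized"}, a no-op).
#' @return The matrix in state \code{"normalized"}.
#' @export
rowSumNormalize <- function(x) {
  stopifnot(methods::is(x, "TagFeatureMatrix"))
  if (x@state == "pareto")
    stop("cannot row-sum normalize a Pareto-scaled matrix")
  if (x@state == "normalized") return(x)
  m <- .rowSumNorm(intensityMatrix(x))
  SummarizedExperiment::assay(x, "intensity") <- t(m)
  x@state <- "normalized"
  methods::validObject(x)
  x
}

#' Pareto scaling
#'
#' Centers each ion by its mean and divides by the square root of its
#' (sample, n-1) standard deviation — intermediate between no scaling and
#' unit-variance scaling, retaining part of the natural intensity hierarchy.
#' Constant ions map to all-zeros. The centers and scale divisors are stored
#' in the returned object so unknown samples can be projected with
#' [applyPretreatment()].
#'
#' @param x A [TagFeatureMatrix-class] in state \code{"normalized"}, with at
#'   least 2 samples.
#' @return The matrix in state \code{"pareto"}, with scaling parameters
#'   retrievable via [scalingParams()].
#' @export
paretoScale <- function(x) {
  stopifnot(methods::is(x, "TagFeatureMatrix"))
  if (x@state != "normalized")
    stop("paretoScale requires a normalized matrix (state 'normalized')")
  if (ncol(x) < 2) stop("Pareto scaling requires at least 2 samples")
  m <- intensityMatrix(x)
  fit <- .paretoFit(m)
  SummarizedExperiment::assay(x, "intensity") <- t(.paretoApply(m, fit))
  x@state <- "pareto"
  x@centers <- fit$centers
  x@scaleDivisors <- fit$scaleDivisors
  methods::validObject(x)
  x
}

#' Project new samples with a reference pretreatment
#'
#' Row-sum normalizes raw samples and applies the Pareto centers/divisors
#' stored in a reference (training) matrix or model, without re-deriving
#' them — the projection used for held-out folds and unknown-product
#' screening.
#'
#' @param x A [TagFeatureMatrix-class] in state \code{"raw"} or
#'   \code{"normalized"} whose ions match the reference.
#' @param reference A Pareto-state [TagFeatureMatrix-class] or a fitted
#'   [PlsdaModel-class].
#' @return Samples x ions numeric matrix in the reference's scaled space.
#' @export
applyPretreatment <- function(x, reference) {
  stopifnot(methods::is(x, "TagFeatureMatrix"))
  fit <- if (methods::is(reference, "TagFeatureMatrix")) scalingParams(reference)
         else if (methods::is(reference, "PlsdaModel")) reference@scaling
         else stop("reference must be a Pareto-scaled TagFeatureMatrix or a PlsdaModel")
  if (is.null(fit)) stop("reference carries no Pareto scaling parameters")
  if (x@state == "pareto") stop("samples are already scaled")
  m <- intensityMatrix(x)
  if (!identical(colnames(m), names(fit$centers)))
    stop("ion set does not match the reference model")
  if (x@state == "raw") m <- .rowSumNorm(m)
  .paretoApply(m, fit)
}
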