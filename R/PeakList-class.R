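#' PeakList: one sample's centroided spectrum
#'
#' An S4 container for a single centroided DART-HRMS spectrum: m/z values
#' (Th, strictly positive, sorted ascending), intensities (cps,
#' non-negative), the sample identifier, the sample's role in the
#' acquisition sequence (\code{sample}, \code{QC} or \code{blank}) and its
#' run index (position in the acquisition order, \code{NA} before
#' sequencing).
#'
#' @slot sampleId character scalar.
#' @slot mz numeric, sorted ascending, > 0.
#' @slot intensity numeric, >= 0, same length as \code{mz}.
#' @slot role character scalar, one of \code{"sample"}, \code{"QC"},
#'   \code{"blank"}.
#' @slot runIndex integer scalar (may be \code{NA}).
#' @exportClass PeakList
setClass("PeakList",
  representation(
    sampleId = "character",
    mz = "numeric",
    intensity = "numeric",
    role = "character",
    runIndex = "integer"
  ),
  prototype(role = "sample", runIndex = NA_integer_)
)

setValidity("PeakList", function(object) {
  msg <- character(0)
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a non-empty string")
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have the same length")
  if (length(object@mz) && any(object@mz <= 0))
    msg <- c(msg, "all m/z must be strictly positive")
  if (is.unsorted(object@mz, strictly = FALSE))
    msg <- c(msg, "m/z must be sorted ascending")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (!object@role %in% c("sample", "QC", "blank"))
    msg <- c(msg, "role must be one of 'sample', 'QC', 'blank'")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakList
#'
#' @param sampleId Sample identifier.
#' @param mz Numeric m/z values in Th (sorted internally).
#' @param intensity Numeric intensities in cps.
#' @param role One of \code{"sample"}, \code{"QC"}, \code{"blank"}.
#' @param runIndex Position in the acquisition sequence, or \code{NA}.
#' @return A [PeakList-class] object.
#' @examples
#' PeakList("s1", c(874.7837, 848.7682), c(5e4, 1e5))
#' @export
PeakList <- function(sampleId, mz, intensity, role = "sample",
                     runIndex = NA_integer_) {
  o <- order(mz)
  methods::new("PeakList",
    sampleId = as.character(sampleId),
    mz = as.numeric(mz)[o],
    intensity = as.numeric(intensity)[o],
    role = role,
    runIndex = as.integer(runIndex))
}

#' @describeIn PeakList-class sample identifier
#' @param object,x A \code{PeakList}.
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @export
setMethod("sampleId", "PeakList", function(object) object@sampleId)

#' @describeIn PeakList-class acquisition role
#' @export
setGeneric("peakRole", function(object) standardGeneric("peakRole"))

#' @export
setMethod("peakRole", "PeakList", function(object) object@role)

#' @describeIn PeakList-class peaks as a two-column data.frame (mz, intensity)
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))

#' @export
setMethod("peakTable", "PeakList", function(object)
  data.frame(mz = object@mz, intensity = object@intensity))

setMethod("show", "PeakList", function(object) {
  cat("PeakList '", object@sampleId, "' (", object@role, "): ",
      length(object@mz), " centroids",
      if (length(object@mz))
        sprintf(", m/z %.4f-%.4f, max %.0f cps",
                min(object@mz), max(object@mz), max(object@intensity)),
      "\n", sep = "")
})

#' Number of centroids in a PeakList
#' @param x A \code{PeakList}.
#' @export
setMethod("length", "PeakList", function(x) length(x@mz))

#' Read a peak list from a two-column CSV
#'
#' @param file CSV with columns \code{mz}, \code{intensity}.
#' @param sampleId Sample identifier (defaults to the file base name).
#' @param role,runIndex Passed to [PeakList()].
#' @return A [PeakList-class].
#' @export
readPeakList <- function(file, sampleId = sub("\\.csv$", "", basename(file)),
                         role = "sample", runIndex = NA_integer_) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(d)))
    stop("peak-list CSV must have columns 'mz' and 'intensity': ", file)
  PeakList(sampleId, d$mz, d$intensity, role = role, runIndex = runIndex)
}

#' Write a peak list to CSV
#'
#' @param x A [PeakList-class].
#' @param file Output path.
#' @return \code{file}, invisibly.
#' @export
writePeakList <- function(x, file) {
  utils::write.csv(peakTable(x), file, row.names = FALSE)
  invisible(file)
}

#' Read a sample manifest and its peak lists
#'
#' The manifest CSV has columns \code{sample_id}, \code{path}, \code{role}
#' and optionally \code{class_label}; paths are resolved relative to the
#' manifest's directory.
#'
#' @param file Manifest CSV path.
#' @return Named list of [PeakList-class] objects with a
#'   \code{"class_label"} attribute (named character vector) when labels are
#'   present.
#' @export
readManifest <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "path") %in% names(d)))
    stop("manifest must have columns 'sample_id' and 'path'")
  base <- dirname(file)
  roles <- if ("role" %in% names(d)) d$role else rep("sample", nrow(d))
  out <- lapply(seq_len(nrow(d)), function(i) {
    p <- d$path[i]
    if (!file.exists(p)) p <- file.path(base, d$path[i])
    readPeakList(p, sampleId = d$sample_id[i], role = roles[i])
  })
  names(out) <- d$sample_id
  if ("class_label" %in% names(d))
    attr(out, "class_label") <- stats::setNames(d$class_label, d$sample_id)
  out
}
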