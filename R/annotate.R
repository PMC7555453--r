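#' Annotate a peak list against a TAG marker library
#'
#' Matches each library compound to the nearest centroid (in ppm) within the
#' mass tolerance whose intensity clears the detection threshold. Matching is
#' performed against the library's canonical annotated m/z (falling back to
#' the theoretical adduct m/z when no annotation is present), so an
#' instrument-calibration offset baked into the curated annotations does not
#' unmatch peaks acquired on the same calibration. Each peak is assigned to
#' at most one compound: assignments are made globally in order of increasing
#' absolute ppm error, with exact ties resolved in favour of the lower-m/z
#' library entry.
#'
#' @param peaks A [PeakList-class].
#' @param library Marker library data.frame from [markerLibrary()] (or any
#'   data.frame with \code{label}, \code{annotated_mz} and/or
#'   \code{theoretical_mz}).
#' @param tolPpm Matching tolerance in ppm (> 0; default 5).
#' @param minIntensity Intensity threshold in cps (default 1000); weaker
#'   centroids are invisible to the matcher.
#' @return An annotated ion table: \code{data.frame} with one row per library
#'   compound — \code{label}, \code{theoretical_mz}, \code{annotated_mz},
#'   \code{matched_mz} (\code{NA} if unmatched), \code{ppm_error}
#'   (vs the match reference; \code{NA} if unmatched) and \code{intensity}
#'   (0 if unmatched). The sample id is carried in attribute
#'   \code{"sample_id"}.
#' @examples
#' lib <- markerLibrary()
#' pk <- PeakList("stick", lib$annotated_mz, rep(1e4, nrow(lib)))
#' tab <- annotatePeaks(pk, lib)
#' sum(!is.na(tab$matched_mz))   # 15
#' @export
annotatePeaks <- function(peaks, library, tolPpm = 5, minIntensity = 1000) {
  stopifnot(methods::is(peaks, "PeakList"))
  if (!is.data.frame(library) || nrow(library) == 0L)
    stop("empty marker library")
  if (tolPpm <= 0) stop("tolPpm must be > 0")
  ref <- if ("annotated_mz" %in% names(library)) library$annotated_mz
         else library$theoretical_mz
  if (is.null(ref)) stop("library must provide annotated_mz or theoretical_mz")
  ref <- ifelse(is.na(ref), library$theoretical_mz, ref)
  n <- nrow(library)
  out <- data.frame(
    label = library$label,
    theoretical_mz = if ("theoretical_mz" %in% names(library))
      library$theoretical_mz else NA_real_,
    annotated_mz = ref,
    matched_mz = NA_real_,
    ppm_error = NA_real_,
    intensity = 0,
    stringsAsFactors = FALSE
  )
  mz <- peaks@mz
  keep <- peaks@intensity >= minIntensity
  mz <- mz[keep]
  inten <- peaks@intensity[keep]
  if (length(mz)) {
    ## all (compound, peak) candidates within tolerance
    cand <- do.call(rbind, lapply(seq_len(n), function(i) {
      pe <- ppmError(mz, ref[i])
      hit <- which(abs(pe) <= tolPpm)
      if (!length(hit)) return(NULL)
      data.frame(compound = i, peak = hit, ppm = pe[hit], absppm = abs(pe[hit]))
    }))
    if (!is.null(cand) && nrow(cand)) {
      ## greedy assignment by ascending |ppm|; exact tie -> lower-m/z entry
      cand <- cand[order(cand$absppm, ref[cand$compound], cand$peak), , drop = FALSE]
      usedPeak <- logical(length(mz))
      usedComp <- logical(n)
      for (r in seq_len(nrow(cand))) {
        i <- cand$compound[r]; j <- cand$peak[r]
        if (usedPeak[j] || usedComp[i]) next
        usedPeak[j] <- TRUE; usedComp[i] <- TRUE
        out$matched_mz[i] <- mz[j]
        out$ppm_error[i] <- cand$ppm[r]
        out$intensity[i] <- inten[j]
      }
    }
  }
  attr(out, "sample_id") <- peaks@sampleId
  out
}

#' Annotate a collection of peak lists
#'
#' @param peakLists Named list of [PeakList-class] objects (e.g. from
#'   [readManifest()] or the synthetic generator).
#' @inheritParams annotatePeaks
#' @return Named list of annotated ion tables (see [annotatePeaks()]).
#' @export
annotateSamples <- function(peakLists, library, tolPpm = 5, minIntensity = 1000) {
  out <- lapply(peakLists, annotatePeaks, library = library,
                tolPpm = tolPpm, minIntensity = minIntensity)
  if (is.null(names(out)))
    names(out) <- vapply(peakLists, sampleId, character(1))
  out
}
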