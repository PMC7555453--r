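#' TAG shorthand to neutral elemental formula
#'
#' Converts a triacylglycerol shorthand \code{Cn:d} (n total acyl carbons,
#' d double bonds) into its neutral summary formula
#' \eqn{C_{n+3} H_{2n+2-2d} O_6}.
#'
#' @param carbons Total acyl carbon count (even in natural fats).
#' @param doubleBonds Total number of C=C double bonds.
#' @return Named integer vector of element counts.
#' @examples
#' tagFormula(50, 2)   # C53 H98 O6, the neutral TAG behind "C 50:2"
#' @export
tagFormula <- function(carbons, doubleBonds) {
  if (carbons < 10 || doubleBonds < 0 || 2 * carbons + 2 - 2 * doubleBonds <= 0)
    stop("invalid TAG composition")
  c(C = as.integer(carbons + 3L),
    H = as.integer(2L * carbons + 2L - 2L * doubleBonds),
    O = 6L)
}

#' Load the TAG marker library
#'
#' Reads a marker-library CSV (columns \code{label}, \code{formula},
#' \code{annotated_mz}, \code{marker_species}, optionally \code{delta_ppm})
#' and returns a validated library with theoretical adduct m/z computed from
#' each composite formula. The packaged library of 15 characteristic
#' \eqn{[M+NH_4]^+} TAG ions for chicken, pork and beef is used when
#' \code{file} is missing.
#'
#' The curated annotated m/z is the canonical matching reference for
#' annotation (it reflects the calibration of the instrument the library was
#' curated on); the theoretical m/z is carried alongside for mass-error
#' diagnostics. Each composite ion formula must contain exactly 1 N and 6 O
#' (an ammoniated TAG) and each annotated m/z must lie in (800, 1000) Th.
#'
#' @param file Path to a library CSV; defaults to the packaged library.
#' @return A \code{data.frame} with columns \code{label}, \code{formula},
#'   \code{annotated_mz}, \code{theoretical_mz}, \code{delta_ppm} (as
#'   curated, carried as metadata), and \code{marker_species} (a list column
#'   of species character vectors).
#' @examples
#' lib <- markerLibrary()
#' nrow(lib)   # 15
#' @export
markerLibrary <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "table3_markers.csv", package = "tagprint",
                        mustWork = TRUE)
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("label", "formula", "annotated_mz", "marker_species")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("marker library is missing column(s): ", paste(missing, collapse = ", "))
  lib <- data.frame(
    label = as.character(raw$label),
    formula = as.character(raw$formula),
    annotated_mz = as.numeric(raw$annotated_mz),
    delta_ppm = if ("delta_ppm" %in% names(raw)) as.numeric(raw$delta_ppm) else NA_real_,
    stringsAsFactors = FALSE
  )
  lib$theoretical_mz <- vapply(lib$formula, function(f)
    monoisotopicMass(parseFormula(f), charge = 1L), numeric(1))
  lib$marker_species <- lapply(strsplit(as.character(raw$marker_species), ";"),
                               trimws)
  known <- c("chicken", "pork", "beef")
  for (i in seq_len(nrow(lib))) {
    fm <- parseFormula(lib$formula[i])
    if (is.na(fm["N"]) || fm[["N"]] != 1L || is.na(fm["O"]) || fm[["O"]] != 6L)
      stop("marker '", lib$label[i],
           "': an ammoniated TAG ion must contain exactly 1 N and 6 O")
    if (lib$annotated_mz[i] <= 800 || lib$annotated_mz[i] >= 1000)
      stop("marker '", lib$label[i], "': annotated m/z outside (800, 1000) Th")
    bad <- setdiff(lib$marker_species[[i]], known)
    if (length(bad))
      stop("marker '", lib$label[i], "': unknown species ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(lib$label))
    stop("duplicated marker labels in library")
  lib[order(lib$annotated_mz), , drop = FALSE]
}

## labels of markers associated with `species` (and, optionally, not with
## `excluding`) — used for species-specific detection logic
.speciesMarkers <- function(library, species, excluding = NULL) {
  keep <- vapply(library$marker_species, function(s) {
    species %in% s && (is.null(excluding) || !excluding %in% s)
  }, logical(1))
  library$label[keep]
}
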